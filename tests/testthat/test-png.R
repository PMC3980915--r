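test_that("fragment extraction is onset-relative and keeps empty windows", {
  ev <- data.frame(time = c(5L, 107L, 165L, 205L),
                   id = c(3L, 1005L, 1700L, 1005L),
                   kind = c("input", "exc", "inh", "exc"))
  raster <- new("SpikeRaster", events = ev)
  sched <- new("PresentationSchedule", entries = data.frame(
    label = c("A", "B", "A"), onset = c(100L, 160L, 200L),
    end = c(160L, 200L, 260L)))
  fs <- extractFragments(raster, sched, "A", NetworkSpec())
  expect_length(fragments(fs), 2)
  expect_equal(fragments(fs)[[1]], cbind(neuron = 1005L, time = 7L),
               ignore_attr = TRUE)
  fsB <- extractFragments(raster, sched, "B", NetworkSpec())
  expect_equal(nrow(fragments(fsB)[[1]]), 0)  # inhibitory spike excluded
  expect_error(extractFragments(raster, sched, "C", NetworkSpec()), "absent")
})

test_that("best shift maximizes the count-matrix overlap with fair ties", {
  f1 <- cbind(c(0L, 1L, 3L), c(0L, 2L, 5L))
  fs <- fragSet(list(f1), L = 8)
  C <- buildCountMatrix(fs)$C
  expect_equal(bestShift(C, f1), list(shift = 0L, score = 3L))
  shifted <- cbind(f1[, 1], f1[, 2] + 2L)
  expect_equal(bestShift(C, shifted)$shift, 2L)
  disjoint <- cbind(c(4L, 5L), c(1L, 2L))
  expect_equal(bestShift(C, disjoint), list(shift = 0L, score = 0L))
})

test_that("detection reproduces exact repetition and rejects high supports", {
  f <- cbind(c(0L, 2L, 4L), c(3L, 4L, 9L))
  fs <- fragSet(rep(list(f), 5), L = 12)
  g <- detectPNG(fs, 5)
  expect_s4_class(g, "PolychronousGroup")
  expect_equal(spikePairs(g),
               cbind(neuron = c(0L, 2L, 4L), time = c(0L, 1L, 6L)),
               ignore_attr = TRUE)
  # support above the maximal achieved count gives the empty group
  fsMix <- fragSet(c(rep(list(f), 4), list(cbind(5L, 0L))), L = 12)
  expect_null(detectPNG(fsMix, 5, C = buildCountMatrix(fsMix)))
  expect_error(detectPNG(fs, 0), "support")
})

test_that("a three-fragment toy instance matches the brute-force oracle", {
  # 4 neurons x 4 time steps, three noisy repetitions of one pattern
  frags <- list(
    cbind(c(0L, 1L, 2L), c(0L, 1L, 3L)),
    cbind(c(0L, 1L, 2L, 3L), c(1L, 2L, 0L, 3L)),  # pattern shifted by +1
    cbind(c(0L, 1L, 3L), c(2L, 3L, 1L)))          # shifted by +2
  fs <- fragSet(frags, L = 4, nExc = 4L)
  C <- buildCountMatrix(fs)
  for (n in 1:3) {
    g <- detectPNG(fs, n, C = C)
    o <- oracleDetect(frags, n, 4L, 4L)
    if (is.null(o)) expect_null(g)
    else expect_equal(spikePairs(g), o, ignore_attr = TRUE)
  }
  expect_true(max(C$C) <= 3)
})

test_that("detection equals the brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    nn <- sample(2:6, 1); L <- sample(3:8, 1); k <- sample(2:4, 1)
    frags <- replicate(k, randomFragment(nn, L), simplify = FALSE)
    if (any(vapply(frags, nrow, 1L) == 0)) next
    fs <- fragSet(frags, L = L, nExc = nn)
    C <- buildCountMatrix(fs)
    for (n in seq_len(k)) {
      g <- detectPNG(fs, n, C = C)
      o <- oracleDetect(frags, n, nn, L)
      if (is.null(o)) expect_null(g)
      else expect_equal(spikePairs(g), o, ignore_attr = TRUE)
    }
    expect_lte(max(C$C), k)
  }
})

test_that("threshold sets are nested across supports", {
  set.seed(12)
  frags <- replicate(4, randomFragment(6, 8), simplify = FALSE)
  fs <- fragSet(frags, L = 8)
  C <- buildCountMatrix(fs)$C
  for (n in 2:4) {
    hi <- which(C >= n); lo <- which(C >= n - 1)
    expect_true(all(hi %in% lo))
  }
})

test_that("activity equals exhaustive shift enumeration", {
  g <- cbind(c(0L, 1L, 2L), c(0L, 2L, 5L))
  expect_equal(pngActivity(g, g), 3L)
  expect_equal(pngActivity(g, cbind(c(4L, 5L), c(0L, 1L))), 0L)
  set.seed(8)
  for (rep in 1:50) {
    ga <- randomFragment(6, 8); fr <- randomFragment(6, 8)
    expect_equal(pngActivity(ga, fr), oracleActivity(ga, fr))
    expect_lte(pngActivity(ga, fr), min(nrow(ga), nrow(fr)))
  }
})

test_that("reaction strength is the worst-case presentation activity", {
  f <- cbind(c(0L, 1L), c(0L, 3L))
  fs <- fragSet(rep(list(f), 4), L = 6)
  g <- detectPNG(fs, 4)
  expect_equal(pngReactionStrength(g, fs), 2L)
  fsEmpty <- fragSet(c(rep(list(f), 3), list(f[0, ])), L = 6)
  expect_equal(pngReactionStrength(g, fsEmpty), 0L)
})

test_that("selectivity counts qualifying fragments over all stimuli", {
  f <- cbind(c(0L, 1L, 2L), c(0L, 1L, 4L))
  fsA <- fragSet(rep(list(f), 5), L = 6, label = "A")
  g <- detectPNG(fsA, 5)

  expect_equal(pngSelectivity(g, list(A = fsA), "A"), 1)

  # one foreign fragment matches the pattern fully: S = N_A / (N_A + 1)
  other <- cbind(c(3L, 4L), c(0L, 1L))
  fsB <- fragSet(list(f, other, other, other), L = 6, label = "B")
  expect_equal(pngSelectivity(g, list(A = fsA, B = fsB), "A"), 5 / 6)

  # degenerate reaction strength is flagged, not silently 1
  fsZ <- fragSet(c(rep(list(f), 4), list(f[0, ])), L = 6, label = "A")
  gz <- detectPNG(fsZ, 4)
  s <- pngSelectivity(gz, list(A = fsZ), "A")
  expect_true(is.na(s))
  expect_true(attr(s, "degenerate"))
})

test_that("intersection ratio measures departure from independence", {
  g1 <- cbind(0:4, rep(0L, 5)); g2 <- cbind(5:9, rep(0L, 5))
  expect_equal(pngIntersectionRatio(g1, g1, 700), 700 / 5)
  expect_equal(pngIntersectionRatio(g1, g2, 700), 0)
  expect_error(pngIntersectionRatio(g1[0, , drop = FALSE], g2, 700),
               "non-empty")

  # independent uniform subsets have expected ratio 1 (Monte-Carlo oracle)
  set.seed(21)
  ratios <- replicate(1e4, {
    k1 <- sample(20:60, 1); k2 <- sample(20:60, 1)
    s1 <- sample.int(700, k1); s2 <- sample.int(700, k2)
    length(intersect(s1, s2)) * 700 / (k1 * k2)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("the support scan returns the highest fully selective group", {
  f <- cbind(c(0L, 1L, 2L), c(0L, 2L, 3L))
  fsA <- fragSet(rep(list(f), 6), L = 6, label = "A")
  other <- cbind(c(4L, 5L), c(0L, 2L))
  fsB <- fragSet(rep(list(other), 6), L = 6, label = "B")
  res <- findSelectivePNG(fsA, list(A = fsA, B = fsB))
  expect_true(res$success)
  expect_equal(pngSupport(res$group), 6L)
  expect_equal(selectivity(res$group), 1)
  expect_equal(reactionStrength(res$group), 3)
  expect_error(findSelectivePNG(fragSet(list(f), L = 6), list()), "2 fragments")
})
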