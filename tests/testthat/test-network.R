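test_that("sphere sampling is uniform on the surface", {
  expect_equal(nrow(sampleSpherePoints(0, 4)), 0)
  expect_error(sampleSpherePoints(5, 1), "dim")

  set.seed(11)
  p <- sampleSpherePoints(1e4, 4)
  expect_equal(sqrt(rowSums(p^2)), rep(1, 1e4), tolerance = 1e-12)
  # first and second moments agree with an independent rejection sampler
  q <- oracleSpherePoints(1e4, 4)
  expect_true(all(abs(colMeans(p)) < 0.04))
  expect_true(all(abs(colMeans(p) - colMeans(q)) < 0.06))
  expect_true(all(abs(colMeans(p^2) - colMeans(q^2)) < 0.02))
})

test_that("spherical distance matches numeric geodesic integration", {
  set.seed(7)
  p <- sampleSpherePoints(5, 4)
  expect_equal(sphericalDistance(p[1, ], p[1, ]), 0)
  expect_equal(sphericalDistance(p[1, ], -p[1, ]), pi)
  expect_error(sphericalDistance(p[1, ] * 2, p[2, ]), "unit")
  for (i in 2:5)
    expect_equal(sphericalDistance(p[1, ], p[i, ]),
                 oracleArcLength(p[1, ], p[i, ]), tolerance = 1e-8)
})

test_that("distance-to-delay map is affine, bounded and monotone", {
  expect_identical(delayFromDistance(0, c(1L, 10L)), 1L)
  expect_identical(delayFromDistance(pi, c(1L, 10L)), 10L)
  grid <- seq(0, pi, length.out = 1000)
  d <- delayFromDistance(grid, c(1L, 10L))
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 1L & d <= 10L))
  expect_equal(unname(d), as.integer(round(1 + grid / pi * 9)))
})

test_that("built networks satisfy every structural audit", {
  spec <- NetworkSpec()
  net <- buildNetwork(spec, seed = 42)
  e <- edges(net)
  ids <- polychron:::unitIds(spec)

  # per-target synapse counts match the specification exactly
  key <- interaction(e$type, e$group)
  for (tg in c(ids$exc[c(1, 350, 700)], ids$inh[c(1, 300)])) {
    cnt <- table(key[e$target == tg])
    isExc <- tg %in% ids$exc
    expect_equal(unname(cnt[["exc.afferent"]]), 300)
    expect_equal(unname(cnt[["inh.afferent"]]), if (isExc) 10 else 30)
    expect_equal(unname(cnt[["exc.recurrent"]]), 100)
    expect_equal(unname(cnt[["inh.recurrent"]]), if (isExc) 10 else 3)
  }
  expect_equal(nrow(e), 1000 * 400 + 700 * 20 + 300 * 33)

  # no self-edges, sources segregated by type
  expect_false(any(e$source == e$target))
  excSources <- c(ids$inputExc, ids$exc)
  expect_true(all(e$source[e$type == "exc"] %in% excSources))
  expect_false(any(e$source[e$type == "inh"] %in% excSources))

  # open-interval weights, delay ranges
  expect_true(all(e$weight > 0))
  expect_true(all(e$weight[e$type == "exc"] < 0.19))
  expect_true(all(e$weight[e$type == "inh"] < 10))
  expect_true(all(e$delay[e$type == "exc"] %in% 1:10))
  expect_true(all(e$delay[e$type == "inh"] %in% 1:3))

  # expected total afferent excitatory weight per neuron = 300 * 0.19/2
  wsum <- tapply(e$weight[e$type == "exc" & e$group == "afferent"],
                 e$target[e$type == "exc" & e$group == "afferent"], sum)
  expect_equal(mean(wsum), 28.5, tolerance = 0.02)

  # recurrent excitatory delays are recomputable from stored positions
  rec <- e[e$type == "exc" & e$group == "recurrent", ]
  rec <- rec[sample.int(nrow(rec), 2000), ]
  pos <- positions(net)
  d <- acos(pmin(1, pmax(-1, rowSums(
    pos[rec$source - ids$excOffset + 1, ] *
    pos[rec$target - ids$excOffset + 1, ]))))
  expect_identical(rec$delay, delayFromDistance(d, spec@delayExcRange))
})

test_that("weight and delay distributions are homogeneous across neurons", {
  net <- buildNetwork(NetworkSpec(), seed = 5)
  e <- edges(net)
  aff <- e[e$type == "exc" & e$group == "afferent" & e$target < 1700, ]
  half <- aff$target < 1350
  expect_gt(suppressWarnings(
    stats::ks.test(aff$weight[half], aff$weight[!half])$p.value), 0.01)
  rec <- e[e$type == "exc" & e$group == "recurrent" & e$target < 1700, ]
  expect_gt(suppressWarnings(
    stats::ks.test(rec$delay[rec$target < 1350],
                   rec$delay[rec$target >= 1350])$p.value), 0.01)
})

test_that("oversized synapse requests fail with a configuration error", {
  spec <- smallSpec()
  spec@synCounts[["affExcOnExc"]] <- 40L  # pool has only 30 nodes
  expect_error(buildNetwork(spec, seed = 1), "pool")
})

test_that("delay permutation shuffles recurrent excitatory delays only", {
  net <- buildNetwork(smallSpec(), seed = 9)
  per <- permuteExcitatoryDelays(net, seed = 3)
  e0 <- edges(net); e1 <- edges(per)
  idx <- e0$type == "exc" & e0$group == "recurrent"
  expect_identical(sort(e1$delay[idx]), sort(e0$delay[idx]))
  expect_identical(e1$delay[!idx], e0$delay[!idx])
  expect_identical(e1[c("source", "target", "weight", "type", "group")],
                   e0[c("source", "target", "weight", "type", "group")])
  expect_identical(positions(per), positions(net))
  # reproducible under the same seed, different under another
  expect_identical(edges(permuteExcitatoryDelays(net, seed = 3))$delay,
                   e1$delay)
})

test_that("specification invariants are enforced", {
  expect_error(NetworkSpec(wExcMax = 0.21), "five")
  expect_error(NetworkSpec(wExcMax = 0.15), "six")
  expect_error(NetworkSpec(nExc = 0), "positive")
  expect_error(NetworkSpec(delayInhRange = c(0L, 3L)), "delay")
})
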