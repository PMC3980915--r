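test_that("stimulus subsets are uniform samples of the right size", {
  spec <- NetworkSpec()
  sset <- makeStimulusSet(10, spec, seed = 1)
  expect_identical(unname(lengths(stimuli(sset))), rep(100L, 10))
  expect_true(all(unlist(stimuli(sset)) %in% 0:999))

  # forced full-pool case
  full <- makeStimulusSet(3, spec, nodesPerStimulus = 1000, seed = 1)
  for (s in stimuli(full)) expect_identical(s, 0:999)
  expect_error(makeStimulusSet(1, spec, nodesPerStimulus = 1001), "pool")

  # pairwise overlap matches the hypergeometric expectation k^2/N
  set.seed(2)
  ov <- replicate(300, {
    s <- makeStimulusSet(2, spec)
    length(intersect(stimuli(s)[[1]], stimuli(s)[[2]]))
  })
  expect_equal(mean(ov), 100 * 100 / 1000, tolerance = 0.05)
})

test_that("presentation order is a balanced interleaved shuffle", {
  sset <- makeStimulusSet(5, NetworkSpec(), seed = 1)
  ord <- presentationOrder(sset, 40, seed = 2)
  expect_length(ord, 200)
  expect_identical(unname(table(ord)[names(stimuli(sset))]),
                   table(rep(names(stimuli(sset)), 40))[names(stimuli(sset))] |>
                     unname())
  expect_false(identical(ord, sort(ord)))
})

test_that("input spike generation follows the Poisson stimulus model", {
  spec <- NetworkSpec()
  sset <- makeStimulusSet(2, spec, seed = 3)
  gen <- generateInputSpikes(sset, rep(c("S1", "S2"), 5), gapMs = 100,
                             seed = 4)
  e <- spikeEvents(gen$raster)
  s <- scheduleEntries(gen$schedule)

  expect_equal(nrow(s), 10)
  expect_true(all(diff(s$onset) > 0))
  expect_true(all(s$end[-10] <= s$onset[-1]))
  expect_true(all(e$time >= 0 & e$time < max(s$end)))
  expect_false(is.unsorted(e$time))

  # expected 300 Hz * 30 ms = 9 spikes per stimulated node per presentation
  idx <- findInterval(e$time, s$onset)
  nStimSpikes <- sum(vapply(seq_len(10), function(p) {
    sub <- stimuli(sset)[[s$label[p]]]
    sum(idx == p & e$id %in% sub &
          e$time < s$onset[p] + sset@stimDuration)
  }, numeric(1)))
  # subtract nothing: noise inside subsets during the stimulus is part of
  # the count but contributes only 3/1000 * 30 * 100 per presentation
  expected <- 10 * 100 * 9 + 10 * 100 * 30 * 3 / 1000
  expect_lt(abs(nStimSpikes - expected) / sqrt(expected), 4)

  # silence when nothing is presented and noise is off
  quiet <- makeStimulusSet(1, spec, stimRate = 0, noiseRate = 0, seed = 1)
  g2 <- generateInputSpikes(quiet, "S1", seed = 1)
  expect_equal(nrow(spikeEvents(g2$raster)), 0)

  expect_error(generateInputSpikes(sset, c("S1", "nope")), "unknown")
})

test_that("per-node stimulus spike counts are Poisson distributed", {
  spec <- NetworkSpec()
  sset <- makeStimulusSet(1, spec, seed = 5)
  gen <- generateInputSpikes(sset, rep("S1", 100), gapMs = 50, seed = 6)
  e <- spikeEvents(gen$raster)
  s <- scheduleEntries(gen$schedule)
  sub <- stimuli(sset)[[1]]
  idx <- findInterval(e$time, s$onset)
  inStim <- e$id %in% sub & (e$time - s$onset[idx]) < sset@stimDuration
  counts <- table(factor(paste(idx[inStim], e$id[inStim]),
                         levels = as.vector(outer(1:100, sub, paste))))
  # chi-square GOF against Poisson(9 + noise share), binning the tails
  lam <- 9 + sset@noiseRate * sset@stimDuration / 1000
  breaks <- c(-1, 4:14, Inf)
  obs <- table(cut(as.integer(counts), breaks))
  pr <- diff(stats::ppois(breaks, lam))
  pv <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr))$p.value)
  expect_gt(pv, 0.01)
})
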