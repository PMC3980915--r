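test_that("membrane potential decays by exp(-dt/tau) per step", {
  net <- probeNetwork(3, w = 0.18)
  # three coincident arrivals of 0.18 leave v = 0.54 < 1 at t = 2,
  # which then decays for three further steps
  out <- simulateRaster(net, inputRaster(c(1, 1, 1), 0:2), tEnd = 5,
                        returnState = TRUE)
  expect_equal(nrow(spikeEvents(out$raster)), 0)
  expect_equal(out$v[1], 0.54 * exp(-3 / 3), tolerance = 1e-12)
})

test_that("six coincident maximal spikes fire a neuron, five do not", {
  net6 <- probeNetwork(6)
  r6 <- simulateRaster(net6, inputRaster(rep(1, 6), 0:5), tEnd = 10)
  expect_equal(spikeEvents(r6)$time, 2)  # delay-1 arrivals at t = 2

  net5 <- probeNetwork(5)
  r5 <- simulateRaster(net5, inputRaster(rep(1, 5), 0:4), tEnd = 30)
  expect_equal(nrow(spikeEvents(r5)), 0)
})

test_that("absolute refractoriness holds under saturating input", {
  net <- probeNetwork(6)
  times <- rep(1:40, each = 6)
  ids <- rep(0:5, 40)
  r <- spikeEvents(simulateRaster(net, inputRaster(times, ids), tEnd = 45))
  expect_gt(nrow(r), 3)
  expect_true(all(diff(r$time) == 6))  # fires at exactly the refractory pace
  expect_equal(refractoryViolations(
    simulateRaster(net, inputRaster(times, ids), tEnd = 45), 6), 0)
})

test_that("a delayed synaptic event is delivered exactly once, on time", {
  # chain: 6 input nodes -> neuron A (delay 2); A -> B via 6 edges (delay 4)
  spec <- probeNetwork(6)@spec
  spec@nExc <- 2L
  nIn <- spec@nInputExc + spec@nInputInh
  edges <- rbind(
    data.frame(source = 0:5, target = nIn, weight = 0.19, delay = 2L,
               type = "exc", group = "afferent"),
    data.frame(source = nIn, target = nIn + 1L, weight = 0.19, delay = 4L,
               type = "exc", group = "recurrent")[rep(1, 6), ])
  net <- new("SpikingNetwork", spec = spec,
             positions = sampleSpherePoints(3, 4), edges = edges)
  r <- spikeEvents(simulateRaster(net, inputRaster(rep(1, 6), 0:5), tEnd = 20))
  expect_equal(r$time[r$id == nIn], 3)       # 1 + delay 2
  expect_equal(r$time[r$id == nIn + 1], 7)   # 3 + delay 4, exactly once
  expect_equal(nrow(r), 2)
})

test_that("inhibitory input suppresses an otherwise certain spike", {
  net <- probeNetwork(6)
  nIn <- net@spec@nInputExc + net@spec@nInputInh
  inh <- data.frame(source = nIn - 1L, target = nIn, weight = 2,
                    delay = 1L, type = "inh", group = "afferent")
  net@edges <- rbind(net@edges, inh)
  r <- simulateRaster(net, inputRaster(rep(1, 7), c(0:5, nIn - 1L)),
                      tEnd = 10, returnState = TRUE)
  expect_equal(nrow(spikeEvents(r$raster)), 0)
  expect_lt(r$v[1], 0)  # no lower clamp between spikes
})

test_that("the network is silent without input", {
  net <- buildNetwork(smallSpec(), seed = 1)
  r <- simulateRaster(net, inputRaster(integer(0), integer(0)), tEnd = 200)
  expect_equal(nrow(spikeEvents(r)), 0)
})

test_that("closed-loop runs are deterministic and well-formed", {
  spec <- NetworkSpec()
  net <- buildNetwork(spec, seed = 2)
  sset <- makeStimulusSet(3, spec, seed = 2)
  ord <- presentationOrder(sset, 8, seed = 2)
  run1 <- presentStimuli(net, sset, ord, seed = 7)
  run2 <- presentStimuli(net, sset, ord, seed = 7)
  expect_identical(spikeEvents(run1$raster), spikeEvents(run2$raster))
  expect_identical(scheduleEntries(run1$schedule),
                   scheduleEntries(run2$schedule))

  s <- scheduleEntries(run1$schedule)
  expect_identical(s$onset[-1], s$end[-nrow(s)])  # windows abut exactly
  expect_true(all(s$end - s$onset >= sset@stimDuration))
  expect_equal(refractoryViolations(run1$raster, spec@tRefract), 0)

  # inhibitory neurons fire mainly after the stimulus ends
  e <- spikeEvents(run1$raster)
  inh <- e[e$kind == "inh" & e$time >= s$onset[1], ]
  idx <- findInterval(inh$time, s$onset)
  rel <- inh$time - s$onset[idx]
  during <- sum(rel < 30) / (30 * nrow(s))
  after <- sum(rel >= 30 & rel < 50) / (20 * nrow(s))
  expect_gt(after, during)
})

test_that("stronger inhibition cannot increase the evoked spike count", {
  spec10 <- NetworkSpec(wInhMax = 10)
  spec20 <- NetworkSpec(wInhMax = 20)
  count <- function(spec) {
    net <- buildNetwork(spec, seed = 3)
    sset <- makeStimulusSet(2, spec, seed = 3)
    run <- presentStimuli(net, sset, presentationOrder(sset, 5, seed = 3),
                          seed = 3)
    sum(spikeEvents(run$raster)$kind != "input")
  }
  expect_lte(count(spec20), count(spec10))
})

test_that("an under-inhibited network aborts with a runaway diagnostic", {
  spec <- NetworkSpec(wInhMax = 0.3)
  net <- buildNetwork(spec, seed = 4)
  sset <- makeStimulusSet(1, spec, seed = 4)
  expect_error(
    presentStimuli(net, sset, rep("S1", 10), runawayLimit = 3, seed = 4),
    "runaway")
})
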