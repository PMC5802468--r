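test_that("a leak-only cell relaxes exponentially to E_leak", {
  g <- 0.02; E <- -70; C <- 0.25          # tau = C/g = 12.5 ms
  m <- leak_only_neuron(g_leak = g, E_leak = E)
  s0 <- m$state0; s0[["Vs"]] <- -40
  res <- integrate_cell(m, duration = 60, state0 = s0, dt_record = 0.05)
  tau <- C / g
  expected <- E + (-40 - E) * exp(-res$time / tau)
  expect_lt(max(abs(res$states[, "Vs"] - expected)) / abs(E + 40), 1e-3)
})

test_that("with zero stimulus and zero conductances V stays constant", {
  m <- leak_only_neuron(g_leak = 0)
  s0 <- m$state0; s0[["Vs"]] <- -55.5
  res <- integrate_cell(m, duration = 100, state0 = s0)
  expect_equal(unname(res$states[, "Vs"]), rep(-55.5, nrow(res$states)),
               tolerance = 1e-10)
})

test_that("identical calls give bit-identical trajectories", {
  m <- san_mouse()
  r1 <- integrate_cell(m, duration = 1500)
  r2 <- integrate_cell(m, duration = 1500)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$time, r2$time)
})

test_that("gates stay in [0,1] and concentrations positive on SAN runs", {
  res <- mouse_run()
  gates <- res$states[, c("dL12", "fL12", "dL13", "fL13", "dT", "fT",
                          "pa", "pi_", "y", "m", "h", "w")]
  expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
  expect_true(all(res$states[, "Cai"] > 0))
  expect_true(all(res$states[, "CaSR"] > 0))
})

test_that("piecewise stimuli are assembled correctly", {
  segs <- pleiosim:::.stimulus_segments(
    data.frame(start = c(100, 400), end = c(200, 600),
               amplitude = c(0.5, -0.2)), 1000, "neuron")
  expect_equal(segs$amp_soma[segs$start == 100], 0.5)
  expect_equal(segs$amp_soma[segs$start == 400], -0.2)
  expect_equal(segs$amp_soma[segs$start == 0], 0)
  expect_equal(max(segs$end), 1000)
  expect_error(
    pleiosim:::.stimulus_segments(
      data.frame(start = 10, end = 5, amplitude = 1), 100, "neuron"),
    "end > start")
})

test_that("simulation results serialise to tidy CSV", {
  m <- leak_only_neuron()
  res <- integrate_cell(m, duration = 10, dt_record = 1)
  path <- tempfile(fileext = ".csv")
  write_simulation_csv(res, path)
  back <- read.csv(path, comment.char = "#")
  expect_equal(names(back)[1], "time")
  expect_equal(nrow(back), length(res$time))
  expect_equal(back$Vs, unname(res$states[, "Vs"]), tolerance = 1e-6)
})
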