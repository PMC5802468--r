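test_that("threshold current matches the closed form for a leak-only cell", {
  # without active currents, "spiking" is crossing the detector threshold:
  # rheobase = g_L * (V_thr - E_L) exactly
  g <- 0.02; E <- -70
  m <- leak_only_neuron(g_leak = g, E_leak = E)
  expected <- g * (-20 - E)              # 1.0 nA
  th <- threshold_current(m, bracket = c(0.2, 2), tol = 0.001,
                          duration = 200, threshold = -20)
  expect_equal(as.numeric(th), expected, tolerance = 0.005)
  # iteration count obeys the bisection bound
  expect_lte(attr(th, "iterations"), ceiling(log2((2 - 0.2) / 0.001)))
})

test_that("threshold current is invariant to the bracket choice", {
  m <- neuron()
  t1 <- threshold_current(m, bracket = c(0.05, 1.0), tol = 0.005,
                          duration = 400)
  t2 <- threshold_current(m, bracket = c(0.15, 0.8), tol = 0.005,
                          duration = 400)
  expect_lt(abs(as.numeric(t1) - as.numeric(t2)), 2 * 0.005)
})

test_that("a non-straddling bracket is rejected", {
  m <- neuron()
  expect_error(threshold_current(m, bracket = c(1.5, 3), duration = 300),
               "straddle")
})

test_that("f-I amplitudes below rheobase give zero frequency", {
  fi <- neuron_fi()
  rheo <- 0.3   # control rheobase is near 0.30 nA
  expect_true(all(fi$frequency[fi$amplitude < rheo * 0.8] == 0))
  expect_error(fi_curve(neuron(), amplitudes = c(0.5, 0.4)), "increasing")
})

test_that("pacemaking frequency counts cycles correctly", {
  # synthetic 250 ms period -> 4 Hz exactly
  t <- seq(0, 10000, by = 0.5)
  v <- -60 + 80 * (sin(2 * pi * t / 250) > 0.99)
  pf <- pacemaking_frequency(list(time = t, V = v), settle = 1000)
  expect_equal(pf$frequency, 4, tolerance = 1e-3)
  expect_false(pf$quiescent)
  # flat trace -> quiescent, frequency zero
  pq <- pacemaking_frequency(list(time = t, V = rep(-60, length(t))))
  expect_true(pq$quiescent)
  expect_equal(pq$frequency, 0)
})

test_that("cycle counting matches 1/mean-ISI on a stationary SAN trace", {
  run <- mouse_run()
  pf <- pacemaking_frequency(run, settle = 2000)
  sel <- run$time >= 2000
  cross <- upward_crossings(run$time[sel], run$states[sel, "V"], 0, 50)
  f_isi <- 1000 / mean(diff(cross))
  expect_lt(abs(pf$frequency - f_isi) / f_isi, 0.005)
})

test_that("mean rate averages exactly over the requested interval", {
  fi <- structure(data.frame(amplitude = c(0.2, 0.5, 0.8, 1.1),
                             frequency = c(0, 5, 10, 15),
                             failed = FALSE),
                  class = c("fi_curve", "data.frame"))
  expect_equal(mean_rate(fi, c(0.2, 1.1)), 7.5)
  expect_equal(mean_rate(fi, c(0.5, 1.1)), 10)
  expect_equal(mean_rate(fi, c(0.4, 0.9)), 7.5)  # drops excluded amplitudes
  expect_error(mean_rate(fi, c(1.5, 2)), "range")
})

test_that("relative difference from control is reported", {
  t <- seq(0, 8000, by = 0.5)
  v <- -60 + 80 * (sin(2 * pi * t / 200) > 0.99)   # 5 Hz
  pf <- pacemaking_frequency(list(time = t, V = v), settle = 500,
                             control_frequency = 4)
  expect_equal(pf$relative_difference, 0.25, tolerance = 1e-3)
})
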