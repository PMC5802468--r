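test_that("spike detection handles flat and synthetic traces", {
  t <- seq(0, 1000, by = 0.5)
  expect_length(detect_spikes(list(time = t, V = rep(-70, length(t))),
                              threshold = -20), 0)
  # three clean crossings
  v <- rep(-70, length(t))
  for (tc in c(100, 400, 700)) v[t >= tc & t <= tc + 5] <- 10
  sp <- detect_spikes(list(time = t, V = v), threshold = -20, refractory = 2)
  expect_length(sp, 3)
  # crossings interpolate within the 0.5 ms sample preceding each step
  expect_equal(sp, c(100, 400, 700), tolerance = 0.5)
})

test_that("spike detector matches a brute-force sign-change scan", {
  set.seed(101)
  for (rep in 1:20) {
    t <- seq(0, 500, by = 0.25)
    v <- -60 + cumsum(stats::rnorm(length(t), 0, 4))
    thr <- stats::runif(1, -60, -20)
    got <- upward_crossings(t, v, thr, refractory = 0)
    # brute force: every index where (V - thr) changes sign upward
    s <- sign(v - thr)
    idx <- which(s[-length(s)] < 1 & s[-1] >= 1 & v[-length(v)] < thr)
    expect_length(got, length(idx))
  }
})

test_that("refractory period suppresses rapid re-crossings", {
  t <- seq(0, 100, by = 0.1)
  v <- -70 + 60 * (sin(2 * pi * t / 4) > 0.9)  # bursts every 4 ms
  sp_all <- upward_crossings(t, v, -20, refractory = 0)
  sp_ref <- upward_crossings(t, v, -20, refractory = 10)
  expect_gt(length(sp_all), length(sp_ref))
  expect_true(all(diff(sp_ref) >= 10))
})

test_that("AP metrics are exact on a constructed triangular AP", {
  # triangular AP: baseline -80, linear rise to +20 over 2 ms, fall over 4 ms
  t <- seq(0, 50, by = 0.01)
  v <- rep(-80, length(t))
  up <- t >= 10 & t <= 12
  dn <- t > 12 & t <= 16
  v[up] <- -80 + (t[up] - 10) / 2 * 100
  v[dn] <- 20 - (t[dn] - 12) / 4 * 100
  m <- ap_metrics(list(time = t, V = v), threshold = -20)
  expect_false(m$no_ap)
  expect_equal(m$peak, 20, tolerance = 1e-3)
  expect_equal(m$mdp, -80, tolerance = 1e-3)
  expect_equal(m$amplitude, 100, tolerance = 1e-3)
  # half-amplitude level -30: crossed at t = 11 (rise) and t = 14 (fall)
  expect_equal(m$half_width, 3, tolerance = 0.02)
})

test_that("cycle length equals the constructed inter-AP interval", {
  t <- seq(0, 1000, by = 0.1)
  v <- -70 + 80 * (sin(2 * pi * (t - 52.5) / 210) > 0.98)
  m <- ap_metrics(list(time = t, V = v), threshold = -20, refractory = 50)
  expect_equal(m$cycle_length, 210, tolerance = 0.01)
})

test_that("metrics are stable under time-grid refinement", {
  mk <- function(dt) {
    t <- seq(0, 60, by = dt)
    v <- -75 + 95 * exp(-((t - 30) / 3)^2)
    ap_metrics(list(time = t, V = v), threshold = -20)
  }
  coarse <- mk(0.1); fine <- mk(0.005)
  expect_equal(coarse$peak, fine$peak, tolerance = 0.01)
  expect_equal(coarse$half_width, fine$half_width, tolerance = 0.02)
})

test_that("a window without APs yields the explicit no-AP marker", {
  t <- seq(0, 100, by = 0.5)
  m <- ap_metrics(list(time = t, V = rep(-70, length(t))))
  expect_true(m$no_ap)
  expect_true(is.na(m$peak))
  expect_equal(m$n_ap, 0L)
})
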