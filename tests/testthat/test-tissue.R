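test_that("conduction velocity is exact on synthetic activation times", {
  cfg <- cable_config(n_cells = 50, cell_length = 70)
  v_true <- 3.5   # cells per ms
  act <- c(rep(NA, 10), (11:50) / v_true)
  res <- list(activation = act, config = cfg)
  cv <- conduction_velocity(res, boundary = 0)
  expect_equal(as.numeric(cv), v_true * 70, tolerance = 1e-9)
  expect_equal(attr(cv, "r_squared"), 1)
  # reversed wave: same magnitude, negative sign
  rev <- list(activation = c(rep(NA, 10), (50:11) / v_true), config = cfg)
  cvr <- conduction_velocity(rev, boundary = 0)
  expect_equal(as.numeric(cvr), -v_true * 70, tolerance = 1e-9)
  # mixed direction is an error
  mix <- list(activation = c(rep(NA, 10), 1:20, 20:1), config = cfg)
  expect_error(conduction_velocity(mix, boundary = 0), "mixed")
})

test_that("without coupling the pulse does not propagate", {
  # the observation window ends before the released pacemakers fire on
  # their own, so any activation must come through the coupling
  m <- san_mouse()
  r0 <- simulate_cable(m, cable_config(n_cells = 30, D = 0, pre_mV = -90,
                                       clamp_fraction = 0.2),
                       post_release = 20)
  expect_true(all(is.na(r0$activation)))
  r1 <- simulate_cable(m, cable_config(n_cells = 30, D = 6e4, pre_mV = -90,
                                       clamp_fraction = 0.2),
                       post_release = 20)
  expect_gt(sum(!is.na(r1$activation)), 15)
})

test_that("a uniform chain supports an affine activation front", {
  m <- san_mouse()
  r <- simulate_cable(m, cable_config(n_cells = 80, D = 6e4, pre_mV = -90,
                                      clamp_fraction = 0.1),
                      post_release = 100)
  cv <- conduction_velocity(r, fit_cells = 15:65)
  expect_gt(attr(cv, "r_squared"), 0.99)
  expect_gt(as.numeric(cv), 0)
})

test_that("refining the spatial discretisation preserves the velocity", {
  m <- san_mouse()
  # same physical length and diffusion constant, twice the cell count
  r1 <- simulate_cable(m, cable_config(n_cells = 60, cell_length = 70,
                                       D = 6e4, pre_mV = -90,
                                       clamp_fraction = 0.1),
                       post_release = 60)
  r2 <- simulate_cable(m, cable_config(n_cells = 120, cell_length = 35,
                                       D = 6e4, pre_mV = -90,
                                       clamp_fraction = 0.1),
                       post_release = 60)
  win1 <- which(!is.na(r1$activation) & r1$activation - 300 >= 2 &
                r1$activation - 300 <= 6)
  win2 <- which(!is.na(r2$activation) & r2$activation - 300 >= 2 &
                r2$activation - 300 <= 6)
  cv1 <- as.numeric(conduction_velocity(r1, fit_cells = win1))
  cv2 <- as.numeric(conduction_velocity(r2, fit_cells = win2))
  expect_lt(abs(cv2 - cv1) / cv1, 0.02)
})

test_that("exit-block detection matches brute-force event matching", {
  # synthetic 3:2 pattern: every third SAN cycle has no atrial partner
  san <- seq(0, 3000, by = 300)
  atr <- san[seq_along(san) %% 3 != 0] + 40
  rep <- detect_exit_block(san_times = san, atrial_times = atr,
                           window = 150)
  expect_equal(rep$events, san[seq_along(san) %% 3 == 0])
  # 1:1 conduction: zero events, constant intervals
  rep2 <- detect_exit_block(san_times = san, atrial_times = san + 35,
                            window = 150)
  expect_equal(rep2$n_blocked, 0)
  expect_true(all(abs(rep2$intervals - 300) < 1e-9))
  # random series against a brute-force double loop
  set.seed(77)
  for (k in 1:10) {
    s <- sort(runif(20, 0, 5000))
    a <- sort(runif(15, 0, 5000))
    w <- runif(1, 50, 300)
    got <- detect_exit_block(san_times = s, atrial_times = a, window = w)
    brute <- sum(vapply(s, function(ts) !any(a >= ts & a <= ts + w),
                        logical(1)))
    expect_equal(got$n_blocked, brute)
  }
})

test_that("the diffusion step conserves total membrane charge", {
  m <- san_mouse()
  n <- 31L
  centre <- (n + 1) / 2
  xy <- (seq_len(n) - centre) * 0.04
  w <- outer(xy, xy, function(x, y) as.numeric(sqrt(x^2 + y^2) <= 0.3))
  ap <- atrial_params()
  probes <- cbind(16L, 16L)
  out <- pleiosim:::tissue2d_sim_cpp(m$params, m$state0, ap, w, 0.04,
                          1.2e-3, 0.25e-3, 0.125, 1L, 50,
                          probes, 1, diffusion_only = TRUE)
  v_init <- mean(ifelse(w > 0, m$state0[["V"]], ap[["V0"]]))
  expect_equal(out$V_mean_final, v_init, tolerance = 1e-10)
})

test_that("tissue configuration geometry is validated", {
  cfg <- tissue_config(preset = "desk")
  expect_equal(cfg$nodes, 76L)
  expect_equal(cfg$dx * (cfg$nodes - 1), 3, tolerance = 1e-12)
  full <- tissue_config(preset = "full")
  expect_equal(full$nodes, 151L)
  expect_equal(full$dx, 0.02, tolerance = 1e-12)
  expect_error(tissue_config(san_radius_cm = 2), "san_radius_cm")
})
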