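test_that("threshold search matches closed forms on analytic surrogates", {
  # surrogate frequency f(c) = f0 (1 + 2c), single 25% tolerance:
  # violation at 2c > 0.25, threshold c = 0.125
  res <- find_threshold_scale(function(s) abs(2 * s) <= 0.25,
                              step = 0.1, tol = 1e-3)
  expect_equal(res$c, 0.125, tolerance = 1e-3)
  # quadratic violation |c^2 * 3| > 0.6 -> c = sqrt(0.2)
  res2 <- find_threshold_scale(function(s) 3 * s^2 <= 0.6,
                               step = 0.1, tol = 1e-3)
  expect_equal(res2$c, sqrt(0.2), tolerance = 1e-3)
  # never violated -> c = 1
  expect_equal(find_threshold_scale(function(s) TRUE)$c, 1)
  # violated everywhere -> c = 0
  expect_equal(find_threshold_scale(function(s) FALSE, tol = 1e-3)$c, 0,
               tolerance = 1e-3)
})

test_that("bisection agrees with an exhaustive fine-grid scan", {
  viol_at <- c(0.237, 0.5001, 0.849)
  for (v in viol_at) {
    pass <- function(s) s < v
    res <- find_threshold_scale(pass, step = 0.1, tol = 1e-3)
    grid <- seq(0, 1, by = 1e-3)
    brute <- max(grid[vapply(grid, pass, logical(1))])
    expect_lt(abs(res$c - brute), 2e-3)
  }
})

test_that("first violation from below wins on non-monotone patterns", {
  # pass on [0, 0.3], fail on (0.3, 0.5], pass again above: threshold 0.3
  pass <- function(s) s <= 0.3 || s > 0.5
  res <- find_threshold_scale(pass, step = 0.1, tol = 1e-3)
  expect_lt(abs(res$c - 0.3), 2e-3)
})

test_that("control evaluated against itself passes all conditions", {
  cs <- condition_set("san", record = 4000, settle = 1500)
  ref <- condition_reference(san_mouse(), cs)
  rep <- evaluate_conditions(san_mouse(), san_mouse(), cs, reference = ref)
  expect_true(all(rep$pass))
  expect_false(attr(rep, "qualitative_loss"))
})

test_that("gross frequency and amplitude deviations fail their conditions", {
  cs <- condition_set("san", record = 4000, settle = 1500, freq_tol = 0.25)
  ref <- condition_reference(san_mouse(), cs)
  # a variant far beyond any plausible threshold: T-type tripled with a
  # -10 mV activation shift roughly doubles the pacemaking rate
  eff <- variant_effect("gross", "CACNA1I", list(
    parameter_modification("CaT.gbar", "mult", 8),
    parameter_modification("CaT.act.vhalf", "add", -12)))
  cand <- apply_variant(san_mouse(), eff, 1, 1)
  rep <- evaluate_conditions(san_mouse(), cand, cs, reference = ref)
  expect_false(all(rep$pass))
  expect_false(rep$pass[rep$condition == "B1"])
})

test_that("identity variants calibrate to c = 1 on a live model", {
  cs <- condition_set("san", record = 4000, settle = 1500)
  cal <- find_threshold_c(san_mouse(),
                          variant_effect("id", "SCN1A", list()),
                          cs, step = 0.5, tol = 0.05)
  expect_equal(cal$c, 1)
  expect_true(all(cal$report$pass))
})

test_that("scaled-down applications at fractions of c satisfy conditions", {
  cs <- condition_set("san", record = 4000, settle = 1500)
  ref <- condition_reference(san_rabbit(), cs)
  eff <- tissue_ca_variant()
  cal <- find_threshold_c(san_rabbit(), eff, cs, reference = ref,
                          step = 0.2, tol = 0.02)
  expect_gt(cal$c, 0)
  for (eps in c(-0.5, -0.25, 0.25, 0.5)) {
    cand <- apply_variant(san_rabbit(), eff, epsilon = eps, c_scale = cal$c)
    rep <- evaluate_conditions(san_rabbit(), cand, cs, reference = ref)
    expect_true(all(rep$pass),
                label = sprintf("conditions at epsilon=%g", eps))
  }
})

test_that("tighter condition sets never calibrate to a larger c", {
  loose <- condition_set("san", record = 4000, settle = 1500,
                         freq_tol = 0.25)
  tight <- condition_set("san", record = 4000, settle = 1500,
                         freq_tol = 0.10)
  eff <- tissue_ca_variant()
  c_loose <- find_threshold_c(san_rabbit(), eff, loose,
                              step = 0.25, tol = 0.05)$c
  c_tight <- find_threshold_c(san_rabbit(), eff, tight,
                              step = 0.25, tol = 0.05)$c
  expect_lte(c_tight, c_loose + 1e-9)
})
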