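test_that("modification scaling follows the linear/log rules", {
  add <- parameter_modification("Na.act.vhalf", "add", 4)
  expect_equal(scale_modification(add, 0.5)$value, 2)
  expect_equal(scale_modification(add, 0)$value, 0)
  expect_equal(scale_modification(add, 1)$value, 4)
  expect_equal(scale_modification(add, -1)$value, -4)
  mult <- parameter_modification("Na.gbar", "mult", 2)
  expect_equal(scale_modification(mult, 0.5)$value, sqrt(2))
  expect_equal(scale_modification(mult, 0)$value, 1)
  expect_equal(scale_modification(mult, 1)$value, 2)
  expect_equal(scale_modification(mult, -1)$value, 0.5)  # reversed variant
})

test_that("modification modes are validated against parameter kind", {
  expect_error(parameter_modification("Na.gbar", "add", 4), "additive")
  expect_error(parameter_modification("Na.act.vhalf", "mult", 2),
               "not valid")
  expect_error(parameter_modification("Na.gbar", "mult", -1), "> 0")
})

test_that("variant application is exact and leaves the control untouched", {
  ctrl <- san_mouse()
  eff <- variant_effect("v1", "CACNA1D", list(
    parameter_modification("CaL13.gbar", "mult", 2),
    parameter_modification("CaL13.act.vhalf", "add", 5)))
  g0 <- model_parameter(ctrl, "CaL13.gbar")
  v0 <- model_parameter(ctrl, "CaL13.act.vhalf")
  var <- apply_variant(ctrl, eff, epsilon = 1, c_scale = 1)
  expect_equal(model_parameter(var, "CaL13.gbar"), 2 * g0)
  expect_equal(model_parameter(var, "CaL13.act.vhalf"), v0 + 5)
  expect_equal(model_parameter(ctrl, "CaL13.gbar"), g0)  # control intact
  # identity effect reproduces the control parameters exactly
  id <- apply_variant(ctrl, variant_effect("id", "SCN1A", list()), 1, 1)
  expect_identical(id$params, ctrl$params)
})

test_that("epsilon = 0 yields a model whose integration is bit-identical", {
  ctrl <- san_mouse()
  eff <- variant_effect("v", "CACNA1I", list(
    parameter_modification("CaT.gbar", "mult", 3),
    parameter_modification("CaT.act.vhalf", "add", -7)))
  zero <- apply_variant(ctrl, eff, epsilon = 0, c_scale = 0.7)
  r0 <- integrate_cell(ctrl, duration = 800)
  r1 <- integrate_cell(zero, duration = 800)
  expect_identical(r0$states, r1$states)
})

test_that("sequential scaling composes additively in the exponent", {
  ctrl <- san_mouse()
  eff <- variant_effect("v", "HCN1", list(
    parameter_modification("HCN.gbar", "mult", 2.5),
    parameter_modification("HCN.act.vhalf", "add", 6)))
  a <- 0.3; b <- 0.45
  twice <- apply_variant(apply_variant(ctrl, eff, a, 1), eff, b, 1)
  once <- apply_variant(ctrl, eff, a + b, 1)
  expect_equal(twice$params, once$params, tolerance = 1e-12)
})

test_that("epsilon and -epsilon bracket the control symmetrically", {
  ctrl <- san_rabbit()
  effs <- generate_variant_table(variant_generator_config(n = 6, seed = 3))
  for (eff in effs) for (eps in c(0.25, 0.5)) {
    up <- apply_variant(ctrl, eff, eps, 1)
    dn <- apply_variant(ctrl, eff, -eps, 1)
    for (mod in eff$modifications) {
      key <- resolve_parameter_path(ctrl, mod$path)
      p0 <- ctrl$params[[key]]
      if (mod$mode == "mult") {
        # geometric bracketing: up/ctrl == ctrl/dn
        expect_equal(up$params[[key]] / p0, p0 / dn$params[[key]],
                     tolerance = 1e-10)
      } else {
        expect_equal(up$params[[key]] - p0, p0 - dn$params[[key]],
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("inapplicable paths raise errors listing the path", {
  nrn <- neuron()
  eff <- variant_effect("kr", "CACNA1C", list(
    parameter_modification("Kr.gbar", "mult", 2)))
  expect_false(variant_applicable(nrn, eff))
  expect_error(apply_variant(nrn, eff, 1, 1), "Kr.gbar")
  expect_warning(apply_variant(nrn, eff, 1, 1, partial = TRUE), "skipping")
  expect_true(variant_applicable(san_mouse(), eff))
})

test_that("variant tables round-trip through TSV and JSON", {
  effs <- generate_variant_table(variant_generator_config(n = 8, seed = 42))
  for (ext in c(".tsv", ".json")) {
    path <- tempfile(fileext = ext)
    write_variant_table(effs, path, header = "round-trip check")
    back <- read_variant_table(path)
    expect_identical(names(back), names(effs))
    for (id in names(effs)) {
      expect_equal(back[[id]]$gene, effs[[id]]$gene)
      expect_equal(lapply(back[[id]]$modifications, unclass),
                   lapply(effs[[id]]$modifications, unclass),
                   tolerance = 1e-12)
    }
  }
})

test_that("model parameters serialise to a diffable flat text file", {
  path <- tempfile(fileext = ".txt")
  write_model_parameters(san_mouse(), path)
  lines <- readLines(path)
  expect_true(any(grepl("^gf = ", lines)))
  vals <- lines[!grepl("^#", lines)]
  expect_length(vals, length(san_mouse()$params))
})
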