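test_that("the generator is fully determined by its seed", {
  cfg <- variant_generator_config(n = 20, seed = 99)
  t1 <- generate_variant_table(cfg)
  t2 <- generate_variant_table(cfg)
  expect_identical(lapply(t1, function(e) lapply(e$modifications, unclass)),
                   lapply(t2, function(e) lapply(e$modifications, unclass)))
  t3 <- generate_variant_table(variant_generator_config(n = 20, seed = 100))
  expect_false(identical(
    lapply(t1, function(e) lapply(e$modifications, unclass)),
    lapply(t3, function(e) lapply(e$modifications, unclass))))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_variant_table(variant_generator_config(n = 5, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("the default mixture reproduces the 80:14 class split at n=94", {
  effs <- generate_variant_table(variant_generator_config(n = 94, seed = 1))
  classes <- gene_class(vapply(effs, `[[`, character(1), "gene"))
  expect_length(effs, 94)
  expect_equal(sum(classes == "Ca/transporter"), 80)
  expect_equal(sum(classes == "Na/HCN"), 14)
})

test_that("all generated effect sizes respect the declared ranges", {
  effs <- generate_variant_table(variant_generator_config(n = 200, seed = 2))
  for (eff in effs) {
    expect_gte(length(eff$modifications), 1)
    expect_lte(length(eff$modifications), 4)
    paths <- vapply(eff$modifications, `[[`, character(1), "path")
    expect_false(any(duplicated(paths)))
    for (mod in eff$modifications) {
      if (mod$mode == "add") {
        expect_gte(mod$value, -10); expect_lte(mod$value, 10)
      } else {
        expect_gte(mod$value, 1 / 3); expect_lte(mod$value, 3)
      }
    }
  }
})

test_that("gene targets match each gene's channel", {
  effs <- generate_variant_table(variant_generator_config(n = 300, seed = 8))
  prefix <- list(SCN1A = "Na", HCN1 = "HCN", CACNA1C = "CaL12",
                 CACNA1D = "CaL13", CACNB2 = c("CaL12", "CaL13"),
                 CACNA1I = "CaT", ATP2A2 = "SERCA")
  for (eff in effs) {
    # every variant carries at least one current-density modification
    expect_true(any(grepl("\\.(gbar|P_up)$",
                          vapply(eff$modifications, `[[`, character(1),
                                 "path"))),
                label = paste(eff$id, "density effect"))
    for (mod in eff$modifications)
      expect_true(any(startsWith(mod$path, prefix[[eff$gene]])),
                  label = paste(eff$gene, mod$path))
  }
})

test_that("effect-size distributions are symmetric around neutral", {
  effs <- generate_variant_table(variant_generator_config(n = 4000, seed = 4,
                                                          max_mods = 4))
  mods <- unlist(lapply(effs, `[[`, "modifications"), recursive = FALSE)
  deltas <- vapply(Filter(function(m) m$mode == "add", mods),
                   `[[`, numeric(1), "value")
  lgammas <- log(vapply(Filter(function(m) m$mode == "mult", mods),
                        `[[`, numeric(1), "value"))
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
  expect_lt(abs(mean(lgammas)),
            3 * stats::sd(lgammas) / sqrt(length(lgammas)))
})
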