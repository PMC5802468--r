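test_that("correlation matrix reproduces hand-computed Pearson values", {
  tab <- data.frame(variant = paste0("v", 1:4), gene = "CACNA1C",
                    class = "Ca/transporter",
                    neuron_rate = c(10, 12, 8, 11),
                    san_rate = c(3.1, 2.5, 3.4, 2.8))
  cm <- correlation_matrix(tab)
  hand <- cor(tab$neuron_rate, tab$san_rate)    # textbook formula
  byhand <- sum((tab$neuron_rate - mean(tab$neuron_rate)) *
                (tab$san_rate - mean(tab$san_rate))) /
    sqrt(sum((tab$neuron_rate - mean(tab$neuron_rate))^2) *
         sum((tab$san_rate - mean(tab$san_rate))^2))
  expect_equal(cm["neuron_rate", "san_rate"], byhand)
  expect_equal(hand, byhand)
  expect_equal(diag(cm), c(neuron_rate = 1, san_rate = 1))
  expect_equal(cm, t(cm))
})

test_that("identical and negated columns give +1 and -1", {
  x <- c(1, 4, 2, 8, 5)
  tab <- data.frame(class = "Na/HCN", a = x, b = x, c = -x)
  cm <- correlation_matrix(tab, model_cols = c("a", "b", "c"))
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
})

test_that("correlations are invariant to row order and affine rescaling", {
  set.seed(5)
  tab <- data.frame(class = "Na/HCN", a = rnorm(10), b = rnorm(10))
  cm1 <- correlation_matrix(tab, model_cols = c("a", "b"))
  shuf <- tab[sample(nrow(tab)), ]
  cm2 <- correlation_matrix(shuf, model_cols = c("a", "b"))
  expect_equal(cm1, cm2)
  scaled <- tab; scaled$b <- 3.7 * scaled$b - 11
  cm3 <- correlation_matrix(scaled, model_cols = c("a", "b"))
  expect_equal(cm1["a", "b"], cm3["a", "b"])
})

test_that("degenerate inputs are rejected or flagged", {
  small <- data.frame(class = "Na/HCN", a = 1:2, b = 2:1)
  expect_error(correlation_matrix(small, model_cols = c("a", "b")),
               "at least 3")
  flat <- data.frame(class = "Na/HCN", a = 1:5, b = rep(2, 5))
  expect_warning(cm <- correlation_matrix(flat, model_cols = c("a", "b")),
                 "zero variance")
  expect_true(is.na(cm["a", "b"]))
  # rows with missing model values are dropped, not partially used
  nas <- data.frame(class = "Na/HCN", a = c(1:4, NA), b = c(2, 1, 4, 3, 9))
  cm2 <- correlation_matrix(nas, model_cols = c("a", "b"))
  expect_equal(cm2["a", "b"], cor(c(1, 2, 3, 4), c(2, 1, 4, 3)))
})

test_that("pleiotropy classification follows the dead-band rule", {
  expect_equal(classify_pleiotropy(0.05, 0.04), "analogous")
  expect_equal(classify_pleiotropy(0.05, -0.04), "non-analogous")
  expect_equal(classify_pleiotropy(0.001, -0.08, dead_band = 0.01),
               "neutral")
  expect_equal(classify_pleiotropy(-0.03, -0.06), "analogous")
  expect_equal(
    classify_pleiotropy(c(0.05, -0.02, 0.005), c(0.04, 0.03, 0.09)),
    c("analogous", "non-analogous", "neutral"))
})

test_that("gene symbols map onto the two analysis classes", {
  expect_equal(gene_class(c("SCN1A", "HCN1")), rep("Na/HCN", 2))
  expect_equal(gene_class(c("CACNA1C", "CACNA1D", "CACNB2", "CACNA1I",
                            "ATP2A2")),
               rep("Ca/transporter", 5))
  expect_error(gene_class("KCNQ1"), "unknown")
})
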