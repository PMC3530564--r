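test_that("normalisation reproduces the published per-million values", {
  expect_equal(round(normalize_tpm(385, 14851375), 4), 25.9235)
  expect_equal(round(normalize_tpm(1671, 15712891), 4), 106.3458)
  expect_equal(normalize_tpm(123456, 123456), 1e6)
  expect_error(normalize_tpm(5, 0), "positive")
})

test_that("zero adjustment and the both-below-one filter behave", {
  r <- adjust_and_filter(0, 5.2)
  expect_equal(r$X, 0.01); expect_equal(r$Y, 5.2); expect_false(r$filtered)
  expect_true(adjust_and_filter(0.4, 0.7)$filtered)
  r0 <- adjust_and_filter(0, 0)
  expect_equal(c(r0$X, r0$Y), c(0.01, 0.01))
  expect_true(r0$filtered)
})

test_that("fold changes match the published four-decimal values", {
  N <- mammary_library_sizes()
  fc <- function(x, y) fold_change(normalize_tpm(x, N[["dry"]]),
                                   normalize_tpm(y, N[["peak"]]))
  expect_equal(round(fc(385, 1671), 4), 2.0364)    # miR-2887
  expect_equal(round(fc(749, 1665), 4), 1.0711)    # miR-451
  expect_equal(round(fc(869, 1888), 4), 1.0381)    # miR-2478
  expect_equal(round(fc(443620, 32993), 4), -3.8304)  # let-7b
  expect_equal(round(fc(341112, 27377), 4), -3.7206)  # let-7c
  expect_equal(fold_change(7, 7), 0)
})

test_that("the conditional count distribution is a proper probability", {
  for (x in c(0, 1, 10, 50)) {
    expect_equal(oracle_ac_lower(x, 5000, 1e6, 1.3e6), 1, tolerance = 1e-9)
  }
})

test_that("tail probabilities agree with direct term-by-term summation", {
  set.seed(51)
  for (i in 1:30) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    N1 <- sample(5e5:2e6, 1); N2 <- sample(5e5:2e6, 1)
    lower <- ac_pvalue(x, y, N1, N2, variant = "less", condition = "x")
    upper <- ac_pvalue(x, y, N1, N2, variant = "greater", condition = "x")
    expect_equal(lower, oracle_ac_lower(x, y, N1, N2), tolerance = 1e-9)
    expect_equal(upper, oracle_ac_upper(x, y, N1, N2), tolerance = 1e-9)
    pt <- ac_pvalue(x, y, N1, N2, variant = "point", condition = "x")
    expect_equal(pt, oracle_ac_point(x, y, N1, N2), tolerance = 1e-9)
  }
})

test_that("a central observation is not significant", {
  expect_gte(ac_pvalue(100, 100, 1e6, 1e6), 0.9)
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6), 1)
})

test_that("swapping libraries negates the fold change and keeps the p-value", {
  set.seed(52)
  for (i in 1:20) {
    x <- sample(0:500, 1); y <- sample(0:500, 1)
    N1 <- 14851375; N2 <- 15712891
    p1 <- ac_pvalue(x, y, N1, N2)
    p2 <- ac_pvalue(y, x, N2, N1)
    expect_equal(p1, p2, tolerance = 1e-12)
    X <- adjust_and_filter(normalize_tpm(x, N1), normalize_tpm(y, N2))
    expect_equal(fold_change(X$X, X$Y), -fold_change(X$Y, X$X))
  }
})

test_that("the significance label applies both strict gates", {
  expect_equal(sig_label(2.0364, 4.3e-175), "**")
  expect_equal(sig_label(0.5, 1e-10), "")
  expect_equal(sig_label(1.0, 1e-10), "")       # strict fold-change gate
  expect_equal(sig_label(-1.5, 0.01), "")       # strict p gate
  expect_equal(sig_label(-1.5, 0.009), "**")
})

test_that("the table builder unions names, fills zeros and summarises", {
  de <- diff_table(c(a = 10, b = 0, c = 500), c(a = 12, c = 5, d = 40),
                   N1 = 1e6, N2 = 1e6)
  expect_setequal(de$name, c("a", "b", "c", "d"))
  expect_equal(de$y[de$name == "b"], 0)
  expect_equal(de$X[de$name == "d"], 0.01)   # zero-adjusted
  s <- attr(de, "summary")
  expect_true(s$down >= 1)  # c: 500 -> 5
  empty <- diff_table(numeric(0), numeric(0), N1 = 1, N2 = 1)
  expect_equal(nrow(empty), 0)
})

test_that("null counts are labelled significant at no more than the gate rate", {
  set.seed(53)
  n <- 500
  x <- rpois(n, 100); y <- rpois(n, 100)
  de <- diff_table(setNames(x, paste0("m", 1:n)),
                   setNames(y, paste0("m", 1:n)), N1 = 1e6, N2 = 1e6)
  expect_lte(mean(de$sig == "**"), 0.02)
})
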