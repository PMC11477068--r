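zero_rows <- function(n, m) {
  rows <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     y_density = 0, methylated = c(rep(TRUE, m),
                                                   rep(FALSE, n - m)))
  for (cn in c("x01_00", "x01_01", "x01_11", "x11_00", "x11_01", "x11_11"))
    rows[[cn]] <- 0L
  rows$y_density[rows$methylated] <- 0.01
  rows
}

test_that("all-zero covariates give the closed-form intercept-only logistic fit", {
  rows <- zero_rows(50, 20)
  fit <- fit_logistic(rows)
  expect_equal(nrow(fit$terms), 1)
  expect_equal(fit$terms$estimate[1], log(20 / 30), tolerance = 1e-8)
  expect_equal(nrow(fit$dropped_terms), 6)
  expect_true(all(fit$dropped_terms$reason == "all zero"))
})

test_that("single-class responses and tiny classes are refused", {
  rows <- zero_rows(50, 20)
  rows$methylated <- TRUE
  expect_error(fit_logistic(rows), "single-class")
  rows2 <- zero_rows(50, 1)
  expect_error(fit_logistic(rows2), ">= 2 rows")
})

test_that("a duplicated covariate column is dropped as collinear", {
  set.seed(5)
  rows <- simulate_feature_rows(400, seed = 5)
  rows$x11_00 <- rows$x01_01          # duplicate content
  fit <- fit_logistic(rows)
  expect_true("x11_00" %in% fit$dropped_terms$term)
  expect_equal(fit$dropped_terms$reason[fit$dropped_terms$term == "x11_00"],
               "collinear")
  expect_false("1/1_0/0" %in% fit$terms$term)
})

test_that("complete separation is a declared failure naming the covariate", {
  rows <- zero_rows(60, 30)
  rows$x01_01 <- ifelse(rows$methylated, 5L, 0L)     # perfect separator
  expect_error(fit_logistic(rows), "separation.*0/1_0/1")
})

test_that("logistic and linear fits agree with hand-rolled IRLS / normal equations", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 150
    rows <- simulate_feature_rows(n, seed = seed)
    # keep fixtures that have both classes and no separation
    if (length(unique(rows$methylated)) < 2) next
    fit <- tryCatch(fit_logistic(rows), error = function(e) NULL)
    if (!is.null(fit)) {
      kept <- fit$terms$term[-1]
      X <- as.matrix(rows[, transmit_col(kept), drop = FALSE])
      ref <- oracle_logistic(X, as.integer(rows$methylated))
      expect_equal(fit$terms$estimate, ref$beta, tolerance = 1e-6)
      expect_equal(fit$terms$std_error, ref$se, tolerance = 1e-6)
    }
    mrows <- rows[rows$methylated, , drop = FALSE]
    mrows$y_density <- mrows$y_density + 1e-4 * mrows$x01_01
    lfit <- fit_linear(mrows)
    keptl <- lfit$terms$term[-1]
    Xl <- as.matrix(mrows[, transmit_col(keptl), drop = FALSE])
    refl <- oracle_ols(Xl, mrows$y_density)
    expect_equal(lfit$terms$estimate, refl$beta, tolerance = 1e-6)
    expect_equal(lfit$terms$std_error, refl$se, tolerance = 1e-6)
  }
})

test_that("noiseless linear data is recovered exactly", {
  rows <- zero_rows(40, 40)
  rows$x01_00 <- rep(0:3, 10)
  rows$y_density <- 1e-4 + 5e-4 * rows$x01_00
  fit <- fit_linear(rows)
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(unname(est["(Intercept)"]), 1e-4, tolerance = 1e-10)
  expect_equal(unname(est["0/1_0/0"]), 5e-4, tolerance = 1e-10)
})

test_that("a constant response yields a flagged degenerate linear fit", {
  rows <- zero_rows(30, 30)
  rows$x01_01 <- rep(c(0L, 2L), 15)
  rows$y_density <- 0.007
  fit <- fit_linear(rows)
  expect_true(fit$degenerate)
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(unname(est["(Intercept)"]), 0.007)
  expect_equal(unname(est["0/1_0/1"]), 0)
})

test_that("row order never changes coefficients or p-values", {
  rows <- simulate_feature_rows(500, seed = 9)
  set.seed(1)
  perm <- rows[sample(nrow(rows)), ]
  f1 <- fit_logistic(rows); f2 <- fit_logistic(perm)
  expect_equal(f1$terms, f2$terms)
  m1 <- fit_linear(rows[rows$methylated, ])
  m2 <- fit_linear(perm[perm$methylated, ])
  expect_equal(m1$terms, m2$terms)
})

test_that("planted logistic and linear coefficients are recovered within 2 SE", {
  rows <- simulate_feature_rows(5000, seed = 31)
  beta <- attr(rows, "beta")
  fit <- fit_logistic(rows)
  for (lab in c("0/1_0/1", "1/1_1/1")) {
    tr <- fit$terms[fit$terms$term == lab, ]
    truth <- beta[transmit_col(lab)]
    expect_lt(abs(tr$estimate - truth), 2 * tr$std_error)
    expect_lt(tr$p_value, 0.01)
  }
  lrows <- simulate_linear_rows(5000, seed = 32)
  a <- attr(lrows, "a")
  lfit <- fit_linear(lrows)
  tr <- lfit$terms[lfit$terms$term == "0/1_0/0", ]
  expect_lt(abs(tr$estimate - a[["x01_00"]]), 2 * tr$std_error)
  expect_lt(tr$p_value, 0.01)
})

test_that("imprinting contrasts produce the four comparisons of the 2x2 design", {
  set.seed(17)
  n <- 400
  rows <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     y_density = 0, methylated = rep(c(TRUE, FALSE), n / 2),
                     imprinted = sample(c(TRUE, FALSE), n, TRUE,
                                        prob = c(0.2, 0.8)))
  # methylated genes mutate less; imprinting has no effect of its own
  rows$n_var_dna <- rpois(n, ifelse(rows$methylated, 3, 6))
  out <- imprinting_contrasts(rows)
  expect_equal(nrow(out), 4)
  expect_true(all(out$computable))
  meth_vs_unmeth <- out[grepl("^methylated-non-imprinted vs unmethylated-non",
                              out$comparison), ]
  expect_lt(meth_vs_unmeth$p_value, 0.01)
  expect_lt(meth_vs_unmeth$mean1, meth_vs_unmeth$mean2)
  # an empty cell is reported as not computable, not an error
  rows2 <- rows[!(rows$methylated & rows$imprinted), ]
  out2 <- imprinting_contrasts(rows2)
  expect_false(all(out2$computable))
  expect_equal(sum(!out2$computable), 2)
  # identical constant groups give p = 1
  rows3 <- rows; rows3$n_var_dna <- 5L
  out3 <- imprinting_contrasts(rows3)
  expect_true(all(out3$p_value == 1))
})
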