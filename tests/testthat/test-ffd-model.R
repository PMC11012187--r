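test_that("zero-noise responses from the coefficient table are refitted exactly", {
  d <- mae_design_11()
  B <- mae_coefficient_table()
  X <- ffd_model_matrix(d)
  for (resp in colnames(B)) {
    fit <- fit_ffd(d, drop(X %*% B[, resp]), resp)
    expect_equal(coef(fit), B[, resp], tolerance = 1e-12,
                 ignore_attr = TRUE, label = resp)
    expect_equal(fit$r2_adj, 1)
  }
  # spot checks on printed values
  lpi <- fit_ffd(d, drop(X %*% B[, "LPI"]), "LPI")
  expect_equal(unname(coef(lpi)["b1"]), 0.345)
  expect_equal(unname(coef(lpi)["b0"]), 0.364)
  cer <- fit_ffd(d, drop(X %*% B[, "Cer"]), "Cer")
  expect_equal(unname(coef(cer)["b23"]), 0.236)
})

test_that("a constant response yields an intercept-only fit", {
  d <- mae_design_11()
  fit <- fit_ffd(d, rep(0.7, 11))
  expect_equal(unname(coef(fit)["b0"]), 0.7)
  expect_equal(unname(coef(fit)[-1]), rep(0, 7))
})

test_that("fitted coefficients equal the normal-equations solution", {
  d <- mae_design_11()
  X <- ffd_model_matrix(d)
  set.seed(21)
  for (i in 1:20) {
    y <- stats::rnorm(11)
    expect_equal(coef(fit_ffd(d, y)), normal_eq_beta(X, y),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("coefficient estimates are unbiased under Gaussian noise", {
  d <- mae_design_11()
  X <- ffd_model_matrix(d)
  beta <- c(0.4, 0.3, -0.2, 0.1, 0.05, -0.05, 0.15, -0.1)
  mu <- drop(X %*% beta)
  sigma <- 0.05
  nsim <- 500
  set.seed(33)
  est <- matrix(0, nsim, 8)
  for (i in seq_len(nsim)) {
    est[i, ] <- coef(fit_ffd(d, mu + stats::rnorm(11, 0, sigma)))
  }
  # linear-term sd is sigma/sqrt(8); allow 3 standard errors of the mean
  expect_true(all(abs(colMeans(est) - beta)[2:4] <
                    3 * sigma / sqrt(8 * nsim) + 1e-12))
})

test_that("inference degrades gracefully when the design is saturated", {
  d8 <- build_full_factorial(mae_factors(), n_center = 0)
  fit <- fit_ffd(d8, stats::rnorm(8))
  expect_false(fit$inference)
  expect_true(all(is.na(fit$coefficients$p_value)))
  expect_error(fit_ffd(d8, stats::rnorm(7)), "does not match")
})

test_that("range scaling maps columns onto [0,1], preserves order, and is idempotent", {
  expect_equal(range_scale_responses(data.frame(a = c(2, 4, 6)))$a, c(0, 0.5, 1))
  set.seed(5)
  df <- as.data.frame(matrix(stats::rnorm(60), 10))
  sc <- range_scale_responses(df)
  expect_true(all(vapply(sc, min, numeric(1)) == 0))
  expect_true(all(vapply(sc, max, numeric(1)) == 1))
  for (j in seq_along(df)) expect_equal(order(sc[[j]]), order(df[[j]]))
  resc <- range_scale_responses(sc)
  for (j in seq_along(sc)) expect_equal(resc[[j]], sc[[j]])
  expect_error(range_scale_responses(data.frame(ok = 1:3, flat = rep(2, 3))),
               "flat")
})

test_that("significance table retains responses by model p and blanks ns entries", {
  d <- mae_design_11()
  X <- ffd_model_matrix(d)
  set.seed(8)
  # strong response, weak response, pure-noise response
  resp <- data.frame(
    strong = drop(X %*% c(0.5, 0.4, -0.3, 0.2, 0, 0, 0.25, 0)) + rnorm(11, 0, 0.01),
    noise1 = rnorm(11, 0.5, 0.05),
    noise2 = rnorm(11, 0.5, 0.05)
  )
  fits <- fit_ffd_all(d, resp)
  st <- significance_table(fits, keep_if_model_p = 0.05)
  # retained set equals the brute-force filter on p_model
  want <- names(fits)[vapply(fits, `[[`, numeric(1), "p_model") <= 0.05]
  expect_setequal(st$retained, want)
  expect_true("strong" %in% st$retained)
  # blanks exactly where tier is ns
  for (resp_nm in st$retained) {
    cf <- fits[[resp_nm]]$coefficients
    expect_equal(is.na(st$wide[cf$term, resp_nm]), cf$tier == "ns",
                 ignore_attr = TRUE)
  }
  expect_error(significance_table(list()), "empty")
})

test_that("coefficient tiers encode the 0.05/0.01 thresholds", {
  d <- mae_design_11()
  set.seed(9)
  fit <- fit_ffd(d, rnorm(11))
  cf <- fit$coefficients
  expect_true(all(cf$tier[cf$p_value < 0.01] == "p01"))
  expect_true(all(cf$tier[cf$p_value >= 0.01 & cf$p_value < 0.05] == "p05"))
  expect_true(all(cf$tier[cf$p_value >= 0.05] == "ns"))
})

test_that("significance table export writes wide and long formats", {
  d <- mae_design_11()
  X <- ffd_model_matrix(d)
  set.seed(10)
  fits <- fit_ffd_all(d, data.frame(
    a = drop(X %*% c(0.5, 0.4, 0, 0, 0, 0, 0, 0)) + rnorm(11, 0, 0.01)))
  st <- significance_table(fits)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_significance_table(st, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.tsv$", "_long.tsv", path)))
  wide <- utils::read.delim(path)
  expect_equal(nrow(wide), 8L)
})
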