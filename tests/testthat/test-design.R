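test_that("the MAE design has 11 runs and the documented factor mapping", {
  d <- mae_design_11()
  expect_equal(nrow(d), 11L)
  expect_equal(sum(d$is_center), 3L)
  centre <- d[d$is_center, ][1, ]
  expect_equal(centre$solvent_to_solid, 24)
  expect_equal(centre$time_min, 18)
  expect_equal(centre$temperature_C, 65)
})

test_that("corner enumeration matches a recursive cartesian-product oracle", {
  for (k in 1:5) {
    factors <- lapply(seq_len(k), function(j) factor_spec(paste0("f", j), 0, 1))
    d <- build_full_factorial(factors, n_center = 0)
    expect_equal(nrow(d), 2^k)
    got <- design_coded(d)
    want <- recursive_corners(k)
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(want, 1, paste, collapse = ","))
    expect_equal(anyDuplicated(apply(got, 1, paste, collapse = ",")), 0L)
    # documented Yates convention: the first factor alternates fastest
    expect_equal(unname(got[1:2, 1]), c(-1, 1))
  }
  # 2-factor corner set, explicitly
  d2 <- build_full_factorial(list(factor_spec("a", 0, 1), factor_spec("b", 0, 1)), 0)
  expect_setequal(apply(design_coded(d2), 1, paste, collapse = ","),
                  c("-1,-1", "-1,1", "1,-1", "1,1"))
})

test_that("coded/real conversion is affine, increasing, and round-trips", {
  f <- factor_spec("temperature_C", 50, 80, "degC")
  expect_equal(coded_to_real(-1, f), 50)
  expect_equal(coded_to_real(0, f), 65)
  expect_equal(coded_to_real(1, f), 80)
  set.seed(11)
  x <- stats::runif(100, -1, 1)
  expect_equal(real_to_coded(coded_to_real(x, f), f), x)
  expect_true(all(diff(coded_to_real(sort(x), f)) > 0))
  expect_warning(coded_to_real(1.5, f), "extrapolating")
})

test_that("invalid factor specs and designs are rejected", {
  expect_error(factor_spec("x", 5, 5), "strictly below")
  expect_error(build_full_factorial(list(factor_spec("a", 0, 1),
                                         factor_spec("a", 1, 2)), 0),
               "duplicate")
  d2 <- build_full_factorial(list(factor_spec("a", 0, 1),
                                  factor_spec("b", 0, 1)), 0)
  expect_error(ffd_model_matrix(d2), "exactly 3 factors")
})

test_that("the 8-term model matrix has the documented rows and exact orthogonality", {
  d <- mae_design_11()
  X <- ffd_model_matrix(d)
  expect_equal(colnames(X), c("b0", "b1", "b2", "b3", "b12", "b13", "b23", "b123"))
  corner_ppp <- which(apply(design_coded(d), 1, function(r) all(r == 1)))
  expect_equal(unname(X[corner_ppp, ]), rep(1, 8))
  centre <- which(d$is_center)[1]
  expect_equal(unname(X[centre, ]), c(1, rep(0, 7)))
  # (-1,+1,-1): interactions by direct sign multiplication
  row_mpm <- which(apply(design_coded(d), 1, function(r) all(r == c(-1, 1, -1))))
  expect_equal(unname(X[row_mpm, c("b12", "b13", "b23", "b123")]),
               c(-1, 1, -1, 1))
  # pairwise orthogonality over the 8 corners, exact in integer arithmetic
  Xc <- X[!d$is_center, -1]
  G <- t(Xc) %*% Xc
  expect_true(all(G[upper.tri(G)] == 0))
  expect_equal(qr(X)$rank, 8L)
})

test_that("reorder_to_match permutes corners to an external run listing", {
  d <- mae_design_11()
  perm <- c(8:1, 9:11)
  target <- design_coded(d)[perm, ]
  re <- reorder_to_match(d, target)
  expect_equal(design_coded(re), target, ignore_attr = TRUE)
  expect_setequal(re$run_id, d$run_id)
  expect_error(reorder_to_match(d, design_coded(d) * 2), "not a permutation")
})

test_that("design tables round-trip through delimited text", {
  d <- mae_design_11()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(design_coded(d2), design_coded(d), ignore_attr = TRUE)
  expect_equal(d2$solvent_to_solid, d$solvent_to_solid)
  f2 <- attr(d2, "factors")[[3]]
  expect_equal(c(f2$low, f2$high), c(50, 80))
})
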