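test_that("grid construction counts points and hits the range endpoints", {
  g40 <- build_grid(mae_factors(), 40)
  expect_equal(g40$n_points, 64000L)
  expect_equal(nrow(g40$real), 64000L)
  g2 <- build_grid(mae_factors(), 2)
  expect_equal(g2$n_points, 8L)
  expect_setequal(apply(g2$coded, 1, paste, collapse = ","),
                  apply(design_coded(build_full_factorial(mae_factors(), 0)),
                        1, paste, collapse = ","))
  for (f in mae_factors()) {
    lv <- g40$levels[[f$name]]
    expect_equal(range(lv), c(f$low, f$high))
    expect_true(all(abs(diff(diff(lv))) < 1e-12))  # uniform spacing
  }
  expect_error(build_grid(mae_factors(), 1), "n_levels")
})

test_that("surface evaluation matches term-by-term polynomial expansion", {
  d <- mae_design_11()
  beta1 <- c(0.2, 0.5, -0.3, 0.1, 0.25, -0.15, 0.05, 0.4)
  beta2 <- c(-1, 0.3, 0.2, -0.6, 0, 0.1, -0.2, 0)
  scores <- cbind(PC1 = drop(ffd_model_matrix(d) %*% beta1),
                  PC2 = drop(ffd_model_matrix(d) %*% beta2))
  s <- fit_pc_surfaces(d, scores)
  expect_equal(unname(s$PC1$coefficients), beta1, tolerance = 1e-10)
  expect_equal(unname(s$PC2$coefficients), beta2, tolerance = 1e-10)
  expect_equal(s$PC1$r2, 1)
  g <- build_grid(mae_factors(), 5)
  ev <- evaluate_surfaces(g, s)
  set.seed(60)
  for (i in sample(g$n_points, 10)) {
    x <- g$coded[i, ]
    hand <- beta1[1] + beta1[2] * x[1] + beta1[3] * x[2] + beta1[4] * x[3] +
      beta1[5] * x[1] * x[2] + beta1[6] * x[1] * x[3] +
      beta1[7] * x[2] * x[3] + beta1[8] * x[1] * x[2] * x[3]
    expect_equal(ev$PC1[i], unname(hand))
  }
  # flat second surface stays flat
  flat <- fit_pc_surfaces(d, cbind(PC1 = scores[, 1], PC2 = rep(2, 11)))
  evf <- evaluate_surfaces(g, flat)
  expect_equal(evf$PC2, rep(2, g$n_points))
})

test_that("misaligned scores are rejected", {
  d <- mae_design_11()
  expect_error(fit_pc_surfaces(d, matrix(0, 10, 2)), "align")
})

test_that("pareto front equals the brute-force dominance filter", {
  set.seed(61)
  P <- matrix(stats::rnorm(1000), ncol = 2)
  for (dirs in list(c("max", "max"), c("max", "min"),
                    c("min", "max"), c("min", "min"))) {
    expect_equal(pareto_front(P, dirs), brute_pareto(P, dirs),
                 label = paste(dirs, collapse = "/"))
  }
  # duplicated coordinates: all tied extreme points retained
  Q <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_equal(pareto_front(Q, c("max", "max")), c(1L, 2L))
})

test_that("pareto front handles degenerate inputs and total orders", {
  expect_equal(pareto_front(matrix(c(3, 7), 1), c("max", "max")), 1L)
  # increasing line, maximize both: single extreme point
  line <- cbind(1:10, 1:10)
  expect_equal(pareto_front(line, c("max", "max")), 10L)
  expect_error(pareto_front(matrix(numeric(0), 0, 2), c("max", "max")),
               "empty")
})

test_that("the front is invariant under positive objective scaling", {
  set.seed(62)
  P <- matrix(stats::rnorm(600), ncol = 2)
  f0 <- pareto_front(P, c("max", "min"))
  for (sc in list(c(2, 1), c(0.001, 500), c(7, 7))) {
    expect_equal(pareto_front(sweep(P, 2, sc, "*"), c("max", "min")), f0)
  }
})

test_that("monotone surfaces put the whole front on the all-high corner", {
  d <- mae_design_11()
  inc1 <- c(0, 1, 2, 3, 0, 0, 0, 0)   # strictly increasing in every factor
  inc2 <- c(5, 2, 1, 1, 0, 0, 0, 0)
  s <- fit_pc_surfaces(d, cbind(PC1 = drop(ffd_model_matrix(d) %*% inc1),
                                PC2 = drop(ffd_model_matrix(d) %*% inc2)))
  g <- build_grid(mae_factors(), 7)
  ev <- evaluate_surfaces(g, s)
  fr <- pareto_front(ev[c("PC1", "PC2")], c("max", "max"))
  expect_equal(length(fr), 1L)
  expect_equal(unlist(ev[fr, 1:3]),
               c(solvent_to_solid = 32, time_min = 30, temperature_C = 80))
})

test_that("front hypervolume does not shrink under grid refinement", {
  d <- mae_design_11()
  beta1 <- c(0, 1, 0.5, 0.2, 0.8, 0, 0, 0)
  beta2 <- c(0, -1, 0.4, -0.3, 0, 0.5, 0, 0)
  s <- fit_pc_surfaces(d, cbind(PC1 = drop(ffd_model_matrix(d) %*% beta1),
                                PC2 = drop(ffd_model_matrix(d) %*% beta2)))
  nadir <- c(-4, -4)  # fixed reference below every evaluated value
  hypervol <- function(n_levels) {
    ev <- evaluate_surfaces(build_grid(mae_factors(), n_levels), s)
    fr <- pareto_front(ev[c("PC1", "PC2")], c("max", "max"))
    pts <- unique(ev[fr, c("PC1", "PC2")])
    o <- order(pts$PC1)
    x <- pts$PC1[o]; y <- pts$PC2[o]   # x ascending => y non-increasing
    sum(diff(c(nadir[1], x)) * (y - nadir[2]))
  }
  hv <- vapply(c(3, 5, 9, 17), hypervol, numeric(1))
  expect_true(all(diff(hv) >= -1e-9))
})

test_that("compromise selection is symmetric and respects degenerate fronts", {
  # symmetric front: objectives swap under reflection -> compromise on axis
  t <- seq(0, 1, length.out = 101)
  ev <- data.frame(x = t, PC1 = 1 - t^2, PC2 = 1 - (1 - t)^2)
  fr <- pareto_front(ev[c("PC1", "PC2")], c("max", "max"))
  cp <- select_compromise(ev, fr, c("PC1", "PC2"), c("max", "max"))
  expect_equal(cp$setting$x, 0.5)
  # single-point front returned directly
  one <- data.frame(x = 1, PC1 = 2, PC2 = 3)
  cp1 <- select_compromise(one, 1L, c("PC1", "PC2"))
  expect_equal(cp1$index, 1L)
  expect_equal(cp1$distance, 0)
})

test_that("generator-driven optimization yields an interior compromise ratio", {
  # lyso-lipids and phospholipids pull the solvent-to-solid ratio in
  # opposite directions; under the trade-off orientation the compromise
  # must sit strictly inside the experimental range
  d <- mae_design_11()
  resp <- gen_ffd_responses(d, generator_config(seed = 17, noise_sd = 0.01))
  rep <- run_optimization(d, resp, grid_levels = 21,
                          directions = c("max", "min"))
  ratio <- rep$compromise$setting$solvent_to_solid
  expect_gt(ratio, 16)
  expect_lt(ratio, 32)
})
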