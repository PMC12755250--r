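test_that("standardize produces exact z-scores and preserves roles", {
  tab <- variable_table(cbind(a = c(1, 2, 3), b = c(10, 30, 20)),
                        roles = c(b = "outcome"))
  z <- standardize(tab)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_equal(variable_roles(z), c(a = "predictor", b = "outcome"))
})

test_that("standardize is idempotent", {
  set.seed(11)
  tab <- variable_table(matrix(rnorm(60, 5, 3), 20, 3,
                               dimnames = list(NULL, c("x", "y", "z"))))
  once <- standardize(tab)
  twice <- standardize(once)
  expect_lt(max(abs(unclass(twice) - unclass(once))), 1e-10)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(standardize(toy_table(u = c(5, 5, 5), v = 1:3)),
               "zero variance.*u")
  expect_error(variable_table(cbind(a = c(1, NA, 3))), "missing values")
  expect_error(variable_table(cbind(a = 1:3, a = 4:6)), "duplicate")
  expect_error(variable_table(cbind(a = 1:2)), "at least 3 samples")
  expect_error(variable_table(cbind(1:3, 4:6)), "non-empty names")
})

test_that("correlation matrix matches an explicit cross-product oracle", {
  set.seed(21)
  x <- rnorm(4); y <- 2 * x + rnorm(4); w <- rnorm(4)
  tab <- standardize(toy_table(x = x, y = y, w = w))
  r <- correlation_matrix(tab)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_identical(unclass(r), t(unclass(r)))
  for (a in colnames(tab)) for (b in colnames(tab))
    expect_equal(r[a, b], oracle_pearson(tab[, a], tab[, b]),
                 tolerance = 1e-12)
  neg <- correlation_matrix(toy_table(p = c(1, 2, 4), q = -c(1, 2, 4)))
  expect_equal(neg["p", "q"], -1)
})

test_that("clustering merges exactly the above-threshold groups", {
  # forced two-cluster case: only A,B are strongly correlated
  set.seed(5)
  a <- rnorm(200)
  tab <- standardize(toy_table(A = a, B = a + rnorm(200, 0, 0.4),
                               C = rnorm(200)))
  r <- correlation_matrix(tab)
  cl <- cluster_variables(r, 0.7)
  expect_setequal(lapply(cl$clusters, sort), list(c("A", "B"), "C"))
  # everything strongly correlated: one cluster
  r_all <- structure(matrix(0.95, 3, 3, dimnames = list(c("A", "B", "C"),
                                                        c("A", "B", "C"))),
                     class = c("correlation_matrix", "matrix"))
  diag(r_all) <- 1
  expect_length(cluster_variables(r_all, 0.7)$clusters, 1L)
  expect_error(cluster_variables(r, 1.2), "threshold")
  expect_error(cluster_variables(r, 0), "threshold")
})

test_that("block-structured data clusters like the brute-force merge oracle", {
  tab <- make_correlated_blocks(c(3, 3), within_r = 0.8, between_r = 0.1,
                                n = 2000, seed = 42)
  r <- correlation_matrix(tab)
  cl <- cluster_variables(r, 0.7)
  got <- unname(lapply(cl$clusters, sort))
  want <- oracle_avg_linkage(r, cut = 1 - 0.7)
  expect_setequal(got, want)
  expect_setequal(got, list(c("B1V1", "B1V2", "B1V3"),
                            c("B2V1", "B2V2", "B2V3")))
})

test_that("a threshold near one leaves every variable a singleton", {
  tab <- make_correlated_blocks(c(2, 2), within_r = 0.9, n = 500, seed = 3)
  cl <- cluster_variables(correlation_matrix(tab), 0.999)
  expect_length(cl$clusters, 4L)
  expect_true(all(lengths(cl$clusters) == 1L))
})

test_that("PCA aggregation: singletons pass through, pairs follow (1+|r|)/2", {
  set.seed(9)
  x <- rnorm(500)
  tab <- standardize(toy_table(P = x, Q = x + rnorm(500, 0, 0.5),
                               Drug = rnorm(500)))
  cl <- list(clusters = list(F1 = c("P", "Q"), Drug = "Drug"))
  agg <- pca_aggregate(tab, cl)
  expect_equal(unname(agg$factors[, "Drug"]), unname(tab[, "Drug"]))
  expect_equal(unname(agg$variance_explained["Drug"]), 1)
  r <- correlation_matrix(tab)["P", "Q"]
  expect_equal(unname(agg$variance_explained["F1"]), (1 + abs(r)) / 2,
               tolerance = 1e-9)
  expect_lt(abs(mean(agg$factors[, "F1"])), 1e-10)
  expect_error(pca_aggregate(tab, list(clusters = list(F1 = c("P", "nope")))),
               "unknown variable")
})

test_that("variance explained of an equicorrelated block approaches its eigenvalue", {
  tab <- make_correlated_blocks(5, within_r = 0.6, n = 50000, seed = 77)
  cl <- cluster_variables(correlation_matrix(tab), 0.5)
  expect_length(cl$clusters, 1L)
  agg <- pca_aggregate(tab, cl)
  # analytic leading eigenvalue of a 5-var equicorrelated block: 1 + 4*rho
  expect_equal(unname(agg$variance_explained), (1 + 4 * 0.6) / 5,
               tolerance = 0.02)
})

test_that("flipping every variable in a cluster flips the factor sign", {
  set.seed(13)
  x <- rnorm(300)
  m <- cbind(U = x + rnorm(300, 0, 0.3), V = x + rnorm(300, 0, 0.3))
  tab <- standardize(variable_table(m))
  flipped <- standardize(variable_table(-m))
  cl <- list(clusters = list(F1 = c("U", "V")))
  f1 <- pca_aggregate(tab, cl)$factors[, "F1"]
  f2 <- pca_aggregate(flipped, cl)$factors[, "F1"]
  expect_equal(unname(f2), unname(-f1), tolerance = 1e-10)
})

test_that("LMG shares match the all-orderings oracle and sum to R^2", {
  set.seed(31)
  n <- 20
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- rnorm(n) - 0.3 * x2
  y <- 0.5 * x1 - 0.4 * x3 + rnorm(n)
  tab <- standardize(toy_table(x1 = x1, x2 = x2, x3 = x3, y = y))
  got <- lmg_importance(tab, "y", c("x1", "x2", "x3"))
  want <- oracle_lmg(tab, "y", c("x1", "x2", "x3"))
  expect_equal(got, want, tolerance = 1e-9)
  full_r2 <- 1 - oracle_rss(unclass(tab)[, c("x1", "x2", "x3")],
                            tab[, "y"]) /
    sum((tab[, "y"] - mean(tab[, "y"]))^2)
  expect_equal(unname(sum(got)), full_r2, tolerance = 1e-9)
})

test_that("LMG degenerates correctly for one or orthogonal predictors", {
  set.seed(41)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.4 * x1 + 0.2 * x2 + rnorm(n)
  tab <- standardize(toy_table(x1 = x1, x2 = x2, y = y))
  single <- lmg_importance(tab, "y", "x1")
  expect_equal(unname(single), cor(tab[, "x1"], tab[, "y"])^2,
               tolerance = 1e-9)
  # near-orthogonal predictors: shares approach the squared correlations
  both <- lmg_importance(tab, "y", c("x1", "x2"))
  expect_lt(abs(both["x1"] - cor(tab[, "x1"], tab[, "y"])^2), 0.01)
  expect_lt(abs(both["x2"] - cor(tab[, "x2"], tab[, "y"])^2), 0.01)
  expect_error(lmg_importance(tab, "y", c("y", "x1")), "outcome")
  big <- standardize(variable_table(
    matrix(rnorm(20 * 14), 20, 14,
           dimnames = list(NULL, c(paste0("p", 1:13), "out")))))
  expect_error(lmg_importance(big, "out", paste0("p", 1:13)), "12")
})
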