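test_that("identity input is a fixed point with an empty network", {
  f <- glasso_fit(diag(4), 0.2, n = 100)
  expect_equal(f$precision, diag(4), tolerance = 1e-10)
  expect_equal(f$edge_count, 0)
  expect_true(all(f$network$weights == 0))
})

test_that("penalties at or above max |S_ij| empty the network (verified optimum)", {
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  S3 <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3)
  for (S in list(S2, S3)) {
    lam <- max(abs(S[upper.tri(S)]))
    f <- glasso_fit(S, lam, n = 100)
    expect_equal(f$edge_count, 0)
    # independent first-order check that the diagonal solution is optimal
    expect_true(oracle_empty_is_optimal(S, lam))
    expect_true(oracle_empty_is_optimal(S, lam * 1.5))
  }
})

test_that("glasso matches direct numerical maximization for p = 2 and 3", {
  cfg <- glasso_config(convergence_tol = 1e-8)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  f2 <- glasso_fit(S2, 0.1, n = 100, config = cfg)
  o2 <- oracle_glasso(S2, 0.1)
  expect_lt(max(abs(f2$network$weights - o2$partials)), 1e-5)
  # p = 2 closed form: the covariance off-diagonal soft-thresholds
  expect_equal(f2$network$weights[1, 2], 0.5 - 0.1, tolerance = 1e-7)

  S3 <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3)
  f3 <- glasso_fit(S3, 0.05, n = 100, config = cfg)
  o3 <- oracle_glasso(S3, 0.05)
  expect_lt(max(abs(f3$network$weights - o3$partials)), 1e-5)
  expect_lt(max(abs(f3$precision - o3$precision)), 1e-5)
})

test_that("lambda path is log-spaced, descending, with documented endpoints", {
  S <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.1, 0.2, 0.1, 1), 3)
  expect_equal(lambda_path(S, glasso_config(n_lambdas = 1)), 0.5)
  path <- lambda_path(S, glasso_config(n_lambdas = 3,
                                       lambda_min_ratio = 0.01))
  expect_equal(path, c(0.5, 0.05, 0.005), tolerance = 1e-12)
  long <- lambda_path(S, glasso_config())
  expect_length(long, 100)
  expect_true(all(diff(long) < 0))
  expect_warning(p0 <- lambda_path(diag(3)), "zero")
  expect_equal(p0, 0)
})

test_that("EBIC arithmetic matches the closed formula", {
  expect_equal(ebic_score(-100, 3, 100, 10, 0.5),
               200 + 3 * log(100) + 6 * log(10))
  expect_equal(round(ebic_score(-100, 3, 100, 10, 0.5), 3), 227.631)
})

test_that("selection scans the whole path and prefers sparsity on ties", {
  d <- tiny_dataset(n = 60, seed = 2, p_dep = 3, p_anx = 2, p_ptsd = 3)
  fit <- select_network(d, config = glasso_config(n_lambdas = 25))
  # independent re-computation of the EBIC minimum from the stored path
  refit <- lapply(fit$path_lambdas, function(l)
    glasso_fit(correlation_matrix(d), l,
               config = glasso_config(n_lambdas = 25)))
  ebics <- vapply(refit, `[[`, numeric(1), "ebic")
  expect_equal(ebics, fit$path_ebics, tolerance = 1e-8)
  expect_equal(fit$ebic, min(ebics))
  expect_equal(fit$lambda, fit$path_lambdas[which.min(ebics)])
  # ties (plateaus of identical EBIC) resolve to the largest lambda
  expect_true(which.min(ebics) == Position(function(e)
    isTRUE(all.equal(e, min(ebics))), ebics))
})

test_that("independent data select an empty network", {
  items <- phq_gad_tsq_items(3, 2, 3)
  set.seed(5)
  x <- vapply(seq_len(8), function(j)
    sample(0L:items$level_max[j], 4000, replace = TRUE), integer(4000))
  colnames(x) <- items$name
  fit <- select_network(symptom_dataset(x, rep("g", 4000), items))
  expect_equal(fit$edge_count, 0)
})

test_that("edge count is non-increasing along the descending lambda path", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  d <- sample_group(group_sim_spec("g", 1500, tn, seed = 4))
  S <- correlation_matrix(d)
  lams <- lambda_path(S, glasso_config(n_lambdas = 30))
  counts <- vapply(lams, function(l)
    glasso_fit(S, l)$edge_count, numeric(1))
  expect_true(all(diff(counts) >= 0))  # descending lambda, growing edges
})

test_that("unpenalized partials equal the regression-based definition", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  d <- sample_group(group_sim_spec("g", 3000, tn, seed = 9))
  S <- correlation_matrix(d)
  f0 <- glasso_fit(S, 0)
  x <- scale(d$scores)
  # partial correlation of (i, j) = correlation of residuals from
  # regressing each on all remaining variables
  for (pair in list(c(1, 2), c(3, 8), c(5, 6))) {
    i <- pair[1]; j <- pair[2]
    ri <- lm.fit(x[, -c(i, j), drop = FALSE], x[, i])$residuals
    rj <- lm.fit(x[, -c(i, j), drop = FALSE], x[, j])$residuals
    expect_equal(f0$network$weights[i, j], cor(ri, rj), tolerance = 1e-6)
  }
})

test_that("global strength sums absolute upper-triangle weights", {
  expect_equal(global_strength(symptom_network(matrix(0, 3, 3))), 0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[1, 3] <- w[3, 1] <- -0.2
  net <- symptom_network(w, c("a", "b", "c"))
  expect_equal(global_strength(net), 0.5)
  perm <- c(3, 1, 2)
  net_p <- symptom_network(w[perm, perm], c("c", "a", "b"))
  expect_equal(global_strength(net_p), global_strength(net))
})

test_that("solver failure surfaces as a numerical error with diagnostics", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_error(glasso_fit(S, 0.1, n = 100,
                          config = glasso_config(max_iter = 1,
                                                 convergence_tol = 1e-14)),
               "converge", class = "sn_numerical_error")
  # singular S cannot be inverted unpenalized
  Ssing <- matrix(1, 3, 3)
  expect_error(glasso_fit(Ssing, 0, n = 10), class = "sn_numerical_error")
})
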