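# a stub estimator returning a fixed network regardless of the data
stub_estimator <- function(net) function(data) net

test_that("a constant estimator yields zero-width intervals", {
  d <- tiny_dataset(n = 120, seed = 3, p_dep = 2, p_anx = 2, p_ptsd = 2)
  w <- matrix(0, 6, 6, dimnames = list(d$items$name, d$items$name))
  w[1, 2] <- w[2, 1] <- 0.3
  bs <- bootstrap_edges(d, stub_estimator(symptom_network(w)),
                        bootstrap_config(n_boot = 25, seed = 1))
  expect_true(all(bs$summary$ci_upper - bs$summary$ci_lower == 0))
  expect_equal(bs$summary$estimate[bs$summary$edge == "PHQ.1--PHQ.2"], 0.3)
})

test_that("a single replicate's CI collapses to that replicate's value", {
  tn <- make_true_network(2, 2, 2, density = 1, seed = 1)
  d <- sample_group(group_sim_spec("g", 400, tn, seed = 2))
  est <- ebicglasso_estimator(lambda = 0)
  bs <- bootstrap_edges(d, est, bootstrap_config(n_boot = 1, seed = 5),
                        centrality_indices = character(0))
  expect_equal(bs$summary$ci_lower, unname(bs$edge_draws[1, ]))
  expect_equal(bs$summary$ci_upper, unname(bs$edge_draws[1, ]))
})

test_that("bootstrap draws are reproducible bit-for-bit under one seed", {
  tn <- make_true_network(2, 2, 2, density = 1, seed = 1)
  d <- sample_group(group_sim_spec("g", 300, tn, seed = 2))
  est <- ebicglasso_estimator(config = glasso_config(n_lambdas = 15))
  b1 <- bootstrap_edges(d, est, bootstrap_config(n_boot = 30, seed = 7))
  b2 <- bootstrap_edges(d, est, bootstrap_config(n_boot = 30, seed = 7))
  expect_identical(b1$edge_draws, b2$edge_draws)
  expect_identical(b1$summary, b2$summary)
})

test_that("percentile CIs cover a known partial correlation near nominal rate", {
  # three ordinal items, latent partial 0.3 on the first pair; the
  # estimator is the unpenalized partial-correlation network, whose
  # population target under discretization is computed once by a
  # large-sample Monte-Carlo oracle
  items <- phq_gad_tsq_items(3, 0, 0)
  part <- matrix(0, 3, 3)
  part[1, 2] <- part[2, 1] <- 0.3
  tn <- true_network_spec(part, items = items)
  big <- sample_group(group_sim_spec("g", 400000, tn, seed = 99))
  Sbig <- cor(big$scores)
  Kbig <- solve(Sbig)
  target <- -Kbig[1, 2] / sqrt(Kbig[1, 1] * Kbig[2, 2])

  est <- ebicglasso_estimator(lambda = 0)
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    d <- sample_group(group_sim_spec("g", 3000, tn, seed = 1000 + r))
    bs <- bootstrap_edges(d, est,
                          bootstrap_config(n_boot = 500, seed = r),
                          centrality_indices = character(0))
    row <- bs$summary[bs$summary$edge == "PHQ.1--PHQ.2", ]
    hits <- hits + (row$ci_lower <= target && target <= row$ci_upper)
  }
  se3 <- 3 * sqrt(0.95 * 0.05 / n_rep)
  expect_gte(hits / n_rep, 0.95 - se3)
})

test_that("edge difference tests separate a real gap and respect symmetry", {
  # two true edges, 0.4 versus 0.05
  items <- phq_gad_tsq_items(4, 0, 0)
  part <- matrix(0, 4, 4)
  part[1, 2] <- part[2, 1] <- 0.4
  part[3, 4] <- part[4, 3] <- 0.05
  tn <- true_network_spec(part, items = items)
  d <- sample_group(group_sim_spec("g", 3000, tn, seed = 17))
  bs <- bootstrap_edges(d, ebicglasso_estimator(lambda = 0),
                        bootstrap_config(n_boot = 300, seed = 2),
                        centrality_indices = "expected_influence")
  expect_true(edge_difference_test(bs, "PHQ.1--PHQ.2", "PHQ.3--PHQ.4"))
  expect_identical(edge_difference_test(bs, "PHQ.1--PHQ.2", "PHQ.3--PHQ.4"),
                   edge_difference_test(bs, "PHQ.3--PHQ.4", "PHQ.1--PHQ.2"))
  expect_error(edge_difference_test(bs, "PHQ.1--PHQ.2", "PHQ.1--PHQ.2"),
               class = "sn_usage_error")
  expect_error(edge_difference_test(bs, "PHQ.1--PHQ.2", "no--edge"),
               class = "sn_usage_error")
  # centrality difference machinery on the same draws
  expect_true(centrality_difference_test(bs, "PHQ.1", "PHQ.3",
                                         "expected_influence"))
  expect_error(centrality_difference_test(bs, "PHQ.1", "PHQ.1"),
               class = "sn_usage_error")
})

test_that("identical draws for two edges are never declared different", {
  d <- tiny_dataset(n = 80, seed = 5, p_dep = 2, p_anx = 2, p_ptsd = 2)
  w <- matrix(0, 6, 6, dimnames = list(d$items$name, d$items$name))
  w[1, 2] <- w[2, 1] <- 0.2
  w[3, 4] <- w[4, 3] <- 0.2
  bs <- suppressWarnings(   # n below the advisory floor is intentional
    bootstrap_edges(d, stub_estimator(symptom_network(w)),
                    bootstrap_config(n_boot = 20, seed = 3)))
  expect_false(edge_difference_test(bs, "PHQ.1--PHQ.2", "GAD.1--GAD.2"))
})

test_that("duplicated-row stability yields perfect correlation at the first step", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  d0 <- sample_group(group_sim_spec("g", 150, tn, seed = 1))
  # duplicate every row so any large subsample carries the same signal
  d <- symptom_dataset(d0$scores[rep(seq_len(150), 4), ],
                       rep("g", 600), d0$items)
  cfg <- bootstrap_config(n_boot = 15, seed = 2, drop_proportions = 0.05)
  st <- case_dropping_stability(d, ebicglasso_estimator(lambda = 0.05),
                                indices = "strength", config = cfg)
  expect_equal(unname(st$cs["strength"]), 0.05)
  expect_true(all(st$curve$strength > 0.97))
})

test_that("the CS-coefficient is monotone in the correlation threshold", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  d <- sample_group(group_sim_spec("g", 900, tn, seed = 4))
  est <- ebicglasso_estimator(config = glasso_config(n_lambdas = 15))
  cs_at <- function(r) {
    cfg <- bootstrap_config(n_boot = 40, seed = 6,
                            stability_correlation = r)
    case_dropping_stability(d, est, "strength", cfg)$cs[["strength"]]
  }
  cs <- vapply(c(0.5, 0.7, 0.9), cs_at, numeric(1))
  expect_true(all(diff(cs) <= 0))
})

test_that("deep drop proportions below p + 1 cases are skipped with a warning", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  d <- sample_group(group_sim_spec("g", 30, tn, seed = 4))
  cfg <- bootstrap_config(n_boot = 5, seed = 1,
                          drop_proportions = c(0.1, 0.8))
  expect_warning(
    st <- case_dropping_stability(d, ebicglasso_estimator(lambda = 0.1),
                                  "strength", cfg),
    "skipping")
  expect_equal(st$curve$proportion, 0.1)
})
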