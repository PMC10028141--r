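test_that("true networks are symmetric with a PD precision and exact round-trip", {
  tn <- make_true_network(9, 7, 10, 0.3, 0.1, 0.2, seed = 1)
  expect_equal(length(tn$nodes), 26)
  expect_identical(tn$partials, t(tn$partials))
  ev <- eigen(tn$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # precision -> partial -> precision algebraic round-trip
  expect_lt(max(abs(precision_to_partials(tn$precision) - tn$partials)),
            1e-10)
  K2 <- diag(26) - tn$partials
  expect_lt(max(abs(K2 - tn$precision)), 1e-10)
})

test_that("zero weights produce an empty true network", {
  tn <- make_true_network(9, 7, 10, within_weight = 0,
                          bridge_weight = 0, density = 1)
  expect_true(all(tn$partials == 0))
})

test_that("group sampling is deterministic, in range, and size-checked", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  expect_error(group_sim_spec("g", 0, tn), "size")
  d1 <- sample_group(group_sim_spec("g", 1, tn, seed = 5))
  expect_equal(d1$n, 1)
  d <- sample_group(group_sim_spec("g", 200, tn, seed = 5))
  d2 <- sample_group(group_sim_spec("g", 200, tn, seed = 5))
  expect_identical(d$scores, d2$scores)
  for (j in seq_len(d$p)) {
    expect_true(all(d$scores[, j] >= d$items$level_min[j]))
    expect_true(all(d$scores[, j] <= d$items$level_max[j]))
  }
})

test_that("extreme low cut-points saturate ordinal items at the maximum", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  thr <- lapply(seq_len(8), function(j)
    if (tn$items$level_max[j] == 1L) -10 else c(-12, -11, -10))
  d <- sample_group(group_sim_spec("g", 50, tn, thr, seed = 1))
  expect_true(all(d$scores == rep(tn$items$level_max, each = 50)))
})

test_that("a single latent edge of 0.4 survives discretization clearly", {
  # two ordinal items with partial (= marginal) correlation 0.4; the
  # Pearson correlation of the discretized scores attenuates but stays
  # well above 0.2 at n = 5000
  items <- phq_gad_tsq_items(2, 2, 2)
  part <- matrix(0, 6, 6)
  part[1, 2] <- part[2, 1] <- 0.4
  tn <- true_network_spec(part, items = items)
  d <- sample_group(group_sim_spec("g", 5000, tn, seed = 3))
  expect_gt(cor(d$scores[, 1], d$scores[, 2]), 0.2)
})

test_that("marginal level frequencies match the normal orthant probabilities", {
  tn <- make_true_network(3, 2, 3, density = 0.6, seed = 2)
  thr <- default_group_thresholds(tn$items, 11.25, 8.54, 6.10)
  n <- 50000
  d <- sample_group(group_sim_spec("g", n, tn, thr, seed = 8))
  for (j in c(1, 4, 7)) {  # one item per instrument
    cuts <- thr[[j]]
    probs <- diff(c(0, pnorm(cuts), 1))
    obs <- tabulate(d$scores[, j] + 1L, nbins = length(probs)) / n
    se <- sqrt(probs * (1 - probs) / n)
    expect_true(all(abs(obs - probs) <= 3 * se + 1e-12),
                label = sprintf("item %d within 3 MC SEs", j))
  }
})

test_that("three-group study differs from base in exactly the overridden edges", {
  base <- make_true_network()
  st <- make_three_group_study(sizes = c(EA = 30, PA = 30, SA = 30),
                               seed = 1)
  pert <- default_study_perturbations()
  for (g in c("EA", "PA", "SA")) {
    dif <- st$networks[[g]]$partials - base$partials
    idx <- which(dif != 0 & upper.tri(dif), arr.ind = TRUE)
    a <- rownames(dif)[idx[, 1]]; b <- colnames(dif)[idx[, 2]]
    got <- sort(paste(pmin(a, b), pmax(a, b)))
    want <- sort(paste(pmin(pert[[g]]$from, pert[[g]]$to),
                       pmax(pert[[g]]$from, pert[[g]]$to)))
    expect_identical(got, want, label = g)
    expect_equal(unique(dif[idx]), 0.25)
  }
})

test_that("a null study shares one true network across all groups", {
  st <- make_three_group_study(perturbations = list(),
                               sizes = c(EA = 20, PA = 20, SA = 20),
                               seed = 1)
  expect_identical(st$networks$EA$partials, st$networks$SA$partials)
})

test_that("the default study reproduces byte-identical CSV under one seed", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(make_three_group_study(sizes = c(EA = 40, PA = 40, SA = 60),
                                       seed = 12)$data, f1)
  write_dataset(make_three_group_study(sizes = c(EA = 40, PA = 40, SA = 60),
                                       seed = 12)$data, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("perturbations on the diagonal or unknown nodes are rejected", {
  base <- make_true_network()
  expect_error(
    make_three_group_study(
      perturbations = list(EA = data.frame(from = "PHQ.1", to = "PHQ.1",
                                           delta = 0.1)),
      sizes = c(EA = 10, PA = 10, SA = 10)),
    class = "sn_validation_error")
  expect_error(
    make_three_group_study(
      perturbations = list(EA = data.frame(from = "PHQ.1", to = "XX",
                                           delta = 0.1)),
      sizes = c(EA = 10, PA = 10, SA = 10)),
    class = "sn_schema_error")
})

test_that("simulated sum-score means track the calibration targets", {
  st <- make_three_group_study(sizes = c(EA = 2000, PA = 2000, SA = 2000),
                               seed = 3)
  phq <- rowSums(st$data$scores[, 1:9])
  means <- tapply(phq, st$data$group, mean)
  expect_equal(unname(means[["EA"]]), 11.25, tolerance = 0.05)
  expect_equal(unname(means[["SA"]]), 6.91, tolerance = 0.05)
})
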