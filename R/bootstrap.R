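#' A network estimator closure for resampling and comparison routines
#'
#' Returns a function mapping a [symptom_dataset()] to a
#' [symptom_network()] by EBIC-glasso on the chosen correlation input.
#' The bootstrap and NCT machinery accept any such closure, which keeps
#' them testable with stub estimators.
#'
#' @param method correlation method passed to [correlation_matrix()].
#' @param config a [glasso_config()].
#' @param lambda if non-`NULL`, skip EBIC selection and fit at this fixed
#'   penalty (`0` gives the unregularized partial-correlation network).
#' @return A function `function(data) -> symptom_network`.
#' @export
ebicglasso_estimator <- function(method = "pearson",
                                 config = glasso_config(),
                                 lambda = NULL) {
  force(method); force(config); force(lambda)
  function(data) {
    if (is.null(lambda)) {
      select_network(data, method = method, config = config)$network
    } else {
      glasso_fit(correlation_matrix(data, method = method), lambda,
                 config = config)$network
    }
  }
}

#' Bootstrap and stability configuration
#'
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci_level confidence level for quantile intervals (default 0.95).
#' @param seed master RNG seed; per-replicate substreams are derived from
#'   it, so serial and parallel execution agree.
#' @param drop_proportions case-dropping grid; default 10 equal steps
#'   from 0.05 to 0.75.
#' @param stability_correlation correlation threshold `r` of the
#'   CS-coefficient (default 0.7).
#' @param stability_probability probability threshold `q` of the
#'   CS-coefficient (default 0.95).
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, ci_level = 0.95, seed = 1L,
                             drop_proportions = seq(0.05, 0.75,
                                                    length.out = 10),
                             stability_correlation = 0.7,
                             stability_probability = 0.95) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1,
            all(drop_proportions > 0), all(drop_proportions < 1),
            !is.unsorted(drop_proportions, strictly = TRUE))
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed),
                 drop_proportions = drop_proportions,
                 stability_correlation = stability_correlation,
                 stability_probability = stability_probability),
            class = "bootstrap_config")
}

edge_names <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste0(nodes[idx[, 1]], "--", nodes[idx[, 2]])
}

net_edge_vector <- function(net) {
  w <- net$weights
  setNames(w[upper.tri(w)], edge_names(net$nodes))
}

#' Non-parametric bootstrap of edge weights and centralities
#'
#' Resamples respondents with replacement at full `n`, re-runs the whole
#' estimation pipeline per replicate and summarizes per-edge quantile
#' confidence intervals.  Per-replicate centrality vectors are kept so
#' that bootstrapped difference tests for edges and centralities can be
#' read off the same draws.  Replicates whose estimation fails are
#' dropped and counted; more than 5% failures is an error.
#'
#' @param data a [symptom_dataset()].
#' @param estimator a `function(data) -> symptom_network`, e.g.
#'   [ebicglasso_estimator()].
#' @param config a [bootstrap_config()].
#' @param centrality_indices which centrality indices to track.
#' @return An object of class `bootstrap_summary` with the observed
#'   network, per-edge draws and CI table, per-node centrality draws and
#'   the failed-replicate count.
#' @export
bootstrap_edges <- function(data, estimator = ebicglasso_estimator(),
                            config = bootstrap_config(),
                            centrality_indices = c("strength",
                                                   "expected_influence")) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (data$n < 100)
    warning(sprintf("n = %d is small for bootstrap inference", data$n))
  observed <- estimator(data)
  obs_edges <- net_edge_vector(observed)
  seeds <- derive_seeds(config$seed, config$n_boot)
  draws <- matrix(NA_real_, config$n_boot, length(obs_edges),
                  dimnames = list(NULL, names(obs_edges)))
  cent_draws <- lapply(centrality_indices, function(i)
    matrix(NA_real_, config$n_boot, length(observed$nodes),
           dimnames = list(NULL, observed$nodes)))
  names(cent_draws) <- centrality_indices
  failed <- 0L
  for (b in seq_len(config$n_boot)) {
    idx <- with_seed(seeds[b], sample.int(data$n, data$n, replace = TRUE))
    net <- tryCatch(estimator(subset_dataset(data, rows = idx)),
                    error = function(e) NULL)
    if (is.null(net)) { failed <- failed + 1L; next }
    draws[b, ] <- net_edge_vector(net)
    if (length(centrality_indices)) {
      ct <- centrality_table(net)
      for (i in centrality_indices) cent_draws[[i]][b, ] <- ct[[i]]
    }
  }
  if (failed > 0.05 * config$n_boot)
    sn_stop("sn_numerical_error",
            "%d of %d bootstrap replicates failed", failed, config$n_boot)
  ok <- !apply(is.na(draws), 1, all)
  alpha <- (1 - config$ci_level) / 2
  ci <- t(apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = c(alpha, 1 - alpha)))
  summary <- data.frame(edge = names(obs_edges), estimate = obs_edges,
                        boot_mean = colMeans(draws[ok, , drop = FALSE]),
                        ci_lower = ci[, 1], ci_upper = ci[, 2],
                        row.names = NULL)
  structure(list(observed = observed, summary = summary,
                 edge_draws = draws[ok, , drop = FALSE],
                 centrality_draws = lapply(cent_draws, function(m)
                   m[ok, , drop = FALSE]),
                 failed = failed, config = config),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary: %d edges, %d replicates (%d failed)\n",
              ncol(x$edge_draws), nrow(x$edge_draws), x$failed))
  invisible(x)
}

#' Bootstrapped difference test between two edge weights
#'
#' Significant iff the quantile interval (at the bootstrap's CI level) of
#' the per-replicate difference excludes zero.
#'
#' @param bs a [bootstrap_edges()] result.
#' @param edge_a,edge_b edge names of the form `"PHQ.1--PHQ.2"`.
#' @return Logical flag.
#' @export
edge_difference_test <- function(bs, edge_a, edge_b) {
  stopifnot(inherits(bs, "bootstrap_summary"))
  if (identical(edge_a, edge_b))
    sn_stop("sn_usage_error", "cannot compare an edge with itself")
  for (e in c(edge_a, edge_b)) if (!e %in% colnames(bs$edge_draws))
    sn_stop("sn_usage_error", "edge '%s' not tracked in the bootstrap", e)
  diff <- bs$edge_draws[, edge_a] - bs$edge_draws[, edge_b]
  alpha <- (1 - bs$config$ci_level) / 2
  ci <- quantile(diff, c(alpha, 1 - alpha))
  ci[1] > 0 || ci[2] < 0
}

#' Bootstrapped difference test between two nodes' centralities
#'
#' @param bs a [bootstrap_edges()] result tracking `index`.
#' @param node_a,node_b node names.
#' @param index tracked centrality index.
#' @return Logical flag.
#' @export
centrality_difference_test <- function(bs, node_a, node_b,
                                       index = "expected_influence") {
  stopifnot(inherits(bs, "bootstrap_summary"))
  if (identical(node_a, node_b))
    sn_stop("sn_usage_error", "cannot compare a node with itself")
  cd <- bs$centrality_draws[[index]]
  if (is.null(cd))
    sn_stop("sn_usage_error", "index '%s' not tracked in the bootstrap",
            index)
  diff <- cd[, node_a] - cd[, node_b]
  alpha <- (1 - bs$config$ci_level) / 2
  ci <- quantile(diff, c(alpha, 1 - alpha))
  ci[1] > 0 || ci[2] < 0
}

#' Case-dropping bootstrap and the correlation-stability coefficient
#'
#' For each drop proportion `d`, draws `n_boot` subsamples of size
#' `round((1 - d) n)` without replacement, re-estimates the network and
#' correlates (Pearson, across nodes) each subsample's centrality vector
#' with the full-sample one.  The CS-coefficient is the largest `d` on
#' the grid at which at least `stability_probability` of subsamples reach
#' a correlation of `stability_correlation` or more (0 if none does).
#' Proportions leaving fewer than `p + 1` cases are skipped with a
#' warning.
#'
#' @param data a [symptom_dataset()].
#' @param estimator a `function(data) -> symptom_network`.
#' @param indices centrality indices to track.
#' @param config a [bootstrap_config()].
#' @return An object of class `stability_result` with elements `curve`
#'   (mean correlation per proportion and index), `prop_above` (fraction
#'   of subsamples at or above the correlation threshold), `cs` (named
#'   CS-coefficient per index) and `dropped_replicates`.
#' @export
case_dropping_stability <- function(data,
                                    estimator = ebicglasso_estimator(),
                                    indices = c("strength",
                                                "expected_influence"),
                                    config = bootstrap_config()) {
  stopifnot(inherits(data, "symptom_dataset"))
  full <- centrality_table(estimator(data))
  props <- config$drop_proportions
  keep_n <- round((1 - props) * data$n)
  usable <- keep_n >= data$p + 1
  if (any(!usable))
    warning(sprintf("skipping %d drop proportions leaving < p + 1 cases",
                    sum(!usable)))
  props <- props[usable]
  keep_n <- keep_n[usable]
  seeds <- derive_seeds(config$seed, length(props) * config$n_boot)
  cors <- array(NA_real_, c(length(props), config$n_boot, length(indices)),
                dimnames = list(NULL, NULL, indices))
  dropped <- 0L
  for (di in seq_along(props)) {
    for (b in seq_len(config$n_boot)) {
      sd_ <- seeds[(di - 1L) * config$n_boot + b]
      idx <- with_seed(sd_, sample.int(data$n, keep_n[di]))
      ct <- tryCatch(centrality_table(
        estimator(subset_dataset(data, rows = idx))),
        error = function(e) NULL)
      if (is.null(ct)) { dropped <- dropped + 1L; next }
      for (ii in seq_along(indices)) {
        a <- full[[indices[ii]]]; b2 <- ct[[indices[ii]]]
        if (sd(a) == 0 || sd(b2) == 0) { dropped <- dropped + 1L; next }
        cors[di, b, ii] <- cor(a, b2)
      }
    }
  }
  curve <- apply(cors, c(1, 3), mean, na.rm = TRUE)
  prop_above <- apply(cors >= config$stability_correlation, c(1, 3),
                      mean, na.rm = TRUE)
  cs <- vapply(seq_along(indices), function(ii) {
    ok <- which(prop_above[, ii] >= config$stability_probability)
    if (length(ok)) max(props[ok]) else 0
  }, numeric(1))
  names(cs) <- indices
  structure(list(curve = data.frame(proportion = props, curve),
                 prop_above = data.frame(proportion = props, prop_above),
                 cs = cs, dropped_replicates = dropped, config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("case-dropping stability (CS-coefficient):\n")
  print(round(x$cs, 3))
  invisible(x)
}
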