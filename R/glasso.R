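#' Configuration of the EBIC-glasso estimator
#'
#' @param n_lambdas number of penalty values on the path (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest penalty
#'   (default 0.01).
#' @param gamma EBIC hyperparameter trading likelihood against sparsity;
#'   0.5 is the field's default, 0 recovers ordinary BIC.
#' @param penalize_diagonal whether the L1 penalty also covers the
#'   precision diagonal (default `FALSE`, matching common EBIC-glasso
#'   practice).
#' @param convergence_tol solver convergence tolerance: a sweep ends the
#'   optimization when no parameter moved by more than this.
#' @param max_iter maximum solver sweeps.
#' @return A list of class `glasso_config`.
#' @export
glasso_config <- function(n_lambdas = 100L, lambda_min_ratio = 0.01,
                          gamma = 0.5, penalize_diagonal = FALSE,
                          convergence_tol = 1e-6, max_iter = 10000L) {
  stopifnot(n_lambdas >= 1, lambda_min_ratio > 0, lambda_min_ratio <= 1,
            gamma >= 0, convergence_tol > 0, max_iter >= 1)
  structure(list(n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio, gamma = gamma,
                 penalize_diagonal = isTRUE(penalize_diagonal),
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter)),
            class = "glasso_config")
}

as_assoc_values <- function(S) {
  if (inherits(S, "association_matrix")) S$values else as.matrix(S)
}

# weights below this magnitude are coordinate-descent dust, treated as
# structural zeros when counting edges
ZERO_TOL <- 1e-7

ggm_fit_from_theta <- function(theta, S, lambda, n, config, nodes,
                               method = NA_character_) {
  part <- precision_to_partials(theta)
  part[abs(part) < ZERO_TOL] <- 0
  E <- sum(part[upper.tri(part)] != 0)
  # Gaussian log-likelihood term, additive constants dropped: EBIC values
  # are comparable only across fits to the same data
  ld <- determinant(theta, logarithm = TRUE)
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
  ebic <- ebic_score(ll, E, n, nrow(S), config$gamma)
  net <- symptom_network(part, nodes,
                         metadata = list(estimator = "glasso",
                                         method = method, lambda = lambda,
                                         gamma = config$gamma, n = n))
  structure(list(precision = theta, network = net, lambda = lambda,
                 loglik = ll, edge_count = E, ebic = ebic, n = n,
                 gamma = config$gamma),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "ggm_fit: %d nodes, %d edges, lambda = %.4g, EBIC = %.2f\n",
    length(x$network$nodes), x$edge_count, x$lambda, x$ebic))
  invisible(x)
}

#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 l + E log n + 4 E gamma log p`, where `l` is the Gaussian
#' log-likelihood term, `E` the number of nonzero edges, `n` the sample
#' size and `p` the number of nodes.
#'
#' @param loglik log-likelihood term `l`.
#' @param n_edges nonzero edge count `E`.
#' @param n sample size.
#' @param p node count.
#' @param gamma EBIC hyperparameter.
#' @return The EBIC value.
#' @export
ebic_score <- function(loglik, n_edges, n, p, gamma) {
  -2 * loglik + n_edges * log(n) + 4 * n_edges * gamma * log(p)
}

#' Fit a graphical lasso model at a fixed penalty
#'
#' Maximizes `log det K - trace(S K) - lambda * sum_{i != j} |K_ij|`
#' (diagonal unpenalized by default) by block coordinate descent, and
#' converts the precision matrix to partial-correlation edge weights
#' `w_ij = -K_ij / sqrt(K_ii K_jj)`.  At `lambda = 0` the solution is the
#' direct inverse of `S`.
#'
#' @param S an `association_matrix` or plain correlation matrix.
#' @param lambda penalty, `>= 0`.
#' @param n sample size (needed for the likelihood/EBIC terms; taken from
#'   `S$n_effective` when `S` is an `association_matrix`).
#' @param config a [glasso_config()].
#' @return An object of class `ggm_fit` with elements `precision`,
#'   `network`, `lambda`, `loglik`, `edge_count` and `ebic`.
#' @export
glasso_fit <- function(S, lambda, n = NULL, config = glasso_config()) {
  Sv <- as_assoc_values(S)
  if (is.null(n)) {
    if (inherits(S, "association_matrix")) n <- S$n_effective
    else sn_stop("sn_usage_error", "sample size n is required")
  }
  stopifnot(lambda >= 0)
  ev <- eigen(Sv, symmetric = TRUE, only.values = TRUE)$values
  if (lambda == 0 && min(ev) <= 1e-10)
    sn_stop("sn_numerical_error",
            "S is singular; lambda = 0 requires a positive definite S")
  if (min(ev) < -1e-8)
    sn_stop("sn_numerical_error", "S is not positive semi-definite")
  nodes <- rownames(Sv)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(Sv)))
  if (lambda == 0) {
    theta <- solve(Sv)
    theta <- (theta + t(theta)) / 2
  } else {
    fit <- .glasso_cd(Sv, lambda, config$convergence_tol, config$max_iter,
                      config$penalize_diagonal)
    if (!fit$converged)
      sn_stop("sn_numerical_error",
              "glasso did not converge in %d sweeps (lambda = %g, tol = %g)",
              config$max_iter, lambda, config$convergence_tol)
    theta <- fit$theta
  }
  method <- if (inherits(S, "association_matrix")) S$method else NA_character_
  ggm_fit_from_theta(theta, Sv, lambda, n, config, nodes, method)
}

#' Penalty path for EBIC selection
#'
#' `n_lambdas` values log-spaced (descending) from `lambda_max`, the
#' largest off-diagonal `|S_ij|` (at which the estimated network is
#' empty), down to `lambda_max * lambda_min_ratio`.
#'
#' @param S an `association_matrix` or plain correlation matrix.
#' @param config a [glasso_config()].
#' @return Numeric vector of penalties, strictly decreasing.
#' @export
lambda_path <- function(S, config = glasso_config()) {
  Sv <- as_assoc_values(S)
  lam_max <- max(abs(Sv[upper.tri(Sv)]))
  if (lam_max == 0) {
    warning("all off-diagonal correlations are zero; degenerate path {0}")
    return(0)
  }
  exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
          length.out = config$n_lambdas))
}

#' Estimate a network by EBIC model selection over the glasso path
#'
#' Fits every penalty on [lambda_path()], scores each fit by EBIC and
#' returns the minimizer; ties are broken towards the larger penalty
#' (the sparser model).  The selection is an exhaustive scan, never an
#' early stop.
#'
#' @param x a [symptom_dataset()] (correlations computed internally with
#'   `method`) or an `association_matrix`/plain matrix.
#' @param n sample size; required when `x` is a plain matrix.
#' @param method correlation method when `x` is a dataset.
#' @param config a [glasso_config()].
#' @return The selected `ggm_fit`, with the scanned `lambdas` and `ebics`
#'   attached as elements `path_lambdas`/`path_ebics`.
#' @export
select_network <- function(x, n = NULL, method = "pearson",
                           config = glasso_config()) {
  if (inherits(x, "symptom_dataset")) {
    S <- correlation_matrix(x, method = method)
  } else if (inherits(x, "association_matrix")) {
    S <- x
  } else {
    if (is.null(n)) sn_stop("sn_usage_error", "n is required for a bare matrix")
    S <- structure(list(values = as.matrix(x), method = NA_character_,
                        n_effective = n, smoothed = FALSE),
                   class = "association_matrix")
  }
  if (is.null(n)) n <- S$n_effective
  Sv <- S$values
  nodes <- rownames(Sv)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(Sv)))
  lambdas <- lambda_path(S, config)
  if (identical(lambdas, 0)) {
    fit <- glasso_fit(S, 0, n, config)
    fit$path_lambdas <- 0
    fit$path_ebics <- fit$ebic
    return(fit)
  }
  path <- .glasso_path_cd(Sv, lambdas, config$convergence_tol,
                          config$max_iter, config$penalize_diagonal)
  if (any(path$iterations < 0))
    sn_stop("sn_numerical_error",
            "glasso did not converge at lambda = %g",
            lambdas[which(path$iterations < 0)[1]])
  # light EBIC scan over the path; only the winner becomes a full fit
  p <- nrow(Sv)
  ebics <- vapply(seq_along(lambdas), function(l) {
    theta <- path$thetas[, , l]
    part <- precision_to_partials(theta)
    E <- sum(abs(part[upper.tri(part)]) >= ZERO_TOL)
    ld <- as.numeric(determinant(theta, logarithm = TRUE)$modulus)
    ll <- (n / 2) * (ld - sum(S$values * theta))
    ebic_score(ll, E, n, p, config$gamma)
  }, numeric(1))
  best <- which.min(ebics)          # lambdas descend: first min = sparsest
  fit <- ggm_fit_from_theta(path$thetas[, , best], Sv, lambdas[best], n,
                            config, nodes, S$method)
  fit$path_lambdas <- lambdas
  fit$path_ebics <- ebics
  fit
}

#' Global strength of a network
#'
#' The sum of absolute edge weights over the upper triangle; one of the
#' two invariance statistics of the Network Comparison Test.
#'
#' @param net a [symptom_network()].
#' @return A single number.
#' @export
global_strength <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  sum(abs(net$weights[upper.tri(net$weights)]))
}
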