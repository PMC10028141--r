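#' Sample association matrix feeding the graphical lasso
#'
#' Computes the `p x p` item correlation matrix by one of three methods:
#' product-moment (`pearson`, the default), rank-based (`spearman`) or
#' latent-threshold (`polychoric`, estimated pairwise by
#' [polychoric_pair()]; binary pairs reduce to the tetrachoric case).
#' If the resulting matrix is not positive definite it is repaired by
#' [nearest_pd_repair()] and flagged.
#'
#' @param data a [symptom_dataset()] (no missing values by construction).
#' @param method correlation type.
#' @return An object of class `association_matrix` with elements
#'   `values`, `method`, `n_effective` and `smoothed`.
#' @export
correlation_matrix <- function(data,
                               method = c("pearson", "spearman",
                                          "polychoric")) {
  stopifnot(inherits(data, "symptom_dataset"))
  method <- match.arg(method)
  x <- data$scores
  if (data$n < data$p + 1)
    warning(sprintf("n = %d below the recommended floor p + 1 = %d",
                    data$n, data$p + 1))
  v <- apply(x, 2, var)
  if (any(v == 0))
    sn_stop("sn_validation_error",
            "zero-variance item: %s (correlation undefined)",
            colnames(x)[which(v == 0)[1]])
  if (method == "polychoric") {
    p <- ncol(x)
    m <- diag(p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      m[i, j] <- m[j, i] <- polychoric_pair(x[, i], x[, j])
    }
  } else {
    m <- cor(x, method = method)
  }
  dimnames(m) <- list(colnames(x), colnames(x))
  smoothed <- FALSE
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    m <- nearest_pd_repair(m)
    smoothed <- TRUE
  }
  structure(list(values = m, method = method, n_effective = data$n,
                 smoothed = smoothed),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d items, method = %s%s\n",
              nrow(x$values), x$method,
              if (x$smoothed) " (PD-repaired)" else ""))
  invisible(x)
}

# Bivariate standard-normal CDF P(X <= h, Y <= k) at correlation rho,
# by 64-point Gauss-Legendre quadrature of
#   int_{-8.5}^{h} phi(z) Phi((k - rho z)/sqrt(1 - rho^2)) dz.
# Accurate to ~1e-10 for |rho| <= 0.999; vectorized over h, k.
pbvnorm <- function(h, k, rho) {
  if (abs(rho) > 0.9999) rho <- sign(rho) * 0.9999
  n <- max(length(h), length(k))
  h <- rep_len(pmin(pmax(h, -8.5), 8.5), n)
  k <- rep_len(pmin(pmax(k, -8.5), 8.5), n)
  gl <- gauss_legendre_64
  s <- sqrt(1 - rho^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- -8.5; b <- h[i]
    if (b <= a) { out[i] <- 0; next }
    z <- (b - a) / 2 * gl$nodes + (b + a) / 2
    f <- stats::dnorm(z) * pnorm((k[i] - rho * z) / s)
    out[i] <- (b - a) / 2 * sum(gl$weights * f)
  }
  out
}

gauss_legendre_64 <- local({
  # nodes/weights of 64-point Gauss-Legendre on [-1, 1] via the
  # Golub-Welsch eigenvalue method (computed once at load)
  n <- 64
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
})

#' Two-step polychoric (or tetrachoric) correlation of two ordinal items
#'
#' Step one fixes each variable's thresholds at the inverse-normal of its
#' cumulative marginal proportions; step two finds the single latent
#' correlation maximizing the bivariate-normal cell likelihood by bounded
#' scalar optimization on (-0.999, 0.999).  A degenerate table whose
#' likelihood increases towards a boundary (e.g., an empty discordant
#' cell) is clamped at the bound with a warning.
#'
#' @param x,y integer vectors of equal length, each with at least two
#'   observed levels.
#' @return The latent correlation estimate.
#' @export
polychoric_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    sn_stop("sn_validation_error",
            "polychoric_pair needs >= 2 observed levels per variable")
  n <- sum(tab)
  tx <- qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  ty <- qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  nll <- function(rho) {
    P <- cell_probs(tx, ty, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  bound <- 0.999
  opt <- optimize(nll, c(-bound, bound), tol = 1e-7)
  rho <- opt$minimum
  # detect an unbounded likelihood running into the bound
  if (bound - abs(rho) < 2e-3) {
    edge <- sign(rho) * bound
    if (nll(edge) <= opt$objective + 1e-8) {
      warning("polychoric likelihood unbounded; estimate clamped at bound")
      return(edge)
    }
  }
  rho
}

# bivariate-normal cell probabilities for threshold vectors tx, ty
cell_probs <- function(tx, ty, rho) {
  bx <- c(-Inf, tx, Inf)
  by <- c(-Inf, ty, Inf)
  r <- length(bx) - 1; s <- length(by) - 1
  Fgrid <- matrix(0, r + 1, s + 1)
  for (i in seq_len(r + 1)) for (j in seq_len(s + 1)) {
    h <- bx[i]; k <- by[j]
    Fgrid[i, j] <-
      if (h == -Inf || k == -Inf) 0
      else if (h == Inf && k == Inf) 1
      else if (h == Inf) pnorm(k)
      else if (k == Inf) pnorm(h)
      else pbvnorm(h, k, rho)
  }
  P <- Fgrid[-1, -1, drop = FALSE] - Fgrid[-(r + 1), -1, drop = FALSE] -
    Fgrid[-1, -(s + 1), drop = FALSE] +
    Fgrid[-(r + 1), -(s + 1), drop = FALSE]
  pmax(P, 0)
}

#' Repair a symmetric correlation matrix to positive definiteness
#'
#' Eigenvalue clipping at a small floor followed by re-standardization to
#' a unit diagonal, iterated until the smallest eigenvalue respects the
#' floor (one pass almost always suffices).  A matrix already positive
#' definite is returned unchanged, so the repair is idempotent.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param floor smallest admissible eigenvalue.
#' @return The repaired matrix, with attribute `smoothed` (`TRUE` if any
#'   clipping occurred) and `max_change` (largest elementwise change).
#' @export
nearest_pd_repair <- function(m, floor = 1e-8) {
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-10)
    sn_stop("sn_validation_error", "input must be symmetric")
  m0 <- m
  changed <- FALSE
  for (pass in 1:100) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= floor) break
    changed <- TRUE
    lam <- pmax(e$values, floor)
    m <- e$vectors %*% (lam * t(e$vectors))
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
  }
  dimnames(m) <- dimnames(m0)
  attr(m, "smoothed") <- changed
  attr(m, "max_change") <- max(abs(m - m0))
  m
}
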