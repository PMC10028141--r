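# Independent oracles used across the suite.  Each is a deliberately
# naive computation (brute force, enumeration, direct integration) kept
# free of the package's own code paths.

# ---- penalized-likelihood oracle (p <= 3) ------------------------------
# maximizes log det K - tr(SK) - lambda * sum_{i != j} |K_ij| over the
# Cholesky factor of K by repeated Nelder-Mead restarts
oracle_glasso <- function(S, lambda, restarts = 3) {
  p <- nrow(S)
  stopifnot(p <= 3)
  ltri <- lower.tri(diag(p), diag = TRUE)
  obj <- function(par) {
    L <- matrix(0, p, p)
    L[ltri] <- par
    diag(L) <- exp(diag(L))
    K <- L %*% t(L)
    -(determinant(K)$modulus[1] - sum(S * K) -
        lambda * sum(abs(K[row(K) != col(K)])))
  }
  par <- rep(0, sum(ltri))
  for (r in seq_len(restarts)) {
    par <- optim(par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 1e5))$par
  }
  L <- matrix(0, p, p)
  L[ltri] <- par
  diag(L) <- exp(diag(L))
  K <- L %*% t(L)
  P <- -stats::cov2cor(K)
  diag(P) <- 0
  list(precision = K, partials = P)
}

# first-order check that a diagonal precision matrix is the penalized
# optimum: nudging any off-diagonal pair must not improve the objective
oracle_empty_is_optimal <- function(S, lambda, eps = 1e-4) {
  p <- nrow(S)
  pen_obj <- function(K) determinant(K)$modulus[1] - sum(S * K) -
    lambda * sum(abs(K[row(K) != col(K)]))
  K0 <- diag(1 / diag(S))
  f0 <- pen_obj(K0)
  ok <- TRUE
  for (i in seq_len(p - 1)) for (j in (i + 1):p) for (s in c(-1, 1)) {
    K <- K0
    K[i, j] <- K[j, i] <- s * eps
    if (pen_obj(K) > f0 + 1e-12) ok <- FALSE
  }
  ok
}

# ---- exhaustive shortest-path oracle (<= 8 nodes) ----------------------
# enumerates all simple paths; returns closeness (1/sum of distances,
# 0 on any unreachable partner) and Brandes-style betweenness with
# fractional credit over tied geodesics
oracle_paths <- function(w, tol = 1e-9) {
  p <- nrow(w)
  len <- 1 / abs(w)
  len[w == 0] <- Inf
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, d) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, d = d)
        return()
      }
      for (nx in seq_len(p)) {
        if (is.finite(len[last, nx]) && !(nx %in% path))
          walk(c(path, nx), d + len[last, nx])
      }
    }
    walk(s, 0)
    out
  }
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  through <- array(0, c(p, p, p))   # geodesic counts passing node k
  counts <- matrix(0, p, p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dist[s, t] <- dist[t, s] <- min(ds)
    geo <- ps[ds <= min(ds) + tol]
    counts[s, t] <- length(geo)
    for (g in geo) {
      inner <- setdiff(g$path, c(s, t))
      for (k in inner) through[s, t, k] <- through[s, t, k] + 1
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    d <- dist[i, -i]
    if (any(is.infinite(d)) || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  betweenness <- vapply(seq_len(p), function(k) {
    tot <- 0
    for (s in seq_len(p - 1)) for (t in (s + 1):p) {
      if (s == k || t == k || counts[s, t] == 0) next
      tot <- tot + through[s, t, k] / counts[s, t]
    }
    tot
  }, numeric(1))
  list(closeness = closeness, betweenness = betweenness, dist = dist)
}

# ---- direct 2-D integration tetrachoric oracle -------------------------
# cell probabilities of a 2x2 table by Simpson integration of the
# bivariate normal density; rho estimated by bounded scalar optimization
oracle_tetrachoric <- function(tab, tau_x, tau_y) {
  simpson <- function(a, b, m = 201) {
    g <- seq(a, b, length.out = m)
    w <- rep(c(4, 2), length.out = m)
    w[1] <- w[m] <- 1
    w[seq(2, m - 1, by = 2)] <- 4
    w[seq(3, m - 2, by = 2)] <- 2
    list(g = g, w = w * (g[2] - g[1]) / 3)
  }
  orthant <- function(h, k, rho) {
    qx <- simpson(h, 8)
    qy <- simpson(k, 8)
    den <- outer(qx$g, qy$g, function(x, y)
      exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
        (2 * pi * sqrt(1 - rho^2)))
    sum(outer(qx$w, qy$w) * den)
  }
  nll <- function(rho) {
    p11 <- orthant(tau_x, tau_y, rho)
    p1x <- 1 - pnorm(tau_x)
    px1 <- 1 - pnorm(tau_y)
    P <- matrix(c(1 - p1x - px1 + p11, px1 - p11,
                  p1x - p11, p11), 2, 2, byrow = TRUE)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  optimize(nll, c(-0.99, 0.99), tol = 1e-6)$minimum
}

# ---- misc fixtures -----------------------------------------------------
tiny_dataset <- function(n = 8, seed = 1, p_dep = 9, p_anx = 7,
                         p_ptsd = 10) {
  items <- phq_gad_tsq_items(p_dep, p_anx, p_ptsd)
  withr_seed <- function(expr) { set.seed(seed); expr }
  scores <- withr_seed(vapply(seq_len(nrow(items)), function(j)
    sample(items$level_min[j]:items$level_max[j], n, replace = TRUE),
    integer(n)))
  symptom_dataset(matrix(as.integer(scores), nrow = n,
                         dimnames = list(NULL, items$name)),
                  rep("G", n), items)
}

# a fixed 4-node network for hand checks
net4 <- function() {
  w <- matrix(0, 4, 4, dimnames = list(paste0("V", 1:4), paste0("V", 1:4)))
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.25
  w[1, 4] <- w[4, 1] <- -0.1
  symptom_network(w)
}
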