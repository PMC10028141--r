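#' Build a sparse block-structured true partial-correlation network
#'
#' Constructs the data-generating network for simulation studies: three
#' symptom communities (depression, anxiety, PTSD) with within-block
#' edges drawn at the requested density and weight, plus a small fixed
#' set of cross-block bridge edges.  The network is encoded directly as
#' a unit-diagonal precision matrix (off-diagonal `-w_ij`); if that
#' matrix is not comfortably positive definite, all off-diagonals are
#' shrunk by a common factor until it is, so the realized weights may be
#' proportionally smaller than `within_weight`/`bridge_weight`.
#'
#' The positive-definiteness margin is kept generous (smallest eigenvalue
#' at least 0.4) so that moderate group-specific edge perturbations (see
#' [make_three_group_study()]) cannot push a group network out of the
#' feasible set.
#'
#' @param p_dep,p_anx,p_ptsd nodes per community.
#' @param within_weight target partial correlation of within-block edges.
#' @param bridge_weight target partial correlation of the bridge edges.
#' @param density fraction of within-block pairs that receive an edge.
#' @param seed seed for the edge-placement draw (construction is
#'   otherwise deterministic).
#' @param eig_floor smallest admissible eigenvalue of the precision
#'   matrix before shrinkage stops.
#' @return An object of class `true_network_spec` with elements `nodes`,
#'   `partials`, `precision`, `blocks` and `items`.
#' @export
make_true_network <- function(p_dep = 9L, p_anx = 7L, p_ptsd = 10L,
                              within_weight = 0.3, bridge_weight = 0.1,
                              density = 0.2, seed = 1L, eig_floor = 0.4) {
  stopifnot(abs(within_weight) < 1, abs(bridge_weight) < 1,
            density > 0, density <= 1, p_dep >= 2, p_anx >= 2, p_ptsd >= 2)
  items <- phq_gad_tsq_items(p_dep, p_anx, p_ptsd)
  nodes <- items$name
  p <- length(nodes)
  blocks <- rep(c("depression", "anxiety", "PTSD"),
                c(p_dep, p_anx, p_ptsd))
  part <- matrix(0, p, p, dimnames = list(nodes, nodes))
  offs <- cumsum(c(0, p_dep, p_anx))
  with_seed(seed, for (b in 1:3) {
    idx <- offs[b] + seq_len(c(p_dep, p_anx, p_ptsd)[b])
    for (i in idx) for (j in idx) if (i < j && runif(1) < density) {
      part[i, j] <- part[j, i] <- within_weight
    }
  })
  # fixed bridge set: mood-worry, anxiety-PTSD irritability, sleep pair
  bridges <- rbind(c(min(2, p_dep), offs[2] + min(2, p_anx)),
                   c(offs[2] + p_anx, offs[3] + min(7, p_ptsd)),
                   c(min(3, p_dep), offs[3] + min(6, p_ptsd)))
  for (k in seq_len(nrow(bridges))) {
    i <- bridges[k, 1]; j <- bridges[k, 2]
    part[i, j] <- part[j, i] <- bridge_weight
  }
  true_network_spec(part, blocks, items)
}

#' Construct a true-network specification from a partial-correlation matrix
#'
#' Validates symmetry, zero diagonal and `|partial| < 1`, then checks
#' positive definiteness of the implied unit-diagonal precision matrix,
#' shrinking all off-diagonals by factors of 0.9 (at most 60 times) if
#' needed.  The stored partials are exactly those recovered from the
#' stored precision matrix.
#'
#' @param partials `p x p` sparse symmetric matrix of target partial
#'   correlations, zero diagonal.
#' @param blocks community label per node.
#' @param items item specification table aligned with the nodes.
#' @param eig_floor smallest admissible precision eigenvalue.
#' @return A `true_network_spec`.
#' @export
true_network_spec <- function(partials, blocks = NULL,
                              items = phq_gad_tsq_items(),
                              eig_floor = 1e-6) {
  partials <- as.matrix(partials)
  p <- nrow(partials)
  stopifnot(ncol(partials) == p, nrow(items) == p)
  if (max(abs(partials - t(partials))) > 1e-12 ||
      any(diag(partials) != 0) || any(abs(partials) >= 1))
    sn_stop("sn_validation_error",
            "partials must be symmetric, zero-diagonal, |r| < 1")
  if (is.null(blocks)) blocks <- items$instrument
  K <- diag(p) - partials
  tries <- 0L
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <
         eig_floor) {
    tries <- tries + 1L
    if (tries > 60L)
      sn_stop("sn_construction_error",
              "cannot reach a positive definite precision matrix")
    partials <- partials * 0.9
    K <- diag(p) - partials
  }
  nodes <- items$name
  dimnames(K) <- dimnames(partials) <- list(nodes, nodes)
  structure(list(nodes = nodes, partials = partials, precision = K,
                 blocks = blocks, items = items),
            class = "true_network_spec")
}

#' Partial correlations implied by a precision matrix
#'
#' `r_ij = -k_ij / sqrt(k_ii * k_jj)`, the standard conversion from the
#' concentration (precision) matrix to partial-correlation edge weights.
#'
#' @param K symmetric positive definite precision matrix.
#' @return Matrix of partial correlations with zero diagonal.
#' @export
precision_to_partials <- function(K) {
  d <- sqrt(diag(K))
  P <- -K / tcrossprod(d)
  diag(P) <- 0
  dimnames(P) <- dimnames(K)
  P
}

#' Latent-scale thresholds targeting a given item mean
#'
#' For a 0-3 ordinal item, returns three increasing cut-points on the
#' standard normal latent scale, spaced 0.8 apart, whose implied expected
#' score equals `target_mean`.  For a binary item, a single cut-point
#' with exceedance probability `target_mean`.
#'
#' @param target_mean desired expected item score (in `(0, 3)` for
#'   ordinal items, `(0, 1)` for binary ones).
#' @param binary whether the item is binary.
#' @return Numeric vector of strictly increasing cut-points.
#' @export
item_thresholds <- function(target_mean, binary = FALSE) {
  if (binary) {
    stopifnot(target_mean > 0, target_mean < 1)
    return(qnorm(1 - target_mean))
  }
  stopifnot(target_mean > 0, target_mean < 3)
  f <- function(t0) sum(1 - pnorm(t0 + c(0, 0.8, 1.6))) - target_mean
  t0 <- stats::uniroot(f, c(-8, 8), tol = 1e-10)$root
  t0 + c(0, 0.8, 1.6)
}

#' Per-item latent thresholds targeting instrument sum-score means
#'
#' Builds the per-item cut-point list for [group_sim_spec()] from target
#' PHQ-9, GAD-7 and TSQ sum-score means.  Sum-score targets refer to the
#' full instruments (9/7/10 items), so the implied per-item severity
#' carries over unchanged to reduced batteries; per-item means are
#' clamped away from the scale boundaries.
#'
#' @param items item specification table, see [phq_gad_tsq_items()].
#' @param phq_mean,gad_mean,tsq_mean target sum-score means.
#' @return List of per-item cut-point vectors.
#' @export
default_group_thresholds <- function(items, phq_mean, gad_mean, tsq_mean) {
  per_item <- c(PHQ9 = phq_mean / 9, GAD7 = gad_mean / 7,
                TSQ = tsq_mean / 10)
  lapply(seq_len(nrow(items)), function(j) {
    binary <- items$level_max[j] == 1L
    m <- per_item[[items$instrument[j]]]
    m <- if (binary) min(max(m, 0.05), 0.95) else min(max(m, 0.05), 2.95)
    item_thresholds(m, binary = binary)
  })
}

#' Specify one simulated respondent group
#'
#' @param name group label.
#' @param size respondent count (at least 1).
#' @param network a [true_network_spec()].
#' @param thresholds list of per-item cut-point vectors on the latent
#'   scale (3 cut-points for 0-3 items, 1 for binary); defaults target
#'   moderate symptom severity.
#' @param seed RNG seed for this group's draw.
#' @return An object of class `group_sim_spec`.
#' @export
group_sim_spec <- function(name, size, network, thresholds = NULL,
                           seed = 1L) {
  stopifnot(inherits(network, "true_network_spec"), size >= 1)
  if (is.null(thresholds))
    thresholds <- default_group_thresholds(network$items, 8, 6, 4.5)
  stopifnot(length(thresholds) == length(network$nodes))
  for (j in seq_along(thresholds)) {
    ct <- thresholds[[j]]
    binary <- network$items$level_max[j] == 1L
    if (length(ct) != (if (binary) 1L else 3L) ||
        is.unsorted(ct, strictly = TRUE))
      sn_stop("sn_validation_error",
              "thresholds for item %s must be %d strictly increasing values",
              network$nodes[j], if (binary) 1L else 3L)
  }
  structure(list(name = name, size = as.integer(size), network = network,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "group_sim_spec")
}

#' Draw one group of ordinal/binary symptom data from its latent network
#'
#' Respondents are sampled from the multivariate normal with unit
#' variances whose correlation structure is implied by the group's true
#' precision matrix; each latent value is then discretized by the item's
#' cut-points (score = number of cut-points below the value).  The draw
#' is fully determined by the spec's seed.
#'
#' @param spec a [group_sim_spec()].
#' @return A [symptom_dataset()] with a single group level.
#' @export
sample_group <- function(spec) {
  stopifnot(inherits(spec, "group_sim_spec"))
  Sigma <- stats::cov2cor(solve(spec$network$precision))
  lat <- with_seed(spec$seed,
                   MASS::mvrnorm(spec$size, mu = rep(0, nrow(Sigma)),
                                 Sigma = Sigma))
  lat <- matrix(lat, nrow = spec$size)
  scores <- vapply(seq_along(spec$thresholds), function(j)
    findInterval(lat[, j], spec$thresholds[[j]]),
    integer(spec$size))
  scores <- matrix(as.integer(scores), nrow = spec$size,
                   dimnames = list(NULL, spec$network$nodes))
  symptom_dataset(scores, rep(spec$name, spec$size), spec$network$items)
}

#' Default group-specific edge perturbations for the three-group study
#'
#' The sexual-abuse (SA) group strengthens PTSD-PTSD edges
#' (PTSD.7-PTSD.9, PTSD.6-PTSD.9, PTSD.3-PTSD.4), the emotional-abuse
#' (EA) group strengthens suicide-incident edges (PHQ.9-PHQ.2,
#' PHQ.9-PHQ.8) and the physical-abuse (PA) group strengthens anxiety
#' edges (GAD.4-GAD.6, GAD.5-PHQ.9).
#'
#' @param delta partial-correlation increment applied to each listed edge.
#' @return Named list (EA/PA/SA) of data.frames with columns `from`,
#'   `to`, `delta`.
#' @export
default_study_perturbations <- function(delta = 0.25) {
  list(
    EA = data.frame(from = c("PHQ.9", "PHQ.9"), to = c("PHQ.2", "PHQ.8"),
                    delta = delta),
    PA = data.frame(from = c("GAD.4", "GAD.5"), to = c("GAD.6", "PHQ.9"),
                    delta = delta),
    SA = data.frame(from = c("PTSD.7", "PTSD.6", "PTSD.3"),
                    to = c("PTSD.9", "PTSD.9", "PTSD.4"), delta = delta))
}

apply_perturbation <- function(base, pert) {
  part <- base$partials
  for (i in seq_len(nrow(pert))) {
    a <- pert$from[i]; b <- pert$to[i]
    if (!a %in% base$nodes || !b %in% base$nodes)
      sn_stop("sn_schema_error", "unknown node in perturbation: %s/%s", a, b)
    if (a == b)
      sn_stop("sn_validation_error",
              "perturbation on the diagonal (%s) is not allowed", a)
    part[a, b] <- part[b, a] <- part[a, b] + pert$delta[i]
  }
  K <- diag(nrow(part)) - part
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < 1e-6)
    sn_stop("sn_construction_error",
            "perturbed network is not positive definite")
  spec <- base
  spec$partials <- part
  dimnames(K) <- dimnames(part)
  spec$precision <- K
  spec
}

#' Simulate the three-group childhood-trauma study
#'
#' Generates one concatenated dataset with groups EA, PA and SA drawn
#' from group-specific true networks: a shared base network plus the
#' group's edge perturbations (default [default_study_perturbations()]).
#' Group sizes default to 1191/1272/3479 and per-group thresholds are
#' calibrated so instrument sum-score means approximate the cohort's
#' group profiles (PHQ-9 near 11.25/7.92/6.91 for EA/PA/SA, and
#' correspondingly for GAD-7 and TSQ).
#'
#' Each group's draw uses a sub-stream seeded at `seed + 0/1/2`, so the
#' groups are independent and the whole dataset is reproduced exactly by
#' the same call.
#'
#' @param base shared [true_network_spec()].
#' @param perturbations named list of per-group edge overrides (may be
#'   `NULL` entries or an empty list for a null study in which all groups
#'   share `base`).
#' @param sizes named integer vector of group sizes.
#' @param seed master seed.
#' @param target_means named list of per-group `c(phq, gad, tsq)`
#'   sum-score means used to calibrate the thresholds.
#' @return A list with the combined `data` ([symptom_dataset()]) and
#'   `networks`, the named list of per-group `true_network_spec`s.
#' @export
make_three_group_study <- function(base = make_true_network(),
                                   perturbations = default_study_perturbations(),
                                   sizes = c(EA = 1191L, PA = 1272L,
                                             SA = 3479L),
                                   seed = 1L,
                                   target_means = list(
                                     EA = c(11.25, 8.54, 6.10),
                                     PA = c(7.92, 5.74, 4.45),
                                     SA = c(6.91, 5.18, 4.32))) {
  stopifnot(inherits(base, "true_network_spec"),
            !is.null(names(sizes)), all(sizes >= 1))
  groups <- names(sizes)
  nets <- lapply(groups, function(g) {
    pert <- perturbations[[g]]
    if (is.null(pert) || nrow(pert) == 0) base
    else apply_perturbation(base, pert)
  })
  names(nets) <- groups
  parts <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[k]
    tm <- target_means[[g]]
    if (is.null(tm)) tm <- c(8, 6, 4.5)
    thr <- default_group_thresholds(base$items, tm[1], tm[2], tm[3])
    spec <- group_sim_spec(g, sizes[[k]], nets[[g]], thr,
                           seed = seed + k - 1L)
    parts[[k]] <- sample_group(spec)
  }
  scores <- do.call(rbind, lapply(parts, `[[`, "scores"))
  group <- factor(unlist(lapply(parts, function(d) as.character(d$group))),
                  levels = groups)
  list(data = symptom_dataset(scores, group, base$items),
       networks = nets)
}
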