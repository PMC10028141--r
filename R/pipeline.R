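#' Run the full symptom-network workflow and write its artifacts
#'
#' Ties the stages together the way the study design prescribes: for
#' each group, correlation input, EBIC-glasso network and centrality
#' table; optionally a bootstrap summary per group; then the pairwise
#' Network Comparison Tests between all groups.  Every artifact is
#' written under `out_dir` together with a run manifest recording the
#' seed and settings, so identical calls reproduce byte-identical
#' outputs.
#'
#' @param data a [symptom_dataset()] with at least two groups; when
#'   `NULL`, the default three-group study is simulated with
#'   [make_three_group_study()] under `seed`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed, recorded in the manifest and reused for the
#'   simulation, bootstrap and NCT stages.
#' @param method correlation method for every estimation stage.
#' @param glasso a [glasso_config()].
#' @param bootstrap a [bootstrap_config()], or `NULL` to skip the
#'   bootstrap stage.
#' @param nct an [nct_config()], or `NULL` to skip comparisons.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(data = NULL, out_dir, seed = 1L,
                         method = "pearson", glasso = glasso_config(),
                         bootstrap = NULL, nct = nct_config()) {
  if (is.null(data))
    data <- make_three_group_study(seed = seed)$data
  stopifnot(inherits(data, "symptom_dataset"))
  if (nlevels(data$group) < 2)
    sn_stop("sn_usage_error", "pipeline needs at least two groups")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  estimator <- ebicglasso_estimator(method = method, config = glasso)
  groups <- levels(data$group)
  files <- character()
  for (g in groups) {
    dg <- subset_dataset(data, group = g)
    fit <- select_network(dg, method = method, config = glasso)
    f_net <- file.path(out_dir, paste0("network_", g, ".json"))
    write_network(fit$network, f_net, "json")
    ct <- centrality_table(fit$network)
    f_ct <- file.path(out_dir, paste0("centrality_", g, ".csv"))
    write.csv(ct, f_ct, row.names = FALSE)
    files <- c(files, f_net, f_ct)
    if (!is.null(bootstrap)) {
      bcfg <- bootstrap; bcfg$seed <- as.integer(seed)
      bs <- bootstrap_edges(dg, estimator, bcfg)
      f_bs <- file.path(out_dir, paste0("bootstrap_", g, ".csv"))
      write.csv(bs$summary, f_bs, row.names = FALSE)
      files <- c(files, f_bs)
    }
  }
  if (!is.null(nct) && length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ncfg <- nct; ncfg$seed <- as.integer(seed)
      res <- nct_run(subset_dataset(data, group = a),
                     subset_dataset(data, group = b), estimator, ncfg)
      f_nct <- file.path(out_dir, paste0("nct_", a, "_vs_", b, ".json"))
      jsonlite::write_json(
        list(groups = c(a, b), m_observed = res$m_observed,
             s_observed = res$s_observed,
             p_structure = res$p_structure,
             p_strength = res$p_strength,
             iterations = res$iterations, seed = res$seed,
             edge_tests = res$edge_tests),
        f_nct, auto_unbox = TRUE, digits = NA)
      files <- c(files, f_nct)
    }
  }
  manifest <- list(
    package = "symptomnet",
    version = as.character(utils::packageVersion("symptomnet")),
    seed = as.integer(seed), method = method,
    glasso = unclass(glasso),
    bootstrap = if (is.null(bootstrap)) NULL else unclass(bootstrap),
    nct = if (is.null(nct)) NULL else unclass(nct),
    groups = groups, n = data$n, p = data$p,
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
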