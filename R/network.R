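#' Construct a weighted symptom network
#'
#' A network over the battery's items: symptoms are nodes, regularized
#' partial correlations are signed edge weights.  The weight matrix must
#' be symmetric with a zero diagonal and all `|w| < 1`.
#'
#' @param weights numeric `p x p` matrix of edge weights.
#' @param nodes character vector of node names (defaults to the matrix
#'   dimnames).
#' @param metadata named list of estimator settings (method, lambda,
#'   gamma, n, ...) carried along into every serialization.
#' @return An object of class `symptom_network` with elements `nodes`,
#'   `weights` and `metadata`.
#' @export
symptom_network <- function(weights, nodes = rownames(weights),
                            metadata = list()) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  if (length(nodes) != p || ncol(weights) != p)
    sn_stop("sn_schema_error", "weights must be square and match nodes")
  if (max(abs(weights - t(weights))) > 1e-10)
    sn_stop("sn_validation_error", "weight matrix is not symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    sn_stop("sn_validation_error", "diagonal weights must be zero")
  if (any(abs(weights) >= 1))
    sn_stop("sn_validation_error", "edge weights must satisfy |w| < 1")
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = as.character(nodes), weights = weights,
                 metadata = metadata),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat(sprintf("symptom_network: %d nodes, %d edges\n",
              length(x$nodes), edge_count(x)))
  invisible(x)
}

edge_count <- function(net) {
  sum(net$weights[upper.tri(net$weights)] != 0)
}

# upper-triangle edge data.frame (nonzero only unless all = TRUE)
edge_list <- function(net, all = FALSE) {
  w <- net$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  df <- data.frame(source = net$nodes[idx[, 1]],
                   target = net$nodes[idx[, 2]],
                   weight = w[idx], stringsAsFactors = FALSE)
  if (!all) df <- df[df$weight != 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a network to edge-list CSV, JSON or GraphML
#'
#' The edge-list CSV holds only the nonzero upper-triangle edges
#' (`source,target,weight`); JSON embeds the full weight matrix, node
#' list and metadata; GraphML attaches the weight as a `weight` edge
#' attribute.  All formats store weights at full double precision, so
#' [read_network()] reproduces them exactly.
#'
#' @param net a [symptom_network()].
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "json", "graphml")) {
  stopifnot(inherits(net, "symptom_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       sn_stop("sn_usage_error", "unknown format '%s'",
                               format[1]))
  if (format == "csv") {
    df <- edge_list(net)
    df$weight <- fmt_full(df$weight)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(nodes = net$nodes, weights = net$weights,
           metadata = net$metadata),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    write_graphml(net, path)
  }
  invisible(path)
}

write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- xml2::xml_add_child(doc, "key", id = "w", `for` = "edge",
                             attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G",
                           edgedefault = "undirected")
  for (nd in net$nodes) xml2::xml_add_child(g, "node", id = nd)
  df <- edge_list(net)
  for (i in seq_len(nrow(df))) {
    e <- xml2::xml_add_child(g, "edge", source = df$source[i],
                             target = df$target[i])
    d <- xml2::xml_add_child(e, "data", key = "w")
    xml2::xml_text(d) <- fmt_full(df$weight[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input file path.
#' @param format `"csv"`, `"json"` or `"graphml"`.
#' @param nodes node names; required for CSV when isolated nodes must be
#'   retained (the edge list alone cannot name them), taken from the file
#'   for JSON/GraphML.
#' @return A [symptom_network()].
#' @export
read_network <- function(path, format = c("csv", "json", "graphml"),
                         nodes = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       sn_stop("sn_usage_error", "unknown format '%s'",
                               format[1]))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    w <- matrix(as.numeric(obj$weights), nrow = length(obj$nodes))
    meta <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
    return(symptom_network(w, obj$nodes, meta))
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
    if (is.null(nodes)) nodes <- sort(unique(c(df$source, df$target)))
    w <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(df))) {
      w[df$source[i], df$target[i]] <- df$weight[i]
      w[df$target[i], df$source[i]] <- df$weight[i]
    }
    return(symptom_network(w, nodes))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nd <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- xml2::xml_attr(nd, "id")
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in xml2::xml_find_all(doc, ".//g:edge", ns)) {
    s <- xml2::xml_attr(e, "source"); t <- xml2::xml_attr(e, "target")
    val <- as.numeric(xml2::xml_text(xml2::xml_find_first(e, "./g:data", ns)))
    w[s, t] <- val; w[t, s] <- val
  }
  symptom_network(w, nodes)
}
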