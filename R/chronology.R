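#' Calibrate a substitution rate from a dated node
#'
#' A node of known age `T` years sitting `k` substitutions above its tips
#' yields the rate `r = k / (L * T)` in substitutions/site/year.
#'
#' @param k substitutions on the calibrated branch/path (> 0; may be
#'   fractional when taken from an averaged network depth).
#' @param L alignment length in sites (>= 1).
#' @param age_years calibration age in years before present (> 0).
#' @return rate `r` in substitutions/site/year.
#' @export
calibrate_rate <- function(k, L, age_years) {
  if (length(age_years) != 1L || is.na(age_years) || age_years <= 0)
    stop("age_years must be > 0", call. = FALSE)
  if (length(k) != 1L || is.na(k) || k <= 0)
    stop("k must be > 0: a zero-length calibration branch is uninformative",
         call. = FALSE)
  if (length(L) != 1L || is.na(L) || L < 1)
    stop("L must be >= 1", call. = FALSE)
  k / (L * age_years)
}

## Substitution depth of every node: the aggregated shortest-path
## substitution count from the node to its descendant sampled tips.  A tip t
## is a descendant of v (relative to the root) when v lies on a shortest
## root-to-t path.  Paths through reticulations take the minimum-substitution
## route.
network_depths <- function(net, root,
                           depth_mode = c("mean_tip_path", "max_tip_path",
                                          "min_tip_path")) {
  depth_mode <- match.arg(depth_mode)
  g <- net$graph
  ids <- igraph::V(g)$name
  if (!root %in% ids) stop("unknown root node: ", root, call. = FALSE)
  if (igraph::ecount(g) > 0 && !igraph::is_connected(g))
    stop("network is disconnected", call. = FALSE)
  wt <- if (igraph::ecount(g) > 0) igraph::E(g)$n_subs else NULL
  dmat <- igraph::distances(g, weights = wt)
  rownames(dmat) <- colnames(dmat) <- ids
  tips <- ids[igraph::V(g)$sampled]
  agg <- switch(depth_mode, mean_tip_path = mean, max_tip_path = max,
                min_tip_path = min)
  depth <- vapply(ids, function(v) {
    desc <- tips[abs(dmat[root, tips] - (dmat[root, v] + dmat[v, tips])) <
                   1e-9]
    desc <- setdiff(desc, v)   # a node's own samples sit at depth 0
    if (length(desc) == 0L) return(0)
    agg(dmat[v, desc])
  }, 0)
  names(depth) <- ids
  depth
}

#' Date network nodes from a calibrated substitution rate
#'
#' Converts each node's substitution depth (distance to its descendant
#' sampled tips along shortest parsimony paths, aggregated per `depth_mode`)
#' into an age in years before present: `age = depth / (r * L)`.
#'
#' @param net a [build_network()] result.
#' @param r substitution rate (subs/site/year), e.g. from
#'   [calibrate_rate()].
#' @param L alignment length in sites.
#' @param depth_mode how multi-tip depths are aggregated:
#'   `"mean_tip_path"` (default), `"max_tip_path"`, or `"min_tip_path"`.
#' @param root node id the depths are rooted at (typically the DCA).
#' @return An object of class `hap_chronology`: data.frame with columns
#'   `node`, `sampled`, `depth`, `age_years`, plus attributes `r`, `L`,
#'   `depth_mode`.
#' @export
date_nodes <- function(net, r, L,
                       depth_mode = c("mean_tip_path", "max_tip_path",
                                      "min_tip_path"),
                       root) {
  depth_mode <- match.arg(depth_mode)
  if (r <= 0) stop("rate must be > 0", call. = FALSE)
  depth <- network_depths(net, root, depth_mode)
  out <- data.frame(node = names(depth),
                    sampled = igraph::V(net$graph)$sampled,
                    depth = unname(depth),
                    age_years = unname(depth) / (r * L),
                    stringsAsFactors = FALSE)
  attr(out, "r") <- r; attr(out, "L") <- L
  attr(out, "depth_mode") <- depth_mode; attr(out, "root") <- root
  class(out) <- c("hap_chronology", "data.frame")
  out
}

#' Calibrate on a network node and date every node
#'
#' Convenience wrapper: takes the calibration node's own network depth as the
#' calibrated substitution count `k`, derives the rate, and dates all nodes.
#' By construction the calibration node's age reproduces `age_years` exactly
#' under every `depth_mode`.
#'
#' @param net a [build_network()] result.
#' @param node calibration node id.
#' @param age_years known age of that node (years before present).
#' @param L alignment length in sites.
#' @inheritParams date_nodes
#' @return list with `r` (the calibrated rate) and `chronology` (a
#'   [date_nodes()] table).
#' @export
calibrate_from_network <- function(net, node, age_years, L,
                                   depth_mode = c("mean_tip_path",
                                                  "max_tip_path",
                                                  "min_tip_path"),
                                   root = node) {
  depth_mode <- match.arg(depth_mode)
  k <- network_depths(net, root, depth_mode)[[node]]
  r <- calibrate_rate(k, L, age_years)
  list(r = r, chronology = date_nodes(net, r, L, depth_mode, root))
}

#' Write a chronology table as TSV
#'
#' @param chron a [date_nodes()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_chronology <- function(chron, file) {
  stopifnot(inherits(chron, "hap_chronology"))
  out <- as.data.frame(chron)
  out$depth_mode <- attr(chron, "depth_mode")
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
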