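#' Per-mutation homoplasy probability model
#'
#' Under a uniform-mutation null, the chance that a given mutation repeats an
#' earlier one exactly (same alignment column and same derived base, hence the
#' factor 1/3) anywhere among the `m` substitutions of a network over an
#' alignment of `L` sites is `p = (1/3) * (1/L) * m`, giving an expected
#' total of `E = m * p = m^2 / (3L)` homoplasies.
#'
#' @param L alignment length in sites (>= 1).
#' @param m total substitution occurrences on the network edges (>= 0).
#' @return An object of class `homoplasy_model`: list with `L`, `m`,
#'   `P` (= 1/L), `p`, `E` at full precision, and display-precision mirrors
#'   `p_printed` (one significant figure) and `E_printed` (truncated to two
#'   decimals), matching how such models are conventionally reported.
#' @export
homoplasy_model <- function(L, m) {
  if (length(L) != 1L || is.na(L) || L < 1)
    stop("L must be a single value >= 1", call. = FALSE)
  if (length(m) != 1L || is.na(m) || m < 0)
    stop("m must be a single value >= 0", call. = FALSE)
  p <- m / (3 * L)
  E <- m * p
  structure(
    list(L = L, m = m, P = 1 / L, p = p, E = E,
         p_printed = signif(p, 1), E_printed = trunc(E * 100) / 100),
    class = "homoplasy_model"
  )
}

#' @export
print.homoplasy_model <- function(x, ...) {
  cat(sprintf("homoplasy model: L = %d sites, m = %d substitutions\n",
              as.integer(x$L), as.integer(x$m)))
  cat(sprintf("  p = %.7f (prints %g), E = %.5f (prints %.2f)\n",
              x$p, x$p_printed, x$E, x$E_printed))
  invisible(x)
}

#' Branch-level binomial test for recombination
#'
#' Upper-tail probability of observing `H` or more homoplasies among the `N`
#' substitutions of a branch when each substitution is independently
#' homoplasious with probability `p`.  A small tail probability means repeat
#' mutation is an implausible explanation for the observed character
#' conflict, favouring recombination.
#'
#' @param N substitutions on the branch (>= 0).
#' @param H homoplasies on the branch (0 <= H <= N).
#' @param p per-mutation homoplasy probability, in (0, 1); a
#'   [homoplasy_model()] may be passed instead.
#' @return `P(X >= H | N, p)`; 1 when `H = 0`.
#' @export
branch_test <- function(N, H, p) {
  if (inherits(p, "homoplasy_model")) p <- p$p
  if (H < 0 || N < 0 || H > N)
    stop("need 0 <= H <= N", call. = FALSE)
  if (p <= 0 || p >= 1)
    stop("p must lie in (0, 1)", call. = FALSE)
  if (H == 0) return(1)
  stats::pbinom(H - 1, N, p, lower.tail = FALSE)
}

#' Network-wide homoplasy probability
#'
#' Binomial probability of the total homoplasy count over all `m` network
#' substitutions.  Both the point probability `P(X = H_net)` and the upper
#' tail `P(X >= H_net)` are reported: the conventional printed network-wide
#' figure corresponds to the point probability at full-precision `p`, while
#' branch-level tests are defined as tails.
#'
#' @param model a [homoplasy_model()].
#' @param H_net observed homoplasy count (0 <= H_net <= m).
#' @return list with `point` and `tail` probabilities.
#' @export
network_test <- function(model, H_net) {
  stopifnot(inherits(model, "homoplasy_model"))
  if (H_net < 0 || H_net > model$m)
    stop("need 0 <= H_net <= m", call. = FALSE)
  list(point = stats::dbinom(H_net, model$m, model$p),
       tail = if (H_net == 0) 1
              else stats::pbinom(H_net - 1, model$m, model$p,
                                 lower.tail = FALSE))
}

#' Enumerate recombination events from network reticulations
#'
#' Each independent cycle (reticulation) of the network is treated as one
#' candidate recombination event.  Within a cycle, the branch whose label
#' carries homoplasious characters is the tested branch: its substitution
#' count `N` and homoplasy count `H` feed [branch_test()].  When several
#' branches of the cycle carry homoplasies each is tested and the event
#' reports the minimum tail probability with a flag.  The two cycle corners
#' farthest from the tested branch are reported as the alternative ancestral
#' candidate nodes.  Events are labelled `R1...Rk` in deterministic order of
#' increasing network distance from the reference node (the DCA when
#' supplied).
#'
#' @param net a [build_network()] result.
#' @param model a [homoplasy_model()]; defaults to one built from the
#'   network's own `m` and the alignment length implied by `L`.
#' @param L alignment length used when `model` is missing.
#' @param dca_node optional node id used to order events.
#' @return data.frame of class `recomb_events` with columns `event`, `N`,
#'   `N_positions`, `H`, `H_positions`, `ratio` (H/N as conventionally
#'   printed), `P_binom`, `significant_05`, `significant_01`,
#'   `ancestral_candidates`, `multiple_branches`; zero rows for an acyclic
#'   network.
#' @export
enumerate_events <- function(net, model = NULL, L = NULL, dca_node = NULL) {
  stopifnot(inherits(net, "hap_network"))
  if (is.null(model)) {
    if (is.null(L)) stop("supply either model or L", call. = FALSE)
    model <- homoplasy_model(L, net$m)
  }
  g <- net$graph
  empty <- data.frame(event = character(0), N = integer(0),
                      N_positions = character(0), H = integer(0),
                      H_positions = character(0), ratio = numeric(0),
                      P_binom = numeric(0), significant_05 = logical(0),
                      significant_01 = logical(0),
                      ancestral_candidates = character(0),
                      multiple_branches = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("recomb_events", "data.frame")
  if (igraph::ecount(g) < 3L) return(empty)

  ## fundamental cycles from a BFS spanning tree rooted at the reference node
  ids <- igraph::V(g)$name
  root <- if (!is.null(dca_node) && dca_node %in% ids) dca_node else ids[1]
  dist_root <- igraph::distances(g, v = root, weights = igraph::E(g)$weight)[1, ]
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  ## deterministic spanning tree (ranked by edge index); every non-tree edge
  ## closes one fundamental cycle
  mst <- igraph::mst(g, weights = seq_len(igraph::ecount(g)))
  in_tree <- apply(ends, 1, function(e)
    igraph::are_adjacent(mst, e[1], e[2]))
  extra <- which(!in_tree)
  if (length(extra) == 0L) return(empty)

  hchars <- homoplasious_chars(net)
  info <- net$char_info

  cycles <- list()
  for (eid in extra) {
    u <- ends[eid, 1]; v <- ends[eid, 2]
    sp <- igraph::shortest_paths(mst, from = u, to = v, output = "both")
    vpath <- igraph::as_ids(sp$vpath[[1]])
    ## tree path edge ids mapped back to the full graph
    epath_ids <- integer(0)
    for (k in seq_len(length(vpath) - 1L))
      epath_ids <- c(epath_ids,
                     igraph::get_edge_ids(g, c(vpath[k], vpath[k + 1L])))
    cyc_edges <- c(epath_ids, eid)
    cyc_vertices <- vpath
    cycles[[length(cycles) + 1L]] <-
      list(edges = cyc_edges, vertices = cyc_vertices,
           key = min(dist_root[cyc_vertices]))
  }
  cycles <- cycles[order(vapply(cycles, `[[`, 0, "key"),
                         vapply(cycles, function(c)
                           paste(sort(c$vertices), collapse = "|"), ""))]

  rows <- list()
  for (k in seq_along(cycles)) {
    cyc <- cycles[[k]]
    ce <- cyc$edges
    hp_per_edge <- vapply(ce, function(e)
      sum(net$edges$chars[[e]] %in% hchars), 0L)
    cand <- ce[hp_per_edge > 0L]
    multiple <- length(cand) > 1L
    if (length(cand) == 0L) {
      ## conflict without a repeated character label: test the longest branch
      cand <- ce[which.max(net$edges$weight[ce])]
    }
    best <- NULL
    for (e in cand) {
      cs <- net$edges$chars[[e]]
      sub <- cs[info$type[match(cs, info$char)] == "substitution"]
      N <- length(sub)
      hsub <- sub[sub %in% hchars]
      H <- length(hsub)
      P <- if (N == 0L) 1 else branch_test(N, H, model$p)
      if (is.null(best) || P < best$P) {
        best <- list(edge = e, N = N, H = H, P = P,
                     Npos = paste(info$label[match(sub, info$char)],
                                  collapse = ","),
                     Hpos = paste(info$label[match(hsub, info$char)],
                                  collapse = ","))
      }
    }
    ## ancestral candidates: the two cycle vertices farthest (along the
    ## cycle) from the tested branch, i.e. the opposite corners
    everts <- ends[best$edge, ]
    ring <- cyc$vertices
    if (!all(everts %in% ring)) ring <- unique(c(ring, everts))
    off <- vapply(ring, function(v) {
      dv <- igraph::distances(g, v = v, to = everts,
                              weights = igraph::E(g)$weight)
      min(dv)
    }, 0)
    far <- ring[order(-off, ring)][seq_len(min(2L, length(ring)))]
    rows[[length(rows) + 1L]] <- data.frame(
      event = sprintf("R%d", k), N = best$N, N_positions = best$Npos,
      H = best$H, H_positions = best$Hpos,
      ratio = if (best$N > 0) round(best$H / best$N, 2) else NA_real_,
      P_binom = best$P,
      significant_05 = best$P < 0.05, significant_01 = best$P < 0.01,
      ancestral_candidates = paste(sort(far), collapse = ","),
      multiple_branches = multiple, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recomb_events", "data.frame")
  out
}

#' Write the recombination-event table as TSV
#'
#' @param events an [enumerate_events()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_events <- function(events, file) {
  utils::write.table(as.data.frame(events), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
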