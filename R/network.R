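## Weighted Hamming distance between two 0/1/NA character vectors.
char_dist <- function(a, b, w) {
  d <- a != b
  sum(w[which(d)])
}

## All-pairs distance matrix over the rows of a character matrix.
dist_matrix <- function(mat, w) {
  n <- nrow(mat)
  D <- matrix(0, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- char_dist(mat[i, ], mat[j, ], w)
  D
}

## Minimum spanning network (Excoffier & Smouse): an edge (i, j) of weight w
## is retained iff i and j lie in different components of the graph formed by
## all edges of weight < w.  The result contains every edge belonging to at
## least one minimum spanning tree, so equally parsimonious alternative
## connections survive as cycles.
msn_edges <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  comp <- seq_len(n)
  edges <- matrix(integer(0), ncol = 2)
  ut <- which(upper.tri(D))
  ws <- sort(unique(D[ut]))
  ws <- ws[ws > 0]
  for (w in ws) {
    batch <- matrix(integer(0), ncol = 2)
    for (idx in ut) {
      if (D[idx] == w) {
        j <- ((idx - 1L) %/% n) + 1L
        i <- idx - (j - 1L) * n
        if (comp[i] != comp[j]) batch <- rbind(batch, c(i, j))
      }
    }
    edges <- rbind(edges, batch)
    for (r in seq_len(nrow(batch))) {
      a <- comp[batch[r, 1]]; b <- comp[batch[r, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1L) break
  }
  edges
}

## Total weight of a minimum spanning tree over a distance matrix (Prim).
mst_length <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  total
}

## Majority-state median of three character vectors (binary characters with
## possible NA; ties from missing data resolved toward the first vector).
median_vector <- function(u, v, w) {
  m <- integer(length(u))
  for (k in seq_along(u)) {
    vals <- c(u[k], v[k], w[k])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) { m[k] <- NA_integer_; next }
    ones <- sum(vals == 1L)
    m[k] <- if (ones * 2L > length(vals)) 1L
            else if (ones * 2L < length(vals)) 0L
            else vals[1]
  }
  m
}

#' Build a reticulate parsimony network over haplotypes
#'
#' Median-joining-style construction (epsilon = 0) on the binary character
#' matrix (biallelic substitutions, expanded multi-allelic alleles, and the
#' indel presence/absence character).  In each round the minimum spanning
#' network over the current node set is computed; for every triple of nodes
#' joined by two network links, the majority-state median (Steiner) vector is
#' a candidate node, and the medians with minimal connection cost are added.
#' Iteration stops when no new median is needed.  All minimum-length
#' alternative connections are retained, so character conflict (recombination
#' or repeat mutation) appears as cycles — reticulations — rather than being
#' resolved arbitrarily.
#'
#' @param hapset a [hap_set()] from [collapse_haplotypes()].
#' @param max_iter safety cap on median-addition rounds.
#' @return An object of class `hap_network`: list with
#'   \describe{
#'     \item{graph}{an `igraph` graph; vertex attributes `name`, `sampled`,
#'       `roman`, `size` (member count), `groups`; edge attributes
#'       `positions` (comma-joined labels), `chars`, `weight`.}
#'     \item{node_states}{node x character 0/1 matrix (sampled + median
#'       nodes).}
#'     \item{edges}{data.frame `from`, `to`, `chars` (list-column),
#'       `positions`.}
#'     \item{m}{total substitution occurrences over edge labels (repeats
#'       counted).}
#'     \item{char_info}{character metadata from the encoding.}
#'     \item{hapset}{the input haplotype set.}
#'   }
#' @export
build_network <- function(hapset, max_iter = 200L) {
  stopifnot(inherits(hapset, "hap_set"))
  info <- hapset$char_info
  w <- info$weight
  nodes <- hapset$char_matrix
  sampled <- rep(TRUE, nrow(nodes))
  n_median <- 0L

  if (nrow(nodes) > 1L && ncol(nodes) > 0L) {
    for (iter in seq_len(max_iter)) {
      D <- dist_matrix(nodes, w)
      ed <- msn_edges(D)
      adj <- vector("list", nrow(nodes))
      for (r in seq_len(nrow(ed))) {
        adj[[ed[r, 1]]] <- c(adj[[ed[r, 1]]], ed[r, 2])
        adj[[ed[r, 2]]] <- c(adj[[ed[r, 2]]], ed[r, 1])
      }
      cand <- list(); cost <- numeric(0)
      seen_key <- character(0)
      node_keys <- apply(nodes, 1, function(r)
        paste(ifelse(is.na(r), "?", r), collapse = ""))
      for (u in seq_len(nrow(nodes))) {
        nb <- adj[[u]]
        if (length(nb) < 2L) next
        for (a in seq_len(length(nb) - 1L)) {
          for (b in (a + 1L):length(nb)) {
            med <- median_vector(nodes[u, ], nodes[nb[a], ], nodes[nb[b], ])
            key <- paste(ifelse(is.na(med), "?", med), collapse = "")
            if (key %in% node_keys || key %in% seen_key) next
            lam <- char_dist(med, nodes[u, ], w) +
              char_dist(med, nodes[nb[a], ], w) +
              char_dist(med, nodes[nb[b], ], w)
            cand[[length(cand) + 1L]] <- med
            cost <- c(cost, lam)
            seen_key <- c(seen_key, key)
          }
        }
      }
      if (length(cand) == 0L) break
      ## add one median per round (minimal connection cost, deterministic
      ## tie-break on the state key) and recompute the spanning network, so
      ## an early median cannot lock in a poor Steiner layout
      best <- which(cost == min(cost))
      if (length(best) > 1L) best <- best[order(seen_key[best])][1]
      n_median <- n_median + 1L
      nodes <- rbind(nodes, cand[[best]])
      rownames(nodes)[nrow(nodes)] <- sprintf("M%02d", n_median)
      sampled <- c(sampled, FALSE)
    }
  }

  ## Steiner improvement: the greedy median rounds can misplace a repeated
  ## mutation as a false synapomorphy, inflating total network length.
  ## Propose the majority median of every node triple and accept additions
  ## that strictly shorten the minimum spanning tree over the node set.
  if (nrow(nodes) > 2L && ncol(nodes) > 0L) {
    for (round in seq_len(max_iter)) {
      D <- dist_matrix(nodes, w)
      T0 <- mst_length(D)
      node_keys <- apply(nodes, 1, function(r)
        paste(ifelse(is.na(r), "?", r), collapse = ""))
      cand <- list(); seen <- character(0)
      nn <- nrow(nodes)
      for (i in seq_len(nn - 2L))
        for (j in (i + 1L):(nn - 1L))
          for (k in (j + 1L):nn) {
            med <- median_vector(nodes[i, ], nodes[j, ], nodes[k, ])
            key <- paste(ifelse(is.na(med), "?", med), collapse = "")
            if (key %in% node_keys || key %in% seen) next
            seen <- c(seen, key)
            cand[[length(cand) + 1L]] <- med
          }
      if (length(cand) == 0L) break
      scores <- vapply(cand, function(med) {
        dmed <- apply(nodes, 1, char_dist, b = med, w = w)
        mst_length(rbind(cbind(D, dmed), c(dmed, 0)))
      }, 0)
      ord <- order(scores, seen)
      if (scores[ord[1]] >= T0 - 1e-9) break
      n_median <- n_median + 1L
      nodes <- rbind(nodes, cand[[ord[1]]])
      rownames(nodes)[nrow(nodes)] <- sprintf("M%02d", n_median)
      sampled <- c(sampled, FALSE)
    }
  }

  D <- dist_matrix(nodes, w)
  ed <- msn_edges(D)

  ## prune unsampled leaves (medians that ended up informative for nothing)
  repeat {
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(nodes))
    drop <- which(!sampled & deg <= 1L)
    if (length(drop) == 0L || nrow(nodes) <= 1L) break
    keep <- setdiff(seq_len(nrow(nodes)), drop)
    remap <- match(seq_len(nrow(nodes)), keep)
    nodes <- nodes[keep, , drop = FALSE]
    sampled <- sampled[keep]
    ed <- ed[ed[, 1] %in% keep & ed[, 2] %in% keep, , drop = FALSE]
    ed[] <- remap[ed]
  }

  node_ids <- rownames(nodes)
  edges <- data.frame(from = node_ids[ed[, 1]], to = node_ids[ed[, 2]],
                      stringsAsFactors = FALSE)
  chars <- lapply(seq_len(nrow(ed)), function(r) {
    diff <- which(nodes[ed[r, 1], ] != nodes[ed[r, 2], ])
    info$char[diff]
  })
  edges$chars <- chars
  edges$positions <- vapply(chars, function(cs)
    paste(info$label[match(cs, info$char)], collapse = ","), "")
  edges$weight <- vapply(chars, function(cs)
    sum(info$weight[match(cs, info$char)]), 0)
  edges$n_subs <- vapply(chars, function(cs)
    sum(info$type[match(cs, info$char)] == "substitution"), 0L)

  m <- sum(edges$n_subs)

  hap_ids <- vapply(hapset$haplotypes, `[[`, "", "id")
  sizes <- integer(length(node_ids)); romans <- rep("", length(node_ids))
  grp <- rep("", length(node_ids))
  for (i in seq_along(node_ids)) {
    h <- match(node_ids[i], hap_ids)
    if (!is.na(h)) {
      sizes[i] <- length(hapset$haplotypes[[h]]$members)
      romans[i] <- hapset$haplotypes[[h]]$roman
      gc <- hapset$haplotypes[[h]]$group_counts
      grp[i] <- paste(names(gc), gc, sep = ":", collapse = ",")
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = node_ids, sampled = sampled, roman = romans,
                          size = sizes, groups = grp,
                          stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$positions <- edges$positions
    igraph::E(g)$weight <- edges$weight
    igraph::E(g)$n_subs <- edges$n_subs
  }

  structure(
    list(graph = g, node_states = nodes, sampled = sampled, edges = edges,
         m = m, char_info = info, hapset = hapset),
    class = "hap_network"
  )
}

#' @export
print.hap_network <- function(x, ...) {
  cat("hap_network:", sum(x$sampled), "sampled +", sum(!x$sampled),
      "median nodes,", nrow(x$edges), "edges, m =", x$m,
      "substitution occurrences\n")
  hp <- count_homoplasies(x)
  cat("homoplasies:", hp$H_net, "\n")
  invisible(x)
}

#' Count homoplasies in a haplotype network
#'
#' A homoplasy is a character (position plus derived state) appearing on two
#' or more edges of the network; each extra occurrence counts once, so a
#' character on `k` edges contributes `k - 1`.
#'
#' @param net a [build_network()] result.
#' @return list with `H_net` (total count) and `per_position` (named integer
#'   vector of extra occurrences for each homoplasious character, named by
#'   its position label).
#' @export
count_homoplasies <- function(net) {
  stopifnot(inherits(net, "hap_network"))
  occ <- table(unlist(net$edges$chars))
  extra <- occ[occ >= 2L] - 1L
  per_position <- stats::setNames(
    as.integer(extra),
    net$char_info$label[match(names(extra), net$char_info$char)])
  list(H_net = sum(extra), per_position = per_position)
}

## characters appearing on >= 2 edges (the homoplasy set)
homoplasious_chars <- function(net) {
  occ <- table(unlist(net$edges$chars))
  names(occ)[occ >= 2L]
}

#' Identify the domestication common ancestor (DCA) node
#'
#' Scores every network node by its total shortest-path parsimony length to
#' all nodes carrying at least one cultivated-group member, and returns the
#' minimizer.  Ties are broken by the fewest homoplasious characters on the
#' connecting shortest paths, then by lexicographic node id.
#'
#' @param net a [build_network()] result.
#' @param cultivated_groups character vector of group labels counted as
#'   cultivated.
#' @return list with `node` (the DCA node id) and `scores` (data.frame of
#'   `node`, `total_length`, `path_homoplasies` for every candidate).
#' @export
identify_dca <- function(net, cultivated_groups) {
  stopifnot(inherits(net, "hap_network"))
  hap_ids <- vapply(net$hapset$haplotypes, `[[`, "", "id")
  has_cult <- vapply(net$hapset$haplotypes, function(h)
    any(names(h$group_counts) %in% cultivated_groups &
          h$group_counts > 0), TRUE)
  targets <- hap_ids[has_cult]
  targets <- intersect(targets, rownames(net$node_states))
  if (length(targets) == 0L)
    stop("no cultivated samples in any network node", call. = FALSE)

  g <- net$graph
  ids <- igraph::V(g)$name
  dmat <- igraph::distances(g, weights = igraph::E(g)$weight)
  hchars <- homoplasious_chars(net)

  total_len <- rowSums(dmat[, targets, drop = FALSE])
  path_hp <- vapply(ids, function(v) {
    tot <- 0L
    for (t in targets) {
      if (v == t) next
      sp <- igraph::shortest_paths(g, from = v, to = t, output = "epath",
                                   weights = igraph::E(g)$weight)$epath[[1]]
      cs <- unlist(net$edges$chars[as.integer(sp)])
      tot <- tot + sum(cs %in% hchars)
    }
    tot
  }, 0L)

  ord <- order(total_len, path_hp, ids)
  list(node = ids[ord[1]],
       scores = data.frame(node = ids, total_length = unname(total_len),
                           path_homoplasies = unname(path_hp),
                           stringsAsFactors = FALSE)[ord, ])
}

#' Export the network as GraphML
#'
#' @param net a [build_network()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network_graphml <- function(net, file) {
  igraph::write_graph(net$graph, file, format = "graphml")
  invisible(file)
}

#' Export the network as Graphviz DOT
#'
#' Nodes are labelled by haplotype id (Roman numeral alias and member count
#' for sampled nodes); edges carry a `label`/`positions` attribute listing
#' the mutated positions.
#'
#' @param net a [build_network()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network_dot <- function(net, file) {
  g <- net$graph
  lab <- ifelse(igraph::V(g)$sampled,
                paste0(igraph::V(g)$roman, " (", igraph::V(g)$size, ")"),
                igraph::V(g)$name)
  igraph::V(g)$label <- lab
  igraph::V(g)$sampled <- as.integer(igraph::V(g)$sampled)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$label <- igraph::E(g)$positions
  igraph::write_graph(g, file, format = "dot")
  invisible(file)
}
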