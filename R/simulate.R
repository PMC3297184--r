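#' Simulation configuration
#'
#' Describes a synthetic locus survey: a random ranked-coalescent haplotype
#' genealogy carrying infinite-sites mutations, optional planted homoplasies
#' (exact repeat mutations: same column, same derived base, on branches whose
#' conflict is detectable), optional recombinant mosaic haplotypes appended as
#' extra nodes, one multi-column indel segregating as a single character, and
#' group-structured sample counts.
#'
#' @param seed integer RNG seed; output is byte-reproducible given the seed.
#' @param L alignment length in bp.
#' @param n_haplotypes number of genealogy tips (before recombinants).
#' @param mutations_per_branch fixed count (`mutation_dist = "fixed"`) or
#'   Poisson mean (`"poisson"`) of mutations per branch.
#' @param mutation_dist `"fixed"` or `"poisson"`.
#' @param n_homoplasies exact number of repeat mutations to plant (ignored
#'   when `homoplasy_prob` is given).
#' @param homoplasy_prob per-mutation probability that a mutation is planted
#'   as a repeat of another; `NULL` for exact-count planting.
#' @param recombinants data.frame with columns `parent1`, `parent2`,
#'   `breakpoint`: each row appends one mosaic haplotype equal to
#'   `parent1[1..b]` followed by `parent2[(b+1)..L]`.
#' @param indel `NULL`, or list with `start`, `length`, and `carriers`
#'   (haplotype indices receiving the deletion).
#' @param samples_per_haplotype integer (recycled) or vector of member counts
#'   per haplotype (tree tips first, then recombinants).
#' @param group_labels character vector (recycled) of group per haplotype.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, L = 1000L, n_haplotypes = 6L,
                       mutations_per_branch = 2,
                       mutation_dist = c("fixed", "poisson"),
                       n_homoplasies = 0L, homoplasy_prob = NULL,
                       recombinants = NULL, indel = NULL,
                       samples_per_haplotype = 3L,
                       group_labels = "g1") {
  mutation_dist <- match.arg(mutation_dist)
  if (L < 2L) stop("L must be >= 2", call. = FALSE)
  if (n_haplotypes < 2L) stop("need at least 2 haplotypes", call. = FALSE)
  n_total <- n_haplotypes + if (is.null(recombinants)) 0L else nrow(recombinants)
  if (!is.null(recombinants)) {
    stopifnot(all(c("parent1", "parent2", "breakpoint") %in%
                    names(recombinants)))
    if (any(recombinants$breakpoint < 1L | recombinants$breakpoint >= L))
      stop("breakpoint must lie in [1, L-1]", call. = FALSE)
    if (any(recombinants$parent1 > n_haplotypes |
              recombinants$parent2 > n_haplotypes))
      stop("recombinant parents must be genealogy tips", call. = FALSE)
  }
  if (!is.null(indel)) {
    stopifnot(all(c("start", "length", "carriers") %in% names(indel)))
    if (indel$start < 1L || indel$start + indel$length - 1L > L)
      stop("indel outside alignment", call. = FALSE)
    if (!identical(indel$carriers, "clade") &&
        any(indel$carriers > n_total))
      stop("indel carriers out of range", call. = FALSE)
  }
  sph <- rep_len(as.integer(samples_per_haplotype), n_total)
  if (any(sph < 1L)) stop("each haplotype needs >= 1 sample", call. = FALSE)
  structure(
    list(seed = as.integer(seed), L = as.integer(L),
         n_haplotypes = as.integer(n_haplotypes),
         mutations_per_branch = mutations_per_branch,
         mutation_dist = mutation_dist,
         n_homoplasies = as.integer(n_homoplasies),
         homoplasy_prob = homoplasy_prob,
         recombinants = recombinants, indel = indel,
         samples_per_haplotype = sph,
         group_labels = rep_len(group_labels, n_total)),
    class = "sim_config"
  )
}

## random ranked coalescent topology: tips 1..n, internals n+1..2n-1 (root
## last); returns parent vector indexed by node id (root = NA)
random_topology <- function(n) {
  parent <- rep(NA_integer_, 2L * n - 1L)
  active <- seq_len(n)
  nxt <- n + 1L
  while (length(active) > 1L) {
    pick <- sample(length(active), 2L)
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  parent
}

## tip set below each node
node_tipsets <- function(parent, n) {
  total <- length(parent)
  tips <- vector("list", total)
  for (t in seq_len(n)) {
    v <- t
    while (!is.na(v)) {
      tips[[v]] <- c(tips[[v]], t)
      v <- parent[v]
    }
  }
  lapply(tips, sort)
}

## Detectability rule for a planted repeat: the two branches must carry
## disjoint tip sets (a repeat below an ancestor of the first hit never
## changes any sequence), and the combined carrier set must form a split
## incompatible with every branch of the unrooted genealogy: neither the
## union nor its complement may equal an existing clade, otherwise the
## repeated character aliases a single mutation on that branch and no
## character conflict is observable.
eligible_partner <- function(b1, b2, tipsets, branch_nodes, n_tips) {
  t1 <- tipsets[[b1]]; t2 <- tipsets[[b2]]
  if (length(intersect(t1, t2)) > 0L) return(FALSE)
  u <- sort(c(t1, t2))
  ## a repeat covering every tip makes the column monomorphic again
  if (length(u) == n_tips) return(FALSE)
  comp <- setdiff(seq_len(n_tips), u)
  for (b in branch_nodes) {
    if (identical(u, tipsets[[b]])) return(FALSE)
    if (identical(comp, tipsets[[b]])) return(FALSE)
  }
  TRUE
}

#' Simulate a synthetic locus alignment with truth record
#'
#' @param config a [sim_config()].
#' @return list of class `hap_sim` with elements `alignment` (a
#'   [hap_alignment()]), `truth` (machine-readable truth record: genealogy,
#'   per-branch mutations with homoplasy flags, recombinants, indel carriers,
#'   haplotype membership, root sequence), and `config`.
#' @seealso [truth_replay()], [sim_write()]
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_haplotypes
  L <- config$L
  parent <- random_topology(n)
  total_nodes <- length(parent)
  root <- which(is.na(parent))
  branch_nodes <- setdiff(seq_len(total_nodes), root)
  tipsets <- node_tipsets(parent, n)

  ## positions available for substitution mutations (indel block reserved)
  pool <- seq_len(L)
  if (!is.null(config$indel))
    pool <- setdiff(pool, config$indel$start:(config$indel$start +
                                                config$indel$length - 1L))

  root_seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  ## infinite-sites mutations per branch
  counts <- vapply(branch_nodes, function(b) {
    if (config$mutation_dist == "fixed") as.integer(config$mutations_per_branch)
    else stats::rpois(1L, config$mutations_per_branch)
  }, 1L)
  m_total <- sum(counts)
  if (m_total > length(pool))
    stop("more mutations than available positions", call. = FALSE)
  pos_all <- sample(pool, m_total)
  mut <- data.frame(branch = rep(branch_nodes, counts), pos = pos_all,
                    stringsAsFactors = FALSE)
  mut$from <- root_seq[mut$pos]
  mut$to <- vapply(mut$from, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  mut$homoplasy <- rep(FALSE, nrow(mut))

  ## planted repeat mutations
  plant <- function(donor_idx) {
    b1 <- mut$branch[donor_idx]
    elig <- branch_nodes[vapply(branch_nodes, function(b2)
      b2 != b1 && eligible_partner(b1, b2, tipsets, branch_nodes, n), TRUE)]
    elig <- setdiff(elig, mut$branch[mut$pos == mut$pos[donor_idx]])
    if (length(elig) == 0L) return(NULL)
    b2 <- if (length(elig) == 1L) elig else sample(elig, 1L)
    data.frame(branch = b2, pos = mut$pos[donor_idx],
               from = mut$from[donor_idx], to = mut$to[donor_idx],
               homoplasy = TRUE, stringsAsFactors = FALSE)
  }
  if (!is.null(config$homoplasy_prob)) {
    ## each mutation is independently homoplasious with the given
    ## probability; when the flagged mutation itself has no detectable
    ## partner branch the repeat is redirected to a feasible donor, keeping
    ## the total planted count Binomial(m, prob)
    hits <- which(stats::runif(nrow(mut)) < config$homoplasy_prob)
    for (i in hits) {
      row <- plant(i)
      if (is.null(row)) {
        donors <- which(!mut$homoplasy)
        donors <- if (length(donors) > 1L) sample(donors) else donors
        for (j in donors) {
          row <- plant(j)
          if (!is.null(row)) break
        }
      }
      if (!is.null(row)) mut <- rbind(mut, row)
    }
  } else if (config$n_homoplasies > 0L) {
    planted <- 0L
    guard <- 0L
    while (planted < config$n_homoplasies) {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("infeasible config: cannot place ", config$n_homoplasies,
             " detectable homoplasies", call. = FALSE)
      donors <- which(!mut$homoplasy)
      row <- plant(if (length(donors) == 1L) donors else sample(donors, 1L))
      if (!is.null(row)) {
        mut <- rbind(mut, row)
        planted <- planted + 1L
      }
    }
  }

  ## tip sequences: apply branch mutations along the root-to-tip path
  branch_mut <- split(seq_len(nrow(mut)), mut$branch)
  hap_seq <- vector("list", n)
  for (t in seq_len(n)) {
    s <- root_seq
    path <- t
    v <- t
    while (!is.na(parent[v])) { v <- parent[v]; path <- c(path, v) }
    for (b in rev(path)) {
      idx <- branch_mut[[as.character(b)]]
      if (!is.null(idx)) s[mut$pos[idx]] <- mut$to[idx]
    }
    hap_seq[[t]] <- s
  }

  ## recombinant mosaics appended as extra haplotypes
  rec <- config$recombinants
  if (!is.null(rec)) {
    for (r in seq_len(nrow(rec))) {
      b <- rec$breakpoint[r]
      s <- c(hap_seq[[rec$parent1[r]]][1:b],
             hap_seq[[rec$parent2[r]]][(b + 1L):L])
      hap_seq[[length(hap_seq) + 1L]] <- s
    }
  }
  n_total <- length(hap_seq)

  ## the indel: one multi-column deletion carried by the configured
  ## haplotypes; carriers = "clade" resolves to the largest internal-branch
  ## clade holding at most half the tips, so the deletion segregates as a
  ## single tree-consistent character
  indel_carriers <- NULL
  if (!is.null(config$indel)) {
    indel_carriers <- config$indel$carriers
    if (identical(indel_carriers, "clade")) {
      sizes <- vapply(tipsets[branch_nodes], length, 1L)
      ok <- which(sizes >= 2L & sizes <= ceiling(n / 2))
      if (length(ok) == 0L) ok <- which(sizes >= 1L & sizes < n)
      pick <- branch_nodes[ok[order(-sizes[ok], branch_nodes[ok])][1]]
      indel_carriers <- tipsets[[pick]]
    }
    span <- config$indel$start:(config$indel$start + config$indel$length - 1L)
    for (h in indel_carriers) hap_seq[[h]][span] <- "-"
  }

  ## samples
  sph <- config$samples_per_haplotype
  ids <- sprintf("acc%03d", seq_len(sum(sph)))
  hap_of <- rep(seq_len(n_total), sph)
  seqs <- vapply(hap_of, function(h) paste(hap_seq[[h]], collapse = ""), "")
  groups <- stats::setNames(config$group_labels[hap_of], ids)
  aln <- hap_alignment(ids, seqs, groups)

  truth <- list(
    seed = config$seed, L = L, n_haplotypes = n,
    tree = data.frame(child = branch_nodes, parent = parent[branch_nodes]),
    root_seq = paste(root_seq, collapse = ""),
    mutations = mut,
    recombinants = rec,
    indel = if (is.null(config$indel)) NULL else
      list(start = config$indel$start, length = config$indel$length,
           carriers = indel_carriers),
    haplotype_of = stats::setNames(hap_of, ids),
    groups = as.list(groups)
  )
  structure(list(alignment = aln, truth = truth, config = config),
            class = "hap_sim")
}

#' Rebuild the simulated alignment from its truth record alone
#'
#' Deterministic replay (no random number generation): haplotype sequences
#' are reconstructed from the recorded root sequence, genealogy, and
#' per-branch mutations, then recombinants, the indel, and sample membership
#' are re-applied.  The result is identical to the originally emitted
#' alignment, which is the closure property validating the truth record.
#'
#' @param truth the `truth` element of a [simulate_alignment()] result.
#' @return a [hap_alignment()].
#' @export
truth_replay <- function(truth) {
  L <- truth$L; n <- truth$n_haplotypes
  parent <- rep(NA_integer_, max(c(truth$tree$child, truth$tree$parent)))
  parent[truth$tree$child] <- truth$tree$parent
  root_seq <- strsplit(truth$root_seq, "")[[1]]
  mut <- truth$mutations
  branch_mut <- split(seq_len(nrow(mut)), mut$branch)
  hap_seq <- vector("list", n)
  for (t in seq_len(n)) {
    s <- root_seq
    path <- t; v <- t
    while (!is.na(parent[v])) { v <- parent[v]; path <- c(path, v) }
    for (b in rev(path)) {
      idx <- branch_mut[[as.character(b)]]
      if (!is.null(idx)) s[mut$pos[idx]] <- mut$to[idx]
    }
    hap_seq[[t]] <- s
  }
  if (!is.null(truth$recombinants)) {
    rec <- truth$recombinants
    for (r in seq_len(nrow(rec))) {
      b <- rec$breakpoint[r]
      hap_seq[[length(hap_seq) + 1L]] <-
        c(hap_seq[[rec$parent1[r]]][1:b],
          hap_seq[[rec$parent2[r]]][(b + 1L):L])
    }
  }
  if (!is.null(truth$indel)) {
    span <- truth$indel$start:(truth$indel$start + truth$indel$length - 1L)
    for (h in truth$indel$carriers) hap_seq[[h]][span] <- "-"
  }
  ids <- names(truth$haplotype_of)
  hap_of <- unlist(truth$haplotype_of)
  seqs <- vapply(hap_of, function(h) paste(hap_seq[[h]], collapse = ""), "")
  hap_alignment(ids, unname(seqs),
                stats::setNames(unlist(truth$groups), names(truth$groups)))
}

#' Write a simulation to disk (FASTA + groups TSV + truth JSON)
#'
#' @param sim a [simulate_alignment()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
sim_write <- function(sim, dir) {
  stopifnot(inherits(sim, "hap_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "alignment.fasta")
  gr <- file.path(dir, "groups.tsv")
  tj <- file.path(dir, "truth.json")
  write_alignment(sim$alignment, fa, gr)
  truth <- sim$truth
  truth$haplotype_of <- as.list(truth$haplotype_of)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fa, groups = gr, truth = tj))
}

#' Domestication-scale simulation preset
#'
#' A fixed configuration mirroring the magnitudes of a locus-specific crop
#' domestication survey: a 2560-bp alignment, 113 samples, 11 haplotypes
#' (9 genealogy tips plus 2 recombinant mosaics), 2 fixed mutations per
#' branch (32 tree substitutions, 39 total edge occurrences once the 7
#' planted repeat mutations are added), one 46-bp deletion carried by a wild
#' clade plus the dehiscent group, and wild groups spread over more
#' haplotypes than the bottlenecked cultivated groups.
#'
#' @param seed RNG seed (the preset's genealogy and mutation layout follow
#'   from it; the default defines the reference conditions used in the
#'   package's integration tests).
#' @return a [sim_config()].
#' @export
sim_preset_domestication <- function(seed = 101L) {
  sim_config(
    seed = seed, L = 2560L, n_haplotypes = 9L,
    mutations_per_branch = 2, mutation_dist = "fixed",
    n_homoplasies = 2L,
    recombinants = data.frame(parent1 = c(1L, 3L), parent2 = c(9L, 7L),
                              breakpoint = c(1280L, 1600L)),
    indel = list(start = 562L, length = 46L, carriers = "clade"),
    samples_per_haplotype = c(12L, 10L, 8L, 7L, 6L, 8L, 19L, 16L, 15L,
                              9L, 3L),
    group_labels = c("wild-turkey", "wild-turkey", "wild-turkey",
                     "wild-other", "wild-other", "dehiscent", "oil",
                     "fiber", "winter", "landrace", "oil")
  )
}

#' Cultivated group labels of the domestication preset
#' @return character vector of the preset's cultivated group labels.
#' @export
preset_cultivated_groups <- function() {
  c("dehiscent", "oil", "fiber", "winter", "landrace")
}
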