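#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Four-gamete scan over all pairs of biallelic substitution sites: a pair
#' showing all four allele combinations is incompatible with a single
#' genealogy under infinite sites and brackets at least one recombination
#' event.  The incompatible site pairs are reduced to a maximal set of
#' disjoint intervals (Hudson & Kaplan 1985), whose size is the lower bound
#' Rm.  Samples missing a base at either site of a pair are excluded pairwise;
#' sites with more than two alleles are skipped.
#'
#' @param aln a [hap_alignment()] object.
#' @param group optional group label restricting the samples.
#' @param regions,region optional region restriction.
#' @return list with `Rm` (integer) and `intervals` (data.frame `left`,
#'   `right` of 1-based site positions bracketing each inferred event;
#'   zero rows when no incompatible pair exists).
#' @export
hudson_kaplan_rm <- function(aln, group = NULL, regions = NULL,
                             region = NULL) {
  samples <- group_samples(aln, group)
  sub <- subset_alignment(aln, samples = samples)
  st <- segregating_sites(sub, regions, region)
  biallelic <- which(vapply(st$alleles, length, 1L) == 2L)
  pos <- st$positions[biallelic]
  states <- st$states[, biallelic, drop = FALSE]
  empty <- list(Rm = 0L,
                intervals = data.frame(left = integer(0), right = integer(0)))
  if (length(pos) < 2L) return(empty)

  ## all incompatible (four-gamete) pairs, as intervals (pos_i, pos_j)
  ivl <- matrix(integer(0), ncol = 2)
  for (i in seq_len(length(pos) - 1L)) {
    for (j in (i + 1L):length(pos)) {
      a <- states[, i]; b <- states[, j]
      ok <- a != "N" & b != "N"
      if (four_gametes(a[ok], b[ok]))
        ivl <- rbind(ivl, c(pos[i], pos[j]))
    }
  }
  if (nrow(ivl) == 0L) return(empty)
  sel <- disjoint_intervals(ivl)
  list(Rm = nrow(sel),
       intervals = data.frame(left = sel[, 1], right = sel[, 2]))
}

## TRUE when two site columns show all four allele combinations.
four_gametes <- function(a, b) {
  length(unique(paste(a, b))) == 4L
}

## Hudson-Kaplan reduction: drop intervals containing another interval, then
## greedily pick non-overlapping intervals left to right (events occur in the
## open interval, so (a,b) and (b,c) are disjoint).
disjoint_intervals <- function(ivl) {
  keep <- rep(TRUE, nrow(ivl))
  for (i in seq_len(nrow(ivl))) {
    for (j in seq_len(nrow(ivl))) {
      if (i != j && keep[i] &&
          ivl[j, 1] >= ivl[i, 1] && ivl[j, 2] <= ivl[i, 2] &&
          !(ivl[j, 1] == ivl[i, 1] && ivl[j, 2] == ivl[i, 2]))
        keep[i] <- FALSE
    }
  }
  ivl <- ivl[keep, , drop = FALSE]
  ivl <- ivl[order(ivl[, 2], ivl[, 1]), , drop = FALSE]
  out <- matrix(integer(0), ncol = 2)
  last_end <- -Inf
  for (i in seq_len(nrow(ivl))) {
    if (ivl[i, 1] >= last_end) {
      out <- rbind(out, ivl[i, ])
      last_end <- ivl[i, 2]
    }
  }
  out
}
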