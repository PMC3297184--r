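#' Tabulate segregating sites and indel events
#'
#' Scans the alignment for variable columns.  Maximal runs of gap columns
#' sharing the same carrier pattern are collapsed into single indel events and
#' are excluded from the substitution site list, so a multi-base deletion
#' segregates as one character rather than one per column.  Columns containing
#' any gap are excluded from the substitution scan (complete deletion); `N`
#' symbols are treated as missing within a column but do not remove it.
#'
#' @param aln a [hap_alignment()] object.
#' @param regions optional [hap_regions()] annotation.
#' @param region optional region name restricting the scan.
#' @return An object of class `hap_sites`: list with
#'   \describe{
#'     \item{positions}{sorted 1-based columns of biallelic/multiallelic
#'       substitution sites.}
#'     \item{alleles}{list (per position) of allele -> count tables over
#'       non-missing states.}
#'     \item{states}{n x S character matrix of per-sample states at
#'       `positions`.}
#'     \item{informative}{logical per position: >= 2 alleles each carried by
#'       >= 2 samples.}
#'     \item{gap_columns}{columns containing at least one gap symbol.}
#'     \item{indel_events}{data.frame `start`, `end`, `length` plus a
#'       `carriers` list-column of gap-carrying sample ids.}
#'   }
#' @export
segregating_sites <- function(aln, regions = NULL, region = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  cols <- region_columns(regions, region, aln$L)
  mat <- aln$seq[, cols, drop = FALSE]

  gap_local <- which(apply(mat == "-", 2, any))
  gap_columns <- cols[gap_local]

  ## collapse maximal runs of adjacent gap columns with identical carrier
  ## pattern into indel events
  indel_events <- data.frame(start = integer(0), end = integer(0),
                             length = integer(0))
  indel_events$carriers <- list()
  if (length(gap_local)) {
    pat <- apply(mat[, gap_local, drop = FALSE] == "-", 2, paste,
                 collapse = "")
    run_id <- cumsum(c(TRUE, diff(gap_local) != 1L | pat[-1] != pat[-length(pat)]))
    starts <- ends <- integer(0); carriers <- list()
    for (r in unique(run_id)) {
      idx <- gap_local[run_id == r]
      starts <- c(starts, cols[idx[1]])
      ends <- c(ends, cols[idx[length(idx)]])
      carriers <- c(carriers, list(aln$sample_ids[mat[, idx[1]] == "-"]))
    }
    indel_events <- data.frame(start = starts, end = ends,
                               length = ends - starts + 1L)
    indel_events$carriers <- carriers
  }

  subs_local <- setdiff(seq_len(ncol(mat)), gap_local)
  keep <- positions <- integer(0)
  alleles <- list(); informative <- logical(0)
  for (j in subs_local) {
    col <- mat[, j]
    tab <- table(col[col != "N"])
    if (length(tab) >= 2L) {
      keep <- c(keep, j)
      positions <- c(positions, cols[j])
      alleles <- c(alleles, list(tab))
      informative <- c(informative, sum(tab >= 2L) >= 2L)
    }
  }
  states <- mat[, keep, drop = FALSE]
  colnames(states) <- as.character(positions)

  structure(
    list(positions = positions, alleles = alleles, states = states,
         informative = informative, gap_columns = gap_columns,
         indel_events = indel_events, n = aln$n),
    class = "hap_sites"
  )
}

#' @export
print.hap_sites <- function(x, ...) {
  cat("hap_sites: S =", length(x$positions), "substitution sites,",
      nrow(x$indel_events), "indel event(s)\n")
  invisible(x)
}
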