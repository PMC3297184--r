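## Binary character encoding shared by haplotype collapsing and network
## construction.  Each biallelic substitution site becomes one 0/1 character;
## a site with k > 2 alleles expands into k - 1 characters (one per derived
## allele, the majority allele taken as reference); each indel event becomes
## one presence/absence character when indel_mode = "include".  Missing
## states are NA.
encode_characters <- function(aln, sites,
                              indel_mode = c("include", "exclude"),
                              indel_weight = 1) {
  indel_mode <- match.arg(indel_mode)
  n <- aln$n
  cols <- list(); info <- list()
  for (k in seq_along(sites$positions)) {
    tab <- sort(sites$alleles[[k]], decreasing = TRUE)
    ref <- names(tab)[1]
    states <- sites$states[, k]
    for (alt in names(tab)[-1]) {
      v <- ifelse(states == "N", NA_integer_, as.integer(states == alt))
      cols[[length(cols) + 1L]] <- v
      info[[length(info) + 1L]] <- data.frame(
        label = as.character(sites$positions[k]),
        position = sites$positions[k], type = "substitution",
        ref = ref, alt = alt, weight = 1,
        stringsAsFactors = FALSE)
    }
  }
  if (indel_mode == "include" && nrow(sites$indel_events) > 0L) {
    for (k in seq_len(nrow(sites$indel_events))) {
      ev <- sites$indel_events[k, ]
      v <- as.integer(aln$sample_ids %in% ev$carriers[[1]])
      cols[[length(cols) + 1L]] <- v
      info[[length(info) + 1L]] <- data.frame(
        label = sprintf("indel%d-%d", ev$start, ev$end),
        position = ev$start, type = "indel",
        ref = "present", alt = "gap", weight = indel_weight,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cols)) {
    mat <- do.call(cbind, cols)
    info <- do.call(rbind, info)
    ## character key: label + derived state, the unit homoplasies are counted
    ## over (same position AND same derived base)
    info$char <- ifelse(info$type == "substitution",
                        paste0(info$label, ">", info$alt), info$label)
    colnames(mat) <- info$char
  } else {
    mat <- matrix(integer(0), nrow = n, ncol = 0)
    info <- data.frame(label = character(0), position = integer(0),
                       type = character(0), ref = character(0),
                       alt = character(0), weight = numeric(0),
                       char = character(0), stringsAsFactors = FALSE)
  }
  rownames(mat) <- aln$sample_ids
  list(matrix = mat, info = info)
}

#' Collapse samples into haplotypes
#'
#' Samples sharing the same state at every segregating character (substitution
#' sites, plus indel events when `indel_mode = "include"`) are merged into one
#' haplotype.  Haplotype ids are deterministic: numbered in order of the first
#' occurring member sample, with Roman numeral aliases for report parity with
#' the conventional network figure labelling.
#'
#' @param aln a [hap_alignment()] object.
#' @param sites a [segregating_sites()] table for the same alignment (computed
#'   if omitted).
#' @param indel_mode `"include"` (default) codes each indel event as one extra
#'   presence/absence character; `"exclude"` drops indels entirely.
#' @param indel_weight weight of an indel character in network distances.
#' @return An object of class `hap_set`: list with `haplotypes` (a list of
#'   per-haplotype records: `id`, `roman`, `members`, `group_counts`,
#'   `states`), `char_matrix` (haplotype x character 0/1 matrix),
#'   `char_info`, `sample_haplotype` (named vector sample -> haplotype id),
#'   and `n` (sample count).
#' @export
collapse_haplotypes <- function(aln, sites = NULL,
                                indel_mode = c("include", "exclude"),
                                indel_weight = 1) {
  indel_mode <- match.arg(indel_mode)
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(sites)) sites <- segregating_sites(aln)
  enc <- encode_characters(aln, sites, indel_mode, indel_weight)
  key <- apply(enc$matrix, 1, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  first <- !duplicated(key)
  hap_keys <- key[first]
  hap_of <- match(key, hap_keys)
  names(hap_of) <- aln$sample_ids

  haplotypes <- lapply(seq_along(hap_keys), function(h) {
    members <- aln$sample_ids[hap_of == h]
    list(id = sprintf("H%02d", h),
         roman = as.character(utils::as.roman(h)),
         members = members,
         group_counts = table(aln$groups[members]),
         states = enc$matrix[members[1], ])
  })
  char_matrix <- enc$matrix[aln$sample_ids[first], , drop = FALSE]
  rownames(char_matrix) <- vapply(haplotypes, `[[`, "", "id")
  sample_haplotype <- stats::setNames(
    vapply(haplotypes, `[[`, "", "id")[hap_of], aln$sample_ids)

  structure(
    list(haplotypes = haplotypes, char_matrix = char_matrix,
         char_info = enc$info, sample_haplotype = sample_haplotype,
         n = aln$n, sites = sites),
    class = "hap_set"
  )
}

#' @export
print.hap_set <- function(x, ...) {
  cat("hap_set:", length(x$haplotypes), "haplotypes over",
      ncol(x$char_matrix), "characters from", x$n, "samples\n")
  invisible(x)
}

#' Per-sample haplotype state table
#'
#' One row per sample with its group, haplotype id, and the base carried at
#' every substitution position (the classic per-sample site-composition
#' layout); indel characters are appended as presence/absence columns.
#'
#' @param hapset a [hap_set()] from [collapse_haplotypes()].
#' @param aln the source [hap_alignment()].
#' @param file optional TSV output path.
#' @return data.frame with columns `group`, `sample_id`, `haplotype`, then one
#'   column per character.
#' @export
export_haplotype_table <- function(hapset, aln, file = NULL) {
  stopifnot(inherits(hapset, "hap_set"), inherits(aln, "hap_alignment"))
  sites <- hapset$sites
  base <- data.frame(group = unname(aln$groups[aln$sample_ids]),
                     sample_id = aln$sample_ids,
                     haplotype = unname(hapset$sample_haplotype[aln$sample_ids]),
                     stringsAsFactors = FALSE)
  if (length(sites$positions)) {
    st <- sites$states
    colnames(st) <- paste0("pos", sites$positions)
    base <- cbind(base, as.data.frame(st, stringsAsFactors = FALSE))
  }
  idx <- which(hapset$char_info$type == "indel")
  for (k in idx) {
    ch <- hapset$char_info$char[k]
    base[[ch]] <- unname(hapset$char_matrix[hapset$sample_haplotype[aln$sample_ids], ch])
  }
  ord <- order(base$haplotype, base$sample_id)
  base <- base[ord, , drop = FALSE]
  rownames(base) <- NULL
  if (!is.null(file))
    utils::write.table(base, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  base
}

#' Export haplotype (or sample) sequences as NEXUS
#'
#' Writes the aligned sequences in NEXUS format for use in external Bayesian
#' dating tools.  With `collapse = TRUE` one representative sequence per
#' haplotype is written, named by haplotype id.
#'
#' @param aln a [hap_alignment()] object.
#' @param file output path.
#' @param hapset optional [collapse_haplotypes()] result.
#' @param collapse write one sequence per haplotype instead of per sample.
#' @return `file`, invisibly.
#' @export
export_nexus <- function(aln, file, hapset = NULL, collapse = FALSE) {
  stopifnot(inherits(aln, "hap_alignment"))
  seqs <- lapply(seq_len(aln$n), function(i) tolower(aln$seq[i, ]))
  names(seqs) <- aln$sample_ids
  if (collapse) {
    if (is.null(hapset)) hapset <- collapse_haplotypes(aln)
    reps <- vapply(hapset$haplotypes, function(h) h$members[1], "")
    seqs <- seqs[reps]
    names(seqs) <- vapply(hapset$haplotypes, `[[`, "", "id")
  }
  ape::write.nexus.data(seqs, file, interleaved = FALSE)
  invisible(file)
}
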