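#' Construct an alignment object
#'
#' An alignment holds one gapped sequence per accession, the sample ids, and a
#' sample-to-group map.  All downstream analyses (site tables, diversity
#' summaries, haplotype networks, dating) consume this object.  Coordinates
#' used anywhere in the package are 1-based inclusive alignment columns.
#'
#' @param sample_ids character vector of unique, non-empty accession ids.
#' @param sequences character vector of aligned sequences (one string per
#'   sample, all the same length) or an n x L character matrix of single
#'   symbols.
#' @param groups named character vector mapping sample id to group label.
#'   Samples absent from the map are assigned group `"unassigned"` with a
#'   warning.
#' @return An object of class `hap_alignment`: a list with elements `seq`
#'   (n x L uppercase character matrix, rownames = sample ids), `sample_ids`,
#'   `n`, `L`, and `groups` (named character vector aligned to `sample_ids`).
#' @details Symbols are upper-cased; any symbol outside `A`, `C`, `G`, `T`,
#'   `-` is recoded to `N` and treated as missing.  How missing columns enter
#'   each statistic is decided per statistic (see [segregating_sites()] and
#'   [nucleotide_diversity()]).
#' @export
hap_alignment <- function(sample_ids, sequences, groups = NULL) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 0L)
    stop("alignment must contain at least one sequence", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(sample_ids)))
    stop("empty sample id", call. = FALSE)

  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("sequences differ in length: not an alignment", call. = FALSE)
    if (lens[1] < 1L)
      stop("alignment length must be >= 1", call. = FALSE)
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  }
  if (nrow(mat) != length(sample_ids))
    stop("number of sequences does not match number of sample ids",
         call. = FALSE)
  mat <- toupper(mat)
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(mat) <- sample_ids

  grp <- rep("unassigned", length(sample_ids))
  names(grp) <- sample_ids
  if (!is.null(groups)) {
    hit <- sample_ids %in% names(groups)
    grp[hit] <- unname(groups[sample_ids[hit]])
    if (any(!hit))
      warning(sum(!hit), " sample(s) without a group entry assigned to ",
              "'unassigned'", call. = FALSE)
  }

  structure(
    list(seq = mat, sample_ids = sample_ids, n = nrow(mat), L = ncol(mat),
         groups = grp),
    class = "hap_alignment"
  )
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment:", x$n, "sequences x", x$L, "columns\n")
  tab <- table(x$groups)
  cat("groups:", paste(names(tab), " (", tab, ")", sep = "", collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an aligned FASTA plus a sample-to-group table
#'
#' @param fasta_path path to an aligned (gapped) FASTA file.
#' @param groups_path optional path to a TSV with header columns `sample_id`
#'   and `group`.
#' @return A validated [hap_alignment()] object.
#' @export
read_alignment <- function(fasta_path, groups_path = NULL) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  dna <- suppressWarnings(ape::read.FASTA(fasta_path))
  if (is.null(dna) || length(dna) == 0L)
    stop("empty FASTA: ", fasta_path, call. = FALSE)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  groups <- if (!is.null(groups_path)) read_groups(groups_path) else NULL
  hap_alignment(names(dna), unname(seqs), groups)
}

#' Read a sample-to-group TSV
#'
#' @param groups_path TSV with header columns `sample_id` and `group`.
#' @return named character vector, sample id -> group label.
#' @export
read_groups <- function(groups_path) {
  if (!file.exists(groups_path))
    stop("groups file not found: ", groups_path, call. = FALSE)
  tab <- utils::read.delim(groups_path, header = TRUE,
                           colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("groups file must have header columns 'sample_id' and 'group'",
         call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in groups file", call. = FALSE)
  stats::setNames(tab$group, tab$sample_id)
}

#' Write an alignment (and optionally its group table) back to disk
#'
#' @param aln a [hap_alignment()] object.
#' @param fasta_path output FASTA path.
#' @param groups_path optional output TSV path for the group table.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, groups_path = NULL) {
  stopifnot(inherits(aln, "hap_alignment"))
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  dna <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  names(dna) <- aln$sample_ids
  ape::write.FASTA(dna, fasta_path)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = aln$sample_ids, group = unname(aln$groups)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Region annotation over alignment columns
#'
#' Ordered, non-overlapping named intervals (1-based inclusive) partitioning
#' the alignment into analysis regions such as flanking/exon/intron blocks.
#' Columns covered by no interval form an implicit `"other"` region.
#'
#' @param name,start,end equal-length vectors defining the intervals.
#' @param L alignment length; intervals must fall inside `[1, L]`.
#' @return data.frame of class `hap_regions` with columns `name`, `start`,
#'   `end`, ordered by `start`.
#' @export
hap_regions <- function(name, start, end, L) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(name) == 0L)
    return(structure(data.frame(name = "all", start = 1L, end = as.integer(L),
                                stringsAsFactors = FALSE),
                     class = c("hap_regions", "data.frame")))
  if (any(start < 1L) || any(end > L) || any(start > end))
    stop("region coordinates must satisfy 1 <= start <= end <= L",
         call. = FALSE)
  ord <- order(start)
  name <- as.character(name)[ord]; start <- start[ord]; end <- end[ord]
  if (anyDuplicated(name))
    stop("duplicate region names", call. = FALSE)
  if (length(start) > 1L && any(start[-1] <= end[-length(end)]))
    stop("overlapping region intervals", call. = FALSE)
  structure(data.frame(name = name, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("hap_regions", "data.frame"))
}

#' Read a BED-like region annotation (1-based inclusive dialect)
#'
#' @param bed_path three-column TSV (`name`, `start`, `end`), no header.
#' @param L alignment length used for validation.
#' @return a [hap_regions()] object; an empty file yields the single region
#'   `"all"` spanning the alignment.
#' @export
read_regions <- function(bed_path, L) {
  if (!file.exists(bed_path))
    stop("region file not found: ", bed_path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(bed_path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L)
    return(hap_regions(character(0), integer(0), integer(0), L))
  if (ncol(raw) < 3L)
    stop("region file needs three columns: name, start, end", call. = FALSE)
  hap_regions(raw[[1]], raw[[2]], raw[[3]], L)
}

## Column indices covered by a named region ("all"/NULL = every column).
region_columns <- function(regions, region, L) {
  if (is.null(region) || identical(region, "all")) return(seq_len(L))
  stopifnot(inherits(regions, "hap_regions"))
  if (identical(region, "other")) {
    covered <- unlist(lapply(seq_len(nrow(regions)),
                             function(i) regions$start[i]:regions$end[i]))
    return(setdiff(seq_len(L), covered))
  }
  i <- match(region, regions$name)
  if (is.na(i))
    stop("unknown region: ", region, call. = FALSE)
  regions$start[i]:regions$end[i]
}

## Subset an alignment to given samples and/or columns, keeping groups.
subset_alignment <- function(aln, samples = NULL, columns = NULL) {
  mat <- aln$seq
  if (!is.null(samples)) {
    miss <- setdiff(samples, aln$sample_ids)
    if (length(miss))
      stop("unknown sample ids: ", paste(miss, collapse = ", "),
           call. = FALSE)
    mat <- mat[samples, , drop = FALSE]
  }
  if (!is.null(columns)) {
    if (length(columns) && (min(columns) < 1L || max(columns) > aln$L))
      stop("columns outside alignment", call. = FALSE)
    mat <- mat[, columns, drop = FALSE]
  }
  hap_alignment(rownames(mat), mat, aln$groups)
}

## Samples belonging to a group label (or "all").
group_samples <- function(aln, group) {
  if (is.null(group) || identical(group, "all")) return(aln$sample_ids)
  hit <- aln$sample_ids[aln$groups == group]
  if (length(hit) == 0L)
    stop("unknown or empty group: ", group, call. = FALSE)
  hit
}
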