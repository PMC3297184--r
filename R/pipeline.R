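#' Run the full locus analysis pipeline
#'
#' Sequences the whole analysis over one aligned region: diversity summaries
#' per group and region, haplotype collapsing and the per-sample state table,
#' the reticulate parsimony network (GraphML + DOT + NEXUS exports), the
#' homoplasy model with branch-level recombination tests, DCA identification,
#' optional calibrated node dating, and a JSON summary tying the outputs
#' together.  Every output is deterministic given identical inputs.
#'
#' @param alignment a [hap_alignment()] or path to an aligned FASTA.
#' @param groups optional path to a groups TSV (ignored when `alignment` is
#'   already an object).
#' @param regions optional [hap_regions()] or path to a BED-like file
#'   (1-based inclusive).
#' @param calibration optional list `list(node =, age_years =)` naming a
#'   network node (id or Roman alias) and its age; enables the dating stage.
#' @param cultivated_groups group labels counted as cultivated for DCA
#'   identification; `NULL` skips the DCA/dating stages.
#' @param indel_mode passed to [collapse_haplotypes()].
#' @param depth_mode passed to [date_nodes()].
#' @param out_dir output directory (created; pre-existing files are
#'   overwritten).
#' @return list with the in-memory stage results (`summary`, `diversity`,
#'   `hapset`, `network`, `model`, `events`, `dca`, `chronology`) and
#'   `files` (the paths written), invisibly.
#' @export
run_pipeline <- function(alignment, groups = NULL, regions = NULL,
                         calibration = NULL, cultivated_groups = NULL,
                         indel_mode = c("include", "exclude"),
                         depth_mode = c("mean_tip_path", "max_tip_path",
                                        "min_tip_path"),
                         out_dir) {
  indel_mode <- match.arg(indel_mode)
  depth_mode <- match.arg(depth_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines("status\tincomplete", manifest)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  aln <- stage("input", {
    if (inherits(alignment, "hap_alignment")) alignment
    else read_alignment(alignment, groups)
  })
  reg <- stage("input", {
    if (is.null(regions)) NULL
    else if (inherits(regions, "hap_regions")) regions
    else read_regions(regions, aln$L)
  })

  diversity <- stage("diversity", {
    f <- file.path(out_dir, "diversity.tsv")
    out <- group_summary(aln, reg, file = f)
    files <- c(files, diversity = f)
    out
  })

  sites <- stage("sites", segregating_sites(aln))
  hapset <- stage("haplotypes", collapse_haplotypes(aln, sites, indel_mode))
  stage("haplotypes", {
    f <- file.path(out_dir, "haplotypes.tsv")
    export_haplotype_table(hapset, aln, f)
    files <- c(files, haplotypes = f)
  })

  net <- stage("network", build_network(hapset))
  stage("network", {
    f1 <- file.path(out_dir, "network.graphml")
    f2 <- file.path(out_dir, "network.dot")
    f3 <- file.path(out_dir, "haplotypes.nex")
    write_network_graphml(net, f1)
    write_network_dot(net, f2)
    export_nexus(aln, f3, hapset, collapse = TRUE)
    files <- c(files, graphml = f1, dot = f2, nexus = f3)
  })

  model <- stage("recombination", homoplasy_model(aln$L, max(net$m, 0L)))
  hp <- stage("recombination", count_homoplasies(net))

  dca <- NULL
  if (!is.null(cultivated_groups))
    dca <- stage("dca", identify_dca(net, cultivated_groups))

  events <- stage("recombination", {
    ev <- enumerate_events(net, model,
                           dca_node = if (!is.null(dca)) dca$node else NULL)
    f <- file.path(out_dir, "events.tsv")
    write_events(ev, f)
    files <- c(files, events = f)
    ev
  })

  chron <- NULL
  if (!is.null(calibration) && !is.null(cultivated_groups)) {
    chron <- stage("dating", {
      node <- calibration$node
      romans <- igraph::V(net$graph)$roman
      ids <- igraph::V(net$graph)$name
      if (node %in% romans && !(node %in% ids)) node <- ids[match(node, romans)]
      if (identical(calibration$node, "DCA")) node <- dca$node
      res <- calibrate_from_network(net, node, calibration$age_years, aln$L,
                                    depth_mode, root = dca$node)
      f <- file.path(out_dir, "chronology.tsv")
      export_chronology(res$chronology, f)
      files <- c(files, chronology = f)
      res
    })
  }

  summary <- stage("summary", {
    s <- list(
      n_samples = aln$n, L = aln$L,
      S = length(sites$positions),
      n_indel_events = nrow(sites$indel_events),
      n_haplotypes = length(hapset$haplotypes),
      n_network_nodes = nrow(net$node_states),
      n_sampled_nodes = sum(net$sampled),
      member_counts = stats::setNames(
        lapply(hapset$haplotypes, function(h) length(h$members)),
        vapply(hapset$haplotypes, `[[`, "", "id")),
      m = net$m,
      H_net = hp$H_net,
      homoplasy_p = model$p,
      homoplasy_E = model$E,
      network_point_prob = network_test(model, hp$H_net)$point,
      pi_per_bp = nucleotide_diversity(aln),
      tajima_D = tajima_d(aln),
      Rm = hudson_kaplan_rm(aln)$Rm,
      n_events = nrow(events),
      event_H_total = sum(events$H),
      dca_node = if (!is.null(dca)) dca$node else NULL,
      rate = if (!is.null(chron)) chron$r else NULL,
      depth_mode = depth_mode, indel_mode = indel_mode)
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(s, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, summary = f)
    s
  })

  writeLines(c("status\tcomplete",
               paste(names(files), unname(files), sep = "\t")), manifest)
  invisible(list(summary = summary, diversity = diversity, hapset = hapset,
                 network = net, model = model, events = events, dca = dca,
                 chronology = chron, alignment = aln, files = files))
}

#' Validate cross-file consistency of a pipeline output bundle
#'
#' Checks that the written outputs agree with each other: the haplotype count
#' matches the number of sampled network nodes, haplotype member counts sum
#' to the sample count, and the per-event homoplasy counts never exceed the
#' network-wide homoplasy total.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return `TRUE` when all checks pass; otherwise `FALSE` with the violated
#'   checks in `attr(, "failures")`.
#' @export
validate_outputs <- function(out_dir) {
  failures <- character(0)
  need <- file.path(out_dir, c("summary.json", "haplotypes.tsv",
                               "events.tsv", "MANIFEST"))
  if (!all(file.exists(need))) {
    failures <- paste("missing file:",
                      basename(need[!file.exists(need)]))
  } else {
    s <- jsonlite::read_json(file.path(out_dir, "summary.json"))
    hap <- utils::read.delim(file.path(out_dir, "haplotypes.tsv"),
                             colClasses = "character")
    ev <- utils::read.delim(file.path(out_dir, "events.tsv"))
    if (length(unique(hap$haplotype)) != s$n_sampled_nodes)
      failures <- c(failures,
                    "haplotype count != sampled network nodes")
    if (nrow(hap) != s$n_samples)
      failures <- c(failures, "haplotype member counts != sample count")
    if (nrow(ev) > 0 && sum(ev$H) > s$H_net)
      failures <- c(failures, "event homoplasies exceed network total")
    mani <- readLines(file.path(out_dir, "MANIFEST"))
    if (!any(grepl("^status\tcomplete$", mani)))
      failures <- c(failures, "MANIFEST not marked complete")
  }
  ok <- length(failures) == 0L
  attr(ok, "failures") <- failures
  ok
}
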