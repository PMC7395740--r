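#' Build the full TF/miRNA regulatory network from raw inputs
#'
#' Runs the complete construction pipeline: CRM filtering of peaks, peak
#' to closest-TSS assignment within the strand-oriented promoter window,
#' host-gene regulation inheritance for intragenic miRNAs, collapse of
#' duplicate assignments into weighted edges, per-TF mean filtering, and
#' the merge with posttranscriptional miRNA target edges.
#'
#' @param peaks Peak tibble ([read_peaks()]).
#' @param crms CRM interval tibble ([read_bed()]).
#' @param genes Gene annotation tibble ([read_gene_annotation()]).
#' @param mirnas miRNA locus tibble ([read_mirna_gff()]); host genes are
#'   determined by transcript-span overlap if not already assigned.
#' @param mirna_targets miRNA target tibble ([read_mirna_targets()]).
#' @param config An [assignment_config()].
#' @return A list of class `network_build` with elements
#'   `network` (the final `regnet`), `trimmed` (regulator-only
#'   sub-network), `report` (a [filter_report()]-style list), `edges_unfiltered`
#'   (collapsed transcriptional edges before mean filtering) and
#'   `removed_peaks` (peaks outside CRMs).
#' @export
build_regulatory_network <- function(peaks, crms, genes, mirnas,
                                     mirna_targets,
                                     config = assignment_config()) {
  if (!"host_gene_id" %in% names(mirnas)) {
    mirnas <- assign_mirna_hosts(mirnas, genes)
  }
  crm_split <- filter_peaks_by_crm(peaks, crms)
  core <- construct_core(crm_split$kept, genes, mirnas, mirna_targets,
                         config)
  report <- filter_report(
    n_input_peaks = nrow(peaks),
    n_in_crm = nrow(crm_split$kept),
    n_assigned = core$n_assigned,
    n_outside_window = core$n_outside_window,
    mean_filter_thresholds = core$thresholds)
  structure(list(network = core$network,
                 trimmed = trim_to_regulators(core$network),
                 report = report,
                 edges_unfiltered = core$edges_unfiltered,
                 removed_peaks = crm_split$removed),
            class = "network_build")
}

# shared by the pooled build and the per-tissue builds: everything after
# the CRM filter
construct_core <- function(kept_peaks, genes, mirnas, mirna_targets,
                           config) {
  assignments <- assign_peaks_to_tss(kept_peaks, genes, config)
  n_assigned <- nrow(assignments)
  assignments <- inherit_host_regulation(assignments, mirnas, genes)
  edges <- collapse_assignments(assignments)
  mf <- mean_filter(edges, config)
  network <- build_network(mf$edges, mirna_targets, genes)
  list(network = network, edges_unfiltered = edges,
       thresholds = mf$thresholds, n_assigned = n_assigned,
       n_outside_window = attr(assignments, "n_outside_window") %||% 0L)
}

#' Filtering report of a network build
#'
#' Book-keeping of how many peaks each construction stage retained.
#'
#' @param n_input_peaks,n_in_crm,n_assigned,n_outside_window Non-negative
#'   counts; `n_in_crm <= n_input_peaks` and
#'   `n_assigned <= n_in_crm`.
#' @param mean_filter_thresholds Per-TF threshold tibble from
#'   [mean_filter()].
#' @return A list of class `filter_report`.
#' @export
filter_report <- function(n_input_peaks, n_in_crm, n_assigned,
                          n_outside_window, mean_filter_thresholds) {
  stopifnot(n_in_crm <= n_input_peaks, n_assigned <= n_in_crm,
            n_input_peaks >= 0, n_outside_window >= 0)
  structure(list(n_input_peaks = as.integer(n_input_peaks),
                 n_in_crm = as.integer(n_in_crm),
                 n_assigned = as.integer(n_assigned),
                 n_outside_window = as.integer(n_outside_window),
                 mean_filter_thresholds = mean_filter_thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  input peaks       %d\n", x$n_input_peaks))
  cat(sprintf("  in CRMs           %d\n", x$n_in_crm))
  cat(sprintf("  assigned to TSS   %d (%d outside window)\n",
              x$n_assigned, x$n_outside_window))
  cat(sprintf("  TFs mean-filtered %d (edges %d -> %d)\n",
              nrow(x$mean_filter_thresholds),
              sum(x$mean_filter_thresholds$n_before),
              sum(x$mean_filter_thresholds$n_after)))
  invisible(x)
}

#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    n_input_peaks = x$n_input_peaks, n_in_crm = x$n_in_crm,
    n_assigned = x$n_assigned, n_outside_window = x$n_outside_window,
    n_edges_before_mean_filter = sum(x$mean_filter_thresholds$n_before),
    n_edges_after_mean_filter = sum(x$mean_filter_thresholds$n_after))
}

#' Serialise a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @export
print.network_build <- function(x, ...) {
  cat("<network_build>\n")
  print(x$report)
  print(x$network)
  invisible(x)
}
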