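#' Build per-tissue regulatory sub-networks
#'
#' Partitions the peaks by tissue via their dataset label and reruns the
#' full construction pipeline within each tissue (CRM filter, TSS
#' assignment, host inheritance, collapse, mean filter with thresholds
#' recomputed per tissue). The posttranscriptional miRNA edges carry no
#' tissue information and are appended unchanged to every tissue network.
#' A TF "has data" in a tissue when at least one of its peaks from that
#' tissue survives CRM filtering, regardless of whether any edge survives
#' the mean filter.
#'
#' @param peaks Peak tibble.
#' @param tissue_map Tibble with columns `dataset`, `tissue`, covering
#'   every dataset label in `peaks`.
#' @param crms,genes,mirnas,mirna_targets,config As in
#'   [build_regulatory_network()].
#' @return An object of class `tissue_network_set`: `networks` (named
#'   list of `regnet`, one per tissue), `tf_data` (tibble `tissue`, `tf`)
#'   and `tissues`.
#' @export
split_by_tissue <- function(peaks, tissue_map, crms, genes, mirnas,
                            mirna_targets, config = assignment_config()) {
  unmapped <- setdiff(unique(peaks$dataset), tissue_map$dataset)
  if (length(unmapped) > 0) {
    rlang::abort(paste0("dataset label(s) missing from tissue map: ",
                        paste(utils::head(unmapped, 10), collapse = ", ")))
  }
  if (!"host_gene_id" %in% names(mirnas)) {
    mirnas <- assign_mirna_hosts(mirnas, genes)
  }
  peaks <- dplyr::left_join(peaks, tissue_map, by = "dataset")
  tissues <- sort(unique(tissue_map$tissue))
  networks <- list()
  tf_data <- list()
  for (ti in tissues) {
    p <- peaks[peaks$tissue == ti, , drop = FALSE]
    kept <- filter_peaks_by_crm(p, crms)$kept
    tf_data[[ti]] <- tibble::tibble(tissue = ti,
                                    tf = sort(unique(kept$tf)))
    networks[[ti]] <- construct_core(kept, genes, mirnas, mirna_targets,
                                     config)$network
  }
  structure(list(networks = networks,
                 tf_data = dplyr::bind_rows(tf_data),
                 tissues = tissues),
            class = "tissue_network_set")
}

#' Assemble a tissue network set from prebuilt networks
#'
#' Lower-level constructor used when the per-tissue networks are already
#' available (e.g. hand-built fixtures): supply the networks and the
#' table of tissues where each TF has binding data.
#'
#' @param networks Named list of `regnet`, one per tissue.
#' @param tf_data Tibble with columns `tissue`, `tf`.
#' @return A `tissue_network_set`.
#' @export
tissue_network_set <- function(networks, tf_data) {
  stopifnot(is.list(networks), !is.null(names(networks)),
            all(c("tissue", "tf") %in% names(tf_data)))
  structure(list(networks = networks,
                 tf_data = tibble::as_tibble(tf_data),
                 tissues = names(networks)),
            class = "tissue_network_set")
}

#' @export
print.tissue_network_set <- function(x, ...) {
  cat("<tissue_network_set>", length(x$networks), "tissues:",
      paste(utils::head(x$tissues, 8), collapse = ", "),
      if (length(x$tissues) > 8) "..." else "", "\n")
  invisible(x)
}

# per-tissue M2 pairs as a tibble (tissue, tf, mirna)
m2_by_tissue <- function(set) {
  purrr::map_dfr(set$tissues, function(ti) {
    inst <- find_m2(set$networks[[ti]])
    tibble::tibble(tissue = rep(ti, nrow(inst)), tf = inst$member_1,
                   mirna = inst$member_2)
  })
}

# per-tissue autoregulators (tissue, tf)
m1_by_tissue <- function(set) {
  purrr::map_dfr(set$tissues, function(ti) {
    tfs <- find_m1(set$networks[[ti]])$member_1
    tibble::tibble(tissue = rep(ti, length(tfs)), tf = tfs)
  })
}

#' Motif conservation across tissues
#'
#' For every TF with binding data in at least two tissues, scores how
#' consistently a motif recurs: the number of data tissues containing the
#' motif as a percentage of the tissues where data for the TF exists.
#' TFs with data in a single tissue are excluded. Levels:
#' * `"M1"` - the TF autoregulates in the tissue network;
#' * `"M2_tf"` - the TF participates in at least one M2 motif;
#' * `"M2_full"` - one record per (TF, miRNA) pair seen in any tissue,
#'   scoring that exact pair's recurrence.
#'
#' @param set A `tissue_network_set`.
#' @param level `"M1"`, `"M2_tf"` or `"M2_full"`.
#' @return A tibble with columns `tf`, `mirna` (`NA` except for
#'   `M2_full`), `level`, `n_tissues_with_data`, `n_tissues_with_motif`,
#'   `percent`.
#' @export
motif_conservation <- function(set, level = c("M1", "M2_tf", "M2_full")) {
  level <- match.arg(level)
  data_count <- set$tf_data |>
    dplyr::count(.data$tf, name = "n_tissues_with_data") |>
    dplyr::filter(.data$n_tissues_with_data >= 2)
  if (nrow(data_count) == 0) {
    return(tibble::tibble(tf = character(), mirna = character(),
                          level = character(),
                          n_tissues_with_data = integer(),
                          n_tissues_with_motif = integer(),
                          percent = double()))
  }
  if (level %in% c("M1", "M2_tf")) {
    present <- if (level == "M1") m1_by_tissue(set)
               else dplyr::distinct(m2_by_tissue(set), .data$tissue,
                                    .data$tf)
    # only count motif occurrences in tissues where the TF has data
    present <- dplyr::semi_join(present, set$tf_data,
                                by = c("tissue", "tf"))
    hit <- present |> dplyr::count(.data$tf, name = "n_tissues_with_motif")
    out <- data_count |>
      dplyr::left_join(hit, by = "tf") |>
      dplyr::mutate(
        n_tissues_with_motif = dplyr::coalesce(.data$n_tissues_with_motif,
                                               0L),
        mirna = NA_character_, level = level)
  } else {
    pairs <- m2_by_tissue(set) |>
      dplyr::semi_join(set$tf_data, by = c("tissue", "tf"))
    out <- pairs |>
      dplyr::count(.data$tf, .data$mirna, name = "n_tissues_with_motif") |>
      dplyr::inner_join(data_count, by = "tf") |>
      dplyr::mutate(level = level)
  }
  out |>
    dplyr::mutate(percent = 100 * .data$n_tissues_with_motif /
                    .data$n_tissues_with_data) |>
    dplyr::select("tf", "mirna", "level", "n_tissues_with_data",
                  "n_tissues_with_motif", "percent") |>
    dplyr::arrange(.data$tf, .data$mirna)
}

#' Pairwise Jaccard similarity of tissue networks
#'
#' For each pair of tissues, the Jaccard index over transcriptional edges
#' identified by (source, target): shared edges divided by the union.
#' miRNA edges are excluded since they are identical in every tissue
#' network. The matrix is symmetric with diagonal 1 (`NA` for a tissue
#' with no transcriptional edges).
#'
#' @param set A `tissue_network_set`.
#' @return A numeric tissue x tissue matrix.
#' @export
pairwise_jaccard <- function(set) {
  keys <- lapply(set$networks, function(net) {
    e <- net$edges[net$edges$edge_class == "transcriptional", ]
    unique(paste(e$source_id, e$target_id, sep = "\r"))
  })
  k <- length(keys)
  out <- matrix(NA_real_, k, k, dimnames = list(set$tissues, set$tissues))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      u <- length(union(keys[[i]], keys[[j]]))
      if (u > 0) out[i, j] <- length(intersect(keys[[i]], keys[[j]])) / u
    }
  }
  out
}

#' Attribute M2 motif losses between tissues
#'
#' For each M2 pair (TF, miRNA) present in at least one tissue, every
#' other tissue where the TF has binding data but the pair is absent is
#' classified by what is missing there: the autoregulatory edge
#' (`"lost_autoregulation"`), the TF's regulation of the miRNA
#' (`"missing_tf_mirna_regulation"`), or both (`"both_missing"`). The
#' miRNA -> TF edge cannot be the cause because posttranscriptional
#' edges are shared by all tissue networks.
#'
#' @param set A `tissue_network_set`.
#' @return A list with `records` (tibble `tf`, `mirna`, `tissue`,
#'   `reason`) and `frequencies` (per-reason counts; `percent` is
#'   relative to all pair x data-tissue combinations, absences and
#'   presences together).
#' @export
loss_attribution <- function(set) {
  pairs_by_tissue <- m2_by_tissue(set)
  pairs <- dplyr::distinct(pairs_by_tissue, .data$tf, .data$mirna)
  auto <- m1_by_tissue(set)
  tf_mir_edge <- purrr::map_dfr(set$tissues, function(ti) {
    e <- set$networks[[ti]]$edges
    e <- e[e$edge_class == "transcriptional", ]
    tibble::tibble(tissue = rep(ti, nrow(e)), tf = e$source_id,
                   mirna = e$target_id)
  })
  opportunities <- pairs |>
    dplyr::inner_join(set$tf_data, by = "tf",
                      relationship = "many-to-many")
  absent <- opportunities |>
    dplyr::anti_join(pairs_by_tissue, by = c("tf", "mirna", "tissue"))
  has_auto <- !is.na(dplyr::left_join(
    absent, dplyr::mutate(auto, flag = TRUE),
    by = c("tf", "tissue"))$flag)
  has_reg <- !is.na(dplyr::left_join(
    absent, dplyr::mutate(tf_mir_edge, flag = TRUE),
    by = c("tf", "mirna", "tissue"))$flag)
  reason <- dplyr::case_when(
    !has_auto & !has_reg ~ "both_missing",
    !has_auto ~ "lost_autoregulation",
    !has_reg ~ "missing_tf_mirna_regulation",
    TRUE ~ "other")
  records <- dplyr::mutate(absent, reason = reason)
  frequencies <- records |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / nrow(opportunities))
  list(records = records, frequencies = frequencies,
       n_opportunities = nrow(opportunities))
}
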