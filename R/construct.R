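#' Assignment configuration
#'
#' Parameters of the peak-to-TSS assignment and the per-TF mean filter.
#' The defaults follow the promoter-window convention used throughout the
#' pipeline: binding sites are credited to the closest TSS within 50 kb
#' upstream and 10 kb downstream, and per-TF edge-weight outliers beyond
#' 2 sample standard deviations of the mean are excluded when computing
#' the retention threshold.
#'
#' @param upstream_bp Window size upstream of the TSS, in bp.
#' @param downstream_bp Window size downstream of the TSS, in bp.
#' @param outlier_sd SD multiplier for two-sided outlier exclusion in
#'   [mean_filter()].
#' @return A list of class `assignment_config`.
#' @export
assignment_config <- function(upstream_bp = 50000, downstream_bp = 10000,
                              outlier_sd = 2) {
  stopifnot(upstream_bp > 0, downstream_bp > 0, outlier_sd > 0)
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp),
                 outlier_sd = outlier_sd),
            class = "assignment_config")
}

#' Partition peaks by cis-regulatory module membership
#'
#' A peak is kept iff it overlaps at least one CRM by at least 1 bp on the
#' same chromosome. Binding sites outside CRMs are treated as likely
#' non-specific and are removed before TSS assignment; the removed set is
#' returned too so it can be compared against candidate regulatory
#' elements ([intersect_candidate_elements()]).
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param crms CRM tibble with `chrom`, `start`, `end` (half-open).
#' @return A list with tibbles `kept` and `removed`; together they
#'   partition the input, preserving input order within each.
#' @export
filter_peaks_by_crm <- function(peaks, crms) {
  hit <- overlaps_any_interval(peaks, crms)
  list(kept = peaks[hit, , drop = FALSE],
       removed = peaks[!hit, , drop = FALSE])
}

#' Assign peaks to their closest eligible TSS
#'
#' For each peak, every TSS whose strand-oriented promoter window contains
#' the peak midpoint is eligible; the peak is assigned to the single
#' eligible TSS minimising `|midpoint - TSS|`. The window is
#' `[TSS - upstream, TSS + downstream)` on the + strand and its mirror
#' image on the - strand. The peak reference point is the integer midpoint
#' `floor((start + end) / 2)`. Ties between equidistant TSSs of different
#' genes go to the lexicographically smallest `gene_id` (deterministic,
#' and reported via a message). Peaks with no eligible TSS are dropped and
#' counted in the `n_outside_window` attribute of the result.
#'
#' @param peaks CRM-filtered peak tibble.
#' @param genes Gene annotation tibble ([read_gene_annotation()]); every
#'   gene must have a non-empty `tss` list.
#' @param config An [assignment_config()].
#' @return A tibble with columns `tf`, `dataset`, `gene_id`, `tss`,
#'   `distance`, one row per assigned peak, with attribute
#'   `n_outside_window`.
#' @export
assign_peaks_to_tss <- function(peaks, genes, config = assignment_config()) {
  stopifnot(inherits(config, "assignment_config"))
  if (any(lengths(genes$tss) == 0)) {
    rlang::abort("gene(s) with empty TSS list in annotation")
  }
  tss_tab <- tidyr::unnest(
    genes[, c("gene_id", "chrom", "strand", "tss")], "tss")
  up <- config$upstream_bp
  dn <- config$downstream_bp
  minus <- tss_tab$strand == "-"
  # half-open [lo, hi) windows containing eligible midpoints
  tss_tab$lo <- ifelse(minus, tss_tab$tss - dn + 1L, tss_tab$tss - up)
  tss_tab$hi <- ifelse(minus, tss_tab$tss + up + 1L, tss_tab$tss + dn)

  mid <- (peaks$start + peaks$end) %/% 2L
  pts <- tibble::tibble(chrom = peaks$chrom, start = mid, end = mid + 1L)
  win <- tibble::tibble(chrom = tss_tab$chrom, start = tss_tab$lo,
                        end = tss_tab$hi)
  hits <- overlap_pairs(pts, win)
  if (nrow(hits) == 0) {
    out <- tibble::tibble(tf = character(), dataset = character(),
                          gene_id = character(), tss = integer(),
                          distance = integer())
    attr(out, "n_outside_window") <- nrow(peaks)
    return(out)
  }
  cand <- tibble::tibble(
    peak_row = hits$query_row,
    gene_id = tss_tab$gene_id[hits$subject_row],
    tss = tss_tab$tss[hits$subject_row],
    distance = abs(mid[hits$query_row] - tss_tab$tss[hits$subject_row]))
  best <- cand |>
    dplyr::arrange(.data$peak_row, .data$distance, .data$gene_id,
                   .data$tss) |>
    dplyr::distinct(.data$peak_row, .keep_all = TRUE)
  ties <- cand |>
    dplyr::inner_join(best, by = c("peak_row", "distance"),
                      suffix = c("", ".best")) |>
    dplyr::filter(.data$gene_id != .data$gene_id.best)
  if (nrow(ties) > 0) {
    rlang::inform(sprintf(
      "%d peak(s) equidistant from TSSs of several genes; assigned to the lexicographically smallest gene_id",
      length(unique(ties$peak_row))))
  }
  out <- tibble::tibble(
    tf = peaks$tf[best$peak_row],
    dataset = peaks$dataset[best$peak_row],
    gene_id = best$gene_id,
    tss = best$tss,
    distance = best$distance)
  attr(out, "n_outside_window") <- nrow(peaks) - nrow(out)
  out
}

#' Determine host genes of intragenic microRNAs
#'
#' A miRNA is intragenic when its locus overlaps a transcript span of a
#' (non-miRNA) gene. When several transcripts overlap, the host with the
#' largest overlap is chosen; ties go to the lexicographically smallest
#' `gene_id`.
#'
#' @param mirnas miRNA locus tibble ([read_mirna_gff()]).
#' @param genes Gene annotation tibble.
#' @return `mirnas` with a `host_gene_id` column (`NA` for intergenic).
#' @export
assign_mirna_hosts <- function(mirnas, genes) {
  hosts <- genes[genes$biotype != "miRNA", ]
  spans <- hosts |>
    dplyr::select("gene_id", "chrom", "tx_starts", "tx_ends") |>
    tidyr::unnest(c("tx_starts", "tx_ends")) |>
    dplyr::rename(start = "tx_starts", end = "tx_ends")
  hits <- overlap_pairs(mirnas, spans)
  mirnas$host_gene_id <- NA_character_
  if (nrow(hits) > 0) {
    ov <- pmin(mirnas$end[hits$query_row], spans$end[hits$subject_row]) -
      pmax(mirnas$start[hits$query_row], spans$start[hits$subject_row])
    cand <- tibble::tibble(row = hits$query_row,
                           gene_id = spans$gene_id[hits$subject_row],
                           overlap = ov) |>
      dplyr::arrange(.data$row, dplyr::desc(.data$overlap), .data$gene_id) |>
      dplyr::distinct(.data$row, .keep_all = TRUE)
    mirnas$host_gene_id[cand$row] <- cand$gene_id
  }
  mirnas
}

#' Copy host-gene regulation onto hosted microRNAs
#'
#' Intragenic miRNAs inherit the transcriptional inputs of their host
#' gene: for every assignment `(tf, host_gene, tss)` a copy
#' `(tf, mirna_id, tss)` is appended for each miRNA hosted in that gene.
#' Assignments made directly to the miRNA's own TSS are retained
#' unchanged, so after [collapse_assignments()] the edge weight is the sum
#' of inherited and direct support.
#'
#' @param assignments Assignment tibble from [assign_peaks_to_tss()].
#' @param mirnas miRNA tibble with a `host_gene_id` column.
#' @param genes Gene annotation tibble (used to validate hosts).
#' @return The augmented assignment tibble.
#' @export
inherit_host_regulation <- function(assignments, mirnas, genes) {
  hosted <- mirnas[!is.na(mirnas$host_gene_id),
                   c("mirna_id", "host_gene_id")]
  if (nrow(hosted) == 0) return(assignments)
  absent <- setdiff(hosted$host_gene_id, genes$gene_id)
  if (length(absent) > 0) {
    rlang::abort(paste0("host_gene_id not in gene table: ",
                        paste(utils::head(absent, 5), collapse = ", ")))
  }
  copies <- assignments |>
    dplyr::inner_join(hosted, by = c(gene_id = "host_gene_id"),
                      relationship = "many-to-many") |>
    dplyr::mutate(gene_id = .data$mirna_id) |>
    dplyr::select(-"mirna_id")
  out <- dplyr::bind_rows(assignments, copies)
  attr(out, "n_outside_window") <- attr(assignments, "n_outside_window")
  out
}

#' Collapse duplicate TF -> gene assignments into weighted edges
#'
#' One transcriptional edge per (TF, target gene); the number of
#' supporting assignments (over all of the gene's TSSs) becomes the edge
#' weight, so the weight total equals the number of input assignments.
#'
#' @param assignments Assignment tibble.
#' @return A tibble with columns `source_id`, `target_id`, `weight`.
#' @export
collapse_assignments <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(source_id = character(), target_id = character(),
                          weight = integer()))
  }
  assignments |>
    dplyr::count(source_id = .data$tf, target_id = .data$gene_id,
                 name = "weight") |>
    dplyr::mutate(weight = as.integer(.data$weight))
}

#' Per-TF mean filtering of weighted transcriptional edges
#'
#' Keeps, for each TF, only target regions where the number of binding
#' sites is at least the TF's average. The threshold is robust to extreme
#' targets: per TF, (i) compute the mean and sample SD of its edge
#' weights, (ii) exclude weights more than `outlier_sd` SDs from the mean
#' *from the threshold computation only*, (iii) recompute the mean over
#' the remaining weights, and (iv) keep every edge (outliers included)
#' whose weight is at least that mean. A TF with a single edge keeps it.
#'
#' @param edges Tibble of transcriptional edges (`source_id`, `target_id`,
#'   `weight`), weights positive integers.
#' @param config An [assignment_config()]; only `outlier_sd` is used.
#' @return A list with `edges` (the kept rows, input order preserved) and
#'   `thresholds` (per-TF tibble: `source_id`, `n_before`, `n_after`,
#'   `n_outliers`, `threshold`).
#' @export
mean_filter <- function(edges, config = assignment_config()) {
  if (nrow(edges) == 0) {
    return(list(edges = edges,
                thresholds = tibble::tibble(
                  source_id = character(), n_before = integer(),
                  n_after = integer(), n_outliers = integer(),
                  threshold = double())))
  }
  if (any(edges$weight <= 0)) rlang::abort("edge weights must be positive")
  k <- config$outlier_sd
  thr_one <- function(w) {
    if (length(w) == 1) return(c(thr = w, out = 0))
    mu0 <- mean(w)
    sd0 <- stats::sd(w)
    if (is.na(sd0) || sd0 == 0) return(c(thr = mu0, out = 0))
    inlier <- abs(w - mu0) <= k * sd0
    if (!any(inlier)) inlier <- rep(TRUE, length(w))
    c(thr = mean(w[inlier]), out = sum(!inlier))
  }
  stats_tab <- edges |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(n_before = dplyr::n(),
                     threshold = thr_one(.data$weight)[["thr"]],
                     n_outliers = as.integer(thr_one(.data$weight)[["out"]]),
                     .groups = "drop")
  thr <- stats_tab$threshold[match(edges$source_id, stats_tab$source_id)]
  kept <- edges[edges$weight >= thr, , drop = FALSE]
  after <- kept |> dplyr::count(.data$source_id, name = "n_after")
  thresholds <- stats_tab |>
    dplyr::left_join(after, by = "source_id") |>
    dplyr::mutate(n_after = dplyr::coalesce(.data$n_after, 0L)) |>
    dplyr::select("source_id", "n_before", "n_after", "n_outliers",
                  "threshold")
  list(edges = kept, thresholds = thresholds)
}

#' Merge transcriptional and miRNA-target edges into one network
#'
#' Transcriptional TF edges (post [mean_filter()]) and posttranscriptional
#' miRNA -> target edges are combined into a [regulatory_network()]. Node
#' kinds come from the annotation biotypes; a node is a TF iff it appears
#' as a transcriptional source. Duplicate (miRNA, target) rows have their
#' weights summed.
#'
#' @param trans_edges Tibble `source_id`, `target_id`, `weight`.
#' @param mirna_targets Tibble `mirna_id`, `target_gene_id`, `weight`
#'   ([read_mirna_targets()]).
#' @param genes Gene annotation tibble covering every edge endpoint
#'   (miRNA genes carry biotype `"miRNA"`).
#' @return A `regnet`.
#' @export
build_network <- function(trans_edges, mirna_targets, genes) {
  biotype <- stats::setNames(genes$biotype, genes$gene_id)
  post <- mirna_targets |>
    dplyr::group_by(mirna_id = .data$mirna_id,
                    target_id = .data$target_gene_id) |>
    dplyr::summarise(weight = as.integer(sum(.data$weight)),
                     .groups = "drop")
  endpoints <- unique(c(trans_edges$source_id, trans_edges$target_id,
                        post$mirna_id, post$target_id))
  absent <- setdiff(endpoints, genes$gene_id)
  if (length(absent) > 0) {
    rlang::abort(paste0("edge endpoint(s) absent from annotation: ",
                        paste(utils::head(absent, 5), collapse = ", ")))
  }
  trans <- trans_edges |>
    dplyr::group_by(.data$source_id, .data$target_id) |>
    dplyr::summarise(weight = as.integer(sum(.data$weight)),
                     .groups = "drop") |>
    dplyr::mutate(source_kind = "TF",
                  target_kind = unname(biotype[.data$target_id]),
                  edge_class = "transcriptional")
  post <- post |>
    dplyr::transmute(source_id = .data$mirna_id, source_kind = "miRNA",
                     target_id = .data$target_id,
                     target_kind = unname(biotype[.data$target_id]),
                     edge_class = "posttranscriptional",
                     weight = .data$weight)
  edges <- dplyr::bind_rows(trans, post)[
    , c("source_id", "source_kind", "target_id", "target_kind",
        "edge_class", "weight")]
  tf_set <- unique(trans$source_id)
  ids <- unique(c(edges$source_id, edges$target_id))
  node_biotype <- unname(biotype[ids])
  node_kind <- dplyr::case_when(ids %in% tf_set ~ "TF",
                                node_biotype == "miRNA" ~ "miRNA",
                                TRUE ~ "gene")
  nodes <- tibble::tibble(id = ids, kind = node_kind,
                          biotype = node_biotype)
  regulatory_network(edges, nodes)
}

#' Overlap of filtered-out peaks with candidate regulatory elements
#'
#' For peaks removed by a filter (outside CRMs, or outside the promoter
#' window), reports the percentage overlapping at least one candidate
#' element of each class (each peak counted once per class).
#'
#' @param removed_peaks Peak tibble.
#' @param cre Candidate-element tibble with `chrom`, `start`, `end` and a
#'   `class` column (e.g. `PLS`, `pELS`, `dELS`); the `name` column of a
#'   BED file is accepted under either name.
#' @return A tibble with `class`, `n_peaks`, `n_overlapping`, `percent`.
#' @export
intersect_candidate_elements <- function(removed_peaks, cre) {
  if (!"class" %in% names(cre) && "name" %in% names(cre)) {
    cre$class <- cre$name
  }
  classes <- unique(c("PLS", "pELS", "dELS",
                      if (nrow(cre) > 0) cre$class))
  purrr::map_dfr(classes, function(cl) {
    sub <- cre[!is.na(cre$class) & cre$class == cl, , drop = FALSE]
    n_ov <- sum(overlaps_any_interval(removed_peaks, sub))
    tibble::tibble(
      class = cl, n_peaks = nrow(removed_peaks),
      n_overlapping = n_ov,
      percent = if (nrow(removed_peaks) > 0) 100 * n_ov /
        nrow(removed_peaks) else 0)
  })
}

#' Compare per-TF target-count correlations before and after filtering
#'
#' For each TF, counts protein-coding and miRNA targets in the unfiltered
#' and filtered edge sets, computes Spearman's rank correlation between
#' the two counts for each edge set, and compares the two correlations
#' with the Fisher z transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value. Used to check that mean filtering does not
#' distort the balance of target classes.
#'
#' @param edges_before,edges_after Edge tibbles with `source_id` and
#'   `target_kind` columns (e.g. `tidy()` of a `regnet`, or the
#'   transcriptional edge table before/after [mean_filter()]).
#' @return A one-row tibble: `rho_before`, `rho_after`, `n_before`,
#'   `n_after`, `z`, `p`.
#' @export
correlation_report <- function(edges_before, edges_after) {
  per_tf <- function(edges) {
    edges |>
      dplyr::group_by(.data$source_id) |>
      dplyr::summarise(
        n_pc = sum(.data$target_kind == "protein_coding"),
        n_mir = sum(.data$target_kind == "miRNA"), .groups = "drop")
  }
  b <- per_tf(edges_before)
  a <- per_tf(edges_after)
  if (nrow(b) < 4 || nrow(a) < 4) {
    rlang::abort("correlation comparison needs at least 4 TFs per network")
  }
  r1 <- stats::cor(b$n_pc, b$n_mir, method = "spearman")
  r2 <- stats::cor(a$n_pc, a$n_mir, method = "spearman")
  if (isTRUE(all.equal(r1, r2))) {
    z <- 0
  } else {
    z <- (atanh(r1) - atanh(r2)) /
      sqrt(1 / (nrow(b) - 3) + 1 / (nrow(a) - 3))
  }
  tibble::tibble(rho_before = r1, rho_after = r2,
                 n_before = nrow(b), n_after = nrow(a),
                 z = z, p = 2 * stats::pnorm(-abs(z)))
}
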