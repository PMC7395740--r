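#' Simulation configuration for synthetic regulatory data
#'
#' Defines the study conditions the generator emulates: a ReMap-style
#' peak collection (overdispersed per-edge binding-site counts, almost
#' all peaks inside cis-regulatory modules, several cell-type datasets
#' per TF grouped into tissues), an Ensembl-style gene annotation with
#' widely spaced genes so promoter windows are unambiguous, a
#' miRBase-style miRNA locus set with a majority of intragenic miRNAs,
#' and a sparse miRTarBase-style miRNA target table.
#'
#' @param n_tf Number of TFs (the first `n_tf` protein-coding genes).
#' @param n_protein_coding Number of protein-coding genes (incl. TFs).
#' @param n_lincrna Number of lincRNA genes.
#' @param n_mirna Number of miRNAs.
#' @param frac_mirna_intragenic Fraction of miRNAs hosted inside a
#'   protein-coding transcript.
#' @param n_tissues,datasets_per_tf Tissue/dataset structure of the peak
#'   collection.
#' @param p_autoreg Probability that a TF transcriptionally regulates its
#'   own gene.
#' @param p_mirna_feedback Probability that an autoregulating TF is put
#'   in a reciprocal feedback loop with at least one miRNA.
#' @param peaks_per_edge_mean,peaks_per_edge_dispersion Negative-binomial
#'   (mu, size) for the number of binding sites supporting a true edge
#'   (truncated to >= 1).
#' @param background_peak_rate Expected number of background weight-1
#'   binding events per TF (Poisson), scattered over random promoter
#'   windows.
#' @param frac_background_outside_window Expected background peaks per TF
#'   (as a fraction of `background_peak_rate`) placed in gene-free gaps,
#'   outside every promoter window.
#' @param frac_peaks_in_crm Fraction of all peaks placed inside
#'   cis-regulatory modules (allocated exactly, up to rounding).
#' @param targets_per_tf,tf_targets_per_tf,mirna_targets_per_tf Poisson
#'   means for a TF's true protein-coding/lincRNA targets, TF targets,
#'   and (non-feedback) miRNA targets.
#' @param mutual_partners_per_tf Poisson mean for the number of TF
#'   partners with which a TF is placed in mutual (reciprocal)
#'   regulation; these reciprocal pairs are what seeds amplified- and
#'   dual-feedback motifs (M3/M4) in the true network.
#' @param targets_per_mirna Poisson mean for a miRNA's (non-feedback)
#'   post-transcriptional targets.
#' @param gene_spacing,genes_per_chrom Genome layout; the default 200 kb
#'   spacing keeps 60 kb promoter windows of neighbouring genes disjoint.
#' @param seed Integer seed; identical configurations yield identical
#'   bundles.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tf = 40, n_protein_coding = 300, n_lincrna = 10,
                       n_mirna = 60, frac_mirna_intragenic = 0.68,
                       n_tissues = 4, datasets_per_tf = 2,
                       p_autoreg = 0.56, p_mirna_feedback = 0.89,
                       peaks_per_edge_mean = 6,
                       peaks_per_edge_dispersion = 5,
                       background_peak_rate = 40,
                       frac_background_outside_window = 0.05,
                       frac_peaks_in_crm = 0.986,
                       targets_per_tf = 6, tf_targets_per_tf = 1.5,
                       mutual_partners_per_tf = 0.5,
                       mirna_targets_per_tf = 1, targets_per_mirna = 2,
                       gene_spacing = 200000, genes_per_chrom = 100,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(frac_mirna_intragenic, p_autoreg, p_mirna_feedback,
             frac_peaks_in_crm, frac_background_outside_window)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_tf >= 2, n_protein_coding > n_tf, n_mirna >= 1,
            n_tissues >= 1, datasets_per_tf >= 1,
            peaks_per_edge_mean > 0, peaks_per_edge_dispersion > 0,
            gene_spacing >= 120000)
  n_intra <- round(frac_mirna_intragenic * n_mirna)
  if (n_intra > n_protein_coding - n_tf) {
    rlang::abort("infeasible config: more intragenic miRNAs than host capacity")
  }
  structure(cfg, class = "sim_config")
}

# strand-oriented midpoint interval [lo, hi) for peak placement.
# "upstream" of a slot gene's TSS, or "downstream" for a hosted miRNA.
placement_region <- function(tss, strand, side, up = 50000L, dn = 10000L) {
  if (side == "upstream") {
    if (strand == "+") c(tss - up, tss) else c(tss + 1L, tss + up + 1L)
  } else {
    if (strand == "+") c(tss, tss + dn) else c(tss - dn + 1L, tss + 1L)
  }
}

# CRM zone = first 80% of the region; out-zone starts 150 bp later so a
# 200 bp peak centred in it cannot touch the CRM
region_zones <- function(lo, hi) {
  boundary <- lo + as.integer(floor(0.8 * (hi - lo)))
  list(crm = c(lo, boundary), out = c(boundary + 150L, hi))
}

runif_int <- function(n, lo, hi) {
  # uniform integer in [lo, hi)
  lo + as.integer(floor(stats::runif(n) * (hi - lo)))
}

#' Generate a synthetic regulatory-data bundle with planted ground truth
#'
#' Draws a true regulatory network (autoregulation, miRNA feedback, TF
#' cross-regulation, sparse miRNA targeting), lays genes out on widely
#' spaced genomic slots, then materialises the network as input files a
#' real analysis would start from: binding peaks with overdispersed
#' counts per true edge plus weight-1 background peaks, CRM intervals
#' covering a configurable fraction of peaks, gene annotation, miRNA
#' loci (intragenic ones inside host transcripts) and a miRNA target
#' table. Every true transcriptional edge is supported by at least one
#' peak whose midpoint lies in the target's promoter window, and true
#' peaks are placed so that closest-TSS assignment is unambiguous.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: when given, the bundle is also
#'   written as `peaks.bed`, `crms.bed`, `genes.tsv`, `mirna.gff3`,
#'   `mirna_targets.tsv`, `tissue_map.tsv` and `ground_truth.json`.
#' @return A list with `data` (tibbles `peaks`, `crms`, `genes`,
#'   `mirnas`, `mirna_targets`, `tissue_map`), `truth` (true edge table,
#'   planted motif instances from [plant_motifs()], per-peak labels,
#'   miRNA host map) and `paths` (when written).
#' @export
simulate_regulatory_data <- function(config = sim_config(),
                                     out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  up <- 50000L
  dn <- 10000L

  # --- gene layout on slots -------------------------------------------
  n_intra <- round(config$frac_mirna_intragenic * config$n_mirna)
  n_inter <- config$n_mirna - n_intra
  tf_ids <- sprintf("TF%03d", seq_len(config$n_tf))
  pc_ids <- c(tf_ids,
              sprintf("G%04d", seq(config$n_tf + 1, config$n_protein_coding)))
  linc_ids <- if (config$n_lincrna > 0) {
    sprintf("LNC%03d", seq_len(config$n_lincrna))
  } else {
    character()
  }
  mir_ids <- sprintf("MIR%03d", seq_len(config$n_mirna))
  intra_ids <- mir_ids[seq_len(n_intra)]
  inter_ids <- if (n_inter > 0) mir_ids[seq(n_intra + 1,
                                            config$n_mirna)] else character()
  slot_ids <- c(pc_ids, linc_ids, inter_ids)
  n_slots <- length(slot_ids)
  slot_idx <- seq_len(n_slots) - 1L
  slots <- tibble::tibble(
    gene_id = slot_ids,
    biotype = c(rep("protein_coding", length(pc_ids)),
                rep("lincRNA", length(linc_ids)),
                rep("miRNA", length(inter_ids))),
    chrom = paste0("chr", slot_idx %/% config$genes_per_chrom + 1L),
    tss = as.integer(100000L +
                       (slot_idx %% config$genes_per_chrom) *
                       config$gene_spacing),
    strand = sample(c("+", "-"), n_slots, replace = TRUE))
  # hosts: non-TF protein-coding genes, one miRNA per host
  host_pool <- setdiff(pc_ids, tf_ids)
  hosts <- sample(host_pool, n_intra)
  host_row <- match(hosts, slots$gene_id)
  intra <- tibble::tibble(
    mirna_id = intra_ids,
    host_gene_id = hosts,
    chrom = slots$chrom[host_row],
    strand = slots$strand[host_row],
    tss = as.integer(ifelse(slots$strand[host_row] == "+",
                            slots$tss[host_row] + 15000L,
                            slots$tss[host_row] - 15000L)))

  # lookup of every transcription unit: placement side + coordinates
  units <- dplyr::bind_rows(
    tibble::tibble(id = slots$gene_id, chrom = slots$chrom,
                   strand = slots$strand, tss = slots$tss,
                   side = "upstream"),
    tibble::tibble(id = intra$mirna_id, chrom = intra$chrom,
                   strand = intra$strand, tss = intra$tss,
                   side = "downstream"))

  # --- annotation tables ----------------------------------------------
  second_tss <- stats::runif(n_slots) < 0.2
  span_lo <- ifelse(slots$strand == "+", slots$tss, slots$tss - 20000L)
  span_hi <- ifelse(slots$strand == "+", slots$tss + 20000L,
                    slots$tss + 100L)
  genes <- tibble::tibble(
    gene_id = slots$gene_id, name = slots$gene_id,
    biotype = slots$biotype, chrom = slots$chrom, strand = slots$strand,
    tss = purrr::map2(slots$tss, second_tss,
                      function(t, s) if (s) c(t, t + 200L) else t),
    tx_starts = as.list(as.integer(span_lo)),
    tx_ends = as.list(as.integer(span_hi)))
  mir_genes <- tibble::tibble(
    gene_id = intra$mirna_id, name = intra$mirna_id, biotype = "miRNA",
    chrom = intra$chrom, strand = intra$strand,
    tss = as.list(intra$tss),
    tx_starts = as.list(intra$tss - 40L),
    tx_ends = as.list(intra$tss + 40L))
  genes <- dplyr::bind_rows(genes, mir_genes)
  mirnas <- dplyr::bind_rows(
    tibble::tibble(mirna_id = inter_ids,
                   chrom = slots$chrom[match(inter_ids, slots$gene_id)],
                   start = slots$tss[match(inter_ids, slots$gene_id)],
                   end = slots$tss[match(inter_ids, slots$gene_id)] + 80L,
                   strand = slots$strand[match(inter_ids, slots$gene_id)]),
    tibble::tibble(mirna_id = intra$mirna_id, chrom = intra$chrom,
                   start = intra$tss - 40L, end = intra$tss + 40L,
                   strand = intra$strand))

  # --- true regulatory edges ------------------------------------------
  biotype_of <- stats::setNames(genes$biotype, genes$gene_id)
  non_tf_targets <- c(setdiff(pc_ids, tf_ids), linc_ids)
  direct <- list()
  for (a in tf_ids) {
    tgts <- character()
    if (stats::runif(1) < config$p_autoreg) {
      tgts <- a
      if (stats::runif(1) < config$p_mirna_feedback) {
        n_fb <- 1L + stats::rpois(1, 0.5)
        fb <- sample(mir_ids, min(n_fb, length(mir_ids)))
        tgts <- c(tgts, fb)
        direct[[paste0(a, ".fb")]] <- tibble::tibble(
          source_id = fb, target_id = a, edge_class = "posttranscriptional")
      }
    }
    n_pc <- stats::rpois(1, config$targets_per_tf)
    n_tft <- stats::rpois(1, config$tf_targets_per_tf)
    n_mir <- stats::rpois(1, config$mirna_targets_per_tf)
    tgts <- unique(c(
      tgts,
      sample(non_tf_targets, min(n_pc, length(non_tf_targets))),
      sample(setdiff(tf_ids, a), min(n_tft, config$n_tf - 1L)),
      sample(mir_ids, min(n_mir, length(mir_ids)))))
    direct[[a]] <- tibble::tibble(source_id = a, target_id = tgts,
                                  edge_class = "transcriptional")
  }
  # reciprocal TF pairs: the substrate of amplified/dual feedback motifs
  for (a in tf_ids) {
    n_mut <- stats::rpois(1, config$mutual_partners_per_tf)
    if (n_mut == 0) next
    partners <- sample(setdiff(tf_ids, a), min(n_mut, config$n_tf - 1L))
    direct[[paste0(a, ".mut")]] <- tibble::tibble(
      source_id = c(rep(a, length(partners)), partners),
      target_id = c(partners, rep(a, length(partners))),
      edge_class = "transcriptional")
  }
  for (m in mir_ids) {
    n_t <- stats::rpois(1, config$targets_per_mirna)
    if (n_t == 0) next
    tgts <- sample(pc_ids, min(n_t, length(pc_ids)))
    direct[[paste0(m, ".t")]] <- tibble::tibble(
      source_id = m, target_id = tgts, edge_class = "posttranscriptional")
  }
  direct <- dplyr::distinct(dplyr::bind_rows(direct))
  trans_direct <- direct[direct$edge_class == "transcriptional", ]
  post_edges <- direct[direct$edge_class == "posttranscriptional", ]
  # host-inherited edges: regulation of a host gene is also regulation of
  # the miRNA inside it
  inherited <- trans_direct |>
    dplyr::inner_join(intra[, c("mirna_id", "host_gene_id")],
                      by = c(target_id = "host_gene_id")) |>
    dplyr::transmute(source_id = .data$source_id,
                     target_id = .data$mirna_id,
                     edge_class = "transcriptional")
  truth_edges <- dplyr::bind_rows(
    dplyr::mutate(trans_direct, inherited = FALSE),
    dplyr::mutate(inherited, inherited = TRUE),
    dplyr::mutate(post_edges, inherited = FALSE)) |>
    dplyr::arrange(.data$edge_class, .data$source_id, .data$target_id,
                   .data$inherited) |>
    dplyr::distinct(.data$source_id, .data$target_id, .data$edge_class,
                    .keep_all = TRUE) |>
    dplyr::mutate(
      source_kind = ifelse(.data$edge_class == "transcriptional", "TF",
                           "miRNA"),
      target_kind = unname(biotype_of[.data$target_id]),
      weight = 1L)

  # --- peak skeleton ---------------------------------------------------
  datasets <- tibble::tibble(
    tf = base::rep(tf_ids, each = config$datasets_per_tf),
    dataset = paste0(base::rep(tf_ids, each = config$datasets_per_tf),
                     "_ds", seq_len(config$datasets_per_tf)),
    tissue = paste0("tissue", sample.int(config$n_tissues,
                                         config$n_tf *
                                           config$datasets_per_tf,
                                         replace = TRUE)))
  peak_rows <- list()
  for (i in seq_len(nrow(trans_direct))) {
    a <- trans_direct$source_id[i]
    x <- trans_direct$target_id[i]
    w <- max(1L, stats::rnbinom(1, mu = config$peaks_per_edge_mean,
                                size = config$peaks_per_edge_dispersion))
    peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
      tf = base::rep(a, w), target = base::rep(x, w), role = "edge")
  }
  for (a in tf_ids) {
    n_bg <- stats::rpois(1, config$background_peak_rate)
    if (n_bg > 0) {
      peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
        tf = base::rep(a, n_bg),
        target = sample(slot_ids, n_bg, replace = TRUE),
        role = "background")
    }
    n_gap <- stats::rpois(1, config$background_peak_rate *
                            config$frac_background_outside_window)
    if (n_gap > 0) {
      peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
        tf = base::rep(a, n_gap),
        target = sample(slot_ids, n_gap, replace = TRUE),
        role = "gap")
    }
  }
  pk <- dplyr::bind_rows(peak_rows)
  n_pk <- nrow(pk)
  pk$in_crm <- FALSE
  pk$in_crm[sample.int(n_pk, round(config$frac_peaks_in_crm * n_pk))] <- TRUE
  # dataset (and hence tissue) per peak
  ds_pick <- function(tf) {
    opts <- datasets$dataset[datasets$tf == tf]
    opts[sample.int(length(opts), 1)]
  }
  pk$dataset <- vapply(pk$tf, ds_pick, "")
  pk$tissue <- datasets$tissue[match(pk$dataset, datasets$dataset)]

  # --- place peaks and derive CRMs ------------------------------------
  u_row <- match(pk$target, units$id)
  pk$chrom <- units$chrom[u_row]
  mid <- integer(n_pk)
  gap_counter <- new.env(parent = emptyenv())
  crm_gap <- list()
  for (i in seq_len(n_pk)) {
    tss <- units$tss[u_row[i]]
    if (pk$role[i] == "gap") {
      key <- pk$target[i]
      k <- (get0(key, envir = gap_counter, ifnotfound = 0L)) + 1L
      assign(key, k, envir = gap_counter)
      mid[i] <- tss + 60000L + k * 500L
      if (pk$in_crm[i]) {
        crm_gap[[length(crm_gap) + 1L]] <- tibble::tibble(
          chrom = pk$chrom[i], start = mid[i] - 300L, end = mid[i] + 300L)
      }
    } else {
      reg <- placement_region(tss, units$strand[u_row[i]],
                              units$side[u_row[i]], up, dn)
      z <- region_zones(reg[1], reg[2])
      zone <- if (pk$in_crm[i]) z$crm else z$out
      mid[i] <- runif_int(1, zone[1], zone[2])
    }
  }
  pk$start <- mid - 100L
  pk$end <- mid + 100L
  # one CRM interval per transcription-unit region (the 80% zone), plus
  # the small CRMs covering in-CRM gap peaks
  unit_regions <- purrr::pmap_dfr(
    units, function(id, chrom, strand, tss, side) {
      reg <- placement_region(tss, strand, side, up, dn)
      z <- region_zones(reg[1], reg[2])
      tibble::tibble(chrom = chrom, start = z$crm[1], end = z$crm[2])
    })
  crms <- dplyr::bind_rows(unit_regions, dplyr::bind_rows(crm_gap)) |>
    dplyr::arrange(.data$chrom, .data$start)

  peaks <- tibble::tibble(
    chrom = pk$chrom, start = pk$start, end = pk$end, strand = "*",
    tf = pk$tf, dataset = pk$dataset)
  mirna_targets <- post_edges |>
    dplyr::transmute(mirna_id = .data$source_id,
                     target_gene_id = .data$target_id) |>
    dplyr::arrange(.data$mirna_id, .data$target_gene_id) |>
    dplyr::mutate(weight = 1L)

  truth <- list(
    edges = truth_edges,
    motifs = plant_motifs(truth_edges),
    peaks = tibble::tibble(chrom = pk$chrom, start = pk$start,
                           end = pk$end, tf = pk$tf,
                           dataset = pk$dataset, tissue = pk$tissue,
                           target = pk$target, role = pk$role,
                           in_crm = pk$in_crm),
    mirna_hosts = intra[, c("mirna_id", "host_gene_id")],
    config = config)
  data <- list(peaks = peaks, crms = crms[, c("chrom", "start", "end")],
               genes = genes, mirnas = mirnas,
               mirna_targets = mirna_targets,
               tissue_map = datasets[, c("dataset", "tissue")])
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_sim_bundle(data, truth, out_dir)
  }
  list(data = data, truth = truth, paths = paths)
}

#' Enumerate the motifs planted in a true edge set
#'
#' Builds a network from the generator's true edges and enumerates M1-M4
#' instances in it; these are the recovery reference an end-to-end run of
#' the pipeline is scored against.
#'
#' @param truth_edges Edge tibble with `source_id`, `source_kind`,
#'   `target_id`, `target_kind`, `edge_class` (weights optional).
#' @return Named list of instance tibbles (`M1`..`M4`), as
#'   [motif_census()].
#' @export
plant_motifs <- function(truth_edges) {
  if (nrow(truth_edges) == 0) {
    empty <- tibble::tibble(motif_type = character(),
                            member_1 = character(),
                            member_2 = character())
    return(list(M1 = empty, M2 = empty, M3 = empty, M4 = empty))
  }
  if (!"weight" %in% names(truth_edges)) truth_edges$weight <- 1L
  net <- regulatory_network(
    truth_edges[, c("source_id", "source_kind", "target_id",
                    "target_kind", "edge_class", "weight")])
  motif_census(net)$instances
}

#' Write a simulated bundle to disk
#'
#' @param data,truth The `data` and `truth` elements returned by
#'   [simulate_regulatory_data()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_sim_bundle <- function(data, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  bed <- sprintf("%s\t%d\t%d\t%s.%s\t0\t%s", data$peaks$chrom,
                 data$peaks$start, data$peaks$end, data$peaks$tf,
                 data$peaks$dataset, data$peaks$strand)
  writeLines(bed, p("peaks.bed"))
  writeLines(sprintf("%s\t%d\t%d", data$crms$chrom, data$crms$start,
                     data$crms$end), p("crms.bed"))
  write_gene_annotation(data$genes, p("genes.tsv"))
  write_mirna_gff(data$mirnas, p("mirna.gff3"))
  readr::write_tsv(data$mirna_targets, p("mirna_targets.tsv"))
  readr::write_tsv(data$tissue_map, p("tissue_map.tsv"))
  jsonlite::write_json(
    list(edges = truth$edges, motifs = truth$motifs,
         peaks = truth$peaks, mirna_hosts = truth$mirna_hosts),
    p("ground_truth.json"), dataframe = "columns", digits = NA)
  out <- c(peaks = p("peaks.bed"), crms = p("crms.bed"),
           genes = p("genes.tsv"), mirnas = p("mirna.gff3"),
           mirna_targets = p("mirna_targets.tsv"),
           tissue_map = p("tissue_map.tsv"),
           ground_truth = p("ground_truth.json"))
  out
}
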