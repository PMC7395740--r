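# Internal integer representation of a network, used by the motif
# counters and the rewiring loop so per-replicate work is vector-only.
as_netrep <- function(network) {
  ids <- network$nodes$id
  e <- network$edges
  list(ids = ids,
       is_tf = network$nodes$kind == "TF",
       is_mirna = network$nodes$kind == "miRNA",
       src = match(e$source_id, ids),
       tgt = match(e$target_id, ids),
       trans = e$edge_class == "transcriptional",
       weight = e$weight,
       n = length(ids))
}

netrep_to_regnet <- function(rep, template) {
  e <- template$edges
  e$source_id <- rep$ids[rep$src]
  e$target_id <- rep$ids[rep$tgt]
  structure(list(nodes = template$nodes, edges = e), class = "regnet")
}

# motif instance index pairs on the integer representation ----------------

m1_members <- function(rep) {
  sort(unique(rep$src[rep$trans & rep$src == rep$tgt]))
}

m2_pairs <- function(rep) {
  auto <- m1_members(rep)
  sel <- rep$trans & (rep$src %in% auto) & rep$is_mirna[rep$tgt]
  a <- rep$src[sel]
  m <- rep$tgt[sel]
  key <- (a - 1) * rep$n + m
  post <- !rep$trans
  post_rev_key <- (rep$tgt[post] - 1) * rep$n + rep$src[post]
  hit <- key %in% post_rev_key
  list(tf = a[hit], mirna = m[hit])
}

# directed TF-TF edges that are reciprocated, annotated with the
# autoregulatory status of both endpoints
mutual_tf_edges <- function(rep) {
  auto <- m1_members(rep)
  sel <- rep$trans & rep$src != rep$tgt &
    rep$is_tf[rep$src] & rep$is_tf[rep$tgt]
  a <- rep$src[sel]
  b <- rep$tgt[sel]
  key <- (a - 1) * rep$n + b
  rev_key <- (b - 1) * rep$n + a
  mutual <- key %in% rev_key
  list(a = a[mutual], b = b[mutual],
       a_auto = a[mutual] %in% auto, b_auto = b[mutual] %in% auto)
}

count_motif_rep <- function(rep, motif_type, m3_allow_autoreg_partner = FALSE,
                            m4_ordered = FALSE) {
  switch(motif_type,
    M1 = length(m1_members(rep)),
    M2 = length(m2_pairs(rep)$tf),
    M3 = {
      mt <- mutual_tf_edges(rep)
      if (m3_allow_autoreg_partner) sum(mt$a_auto)
      else sum(mt$a_auto & !mt$b_auto)
    },
    M4 = {
      mt <- mutual_tf_edges(rep)
      n_ordered <- sum(mt$a_auto & mt$b_auto)
      if (m4_ordered) n_ordered else n_ordered %/% 2L
    },
    rlang::abort(paste0("unknown motif type: ", motif_type)))
}

#' Find autoregulation (M1) motifs
#'
#' One instance per TF with a transcriptional edge onto its own gene.
#' Autoregulation is the core of every feedback motif handled here: the
#' simplest circuit capable of oscillatory or bistable expression when the
#' feedback is negative.
#'
#' @param network A `regnet`.
#' @return A tibble with columns `motif_type`, `member_1`, `member_2`
#'   (`NA` for M1).
#' @export
find_m1 <- function(network) {
  rep <- as_netrep(network)
  ids <- rep$ids[m1_members(rep)]
  tibble::tibble(motif_type = rep("M1", length(ids)), member_1 = ids,
                 member_2 = NA_character_)
}

#' Find autoregulation-with-miRNA-feedback (M2) motifs
#'
#' One instance per (TF, miRNA) pair where the TF autoregulates,
#' transcriptionally regulates the miRNA, and the miRNA targets the TF
#' post-transcriptionally: the circuit of known ultradian oscillators such
#' as HES1/miR-9.
#'
#' @inheritParams find_m1
#' @return A tibble (`motif_type`, `member_1` = TF, `member_2` = miRNA).
#' @export
find_m2 <- function(network) {
  rep <- as_netrep(network)
  p <- m2_pairs(rep)
  out <- tibble::tibble(motif_type = rep("M2", length(p$tf)),
                        member_1 = rep$ids[p$tf], member_2 = rep$ids[p$mirna])
  dplyr::arrange(out, .data$member_1, .data$member_2)
}

#' Find amplified-feedback (M3) motifs
#'
#' One instance per ordered TF pair (A, B) where A autoregulates, A and B
#' regulate each other, and (by default) B does not autoregulate, keeping
#' M3 and M4 disjoint classes. Set `allow_autoreg_partner = TRUE` for the
#' inclusive convention in which the partner may itself autoregulate.
#'
#' @inheritParams find_m1
#' @param allow_autoreg_partner Count pairs whose partner also
#'   autoregulates (these are otherwise classified M4).
#' @return A tibble (`motif_type`, `member_1` = autoregulator,
#'   `member_2` = partner TF).
#' @export
find_m3 <- function(network, allow_autoreg_partner = FALSE) {
  rep <- as_netrep(network)
  mt <- mutual_tf_edges(rep)
  keep <- if (allow_autoreg_partner) mt$a_auto else mt$a_auto & !mt$b_auto
  out <- tibble::tibble(motif_type = rep("M3", sum(keep)),
                        member_1 = rep$ids[mt$a[keep]],
                        member_2 = rep$ids[mt$b[keep]])
  dplyr::arrange(out, .data$member_1, .data$member_2)
}

#' Find dual-feedback (M4) motifs
#'
#' One instance per unordered pair of autoregulating TFs that mutually
#' regulate each other. Counted once per pair by default (`member_1` <
#' `member_2` lexicographically); set `ordered = TRUE` to count each
#' direction separately.
#'
#' @inheritParams find_m1
#' @param ordered Count each ordered direction of a pair as an instance.
#' @return A tibble (`motif_type`, `member_1`, `member_2`).
#' @export
find_m4 <- function(network, ordered = FALSE) {
  rep <- as_netrep(network)
  mt <- mutual_tf_edges(rep)
  keep <- mt$a_auto & mt$b_auto
  a <- rep$ids[mt$a[keep]]
  b <- rep$ids[mt$b[keep]]
  if (!ordered) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    pair <- !duplicated(paste(lo, hi))
    a <- lo[pair]
    b <- hi[pair]
  }
  out <- tibble::tibble(motif_type = rep("M4", length(a)), member_1 = a,
                        member_2 = b)
  dplyr::arrange(out, .data$member_1, .data$member_2)
}

#' Motif census of a regulatory network
#'
#' Enumerates all four motif classes and summarises counts, participating
#' components, and per-TF partner degrees (for M2 the number of distinct
#' miRNA partners; for M3/M4 the number of distinct TF partners).
#'
#' @inheritParams find_m1
#' @param m3_allow_autoreg_partner,m4_ordered Counting-convention flags,
#'   see [find_m3()] and [find_m4()].
#' @return An object of class `motif_census`: a list with `counts`,
#'   `components` (distinct TFs/miRNAs per motif type), `partners`
#'   (per-TF partner degree per type) and `instances` (named list of
#'   instance tibbles).
#' @export
motif_census <- function(network, m3_allow_autoreg_partner = FALSE,
                         m4_ordered = FALSE) {
  inst <- list(
    M1 = find_m1(network),
    M2 = find_m2(network),
    M3 = find_m3(network, allow_autoreg_partner = m3_allow_autoreg_partner),
    M4 = find_m4(network, ordered = m4_ordered))
  counts <- tibble::tibble(motif_type = names(inst),
                           count = unname(vapply(inst, nrow, 0L)))
  components <- purrr::map_dfr(names(inst), function(ty) {
    x <- inst[[ty]]
    mir <- if (ty == "M2") unique(x$member_2) else character()
    tfs <- unique(c(x$member_1, if (ty %in% c("M3", "M4")) x$member_2))
    tibble::tibble(motif_type = ty, n_tfs = length(tfs[!is.na(tfs)]),
                   n_mirnas = length(mir))
  })
  partners <- purrr::map_dfr(c("M2", "M3", "M4"), function(ty) {
    x <- inst[[ty]]
    if (nrow(x) == 0) {
      return(tibble::tibble(motif_type = character(), tf = character(),
                            n_partners = integer()))
    }
    # for TF-TF motifs both members are TFs and each sees the other
    long <- if (ty == "M2") {
      tibble::tibble(tf = x$member_1, partner = x$member_2)
    } else {
      tibble::tibble(tf = c(x$member_1, x$member_2),
                     partner = c(x$member_2, x$member_1))
    }
    long |>
      dplyr::distinct() |>
      dplyr::count(.data$tf, name = "n_partners") |>
      dplyr::mutate(motif_type = ty, .before = 1)
  })
  structure(list(counts = counts, components = components,
                 partners = partners, instances = inst),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census>\n")
  print(dplyr::left_join(x$counts, x$components, by = "motif_type"))
  invisible(x)
}

#' @method tidy motif_census
#' @export
tidy.motif_census <- function(x, ...) {
  dplyr::left_join(x$counts, x$components, by = "motif_type")
}

# two-sided Mann-Whitney / Wilcoxon rank-sum: exact for small untied
# samples, normal approximation with tie correction otherwise
rank_sum <- function(x, y) {
  exact <- min(length(x), length(y)) <= 8 &&
    !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  c(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare connectivity of autoregulatory and non-autoregulatory TFs
#'
#' Splits the network's TFs by autoregulatory status (M1 membership) and
#' compares, between the groups, the out-degree towards each target
#' biotype and the miRNA in-degree, using two-sided Wilcoxon rank-sum
#' tests (exact for small untied samples, normal approximation with tie
#' correction otherwise).
#'
#' @inheritParams find_m1
#' @return A list of class `degree_comparison` with `degrees` (per-TF
#'   long table: `tf`, `group`, `metric`, `value`) and `tests` (one row
#'   per metric with group sizes, medians, `statistic`, `p_value`).
#'   Metrics with an empty group are skipped with a warning.
#' @export
degree_comparison <- function(network) {
  tfs <- tf_ids(network)
  auto <- find_m1(network)$member_1
  e <- network$edges
  out_by_kind <- e[e$edge_class == "transcriptional" &
                     e$source_id %in% tfs, ] |>
    dplyr::count(tf = .data$source_id, .data$target_kind)
  mir_in <- e[e$edge_class == "posttranscriptional", ] |>
    dplyr::count(tf = .data$target_id, name = "n") |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::mutate(target_kind = "miRNA_in_degree")
  metrics <- c(paste0("out_", sort(unique(out_by_kind$target_kind))),
               "miRNA_in_degree")
  long <- dplyr::bind_rows(
    dplyr::mutate(out_by_kind, metric = paste0("out_", .data$target_kind)),
    dplyr::mutate(mir_in, metric = "miRNA_in_degree")) |>
    dplyr::select("tf", "metric", value = "n")
  # zero-fill: every TF appears for every metric
  full <- tidyr::expand_grid(tf = tfs, metric = metrics) |>
    dplyr::left_join(long, by = c("tf", "metric")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0L),
                  group = ifelse(.data$tf %in% auto, "autoregulatory",
                                 "non_autoregulatory"))
  tests <- purrr::map_dfr(metrics, function(mt) {
    d <- full[full$metric == mt, ]
    x <- d$value[d$group == "autoregulatory"]
    y <- d$value[d$group == "non_autoregulatory"]
    if (length(x) == 0 || length(y) == 0) {
      rlang::warn(paste0("metric ", mt,
                         ": one group is empty, comparison skipped"))
      return(tibble::tibble())
    }
    rs <- suppressWarnings(rank_sum(x, y))
    tibble::tibble(metric = mt, n_auto = length(x), n_non = length(y),
                   median_auto = stats::median(x),
                   median_non = stats::median(y),
                   statistic = rs[["statistic"]],
                   p_value = rs[["p_value"]])
  })
  structure(list(degrees = full[, c("tf", "group", "metric", "value")],
                 tests = tests),
            class = "degree_comparison")
}

#' @export
print.degree_comparison <- function(x, ...) {
  cat("<degree_comparison> autoregulatory vs non-autoregulatory TFs\n")
  print(x$tests)
  invisible(x)
}

#' @method tidy degree_comparison
#' @export
tidy.degree_comparison <- function(x, ...) x$tests
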