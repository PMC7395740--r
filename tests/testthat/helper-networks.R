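# Random network and small-fixture builders used across test files.

# a regnet built from an explicit edge list written as "a->b" strings
quick_net <- function(trans = character(), post = character(),
                      mirnas = character()) {
  split_edge <- function(s) strsplit(s, "->", fixed = TRUE)[[1]]
  te <- lapply(trans, split_edge)
  pe <- lapply(post, split_edge)
  mir_set <- unique(c(mirnas, vapply(pe, `[`, "", 1)))
  kind_of <- function(x) ifelse(x %in% mir_set, "miRNA", "protein_coding")
  edges <- dplyr::bind_rows(
    if (length(te)) tibble::tibble(
      source_id = vapply(te, `[`, "", 1), source_kind = "TF",
      target_id = vapply(te, `[`, "", 2),
      target_kind = kind_of(vapply(te, `[`, "", 2)),
      edge_class = "transcriptional", weight = 1L),
    if (length(pe)) tibble::tibble(
      source_id = vapply(pe, `[`, "", 1), source_kind = "miRNA",
      target_id = vapply(pe, `[`, "", 2),
      target_kind = kind_of(vapply(pe, `[`, "", 2)),
      edge_class = "posttranscriptional", weight = 1L))
  regulatory_network(edges)
}

# Erdos-Renyi-style mixed TF/miRNA network with explicit node table
random_regnet <- function(n_tf = 12, n_mirna = 8, p_trans = 0.15,
                          p_auto = 0.3, p_tm = 0.15, p_post = 0.15,
                          seed = 1) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  mirs <- if (n_mirna > 0) sprintf("m%02d", seq_len(n_mirna)) else character()
  ee <- list()
  for (a in tfs) {
    tg <- setdiff(tfs[stats::runif(n_tf) < p_trans], a)
    if (stats::runif(1) < p_auto) tg <- c(tg, a)
    tgm <- mirs[stats::runif(n_mirna) < p_tm]
    if (length(tg) + length(tgm) > 0) {
      ee[[a]] <- tibble::tibble(
        source_id = a, source_kind = "TF", target_id = c(tg, tgm),
        target_kind = c(rep("protein_coding", length(tg)),
                        rep("miRNA", length(tgm))),
        edge_class = "transcriptional",
        weight = sample(1:5, length(tg) + length(tgm), replace = TRUE))
    }
  }
  for (m in mirs) {
    tg <- tfs[stats::runif(n_tf) < p_post]
    if (length(tg) > 0) {
      ee[[m]] <- tibble::tibble(
        source_id = m, source_kind = "miRNA", target_id = tg,
        target_kind = "protein_coding",
        edge_class = "posttranscriptional",
        weight = sample(1:3, length(tg), replace = TRUE))
    }
  }
  nodes <- tibble::tibble(
    id = c(tfs, mirs),
    kind = c(rep("TF", n_tf), rep("miRNA", n_mirna)),
    biotype = c(rep("protein_coding", n_tf), rep("miRNA", n_mirna)))
  regulatory_network(dplyr::bind_rows(ee), nodes = nodes)
}

# named per-node degree vectors by edge class, computed naively
degree_vectors <- function(net) {
  ids <- sort(net$nodes$id)
  e <- net$edges
  res <- list()
  for (cl in c("transcriptional", "posttranscriptional")) {
    d <- e[e$edge_class == cl, ]
    res[[paste0(cl, ".out")]] <- table(factor(d$source_id, levels = ids))
    res[[paste0(cl, ".in")]] <- table(factor(d$target_id, levels = ids))
  }
  res
}

self_loop_keys <- function(net) {
  e <- net$edges
  sort(paste(e$source_id, e$edge_class)[e$source_id == e$target_id])
}

edge_keys <- function(net) {
  e <- net$edges
  paste(e$source_id, e$target_id, e$edge_class)
}

# hand-built four-tissue fixture with known conservation arithmetic:
#  A: data in all 4 tissues; autoregulates in t1,t2 only; feedback pair
#     (A,x) complete in t1,t2; in t3 A->x survives but autoregulation is
#     lost; in t4 both transcriptional edges are gone.
#  B: data in t1,t2; autoregulates and keeps pair (B,y) in both.
#  C: data in t1 only, so it must be discounted.
hand_tissue_set <- function() {
  nets <- list(
    t1 = quick_net(trans = c("A->A", "A->x", "B->B", "B->y", "C->C"),
                   post = c("x->A", "y->B")),
    t2 = quick_net(trans = c("A->A", "A->x", "B->B", "B->y"),
                   post = c("x->A", "y->B")),
    t3 = quick_net(trans = c("A->x", "A->G1"),
                   post = c("x->A", "y->B")),
    t4 = quick_net(trans = c("A->G1"),
                   post = c("x->A", "y->B")))
  tf_data <- tibble::tibble(
    tissue = c("t1", "t2", "t3", "t4", "t1", "t2", "t1"),
    tf = c("A", "A", "A", "A", "B", "B", "C"))
  tissue_network_set(nets, tf_data)
}
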