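peak_row <- function(chrom, start, end, tf = "TF1", dataset = "ds1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = "*", tf = tf,
                 dataset = dataset)
}

test_that("CRM filter keeps >=1 bp overlaps and partitions the input", {
  crms <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L)
  peaks <- dplyr::bind_rows(
    peak_row("chr1", 100, 200),   # 50 bp overlap -> kept
    peak_row("chr1", 200, 300),   # abuts a CRM ending at 300? overlaps
    peak_row("chr1", 300, 400),   # half-open: abuts at 300, no overlap
    peak_row("chr2", 150, 250))   # wrong chromosome
  res <- filter_peaks_by_crm(peaks, crms)
  expect_equal(res$kept$start, c(100L, 200L))
  expect_equal(res$removed$start, c(300L, 150L))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(peaks))
  # empty CRM set removes everything
  res0 <- filter_peaks_by_crm(peaks, crms[0, ])
  expect_equal(nrow(res0$kept), 0)
  expect_equal(nrow(res0$removed), nrow(peaks))
})

gene_row <- function(gene_id, tss, strand = "+", chrom = "chr1",
                     biotype = "protein_coding") {
  lo <- as.integer(min(tss))
  hi <- as.integer(max(tss) + 1000L)
  tibble::tibble(gene_id = gene_id, name = gene_id, biotype = biotype,
                 chrom = chrom, strand = strand, tss = list(as.integer(tss)),
                 tx_starts = list(lo), tx_ends = list(hi))
}

test_that("peaks go to the closest TSS inside the oriented window", {
  genes <- dplyr::bind_rows(gene_row("G1", 100000L),
                            gene_row("G2", 96000L))
  # midpoint 95000: within 50 kb upstream of both, G2 is nearer
  a <- assign_peaks_to_tss(peak_row("chr1", 94900, 95100), genes)
  expect_equal(a$gene_id, "G2")
  expect_equal(a$distance, 1000L)
  # G1 alone: distance 5000
  a1 <- assign_peaks_to_tss(peak_row("chr1", 94900, 95100), genes[1, ])
  expect_equal(a1$distance, 5000L)
  # downstream limit on + strand: mid 109999 in, mid 110000 out
  a2 <- assign_peaks_to_tss(peak_row("chr1", 109899, 110099), genes[1, ])
  expect_equal(a2$gene_id, "G1")
  a3 <- assign_peaks_to_tss(peak_row("chr1", 109900, 110100), genes[1, ])
  expect_equal(nrow(a3), 0)
  expect_equal(attr(a3, "n_outside_window"), 1L)
})

test_that("minus-strand windows are mirrored", {
  gm <- gene_row("GM", 100000L, strand = "-")
  # upstream of a minus-strand gene lies at higher coordinates
  a <- assign_peaks_to_tss(peak_row("chr1", 107900, 108100), gm)
  expect_equal(a$gene_id, "GM")
  expect_equal(a$distance, 8000L)
  # 11 kb below the TSS is beyond the 10 kb downstream window
  a2 <- assign_peaks_to_tss(peak_row("chr1", 88900, 89100), gm)
  expect_equal(nrow(a2), 0)
  # boundary arithmetic: mid = tss - 10000 + 1 is the last eligible
  a3 <- assign_peaks_to_tss(peak_row("chr1", 89901, 90101), gm)  # mid 90001
  expect_equal(nrow(a3), 1)
  a4 <- assign_peaks_to_tss(peak_row("chr1", 89900, 90100), gm)  # mid 90000
  expect_equal(nrow(a4), 0)
  # mid = tss + 50000 still eligible upstream, +50001 is not
  a5 <- assign_peaks_to_tss(peak_row("chr1", 149900, 150100), gm)
  expect_equal(nrow(a5), 1)
  a6 <- assign_peaks_to_tss(peak_row("chr1", 149901, 150101), gm)
  expect_equal(nrow(a6), 0)
})

test_that("equidistant TSSs of different genes tie-break lexicographically", {
  genes <- dplyr::bind_rows(gene_row("GB", 95000L), gene_row("GA", 105000L))
  expect_message(
    a <- assign_peaks_to_tss(peak_row("chr1", 99900, 100100), genes),
    "equidistant")
  expect_equal(a$gene_id, "GA")
  expect_error(
    assign_peaks_to_tss(peak_row("chr1", 1, 100),
                        tibble::tibble(gene_id = "G", name = "G",
                                       biotype = "protein_coding",
                                       chrom = "chr1", strand = "+",
                                       tss = list(integer()),
                                       tx_starts = list(0L),
                                       tx_ends = list(1L))),
    "empty TSS")
})

test_that("hosted miRNAs inherit host regulation, direct edges retained", {
  genes <- dplyr::bind_rows(gene_row("H", 100000L),
                            gene_row("mirX", 115000L, biotype = "miRNA"))
  mirnas <- tibble::tibble(mirna_id = "mirX", chrom = "chr1",
                           start = 114980L, end = 115060L, strand = "+",
                           host_gene_id = "H")
  assignments <- tibble::tibble(
    tf = c(rep("A", 3), rep("A", 2)),
    dataset = "ds1",
    gene_id = c(rep("H", 3), rep("mirX", 2)),
    tss = c(rep(100000L, 3), rep(115000L, 2)),
    distance = 0L)
  out <- inherit_host_regulation(assignments, mirnas, genes)
  expect_equal(nrow(out), 5 + 3)  # three copies appended
  edges <- collapse_assignments(out)
  expect_equal(edges$weight[edges$target_id == "mirX"], 5L)
  expect_equal(edges$weight[edges$target_id == "H"], 3L)
  # intergenic miRNA leaves assignments unchanged
  mir2 <- tibble::tibble(mirna_id = "mirY", chrom = "chr1", start = 1L,
                         end = 80L, strand = "+",
                         host_gene_id = NA_character_)
  expect_identical(inherit_host_regulation(assignments, mir2, genes),
                   assignments)
  bad <- dplyr::mutate(mirnas, host_gene_id = "NOPE")
  expect_error(inherit_host_regulation(assignments, bad, genes),
               "host_gene_id")
})

test_that("collapse conserves the total number of assignments", {
  a <- tibble::tibble(tf = c("A", "A", "A", "A"), dataset = "d",
                      gene_id = c("G", "G", "G", "H"), tss = 1L,
                      distance = 0L)
  e <- collapse_assignments(a)
  expect_equal(e$weight[e$target_id == "G"], 3L)
  expect_equal(e$weight[e$target_id == "H"], 1L)
  expect_equal(nrow(collapse_assignments(a[0, ])), 0)
  set.seed(99)
  big <- tibble::tibble(
    tf = sample(LETTERS[1:6], 500, replace = TRUE), dataset = "d",
    gene_id = sample(paste0("G", 1:40), 500, replace = TRUE),
    tss = 1L, distance = 0L)
  expect_equal(sum(collapse_assignments(big)$weight), 500L)
})

test_that("mean filter matches the arithmetic oracle on fixed weight sets", {
  mk <- function(w, tf = "TF1") {
    tibble::tibble(source_id = tf, target_id = paste0("G", seq_along(w)),
                   weight = as.integer(w))
  }
  # {1,2,3,10}: mean 4, sd ~4.08, no outliers, threshold 4 -> only the 10
  r1 <- mean_filter(mk(c(1, 2, 3, 10)))
  expect_equal(r1$edges$weight, 10L)
  expect_equal(r1$thresholds$threshold, 4)
  expect_equal(r1$thresholds$n_outliers, 0L)
  # {1 x10, 200}: 200 is a >2 SD outlier, trimmed mean 1 -> all 11 kept
  r2 <- mean_filter(mk(c(rep(1, 10), 200)))
  expect_equal(nrow(r2$edges), 11)
  expect_equal(r2$thresholds$threshold, 1)
  expect_equal(r2$thresholds$n_outliers, 1L)
  # all equal weights: threshold w, everything kept
  r3 <- mean_filter(mk(rep(7, 5)))
  expect_equal(nrow(r3$edges), 5)
  # single edge is kept
  r4 <- mean_filter(mk(3))
  expect_equal(nrow(r4$edges), 1)
  expect_error(mean_filter(mk(0)), "positive")
})

test_that("mean filter keeps exactly the edges at or above each TF threshold", {
  set.seed(7)
  edges <- tibble::tibble(
    source_id = sample(paste0("TF", 1:8), 300, replace = TRUE),
    target_id = paste0("G", 1:300),
    weight = as.integer(1 + stats::rnbinom(300, mu = 5, size = 1)))
  res <- mean_filter(edges)
  thr <- res$thresholds$threshold[match(edges$source_id,
                                        res$thresholds$source_id)]
  expect_identical(edges$weight >= thr,
                   paste(edges$source_id, edges$target_id) %in%
                     paste(res$edges$source_id, res$edges$target_id))
})

test_that("build_network merges classes and validates endpoints", {
  genes <- dplyr::bind_rows(gene_row("A", 1000L), gene_row("G", 5000L),
                            gene_row("m1", 9000L, biotype = "miRNA"))
  trans <- tibble::tibble(source_id = c("A", "A"),
                          target_id = c("A", "G"), weight = c(2L, 1L))
  post <- tibble::tibble(mirna_id = c("m1", "m1"),
                         target_gene_id = c("A", "A"), weight = c(1L, 2L))
  net <- build_network(trans, post, genes)
  expect_equal(nrow(net$edges), 3)
  pe <- net$edges[net$edges$edge_class == "posttranscriptional", ]
  expect_equal(pe$weight, 3L)  # duplicate miRNA rows summed
  expect_equal(net$nodes$kind[net$nodes$id == "A"], "TF")
  expect_equal(net$nodes$kind[net$nodes$id == "m1"], "miRNA")
  expect_error(
    build_network(tibble::tibble(source_id = "A", target_id = "ZZ",
                                 weight = 1L), post, genes),
    "absent")
})

test_that("trimming keeps regulator-to-regulator edges and is idempotent", {
  net <- quick_net(trans = c("A->A", "A->G", "A->m1"), post = "m1->A")
  tr <- trim_to_regulators(net)
  expect_setequal(paste(tr$edges$source_id, tr$edges$target_id),
                  c("A A", "A m1", "m1 A"))
  net2 <- quick_net(trans = c("A->G", "A->H"))
  expect_equal(nrow(trim_to_regulators(net2)$edges), 0)
  big <- random_regnet(n_tf = 15, n_mirna = 10, seed = 5)
  tr1 <- trim_to_regulators(big)
  expect_identical(trim_to_regulators(tr1)$edges, tr1$edges)
  # brute-force reference: targets must be TF or miRNA nodes
  reg <- big$nodes$id[big$nodes$kind %in% c("TF", "miRNA")]
  keep <- vapply(seq_len(nrow(big$edges)),
                 function(i) big$edges$target_id[i] %in% reg, TRUE)
  expect_setequal(edge_keys(tr1), edge_keys(big)[keep])
})

test_that("candidate-element overlap percentages match planted fractions", {
  peaks <- peak_row("chr1", seq(0, 99000, by = 1000),
                    seq(200, 99200, by = 1000))
  inside <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L,
                           class = "dELS")
  res <- intersect_candidate_elements(peaks, inside)
  expect_equal(res$percent[res$class == "dELS"], 100)
  res0 <- intersect_candidate_elements(peaks, inside[0, ])
  expect_true(all(res0$percent == 0))
  # planted 47%: elements covering exactly the first 47 peaks
  cre <- tibble::tibble(chrom = "chr1",
                        start = as.integer(seq(0, 46000, by = 1000)),
                        end = as.integer(seq(100, 46100, by = 1000)),
                        class = "dELS")
  res47 <- intersect_candidate_elements(peaks, cre)
  expect_equal(res47$percent[res47$class == "dELS"], 47)
  expect_equal(res47$percent[res47$class == "PLS"], 0)
})

test_that("correlation report compares Spearman correlations via Fisher z", {
  mk_counts <- function(n_pc, n_mir) {
    purrr::map2_dfr(seq_along(n_pc), seq_along(n_pc), function(i, j) {
      tibble::tibble(
        source_id = paste0("TF", i),
        target_kind = c(rep("protein_coding", n_pc[i]),
                        rep("miRNA", n_mir[i])))
    })
  }
  mono <- mk_counts(1:6, 2 * (1:6))
  r <- correlation_report(mono, mono)
  expect_equal(r$rho_before, 1)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  rev <- mk_counts(1:6, 12 - 2 * (1:6) + 1)
  r2 <- correlation_report(rev, mono)
  expect_equal(r2$rho_before, -1)
  expect_equal(r2$rho_after, 1)
  expect_error(correlation_report(mk_counts(1:3, 1:3), mono), "4 TFs")
})
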