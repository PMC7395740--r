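test_that("tissue splitting partitions transcriptional edges by TF data", {
  sim <- simulate_regulatory_data(
    sim_config(n_tf = 12, n_protein_coding = 80, n_lincrna = 4,
               n_mirna = 20, n_tissues = 3, seed = 9))
  set <- split_by_tissue(sim$data$peaks, sim$data$tissue_map,
                         sim$data$crms, sim$data$genes, sim$data$mirnas,
                         sim$data$mirna_targets)
  expect_s3_class(set, "tissue_network_set")
  first_post <- NULL
  for (ti in set$tissues) {
    net <- set$networks[[ti]]
    trans <- net$edges[net$edges$edge_class == "transcriptional", ]
    tf_here <- set$tf_data$tf[set$tf_data$tissue == ti]
    expect_true(all(trans$source_id %in% tf_here))
    # posttranscriptional edges identical in every tissue
    post <- dplyr::arrange(
      net$edges[net$edges$edge_class == "posttranscriptional", ],
      source_id, target_id)
    if (is.null(first_post)) first_post <- post
    expect_identical(post, first_post)
  }
  # union of per-tissue edges is contained in the pooled pre-filter edges
  kept <- filter_peaks_by_crm(sim$data$peaks, sim$data$crms)$kept
  pooled <- collapse_assignments(inherit_host_regulation(
    assign_peaks_to_tss(kept, sim$data$genes),
    assign_mirna_hosts(sim$data$mirnas, sim$data$genes), sim$data$genes))
  pooled_keys <- paste(pooled$source_id, pooled$target_id)
  for (ti in set$tissues) {
    net <- set$networks[[ti]]
    trans <- net$edges[net$edges$edge_class == "transcriptional", ]
    expect_true(all(paste(trans$source_id, trans$target_id) %in%
                      pooled_keys))
  }
})

test_that("a single tissue reproduces the pooled network", {
  sim <- simulate_regulatory_data(
    sim_config(n_tf = 10, n_protein_coding = 60, n_lincrna = 2,
               n_mirna = 12, n_tissues = 1, seed = 17))
  set <- split_by_tissue(sim$data$peaks, sim$data$tissue_map,
                         sim$data$crms, sim$data$genes, sim$data$mirnas,
                         sim$data$mirna_targets)
  pooled <- build_regulatory_network(
    sim$data$peaks, sim$data$crms, sim$data$genes, sim$data$mirnas,
    sim$data$mirna_targets)
  only <- set$networks[[1]]
  expect_setequal(edge_keys(only), edge_keys(pooled$network))
})

test_that("unmapped dataset labels are reported", {
  sim <- simulate_regulatory_data(
    sim_config(n_tf = 5, n_protein_coding = 30, n_lincrna = 0,
               n_mirna = 6, n_tissues = 2, seed = 3))
  bad_map <- sim$data$tissue_map[-1, ]
  expect_error(
    split_by_tissue(sim$data$peaks, bad_map, sim$data$crms,
                    sim$data$genes, sim$data$mirnas,
                    sim$data$mirna_targets),
    sim$data$tissue_map$dataset[1], fixed = TRUE)
})

test_that("conservation percentages match hand-computed values", {
  set <- hand_tissue_set()
  m1 <- motif_conservation(set, "M1")
  expect_setequal(m1$tf, c("A", "B"))  # C has data in one tissue only
  expect_equal(m1$percent[m1$tf == "A"], 50)
  expect_equal(m1$n_tissues_with_data[m1$tf == "A"], 4L)
  expect_equal(m1$percent[m1$tf == "B"], 100)

  m2tf <- motif_conservation(set, "M2_tf")
  expect_equal(m2tf$percent[m2tf$tf == "A"], 50)
  expect_equal(m2tf$percent[m2tf$tf == "B"], 100)

  full <- motif_conservation(set, "M2_full")
  expect_equal(nrow(full), 2)
  expect_equal(full$percent[full$tf == "A" & full$mirna == "x"], 50)
  expect_equal(full$percent[full$tf == "B" & full$mirna == "y"], 100)
})

test_that("conservation is invariant under tissue relabelling", {
  set <- hand_tissue_set()
  relabel <- c(t1 = "z4", t2 = "z3", t3 = "z2", t4 = "z1")
  nets <- set$networks
  names(nets) <- unname(relabel[names(nets)])
  set2 <- tissue_network_set(
    nets, dplyr::mutate(set$tf_data, tissue = unname(relabel[tissue])))
  for (lev in c("M1", "M2_tf", "M2_full")) {
    a <- motif_conservation(set, lev)
    b <- motif_conservation(set2, lev)
    expect_identical(a, b)
  }
})

test_that("pairwise Jaccard matches set arithmetic on the edge lists", {
  n1 <- quick_net(trans = c("a->b", "a->c"))
  n2 <- quick_net(trans = c("a->b", "a->d"))
  n3 <- quick_net(trans = c("x->y"))
  set <- tissue_network_set(list(t1 = n1, t2 = n2, t3 = n3),
                            tibble::tibble(tissue = c("t1", "t2", "t3"),
                                           tf = c("a", "a", "x")))
  J <- pairwise_jaccard(set)
  expect_equal(diag(J), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(J["t1", "t2"], 1 / 3)
  expect_equal(J["t1", "t3"], 0)
  expect_identical(J, t(J))
  # identical edge sets -> 1 regardless of weights
  set2 <- tissue_network_set(list(u = n1, v = n1),
                             tibble::tibble(tissue = c("u", "v"),
                                            tf = "a"))
  expect_equal(pairwise_jaccard(set2)["u", "v"], 1)
})

test_that("M2 losses are attributed to the missing edge", {
  set <- hand_tissue_set()
  la <- loss_attribution(set)
  rec <- la$records
  # pair (A,x): absent in t3 (autoregulation lost) and t4 (both edges)
  expect_equal(rec$reason[rec$tf == "A" & rec$tissue == "t3"],
               "lost_autoregulation")
  expect_equal(rec$reason[rec$tf == "A" & rec$tissue == "t4"],
               "both_missing")
  expect_equal(nrow(rec[rec$tf == "B", ]), 0)
  # frequencies relative to all pair x data-tissue combinations (6)
  expect_equal(la$n_opportunities, 6L)
  f <- la$frequencies
  expect_equal(f$percent[f$reason == "lost_autoregulation"], 100 / 6)
  # planted missing-TF-regulation case
  set2 <- tissue_network_set(
    list(t1 = quick_net(trans = c("A->A", "A->x"), post = "x->A"),
         t2 = quick_net(trans = c("A->A", "A->G"), post = "x->A")),
    tibble::tibble(tissue = c("t1", "t2"), tf = "A"))
  rec2 <- loss_attribution(set2)$records
  expect_equal(rec2$reason, "missing_tf_mirna_regulation")
})
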