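test_that("motif finders handle the defining hand-built cases", {
  # M1: a self-loop is required
  expect_equal(find_m1(quick_net(trans = "A->A"))$member_1, "A")
  expect_equal(nrow(find_m1(quick_net(trans = c("A->B", "B->A")))), 0)
  # M2: all three edges required
  m2net <- quick_net(trans = c("T->T", "T->m"), post = "m->T")
  expect_equal(find_m2(m2net)$member_2, "m")
  expect_equal(nrow(find_m2(quick_net(trans = "T->m", post = "m->T"))), 0)
  # M3: partner must not autoregulate under the default convention
  m3net <- quick_net(trans = c("A->A", "A->B", "B->A"))
  expect_equal(find_m3(m3net)$member_2, "B")
  both <- quick_net(trans = c("A->A", "B->B", "A->B", "B->A"))
  expect_equal(nrow(find_m3(both)), 0)
  expect_equal(nrow(find_m3(both, allow_autoreg_partner = TRUE)), 2)
  # M4: unordered pair counted once; ordered doubles it
  expect_equal(nrow(find_m4(both)), 1)
  expect_equal(find_m4(both)$member_1, "A")
  expect_equal(nrow(find_m4(both, ordered = TRUE)), 2)
  expect_equal(nrow(find_m4(quick_net(trans = c("A->A", "B->B", "A->B")))),
               0)
})

test_that("motif finders agree with brute-force enumeration on random networks", {
  for (seed in 1:25) {
    net <- random_regnet(n_tf = sample(5:20, 1), n_mirna = sample(3:15, 1),
                         p_trans = stats::runif(1, 0.05, 0.4),
                         p_auto = stats::runif(1, 0.1, 0.6),
                         p_tm = stats::runif(1, 0.05, 0.4),
                         p_post = stats::runif(1, 0.05, 0.4), seed = seed)
    expect_identical(find_m1(net)$member_1, oracle_m1(net))
    expect_same_instances(find_m2(net), oracle_m2(net))
    expect_same_instances(find_m3(net), oracle_m3(net))
    expect_same_instances(find_m3(net, allow_autoreg_partner = TRUE),
                          oracle_m3(net, allow_autoreg_partner = TRUE))
    expect_same_instances(find_m4(net), oracle_m4(net))
    expect_same_instances(find_m4(net, ordered = TRUE),
                          oracle_m4(net, ordered = TRUE))
  }
})

test_that("motif classes satisfy their containment and disjointness relations", {
  for (seed in 26:40) {
    net <- random_regnet(n_tf = 15, n_mirna = 10, p_trans = 0.25,
                         p_auto = 0.4, seed = seed)
    auto <- find_m1(net)$member_1
    m2 <- find_m2(net); m3 <- find_m3(net); m4 <- find_m4(net)
    expect_true(all(m2$member_1 %in% auto))
    expect_true(all(c(m4$member_1, m4$member_2) %in% auto))
    # M3 pairs (partner non-autoregulatory) never coincide with M4 pairs
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_length(intersect(key(m3$member_1, m3$member_2),
                            key(m4$member_1, m4$member_2)), 0)
  }
})

test_that("the census is invariant under node relabelling", {
  net <- random_regnet(n_tf = 12, n_mirna = 8, p_trans = 0.3,
                       p_auto = 0.5, seed = 77)
  cen <- motif_census(net)
  perm <- setNames(sprintf("node%02d", sample(20)), net$nodes$id)
  e <- net$edges
  e$source_id <- unname(perm[e$source_id])
  e$target_id <- unname(perm[e$target_id])
  n2 <- net$nodes
  n2$id <- unname(perm[n2$id])
  cen2 <- motif_census(regulatory_network(e, n2))
  expect_identical(cen$counts, cen2$counts)
  expect_identical(cen$components, cen2$components)
  expect_identical(sort(cen$partners$n_partners),
                   sort(cen2$partners$n_partners))
})

test_that("census counts, components and partner degrees are consistent", {
  net <- quick_net(trans = c("T->T", "T->m1", "T->m2"),
                   post = c("m1->T", "m2->T"))
  cen <- motif_census(net)
  expect_equal(cen$counts$count[cen$counts$motif_type == "M2"], 2L)
  expect_equal(cen$components$n_mirnas[cen$components$motif_type == "M2"],
               2L)
  p <- cen$partners
  expect_equal(p$n_partners[p$motif_type == "M2" & p$tf == "T"], 2L)
  empty <- motif_census(quick_net(trans = "A->B"))
  expect_true(all(empty$counts$count == c(0L, 0L, 0L, 0L)))
})

test_that("rank-sum machinery reproduces exact and asymptotic references", {
  # enumeration over all C(6,3) labelings gives exact two-sided p = 0.1
  rs <- regmotif:::rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(rs["statistic"]), 0)
  expect_equal(unname(rs["p_value"]), 0.1)
  # identical groups are not distinguishable
  rs2 <- suppressWarnings(regmotif:::rank_sum(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(rs2["p_value"]), 1)
  # a 2-sigma shift at n = 200 is overwhelmingly significant
  set.seed(31)
  rs3 <- regmotif:::rank_sum(stats::rnorm(200, 2), stats::rnorm(200, 0))
  expect_lt(unname(rs3["p_value"]), 0.01)
})

test_that("degree comparison splits TFs by autoregulation and tests each metric", {
  net <- random_regnet(n_tf = 20, n_mirna = 12, p_trans = 0.3,
                       p_auto = 0.5, p_tm = 0.3, p_post = 0.3, seed = 13)
  dc <- degree_comparison(net)
  auto <- find_m1(net)$member_1
  expect_setequal(unique(dc$degrees$tf), tf_ids <- net$nodes$id[
    net$nodes$kind == "TF"])
  expect_true(all(dc$degrees$group[dc$degrees$tf %in% auto] ==
                    "autoregulatory"))
  expect_true(all(c("n_auto", "n_non", "p_value") %in% names(dc$tests)))
  # out-degrees in the table match a direct count
  e <- net$edges
  t01_out <- sum(e$source_id == "T01" & e$edge_class == "transcriptional" &
                   e$target_kind == "protein_coding")
  got <- dc$degrees$value[dc$degrees$tf == "T01" &
                            dc$degrees$metric == "out_protein_coding"]
  expect_equal(got, t01_out)
  # all-autoregulatory network: comparisons skipped with warnings
  allauto <- quick_net(trans = c("A->A", "B->B", "A->B"))
  w <- testthat::capture_warnings(dc2 <- degree_comparison(allauto))
  expect_true(all(grepl("empty", w)))
  expect_equal(nrow(dc2$tests), 0)
})
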