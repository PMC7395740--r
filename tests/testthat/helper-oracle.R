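# Brute-force motif enumeration, written independently of the package's
# production path: plain loops over node tuples with membership tests on
# an edge-key set. Deliberately slow and obvious.

oracle_keys <- function(net) {
  e <- net$edges
  trans <- e$edge_class == "transcriptional"
  list(trans = paste(e$source_id[trans], e$target_id[trans]),
       post = paste(e$source_id[!trans], e$target_id[!trans]))
}

oracle_tfs <- function(net) sort(net$nodes$id[net$nodes$kind == "TF"])
oracle_mirnas <- function(net) sort(net$nodes$id[net$nodes$kind == "miRNA"])

oracle_m1 <- function(net) {
  k <- oracle_keys(net)
  tfs <- oracle_tfs(net)
  tfs[vapply(tfs, function(a) paste(a, a) %in% k$trans, TRUE)]
}

oracle_m2 <- function(net) {
  k <- oracle_keys(net)
  out <- list()
  for (a in oracle_tfs(net)) {
    if (!paste(a, a) %in% k$trans) next
    for (m in oracle_mirnas(net)) {
      if (paste(a, m) %in% k$trans && paste(m, a) %in% k$post) {
        out[[length(out) + 1]] <- c(a, m)
      }
    }
  }
  do.call(rbind, out)
}

oracle_m3 <- function(net, allow_autoreg_partner = FALSE) {
  k <- oracle_keys(net)
  tfs <- oracle_tfs(net)
  auto <- oracle_m1(net)
  out <- list()
  for (a in auto) {
    for (b in tfs) {
      if (a == b) next
      if (!allow_autoreg_partner && b %in% auto) next
      if (paste(a, b) %in% k$trans && paste(b, a) %in% k$trans) {
        out[[length(out) + 1]] <- c(a, b)
      }
    }
  }
  do.call(rbind, out)
}

oracle_m4 <- function(net, ordered = FALSE) {
  k <- oracle_keys(net)
  auto <- oracle_m1(net)
  out <- list()
  for (a in auto) {
    for (b in auto) {
      if (ordered) {
        if (a == b) next
      } else {
        if (a >= b) next
      }
      if (paste(a, b) %in% k$trans && paste(b, a) %in% k$trans) {
        out[[length(out) + 1]] <- c(a, b)
      }
    }
  }
  do.call(rbind, out)
}

# compare an instance tibble (member_1, member_2) with an oracle matrix
expect_same_instances <- function(found, oracle_mat) {
  found_keys <- sort(paste(found$member_1, found$member_2))
  oracle_keys <- if (is.null(oracle_mat)) character() else
    sort(paste(oracle_mat[, 1], oracle_mat[, 2]))
  expect_identical(found_keys, oracle_keys)
}
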