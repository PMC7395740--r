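#' Rewiring configuration
#'
#' Parameters of the degree-preserving null model. `"unlocked"` mode
#' rewires every edge (self-loops may appear or disappear, which is what
#' makes the autoregulation count vary under the null); `"locked"` mode
#' holds the autoregulatory (self-loop) edge set fixed, the appropriate
#' null for motifs that are conditional on autoregulation (M2-M4).
#'
#' @param mode `"locked"` or `"unlocked"`.
#' @param swap_factor Attempted swaps per edge class, as a multiple of the
#'   class's edge count (attempts discarded for creating duplicates or
#'   self-loops still count toward the budget).
#' @param n_replicates Number of random networks per enrichment test.
#' @param seed Integer master seed; per-replicate seeds are derived from
#'   it deterministically.
#' @return A list of class `rewire_config`.
#' @export
rewire_config <- function(mode = c("locked", "unlocked"), swap_factor = 1.1,
                          n_replicates = 1000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(swap_factor > 0, n_replicates >= 1)
  structure(list(mode = mode, swap_factor = swap_factor,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "rewire_config")
}

# deterministic, platform-stable replicate seed below 2^31
replicate_seed <- function(seed, replicate_index) {
  as.integer((as.double(seed %% 2147483647L) * 69069 +
                as.double(replicate_index) * 1234567) %% 2147483647)
}

# rewire one integer representation in place; returns updated rep.
# locked semantics apply per edge class (classes rewired independently).
rewire_rep <- function(rep, swap_factor, locked) {
  for (cls in c(TRUE, FALSE)) {
    sel <- rep$trans == cls
    m <- sum(sel)
    if (m < 2) next
    n_att <- as.integer(ceiling(swap_factor * m))
    rep$tgt[sel] <- rewire_class_cpp(rep$src[sel], rep$tgt[sel], n_att,
                                     locked)
  }
  rep
}

#' Degree-preserving rewiring of a regulatory network
#'
#' Produces one random network under the null model: transcriptional and
#' posttranscriptional edges are rewired independently (so miRNAs never
#' acquire transcriptional targets), each class receiving
#' `ceiling(swap_factor x class size)` attempted swaps. A swap draws two
#' distinct eligible edges (a->b, c->d) and proposes (a->d, c->b);
#' attempts that would duplicate an edge, leave the pair unchanged, or
#' (in locked mode) create a self-loop are discarded without retry. Every
#' node's in- and out-degree within each edge class is preserved; locked
#' mode additionally preserves the exact self-loop set.
#'
#' @param network A `regnet`.
#' @param config A [rewire_config()].
#' @param replicate_index Replicate number; together with `config$seed`
#'   it determines the RNG stream, so the same (seed, index) pair always
#'   yields the same network.
#' @return A rewired `regnet` with the same node table.
#' @export
rewire <- function(network, config = rewire_config(), replicate_index = 1) {
  stopifnot(inherits(network, "regnet"), inherits(config, "rewire_config"))
  rep <- as_netrep(network)
  for (cls in c(TRUE, FALSE)) {
    m <- sum(rep$trans == cls)
    eligible <- if (config$mode == "locked") {
      sum(rep$trans == cls & rep$src != rep$tgt)
    } else {
      m
    }
    if (m > 0 && eligible < 2) {
      rlang::warn(sprintf(
        "edge class '%s' has fewer than 2 eligible edges; returned unchanged",
        if (cls) "transcriptional" else "posttranscriptional"))
    }
  }
  set.seed(replicate_seed(config$seed, replicate_index))
  rep <- rewire_rep(rep, config$swap_factor, config$mode == "locked")
  netrep_to_regnet(rep, network)
}

#' Count null draws at least as extreme as the observation
#'
#' `r`, the number of random motif counts greater than or equal to the
#' observed count (inclusive).
#'
#' @param observed Observed motif count.
#' @param random_counts Vector of counts from the rewired null networks.
#' @return Integer `r` with `0 <= r <= length(random_counts)`.
#' @export
count_exceeding <- function(observed, random_counts) {
  sum(random_counts >= observed)
}

#' Empirical enrichment p-value
#'
#' `p = (r + 1) / (n + 1)`: the add-one empirical p-value, bounded below
#' by `1/(n+1)`, so 1,000 null networks can at best support `p ~ 0.001`.
#'
#' @param r Number of null draws at least as extreme as observed
#'   ([count_exceeding()]).
#' @param n Number of null draws.
#' @return The p-value as a double.
#' @export
empirical_p <- function(r, n) {
  stopifnot(n >= 1, r >= 0, r <= n)
  (r + 1) / (n + 1)
}

#' Null z-score of an observed motif count
#'
#' `(observed - mean(random_counts)) / sd(random_counts)`, with the
#' sample (n-1) standard deviation. Undefined (with a warning) when the
#' null counts are constant.
#'
#' @inheritParams count_exceeding
#' @return A double, `NA` if the null SD is zero.
#' @export
z_score <- function(observed, random_counts) {
  s <- stats::sd(random_counts)
  if (is.na(s) || s == 0) {
    rlang::warn("null counts have zero variance; z-score undefined")
    return(NA_real_)
  }
  (observed - mean(random_counts)) / s
}

#' Motif enrichment against the rewiring null
#'
#' Counts the motif in the observed network and in `n_replicates`
#' independently rewired networks, then summarises enrichment with the
#' inclusive exceedance count `r`, the empirical p-value
#' `p = (r+1)/(n+1)` and the null z-score. By default M1 uses the
#' unlocked null (self-loops must be free to vary for the autoregulation
#' count to have a null distribution) and M2-M4 use the locked null
#' (their enrichment is assessed conditionally on the autoregulation
#' backbone).
#'
#' @param network A `regnet` (typically the trimmed regulator network).
#' @param motif_type One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param config A [rewire_config()]. When `mode` is not supplied the
#'   motif-specific default above applies.
#' @param m3_allow_autoreg_partner,m4_ordered Counting-convention flags
#'   passed to the motif counter.
#' @return An object of class `motif_enrichment`: motif type, mode,
#'   `observed`, the full `random_counts` vector, `r`, `p`, `z`, the
#'   replicate count and seed.
#' @export
enrichment_test <- function(network, motif_type = c("M1", "M2", "M3", "M4"),
                            config = NULL,
                            m3_allow_autoreg_partner = FALSE,
                            m4_ordered = FALSE) {
  motif_type <- match.arg(motif_type)
  if (is.null(config)) {
    config <- rewire_config(
      mode = if (motif_type == "M1") "unlocked" else "locked")
  }
  stopifnot(inherits(network, "regnet"), inherits(config, "rewire_config"))
  rep0 <- as_netrep(network)
  observed <- count_motif_rep(rep0, motif_type,
                              m3_allow_autoreg_partner, m4_ordered)
  locked <- config$mode == "locked"
  n <- config$n_replicates
  random_counts <- integer(n)
  for (i in seq_len(n)) {
    set.seed(replicate_seed(config$seed, i))
    rep_i <- rewire_rep(rep0, config$swap_factor, locked)
    random_counts[i] <- count_motif_rep(rep_i, motif_type,
                                        m3_allow_autoreg_partner,
                                        m4_ordered)
  }
  r <- count_exceeding(observed, random_counts)
  structure(list(motif_type = motif_type, mode = config$mode,
                 observed = observed, random_counts = random_counts,
                 r = r, p = empirical_p(r, n),
                 z = suppressWarnings(z_score(observed, random_counts)),
                 n_replicates = n, seed = config$seed),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "<motif_enrichment> %s (%s null, n = %d)\n", x$motif_type, x$mode,
    x$n_replicates))
  cat(sprintf("  observed %d | null mean %.2f | r = %d | p = %.4g | z = %.3g\n",
              x$observed, mean(x$random_counts), x$r, x$p, x$z))
  invisible(x)
}

#' @method tidy motif_enrichment
#' @export
tidy.motif_enrichment <- function(x, ...) {
  tibble::tibble(motif_type = x$motif_type, mode = x$mode,
                 observed = x$observed, null_mean = mean(x$random_counts),
                 null_sd = stats::sd(x$random_counts), r = x$r,
                 n_replicates = x$n_replicates, p = x$p, z = x$z)
}

#' @method glance motif_enrichment
#' @export
glance.motif_enrichment <- function(x, ...) tidy(x)
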