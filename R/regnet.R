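#' Construct a regulatory network
#'
#' The central container every pipeline stage exchanges: a node table and a
#' unique weighted edge set. Edges are directed regulator -> target
#' interactions, classed `"transcriptional"` (TF binding at a promoter
#' region) or `"posttranscriptional"` (miRNA targeting a transcript).
#'
#' @param edges A data frame with columns `source_id`, `source_kind`
#'   (`"TF"` or `"miRNA"`), `target_id`, `target_kind` (a biotype:
#'   `"protein_coding"`, `"miRNA"`, `"lincRNA"` or `"other"`),
#'   `edge_class` (`"transcriptional"` or `"posttranscriptional"`) and
#'   `weight` (positive integer count of supporting interactions).
#' @param nodes Optional node table with columns `id`, `kind`
#'   (`"TF"`, `"miRNA"` or `"gene"`) and `biotype`. When omitted it is
#'   derived from the edge endpoints: any transcriptional source is a TF,
#'   any `miRNA`-biotype node is a miRNA, everything else a gene.
#'
#' @return An object of class `regnet`: a list with tibbles `nodes` and
#'   `edges`.
#'
#' @details Invariants enforced at construction: no two edges share
#'   `(source_id, target_id, edge_class)`; `edge_class` is
#'   `"transcriptional"` exactly when `source_kind` is `"TF"`; weights are
#'   `>= 1`; every edge endpoint appears in the node table.
#'
#' @examples
#' edges <- tibble::tibble(
#'   source_id = c("TF1", "TF1", "mir1"),
#'   source_kind = c("TF", "TF", "miRNA"),
#'   target_id = c("TF1", "mir1", "TF1"),
#'   target_kind = c("protein_coding", "miRNA", "protein_coding"),
#'   edge_class = c("transcriptional", "transcriptional", "posttranscriptional"),
#'   weight = c(3L, 2L, 1L)
#' )
#' net <- regulatory_network(edges)
#' net
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("source_id", "source_kind", "target_id", "target_kind",
                "edge_class", "weight")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    rlang::abort(paste0("edge table is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  edges <- edges[required]
  edges$weight <- as.integer(edges$weight)
  if (nrow(edges) > 0) {
    if (any(edges$weight < 1L)) rlang::abort("edge weights must be >= 1")
    bad_class <- xor(edges$source_kind == "TF",
                     edges$edge_class == "transcriptional")
    if (any(bad_class)) {
      rlang::abort(
        "edge_class must be 'transcriptional' iff source_kind is 'TF'")
    }
    key <- paste(edges$source_id, edges$target_id, edges$edge_class,
                 sep = "\r")
    if (anyDuplicated(key) > 0) {
      rlang::abort("duplicate (source_id, target_id, edge_class) edges")
    }
  }
  if (is.null(nodes)) {
    nodes <- derive_nodes(edges)
  } else {
    nodes <- tibble::as_tibble(nodes)[c("id", "kind", "biotype")]
    endpoints <- unique(c(edges$source_id, edges$target_id))
    absent <- setdiff(endpoints, nodes$id)
    if (length(absent) > 0) {
      rlang::abort(paste0("edge endpoints absent from node table: ",
                          paste(utils::head(absent, 5), collapse = ", ")))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

# Node table from edge endpoints. TF status = appears as transcriptional
# source; miRNA status from either endpoint kind/biotype annotation.
derive_nodes <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(id = character(), kind = character(),
                          biotype = character()))
  }
  src <- tibble::tibble(id = edges$source_id,
                        kind = edges$source_kind,
                        biotype = ifelse(edges$source_kind == "miRNA",
                                         "miRNA", "protein_coding"))
  tgt <- tibble::tibble(id = edges$target_id,
                        kind = ifelse(edges$target_kind == "miRNA",
                                      "miRNA", "gene"),
                        biotype = edges$target_kind)
  all <- dplyr::bind_rows(src, tgt)
  # rank kinds so TF > miRNA > gene when a node plays several roles
  all$rank <- match(all$kind, c("TF", "miRNA", "gene"))
  all <- dplyr::arrange(all, .data$id, .data$rank)
  out <- dplyr::distinct(all, .data$id, .keep_all = TRUE)
  # prefer the biotype under which a node appears as a target
  hit <- match(out$id, tgt$id)
  out$biotype <- ifelse(is.na(hit), out$biotype, tgt$biotype[hit])
  dplyr::select(out, "id", "kind", "biotype")
}

#' @export
print.regnet <- function(x, ...) {
  n_trans <- sum(x$edges$edge_class == "transcriptional")
  n_post <- nrow(x$edges) - n_trans
  cat("<regnet> regulatory network\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d TF, %d miRNA, %d other)\n",
              sum(x$nodes$kind == "TF"), sum(x$nodes$kind == "miRNA"),
              sum(!x$nodes$kind %in% c("TF", "miRNA"))))
  cat("  edges:", nrow(x$edges),
      sprintf("(%d transcriptional, %d posttranscriptional)\n",
              n_trans, n_post))
  invisible(x)
}

#' Tidy a regulatory network into its edge table
#'
#' @param x A `regnet` object.
#' @param ... Unused.
#' @return A tibble of edges (one row per unique directed interaction).
#' @method tidy regnet
#' @export
tidy.regnet <- function(x, ...) x$edges

#' One-row summary of a regulatory network
#'
#' @param x A `regnet` object.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts and mean degrees.
#' @method glance regnet
#' @export
glance.regnet <- function(x, ...) {
  trans <- x$edges[x$edges$edge_class == "transcriptional", ]
  post <- x$edges[x$edges$edge_class == "posttranscriptional", ]
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_tf = sum(x$nodes$kind == "TF"),
    n_mirna = sum(x$nodes$kind == "miRNA"),
    n_edges = nrow(x$edges),
    n_transcriptional = nrow(trans),
    n_posttranscriptional = nrow(post),
    n_autoregulatory = sum(trans$source_id == trans$target_id),
    total_weight = sum(x$edges$weight)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ids of nodes acting as transcription factors (transcriptional sources)
tf_ids <- function(network) {
  network$nodes$id[network$nodes$kind == "TF"]
}

mirna_ids <- function(network) {
  network$nodes$id[network$nodes$kind == "miRNA"]
}

#' Restrict a network to regulator-to-regulator edges
#'
#' Keeps exactly the edges whose target is itself a regulator: a TF (a
#' transcriptional source somewhere in the network) or a miRNA. The node
#' table is restricted to endpoints of the retained edges. Feedback motifs
#' live entirely inside this trimmed network, so motif enumeration and the
#' rewiring null operate on it.
#'
#' @param network A `regnet`.
#' @return A trimmed `regnet`. Trimming is idempotent.
#' @export
trim_to_regulators <- function(network) {
  stopifnot(inherits(network, "regnet"))
  regulators <- union(tf_ids(network), mirna_ids(network))
  keep <- network$edges$target_id %in% regulators
  edges <- network$edges[keep, ]
  ids <- unique(c(edges$source_id, edges$target_id))
  nodes <- network$nodes[network$nodes$id %in% ids, ]
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}
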