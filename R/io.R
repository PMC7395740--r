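#' Read TF binding peaks from a BED-dialect file
#'
#' Expects at least five columns: chrom, start, end, name, score, with an
#' optional sixth strand column. Coordinates are BED convention (0-based,
#' half-open) and are kept that way internally. The name field encodes the
#' TF and the dataset (experiment / cell type) as `"TF.dataset"`, split at
#' the first `"."`, mirroring how ReMap-style peak collections carry their
#' metadata. Lines starting with `#` are ignored.
#'
#' @param path Path to the BED file.
#' @param tf,dataset Optional overrides: when supplied, every peak in the
#'   file is labelled with these values and the name field is not parsed.
#' @return A tibble of peaks with columns `chrom`, `start`, `end`,
#'   `strand`, `tf`, `dataset`.
#' @export
read_peaks <- function(path, tf = NULL, dataset = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_peaks())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  need <- if (is.null(tf)) 5L else 3L
  if (any(nfld < need)) {
    bad <- lineno[which(nfld < need)[1]]
    rlang::abort(sprintf("malformed BED line %d in %s: fewer than %d fields",
                         bad, path, need))
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "malformed BED line %d in %s: need 0 <= start < end", lineno[bad[1]],
      path))
  }
  strand <- ifelse(nfld >= 6, vapply(parts, function(p) p[min(6, length(p))],
                                     ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (is.null(tf)) {
    name <- vapply(parts, `[[`, "", 4)
    no_dot <- !grepl(".", name, fixed = TRUE)
    if (any(no_dot)) {
      rlang::abort(sprintf(
        "malformed BED line %d in %s: name field is not 'TF.dataset'",
        lineno[which(no_dot)[1]], path))
    }
    tf <- sub("\\..*$", "", name)
    dataset <- sub("^[^.]*\\.", "", name)
  } else {
    tf <- rep(tf, length(lines))
    dataset <- rep(dataset %||% "dataset1", length(lines))
  }
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 tf = tf, dataset = dataset)
}

empty_peaks <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), tf = character(),
                 dataset = character())
}

#' Read a set of peak files listed in a sidecar table
#'
#' The sidecar is a TSV with header `tf`, `dataset`, `file` (paths relative
#' to the sidecar's directory), for peak collections whose BED name fields
#' do not encode the metadata.
#'
#' @param sidecar_path Path to the sidecar TSV.
#' @return A tibble of peaks, as [read_peaks()].
#' @export
read_peak_set <- function(sidecar_path) {
  map <- readr::read_tsv(sidecar_path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("tf", "dataset", "file") %in% names(map)))
  base <- dirname(sidecar_path)
  purrr::pmap_dfr(map, function(tf, dataset, file, ...) {
    read_peaks(file.path(base, file), tf = tf, dataset = dataset)
  })
}

#' Read genomic intervals from a plain BED file
#'
#' Used for cis-regulatory modules and candidate regulatory elements.
#' Columns beyond the third are optional; a fourth column is returned as
#' `name` when present.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and (if present)
#'   `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    bad <- lineno[which(lengths(parts) < 3)[1]]
    rlang::abort(sprintf("malformed BED line %d in %s", bad, path))
  }
  out <- tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.integer(vapply(parts, `[[`, "", 2)),
    end = as.integer(vapply(parts, `[[`, "", 3))
  )
  if (any(is.na(out$start) | is.na(out$end) | out$start >= out$end)) {
    bad <- lineno[which(is.na(out$start) | is.na(out$end) |
                          out$start >= out$end)[1]]
    rlang::abort(sprintf("malformed BED line %d in %s: need start < end",
                         bad, path))
  }
  if (all(lengths(parts) >= 4)) out$name <- vapply(parts, `[[`, "", 4)
  out
}

gene_biotypes <- c("protein_coding", "miRNA", "lincRNA", "other")

#' Read a gene annotation table
#'
#' A TSV with header `gene_id`, `name`, `biotype`, `chrom`, `strand`,
#' `tss`, `tx_starts`, `tx_ends`. `tss`, `tx_starts` and `tx_ends` are
#' comma-separated integer lists (0-based; transcript spans half-open).
#' Accepted biotypes are `protein_coding`, `miRNA`, `lincRNA`, `other`.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per gene; `tss`, `tx_starts`, `tx_ends`
#'   become integer list-columns.
#' @export
read_gene_annotation <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("gene_id", "name", "biotype", "chrom", "strand", "tss",
                "tx_starts", "tx_ends")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0("gene annotation is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$biotype), gene_biotypes)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown biotype(s): ", paste(bad, collapse = ", "),
      "; accepted values are: ", paste(gene_biotypes, collapse = ", ")))
  }
  if (any(is.na(tab$tss) | !nzchar(tab$tss))) {
    rlang::abort("gene annotation rows with empty tss column")
  }
  split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(trimws(v)))
  tibble::tibble(
    gene_id = tab$gene_id, name = tab$name, biotype = tab$biotype,
    chrom = tab$chrom, strand = tab$strand,
    tss = split_ints(tab$tss),
    tx_starts = split_ints(tab$tx_starts),
    tx_ends = split_ints(tab$tx_ends)
  )
}

#' Write a gene annotation table
#'
#' Inverse of [read_gene_annotation()].
#' @param genes Gene tibble with list-columns `tss`, `tx_starts`, `tx_ends`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  flat <- function(col) vapply(col, function(v) paste(v, collapse = ","), "")
  out <- tibble::tibble(
    gene_id = genes$gene_id, name = genes$name, biotype = genes$biotype,
    chrom = genes$chrom, strand = genes$strand,
    tss = flat(genes$tss), tx_starts = flat(genes$tx_starts),
    tx_ends = flat(genes$tx_ends)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read microRNA loci from a miRBase-style GFF3 file
#'
#' Keeps `miRNA_primary_transcript` features. GFF3 coordinates are 1-based
#' inclusive and are converted to the package-internal 0-based half-open
#' convention on read.
#'
#' @param path Path to the GFF3 file.
#' @return A tibble with columns `mirna_id` (the `ID` attribute, falling
#'   back to `Name`), `chrom`, `start`, `end`, `strand`.
#' @export
read_mirna_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(mirna_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9)) {
    rlang::abort(sprintf("malformed GFF3 record in %s", path))
  }
  type <- vapply(parts, `[[`, "", 3)
  parts <- parts[type == "miRNA_primary_transcript"]
  attr_field <- vapply(parts, `[[`, "", 9)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  }
  id <- get_attr(attr_field, "ID")
  nm <- get_attr(attr_field, "Name")
  id <- ifelse(is.na(id), nm, id)
  if (anyNA(id)) rlang::abort("GFF3 miRNA record without ID or Name attribute")
  tibble::tibble(
    mirna_id = id,
    chrom = vapply(parts, `[[`, "", 1),
    start = as.integer(vapply(parts, `[[`, "", 4)) - 1L,
    end = as.integer(vapply(parts, `[[`, "", 5)),
    strand = vapply(parts, `[[`, "", 7)
  )
}

#' Write microRNA loci as miRBase-style GFF3
#'
#' Inverse of [read_mirna_gff()]; internal 0-based half-open coordinates
#' are converted back to 1-based inclusive GFF3 on write, so a read/write
#' round trip reproduces the input coordinates.
#'
#' @param mirnas Tibble with `mirna_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff <- function(mirnas, path) {
  header <- "##gff-version 3"
  body <- sprintf(
    "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    mirnas$chrom, mirnas$start + 1L, mirnas$end, mirnas$strand,
    mirnas$mirna_id, mirnas$mirna_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a microRNA -> target gene table
#'
#' A TSV whose first two columns are `mirna_id` and `target_gene_id`
#' (miRTarBase-like). Duplicate (miRNA, target) rows are collapsed and
#' their multiplicity kept as the edge weight.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `mirna_id`, `target_gene_id`, `weight`.
#' @export
read_mirna_targets <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(tab) < 2) rlang::abort("miRNA target table needs >= 2 columns")
  names(tab)[1:2] <- c("mirna_id", "target_gene_id")
  tab |>
    dplyr::count(.data$mirna_id, .data$target_gene_id, name = "weight") |>
    dplyr::mutate(weight = as.integer(.data$weight))
}

#' Read a dataset -> tissue mapping table
#'
#' @param path TSV with header columns `dataset` and `tissue`.
#' @return A tibble with those two columns.
#' @export
read_tissue_map <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  stopifnot(all(c("dataset", "tissue") %in% names(tab)))
  dplyr::distinct(tab[, c("dataset", "tissue")])
}

#' Write / read the canonical edge-list exchange format
#'
#' A TSV with header `source_id`, `source_kind`, `target_id`,
#' `target_kind`, `edge_class`, `weight`: the artifact every pipeline
#' stage exchanges. `read_edge_list(write_edge_list(net))` reproduces the
#' edge set, weights, and the node table derivable from the edges.
#'
#' @param network A `regnet`.
#' @param path File path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a `regnet`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regnet"))
  readr::write_tsv(network$edges, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(weight = "i", .default = "c"))
  key <- paste(tab$source_id, tab$target_id, tab$edge_class)
  if (anyDuplicated(key) > 0) {
    rlang::abort("duplicate (source, target, edge_class) rows in edge list")
  }
  regulatory_network(tab)
}
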