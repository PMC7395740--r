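# Interval overlap helpers. All package coordinates are 0-based half-open
# (BED convention); IRanges is 1-based closed, hence the +1 shifts.

# logical: does each query interval overlap >= 1 subject interval (>= 1 bp,
# same chromosome)?
overlaps_any_interval <- function(query, subject) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L,
                          end = subject$end[si])
    out[qi] <- IRanges::overlapsAny(q, s)
  }
  out
}

# all (query_row, subject_row) pairs with >= 1 bp overlap on a shared
# chromosome; query/subject are tibbles with chrom/start/end (half-open)
overlap_pairs <- function(query, subject) {
  res <- list()
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(si) == 0) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L,
                          end = subject$end[si])
    hits <- IRanges::findOverlaps(q, s)
    res[[ch]] <- tibble::tibble(
      query_row = qi[S4Vectors::queryHits(hits)],
      subject_row = si[S4Vectors::subjectHits(hits)])
  }
  if (length(res) == 0) {
    return(tibble::tibble(query_row = integer(), subject_row = integer()))
  }
  dplyr::bind_rows(res)
}
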