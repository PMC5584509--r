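#' Genomic interval conventions
#'
#' All tables in mirforge locate features with the columns `contig`,
#' `start`, `end` and (where stranded) `strand`, using 0-based half-open
#' coordinates. GFF3 files are written and read 1-based inclusive;
#' BED files are 0-based half-open, matching the internal convention.
#'
#' @name interval-conventions
NULL

# Edge gap between two half-open intervals on the same contig.
# Negative values mean overlap.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) - pmin(end1, end2)
}

#' Chain intervals into single-linkage groups along each contig
#'
#' Adds a `chain` column grouping rows whose edge gap to the running
#' group span satisfies the chaining rule. Used both for overlap
#' de-duplication (gap strictly below the window) and for genomic
#' cluster calling (gap up to and including the maximum distance).
#'
#' @param x data frame with `contig`, `start`, `end` columns.
#' @param max_gap chaining distance in nt.
#' @param inclusive if `TRUE`, rows join when gap <= max_gap; if
#'   `FALSE`, when gap < max_gap. Overlapping rows always join.
#' @param by additional grouping columns (e.g. `"strand"`).
#' @return the input with a `chain` integer column, sorted by
#'   `contig`, `start`, `end`.
#' @keywords internal
chain_intervals <- function(x, max_gap, inclusive = TRUE, by = character()) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) == 0) {
    return(mutate(x, chain = integer()))
  }
  x <- arrange(x, !!!rlang::syms(c("contig", by, "start", "end")))
  key <- do.call(paste, c(x[c("contig", by)], sep = "\r"))
  chain <- integer(nrow(x))
  cur <- 0L
  run_end <- -Inf
  prev_key <- NA_character_
  for (i in seq_len(nrow(x))) {
    gap <- x$start[i] - run_end
    new_chain <- !identical(key[i], prev_key) ||
      (if (inclusive) gap > max_gap else gap >= max_gap)
    if (new_chain) {
      cur <- cur + 1L
      run_end <- x$end[i]
    } else {
      run_end <- max(run_end, x$end[i])
    }
    chain[i] <- cur
    prev_key <- key[i]
  }
  mutate(x, chain = chain)
}

# TRUE where interval a overlaps any interval in b (same contig,
# optionally same strand). Vectorised over a.
overlaps_any <- function(a, b, same_strand = FALSE) {
  if (nrow(b) == 0 || nrow(a) == 0) {
    return(rep(FALSE, nrow(a)))
  }
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    hit <- b$contig == a$contig[i] &
      b$start < a$end[i] & a$start[i] < b$end
    if (same_strand && "strand" %in% names(a) && "strand" %in% names(b)) {
      hit <- hit & b$strand == a$strand[i]
    }
    out[i] <- any(hit)
  }
  out
}
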