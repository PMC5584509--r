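#' Build rectangular read blocks from collapsed alignments
#'
#' Groups collapsed reads on one contig and strand into blocks by
#' overlap chaining: reads whose intervals overlap, touch, or lie
#' within `merge_gap` nt of the running block span join the block.
#' Each block records its interval span, total read count (`height`),
#' the most frequent read 5' position (`mode_start`; count-weighted,
#' ties to the smallest coordinate) and `sharpness`, the fraction of
#' reads whose 5' end lies within +/-2 nt of `mode_start`. Blocks with
#' `height < min_block_reads` are dropped; blocks are returned sorted
#' by start.
#'
#' @param alignments tibble with `start`, `end`, `count` (and
#'   optionally a single-valued `contig`) for one contig/strand.
#' @param min_block_reads minimum total count for a block to be kept.
#' @param merge_gap maximum gap in nt joining reads into one block.
#' @param strand `"+"` or `"-"`; determines which interval edge is the
#'   read 5' end.
#' @return tibble of blocks: `start`, `end`, `height`, `mode_start`,
#'   `sharpness` (plus `contig`/`strand` when supplied).
#' @export
#' @examples
#' reads <- tibble::tibble(start = rep(100, 3), end = rep(122, 3),
#'                         count = c(10, 10, 10))
#' build_blocks(reads)
build_blocks <- function(alignments, min_block_reads = 1, merge_gap = 0,
                         strand = NULL) {
  if ("contig" %in% names(alignments) &&
      length(unique(alignments$contig)) > 1) {
    abort("build_blocks: alignments span more than one contig")
  }
  if (is.null(strand)) {
    strand <- if ("strand" %in% names(alignments) && nrow(alignments) > 0) {
      unique(alignments$strand)
    } else {
      "+"
    }
  }
  if (length(strand) > 1) {
    abort("build_blocks: alignments span more than one strand")
  }
  empty <- tibble(start = integer(), end = integer(), height = integer(),
                  mode_start = integer(), sharpness = numeric())
  if (nrow(alignments) == 0) {
    return(empty)
  }
  x <- alignments |>
    transmute(contig = "x", start = as.integer(.data$start),
              end = as.integer(.data$end),
              count = as.integer(.data$count)) |>
    chain_intervals(max_gap = merge_gap, inclusive = TRUE)
  x$p5 <- if (strand == "-") x$end else x$start
  blocks <- x |>
    group_by(.data$chain) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      height = sum(.data$count),
      mode_start = {
        tab <- tapply(.data$count, .data$p5, sum)
        as.integer(names(tab)[order(-tab, as.integer(names(tab)))[1]])
      },
      sharpness = {
        tab <- tapply(.data$count, .data$p5, sum)
        md <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))[1]])
        sum(.data$count[abs(.data$p5 - md) <= 2]) / sum(.data$count)
      },
      .groups = "drop"
    ) |>
    filter(.data$height >= min_block_reads) |>
    arrange(.data$start) |>
    select(-"chain")
  extras <- intersect(c("contig", "strand"), names(alignments))
  for (col in extras) {
    if (nrow(alignments) > 0) {
      blocks[[col]] <- unique(alignments[[col]])[1]
    }
  }
  blocks
}
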