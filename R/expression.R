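#' Read-profile over a candidate locus
#'
#' Restricts a library's collapsed alignments to the locus plus a
#' flank, computes per-position coverage and read blocks
#' (strand-aware), and totals the read counts. Reads on the opposite
#' strand or outside the window are excluded.
#'
#' @param locus one-row tibble (or list) with `contig`, `start`,
#'   `end`, `strand` and an id column (`id` or `locus_id`).
#' @param alignments tibble of collapsed reads (`contig`, `start`,
#'   `end`, `count`, `strand`).
#' @param flank nt added on each side of the locus.
#' @param min_block_reads passed to [build_blocks()].
#' @return a `mirforge_profile` list: `locus_id`, `window`
#'   (start/end), `coverage` (integer vector over the window),
#'   `blocks`, `total_reads`, plus the locus coordinates.
#' @export
profile_locus <- function(locus, alignments, flank = 20,
                          min_block_reads = 1) {
  locus <- as.list(locus)
  lid <- locus$id %||% locus$locus_id %||% NA_character_
  win_s <- locus$start - flank
  win_e <- locus$end + flank
  sel <- alignments |>
    filter(.data$contig == locus$contig,
           .data$strand == locus$strand,
           .data$start < win_e, .data$end > win_s)
  cov <- integer(win_e - win_s)
  if (nrow(sel) > 0) {
    for (i in seq_len(nrow(sel))) {
      a <- max(sel$start[i], win_s) - win_s + 1L
      b <- min(sel$end[i], win_e) - win_s
      cov[a:b] <- cov[a:b] + sel$count[i]
    }
  }
  blocks <- build_blocks(select(sel, -any_of("name")),
                         min_block_reads = min_block_reads,
                         strand = locus$strand)
  structure(
    list(
      locus_id = lid, contig = locus$contig,
      locus_start = locus$start, locus_end = locus$end,
      strand = locus$strand,
      window = c(start = win_s, end = win_e),
      flank = flank,
      coverage = cov,
      blocks = blocks,
      total_reads = sum(sel$count)
    ),
    class = "mirforge_profile"
  )
}

#' @export
print.mirforge_profile <- function(x, ...) {
  cat(sprintf(
    "<mirforge_profile> %s %s:%d-%d(%s) reads=%d blocks=%d\n",
    x$locus_id, x$contig, x$locus_start, x$locus_end, x$strand,
    x$total_reads, nrow(x$blocks)
  ))
  invisible(x)
}

#' Classify a read profile as verified miRNA expression or not
#'
#' Formalises the curation rule for miRNA read profiles: a locus is
#' verified when its reads form one or two rectangular (sharp) blocks
#' over the mature arms inside the precursor, separated by a gap
#' essentially devoid of reads, with negligible coverage on the
#' flanks; continuous coverage extending beyond the precursor
#' (degradation products) is rejected. All thresholds except
#' `min_reads` are fractions of observed heights, making the verdict
#' invariant to overall sequencing depth.
#'
#' @param profile a [profile_locus()] result.
#' @param min_reads below this total the verdict is `no_expression`.
#' @param min_sharpness minimum block sharpness counted as a mature
#'   arm.
#' @param max_gap_coverage_fraction maximum inter-block coverage as a
#'   fraction of the smaller block's peak coverage.
#' @param max_flank_coverage_fraction maximum flank coverage as a
#'   fraction of the peak coverage.
#' @param max_blocks more blocks than this is diffuse.
#' @param flank_guard nt adjacent to the precursor excluded from the
#'   flank-coverage measurement (tolerates the natural +/-2 nt wobble
#'   of mature 5' ends across an edge-positioned arm).
#' @return a `mirforge_verdict` list: `verdict` in `verified`,
#'   `rejected_extended`, `rejected_diffuse`, `no_expression`;
#'   `mature5p`/`mature3p` intervals (or `NULL`); `gap_ok`.
#' @export
classify_profile <- function(profile, min_reads = 5, min_sharpness = 0.6,
                             max_gap_coverage_fraction = 0.1,
                             max_flank_coverage_fraction = 0.1,
                             max_blocks = 2, flank_guard = 5) {
  vd <- function(verdict, m5 = NULL, m3 = NULL, gap_ok = NA) {
    structure(list(locus_id = profile$locus_id, verdict = verdict,
                   mature5p = m5, mature3p = m3, gap_ok = gap_ok),
              class = "mirforge_verdict")
  }
  if (profile$total_reads < min_reads) {
    return(vd("no_expression"))
  }
  cov <- profile$coverage
  win_s <- profile$window[["start"]]
  n <- length(cov)
  guarded_idx <- seq(max(1L, profile$locus_start - win_s + 1L - flank_guard),
                     min(n, profile$locus_end - win_s + flank_guard))
  flank_idx <- setdiff(seq_len(n), guarded_idx)
  peak <- max(cov)
  if (max(cov[flank_idx], 0) > max_flank_coverage_fraction * peak) {
    return(vd("rejected_extended"))
  }
  blocks <- profile$blocks
  if (nrow(blocks) > max_blocks) {
    return(vd("rejected_diffuse"))
  }
  sharp <- filter(blocks, .data$sharpness >= min_sharpness)
  if (nrow(sharp) == 0) {
    return(vd("rejected_diffuse"))
  }
  # clip arms to precursor bounds
  sharp <- sharp |>
    mutate(start = pmax(.data$start, profile$locus_start),
           end = pmin(.data$end, profile$locus_end)) |>
    arrange(.data$start)
  gap_ok <- TRUE
  if (nrow(sharp) == 2) {
    gap_idx <- if (sharp$start[2] > sharp$end[1]) {
      seq(sharp$end[1] - win_s + 1L, sharp$start[2] - win_s)
    } else {
      integer(0)
    }
    peaks <- vapply(seq_len(2), function(i) {
      max(cov[seq(sharp$start[i] - win_s + 1L, sharp$end[i] - win_s)])
    }, numeric(1))
    gap_cov <- if (length(gap_idx) == 0) 0 else max(cov[gap_idx])
    gap_ok <- gap_cov <= max_gap_coverage_fraction * min(peaks)
    if (!gap_ok) {
      return(vd("rejected_diffuse", gap_ok = FALSE))
    }
  }
  # orient arms: the block nearer the transcript 5' end is the 5p arm
  arms <- if (profile$strand == "-") {
    sharp[rev(seq_len(nrow(sharp))), ]
  } else {
    sharp
  }
  m5 <- c(start = arms$start[1], end = arms$end[1])
  m3 <- if (nrow(arms) == 2) {
    c(start = arms$start[2], end = arms$end[2])
  } else {
    NULL
  }
  vd("verified", m5 = m5, m3 = m3, gap_ok = gap_ok)
}

#' @export
print.mirforge_verdict <- function(x, ...) {
  cat(sprintf("<mirforge_verdict> %s: %s\n", x$locus_id, x$verdict))
  invisible(x)
}

#' Expression calls across libraries
#'
#' A locus is expressed in a library when its profile totals at least
#' `min_reads`; it is expressed overall when any library qualifies.
#'
#' @param locus one-row locus tibble (id used for reporting).
#' @param profiles list of [profile_locus()] results, one per library.
#' @param min_reads per-library read threshold.
#' @return list with `per_library` tibble (`library`, `total_reads`,
#'   `expressed`) and `expressed_any` flag.
#' @export
call_expressed <- function(locus, profiles, min_reads = 5) {
  if (length(profiles) == 0) {
    abort("call_expressed: at least one library profile required")
  }
  tab <- tibble(
    library = names(profiles) %||% sprintf("lib%02d", seq_along(profiles)),
    total_reads = unname(vapply(profiles, function(p) p$total_reads,
                                numeric(1))),
    expressed = unname(vapply(profiles, function(p) {
      p$total_reads >= min_reads
    }, logical(1)))
  )
  list(per_library = tab, expressed_any = any(tab$expressed))
}

#' Coverage plot of a locus read profile
#'
#' @param object a `mirforge_profile`.
#' @param ... unused.
#' @return a ggplot: per-position coverage bars with the precursor
#'   bounds marked.
#' @export
autoplot.mirforge_profile <- function(object, ...) {
  df <- tibble(
    pos = seq(object$window[["start"]], object$window[["end"]] - 1L),
    coverage = object$coverage
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$locus_start,
                                       object$locus_end),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("%s position", object$contig),
      y = "aligned reads",
      title = sprintf("%s (%s strand)", object$locus_id, object$strand)
    ) +
    ggplot2::theme_minimal()
}
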