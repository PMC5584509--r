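#' Trim small-RNA reads: adapter removal, quality clipping, length filter
#'
#' Removes the 3' sequencing adapter at its leftmost occurrence (one
#' mismatch allowed per 10 adapter bases; a terminal match to an
#' adapter prefix of at least 8 nt is also trimmed), hard-clips bases
#' from both read ends until the terminal base qualities reach
#' `min_quality` (Phred+33), and discards reads shorter than
#' `min_length`. The adapter/quality passes iterate to a fixed point,
#' which makes the operation idempotent.
#'
#' @param reads tibble with `id`, `sequence`, `quality` columns (as
#'   from [read_fastq()]).
#' @param adapter 3' adapter sequence (default: TruSeq small-RNA RA3).
#' @param min_quality minimum terminal base quality kept.
#' @param min_length minimum surviving read length in nt.
#' @return tibble of surviving reads with class `mirforge_trimmed`;
#'   summary counts (input, adapter-trimmed, quality-clipped,
#'   discarded short, kept) are attached as the `summary` attribute and
#'   available via [glance()].
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   id = "r1",
#'   sequence = paste0(strrep("ACGT", 8), "TGGAATTCTCGGGTGCCAAGG"),
#'   quality = strrep("I", 53)
#' )
#' trim_reads(reads)
trim_reads <- function(reads,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       min_quality = 20,
                       min_length = 15) {
  if (!all(c("id", "sequence", "quality") %in% names(reads))) {
    abort("trim_reads: reads need id, sequence, quality columns")
  }
  if (!nzchar(adapter)) {
    abort("trim_reads: adapter must be non-empty")
  }
  if (min_length < 1) {
    abort("trim_reads: min_length must be >= 1")
  }
  adapter <- normalize_dna(adapter)
  n_in <- nrow(reads)
  seqs <- normalize_dna(reads$sequence)
  quals <- reads$quality
  adapter_hit <- logical(n_in)
  qual_clipped <- logical(n_in)

  repeat {
    changed <- FALSE
    # adapter: leftmost internal occurrence (mismatch-tolerant) or a
    # >=8 nt adapter prefix at the read 3' end
    pos <- adapter_cut_pos(seqs, adapter)
    hit <- !is.na(pos)
    if (any(hit)) {
      adapter_hit <- adapter_hit | hit
      seqs[hit] <- substr(seqs[hit], 1, pos[hit] - 1)
      quals[hit] <- substr(quals[hit], 1, pos[hit] - 1)
      changed <- TRUE
    }
    # hard quality clip at both ends
    clip <- quality_clip(quals, min_quality)
    did_clip <- clip$from > 1 | clip$to < nchar(quals)
    if (any(did_clip)) {
      qual_clipped <- qual_clipped | did_clip
      seqs <- substr(seqs, clip$from, clip$to)
      quals <- substr(quals, clip$from, clip$to)
      changed <- TRUE
    }
    if (!changed) break
  }

  keep <- nchar(seqs) >= min_length
  out <- tibble(id = reads$id[keep], sequence = seqs[keep],
                quality = quals[keep])
  attr(out, "summary") <- tibble(
    n_input = n_in,
    n_adapter_trimmed = sum(adapter_hit),
    n_quality_clipped = sum(qual_clipped),
    n_too_short = sum(!keep),
    n_kept = sum(keep)
  )
  class(out) <- c("mirforge_trimmed", class(out))
  out
}

# leftmost cut position (1-based; NA if no adapter found) for each read
adapter_cut_pos <- function(seqs, adapter) {
  n <- length(seqs)
  if (n == 0) {
    return(integer(0))
  }
  max_mm <- nchar(adapter) %/% 10
  # internal occurrences only make sense in reads at least as long as
  # the adapter; shorter reads go through the terminal-prefix branch
  searchable <- nchar(seqs) >= nchar(adapter)
  subj <- Biostrings::DNAStringSet(ifelse(searchable, seqs, "N"))
  m <- Biostrings::vmatchPattern(adapter, subj, max.mismatch = max_mm)
  pos <- vapply(as.list(m), function(ir) {
    if (length(ir) == 0) NA_integer_ else min(IRanges::start(ir))
  }, integer(1))
  # terminal prefix match: longest adapter prefix (>=8 nt) at read end
  need <- is.na(pos)
  len <- nchar(seqs)
  max_k <- min(nchar(adapter) - 1, max(len, 0))
  if (any(need) && max_k >= 8) {
    for (k in seq(max_k, 8)) {
      idx <- which(need & len >= k)
      if (length(idx) == 0) next
      tailseq <- substr(seqs[idx], len[idx] - k + 1, len[idx])
      mm_allow <- k %/% 10
      nmm <- vapply(tailseq, function(a) {
        sum(utf8ToInt(a) != utf8ToInt(substr(adapter, 1, k)))
      }, numeric(1))
      ok <- nmm <= mm_allow
      pos[idx[ok]] <- len[idx[ok]] - k + 1L
      need <- is.na(pos)
      if (!any(need)) break
    }
  }
  pos
}

# first/last retained positions after hard quality clipping (Phred+33)
quality_clip <- function(quals, min_quality) {
  from <- integer(length(quals))
  to <- integer(length(quals))
  for (i in seq_along(quals)) {
    q <- utf8ToInt(quals[i]) - 33L
    n <- length(q)
    a <- 1L
    while (a <= n && q[a] < min_quality) a <- a + 1L
    b <- n
    while (b >= a && q[b] < min_quality) b <- b - 1L
    if (a > b) {
      from[i] <- 1L
      to[i] <- 0L
    } else {
      from[i] <- a
      to[i] <- b
    }
  }
  list(from = from, to = to)
}

#' @export
glance.mirforge_trimmed <- function(x, ...) {
  attr(x, "summary")
}
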