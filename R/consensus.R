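#' Re-anchor candidate hairpins by gap-free genome matching
#'
#' Each candidate's hairpin sequence is located in the genome without
#' gaps (up to `max_mismatch` substitutions, both strands). Candidates
#' whose sequence has no gap-free placement are dropped with reason
#' `"no gap-free placement"`. When several placements exist, the
#' originally reported interval wins if it is among them; otherwise the
#' leftmost placement (contig order, then start, `+` before `-`) is
#' taken.
#'
#' @param candidates tibble with `id`, `contig`, `start`, `end`,
#'   `strand`, `hairpin_sequence` (plus any other columns, preserved).
#' @param genome named character vector of contig sequences.
#' @param max_mismatch substitutions tolerated in a placement.
#' @return list with `anchored` (candidates with possibly updated
#'   coordinates) and `dropped` (tibble of removed candidates with a
#'   `reason` column).
#' @export
anchor_gap_free <- function(candidates, genome, max_mismatch = 1) {
  missing <- setdiff(unique(candidates$contig), names(genome))
  if (length(missing) > 0) {
    abort(paste0("anchor_gap_free: contig(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(candidates) == 0) {
    return(list(anchored = candidates,
                dropped = mutate(candidates, reason = character())))
  }
  subjects <- lapply(genome, Biostrings::DNAString)
  hit_cache <- new.env(parent = emptyenv())
  placements_for <- function(seqchr) {
    key <- seqchr
    if (!is.null(hit_cache[[key]])) {
      return(hit_cache[[key]])
    }
    pat <- Biostrings::DNAString(seqchr)
    rc <- Biostrings::reverseComplement(pat)
    hits <- list()
    # exact placements first (fast path); only fall back to the
    # mismatch-tolerant scan when the sequence is nowhere verbatim
    for (mm in unique(c(0, max_mismatch))) {
      for (ct in names(subjects)) {
        for (std in c("+", "-")) {
          p <- if (std == "+") pat else rc
          m <- Biostrings::matchPattern(p, subjects[[ct]],
                                        max.mismatch = mm,
                                        with.indels = FALSE)
          if (length(m) > 0) {
            hits[[length(hits) + 1]] <- tibble(
              contig = ct,
              start = Biostrings::start(m) - 1L,
              end = Biostrings::end(m),
              strand = std
            )
          }
        }
      }
      if (length(hits) > 0) break
    }
    res <- if (length(hits) == 0) {
      tibble(contig = character(), start = integer(),
             end = integer(), strand = character())
    } else {
      bind_rows(hits) |>
        arrange(match(.data$contig, names(genome)), .data$start,
                .data$strand)
    }
    hit_cache[[key]] <- res
    res
  }
  keep_rows <- list()
  drop_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    # fast path: an exact match at the stated interval is a gap-free
    # placement, and the tie rule keeps the original interval anyway
    stated <- extract_genome_seq(genome, cand$contig, cand$start,
                                 cand$end, cand$strand)
    if (identical(normalize_dna(cand$hairpin_sequence),
                  normalize_dna(stated))) {
      keep_rows[[length(keep_rows) + 1]] <- cand
      next
    }
    pl <- placements_for(normalize_dna(cand$hairpin_sequence))
    if (nrow(pl) == 0) {
      drop_rows[[length(drop_rows) + 1]] <-
        mutate(cand, reason = "no gap-free placement")
      next
    }
    same <- pl$contig == cand$contig & pl$start == cand$start &
      pl$end == cand$end & pl$strand == cand$strand
    chosen <- if (any(same)) which(same)[1] else 1L
    cand$contig <- pl$contig[chosen]
    cand$start <- pl$start[chosen]
    cand$end <- pl$end[chosen]
    cand$strand <- pl$strand[chosen]
    keep_rows[[length(keep_rows) + 1]] <- cand
  }
  list(
    anchored = if (length(keep_rows)) bind_rows(keep_rows)
               else candidates[0, ],
    dropped = if (length(drop_rows)) bind_rows(drop_rows)
              else mutate(candidates[0, ], reason = character())
  )
}

#' Filter homology hits by span, gaps and significance
#'
#' Keeps hits covering at least `min_span_fraction` of the query
#' reference sequence (boundary inclusive) with no more than
#' `max_gaps` gaps and significance strictly below
#' `significance_cutoff`; per (candidate, reference) pair only the
#' most significant hit is retained.
#'
#' @param hits tibble with `candidate_id`, `reference_id`,
#'   `query_length`, `aligned_span`, `mismatches`, `gaps`,
#'   `significance`.
#' @param min_span_fraction minimum aligned_span/query_length.
#' @param max_gaps maximum gaps allowed.
#' @param significance_cutoff strict upper bound on significance.
#' @return tibble of accepted hits.
#' @export
filter_homology_hits <- function(hits, min_span_fraction = 0.9,
                                 max_gaps = 0,
                                 significance_cutoff = 1e-7) {
  if (any(hits$aligned_span > hits$query_length)) {
    abort("filter_homology_hits: aligned_span exceeds query_length")
  }
  hits |>
    filter(
      .data$aligned_span / .data$query_length >= min_span_fraction,
      .data$gaps <= max_gaps,
      .data$significance < significance_cutoff
    ) |>
    group_by(.data$candidate_id, .data$reference_id) |>
    slice_min(.data$significance, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Reliability filter: homology rescue or score threshold
#'
#' A candidate is kept if it has a reference hit with at most
#' `max_mismatch` mismatches, or if its score reaches
#' `score_threshold` (inclusive). When `score_tools` is given, only
#' candidates from those tools are subject to the score rule;
#' candidates from other tools pass with reason
#' `"not subject to score rule"` (conservation-based predictions are
#' themselves homology evidence).
#'
#' @param candidates tibble with `id`, `tool`, `score`.
#' @param reference_hits tibble with `candidate_id`, `mismatches`
#'   (e.g. mismatch-tolerant matches against a reference mature set).
#' @param score_threshold minimum score (inclusive) for score rescue.
#' @param max_mismatch maximum mismatches for a rescuing homology hit.
#' @param score_tools tools whose candidates are subject to the score
#'   rule (`NULL`: all).
#' @return list with `kept` and `dropped` tibbles; both carry a
#'   `reason` column.
#' @export
reliability_filter <- function(candidates, reference_hits,
                               score_threshold = 7, max_mismatch = 1,
                               score_tools = NULL) {
  rescued_ids <- unique(
    reference_hits$candidate_id[reference_hits$mismatches <= max_mismatch]
  )
  x <- candidates |>
    mutate(
      has_hit = .data$id %in% rescued_ids,
      subject = if (is.null(score_tools)) TRUE else .data$tool %in% score_tools,
      keep = .data$has_hit | !.data$subject | .data$score >= score_threshold,
      reason = case_when(
        .data$has_hit ~ "reference hit (<=1 mismatch)",
        !.data$subject ~ "not subject to score rule",
        .data$score >= score_threshold ~
          sprintf("score >= %s", format(score_threshold)),
        TRUE ~ sprintf("no reference hit and score < %s",
                       format(score_threshold))
      )
    )
  list(
    kept = select(filter(x, .data$keep), -"has_hit", -"subject", -"keep"),
    dropped = select(filter(x, !.data$keep), -"has_hit", -"subject", -"keep")
  )
}

#' Remove overlapping hairpin loci, keeping the best-scoring candidate
#'
#' Candidates on one contig whose intervals overlap or whose edge gap
#' is strictly below `window` nt are grouped by single linkage
#' (strand-blind: opposite-strand hairpins at one locus are the same
#' physical locus). Within each group the highest-scoring candidate
#' survives as the merged locus; ties go to the interval emitted by
#' the most tools in the group, then to the leftmost start. The union
#' of supporting tools and the group size are recorded.
#'
#' @param candidates anchored, scored candidate tibble (`id`,
#'   `contig`, `start`, `end`, `strand`, `tool`, `score`).
#' @param window merge window in nt ("within 100 nt").
#' @return tibble of merged loci with `supporting_tools`
#'   (comma-separated), `n_tools`, `best_score`, `members`
#'   (comma-separated candidate ids) and the group's union span
#'   (`span_start`, `span_end`).
#' @export
deduplicate_overlaps <- function(candidates, window = 100) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, supporting_tools = character(),
                  n_tools = integer(), best_score = numeric(),
                  members = character(), span_start = integer(),
                  span_end = integer()))
  }
  x <- chain_intervals(candidates, max_gap = window, inclusive = FALSE)
  x |>
    group_by(.data$contig, .data$chain) |>
    group_modify(function(g, key) {
      top <- g[g$score == max(g$score), , drop = FALSE]
      if (nrow(top) > 1) {
        iv_key <- paste(g$start, g$end)
        tools_per_iv <- tapply(g$tool, iv_key, function(t) length(unique(t)))
        top_support <- tools_per_iv[paste(top$start, top$end)]
        top <- top[order(-top_support, top$start), , drop = FALSE]
      }
      win <- top[1, , drop = FALSE]
      win$supporting_tools <- paste(sort(unique(g$tool)), collapse = ",")
      win$n_tools <- length(unique(g$tool))
      win$best_score <- max(g$score)
      win$members <- paste(sort(g$id), collapse = ",")
      # union span of the group: the hairpin extent supported by any
      # member (mature-length calls alone underestimate the precursor)
      win$span_start <- min(g$start)
      win$span_end <- max(g$end)
      win
    }) |>
    ungroup() |>
    select(-"chain") |>
    arrange(.data$contig, .data$start)
}

#' Secondary-structure triage of extended loci
#'
#' The cascade extends unrescued loci by 50 nt on either side and
#' compares them with a structured-RNA reference; the comparison
#' itself is external, and this operation applies its verdicts: loci
#' hitting a known miRNA structure or nothing are kept, loci hitting
#' another ncRNA class are discarded. Loci missing from the verdict
#' table are treated as `no_hit` with a warning.
#'
#' @param loci tibble with an id column named by `id_col`.
#' @param structure_hits tibble mapping ids to `hit_class` in
#'   `mirna_structure_hit`, `no_hit`, `other_ncrna_hit` (id column
#'   also named by `id_col`, or `origin_id`).
#' @param id_col name of the id column used for the join.
#' @return list with `kept` and `dropped` tibbles, each with a
#'   `triage` column.
#' @export
extension_triage <- function(loci, structure_hits, id_col = "id") {
  hit_id <- if (id_col %in% names(structure_hits)) id_col else "origin_id"
  map <- setNames(structure_hits$hit_class, structure_hits[[hit_id]])
  verdict <- unname(map[loci[[id_col]]])
  if (any(is.na(verdict))) {
    warn(sprintf("extension_triage: %d locus id(s) missing from structure table; treated as no_hit",
                 sum(is.na(verdict))))
    verdict[is.na(verdict)] <- "no_hit"
  }
  bad <- !verdict %in% c("mirna_structure_hit", "no_hit", "other_ncrna_hit")
  if (any(bad)) {
    abort("extension_triage: unknown hit_class value(s)")
  }
  x <- mutate(loci, triage = verdict)
  list(
    kept = filter(x, .data$triage != "other_ncrna_hit"),
    dropped = filter(x, .data$triage == "other_ncrna_hit")
  )
}

#' Remove loci conflicting with existing gene annotation
#'
#' Drops loci overlapping features of the configured conflict classes:
#' by default any-strand overlap with non-miRNA ncRNA genes and
#' same-strand overlap with protein-coding exons. Intron-hosted loci
#' are kept (roughly half of real miRNA catalogues are intragenic).
#'
#' @param loci tibble with `contig`, `start`, `end`, `strand`.
#' @param annotation tibble as from [read_gff3()] with `type` (and
#'   optionally `biotype`) columns; `NULL` or empty keeps everything.
#' @param ncrna_types feature types treated as non-miRNA ncRNA genes.
#' @param exon_types feature types treated as exons (same-strand
#'   conflicts).
#' @return list with `kept` and `dropped` (with `reason`).
#' @export
remove_annotation_conflicts <- function(loci, annotation,
                                        ncrna_types = c(
                                          "rRNA", "tRNA", "snoRNA", "snRNA",
                                          "ncRNA_gene", "lnc_RNA", "SRP_RNA",
                                          "RNase_P_RNA"
                                        ),
                                        exon_types = "exon") {
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(list(kept = loci,
                dropped = mutate(loci[0, ], reason = character())))
  }
  nc <- filter(annotation, .data$type %in% ncrna_types)
  ex <- filter(annotation, .data$type %in% exon_types)
  if ("biotype" %in% names(ex)) {
    ex <- filter(ex, is.na(.data$biotype) |
                   .data$biotype == "protein_coding")
  }
  nc_hit <- overlaps_any(loci, nc, same_strand = FALSE)
  ex_hit <- overlaps_any(loci, ex, same_strand = TRUE)
  x <- mutate(loci, reason = case_when(
    nc_hit ~ "overlaps non-miRNA ncRNA gene",
    ex_hit ~ "overlaps same-strand protein-coding exon",
    TRUE ~ NA_character_
  ))
  list(
    kept = select(filter(x, is.na(.data$reason)), -"reason"),
    dropped = filter(x, !is.na(.data$reason))
  )
}

#' Match candidate hairpins against a reference mature set
#'
#' Mismatch-tolerant, gap-free search of each reference mature inside
#' each candidate hairpin sequence (both orientations), producing the
#' homology-rescue hit table used by [reliability_filter()].
#'
#' @param candidates tibble with `id`, `hairpin_sequence`.
#' @param reference tibble with `ref_id`, `mature_seq` (and optional
#'   `family`).
#' @param max_mismatch maximum substitutions.
#' @return tibble with `candidate_id`, `ref_id`, `mismatches` (and
#'   `family` if present).
#' @export
match_reference <- function(candidates, reference, max_mismatch = 1) {
  empty <- tibble(candidate_id = character(), ref_id = character(),
                  mismatches = integer())
  if (nrow(candidates) == 0 || nrow(reference) == 0) {
    return(empty)
  }
  # concatenate hairpins with an N-run longer than the mismatch budget
  # so no match can cross a boundary; one scan per reference pattern
  sep <- strrep("N", max_mismatch + 2)
  hp <- normalize_dna(candidates$hairpin_sequence)
  offsets <- cumsum(c(0, head(nchar(hp) + nchar(sep), -1)))
  subj <- Biostrings::DNAString(paste(hp, collapse = sep))
  out <- list()
  for (r in seq_len(nrow(reference))) {
    pat <- Biostrings::DNAString(normalize_dna(reference$mature_seq[r]))
    for (p in list(pat, Biostrings::reverseComplement(pat))) {
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      pchars <- utf8ToInt(as.character(p))
      mm <- vapply(as.character(m), function(s) {
        sum(utf8ToInt(s) != pchars)
      }, numeric(1))
      idx <- findInterval(Biostrings::start(m) - 1L, offsets)
      # discard matches not fully inside one hairpin (N-run overlap
      # already costs > max_mismatch, but guard the boundary anyway)
      inside <- (Biostrings::end(m) - 1L) <= offsets[idx] + nchar(hp)[idx] - 1L
      keep <- which(inside)
      if (length(keep) == 0) next
      out[[length(out) + 1]] <- tibble(
        candidate_id = candidates$id[idx[keep]],
        ref_id = reference$ref_id[r],
        mismatches = as.integer(mm[keep])
      )
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  hits <- bind_rows(out) |>
    group_by(.data$candidate_id, .data$ref_id) |>
    summarise(mismatches = min(.data$mismatches), .groups = "drop")
  if ("family" %in% names(reference)) {
    hits <- left_join(hits,
                      select(reference, "ref_id", "family"),
                      by = "ref_id")
  }
  hits
}
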