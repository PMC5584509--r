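make_cands <- function(...) {
  rows <- list(...)
  tibble::tibble(
    id = sprintf("c%02d", seq_along(rows)),
    contig = vapply(rows, `[[`, "", "contig"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    strand = vapply(rows, function(r) r$strand %||% "+", character(1)),
    tool = vapply(rows, function(r) r$tool %||% "mirdeep", character(1)),
    score = vapply(rows, function(r) r$score %||% 10, numeric(1))
  )
}

test_that("gap-free anchoring keeps verbatim candidates and drops unplaceable ones", {
  set.seed(21)
  genome <- c(chrA = random_dna(3000))
  hp <- substr(genome[["chrA"]], 501, 580)
  cands <- tibble::tibble(
    id = c("ok", "absent", "indel"),
    contig = "chrA", start = c(500L, 500L, 500L), end = c(580L, 580L, 580L),
    strand = "+", tool = "mirdeep", score = 10,
    hairpin_sequence = c(
      hp,
      random_dna(80),
      paste0(substr(hp, 1, 40), "A", substr(hp, 41, 80))  # 1-nt insertion
    )
  )
  res <- anchor_gap_free(cands, genome)
  expect_equal(res$anchored$id, "ok")
  expect_equal(res$anchored$start, 500L)
  expect_setequal(res$dropped$id, c("absent", "indel"))
  expect_true(all(res$dropped$reason == "no gap-free placement"))

  # one substitution is still placeable; interval is re-anchored
  hp1 <- hp
  substr(hp1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(hp1, 10, 10))[1]
  c2 <- tibble::tibble(id = "mm1", contig = "chrA", start = 100L,
                       end = 180L, strand = "+", tool = "mirdeep",
                       score = 10, hairpin_sequence = hp1)
  res2 <- anchor_gap_free(c2, genome)
  expect_equal(res2$anchored$start, 500L)
  expect_error(
    anchor_gap_free(dplyr::mutate(c2, contig = "nope"), genome),
    "absent"
  )
})

test_that("homology hit filter applies span, gap and significance rules", {
  hits <- tibble::tibble(
    candidate_id = c("a", "b", "c", "d"),
    reference_id = "ref1",
    query_length = 100L,
    aligned_span = c(90L, 95L, 100L, 89L),
    mismatches = 0L,
    gaps = c(0L, 1L, 0L, 0L),
    significance = c(1e-8, 1e-8, 1e-6, 1e-8)
  )
  kept <- filter_homology_hits(hits)
  # 90/100 at the boundary is kept; 1 gap dropped; 1e-6 dropped;
  # 89% span dropped
  expect_equal(kept$candidate_id, "a")

  # per-pair redundancy resolves to the best significance
  dup <- tibble::tibble(
    candidate_id = "a", reference_id = "ref1", query_length = 100L,
    aligned_span = 100L, mismatches = 0L, gaps = 0L,
    significance = c(1e-9, 1e-12)
  )
  expect_equal(filter_homology_hits(dup)$significance, 1e-12)
})

test_that("reliability keeps score >= 7 or a 1-mismatch reference hit", {
  cands <- tibble::tibble(
    id = c("s7", "s699", "rescued", "lost"),
    tool = "mirdeep",
    score = c(7.0, 6.99, 2, 6.5)
  )
  hits <- tibble::tibble(candidate_id = c("rescued", "lost"),
                         mismatches = c(1L, 2L))
  res <- reliability_filter(cands, hits)
  expect_setequal(res$kept$id, c("s7", "rescued"))
  expect_setequal(res$dropped$id, c("s699", "lost"))

  # conservation tools bypass the score rule when score_tools is set
  cons <- tibble::tibble(id = "inf1", tool = "infernal", score = 0.1)
  res2 <- reliability_filter(cons, hits[0, ], score_tools = "mirdeep")
  expect_equal(res2$kept$id, "inf1")

  # raising the threshold never enlarges the kept set
  set.seed(3)
  many <- tibble::tibble(id = sprintf("x%02d", 1:40), tool = "mirdeep",
                         score = runif(40, 0, 14))
  kept_at <- function(th) {
    reliability_filter(many, hits[0, ], score_threshold = th)$kept$id
  }
  for (th in c(2, 5, 7, 9, 12)) {
    expect_true(all(kept_at(th + 1) %in% kept_at(th)))
  }
})

test_that("overlap de-duplication merges within 100 nt and keeps the top score", {
  cands <- make_cands(
    list(contig = "c1", start = 1000, end = 1080, score = 9),
    list(contig = "c1", start = 1179, end = 1259, score = 7)  # gap 99
  )
  cands$hairpin_sequence <- NA_character_
  m <- deduplicate_overlaps(cands)
  expect_equal(nrow(m), 1)
  expect_equal(m$best_score, 9)
  expect_equal(m$start, 1000L)

  far <- make_cands(
    list(contig = "c1", start = 1000, end = 1080, score = 9),
    list(contig = "c1", start = 1230, end = 1310, score = 7)  # gap 150
  )
  expect_equal(nrow(deduplicate_overlaps(far)), 2)

  # exactly at the window the loci stay separate (gap < window joins)
  edge <- make_cands(
    list(contig = "c1", start = 1000, end = 1080, score = 9),
    list(contig = "c1", start = 1180, end = 1260, score = 7)  # gap 100
  )
  expect_equal(nrow(deduplicate_overlaps(edge)), 2)

  # five identical intervals from five tools collapse to one locus
  five <- make_cands(
    list(contig = "c1", start = 500, end = 580, tool = "t1"),
    list(contig = "c1", start = 500, end = 580, tool = "t2"),
    list(contig = "c1", start = 500, end = 580, tool = "t3"),
    list(contig = "c1", start = 500, end = 580, tool = "t4"),
    list(contig = "c1", start = 500, end = 580, tool = "t5")
  )
  m5 <- deduplicate_overlaps(five)
  expect_equal(nrow(m5), 1)
  expect_equal(m5$n_tools, 5L)

  # merging is strand-blind: opposite strands at one locus merge
  pm <- make_cands(
    list(contig = "c1", start = 500, end = 580, strand = "+", score = 8),
    list(contig = "c1", start = 520, end = 600, strand = "-", score = 5)
  )
  expect_equal(nrow(deduplicate_overlaps(pm)), 1)
})

test_that("de-duplication equals the transitive-closure oracle on random instances", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(2:25, 1)
    df <- tibble::tibble(
      id = sprintf("c%02d", 1:n),
      contig = sample(c("c1", "c2"), n, replace = TRUE),
      start = as.integer(sample(0:3000, n)),
      strand = "+",
      tool = sample(letters[1:4], n, replace = TRUE),
      score = runif(n, 0, 15)
    )
    df$end <- df$start + as.integer(sample(60:120, n, replace = TRUE))
    merged <- deduplicate_overlaps(df, window = 100)
    oracle <- brute_force_groups(df, max_gap = 100, inclusive = FALSE)
    expect_equal(
      grouping_sets(df$id, oracle),
      sort(merged$members)
    )
    # winner of each group has the group's top score
    expect_equal(
      sort(merged$best_score),
      sort(as.numeric(tapply(df$score, oracle, max)))
    )
  }
})

test_that("the cascade result is invariant to candidate input order", {
  set.seed(123)
  n <- 40
  df <- tibble::tibble(
    id = sprintf("c%02d", 1:n),
    contig = sample(c("c1", "c2"), n, replace = TRUE),
    start = as.integer(sample(0:5000, n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tool = sample(letters[1:5], n, replace = TRUE),
    score = runif(n, 0, 15)
  )
  df$end <- df$start + 80L
  a <- deduplicate_overlaps(df)
  b <- deduplicate_overlaps(df[sample(n), ])
  expect_equal(a, b)
})

test_that("structure triage keeps miRNA/no-hit loci and drops other ncRNA", {
  loci <- tibble::tibble(id = c("l1", "l2", "l3", "l4"))
  hits <- tibble::tibble(
    id = c("l1", "l2", "l3"),
    hit_class = c("other_ncrna_hit", "no_hit", "mirna_structure_hit")
  )
  expect_warning(res <- extension_triage(loci, hits), "missing")
  expect_setequal(res$kept$id, c("l2", "l3", "l4"))
  expect_equal(res$dropped$id, "l1")
})

test_that("annotation conflicts remove ncRNA/exon overlaps but keep introns", {
  loci <- tibble::tibble(
    id = c("in_rrna", "in_intron", "in_exon_same", "in_exon_anti", "free"),
    contig = "c1",
    start = c(100L, 5000L, 9000L, 12000L, 20000L),
    end = c(180L, 5080L, 9080L, 12080L, 20080L),
    strand = c("+", "+", "+", "+", "+")
  )
  ann <- tibble::tibble(
    contig = "c1",
    start = c(50L, 4000L, 4000L, 6800L, 8950L, 11950L),
    end = c(300L, 7000L, 4500L, 7000L, 9100L, 12100L),
    strand = c("+", "+", "+", "+", "+", "-"),
    type = c("rRNA", "gene", "exon", "exon", "exon", "exon"),
    biotype = "protein_coding"
  )
  res <- remove_annotation_conflicts(loci, ann)
  expect_setequal(res$kept$id, c("in_intron", "in_exon_anti", "free"))
  expect_setequal(res$dropped$id, c("in_rrna", "in_exon_same"))
  # empty annotation keeps everything
  res0 <- remove_annotation_conflicts(loci, NULL)
  expect_equal(nrow(res0$kept), nrow(loci))
})

test_that("reference matching finds matures in hairpins within one mismatch", {
  set.seed(8)
  mature <- random_dna(22)
  hairpin <- paste0(random_dna(10), mature, random_dna(40))
  mat1 <- mature
  substr(mat1, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mat1, 5, 5))[1]
  cands <- tibble::tibble(
    id = c("exact", "onemm", "none"),
    hairpin_sequence = c(hairpin, paste0(random_dna(10), mat1,
                                         random_dna(40)),
                         random_dna(72))
  )
  ref <- tibble::tibble(ref_id = "m1", mature_seq = mature,
                        family = "fam1")
  hits <- match_reference(cands, ref)
  expect_setequal(hits$candidate_id, c("exact", "onemm"))
  expect_equal(hits$mismatches[hits$candidate_id == "exact"], 0L)
  expect_equal(hits$mismatches[hits$candidate_id == "onemm"], 1L)
})
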