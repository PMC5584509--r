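mk_entries <- function(starts, contig = "c1", len = 80L) {
  tibble::tibble(
    id = sprintf("e%02d", seq_along(starts)),
    contig = contig,
    start = as.integer(starts),
    end = as.integer(starts) + len,
    strand = "+"
  )
}

test_that("cluster calling honours the 10-kb distance boundary", {
  # edge gaps of 9999 and 10000 chain; 10001 does not
  e <- mk_entries(c(0, 80 + 9999))
  expect_equal(call_clusters(e)$n_members, 2L)
  e2 <- mk_entries(c(0, 80 + 10000))
  expect_equal(call_clusters(e2)$n_members, 2L)
  e3 <- mk_entries(c(0, 80 + 10001))
  expect_equal(nrow(call_clusters(e3)), 0)
})

test_that("chains break at large gaps into the expected cluster sizes", {
  starts <- c(0, 5080, 10160, 30240, 35320)  # gaps 5k,5k,20k,5k
  cl <- call_clusters(mk_entries(starts))
  expect_equal(cl$n_members, c(3L, 2L))
  expect_equal(sum(cl$n_members), 5L)
})

test_that("cluster calling equals the transitive-closure oracle", {
  set.seed(77)
  for (rep in 1:150) {
    n <- sample(2:20, 1)
    df <- tibble::tibble(
      id = sprintf("e%02d", 1:n),
      contig = sample(c("c1", "c2"), n, replace = TRUE),
      start = as.integer(sample(seq(0, 200000, 50), n))
    )
    df$end <- df$start + 80L
    cl <- call_clusters(df, max_gap = 10000)
    oracle <- brute_force_groups(df, max_gap = 10000, inclusive = TRUE)
    oracle_clusters <- grouping_sets(df$id, oracle)
    oracle_clusters <- oracle_clusters[grepl(",", oracle_clusters)]
    got <- vapply(cl$members, function(m) {
      paste(sort(m$id), collapse = ",")
    }, character(1))
    expect_equal(sort(got), sort(oracle_clusters))
    # every entry is in at most one cluster
    all_members <- unlist(lapply(cl$members, function(m) m$id))
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("family assignment requires identity and seed agreement", {
  set.seed(55)
  base <- random_dna(22)
  ref <- tibble::tibble(family = "mir-9", mature_seq = base)
  mk <- function(seqs) {
    tibble::tibble(id = sprintf("m%d", seq_along(seqs)),
                   mature5p_seq = seqs, mature3p_seq = NA_character_)
  }
  # identical mature -> the family
  expect_equal(assign_family(mk(base), ref)$family, "mir-9")
  # 3 mismatches outside the seed: identity 19/22 = 0.864 < 0.9
  s3 <- base
  for (p in c(10, 14, 18)) {
    substr(s3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(s3, p, p))[1]
  }
  expect_equal(assign_family(mk(s3), ref)$family, "unassigned")
  # 1 mismatch inside the seed (identity 21/22 = 0.955) fails the
  # seed rule, passes when the rule is waived
  s1 <- base
  substr(s1, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(s1, 4, 4))[1]
  expect_equal(assign_family(mk(s1), ref)$family, "unassigned")
  expect_equal(
    assign_family(mk(s1), ref, require_seed_identity = FALSE)$family,
    "mir-9"
  )
  # permutation invariance in the reference order
  ref2 <- tibble::tibble(family = c("mir-9", "mir-1"),
                         mature_seq = c(base, random_dna(22)))
  a <- assign_family(mk(base), ref2)$family
  b <- assign_family(mk(base), ref2[2:1, ])$family
  expect_equal(a, b)
})

test_that("a reference mature is found inside a precursor-length sequence", {
  set.seed(56)
  mature <- random_dna(22)
  hairpin <- paste0(random_dna(15), mature, random_dna(40))
  ref <- tibble::tibble(family = "mir-7", mature_seq = mature)
  entries <- tibble::tibble(id = "hp", mature5p_seq = hairpin,
                            mature3p_seq = NA_character_)
  expect_equal(assign_family(entries, ref)$family, "mir-7")
})

test_that("novel families form by single linkage over identity", {
  set.seed(57)
  a <- random_dna(22)
  mut_at <- function(x, pos) {
    for (p in pos) {
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), substr(x, p, p))[1]
    }
    x
  }
  # chain: a~b (1 mm = .955), b~c (2 mm from b = .909), a~c (.86)
  b <- mut_at(a, 10)
  c_ <- mut_at(b, c(14, 18))
  entries <- tibble::tibble(id = c("x1", "x2", "x3"),
                            mature5p_seq = c(a, b, c_))
  fams <- cluster_novel_families(entries)
  expect_equal(length(unique(fams$family)), 1)
  expect_equal(unique(fams$family), "NF0001")
  # all-distant entries become singleton families
  far <- tibble::tibble(id = sprintf("y%d", 1:6),
                        mature5p_seq = replicate(6, random_dna(22)))
  ff <- cluster_novel_families(far)
  expect_equal(length(unique(ff$family)), 6)
  # identical matures share one family
  twin <- tibble::tibble(id = c("t1", "t2"), mature5p_seq = c(a, a))
  expect_equal(length(unique(cluster_novel_families(twin)$family)), 1)
})

test_that("composition strings follow genomic order and orientation", {
  e <- mk_entries(c(0, 200, 400))
  cl <- call_clusters(e, max_gap = 10000)
  fam <- c(e01 = "29a", e02 = "29b", e03 = "29a")
  expect_equal(cluster_composition(cl[1, ], fam), "29a/29b/29a")
  expect_equal(cluster_composition(cl[1, ], fam, reverse = TRUE),
               paste(rev(c("29a", "29b", "29a")), collapse = "/"))
  # a singleton is not a cluster
  single <- tibble::tibble(id = "s", contig = "c1", start = 0L, end = 80L)
  expect_error(cluster_composition(single, fam), "two members")
})

test_that("catalogue summary counts are conserved", {
  e <- mk_entries(c(0, 5000, 10000, 40000, 48000, 80000))
  e$family <- c("mir-1", "mir-1", "NF0001", "NF0001", "mir-2",
                "unassigned")
  cl <- call_clusters(e)
  s <- summarize_catalogue(e, cl)
  expect_equal(s$n_mirnas, 6L)
  expect_equal(s$n_clusters, 2L)
  expect_equal(s$n_mirnas_in_clusters, sum(cl$n_members))
  expect_equal(s$n_known_families, 2L)
  expect_equal(s$n_novel_families, 1L)
  expect_equal(s$n_known_family_members + s$n_novel_family_members +
                 sum(e$family == "unassigned"), 6L)
  # empty catalogue -> all zeros
  s0 <- summarize_catalogue(e[0, ], call_clusters(e[0, ]))
  expect_true(all(s0 == 0))
})
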