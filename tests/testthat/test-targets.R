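test_that("seed sites are the reverse complement of mature nt 2-7", {
  # mature 5'-UAGCUUAUCAG...: seed AGCUUA, site motif UAAGCU (TAAGCT)
  mature <- "UAGCUUAUCAGACUGAUGUUGA"
  matures <- tibble::tibble(mirna_id = "let7", mature = mature)
  flank <- "GGGGGGGGGG"
  row_fish <- paste0(flank, "TAAGCT", flank)
  alns <- list(g1 = c(nfu = row_fish, dre = row_fish,
                      hsa = gsub("TAAGCT", "TAACCT", row_fish)))
  sites <- find_seed_sites(matures, alns, c("nfu", "dre"))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site, "TAAGCT")
  expect_equal(sites$aln_col, 10L)
  expect_equal(sites$utr_pos, 10L)
  # conservative 3-species mode loses the site absent in human
  none <- find_seed_sites(matures, alns, c("nfu", "dre", "hsa"))
  expect_equal(nrow(none), 0)
  # empty UTR set
  expect_equal(nrow(find_seed_sites(matures, list(), "nfu")), 0)
  # short mature is an input error
  expect_error(
    find_seed_sites(tibble::tibble(mirna_id = "x", mature = "ACGU"),
                    alns, "nfu"),
    "7 nt"
  )
})

test_that("sites must be ungapped and at homologous columns", {
  matures <- tibble::tibble(mirna_id = "m", mature = "TAGCTTATCAGACTGATGTTGA")
  site <- "TAAGCT"
  a <- paste0(strrep("G", 10), site, strrep("G", 10))
  # gap inside the site in one required row breaks it
  gapped <- a
  substr(gapped, 12, 12) <- "-"
  alns <- list(g1 = c(nfu = a, dre = gapped))
  expect_equal(nrow(find_seed_sites(matures, alns, c("nfu", "dre"))), 0)
  # same motif at different columns does not count
  shifted <- paste0(strrep("G", 12), site, strrep("G", 8))
  alns2 <- list(g1 = c(nfu = a, dre = shifted))
  expect_equal(nrow(find_seed_sites(matures, alns2, c("nfu", "dre"))), 0)
  # fewer required species never shrinks the site set
  set.seed(14)
  alns3 <- lapply(1:20, function(i) {
    r <- random_dna(60)
    c(nfu = r, dre = if (i %% 2) r else random_dna(60))
  })
  names(alns3) <- sprintf("g%02d", 1:20)
  m2 <- tibble::tibble(mirna_id = "m", mature = random_dna(22))
  s1 <- find_seed_sites(m2, alns3, "nfu")
  s2 <- find_seed_sites(m2, alns3, c("nfu", "dre"))
  expect_true(all(paste(s2$gene, s2$aln_col) %in%
                    paste(s1$gene, s1$aln_col)))
})

test_that("hypergeometric tail matches hand-computed and degenerate cases", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(hypergeom_pvalue(10, 5, 5, 0), 1)
  # drawing the whole universe forces r = R
  expect_equal(hypergeom_pvalue(20, 6, 20, 6), 1)
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "exceeds")
  expect_error(hypergeom_pvalue(10, 12, 5, 0), "N")
  # full-support normalisation of the underlying pmf
  for (N in c(7, 15, 33)) {
    R <- N %/% 3
    n <- N %/% 2
    lo <- max(0, n - (N - R))
    expect_equal(hypergeom_pvalue(N, R, n, lo), 1)
  }
  # monotone non-increasing in r
  for (r in 0:5) {
    expect_gte(hypergeom_pvalue(40, 12, 15, r),
               hypergeom_pvalue(40, 12, 15, r + 1))
  }
})

test_that("hypergeometric tail equals stats::phyper over an N<=60 lattice", {
  for (N in c(2:12, 20, 30, 45, 60)) {
    step <- max(1, N %/% 8)
    for (R in seq(0, N, step)) {
      for (n in seq(0, N, step)) {
        for (r in seq(max(0, n - (N - R)), min(n, R))) {
          p <- hypergeom_pvalue(N, R, n, r)
          ref <- stats::phyper(r - 1, R, N - R, n, lower.tail = FALSE)
          expect_equal(p, ref, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tail equals an exact big-integer rational oracle", {
  py <- Sys.which("python3")
  if (py == "") py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(60)
  cases <- list()
  for (i in 1:400) {
    N <- sample(2:60, 1)
    R <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n - (N - R))
    r <- sample(lo:min(n, R), 1)
    cases[[i]] <- c(N, R, n, r)
  }
  mat <- do.call(rbind, cases)
  inp <- tempfile()
  writeLines(apply(mat, 1, paste, collapse = " "), inp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in open(sys.argv[1]):",
    "    N, R, n, r = map(int, line.split())",
    "    num = sum(comb(R, i) * comb(N - R, n - i)",
    "              for i in range(r, min(n, R) + 1))",
    "    p = Fraction(num, comb(N, n))",
    "    print(repr(float(p)))"
  ), script)
  exact <- as.numeric(system2(py, c(script, inp), stdout = TRUE))
  got <- vapply(seq_len(nrow(mat)), function(i) {
    hypergeom_pvalue(mat[i, 1], mat[i, 2], mat[i, 3], mat[i, 4])
  }, numeric(1))
  rel_err <- abs(got - exact) / pmax(exact, .Machine$double.xmin)
  expect_lt(max(rel_err), 1e-12)
})

test_that("BH adjustment matches the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # stable under input order
  p <- runif(25)
  o <- sample(25)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("gene-set enrichment fills the contingency and gates on q", {
  target_map <- tibble::tibble(
    mirna_id = rep(c("m1", "m2"), c(3, 2)),
    gene = c("g1", "g2", "g3", "g3", "g4")
  )
  universe <- sprintf("g%d", 1:10)
  sets <- list(hit = c("g1", "g2", "g3"), miss = c("g7", "g8"))
  res <- enrich_gene_sets(target_map, sets, universe)
  expect_equal(res$N, c(10L, 10L))
  expect_equal(res$n, c(4L, 4L))
  expect_equal(res$r[res$set == "hit"], 3L)
  expect_equal(res$r[res$set == "miss"], 0L)
  expect_equal(res$p[res$set == "miss"], 1)
  expect_false(res$significant[res$set == "miss"])
  expect_equal(res$q, bh_adjust(res$p))
  # per-miRNA mode restricts the universe to targeted genes
  pm <- enrich_gene_sets(target_map, sets, universe, mode = "per-mirna")
  expect_true(all(pm$N == 4L))
  expect_equal(pm$n[pm$mirna_id == "m1"], c(3L, 3L))
  # tidy/glance accessors
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_tests, 2L)
  expect_error(enrich_gene_sets(target_map, sets, character()), "universe")
  expect_error(
    enrich_gene_sets(target_map, list(bad = "nope"), universe),
    "outside"
  )
})
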