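test_that("generators are byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 99, cluster_spec = list(c(2, 3000)))
  d1 <- tempfile()
  d2 <- tempfile()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("an empty truth set and zero sensitivity are handled", {
  cfg <- tiny_config(n_true_mirnas = 0, n_decoys = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 0)
  cand <- simulate_tool_predictions(sim, cfg)
  expect_equal(nrow(cand), 0)
  cfg0 <- tiny_config(sensitivity = 0, fp_rate = 0)
  sim0 <- simulate_genome(cfg0)
  expect_equal(nrow(simulate_tool_predictions(sim0, cfg0)), 0)
})

test_that("prescribed clusters are laid out with exact intra-gaps", {
  cfg <- tiny_config(cluster_spec = list(c(3, 5000)))
  sim <- simulate_genome(cfg)
  cl <- sim$truth[!is.na(sim$truth$cluster_id), ]
  expect_equal(nrow(cl), 3)
  expect_equal(length(unique(cl$contig)), 1)
  cl <- cl[order(cl$start), ]
  expect_equal(cl$start[-1] - cl$end[-nrow(cl)], rep(5000, 2))
})

test_that("an oversubscribed contig raises a sizing error naming the shortfall", {
  cfg <- tiny_config(n_contigs = 1, contig_length = 5000,
                     n_true_mirnas = 30)
  expect_error(simulate_genome(cfg), "shortfall")
})

test_that("planted geometry invariants hold across random configurations", {
  set.seed(1234)
  for (rep in 1:400) {
    lo <- sample(48:90, 1)
    cfg <- sim_config(
      seed = sample.int(1e6, 1),
      n_contigs = sample(1:2, 1),
      contig_length = sample(20000:40000, 1),
      n_true_mirnas = sample(1:6, 1),
      n_decoys = sample(0:3, 1),
      hairpin_len_range = c(lo, sample(max(lo + 5, 100):200, 1)),
      min_locus_separation = 250
    )
    sim <- simulate_genome(cfg)
    tr <- sim$truth
    # arms nested inside the precursor and disjoint with a >=4 nt gap
    expect_true(all(tr$m5p_start >= tr$start & tr$m5p_end <= tr$end))
    expect_true(all(tr$m3p_start >= tr$start & tr$m3p_end <= tr$end))
    gaps <- ifelse(tr$strand == "+", tr$m3p_start - tr$m5p_end,
                   tr$m5p_start - tr$m3p_end)
    expect_true(all(gaps >= 4))
    # 3p arm is the reverse complement of the 5p arm up to 3 mismatches
    for (j in seq_len(nrow(tr))) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tr$mature5p_seq[j])
      ))
      mm <- sum(utf8ToInt(rc) != utf8ToInt(tr$mature3p_seq[j]))
      expect_lte(mm, 3)
    }
    # loci do not overlap
    if (nrow(tr) > 1) {
      by_contig <- split(tr, tr$contig)
      for (ct in by_contig) {
        ct <- ct[order(ct$start), ]
        if (nrow(ct) > 1) {
          expect_true(all(ct$start[-1] >= ct$end[-nrow(ct)]))
        }
      }
    }
    # genomic sequence at the arms matches the recorded matures
    j <- sample(nrow(tr), 1)
    g <- sim$genome[[tr$contig[j]]]
    m5 <- substr(g, tr$m5p_start[j] + 1, tr$m5p_end[j])
    if (tr$strand[j] == "-") {
      m5 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(m5)
      ))
    }
    expect_equal(m5, tr$mature5p_seq[j])
  }
})

test_that("truth round-trips through GFF3", {
  cfg <- tiny_config(seed = 13, cluster_spec = list(c(2, 4000)))
  dir <- tempfile()
  objs <- simulate_inputs(cfg, dir)
  back <- read_gff3(file.path(dir, "truth.gff3"))
  tr <- objs$sim$truth
  expect_equal(nrow(back), nrow(tr))
  back <- back[match(tr$id, back$ID), ]
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$strand, tr$strand)
  expect_equal(back$family, tr$family)
  expect_equal(back$expression_class, tr$expression_class)
})

test_that("noiseless tools reproduce truth intervals exactly", {
  cfg <- tiny_config(sensitivity = 1, fp_rate = 0,
                     positional_jitter_sd = 0)
  sim <- simulate_genome(cfg)
  cand <- simulate_tool_predictions(sim, cfg)
  expect_equal(nrow(cand), nrow(sim$truth) * nrow(cfg$tools))
  for (t in seq_len(nrow(cfg$tools))) {
    tl <- cfg$tools[t, ]
    tc <- cand[cand$tool == tl$tool, ]
    tc <- tc[match(sim$truth$id, tc$origin_id), ]
    if (tl$emits == "precursor") {
      expect_equal(tc$start, sim$truth$start)
      expect_equal(tc$end, sim$truth$end)
    } else {
      expect_equal(tc$start, sim$truth$m5p_start)
      expect_equal(tc$end, sim$truth$m5p_end)
    }
  }
})

test_that("per-tool recovery fractions sit inside the binomial band", {
  cfg <- sim_config(seed = 2024, n_true_mirnas = 200, n_decoys = 0)
  sim <- simulate_genome(cfg)
  cand <- simulate_tool_predictions(sim, cfg)
  half_width <- 4 * sqrt(0.8 * 0.2 / 200)
  for (tl in cfg$tools$tool) {
    frac <- length(unique(cand$origin_id[cand$tool == tl])) / 200
    expect_lt(abs(frac - 0.8), half_width)
  }
})

test_that("reads reproduce the mature intervals in the noiseless limit", {
  cfg <- tiny_config(read_start_wobble = 0, expressed_fraction = 1,
                     extended_mapping_fraction = 0,
                     library_detect_prob = 1)
  sim <- simulate_genome(cfg)
  libs <- simulate_read_alignments(sim, cfg)
  reads <- libs[[1]]
  arm_keys <- c(paste(sim$truth$contig, sim$truth$m5p_start,
                      sim$truth$m5p_end),
                paste(sim$truth$contig, sim$truth$m3p_start,
                      sim$truth$m3p_end))
  expect_true(all(paste(reads$contig, reads$start, reads$end) %in%
                    arm_keys))
})

test_that("extended loci are tiled edge to edge including 50-nt flanks", {
  cfg <- tiny_config(extended_mapping_fraction = 1)
  sim <- simulate_genome(cfg)
  reads <- simulate_read_alignments(sim, cfg)[[1]]
  for (j in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[j, ]
    mine <- reads[reads$contig == tr$contig &
                    reads$start >= tr$start - 50 &
                    reads$end <= tr$end + 50, ]
    expect_equal(min(mine$start), tr$start - 50L)
    expect_equal(max(mine$end), tr$end + 50L)
  }
})

test_that("per-arm read depth matches the Poisson mean", {
  cfg <- sim_config(seed = 3030, n_true_mirnas = 100, n_decoys = 0,
                    expressed_fraction = 1,
                    extended_mapping_fraction = 0,
                    library_detect_prob = 1, read_depth_mean = 30)
  sim <- simulate_genome(cfg)
  reads <- simulate_read_alignments(sim, cfg)[[1]]
  depth_5p <- vapply(seq_len(nrow(sim$truth)), function(j) {
    tr <- sim$truth[j, ]
    sum(reads$count[reads$contig == tr$contig &
                      reads$start >= tr$m5p_start - 2 &
                      reads$end <= tr$m5p_end + 2])
  }, numeric(1))
  expect_gte(mean(depth_5p), 25)
  expect_lte(mean(depth_5p), 35)
})

test_that("a null UTR generator plants no sites when site_prob is zero", {
  cfg <- tiny_config(site_prob = 0)
  sim <- simulate_genome(cfg)
  utr <- simulate_utr_set(sim, cfg)
  expect_equal(nrow(utr$target_truth), 0)
  # planted sites are recoverable at their recorded columns
  cfg2 <- tiny_config(site_prob = 0.3)
  utr2 <- simulate_utr_set(sim, cfg2)
  sites <- find_seed_sites(utr2$panel, utr2$alignments,
                           cfg2$site_conserved_species)
  planted_keys <- paste(utr2$target_truth$gene,
                        utr2$target_truth$mirna_id,
                        utr2$target_truth$aln_col)
  found_keys <- paste(sites$gene, sites$mirna_id, sites$aln_col)
  expect_true(all(planted_keys %in% found_keys))
})
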