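#' Simulation configuration for synthetic pipeline inputs
#'
#' Defines a small genome with planted miRNA hairpins (a 60-120 nt
#' precursor carrying two ~22-nt mature arms around a read-free loop),
#' decoy loci, per-tool candidate predictions with configurable
#' sensitivity and false-positive rates, small RNA-seq read pileups,
#' orthologous 3'-UTR alignments with planted seed-match target sites,
#' and a species-by-miRNA expression structure evolved along a planted
#' tree. Every generator is deterministic given `seed`.
#'
#' @param seed integer seed governing all generators.
#' @param n_contigs,contig_length genome shape.
#' @param n_true_mirnas,n_decoys planted positive and decoy locus counts.
#' @param hairpin_len_range precursor length bounds in nt (within 40-200).
#' @param mature_len mature arm length in nt.
#' @param loop_len minimum/maximum loop length in nt; the realised loop
#'   is the sampled precursor length minus both arms, floored at
#'   `loop_len[1]`.
#' @param cluster_spec list of `c(member_count, intra_gap_nt)` genomic
#'   cluster prescriptions; members share one mature sequence and family.
#' @param tools tibble with columns `tool`, `kind`
#'   (`"expression"`/`"conservation"`), `emits`
#'   (`"mature"`/`"precursor"`), `sensitivity`, `fp_rate`. `NULL` uses
#'   the default five-tool panel at `sensitivity`/`fp_rate`.
#' @param sensitivity,fp_rate per-tool detection probability of a true
#'   locus and per-decoy false-call probability (used when `tools` is
#'   `NULL`).
#' @param positional_jitter_sd SD in nt of Gaussian jitter on predicted
#'   interval edges.
#' @param known_family_fraction fraction of planted miRNAs whose family
#'   is present in the simulated reference mature set.
#' @param expressed_fraction fraction of planted loci with read support.
#' @param extended_mapping_fraction fraction of planted loci emitting
#'   degradation-like uniform coverage across precursor and flanks.
#' @param n_libraries small RNA-seq libraries simulated for the
#'   reference species.
#' @param library_detect_prob per-library probability that an expressed
#'   locus shows reads in that library.
#' @param read_depth_mean Poisson mean of per-arm collapsed read depth.
#' @param read_start_wobble maximum offset in nt of read 5' ends
#'   around the mature 5' end (centre-heavy distribution; 0 places
#'   every read exactly on the mature interval).
#' @param n_genes,utr_len,n_de_genes,site_prob,enrichment_odds,utr_divergence
#'   3'-UTR target simulation: gene count, alignment length, size of the
#'   differentially-expressed set, baseline probability that a gene
#'   carries a planted site, odds multiplier for DE genes, and per-base
#'   divergence of non-reference species rows.
#' @param n_target_mirnas number of planted miRNAs in the target panel.
#' @param utr_species,site_conserved_species aligned species and the
#'   subset in which planted sites are conserved.
#' @param planted_tree rooted Newick (with branch lengths) over the
#'   species labels used by [simulate_species_expression()].
#' @param root_presence_prob probability a miRNA is present at the
#'   root.
#' @param loss_rate,gain_rate presence loss/gain rates per unit branch
#'   length; the per-branch event probability is `1 - exp(-rate * l)`
#'   (branches without lengths count as length 1).
#' @param decoy_ncrna_fraction fraction of decoys whose extended
#'   sequence hits another ncRNA class in the structure-triage table.
#' @param min_locus_separation minimum nt between planted loci outside
#'   prescribed clusters; the default exceeds the 10-kb cluster-calling
#'   distance so the clustered architecture is exactly the one
#'   prescribed by `cluster_spec`.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1,
                       n_contigs = 4,
                       contig_length = 1000000,
                       n_true_mirnas = 200,
                       n_decoys = 100,
                       hairpin_len_range = c(60, 120),
                       mature_len = 22,
                       loop_len = c(10, 15),
                       cluster_spec = list(),
                       tools = NULL,
                       sensitivity = 0.8,
                       fp_rate = 0.1,
                       positional_jitter_sd = 0,
                       known_family_fraction = 0.45,
                       expressed_fraction = 0.78,
                       extended_mapping_fraction = 0.05,
                       n_libraries = 2,
                       library_detect_prob = 0.9,
                       read_depth_mean = 30,
                       read_start_wobble = 2,
                       n_genes = 500,
                       utr_len = 300,
                       n_de_genes = 100,
                       site_prob = 0.15,
                       enrichment_odds = 4,
                       utr_divergence = 0.1,
                       n_target_mirnas = 10,
                       utr_species = c("nfu", "dre", "mmu", "hsa"),
                       site_conserved_species = c("nfu", "dre"),
                       planted_tree = paste0(
                         "(((sp1:0.15,sp2:0.15):0.45,",
                         "(sp3:0.2,sp4:0.2):0.4):0.4,",
                         "((sp5:0.15,sp6:0.15):0.45,sp7:0.6):0.4);"
                       ),
                       root_presence_prob = 0.9,
                       loss_rate = 0.5,
                       gain_rate = 0.05,
                       decoy_ncrna_fraction = 0.95,
                       min_locus_separation = 11000) {
  if (is.null(tools)) {
    tools <- tibble(
      tool = c("mirdeep", "infernal", "blastn", "gorap", "cidmirna"),
      kind = c("expression", rep("conservation", 4)),
      emits = c("precursor", "precursor", "mature", "precursor", "precursor"),
      sensitivity = sensitivity,
      fp_rate = fp_rate
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_contigs = n_contigs,
    contig_length = contig_length, n_true_mirnas = n_true_mirnas,
    n_decoys = n_decoys, hairpin_len_range = hairpin_len_range,
    mature_len = mature_len, loop_len = loop_len,
    cluster_spec = cluster_spec, tools = tools,
    positional_jitter_sd = positional_jitter_sd,
    known_family_fraction = known_family_fraction,
    expressed_fraction = expressed_fraction,
    extended_mapping_fraction = extended_mapping_fraction,
    n_libraries = n_libraries,
    library_detect_prob = library_detect_prob,
    read_depth_mean = read_depth_mean,
    read_start_wobble = read_start_wobble,
    n_genes = n_genes, utr_len = utr_len, n_de_genes = n_de_genes,
    site_prob = site_prob, enrichment_odds = enrichment_odds,
    utr_divergence = utr_divergence, n_target_mirnas = n_target_mirnas,
    utr_species = utr_species,
    site_conserved_species = site_conserved_species,
    planted_tree = planted_tree,
    root_presence_prob = root_presence_prob,
    loss_rate = loss_rate,
    gain_rate = gain_rate,
    decoy_ncrna_fraction = decoy_ncrna_fraction,
    min_locus_separation = min_locus_separation
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$tools$sensitivity, cfg$tools$fp_rate, cfg$known_family_fraction,
    cfg$expressed_fraction, cfg$extended_mapping_fraction,
    cfg$library_detect_prob, cfg$site_prob, cfg$utr_divergence,
    cfg$root_presence_prob, cfg$decoy_ncrna_fraction
  )
  if (cfg$loss_rate < 0 || cfg$gain_rate < 0) {
    abort("sim_config: loss_rate and gain_rate must be non-negative")
  }
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: all probabilities must lie in [0, 1]")
  }
  hr <- cfg$hairpin_len_range
  if (length(hr) != 2 || hr[1] > hr[2] || hr[1] < 40 || hr[2] > 200) {
    abort("sim_config: hairpin_len_range must be within [40, 200]")
  }
  if (cfg$mature_len < 15 || 2 * cfg$mature_len + 4 > hr[2]) {
    abort("sim_config: mature arms plus a >=4 nt loop must fit the hairpin")
  }
  if (cfg$enrichment_odds <= 0) {
    abort("sim_config: enrichment_odds must be positive")
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# genome + planted truth

#' Simulate a genome with planted miRNA hairpins and decoy loci
#'
#' Plants `n_true_mirnas` hairpins (two mature arms whose sequences are
#' reverse complements up to <=3 mismatches, separated by a loop) and
#' `n_decoys` featureless decoy intervals at non-overlapping positions.
#' Prescribed genomic clusters are laid out with their exact intra-gaps;
#' cluster members share one mature sequence (tandem-duplication-like)
#' and one family label. A reference set of mature sequences with family
#' labels is emitted for the known-family subset.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `truth` (tibble
#'   of planted miRNAs), `decoys` (tibble), `reference` (tibble of
#'   reference matures with `family`).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  m <- cfg$mature_len
  min_hp <- max(cfg$hairpin_len_range[1], 2 * m + cfg$loop_len[1])
  contigs <- sprintf("ctg%02d", seq_len(cfg$n_contigs))

  # layout units: prescribed clusters, then singleton true loci, then decoys
  cluster_sizes <- vapply(cfg$cluster_spec, `[`, numeric(1), 1)
  n_clustered <- sum(cluster_sizes)
  if (n_clustered > cfg$n_true_mirnas) {
    abort("cluster_spec requests more members than n_true_mirnas")
  }
  units <- list()
  for (ci in seq_along(cfg$cluster_spec)) {
    k <- cfg$cluster_spec[[ci]][1]
    gap <- cfg$cluster_spec[[ci]][2]
    units[[length(units) + 1]] <-
      list(kind = "cluster", k = k, gap = gap, cluster_id = ci)
  }
  for (i in seq_len(cfg$n_true_mirnas - n_clustered)) {
    units[[length(units) + 1]] <- list(kind = "true", k = 1)
  }
  for (i in seq_len(cfg$n_decoys)) {
    units[[length(units) + 1]] <- list(kind = "decoy", k = 1)
  }

  # sample hairpin lengths for all loci
  for (u in seq_along(units)) {
    units[[u]]$lens <- sample(seq(min_hp, cfg$hairpin_len_range[2]),
                              units[[u]]$k, replace = TRUE)
  }

  # assign units to contigs round-robin (clusters stay whole), then
  # place left-to-right with random slack
  unit_contig <- rep(seq_len(cfg$n_contigs), length.out = length(units))
  sep <- cfg$min_locus_separation
  placements <- list()
  for (ct in seq_len(cfg$n_contigs)) {
    mine <- which(unit_contig == ct)
    if (length(mine) == 0) next
    unit_span <- vapply(mine, function(u) {
      un <- units[[u]]
      sum(un$lens) + if (un$kind == "cluster") (un$k - 1) * un$gap else 0
    }, numeric(1))
    need <- sum(unit_span) + (length(mine) + 1) * sep
    if (need > cfg$contig_length) {
      abort(sprintf(
        "contig %s too short: need %d nt to host %d loci, have %d (shortfall %d)",
        contigs[ct], need, length(mine), cfg$contig_length,
        need - cfg$contig_length
      ))
    }
    slack <- cfg$contig_length - need
    cuts <- sort(runif(length(mine), 0, slack))
    extra <- floor(c(cuts, slack) - c(0, cuts))
    pos <- sep + extra[1]
    for (j in seq_along(mine)) {
      u <- mine[j]
      placements[[length(placements) + 1]] <-
        list(unit = u, contig = contigs[ct], start = pos)
      pos <- pos + vapply(list(units[[u]]), function(un) {
        sum(un$lens) + if (un$kind == "cluster") (un$k - 1) * un$gap else 0
      }, numeric(1)) + sep + extra[j + 1]
    }
  }

  # expand placements to individual loci
  rows <- list()
  for (pl in placements) {
    un <- units[[pl$unit]]
    s <- pl$start
    strand <- if (un$kind == "cluster") {
      sample(c("+", "-"), 1)  # one strand per cluster (co-transcription)
    } else {
      NA_character_
    }
    for (j in seq_len(un$k)) {
      rows[[length(rows) + 1]] <- tibble(
        kind = un$kind, contig = pl$contig,
        start = as.integer(s), end = as.integer(s + un$lens[j]),
        strand = if (is.na(strand)) sample(c("+", "-"), 1) else strand,
        cluster_id = if (un$kind == "cluster") un$cluster_id else NA_integer_
      )
      s <- s + un$lens[j] + if (un$kind == "cluster") un$gap else 0
    }
  }
  empty_loci <- tibble(kind = character(), contig = character(),
                       start = integer(), end = integer(),
                       strand = character(), cluster_id = integer())
  loci <- bind_rows(c(list(empty_loci), rows))
  truth <- filter(loci, .data$kind %in% c("true", "cluster"))
  decoys <- filter(loci, .data$kind == "decoy")

  # family structure and mature sequences
  n_true <- nrow(truth)
  truth$id <- sprintf("mir-t%04d", seq_len(n_true))
  is_known <- rbinom(n_true, 1, cfg$known_family_fraction) == 1
  mature5p <- character(n_true)
  family <- character(n_true)
  next_known <- 0L
  next_novel <- 0L
  # clusters: one shared mature + family per cluster
  for (ci in unique(stats::na.omit(truth$cluster_id))) {
    idx <- which(truth$cluster_id == ci)
    seq5p <- rand_dna(cfg$mature_len)
    known <- is_known[idx[1]]
    is_known[idx] <- known
    if (known) {
      next_known <- next_known + 1L
      fam <- sprintf("mir-%d", 100 + next_known)
    } else {
      next_novel <- next_novel + 1L
      fam <- sprintf("novel-%03d", next_novel)
    }
    mature5p[idx] <- seq5p
    family[idx] <- fam
  }
  # non-cluster loci: novel ones form small shared-sequence families
  free <- which(is.na(truth$cluster_id))
  free_novel <- free[!is_known[free]]
  i <- 1
  while (i <= length(free_novel)) {
    size <- min(sample(1:3, 1), length(free_novel) - i + 1)
    idx <- free_novel[i:(i + size - 1)]
    next_novel <- next_novel + 1L
    mature5p[idx] <- rand_dna(cfg$mature_len)
    family[idx] <- sprintf("novel-%03d", next_novel)
    i <- i + size
  }
  for (j in free[is_known[free]]) {
    next_known <- next_known + 1L
    mature5p[j] <- rand_dna(cfg$mature_len)
    family[j] <- sprintf("mir-%d", 100 + next_known)
  }
  truth$family <- family
  truth$family_known <- is_known
  truth$mature5p_seq <- mature5p
  truth$mature3p_seq <- vapply(mature5p, function(s) {
    mutate_dna(revcomp_dna(s), sample(0:3, 1))
  }, character(1))

  # expression class; cluster members are co-transcribed from one
  # promoter and therefore always expressed
  cls <- character(n_true)
  for (j in seq_len(n_true)) {
    if (!is.na(truth$cluster_id[j])) {
      cls[j] <- "expressed"
    } else if (runif(1) < cfg$extended_mapping_fraction) {
      cls[j] <- "extended"
    } else if (runif(1) < cfg$expressed_fraction) {
      cls[j] <- "expressed"
    } else {
      cls[j] <- "silent"
    }
  }
  truth$expression_class <- cls

  # mature arm genomic intervals (5p arm = transcript 5' end)
  L <- truth$end - truth$start
  plus <- truth$strand == "+"
  truth$m5p_start <- ifelse(plus, truth$start, truth$end - cfg$mature_len)
  truth$m5p_end <- truth$m5p_start + cfg$mature_len
  truth$m3p_start <- ifelse(plus, truth$end - cfg$mature_len, truth$start)
  truth$m3p_end <- truth$m3p_start + cfg$mature_len

  # genome sequence: random background, hairpins written in
  genome <- vapply(contigs, function(ct) rand_dna(cfg$contig_length),
                   character(1))
  for (j in seq_len(n_true)) {
    loop <- rand_dna(L[j] - 2 * cfg$mature_len)
    transcript <- paste0(truth$mature5p_seq[j], loop, truth$mature3p_seq[j])
    gseq <- if (truth$strand[j] == "+") transcript else revcomp_dna(transcript)
    str_sub(genome[truth$contig[j]], truth$start[j] + 1, truth$end[j]) <- gseq
  }

  decoys$id <- if (nrow(decoys)) sprintf("decoy-%04d", seq_len(nrow(decoys)))
               else character(0)
  reference <- truth |>
    filter(.data$family_known) |>
    distinct(.data$family, .keep_all = TRUE) |>
    transmute(ref_id = paste0("ref-", .data$family),
              family = .data$family,
              mature_seq = .data$mature5p_seq)

  list(
    genome = genome,
    truth = select(truth, "id", "contig", "start", "end", "strand",
                   "m5p_start", "m5p_end", "m3p_start", "m3p_end",
                   "mature5p_seq", "mature3p_seq", "family",
                   "family_known", "cluster_id", "expression_class"),
    decoys = select(decoys, "id", "contig", "start", "end", "strand"),
    reference = reference
  )
}

# ---------------------------------------------------------------------------
# per-tool candidate predictions

#' Simulate per-tool candidate predictions over planted truth
#'
#' Each tool detects each planted locus with its sensitivity; emitted
#' intervals are precursor- or mature-length depending on the tool, with
#' optional Gaussian edge jitter, and carry the genomic sequence of the
#' emitted interval. False positives are drawn on decoy loci with the
#' per-tool false-positive rate. Expression-based tool scores are drawn
#' so that true loci stochastically exceed the reliability threshold
#' (mean 12 vs mean 4 for false positives).
#'
#' @param sim result of [simulate_genome()].
#' @param config the [sim_config()] used to build `sim`.
#' @return tibble of candidate predictions with `id`, `contig`, `start`,
#'   `end`, `strand`, `tool`, `score`, `hairpin_sequence`, `origin`,
#'   `origin_id`.
#' @export
simulate_tool_predictions <- function(sim, config) {
  with_seed(config$seed + 1001L, {
    out <- list()
    for (t in seq_len(nrow(config$tools))) {
      tl <- config$tools[t, ]
      # true detections
      if (nrow(sim$truth) > 0) {
        det <- runif(nrow(sim$truth)) < tl$sensitivity
        tr <- sim$truth[det, ]
        if (nrow(tr) > 0) {
          if (tl$emits == "mature") {
            s <- tr$m5p_start
            e <- tr$m5p_end
          } else {
            s <- tr$start
            e <- tr$end
          }
          if (config$positional_jitter_sd > 0) {
            s <- s + round(rnorm(length(s), 0, config$positional_jitter_sd))
            e <- e + round(rnorm(length(e), 0, config$positional_jitter_sd))
            e <- pmax(e, s + 15)
          }
          score <- if (tl$kind == "expression") {
            pmax(0, rnorm(length(s), 12, 2.5))
          } else {
            pmax(0, rnorm(length(s), 50, 10))
          }
          out[[length(out) + 1]] <- tibble(
            contig = tr$contig, start = as.integer(s), end = as.integer(e),
            strand = tr$strand, tool = tl$tool, score = score,
            origin = "true", origin_id = tr$id
          )
        }
      }
      # false positives on decoys
      if (nrow(sim$decoys) > 0) {
        fp <- runif(nrow(sim$decoys)) < tl$fp_rate
        dc <- sim$decoys[fp, ]
        if (nrow(dc) > 0) {
          score <- if (tl$kind == "expression") {
            pmax(0, rnorm(nrow(dc), 4, 1.5))
          } else {
            pmax(0, rnorm(nrow(dc), 35, 10))
          }
          out[[length(out) + 1]] <- tibble(
            contig = dc$contig, start = dc$start, end = dc$end,
            strand = dc$strand, tool = tl$tool, score = score,
            origin = "decoy", origin_id = dc$id
          )
        }
      }
    }
    cand <- bind_rows(out)
    if (nrow(cand) == 0) {
      return(tibble(
        id = character(), contig = character(), start = integer(),
        end = integer(), strand = character(), tool = character(),
        score = numeric(), hairpin_sequence = character(),
        origin = character(), origin_id = character()
      ))
    }
    cand <- cand |>
      mutate(
        start = pmax(0L, .data$start),
        end = as.integer(unname(pmin(nchar(sim$genome[.data$contig]),
                                     .data$end)))
      ) |>
      mutate(hairpin_sequence = extract_genome_seq(
        sim$genome, .data$contig, .data$start, .data$end, .data$strand
      )) |>
      arrange(.data$tool, .data$contig, .data$start) |>
      mutate(id = sprintf("cand-%05d", row_number())) |>
      select("id", everything())
    cand
  })
}

# strand-aware sequence extraction from a named character genome
extract_genome_seq <- function(genome, contig, start, end, strand) {
  s <- str_sub(genome[contig], start + 1, end)
  neg <- strand == "-"
  if (any(neg)) {
    s[neg] <- revcomp_dna(s[neg])
  }
  unname(s)
}

# ---------------------------------------------------------------------------
# read alignments

#' Simulate collapsed small RNA-seq read alignments per library
#'
#' Expressed loci receive rectangular pileups over each mature arm:
#' per-arm depth is Poisson(`read_depth_mean`) and read 5' ends wobble
#' within +/-2 nt of the arm 5' end (probabilities 0.05/0.15/0.6/0.15/
#' 0.05). Extended-mapping loci are tiled edge-to-edge with 1-count
#' reads across the precursor plus 50-nt flanks; silent loci receive no
#' reads. Identical reads are collapsed to one BED row with a count.
#'
#' @inheritParams simulate_tool_predictions
#' @return list of per-library tibbles (`contig`, `start`, `end`,
#'   `name`, `count`, `strand`).
#' @export
simulate_read_alignments <- function(sim, config) {
  w <- config$read_start_wobble
  offs_range <- seq(-w, w)
  wobble_p <- stats::dnorm(offs_range, 0, max(w / 2, 0.5))
  wobble_p <- wobble_p / sum(wobble_p)
  lapply(seq_len(config$n_libraries), function(lib) {
    with_seed(config$seed + 2000L + lib, {
      rows <- list()
      for (j in seq_len(nrow(sim$truth))) {
        tr <- sim$truth[j, ]
        if (tr$expression_class == "expressed") {
          if (runif(1) > config$library_detect_prob) next
          for (arm in c("m5p", "m3p")) {
            a_start <- tr[[paste0(arm, "_start")]]
            a_end <- tr[[paste0(arm, "_end")]]
            depth <- rpois(1, config$read_depth_mean)
            if (depth == 0) next
            offs <- offs_range[sample.int(length(offs_range), depth,
                                          replace = TRUE,
                                          prob = wobble_p)]
            cnt <- table(offs)
            for (k in seq_along(cnt)) {
              off <- as.integer(names(cnt)[k])
              if (tr$strand == "+") {
                s <- a_start + off
                e <- a_end + off
              } else {
                s <- a_start - off
                e <- a_end - off
              }
              rows[[length(rows) + 1]] <- tibble(
                contig = tr$contig, start = as.integer(s),
                end = as.integer(e), count = as.integer(cnt[k]),
                strand = tr$strand
              )
            }
          }
        } else if (tr$expression_class == "extended") {
          starts <- unique(c(seq(tr$start - 50L, tr$end + 50L - 30L,
                                 by = 2L),
                             tr$end + 50L - 30L))
          rows[[length(rows) + 1]] <- tibble(
            contig = tr$contig, start = as.integer(starts),
            end = as.integer(starts + 30L), count = 1L,
            strand = tr$strand
          )
        }
      }
      reads <- bind_rows(rows)
      if (nrow(reads) == 0) {
        reads <- tibble(contig = character(), start = integer(),
                        end = integer(), count = integer(),
                        strand = character())
      }
      reads |>
        group_by(.data$contig, .data$start, .data$end, .data$strand) |>
        summarise(count = sum(.data$count), .groups = "drop") |>
        arrange(.data$contig, .data$start, .data$end, .data$strand) |>
        mutate(name = sprintf("read-%06d", row_number())) |>
        select("contig", "start", "end", "name", "count", "strand")
    })
  })
}

# ---------------------------------------------------------------------------
# 3'-UTR alignments with planted target sites

#' Simulate orthologous 3'-UTR alignments with planted seed sites
#'
#' A panel of planted miRNAs is chosen; each gene carries a planted
#' site of one panel miRNA with probability `site_prob` (non-DE genes)
#' or the odds-scaled probability (DE genes), so the odds of a DE gene
#' carrying a site equals `enrichment_odds` times the non-DE odds.
#' Planted sites are the exact reverse complement of mature nt 2-7,
#' written at identical alignment columns in the conserved species
#' rows; other rows diverge at `utr_divergence` per base. Occasional
#' deletions (gap runs) are planted away from site columns.
#'
#' @inheritParams simulate_tool_predictions
#' @return list with `alignments` (list per gene of named species
#'   rows), `target_truth` (tibble gene/mirna_id/aln_col), `de_genes`,
#'   `universe`, `panel` (tibble of panel miRNAs with matures).
#' @export
simulate_utr_set <- function(sim, config) {
  with_seed(config$seed + 3001L, {
    if (nrow(sim$truth) == 0) {
      abort("simulate_utr_set needs at least one planted miRNA")
    }
    panel <- head(sim$truth, config$n_target_mirnas) |>
      select("id", mature = "mature5p_seq")
    n_g <- config$n_genes
    len <- config$utr_len
    genes <- sprintf("gene%04d", seq_len(n_g))
    de_genes <- sort(sample(genes, min(config$n_de_genes, n_g)))
    p0 <- config$site_prob
    odds0 <- p0 / (1 - p0)
    p1 <- (config$enrichment_odds * odds0) /
      (1 + config$enrichment_odds * odds0)
    sp <- config$utr_species
    cons <- config$site_conserved_species
    alphabet <- c(DNA_BASES, "-")

    # reference rows as an integer matrix (1..4 = A,C,G,T; 5 = gap)
    ref <- matrix(sample.int(4, n_g * len, replace = TRUE), nrow = n_g)
    de_flag <- genes %in% de_genes
    has_site <- runif(n_g) < ifelse(de_flag, p1, p0)
    pick <- sample.int(nrow(panel), n_g, replace = TRUE)
    site_col <- sample(10:(len - 15), n_g, replace = TRUE)  # 0-based
    motif_int <- lapply(seed_site_motif(panel$mature), function(m) {
      match(strsplit(m, "", fixed = TRUE)[[1]], DNA_BASES)
    })
    for (g in which(has_site)) {
      ref[g, (site_col[g] + 1):(site_col[g] + 6)] <- motif_int[[pick[g]]]
    }

    rows_int <- setNames(vector("list", length(sp)), sp)
    rows_int[[sp[1]]] <- ref
    for (s in sp[-1]) {
      mut <- matrix(runif(n_g * len) < config$utr_divergence, nrow = n_g)
      for (g in which(has_site)) {
        win <- (site_col[g] + 1):(site_col[g] + 6)
        if (s %in% cons) {
          mut[g, win] <- FALSE
        } else {
          # destroy the site in non-conserved species
          mut[g, site_col[g] + sample(6, 2)] <- TRUE
        }
      }
      delta <- matrix(sample.int(3, n_g * len, replace = TRUE), nrow = n_g)
      out <- ifelse(mut, (ref - 1 + delta) %% 4 + 1, ref)
      # occasional deletion (gap run) away from the site
      has_gap <- runif(n_g) < 0.3
      glen <- sample(1:3, n_g, replace = TRUE)
      for (g in which(has_gap)) {
        avoid <- if (has_site[g]) {
          (site_col[g] - glen[g]):(site_col[g] + 6)
        } else {
          integer(0)
        }
        gpos <- sample(setdiff(seq_len(len - glen[g]), avoid), 1)
        out[g, gpos:(gpos + glen[g] - 1)] <- 5L
      }
      rows_int[[s]] <- out
    }

    alns <- lapply(seq_len(n_g), function(g) {
      setNames(vapply(sp, function(s) {
        paste(alphabet[rows_int[[s]][g, ]], collapse = "")
      }, character(1)), sp)
    })
    names(alns) <- genes
    list(
      alignments = alns,
      target_truth = tibble(gene = genes[has_site],
                            mirna_id = panel$id[pick[has_site]],
                            aln_col = site_col[has_site]),
      de_genes = de_genes,
      universe = genes,
      panel = panel
    )
  })
}

# ---------------------------------------------------------------------------
# species x miRNA expression matrix on a planted tree

#' Simulate cross-species miRNA expression counts on a planted tree
#'
#' miRNA presence evolves from the root (present with
#' `root_presence_prob`) along each branch with loss/gain
#' probabilities `1 - exp(-rate * branch_length)`; present miRNAs
#' receive Poisson(`read_depth_mean`) counts in each of two replicate
#' libraries per species.
#'
#' @inheritParams simulate_tool_predictions
#' @return list with `counts` (tibble species/library/mirna_id/count),
#'   `presence` (species x miRNA logical matrix), `tree` (ape phylo of
#'   the planted topology).
#' @export
simulate_species_expression <- function(sim, config) {
  with_seed(config$seed + 4001L, {
    tree <- ape::read.tree(text = config$planted_tree)
    n_tip <- length(tree$tip.label)
    n_mir <- nrow(sim$truth)
    mir_ids <- sim$truth$id
    n_node <- n_tip + tree$Nnode
    root <- n_tip + 1L
    state <- matrix(FALSE, n_node, n_mir)
    state[root, ] <- runif(n_mir) < config$root_presence_prob
    # preorder edge traversal; event probabilities scale with branch
    # length (length 1 where the tree carries none)
    ord <- ape::reorder.phylo(tree, "cladewise")
    edges <- ord$edge
    blens <- ord$edge.length %||% rep(1, nrow(edges))
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]
      chd <- edges[e, 2]
      p_loss <- 1 - exp(-config$loss_rate * blens[e])
      p_gain <- 1 - exp(-config$gain_rate * blens[e])
      u <- runif(n_mir)
      state[chd, ] <- ifelse(state[par, ], u >= p_loss, u < p_gain)
    }
    presence <- state[seq_len(n_tip), , drop = FALSE]
    rownames(presence) <- tree$tip.label
    colnames(presence) <- mir_ids
    counts <- list()
    for (s in tree$tip.label) {
      for (lib in 1:2) {
        cnt <- ifelse(presence[s, ], rpois(n_mir, config$read_depth_mean), 0L)
        counts[[length(counts) + 1]] <- tibble(
          species = s, library = sprintf("%s_rep%d", s, lib),
          mirna_id = mir_ids, count = as.integer(cnt)
        )
      }
    }
    list(counts = bind_rows(counts), presence = presence, tree = tree)
  })
}

# ---------------------------------------------------------------------------
# auxiliary truth tables and full on-disk input set

#' Simulate the secondary-structure triage table
#'
#' Emulates comparing each 50-nt-extended locus against a structured-RNA
#' reference: planted miRNAs hit a known miRNA structure or nothing;
#' decoys (modelled as fragments of other structured ncRNAs) hit another
#' ncRNA class with probability `decoy_ncrna_fraction`.
#'
#' @inheritParams simulate_tool_predictions
#' @return tibble with `origin_id`, `hit_class`.
#' @export
simulate_structure_hits <- function(sim, config) {
  with_seed(config$seed + 5001L, {
    tr <- tibble(
      origin_id = sim$truth$id,
      hit_class = ifelse(runif(nrow(sim$truth)) < 0.5,
                         "mirna_structure_hit", "no_hit")
    )
    dc <- tibble(
      origin_id = sim$decoys$id,
      hit_class = ifelse(runif(nrow(sim$decoys)) < config$decoy_ncrna_fraction,
                         "other_ncrna_hit", "no_hit")
    )
    bind_rows(tr, dc)
  })
}

#' Simulate a minimal gene annotation
#'
#' Writes protein-coding genes whose introns host a subset of the
#' planted miRNAs (exons kept clear of the precursors), matching the
#' intragenic-miRNA situation the conflict filter must tolerate.
#'
#' @inheritParams simulate_tool_predictions
#' @return tibble of annotation features (`contig`, `start`, `end`,
#'   `strand`, `type`, `ID`).
#' @export
simulate_annotation <- function(sim, config) {
  with_seed(config$seed + 6001L, {
    host <- sim$truth[runif(nrow(sim$truth)) < 0.1, ]
    rows <- list()
    for (j in seq_len(nrow(host))) {
      h <- host[j, ]
      gs <- max(0L, h$start - 2000L)
      ge <- h$end + 2000L
      gid <- sprintf("gene-host%03d", j)
      rows[[length(rows) + 1]] <- tibble(
        contig = h$contig,
        start = c(gs, gs, h$end + 1500L),
        end = c(ge, h$start - 1500L, ge),
        strand = h$strand,
        type = c("gene", "exon", "exon"),
        ID = c(gid, paste0(gid, ".e1"), paste0(gid, ".e2")),
        biotype = "protein_coding"
      )
    }
    bind_rows(rows)
  })
}

#' Write every simulated pipeline input to a directory
#'
#' Runs all generators for one configuration and writes: the genome
#' FASTA, truth and decoy GFF3, per-tool candidate GFF3s, per-library
#' collapsed-read BEDs, the reference mature FASTA (family labels in
#' headers as `id family=<label>`), the structure-triage TSV, the
#' annotation GFF3, per-gene aligned UTR FASTAs, DE/universe gene
#' lists, the species expression count TSV, the planted tree (Newick)
#' and the configuration as YAML.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, the in-memory simulation objects.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))

  truth_gff <- sim$truth |>
    transmute(.data$contig, .data$start, .data$end, .data$strand,
              type = "pre_miRNA", ID = .data$id,
              family = .data$family,
              expression_class = .data$expression_class,
              cluster_id = ifelse(is.na(.data$cluster_id), NA_character_,
                                  as.character(.data$cluster_id)))
  write_gff3(truth_gff, file.path(dir, "truth.gff3"))
  write_gff3(
    transmute(sim$decoys, .data$contig, .data$start, .data$end,
              .data$strand, type = "decoy", ID = .data$id),
    file.path(dir, "decoys.gff3")
  )

  cand <- simulate_tool_predictions(sim, config)
  dir.create(file.path(dir, "tools"), showWarnings = FALSE)
  for (tl in unique(config$tools$tool)) {
    tc <- filter(cand, .data$tool == tl)
    write_gff3(
      transmute(tc, .data$contig, .data$start, .data$end, .data$strand,
                type = "miRNA_candidate", score = .data$score,
                ID = .data$id, tool = .data$tool,
                hairpin_sequence = .data$hairpin_sequence,
                origin_id = .data$origin_id),
      file.path(dir, "tools", paste0(tl, ".gff3"))
    )
  }

  libs <- simulate_read_alignments(sim, config)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  for (i in seq_along(libs)) {
    write_bed(libs[[i]], file.path(dir, "reads", sprintf("lib%02d.bed", i)))
  }

  ref <- setNames(sim$reference$mature_seq,
                  paste0(sim$reference$ref_id, " family=", sim$reference$family))
  write_fasta(ref, file.path(dir, "reference_matures.fa"))

  hits <- simulate_structure_hits(sim, config)
  readr::write_tsv(hits, file.path(dir, "structure_hits.tsv"),
                   progress = FALSE)

  ann <- simulate_annotation(sim, config)
  if (nrow(ann) > 0) {
    write_gff3(ann, file.path(dir, "annotation.gff3"))
  } else {
    writeLines("##gff-version 3", file.path(dir, "annotation.gff3"))
  }

  utr <- simulate_utr_set(sim, config)
  write_alignments(utr$alignments, file.path(dir, "utrs"))
  dir.create(file.path(dir, "gene_sets"), showWarnings = FALSE)
  write_gene_list(utr$de_genes, file.path(dir, "gene_sets", "de_down.txt"))
  write_gene_list(utr$universe, file.path(dir, "universe.txt"))
  readr::write_tsv(utr$target_truth, file.path(dir, "target_truth.tsv"),
                   progress = FALSE)

  spx <- simulate_species_expression(sim, config)
  readr::write_tsv(spx$counts, file.path(dir, "species_counts.tsv"),
                   progress = FALSE)
  ape::write.tree(spx$tree, file.path(dir, "planted_tree.nwk"))

  cfg_plain <- config
  class(cfg_plain) <- NULL
  cfg_plain$tools <- as.list(as.data.frame(cfg_plain$tools))
  yaml::write_yaml(cfg_plain, file.path(dir, "sim_config.yaml"))

  invisible(list(sim = sim, candidates = cand, libraries = libs,
                 structure_hits = hits, annotation = ann, utr = utr,
                 species_expression = spx))
}
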