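#' Pipeline configuration
#'
#' Collects every input path and threshold of the catalogue build.
#' Defaults are the constants of the filter cascade: adapter
#' TGGAATTCTCGGGTGCCAAGG, quality 20, length 15, score threshold 7,
#' 100-nt overlap window, 50-nt extension flank, homology span 0.9
#' with no gaps at significance 1e-7, 10-kb cluster distance, FDR
#' 0.05.
#'
#' @param input_dir directory as written by [simulate_inputs()];
#'   individual paths below override its conventions.
#' @param genome,tool_gffs,reads_beds,reference_fasta,structure_hits,annotation,utr_dir,de_gene_lists,universe,species_counts
#'   input paths (`tool_gffs`, `reads_beds`, `de_gene_lists` are
#'   vectors; optional inputs may be `NULL`).
#' @param adapter,min_quality,min_length read-trimming parameters
#'   (used by the `trim` entry point; the pipeline itself consumes
#'   collapsed alignments).
#' @param score_threshold,max_mismatch,dedup_window,extension_flank
#'   consensus-cascade parameters.
#' @param homology_span,homology_max_gaps,homology_cutoff homology
#'   hit filter.
#' @param score_tools tools whose candidates are subject to the score
#'   rule (expression-based predictors).
#' @param min_reads,min_sharpness,max_gap_coverage_fraction,max_flank_coverage_fraction,profile_flank
#'   expression-verification parameters.
#' @param cluster_max_gap,family_min_identity,require_seed_identity
#'   catalogue-structure parameters.
#' @param required_species,fdr target/enrichment parameters.
#' @param n_boot,presence_min_reads phylogeny parameters.
#' @param seed governs the bootstrap.
#' @param out_dir where stage outputs are written (`NULL`: nowhere).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            genome = NULL, tool_gffs = NULL,
                            reads_beds = NULL, reference_fasta = NULL,
                            structure_hits = NULL, annotation = NULL,
                            utr_dir = NULL, de_gene_lists = NULL,
                            universe = NULL, species_counts = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_quality = 20, min_length = 15,
                            score_threshold = 7, max_mismatch = 1,
                            dedup_window = 100, extension_flank = 50,
                            homology_span = 0.9, homology_max_gaps = 0,
                            homology_cutoff = 1e-7,
                            score_tools = "mirdeep",
                            min_reads = 5, min_sharpness = 0.6,
                            max_gap_coverage_fraction = 0.1,
                            max_flank_coverage_fraction = 0.1,
                            profile_flank = 20,
                            cluster_max_gap = 10000,
                            family_min_identity = 0.9,
                            require_seed_identity = TRUE,
                            required_species = c("nfu", "dre"),
                            fdr = 0.05,
                            n_boot = 1000, presence_min_reads = 5,
                            seed = 1, out_dir = NULL) {
  if (!is.null(input_dir)) {
    pick <- function(x, p) x %||% {
      full <- file.path(input_dir, p)
      if (file.exists(full) || dir.exists(full)) full else NULL
    }
    genome <- pick(genome, "genome.fa")
    reference_fasta <- pick(reference_fasta, "reference_matures.fa")
    structure_hits <- pick(structure_hits, "structure_hits.tsv")
    annotation <- pick(annotation, "annotation.gff3")
    utr_dir <- pick(utr_dir, "utrs")
    universe <- pick(universe, "universe.txt")
    species_counts <- pick(species_counts, "species_counts.tsv")
    tool_gffs <- tool_gffs %||%
      list.files(file.path(input_dir, "tools"), pattern = "\\.gff3$",
                 full.names = TRUE)
    reads_beds <- reads_beds %||%
      list.files(file.path(input_dir, "reads"), pattern = "\\.bed$",
                 full.names = TRUE)
    de_gene_lists <- de_gene_lists %||% {
      gs <- list.files(file.path(input_dir, "gene_sets"),
                       pattern = "\\.txt$", full.names = TRUE)
      if (length(gs)) gs else NULL
    }
  }
  stopifnot(
    score_threshold >= 0, dedup_window >= 0,
    homology_span >= 0 && homology_span <= 1,
    fdr > 0 && fdr < 1, cluster_max_gap >= 0,
    family_min_identity >= 0 && family_min_identity <= 1
  )
  cfg <- as.list(environment())
  cfg$pick <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full catalogue build
#'
#' Executes, in fixed order: candidate ingestion, gap-free
#' re-anchoring, reference homology matching, the reliability filter
#' (homology rescue or score threshold), overlap de-duplication,
#' secondary-structure triage of unrescued loci, annotation-conflict
#' removal, read-profile expression verification across libraries,
#' family assignment plus novel-family clustering, genomic cluster
#' calling, and (when inputs are present) seed-match target
#' enrichment and the cross-species expression phylogeny. Every
#' removal is recorded with exactly one rule in the audit trail, and
#' per-stage counts satisfy kept + removed = input.
#'
#' @param config a [pipeline_config()].
#' @return a `mirforge_run` list: `catalogue`, `clusters`,
#'   `families`, `summary`, `verdicts`, `enrichment`, `tree`,
#'   `manifest`, `audit`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- read_fasta(config$genome)
  manifest <- list()
  audit <- list()
  note <- function(stage, n_in, n_kept) {
    manifest[[length(manifest) + 1]] <<-
      tibble(stage = stage, n_in = n_in, n_kept = n_kept,
             n_removed = n_in - n_kept)
  }
  log_removed <- function(stage, ids, reasons) {
    if (length(ids) > 0) {
      audit[[length(audit) + 1]] <<-
        tibble(stage = stage, id = ids, reason = reasons)
    }
  }

  # -- ingest per-tool candidates -------------------------------------
  cand <- bind_rows(lapply(config$tool_gffs, function(f) {
    g <- read_gff3(f)
    if (nrow(g) == 0) {
      return(NULL)
    }
    transmute(g, id = .data$ID, .data$contig, .data$start, .data$end,
              .data$strand, tool = .data$tool,
              score = as.numeric(.data$score),
              hairpin_sequence = .data$hairpin_sequence,
              origin_id = if ("origin_id" %in% names(g)) .data$origin_id
                          else NA_character_)
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    cand <- tibble(id = character(), contig = character(),
                   start = integer(), end = integer(),
                   strand = character(), tool = character(),
                   score = numeric(), hairpin_sequence = character(),
                   origin_id = character())
  }
  cand <- arrange(cand, .data$id)
  note("ingest", nrow(cand), nrow(cand))

  # -- gap-free re-anchoring ------------------------------------------
  anc <- anchor_gap_free(cand, genome, max_mismatch = config$max_mismatch)
  note("anchor_gap_free", nrow(cand), nrow(anc$anchored))
  log_removed("anchor_gap_free", anc$dropped$id, anc$dropped$reason)
  cand <- anc$anchored

  # -- reference homology + reliability filter ------------------------
  reference <- read_reference_matures(config$reference_fasta)
  ref_hits <- match_reference(cand, reference,
                              max_mismatch = config$max_mismatch)
  rel <- reliability_filter(cand, ref_hits,
                            score_threshold = config$score_threshold,
                            max_mismatch = config$max_mismatch,
                            score_tools = config$score_tools)
  note("reliability_filter", nrow(cand), nrow(rel$kept))
  log_removed("reliability_filter", rel$dropped$id, rel$dropped$reason)
  cand <- select(rel$kept, -"reason")

  # -- overlap de-duplication -----------------------------------------
  loci <- deduplicate_overlaps(cand, window = config$dedup_window)
  note("deduplicate_overlaps", nrow(cand), nrow(loci))
  merged_away <- setdiff(cand$id, loci$id)
  log_removed("deduplicate_overlaps", merged_away,
              rep("merged into higher-scoring overlapping locus",
                  length(merged_away)))

  # -- structure triage of loci without reference hits ----------------
  rescued <- loci$id %in% ref_hits$candidate_id[
    ref_hits$mismatches <= config$max_mismatch
  ]
  need_triage <- loci[!rescued, , drop = FALSE]
  skip_triage <- loci[rescued, , drop = FALSE]
  if (!is.null(config$structure_hits) && nrow(need_triage) > 0) {
    hits <- readr::read_tsv(config$structure_hits, show_col_types = FALSE,
                            progress = FALSE)
    id_col <- if (!is.null(need_triage$origin_id) &&
                  "origin_id" %in% names(hits)) "origin_id" else "id"
    tri <- extension_triage(need_triage, hits, id_col = id_col)
    note("extension_triage", nrow(loci),
         nrow(tri$kept) + nrow(skip_triage))
    log_removed("extension_triage", tri$dropped$id,
                rep("extended sequence hits another ncRNA class",
                    nrow(tri$dropped)))
    loci <- bind_rows(skip_triage, select(tri$kept, -"triage")) |>
      arrange(.data$contig, .data$start)
  } else {
    note("extension_triage", nrow(loci), nrow(loci))
  }

  # -- annotation conflicts -------------------------------------------
  ann <- if (!is.null(config$annotation)) {
    read_gff3(config$annotation)
  } else {
    NULL
  }
  conf <- remove_annotation_conflicts(loci, ann)
  note("annotation_conflicts", nrow(loci), nrow(conf$kept))
  log_removed("annotation_conflicts", conf$dropped$id,
              conf$dropped$reason)
  loci <- conf$kept

  # -- expression verification ----------------------------------------
  libraries <- lapply(config$reads_beds, read_bed)
  names(libraries) <- basename(config$reads_beds %||% character())
  verdicts <- verify_expression(loci, libraries, genome, config)
  catalogue <- verdicts$catalogue
  note("expression_verification", nrow(loci), nrow(catalogue))
  log_removed("expression_verification", verdicts$removed$id,
              verdicts$removed$reason)

  # -- families --------------------------------------------------------
  ref_fam <- select(reference, "family", "mature_seq")
  catalogue <- catalogue |>
    mutate(assign_seq = coalesce(.data$mature5p_seq,
                                 .data$hairpin_sequence))
  fam <- assign_family(
    rename(catalogue, mature5p_seq_orig = "mature5p_seq") |>
      mutate(mature5p_seq = .data$assign_seq),
    ref_fam,
    min_identity = config$family_min_identity,
    require_seed_identity = config$require_seed_identity
  )
  catalogue$family <- fam$family
  un <- which(catalogue$family == "unassigned")
  if (length(un) > 0) {
    nf <- cluster_novel_families(
      tibble(id = catalogue$id[un],
             mature5p_seq = catalogue$assign_seq[un]),
      min_identity = config$family_min_identity
    )
    catalogue$family[un] <- nf$family
  }
  catalogue$assign_seq <- NULL

  # -- clusters --------------------------------------------------------
  clusters <- call_clusters(catalogue, max_gap = config$cluster_max_gap)
  compositions <- if (nrow(clusters) > 0) {
    vapply(seq_len(nrow(clusters)), function(i) {
      cluster_composition(clusters[i, ],
                          setNames(catalogue$family, catalogue$id))
    }, character(1))
  } else {
    character(0)
  }
  clusters$composition <- compositions
  summary_tab <- summarize_catalogue(catalogue, clusters)

  # -- targets + enrichment -------------------------------------------
  enrichment <- NULL
  target_map <- NULL
  if (!is.null(config$utr_dir) && !is.null(config$de_gene_lists) &&
      !is.null(config$universe)) {
    alns <- read_alignments(config$utr_dir)
    panel <- catalogue |>
      filter(!is.na(.data$mature5p_seq)) |>
      transmute(mirna_id = .data$id, mature = .data$mature5p_seq)
    if (nrow(panel) > 0) {
      target_map <- find_seed_sites(panel, alns, config$required_species)
      sets <- lapply(config$de_gene_lists, read_gene_list)
      names(sets) <- sub("\\.txt$", "", basename(config$de_gene_lists))
      enrichment <- enrich_gene_sets(
        target_map, sets, read_gene_list(config$universe),
        mode = "set-level", fdr = config$fdr
      )
    }
  }

  # -- phylogeny -------------------------------------------------------
  tree <- NULL
  presence <- NULL
  if (!is.null(config$species_counts)) {
    counts <- readr::read_tsv(config$species_counts,
                              show_col_types = FALSE, progress = FALSE)
    presence <- build_presence_matrix(
      counts, min_reads = config$presence_min_reads
    )
    tree <- bootstrap_tree(presence, n_boot = config$n_boot,
                           seed = config$seed)
  }

  manifest <- bind_rows(manifest)
  audit <- if (length(audit)) bind_rows(audit) else
    tibble(stage = character(), id = character(), reason = character())
  res <- structure(
    list(
      catalogue = catalogue, clusters = clusters,
      families = count(catalogue, .data$family, name = "n_members"),
      summary = summary_tab, verdicts = verdicts$per_locus,
      enrichment = enrichment, target_map = target_map,
      presence = presence, tree = tree,
      manifest = manifest, audit = audit,
      config_hash = config_hash(config)
    ),
    class = "mirforge_run"
  )
  if (!is.null(config$out_dir)) {
    write_run_outputs(res, config$out_dir)
  }
  res
}

# read reference matures; family labels from "family=" header tags
read_reference_matures <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  fam <- ifelse(grepl("family=", full),
                sub(".*family=([^ ]+).*", "\\1", full), id)
  tibble(ref_id = id, family = fam,
         mature_seq = as.character(unname(x)))
}

# per-locus expression verification across libraries
verify_expression <- function(loci, libraries, genome, config) {
  if (nrow(loci) == 0 || length(libraries) == 0) {
    cat0 <- mutate(loci, status = character(0),
                   mature5p_seq = character(0),
                   mature3p_seq = character(0))
    return(list(
      catalogue = cat0,
      removed = tibble(id = character(), reason = character()),
      per_locus = tibble(id = character(), verdict = character())
    ))
  }
  conservation_tools <- setdiff(
    unique(unlist(strsplit(loci$supporting_tools, ","))),
    config$score_tools
  )
  rows <- list()
  removed <- list()
  per_locus <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    # profile over the union span of the merged group, the best
    # available estimate of the full hairpin extent
    ploc <- locus
    if (all(c("span_start", "span_end") %in% names(ploc))) {
      ploc$start <- ploc$span_start
      ploc$end <- ploc$span_end
    }
    profiles <- lapply(libraries, function(lib) {
      profile_locus(ploc, lib, flank = config$profile_flank,
                    min_block_reads = config$min_reads)
    })
    verdicts <- lapply(profiles, classify_profile,
                       min_reads = config$min_reads,
                       min_sharpness = config$min_sharpness,
                       max_gap_coverage_fraction =
                         config$max_gap_coverage_fraction,
                       max_flank_coverage_fraction =
                         config$max_flank_coverage_fraction)
    states <- vapply(verdicts, function(v) v$verdict, character(1))
    per_locus[[length(per_locus) + 1]] <- tibble(
      id = locus$id, library = names(libraries) %||%
        sprintf("lib%02d", seq_along(libraries)),
      verdict = states
    )
    has_conservation <- any(strsplit(locus$supporting_tools, ",")[[1]]
                            %in% conservation_tools)
    if (any(states == "verified")) {
      best <- which(states == "verified")
      best <- best[which.max(vapply(profiles[best],
                                    function(p) p$total_reads,
                                    numeric(1)))]
      v <- verdicts[[best]]
      m5 <- v$mature5p
      m3 <- v$mature3p
      locus$status <- "verified"
      locus$mature5p_seq <- extract_genome_seq(
        genome, locus$contig, m5[["start"]], m5[["end"]], locus$strand
      )
      locus$mature3p_seq <- if (is.null(m3)) NA_character_ else
        extract_genome_seq(genome, locus$contig, m3[["start"]],
                           m3[["end"]], locus$strand)
      rows[[length(rows) + 1]] <- locus
    } else if (all(states == "no_expression")) {
      if (has_conservation) {
        locus$status <- "putative_unexpressed"
        locus$mature5p_seq <- NA_character_
        locus$mature3p_seq <- NA_character_
        rows[[length(rows) + 1]] <- locus
      } else {
        removed[[length(removed) + 1]] <- tibble(
          id = locus$id,
          reason = "no expression and no conservation support"
        )
      }
    } else {
      bad <- states[states != "no_expression"]
      removed[[length(removed) + 1]] <- tibble(
        id = locus$id,
        reason = sprintf("read profile %s",
                         names(sort(table(bad), decreasing = TRUE))[1])
      )
    }
  }
  list(
    catalogue = if (length(rows)) bind_rows(rows) else
      mutate(loci[0, ], status = character(0),
             mature5p_seq = character(0), mature3p_seq = character(0)),
    removed = if (length(removed)) bind_rows(removed) else
      tibble(id = character(), reason = character()),
    per_locus = bind_rows(per_locus)
  )
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL  # output location does not change the analysis
  plain <- plain[order(names(plain))]
  txt <- paste(utils::capture.output(utils::str(plain, vec.len = 1e6)),
               collapse = "\n")
  # small deterministic FNV-1a hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write all pipeline outputs to a directory
#'
#' @param res a `mirforge_run`.
#' @param dir output directory.
#' @export
write_run_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_gff <- res$catalogue |>
    transmute(.data$contig, .data$start, .data$end, .data$strand,
              type = "pre_miRNA", score = .data$best_score,
              ID = .data$id, status = .data$status,
              tools = .data$supporting_tools, family = .data$family)
  write_gff3(cat_gff, file.path(dir, "catalogue.gff3"))
  readr::write_tsv(select(res$clusters, -"members"),
                   file.path(dir, "clusters.tsv"), progress = FALSE)
  readr::write_tsv(res$families, file.path(dir, "families.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$summary, file.path(dir, "summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$verdicts, file.path(dir, "verdicts.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$audit, file.path(dir, "audit.tsv"),
                   progress = FALSE)
  if (!is.null(res$enrichment)) {
    readr::write_tsv(tidy.mirforge_enrichment(res$enrichment),
                     file.path(dir, "enrichment.tsv"), progress = FALSE)
  }
  if (!is.null(res$tree)) {
    write_boot_tree(res$tree, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}

#' Human-readable attrition report for a pipeline run
#'
#' Prints per-stage input/kept/removed counts with percentages in the
#' style of a filter ledger ("of N candidates, k (x%) kept").
#'
#' @param res a `mirforge_run` (or its `manifest` tibble).
#' @return character vector of report lines, invisibly printed.
#' @export
summarize_run <- function(res) {
  manifest <- if (inherits(res, "mirforge_run")) res$manifest else res
  lines <- vapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    pct <- if (m$n_in > 0) 100 * m$n_kept / m$n_in else 0
    sprintf("%-25s %5d in, %5d kept (%.1f%%), %5d removed",
            m$stage, m$n_in, m$n_kept, pct, m$n_removed)
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.mirforge_run <- function(x, ...) {
  cat("<mirforge_run>\n")
  summarize_run(x)
  cat(sprintf("\ncatalogue: %d entries (%d verified), %d clusters, %d families\n",
              nrow(x$catalogue),
              sum(x$catalogue$status == "verified"),
              nrow(x$clusters), nrow(x$families)))
  invisible(x)
}

#' @export
glance.mirforge_run <- function(x, ...) {
  bind_cols(tibble(config_hash = x$config_hash), x$summary)
}
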