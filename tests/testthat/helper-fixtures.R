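# Shared fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny simulation config: fast to generate, all features exercised
tiny_config <- function(seed = 7, n_contigs = 2, contig_length = 60000,
                        n_true_mirnas = 12, n_decoys = 6,
                        min_locus_separation = 300, n_genes = 80,
                        n_de_genes = 20, n_target_mirnas = 5, ...) {
  sim_config(
    seed = seed, n_contigs = n_contigs, contig_length = contig_length,
    n_true_mirnas = n_true_mirnas, n_decoys = n_decoys,
    min_locus_separation = min_locus_separation, n_genes = n_genes,
    n_de_genes = n_de_genes, n_target_mirnas = n_target_mirnas,
    ...
  )
}

# a read tibble from sequences with uniform quality
make_reads <- function(seqs, q = 40) {
  tibble::tibble(
    id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    quality = strrep(intToUtf8(q + 33), nchar(seqs))
  )
}

RA3 <- "TGGAATTCTCGGGTGCCAAGG"

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force single-linkage grouping of intervals: transitive closure
# over the pairwise "within max_gap" relation (the O(n^2) oracle)
brute_force_groups <- function(df, max_gap, inclusive) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (df$contig[i] != df$contig[j]) next
      gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
      near <- if (inclusive) gap <= max_gap else gap < max_gap
      adj[i, j] <- near
    }
  }
  # transitive closure (Floyd-Warshall style)
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[adj[i, ]] <- cur
      comp[i] <- cur
    }
  }
  comp
}

# canonical form of a grouping for comparison: sorted member-id sets
grouping_sets <- function(ids, groups) {
  unname(sort(vapply(split(ids, groups), function(s) {
    paste(sort(s), collapse = ",")
  }, character(1))))
}
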