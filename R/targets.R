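#' Find conserved seed-match target sites in aligned 3'-UTRs
#'
#' For each miRNA the site motif is the reverse complement of the
#' seed region (mature nt 2-7). A site is reported where the 6-mer
#' occurs, ungapped, at the same alignment columns in every required
#' species row. Positions are reported both as alignment columns and
#' as 0-based positions in the degapped reference (first required)
#' species row.
#'
#' @param matures tibble with `mirna_id` (or `id`) and `mature` (or
#'   `mature5p_seq`) columns.
#' @param alignments named list (gene) of named character vectors
#'   (species rows of equal length; `-` for gaps).
#' @param required_species species that must all carry the site;
#'   must be present in every alignment.
#' @return tibble of sites: `mirna_id`, `gene`, `aln_col` (0-based),
#'   `utr_pos` (0-based in the reference species), `site`.
#' @export
find_seed_sites <- function(matures, alignments, required_species) {
  id_col <- if ("mirna_id" %in% names(matures)) "mirna_id" else "id"
  mat_col <- if ("mature" %in% names(matures)) "mature" else "mature5p_seq"
  if (any(nchar(matures[[mat_col]]) < 7)) {
    abort("find_seed_sites: mature sequences must be at least 7 nt")
  }
  if (length(alignments) == 0 || nrow(matures) == 0) {
    return(tibble(mirna_id = character(), gene = character(),
                  aln_col = integer(), utr_pos = integer(),
                  site = character()))
  }
  for (g in names(alignments)) {
    miss <- setdiff(required_species, names(alignments[[g]]))
    if (length(miss) > 0) {
      abort(sprintf("find_seed_sites: species %s missing from alignment %s",
                    paste(miss, collapse = ","), g))
    }
    if (length(unique(nchar(alignments[[g]]))) != 1) {
      abort(sprintf("find_seed_sites: unequal row lengths in alignment %s", g))
    }
  }
  motifs <- seed_site_motif(matures[[mat_col]])
  genes <- names(alignments)
  # concatenate each species' rows across genes with a separator that
  # can never match a DNA motif; one fixed-string scan per
  # (miRNA, species)
  sep <- "######"
  widths <- vapply(alignments, function(a) nchar(a[[1]]), integer(1))
  offsets <- cumsum(c(0, head(widths + nchar(sep), -1)))
  names(offsets) <- genes
  concat <- lapply(required_species, function(s) {
    paste(vapply(genes, function(g) normalize_dna(alignments[[g]][[s]]),
                 character(1)), collapse = sep)
  })
  names(concat) <- required_species
  hit_mirna <- character(0)
  hit_gene <- character(0)
  hit_col <- integer(0)
  hit_site <- character(0)
  for (k in seq_len(nrow(matures))) {
    hit_sets <- lapply(concat, function(txt) {
      p <- unlist(gregexpr(motifs[k], txt, fixed = TRUE))
      p[p > 0]
    })
    common <- Reduce(intersect, hit_sets)
    if (length(common) == 0) next
    gi <- findInterval(common - 1, offsets)
    col0 <- as.integer((common - 1) - offsets[gi])
    hit_mirna <- c(hit_mirna, rep(matures[[id_col]][k], length(common)))
    hit_gene <- c(hit_gene, genes[gi])
    hit_col <- c(hit_col, col0)
    hit_site <- c(hit_site, rep(motifs[k], length(common)))
  }
  if (length(hit_gene) == 0) {
    return(tibble(mirna_id = character(), gene = character(),
                  aln_col = integer(), utr_pos = integer(),
                  site = character()))
  }
  # alignment column -> degapped reference-row position
  utr_pos <- integer(length(hit_gene))
  for (g in unique(hit_gene)) {
    idx <- which(hit_gene == g)
    ref_row <- normalize_dna(alignments[[g]][[required_species[1]]])
    nongap <- cumsum(strsplit(ref_row, "", fixed = TRUE)[[1]] != "-")
    utr_pos[idx] <- ifelse(hit_col[idx] == 0, 0L,
                           as.integer(nongap[hit_col[idx]]))
  }
  tibble(mirna_id = hit_mirna, gene = hit_gene, aln_col = hit_col,
         utr_pos = utr_pos, site = hit_site) |>
    arrange(.data$mirna_id, .data$gene, .data$aln_col)
}

#' Hypergeometric upper-tail enrichment probability
#'
#' The probability of observing at least `r` annotated genes when `R`
#' genes are drawn from `N` of which `n` are annotated:
#' \deqn{p = \sum_{i=r}^{\min(n,R)} \binom{R}{i}\binom{N-R}{n-i} /
#'   \binom{N}{n}}
#' computed in log space for numerical stability.
#'
#' @param N total genes in the universe.
#' @param R genes in the tested set (e.g. differentially expressed).
#' @param n genes with predicted target sites.
#' @param r genes in the set that carry target sites.
#' @return the upper-tail probability.
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5)  # 1/choose(10, 5)
hypergeom_pvalue <- function(N, R, n, r) {
  if (any(c(N, R, n, r) < 0) || R > N || n > N) {
    abort("hypergeom_pvalue: need 0 <= R, n <= N and r >= 0")
  }
  if (r > min(n, R)) {
    abort("hypergeom_pvalue: r exceeds min(n, R)")
  }
  i <- seq(r, min(n, R))
  i <- i[n - i <= N - R]  # terms with impossible complements vanish
  if (length(i) == 0) {
    return(0)
  }
  logterms <- lchoose(R, i) + lchoose(N - R, n - i) - lchoose(N, n)
  mx <- max(logterms)
  min(1, exp(mx) * sum(exp(logterms - mx)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, clipped at 1;
#' stable under input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 0) {
    return(numeric(0))
  }
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
  q
}

#' Enrichment of miRNA target genes in gene sets
#'
#' Tests whether genes carrying predicted miRNA target sites are
#' over-represented in given gene sets, with the hypergeometric
#' upper tail and BH-FDR control at 0.05 on the adjusted values.
#' In `set-level` mode the universe is all genes and the annotated
#' class is "has any target site". In `per-mirna` mode the universe
#' is restricted to genes with any predicted site and the annotated
#' class is "has a site of this miRNA", tested per miRNA and set.
#'
#' @param target_map tibble with `mirna_id`, `gene` (one row per
#'   predicted target pair), e.g. from [find_seed_sites()].
#' @param gene_sets named list of character vectors (subsets of
#'   `universe`).
#' @param universe character vector of all protein-coding genes.
#' @param mode `"set-level"` or `"per-mirna"`.
#' @param fdr significance level on BH-adjusted values.
#' @return a `mirforge_enrichment` tibble with columns `set`
#'   (and `mirna_id` in per-miRNA mode), `N`, `R`, `n`, `r`, `p`,
#'   `q`, `significant`.
#' @export
enrich_gene_sets <- function(target_map, gene_sets, universe,
                             mode = c("set-level", "per-mirna"),
                             fdr = 0.05) {
  mode <- match.arg(mode)
  if (length(universe) == 0) {
    abort("enrich_gene_sets: empty universe")
  }
  universe <- unique(universe)
  bad <- vapply(gene_sets, function(s) any(!s %in% universe), logical(1))
  if (any(bad)) {
    abort(sprintf("enrich_gene_sets: set(s) %s contain genes outside the universe",
                  paste(names(gene_sets)[bad], collapse = ",")))
  }
  targeted <- unique(target_map$gene[target_map$gene %in% universe])
  rows <- list()
  if (mode == "set-level") {
    for (s in names(gene_sets)) {
      set <- unique(gene_sets[[s]])
      N <- length(universe)
      R <- length(set)
      n <- length(targeted)
      r <- length(intersect(set, targeted))
      rows[[length(rows) + 1]] <- tibble(
        set = s, N = N, R = R, n = n, r = r,
        p = hypergeom_pvalue(N, R, n, r)
      )
    }
  } else {
    N_univ <- targeted
    for (s in names(gene_sets)) {
      set <- intersect(unique(gene_sets[[s]]), N_univ)
      for (mir in unique(target_map$mirna_id)) {
        tg <- intersect(
          unique(target_map$gene[target_map$mirna_id == mir]), N_univ
        )
        rows[[length(rows) + 1]] <- tibble(
          set = s, mirna_id = mir,
          N = length(N_univ), R = length(set), n = length(tg),
          r = length(intersect(set, tg))
        )
      }
    }
    rows <- list(mutate(bind_rows(rows),
                        p = pmap_dbl(list(.data$N, .data$R, .data$n,
                                          .data$r), hypergeom_pvalue)))
  }
  res <- bind_rows(rows) |>
    mutate(q = bh_adjust(.data$p), significant = .data$q < fdr)
  class(res) <- c("mirforge_enrichment", class(res))
  attr(res, "mode") <- mode
  attr(res, "fdr") <- fdr
  res
}

#' @export
tidy.mirforge_enrichment <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.mirforge_enrichment <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    mode = attr(x, "mode"),
    fdr = attr(x, "fdr")
  )
}

#' Enrichment overview plot
#'
#' @param object a `mirforge_enrichment`.
#' @param ... unused.
#' @return a ggplot of -log10 adjusted values per test.
#' @export
autoplot.mirforge_enrichment <- function(object, ...) {
  df <- tidy.mirforge_enrichment(object)
  df$label <- if ("mirna_id" %in% names(df)) {
    paste(df$set, df$mirna_id, sep = ":")
  } else {
    df$set
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$q),
    y = -log10(pmax(.data$q, 1e-300)),
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "fdr")),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10(BH-adjusted p)") +
    ggplot2::theme_minimal()
}
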