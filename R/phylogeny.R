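#' Build a species-by-miRNA presence matrix from expression counts
#'
#' Presence means expression in at least one library of the species at
#' `min_reads` mapped reads. Optionally reports, per species, how many
#' present miRNAs are absent from a designated reference species (the
#' catalogue's annotated-but-unexpressed analogue).
#'
#' @param counts tibble with `species`, `library`, `mirna_id`,
#'   `count`.
#' @param min_reads per-library presence threshold.
#' @param reference_species optional species name for the
#'   not-in-reference report.
#' @return a `mirforge_presence` list: `matrix` (logical species x
#'   miRNA), `per_species` tibble (`species`, `n_expressed`, and
#'   `n_not_in_reference` when requested).
#' @export
build_presence_matrix <- function(counts, min_reads = 5,
                                  reference_species = NULL) {
  species <- unique(counts$species)
  if (length(species) < 2) {
    abort("build_presence_matrix: at least two species required")
  }
  pres <- counts |>
    group_by(.data$species, .data$mirna_id) |>
    summarise(present = any(.data$count >= min_reads), .groups = "drop") |>
    pivot_wider(names_from = "mirna_id", values_from = "present",
                values_fill = FALSE)
  m <- as.matrix(pres[, -1, drop = FALSE])
  rownames(m) <- pres$species
  per_species <- tibble(
    species = rownames(m),
    n_expressed = as.integer(rowSums(m))
  )
  if (!is.null(reference_species)) {
    if (!reference_species %in% rownames(m)) {
      abort("build_presence_matrix: reference_species not in counts")
    }
    ref <- m[reference_species, ]
    per_species$n_not_in_reference <-
      as.integer(m %*% as.numeric(!ref))
  }
  structure(list(matrix = m, per_species = per_species),
            class = "mirforge_presence")
}

#' @export
print.mirforge_presence <- function(x, ...) {
  cat(sprintf("<mirforge_presence> %d species x %d miRNAs\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(x$per_species)
  invisible(x)
}

#' Pairwise species distances
#'
#' `presence` mode: Jaccard distance on the presence sets (1 minus
#' shared over union; two empty sets are at distance 0). `sequence`
#' mode: proportion of differing columns over concatenated aligned
#' mature sequences, ignoring columns where either species has a gap.
#'
#' @param x a `mirforge_presence`, a logical species x miRNA matrix,
#'   or (sequence mode) a named character vector of equal-length
#'   concatenated sequences per species.
#' @param mode `"presence"` or `"sequence"`.
#' @return a `dist` object over species.
#' @export
species_distance <- function(x, mode = c("presence", "sequence")) {
  mode <- match.arg(mode)
  if (mode == "presence") {
    m <- if (inherits(x, "mirforge_presence")) x$matrix else as.matrix(x)
    storage.mode(m) <- "numeric"
    jaccard_dist(m)
  } else {
    seqs <- if (inherits(x, "mirforge_presence")) {
      abort("species_distance: sequence mode needs concatenated sequences")
    } else {
      x
    }
    n <- length(seqs)
    chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- chars[[i]] != "-" & chars[[j]] != "-"
        d[i, j] <- d[j, i] <-
          if (any(ok)) mean(chars[[i]][ok] != chars[[j]][ok]) else 0
      }
    }
    as.dist(d)
  }
}

# Jaccard distance between rows of a binary matrix
jaccard_dist <- function(m) {
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # two empty sets are identical
  diag(d) <- 0
  as.dist(d)
}

#' Bootstrap hierarchical-clustering tree over species
#'
#' Resamples miRNA columns with replacement, recomputes the distance
#' and average-linkage dendrogram per replicate, and reports, for each
#' internal edge of the original tree, the percentage of replicates
#' containing the same clade (ordinary bootstrap proportions).
#'
#' @param x a `mirforge_presence` or logical species x miRNA matrix.
#' @param n_boot bootstrap replicates.
#' @param linkage hclust agglomeration method.
#' @param seed integer seed; the run is deterministic given it.
#' @return a `mirforge_boottree`: `tree` (ape `phylo`, node labels =
#'   support percentages), `supports` tibble (`clade`, `support`),
#'   `n_boot`.
#' @export
bootstrap_tree <- function(x, n_boot = 1000, linkage = "average",
                           seed = 1) {
  m <- if (inherits(x, "mirforge_presence")) x$matrix else as.matrix(x)
  if (nrow(m) < 3) {
    abort("bootstrap_tree: at least three species required")
  }
  storage.mode(m) <- "numeric"
  # stable species order so supports do not depend on input order
  m <- m[order(rownames(m)), , drop = FALSE]
  base_h <- hclust(jaccard_dist(m), method = linkage)
  base_clades <- hclust_clades(base_h)
  counts <- setNames(integer(length(base_clades)), names(base_clades))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      h <- hclust(jaccard_dist(m[, cols, drop = FALSE]), method = linkage)
      cl <- hclust_clades(h)
      hit <- names(counts) %in% names(cl)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / n_boot
  phy <- ape::as.phylo(base_h)
  # attach supports to internal nodes by matching clade tip sets
  node_labels <- character(phy$Nnode)
  for (nd in seq_len(phy$Nnode)) {
    node <- nrow(m) + nd
    tips <- sort(phy$tip.label[clade_tips(phy, node)])
    key <- paste(tips, collapse = "|")
    node_labels[nd] <- if (key %in% names(support)) {
      sprintf("%g", round(support[[key]], 1))
    } else {
      ""
    }
  }
  phy$node.label <- node_labels
  structure(
    list(
      tree = phy,
      supports = tibble(clade = names(support),
                        support = unname(support)),
      n_boot = n_boot,
      linkage = linkage,
      seed = seed
    ),
    class = "mirforge_boottree"
  )
}

# all clades (tip-label sets) of an hclust tree, keyed by sorted labels
hclust_clades <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    get <- function(k) if (k < 0) h$labels[-k] else sets[[k]]
    sets[[i]] <- c(get(h$merge[i, 1]), get(h$merge[i, 2]))
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  setNames(sets, keys)
}

# tip indices descending from an internal node of a phylo tree
clade_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo) > 0) {
    cur <- todo[1]
    todo <- todo[-1]
    if (cur <= n_tip) {
      tips <- c(tips, cur)
    } else {
      todo <- c(todo, phy$edge[phy$edge[, 1] == cur, 2])
    }
  }
  tips
}

#' @export
print.mirforge_boottree <- function(x, ...) {
  cat(sprintf("<mirforge_boottree> %d tips, %d bootstrap replicates (%s linkage)\n",
              length(x$tree$tip.label), x$n_boot, x$linkage))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' @export
tidy.mirforge_boottree <- function(x, ...) {
  x$supports
}

#' @export
glance.mirforge_boottree <- function(x, ...) {
  tibble(
    n_species = length(x$tree$tip.label),
    n_boot = x$n_boot,
    min_support = min(x$supports$support),
    linkage = x$linkage
  )
}

#' Serialize a bootstrap tree to Newick with support labels
#'
#' @param x a `mirforge_boottree`.
#' @param path optional file; when `NULL` the Newick string is
#'   returned.
#' @export
write_boot_tree <- function(x, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(x$tree)
  } else {
    ape::write.tree(x$tree, file = path)
    invisible(path)
  }
}

#' Plot a bootstrap tree with support values
#'
#' @param x a `mirforge_boottree`.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot_boot_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.2, -0.5))
  invisible(x)
}
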