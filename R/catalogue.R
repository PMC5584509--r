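#' Call genomic miRNA clusters
#'
#' A cluster is at least two catalogue entries on one contig chained
#' by single linkage with edge gaps up to `max_gap` nt (inclusive).
#' Strand is ignored for membership and recorded per member.
#'
#' @param entries tibble with `id`, `contig`, `start`, `end` (and
#'   optionally `strand`, `family`).
#' @param max_gap maximum distance between consecutive members in nt.
#' @return tibble of clusters: `cluster`, `contig`, `span_start`,
#'   `span_end`, `n_members`, `members` (list column of member
#'   tibbles sorted by start).
#' @export
#' @examples
#' entries <- tibble::tibble(
#'   id = c("a", "b", "c"), contig = "chr1",
#'   start = c(0, 10060, 30000), end = c(60, 10120, 30060)
#' )
#' call_clusters(entries)  # a+b chain (gap 10000), c is a singleton
call_clusters <- function(entries, max_gap = 10000) {
  empty <- tibble(cluster = character(), contig = character(),
                  span_start = integer(), span_end = integer(),
                  n_members = integer(), members = list())
  if (nrow(entries) == 0) {
    return(empty)
  }
  x <- chain_intervals(entries, max_gap = max_gap, inclusive = TRUE)
  cl <- x |>
    group_by(.data$contig, .data$chain) |>
    summarise(
      span_start = min(.data$start), span_end = max(.data$end),
      n_members = n(),
      members = list(arrange(pick(everything()), .data$start)),
      .groups = "drop"
    ) |>
    filter(.data$n_members >= 2) |>
    arrange(.data$contig, .data$span_start)
  if (nrow(cl) == 0) {
    return(empty)
  }
  cl |>
    mutate(cluster = sprintf("cluster-%03d", row_number())) |>
    select("cluster", "contig", "span_start", "span_end",
           "n_members", "members")
}

#' Assign catalogue entries to known miRNA families
#'
#' Each entry's mature sequence(s) are compared with a reference
#' mature set by ungapped sliding identity; the best reference match
#' donates its family when identity reaches `min_identity` and
#' (optionally) the seed region (nt 2-7) is identical at the best
#' alignment offset. Ties resolve to the highest identity, then the
#' lexicographically smallest family name. Entries without a
#' qualifying match are `unassigned`.
#'
#' @param entries tibble with `id` and one or both of `mature5p_seq`,
#'   `mature3p_seq` (NA allowed).
#' @param reference tibble with `family`, `mature_seq`.
#' @param min_identity identity threshold.
#' @param require_seed_identity require exact seed agreement.
#' @return the entries with `family` and `family_identity` columns.
#' @export
assign_family <- function(entries, reference, min_identity = 0.9,
                          require_seed_identity = TRUE) {
  mat_cols <- intersect(c("mature5p_seq", "mature3p_seq"), names(entries))
  if (length(mat_cols) == 0) {
    abort("assign_family: entries need mature5p_seq and/or mature3p_seq")
  }
  fam <- character(nrow(entries))
  ident <- numeric(nrow(entries))
  ref_order <- order(reference$family)  # deterministic tie-breaks
  for (i in seq_len(nrow(entries))) {
    matures <- stats::na.omit(unlist(entries[i, mat_cols]))
    matures <- matures[nzchar(matures)]
    best_fam <- NA_character_
    best_id <- -1
    for (m in matures) {
      for (r in ref_order) {
        al <- seq_identity(m, reference$mature_seq[r])
        if (al$identity < min_identity) next
        if (require_seed_identity &&
            !seed_identical(m, reference$mature_seq[r])) {
          next
        }
        better <- al$identity > best_id ||
          (al$identity == best_id &&
             !is.na(best_fam) && reference$family[r] < best_fam)
        if (better) {
          best_id <- al$identity
          best_fam <- reference$family[r]
        }
      }
    }
    fam[i] <- if (is.na(best_fam)) "unassigned" else best_fam
    ident[i] <- if (best_id < 0) NA_real_ else best_id
  }
  mutate(entries, family = fam, family_identity = ident)
}

#' Cluster unassigned entries into novel families
#'
#' Single-linkage clustering of mature sequences at ungapped sliding
#' identity >= `min_identity`; each connected component becomes one
#' novel family labelled `NF0001`, `NF0002`, ... in order of the
#' smallest member id.
#'
#' @param entries tibble with `id` and `mature5p_seq` (or a `mature`
#'   column).
#' @param min_identity linkage threshold.
#' @return the entries with a `family` column of novel labels.
#' @export
cluster_novel_families <- function(entries, min_identity = 0.9) {
  if (nrow(entries) == 0) {
    return(mutate(entries, family = character()))
  }
  mat <- entries$mature5p_seq %||% entries$mature
  n <- nrow(entries)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (seq_identity(mat[i], mat[j])$identity >= min_identity) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # label components by their smallest member id
  rep_id <- tapply(entries$id, comp, min)
  labels <- setNames(sprintf("NF%04d", rank(rep_id)), names(rep_id))
  mutate(entries, family = unname(labels[as.character(comp)]))
}

#' Ordered family-composition string of a cluster
#'
#' @param cluster one row of [call_clusters()] output (or its
#'   `members` tibble).
#' @param family_map named vector or tibble (`id`, `family`) mapping
#'   member ids to family labels.
#' @param reverse read the cluster 3'->5' (coordinate reflection).
#' @return composition string, e.g. `"29a/29b"`.
#' @export
cluster_composition <- function(cluster, family_map, reverse = FALSE) {
  members <- if (is.data.frame(cluster) && "members" %in% names(cluster)) {
    cluster$members[[1]]
  } else if (is.data.frame(cluster)) {
    cluster
  } else {
    cluster$members[[1]]
  }
  if (nrow(members) < 2) {
    abort("cluster_composition: a cluster has at least two members")
  }
  if (is.data.frame(family_map)) {
    family_map <- setNames(family_map$family, family_map$id)
  }
  members <- arrange(members, .data$start)
  labels <- unname(family_map[members$id])
  if (any(is.na(labels))) {
    abort("cluster_composition: family missing for some members")
  }
  if (reverse) {
    labels <- rev(labels)
  }
  paste(labels, collapse = "/")
}

#' Catalogue summary counts
#'
#' Mirrors the per-genome summary of a miRNA catalogue: total
#' miRNAs, cluster count, miRNAs in clusters, known families (and
#' their members), novel families (and their members).
#'
#' @param entries catalogue entries with a `family` column
#'   (novel labels start with `"NF"`; `"unassigned"` counts nowhere).
#' @param clusters output of [call_clusters()].
#' @return one-row tibble of counts.
#' @export
summarize_catalogue <- function(entries, clusters) {
  known <- entries$family[!startsWith(entries$family, "NF") &
                            entries$family != "unassigned"]
  novel <- entries$family[startsWith(entries$family, "NF")]
  tibble(
    n_mirnas = nrow(entries),
    n_clusters = nrow(clusters),
    n_mirnas_in_clusters = sum(clusters$n_members),
    n_known_families = length(unique(known)),
    n_known_family_members = length(known),
    n_novel_families = length(unique(novel)),
    n_novel_family_members = length(novel)
  )
}
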