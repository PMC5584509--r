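#' File input/output for pipeline artefacts
#'
#' Thin wrappers around Biostrings, rtracklayer and readr that convert
#' between on-disk standard formats and the tibble conventions used
#' throughout the package (0-based half-open `contig`/`start`/`end`).
#'
#' @name mirforge-io
NULL

#' Read a genome (or any sequence set) from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return tibble with `id`, `sequence`, `quality` (character columns).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (near record %d)",
                  length(lines), length(lines) %/% 4 + 1))
  }
  idx <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[idx], "@") | !startsWith(lines[idx + 2], "+"))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in %s", bad[1], path))
  }
  bad_len <- which(nchar(lines[idx + 1]) != nchar(lines[idx + 3]))
  if (length(bad_len) > 0) {
    abort(sprintf("malformed FASTQ record %d: sequence/quality length mismatch",
                  bad_len[1]))
  }
  tibble(
    id = sub("\\s.*$", "", sub("^@", "", lines[idx])),
    sequence = toupper(lines[idx + 1]),
    quality = lines[idx + 3]
  )
}

#' Write reads to FASTQ
#'
#' @param reads tibble with `id`, `sequence`, `quality`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$sequence
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a GFF3 feature file into a tibble
#'
#' Coordinates are converted from GFF3 1-based inclusive to the
#' package's 0-based half-open convention; attribute tags become
#' columns.
#'
#' @param path GFF3 file.
#' @return tibble with `contig`, `start`, `end`, `strand`, `type`,
#'   `score` and one column per attribute tag.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  meta <- list()
  for (nm in names(mc)) {
    col <- mc[[nm]]
    if (methods::is(col, "List") || is.list(col)) {
      col <- vapply(as.list(col), function(v) {
        if (length(v) == 0) NA_character_ else paste(v, collapse = ",")
      }, character(1))
    }
    meta[[nm]] <- col
  }
  meta <- as_tibble(meta)
  out <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  bind_cols(out, meta)
}

#' Write a feature tibble as GFF3
#'
#' @param x tibble with `contig`, `start`, `end`, `strand` (0-based
#'   half-open) plus optional `type`, `score`, `source` and attribute
#'   columns (everything else).
#' @param path output file.
#' @export
write_gff3 <- function(x, path) {
  col_or <- function(nm, default) {
    if (nm %in% names(x)) x[[nm]] else rep(default, nrow(x))
  }
  type <- col_or("type", "misc_feature")
  src <- col_or("source", "mirforge")
  score <- col_or("score", NA_real_)
  strand <- col_or("strand", "+")
  attr_cols <- setdiff(
    names(x),
    c("contig", "start", "end", "strand", "type", "score", "source", "phase")
  )
  fmt_attr <- function(i) {
    parts <- character(0)
    for (col in attr_cols) {
      v <- x[[col]][i]
      if (!is.na(v) && !identical(v, "")) {
        parts <- c(parts, paste0(col, "=", v))
      }
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(
      x$contig[i], src[i], type[i],
      format(x$start[i] + 1L, scientific = FALSE),
      format(x$end[i], scientific = FALSE),
      ifelse(is.na(score[i]), ".", format(score[i], scientific = FALSE)),
      strand[i], ".", fmt_attr(i),
      sep = "\t"
    )
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a BED6(+) file of collapsed read alignments or blocks
#'
#' @param path BED file; column 5 carries the collapsed read count.
#' @param extra_cols names for columns beyond the sixth.
#' @return tibble with `contig`, `start`, `end`, `name`, `count`,
#'   `strand` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = character()) {
  cols <- c("contig", "start", "end", "name", "count", "strand", extra_cols)
  x <- readr::read_tsv(path, col_names = cols,
                       show_col_types = FALSE, progress = FALSE,
                       comment = "#")
  mutate(x, start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Write a BED6(+) tibble
#'
#' @param x tibble with `contig`, `start`, `end`, `name`, `count`,
#'   `strand` and optional extra columns appended after the sixth.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  first6 <- c("contig", "start", "end", "name", "count", "strand")
  x <- x[c(first6, setdiff(names(x), first6))]
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gapped multiple alignments, one FASTA per gene
#'
#' @param dir directory of `<gene>.fa` aligned FASTA files ('-' gaps),
#'   one row per species.
#' @return named list (gene) of named character vectors (species).
#' @export
read_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa(sta)?$", full.names = TRUE))
  alns <- lapply(files, function(f) {
    x <- Biostrings::readBStringSet(f)
    setNames(toupper(as.character(x)), names(x))
  })
  setNames(alns, sub("\\.fa(sta)?$", "", basename(files)))
}

#' Write gapped multiple alignments, one FASTA per gene
#'
#' @param alns named list of named character vectors.
#' @param dir output directory (created if needed).
#' @export
write_alignments <- function(alns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gene in names(alns)) {
    x <- Biostrings::BStringSet(alns[[gene]])
    Biostrings::writeXStringSet(x, file.path(dir, paste0(gene, ".fa")))
  }
  invisible(dir)
}

#' Read / write plain-text gene lists
#'
#' @param path text file, one gene id per line.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
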