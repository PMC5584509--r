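# Sequence helpers shared across modules. Sequences are plain character
# vectors in DNA space (U is normalised to T on input).

DNA_BASES <- c("A", "C", "G", "T")

normalize_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n_len) {
  paste(sample(DNA_BASES, n_len, replace = TRUE), collapse = "")
}

# Mutate `k` distinct positions of a DNA string to a different base.
mutate_dna <- function(x, k) {
  if (k == 0) {
    return(x)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), min(k, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Ungapped sliding identity between two sequences
#'
#' Slides the shorter sequence along the longer one without gaps and
#' returns the best fraction of matching positions over the length of
#' the shorter sequence, together with the best offset (0-based offset
#' of the shorter within the longer; ties resolve to the leftmost).
#'
#' @param a,b DNA strings (U accepted).
#' @return list with `identity`, `offset`, and `swapped` (`TRUE` when
#'   `b` is the shorter sequence).
#' @export
#' @examples
#' seq_identity("ACGTACGT", "ACGT")$identity
seq_identity <- function(a, b) {
  a <- normalize_dna(a)
  b <- normalize_dna(b)
  swapped <- nchar(b) < nchar(a)
  short <- if (swapped) b else a
  long <- if (swapped) a else b
  s <- utf8ToInt(short)
  l <- utf8ToInt(long)
  n <- length(s)
  best <- -1
  best_off <- 0L
  for (off in 0:(length(l) - n)) {
    m <- sum(s == l[(off + 1):(off + n)])
    if (m > best) {
      best <- m
      best_off <- off
    }
  }
  list(identity = best / n, offset = best_off, swapped = swapped)
}

# Seed (nt 2-7) agreement at the best sliding offset: positions 2-7 of
# the shorter sequence must match the aligned bases of the longer one.
seed_identical <- function(a, b) {
  a <- normalize_dna(a)
  b <- normalize_dna(b)
  if (nchar(a) < 7 || nchar(b) < 7) {
    return(FALSE)
  }
  al <- seq_identity(a, b)
  short <- if (al$swapped) b else a
  long <- if (al$swapped) a else b
  str_sub(short, 2, 7) == str_sub(long, al$offset + 2, al$offset + 7)
}

# Reverse complement of the seed region (mature nt 2-7); the site motif
# searched for in 3'-UTRs.
seed_site_motif <- function(mature) {
  mature <- normalize_dna(mature)
  if (any(nchar(mature) < 7)) {
    abort("mature sequence shorter than 7 nt: no seed region")
  }
  revcomp_dna(str_sub(mature, 2, 7))
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}
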