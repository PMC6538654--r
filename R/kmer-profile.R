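# Per-window k-mer counting and GC-composition-normalized enrichment
# z-scores against a base-shuffle permutation null.
#
# The null randomizes all base pairs of a window: each artificial
# sequence is a uniformly random permutation of the window's letters,
# so mononucleotide composition -- and hence GC content -- is preserved
# exactly. k-mer counts are recomputed on each artificial sequence and
# the observed counts are expressed as z-scores against the null mean
# and sample standard deviation. k-mers are counted strand-specifically
# as written; words containing a letter outside {A,C,G,T} are skipped
# in both observed and shuffled counting (ambiguity codes are permuted
# with the rest of the letters).

#' Count overlapping k-mers in a DNA string
#'
#' @param seq DNA string (case-insensitive).
#' @param k Word length (default 5).
#' @return A tibble with one row per k-mer over ACGT in lexicographic
#'   order, columns `kmer` and `count`. Words containing an ambiguous
#'   letter are skipped.
#' @examples
#' dplyr::filter(count_kmers("ACGTA", 2), count > 0)
#' @export
count_kmers <- function(seq, k = 5) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("k must be >= 1")
  k <- as.integer(k)
  codes <- encode_dna(toupper(seq))
  tibble(kmer = kmer_names(k), count = as.integer(kmer_count_codes(codes, k)))
}

#' Permutation-null moments of k-mer counts
#'
#' Generates `n_shuffles` artificial sequences, each a uniformly random
#' permutation of the letters of `seq` (composition, and hence GC,
#' preserved exactly), recomputes k-mer counts on each, and returns the
#' per-k-mer mean and sample standard deviation (denominator n - 1).
#'
#' @param seq DNA string.
#' @param k Word length (default 5).
#' @param n_shuffles Number of artificial sequences (default 1000,
#'   minimum 2).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `censcape_null`: list with `kmer`,
#'   `mean`, `sd` (each length `4^k`), `k`, `n_shuffles`, `seed`.
#' @export
shuffle_null <- function(seq, k = 5, n_shuffles = 1000, seed = NULL) {
  if (n_shuffles < 2) abort("n_shuffles must be >= 2")
  k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_dna(toupper(seq))
  res <- shuffle_null_codes(codes, k, as.integer(n_shuffles))
  structure(
    list(kmer = kmer_names(k), mean = res$mean, sd = res$sd,
         k = k, n_shuffles = as.integer(n_shuffles), seed = seed),
    class = "censcape_null"
  )
}

#' One composition-preserving shuffle of a DNA string
#'
#' A single uniformly random permutation of the letters of `seq`, the
#' elementary move of the permutation null.
#'
#' @inheritParams shuffle_null
#' @return A character scalar with exactly the letter multiset of
#'   `seq`.
#' @export
shuffle_sequence <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up <- toupper(seq)
  codes <- encode_dna(up)
  perm <- shuffle_codes(seq_along(codes) - 1L) + 1L
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  paste0(chars[perm], collapse = "")
}

#' GC-normalized k-mer enrichment z-scores for one sequence window
#'
#' For each k-mer m, `z = (observed - null mean) / null sd`; when the
#' null sd is 0 the letter composition pins the count, the observed
#' count necessarily equals the null mean, and z is 0 by convention.
#'
#' @inheritParams shuffle_null
#' @return A tibble with columns `kmer`, `observed`, `null_mean`,
#'   `null_sd`, `z` (one row per k-mer, lexicographic order), with the
#'   window GC fraction in attribute `"gc"`.
#' @export
zscore_profile <- function(seq, k = 5, n_shuffles = 1000, seed = NULL) {
  k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_dna(toupper(seq))
  obs <- as.numeric(kmer_count_codes(codes, k))
  null <- shuffle_null_codes(codes, k, as.integer(n_shuffles))
  z <- ifelse(null$sd > 0, (obs - null$mean) / null$sd, 0)
  out <- tibble(
    kmer = kmer_names(k), observed = as.integer(obs),
    null_mean = null$mean, null_sd = null$sd, z = z
  )
  attr(out, "gc") <- gc_fraction(codes)
  out
}

#' Enrichment-profile matrix for a set of genome windows
#'
#' Computes the z-score profile of every window and stacks them into a
#' windows x 4^k matrix (row order = window order, rownames =
#' `window_id`, colnames = k-mers in lexicographic order). Each
#' window's RNG stream is derived deterministically from the master
#' seed and the window's chromosome and within-chromosome index, so
#' results do not depend on evaluation order.
#'
#' @param genome A [genome()] object.
#' @param windows Window tibble from [make_windows()].
#' @param k Word length (default 5).
#' @param n_shuffles Artificial sequences per window (default 1000).
#' @param seed Master seed (default 1).
#' @return A numeric matrix of z-scores with attribute `"gc"` (the
#'   per-window GC fraction).
#' @export
profile_matrix <- function(genome, windows, k = 5, n_shuffles = 1000,
                           seed = 1) {
  k <- as.integer(k)
  nb <- 4L^k
  n <- nrow(windows)
  out <- matrix(0, nrow = n, ncol = nb,
                dimnames = list(windows$window_id, kmer_names(k)))
  gc <- numeric(n)
  for (i in seq_len(n)) {
    chrom <- windows$chrom[[i]]
    L <- genome$lengths[[chrom]]
    if (is.null(L)) abort(sprintf("unknown chromosome: %s", chrom))
    if (windows$start[[i]] < 0 || windows$end[[i]] > L) {
      abort(sprintf("window %s outside chromosome bounds", windows$window_id[[i]]))
    }
    seq <- get_sequence(genome, chrom, windows$start[[i]], windows$end[[i]])
    codes <- encode_dna(seq)
    set.seed(derive_seed(seed, index = windows$index[[i]], key = chrom))
    obs <- as.numeric(kmer_count_codes(codes, k))
    null <- shuffle_null_codes(codes, k, as.integer(n_shuffles))
    out[i, ] <- ifelse(null$sd > 0, (obs - null$mean) / null$sd, 0)
    gc[i] <- gc_fraction(codes)
  }
  attr(out, "gc") <- gc
  out
}

#' Write an enrichment-profile matrix as TSV
#'
#' Row names (window ids) go in the first column, k-mers are the
#' remaining column headers.
#'
#' @param mat Matrix from [profile_matrix()].
#' @param path Output path.
#' @export
write_profile_matrix <- function(mat, path) {
  df <- as_tibble(mat, rownames = "window_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Exact permutation-null expectation of a k-mer count
#'
#' Closed-form expected count of `kmer` in a uniformly random
#' permutation of the letters of `seq`: any k consecutive positions of
#' a random permutation are an ordered sample without replacement from
#' the letter multiset, so the match probability is a product of
#' sequential draw probabilities, summed over the L - k + 1 window
#' positions. Used as the independent oracle for [shuffle_null()].
#'
#' @param seq DNA string (the composition is what matters).
#' @param kmer Word whose expected count is wanted.
#' @return Expected count (a single number).
#' @export
exact_null_mean <- function(seq, kmer) {
  codes <- encode_dna(toupper(seq))
  word <- encode_dna(toupper(kmer))
  if (any(word < 0)) return(0)
  L <- length(codes)
  k <- length(word)
  if (L < k) return(0)
  # ambiguous letters participate in the permutation but can never
  # match, so they only appear in the denominator (total letters)
  avail <- tabulate(codes[codes >= 0L] + 1L, nbins = 4L)
  p <- 1
  total <- L
  for (j in seq_len(k)) {
    need <- word[j] + 1L
    if (avail[need] <= 0) return(0)
    p <- p * avail[need] / (total - j + 1)
    avail[need] <- avail[need] - 1L
  }
  (L - k + 1) * p
}
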