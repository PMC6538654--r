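# Independent oracles used across tests. These deliberately avoid the
# package's fast paths: counting is done by substring extraction and
# the shuffle stream is replayed with interpreted R code.

# count overlapping k-mers by substring extraction, skipping words
# with ambiguous letters
naive_count_kmers <- function(seq, k, kmers = kmer_names(k)) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- setNames(integer(length(kmers)), kmers)
  if (n < k) return(out)
  for (i in seq_len(n - k + 1)) {
    w <- paste0(chars[i:(i + k - 1)], collapse = "")
    if (grepl("^[ACGT]+$", w)) out[w] <- out[w] + 1L
  }
  out
}

# replay of the package's Fisher-Yates stream in interpreted R: one
# runif per position from n down to 2, permutations compound across
# shuffles; returns per-k-mer mean and sample sd of the counts
naive_shuffle_null <- function(seq, k, n_shuffles, seed) {
  set.seed(seed)
  y <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(y)
  kmers <- kmer_names(k)
  counts <- matrix(0, n_shuffles, length(kmers),
                   dimnames = list(NULL, kmers))
  for (t in seq_len(n_shuffles)) {
    for (p in seq(n, 2)) {
      j <- floor(runif(1) * p) + 1
      if (j > p) j <- p
      tmp <- y[p]; y[p] <- y[j]; y[j] <- tmp
    }
    counts[t, ] <- naive_count_kmers(paste0(y, collapse = ""), k, kmers)
  }
  list(mean = colMeans(counts), sd = apply(counts, 2, stats::sd))
}

# all distinct permutations of a character multiset (lengths <= ~6)
multiset_perms <- function(chars) {
  if (length(chars) <= 1) return(list(chars))
  out <- list()
  for (c1 in unique(chars)) {
    rest <- chars[-match(c1, chars)]
    for (p in multiset_perms(rest)) out[[length(out) + 1]] <- c(c1, p)
  }
  out
}

# exact permutation-null mean of a k-mer count by full enumeration
enum_null_mean <- function(seq, kmer) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  perms <- multiset_perms(chars)
  mean(vapply(perms, function(p) {
    naive_count_kmers(paste0(p, collapse = ""), nchar(kmer))[[kmer]]
  }, 0))
}

# a literal ACGT repeat genome of the given chromosome lengths,
# for tests that only need coordinates
coord_genome <- function(lengths) {
  seqs <- vapply(lengths, function(L) {
    substr(strrep("ACGT", ceiling(L / 4)), 1, L)
  }, "")
  names(seqs) <- paste0("chr", seq_along(seqs))
  genome(seqs)
}

random_genome <- function(lengths, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("chr", seq_along(seqs))
  genome(seqs)
}

# small gene tibble builder
gene_tbl <- function(chrom, start, len = 70, strand = "+", amino = "D",
                     anticodon = "GTC") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + len), strand = strand,
                 amino_acid = amino, anticodon = anticodon)
}
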