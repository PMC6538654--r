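# Greedy tRNA gene cluster detection, canonical cluster signatures,
# genome-shuffle permutation significance, q-values, and the
# centromeric/non-centromeric frequency table.

#' Read tRNA genes from BED6 or GFF3
#'
#' BED6 names of the form `"D-GTC"` (cognate amino-acid single-letter
#' code, dash, anticodon) are split into `amino_acid` and `anticodon`.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return Gene tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `amino_acid`, `anticodon`.
#' @export
read_trna_genes <- function(path, format = c("bed", "gff3")) {
  x <- read_intervals(path, format = match.arg(format))
  parts <- strsplit(x$name, "-", fixed = TRUE)
  tibble(
    chrom = x$chrom, start = x$start, end = x$end, strand = x$strand,
    amino_acid = map_chr(parts, 1),
    anticodon = map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_)
  )
}

#' Greedy clustering of tRNA genes
#'
#' A single pass per chromosome chains genes while the gap to the
#' previous gene (`next start - previous end`, half-open coordinates)
#' is strictly less than `gap_max`; genes `< gap_max` bp apart end up
#' in the same cluster and singletons are emitted as 1-gene clusters.
#'
#' @param genes Gene tibble with `chrom`, `start`, `end`, `strand`,
#'   `amino_acid` (and optionally `anticodon`); genes must not
#'   overlap.
#' @param gap_max Gap threshold in bp (strict `<`, default 1000).
#' @return Cluster tibble with columns `cluster_id`, `chrom`, `start`,
#'   `end`, `n_genes`, `signature`, and list-column `genes` (member
#'   rows in genomic order).
#' @export
cluster_trna_genes <- function(genes, gap_max = 1000) {
  if (nrow(genes) == 0) {
    return(tibble(cluster_id = integer(), chrom = character(),
                  start = integer(), end = integer(), n_genes = integer(),
                  signature = character(), genes = list()))
  }
  g <- arrange(genes, match(.data$chrom, unique(genes$chrom)), .data$start)
  gap <- g$start - lag(g$end)
  same_chrom <- g$chrom == lag(g$chrom, default = g$chrom[[1]])
  ovl <- which(same_chrom & !is.na(gap) & gap < 0)
  if (length(ovl) > 0) {
    abort(sprintf("overlapping genes on %s near position %d",
                  g$chrom[ovl[1]], g$start[ovl[1]]))
  }
  new_cluster <- !same_chrom | is.na(gap) | gap >= gap_max
  new_cluster[1] <- TRUE
  cid <- cumsum(new_cluster)
  g$cluster_id <- cid
  spans <- g |>
    group_by(.data$cluster_id) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_genes = n(),
      signature = cluster_signature(.data$amino_acid, .data$strand),
      .groups = "drop"
    )
  nested <- g |>
    select("cluster_id", "chrom", "start", "end", "strand", "amino_acid") |>
    tidyr::nest(genes = c("chrom", "start", "end", "strand", "amino_acid"))
  left_join(spans, nested, by = "cluster_id")
}

#' Canonical signature of a tRNA gene cluster
#'
#' The signature is the sequence of (amino acid, strand) pairs in
#' genomic order, canonicalized as the lexicographic minimum of that
#' string and its orientation flip (order reversed, strands inverted),
#' so a cluster and its reverse-orientation mirror share one
#' signature.
#'
#' @param amino_acid Character vector of single-letter amino-acid
#'   codes, in genomic order.
#' @param strand Matching vector of `"+"`/`"-"`.
#' @return A single signature string, e.g. `"D+V+A+"`.
#' @export
cluster_signature <- function(amino_acid, strand) {
  if (length(amino_acid) == 0) abort("empty cluster")
  fwd <- paste0(amino_acid, strand, collapse = "")
  flip <- paste0(rev(amino_acid), ifelse(rev(strand) == "+", "-", "+"),
                 collapse = "")
  # radix = C-locale byte order, independent of the session locale
  sort(c(fwd, flip), method = "radix")[1]
}

#' Shuffle tRNA gene locations across the genome
#'
#' Places each gene uniformly at random over the whole genome
#' (chromosome chosen proportional to its length, start uniform within
#' bounds), preserving gene length, strand and identity; placements
#' are rejection-sampled to be non-overlapping.
#'
#' @param genome A [genome()] object.
#' @param genes Gene tibble.
#' @param seed Optional integer seed.
#' @param max_tries Retries per gene before giving up (default 1000).
#' @return Gene tibble with new `chrom`, `start`, `end`.
#' @export
shuffle_gene_locations <- function(genome, genes, seed = NULL,
                                   max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  lens <- genes$end - genes$start
  if (sum(lens) >= sum(genome$lengths)) abort("genes do not fit in genome")
  chroms <- names(genome$lengths)
  probs <- genome$lengths / sum(genome$lengths)
  placed_chrom <- character(nrow(genes))
  placed_start <- integer(nrow(genes))
  # per-chromosome occupied intervals for overlap rejection
  occ <- setNames(vector("list", length(chroms)), chroms)
  for (i in seq_len(nrow(genes))) {
    len <- lens[[i]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- chroms[sample.int(length(chroms), 1, prob = probs)]
      maxstart <- genome$lengths[[ci]] - len
      if (maxstart < 0) next
      s <- as.integer(floor(stats::runif(1) * (maxstart + 1)))
      if (s > maxstart) s <- maxstart
      o <- occ[[ci]]
      if (!is.null(o) && any(s < o$end & s + len > o$start)) next
      occ[[ci]] <- list(start = c(o$start, s), end = c(o$end, s + len))
      placed_chrom[i] <- ci
      placed_start[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) abort(sprintf("could not place gene %d after %d tries", i, max_tries))
  }
  mutate(genes, chrom = placed_chrom, start = placed_start,
         end = placed_start + lens)
}

# lean signature tally for the permutation inner loop: same chaining
# rule as cluster_trna_genes but on plain vectors (chrom as integer),
# counting only multi-gene clusters; placements are guaranteed
# non-overlapping so no overlap check is repeated here
signature_counts_fast <- function(chrom_i, start, end, amino, strand,
                                  gap_max) {
  o <- order(chrom_i, start)
  chrom_i <- chrom_i[o]; start <- start[o]; end <- end[o]
  amino <- amino[o]; strand <- strand[o]
  n <- length(start)
  if (n == 0) return(integer(0))
  gap <- start - c(0L, end[-n])
  new_cluster <- c(TRUE, chrom_i[-1] != chrom_i[-n] | gap[-1] >= gap_max)
  cid <- cumsum(new_cluster)
  sizes <- tabulate(cid)
  multi <- which(sizes >= 2L)
  if (length(multi) == 0) return(integer(0))
  sigs <- vapply(multi, function(ci) {
    idx <- which(cid == ci)
    cluster_signature(amino[idx], strand[idx])
  }, "")
  table(sigs)
}

#' Permutation test for recurrent tRNA gene clusters
#'
#' For every multi-gene cluster signature observed in the real gene
#' set, gene locations are shuffled across the genome `n_perm` times;
#' each permutation is re-clustered and the number of occurrences of
#' the signature tallied. The p-value is the raw proportion of
#' permutations in which the signature occurred at least as many times
#' as observed; `below_resolution` flags signatures never matched in
#' any permutation (p = 0, i.e. below the resolution of `n_perm`).
#' Benjamini-Hochberg q-values account for multiple testing.
#'
#' @param genome A [genome()] object.
#' @param genes Gene tibble.
#' @param n_perm Number of location shuffles (default 1000).
#' @param seed Master seed; permutation `i` uses a stream derived from
#'   `(seed, i)`.
#' @param gap_max Clustering gap threshold (default 1000).
#' @param signatures Optional character vector of canonical signatures
#'   to test. By default every multi-gene signature observed in
#'   `genes` is tested; predeclared signatures absent from the real
#'   gene set get `observed_count` 0 and hence p = 1. Predeclaring the
#'   signatures avoids the selection effect of testing only
#'   post-hoc-observed clusters, which matters for calibration
#'   studies.
#' @return Tibble sorted by `p` then `signature`, with columns
#'   `signature`, `observed_count`, `p`, `below_resolution`, `q`,
#'   `n_perm`, and list-column `null_counts`.
#' @export
cluster_permutation_test <- function(genome, genes, n_perm = 1000,
                                     seed = 1, gap_max = 1000,
                                     signatures = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  obs_clusters <- cluster_trna_genes(genes, gap_max = gap_max)
  obs_multi <- obs_clusters[obs_clusters$n_genes >= 2, , drop = FALSE]
  sigs <- if (is.null(signatures)) {
    sort(unique(obs_multi$signature))
  } else {
    sort(unique(signatures))
  }
  if (length(sigs) == 0) {
    return(tibble(signature = character(), observed_count = integer(),
                  p = numeric(), below_resolution = logical(),
                  q = numeric(), n_perm = integer(), null_counts = list()))
  }
  observed <- map_int(sigs, function(s) sum(obs_multi$signature == s))
  null_counts <- matrix(0L, nrow = length(sigs), ncol = n_perm,
                        dimnames = list(sigs, NULL))
  chrom_levels <- names(genome$lengths)
  for (p_i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, index = p_i, key = "perm"))
    shuf <- shuffle_gene_locations(genome, genes)
    tab <- signature_counts_fast(
      match(shuf$chrom, chrom_levels), shuf$start, shuf$end,
      shuf$amino_acid, shuf$strand, gap_max
    )
    if (length(tab) > 0) {
      hit <- intersect(names(tab), sigs)
      null_counts[hit, p_i] <- as.integer(tab[hit])
    }
  }
  ge <- unname(rowSums(null_counts >= matrix(observed, nrow = length(sigs),
                                             ncol = n_perm)))
  observed <- unname(observed)
  pval <- ge / n_perm
  out <- tibble(
    signature = sigs, observed_count = observed, p = pval,
    below_resolution = pval == 0,
    q = bh_qvalues(pval), n_perm = as.integer(n_perm),
    null_counts = lapply(seq_along(sigs), function(i) null_counts[i, ])
  )
  arrange(out, .data$p, .data$signature)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over p_j >= p_i of (m * p_(j) / j)`, capped at 1, input
#' order preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' tRNA gene frequency at centromeric and non-centromeric sites
#'
#' Counts each (anticodon, amino acid) class inside and outside
#' centromere intervals (a gene is centromeric when its interval
#' overlaps a centromere), with the per-class centromeric fraction and
#' an `ALL` totals row carrying the overall centromeric fraction.
#'
#' @param genes Gene tibble with `amino_acid` and `anticodon`.
#' @param centromeres Interval tibble of centromere regions (may be
#'   empty or `NULL`).
#' @return Tibble with columns `amino_acid`, `anticodon`,
#'   `centromeric`, `non_centromeric`, `total`, `centromeric_fraction`.
#' @export
centromere_frequency_matrix <- function(genes, centromeres = NULL) {
  cen <- overlaps_any(genes, centromeres)
  per <- genes |>
    mutate(anticodon = dplyr::coalesce(.data$anticodon, "?"),
           in_cen = cen) |>
    group_by(.data$amino_acid, .data$anticodon) |>
    summarise(centromeric = sum(.data$in_cen),
              non_centromeric = sum(!.data$in_cen), .groups = "drop") |>
    arrange(.data$amino_acid, .data$anticodon)
  per <- mutate(per, total = .data$centromeric + .data$non_centromeric,
                centromeric_fraction = .data$centromeric / .data$total)
  totals <- tibble(
    amino_acid = "ALL", anticodon = "ALL",
    centromeric = sum(per$centromeric),
    non_centromeric = sum(per$non_centromeric),
    total = sum(per$total),
    centromeric_fraction = sum(per$centromeric) / max(1L, sum(per$total))
  )
  bind_rows(per, totals)
}
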