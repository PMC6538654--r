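test_that("greedy chaining uses a strict 1 kb gap", {
  g2 <- dplyr::bind_rows(gene_tbl("chr1", 1000), gene_tbl("chr1", 2069))
  cl <- cluster_trna_genes(g2) # gap = 999
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_genes, 2L)
  expect_identical(cl$start, 1000L)
  expect_identical(cl$end, 2139L)

  g2b <- dplyr::bind_rows(gene_tbl("chr1", 1000), gene_tbl("chr1", 2070))
  expect_identical(nrow(cluster_trna_genes(g2b)), 2L) # gap = 1000

  single <- cluster_trna_genes(gene_tbl("chr1", 50))
  expect_identical(single$n_genes, 1L)

  ovl <- dplyr::bind_rows(gene_tbl("chr1", 1000), gene_tbl("chr1", 1050))
  expect_error(cluster_trna_genes(ovl), "overlapping")
})

test_that("clustering is idempotent and input-order invariant", {
  set.seed(3)
  genes <- dplyr::bind_rows(lapply(seq(0, 40000, by = 1500), function(s) {
    gene_tbl("chr1", s + sample(0:400, 1),
             amino = sample(LETTERS[1:6], 1),
             strand = sample(c("+", "-"), 1))
  }))
  base <- cluster_trna_genes(genes)
  shuffled <- cluster_trna_genes(genes[sample(nrow(genes)), ])
  expect_identical(base, shuffled)
  # clusters of clusters: re-clustering the flattened members is stable
  flat <- dplyr::bind_rows(base$genes)
  flat$anticodon <- "NNN"
  expect_identical(cluster_trna_genes(flat)$signature, base$signature)
})

test_that("signatures are canonical under orientation flips", {
  expect_identical(cluster_signature(c("D", "V"), c("+", "+")),
                   cluster_signature(c("V", "D"), c("-", "-")))
  expect_identical(cluster_signature("E", "+"), cluster_signature("E", "-"))
  expect_identical(cluster_signature(c("A", "I", "R"), c("+", "+", "+")),
                   cluster_signature(c("R", "I", "A"), c("-", "-", "-")))
  # property: random clusters and their mirrors share a signature
  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    aa <- sample(LETTERS, n, replace = TRUE)
    st <- sample(c("+", "-"), n, replace = TRUE)
    expect_identical(
      cluster_signature(aa, st),
      cluster_signature(rev(aa), ifelse(rev(st) == "+", "-", "+"))
    )
  }
})

test_that("location shuffles preserve identity and avoid overlap", {
  g <- coord_genome(c(50000, 30000))
  genes <- dplyr::bind_rows(lapply(seq(0, 45000, 1500), function(s) {
    gene_tbl("chr1", s, amino = sample(LETTERS[1:8], 1))
  }))
  sh <- shuffle_gene_locations(g, genes, seed = 5)
  expect_identical(nrow(sh), nrow(genes))
  expect_identical(sh$end - sh$start, genes$end - genes$start)
  expect_identical(sort(sh$amino_acid), sort(genes$amino_acid))
  expect_identical(shuffle_gene_locations(g, genes, seed = 5), sh)
  # non-overlap within each chromosome
  for (id in unique(sh$chrom)) {
    x <- sh[sh$chrom == id, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  # bounds respected
  expect_true(all(sh$start >= 0))
  expect_true(all(sh$end <= g$lengths[sh$chrom]))
})

test_that("shuffled starts are uniform over the admissible range", {
  g <- coord_genome(1000)
  gene <- gene_tbl("chr1", 0, len = 70)
  starts <- vapply(1:5000, function(i) {
    shuffle_gene_locations(g, gene, seed = i)$start
  }, 0L)
  # uniform on [0, 930]: mean 465, sd 930/sqrt(12)
  se <- (930 / sqrt(12)) / sqrt(5000)
  expect_lt(abs(mean(starts) - 465), 3 * se + 1)
  expect_true(min(starts) >= 0 && max(starts) <= 930)
})

test_that("permutation p-value agrees with a brute-force placement oracle", {
  g <- coord_genome(10000)
  genes <- dplyr::bind_rows(
    gene_tbl("chr1", 1000, len = 70, amino = "D"),
    gene_tbl("chr1", 1500, len = 70, amino = "V")
  )
  obs_sig <- cluster_signature(c("D", "V"), c("+", "+"))
  res <- cluster_permutation_test(g, genes, n_perm = 2000, seed = 13)
  expect_identical(res$signature, obs_sig)
  expect_identical(res$observed_count, 1L)

  # oracle: sequential uniform placement with overlap rejection,
  # counting arrangements whose canonical signature matches
  set.seed(1)
  n <- 1e6
  s1 <- floor(runif(n) * 9931)
  s2 <- floor(runif(n) * 9931)
  redo <- abs(s2 - s1) < 70
  while (any(redo)) {
    s2[redo] <- floor(runif(sum(redo)) * 9931)
    redo <- abs(s2 - s1) < 70
  }
  gap <- pmax(s1, s2) - (pmin(s1, s2) + 70)
  d_first <- s1 < s2 # gene 1 is D
  p_oracle <- mean(gap < 1000 & d_first)
  tol <- 3 * sqrt(p_oracle * (1 - p_oracle) / 2000)
  expect_lt(abs(res$p - p_oracle), tol)
})

test_that("never-matched signatures are flagged below resolution", {
  g <- coord_genome(5e6)
  # three exact copies of a 3-gene cluster, nothing else
  genes <- dplyr::bind_rows(lapply(c(1e5, 2e6, 4e6), function(base) {
    dplyr::bind_rows(
      gene_tbl("chr1", base, amino = "D"),
      gene_tbl("chr1", base + 300, amino = "V"),
      gene_tbl("chr1", base + 600, amino = "A")
    )
  }))
  res <- cluster_permutation_test(g, genes, n_perm = 100, seed = 2)
  expect_identical(res$p, 0)
  expect_true(res$below_resolution)
  expect_identical(res$q, 0)
})

test_that("Benjamini-Hochberg q-values follow the step-up formula", {
  expect_equal(bh_qvalues(0.02), 0.02)
  # hand application of the step-up rule
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(c(0.005, 0.04, 0.8)),
               c(0.015, 0.06, 0.8))
  # monotone non-decreasing in p
  set.seed(4)
  p <- runif(50)
  q <- bh_qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("centromeric frequency table counts genes by anticodon", {
  genes <- dplyr::bind_rows(
    gene_tbl("chr1", 100, amino = "D", anticodon = "GTC"),
    gene_tbl("chr1", 5000, amino = "D", anticodon = "GTC"),
    gene_tbl("chr1", 9000, amino = "V", anticodon = "AAC")
  )
  cen <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  tab <- centromere_frequency_matrix(genes, cen)
  all_row <- tab[tab$amino_acid == "ALL", ]
  expect_equal(all_row$centromeric_fraction, 1 / 3)
  expect_identical(all_row$total, 3L)
  d_row <- tab[tab$anticodon == "GTC", ]
  expect_identical(d_row$centromeric, 1L)
  expect_identical(d_row$non_centromeric, 1L)
  # no centromeres: everything is non-centromeric
  tab0 <- centromere_frequency_matrix(genes, NULL)
  expect_identical(tab0$centromeric[tab0$amino_acid == "ALL"], 0L)
})
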