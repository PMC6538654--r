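# Synthetic genomes, annotations, peak tracks and colony counts with
# the statistical structure the analysis assumes: compositionally
# biased centromere-like domains at exactly matched GC, peak tracks
# consistent with the window-classification rules, planted
# centromere-exclusive tRNA gene clusters among scattered decoys, and
# binomial colony counts.

# fixed amino-acid -> anticodon lookup for decoy genes
TRNA_TYPES <- data.frame(
  amino_acid = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC", "GCC",
                "GTG", "AAT", "AAG", "CTT", "CAT", "GAA", "AGG", "AGA",
                "AGT", "CCA", "GTA", "AAC")
)

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a fission-yeast-scale study system: three 4 Mb
#' chromosomes (~12 Mb), ~36% GC, a mid-chromosome centromere on each
#' chromosome with a 30 kb CENP-A core and 40 kb heterochromatic
#' flanks, 50 kb subtelomeric heterochromatin blocks, one 20 kb
#' mating-type-like region, two 15 kb neocentromere-like regions, one
#' planted `D+V+A+` tRNA gene cluster per centromere plus 100
#' scattered decoy genes, and a binomial colony model matching a
#' high-establishment minichromosome (94% establishment, 5.8% loss
#' per division).
#'
#' The planted compositional signal is a first-order Markov
#' perturbation of strength `bias_epsilon` whose stationary
#' distribution equals `base_composition` exactly, so centromere-like
#' domains match the background GC while their dinucleotide (and
#' hence 5-mer) usage is biased -- the minimal effect the
#' composition-preserving shuffle null is designed to detect.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp (recycled).
#' @param base_composition Named probabilities over A, C, G, T.
#' @param bias_epsilon Dinucleotide perturbation strength in `[0, 1)`.
#' @param cenpa_core_width CENP-A core width (bp).
#' @param het_flank_width H3K9 flank width on each side of the core.
#' @param subtel_width Subtelomeric H3K9 block width at each
#'   chromosome end.
#' @param mat_width Mating-type-like region width (placed on
#'   chromosome 2 at 25% of its length).
#' @param neocen_width Neocentromere-like region width (two regions,
#'   chromosome 1 at 70% and chromosome 3 at 30%; biased composition
#'   like centromere cores).
#' @param planted_cluster Character vector of `"X+"`/`"X-"` gene
#'   specs planted (one copy per centromere, inside the right flank).
#' @param decoy_gene_count Number of scattered singleton tRNA genes.
#' @param gene_length tRNA gene length in bp.
#' @param p_establish,p_loss,n_transformants,n_colonies Colony model.
#' @return A validated list of class `censcape_synth_config`.
#' @export
synth_config <- function(n_chromosomes = 3,
                         chromosome_length = 4e6,
                         base_composition = c(A = 0.32, C = 0.18,
                                              G = 0.18, T = 0.32),
                         bias_epsilon = 0.15,
                         cenpa_core_width = 30000,
                         het_flank_width = 40000,
                         subtel_width = 50000,
                         mat_width = 20000,
                         neocen_width = 15000,
                         planted_cluster = c("D+", "V+", "A+"),
                         decoy_gene_count = 100,
                         gene_length = 72,
                         p_establish = 0.94, p_loss = 0.058,
                         n_transformants = 217, n_colonies = 3284) {
  pi <- base_composition[c("A", "C", "G", "T")]
  if (anyNA(pi) || abs(sum(pi) - 1) > 1e-9 || any(pi <= 0)) {
    abort("base_composition must be positive probabilities over A,C,G,T summing to 1")
  }
  if (bias_epsilon < 0 || bias_epsilon >= 1) {
    abort("bias_epsilon must be in [0, 1)")
  }
  lens <- rep_len(as.integer(chromosome_length), n_chromosomes)
  if (any(lens < 2 * (subtel_width + 1) + cenpa_core_width +
          2 * het_flank_width)) {
    abort("chromosomes too short for the requested domain geometry")
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = lens, base_composition = pi,
         bias_epsilon = bias_epsilon,
         cenpa_core_width = as.integer(cenpa_core_width),
         het_flank_width = as.integer(het_flank_width),
         subtel_width = as.integer(subtel_width),
         mat_width = as.integer(mat_width),
         neocen_width = as.integer(neocen_width),
         planted_cluster = planted_cluster,
         decoy_gene_count = as.integer(decoy_gene_count),
         gene_length = as.integer(gene_length),
         p_establish = p_establish, p_loss = p_loss,
         n_transformants = as.integer(n_transformants),
         n_colonies = as.integer(n_colonies)),
    class = "censcape_synth_config"
  )
}

#' Composition-biased Markov transition matrix with fixed stationary
#' distribution
#'
#' Builds `P[i, j] = pi[j] + eps * a[i] * b[j]` where `a` is the
#' pi-centred AT/GC contrast and `b[j] = pi[j] * (s[j] - sum(pi * s))`.
#' Rows sum to 1 and `pi` is exactly stationary by construction
#' (`colSums(pi * P) == pi`); `eps = 0` gives the i.i.d. kernel. An
#' error is raised if the requested `eps` drives any entry negative.
#'
#' @param pi Named base probabilities (A, C, G, T).
#' @param eps Perturbation strength.
#' @return 4x4 row-stochastic matrix with dimnames A, C, G, T.
#' @export
biased_transition_matrix <- function(pi, eps) {
  pi <- pi[c("A", "C", "G", "T")]
  s <- c(A = 1, C = -1, G = -1, T = 1) # AT vs GC contrast
  ctr <- sum(pi * s)
  a <- s - ctr
  b <- pi * (s - ctr)
  P <- matrix(rep(pi, each = 4), nrow = 4) + eps * outer(a, b)
  dimnames(P) <- list(names(pi), names(pi))
  if (any(P < 0)) {
    abort(sprintf("no valid perturbed kernel for epsilon = %g", eps))
  }
  P
}

# sample n states (1..4) from a first-order Markov chain with
# transition matrix P, initial distribution pi
markov_codes <- function(n, P, pi) {
  cumP <- t(apply(P, 1, cumsum))
  out <- integer(n)
  u <- stats::runif(n)
  state <- findInterval(u[1], cumsum(pi)) + 1L
  if (state > 4L) state <- 4L
  out[1] <- state
  for (i in 2:n) {
    state <- findInterval(u[i], cumP[state, ]) + 1L
    if (state > 4L) state <- 4L
    out[i] <- state
  }
  out
}

# planted domain geometry for a config: one centromere per chromosome
# (core centred, flanks either side), subtel blocks, mat, neocen
synth_geometry <- function(cfg) {
  ids <- paste0("chr", seq_len(cfg$n_chromosomes))
  lens <- setNames(cfg$chromosome_length, ids)
  core <- lapply(seq_along(ids), function(i) {
    mid <- lens[[i]] %/% 2L
    s <- mid - cfg$cenpa_core_width %/% 2L
    tibble(chrom = ids[i], start = s, end = s + cfg$cenpa_core_width,
           name = "cenpa_core", score = 0L, strand = ".")
  })
  core <- bind_rows(core)
  flank <- bind_rows(
    mutate(core, start = .data$start - cfg$het_flank_width,
           end = core$start, name = "het_flank_left"),
    mutate(core, start = core$end,
           end = core$end + cfg$het_flank_width, name = "het_flank_right")
  )
  subtel <- bind_rows(lapply(seq_along(ids), function(i) {
    tibble(chrom = ids[i],
           start = c(0L, lens[[i]] - cfg$subtel_width),
           end = c(cfg$subtel_width, lens[[i]]),
           name = "subtel", score = 0L, strand = ".")
  }))
  mat_chr <- ids[min(2L, length(ids))]
  mat_s <- as.integer(lens[[mat_chr]] * 0.25)
  mat <- tibble(chrom = mat_chr, start = mat_s,
                end = mat_s + cfg$mat_width, name = "mat",
                score = 0L, strand = ".")
  neo_specs <- list(c(ids[1], 0.70),
                    c(ids[min(3L, length(ids))], 0.30))
  neocen <- bind_rows(lapply(neo_specs, function(sp) {
    s <- as.integer(lens[[sp[1]]] * as.numeric(sp[2]))
    tibble(chrom = sp[1], start = s, end = s + cfg$neocen_width,
           name = "neocen", score = 0L, strand = ".")
  }))
  centromere <- mutate(core,
                       start = .data$start - cfg$het_flank_width,
                       end = .data$end + cfg$het_flank_width,
                       name = "centromere")
  list(ids = ids, lengths = lens, core = core, flank = flank,
       subtel = subtel, mat = mat, neocen = neocen,
       centromere = centromere)
}

#' Generate a synthetic genome with planted compositional domains
#'
#' Background sequence is drawn i.i.d. from `base_composition`;
#' centromere cores and neocentromere-like regions are drawn from the
#' biased Markov kernel of [biased_transition_matrix()], so their GC
#' content matches the background exactly in expectation while their
#' dinucleotide (hence 5-mer) usage is biased.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return List with `genome` (a [genome()] object) and `truth` (list
#'   of geometry tibbles: `core`, `flank`, `subtel`, `mat`, `neocen`,
#'   `centromere`).
#' @export
synth_genome <- function(cfg, seed = 1) {
  geo <- synth_geometry(cfg)
  P <- biased_transition_matrix(cfg$base_composition, cfg$bias_epsilon)
  pi <- cfg$base_composition
  biased <- bind_rows(geo$core, geo$neocen)
  chroms <- setNames(character(length(geo$ids)), geo$ids)
  for (i in seq_along(geo$ids)) {
    id <- geo$ids[i]
    L <- geo$lengths[[id]]
    set.seed(derive_seed(seed, index = i, key = "background"))
    codes <- sample.int(4L, L, replace = TRUE, prob = pi)
    b <- biased[biased$chrom == id, , drop = FALSE]
    if (nrow(b) > 0) {
      for (j in seq_len(nrow(b))) {
        set.seed(derive_seed(seed, index = i * 1000L + j, key = "biased"))
        w <- b$end[j] - b$start[j]
        codes[(b$start[j] + 1L):b$end[j]] <- markov_codes(w, P, pi)
      }
    }
    chroms[[id]] <- intToUtf8(c(65L, 67L, 71L, 84L)[codes])
  }
  list(genome = genome(chroms), truth = geo)
}

#' Emit annotation tracks consistent with a synthetic genome
#'
#' Produces CENP-A peaks (the planted cores), H3K9me2 peaks (flanks
#' and subtelomeric blocks), mating-type and neocentromere region
#' intervals, and a tRNA gene set: the configured cluster planted once
#' per centromere (inside the right heterochromatic flank, intra-gene
#' gaps well below the 1 kb clustering threshold) plus
#' `decoy_gene_count` singleton genes scattered outside centromeres
#' with >= 1 kb clearance from their neighbours.
#'
#' @param cfg A [synth_config()].
#' @param truth Geometry list from [synth_genome()].
#' @param seed Integer seed.
#' @return List of tibbles: `cenpa_peaks`, `h3k9_peaks`, `mat`,
#'   `neocen`, `centromeres`, `genes`.
#' @export
synth_annotations <- function(cfg, truth, seed = 1) {
  set.seed(derive_seed(seed, key = "annotations"))
  glen <- cfg$gene_length
  # planted clusters: right flank, 2 kb in from the core edge
  planted <- bind_rows(lapply(seq_len(nrow(truth$core)), function(i) {
    base <- truth$core$end[i] + 2000L
    amino <- substr(cfg$planted_cluster, 1, 1)
    strand <- substr(cfg$planted_cluster, 2, 2)
    starts <- base + (seq_along(amino) - 1L) * (glen + 300L)
    tibble(chrom = truth$core$chrom[i], start = starts,
           end = starts + glen, strand = strand, amino_acid = amino,
           anticodon = TRNA_TYPES$anticodon[match(amino, TRNA_TYPES$amino_acid)],
           planted = TRUE)
  }))
  # scattered decoys outside centromeres, >= 1 kb apart
  lens <- truth$lengths
  ids <- truth$ids
  probs <- lens / sum(lens)
  occupied <- bind_rows(
    truth$centromere[, c("chrom", "start", "end")],
    planted[, c("chrom", "start", "end")]
  )
  decoys <- list()
  tries <- 0L
  while (length(decoys) < cfg$decoy_gene_count) {
    tries <- tries + 1L
    if (tries > 200L * cfg$decoy_gene_count) {
      abort("could not place decoy genes")
    }
    ci <- ids[sample.int(length(ids), 1, prob = probs)]
    s <- as.integer(floor(stats::runif(1) * (lens[[ci]] - glen)))
    cand_s <- s - 1000L
    cand_e <- s + glen + 1000L
    o <- occupied[occupied$chrom == ci, , drop = FALSE]
    if (nrow(o) > 0 && any(cand_s < o$end & cand_e > o$start)) next
    occupied <- bind_rows(occupied, tibble(chrom = ci, start = s,
                                           end = s + glen))
    ty <- TRNA_TYPES[sample.int(nrow(TRNA_TYPES), 1), ]
    decoys[[length(decoys) + 1L]] <- tibble(
      chrom = ci, start = s, end = s + glen,
      strand = sample(c("+", "-"), 1),
      amino_acid = ty$amino_acid, anticodon = ty$anticodon,
      planted = FALSE
    )
  }
  genes <- bind_rows(planted, bind_rows(decoys)) |>
    arrange(match(.data$chrom, ids), .data$start)
  list(
    cenpa_peaks = truth$core,
    h3k9_peaks = bind_rows(truth$flank, truth$subtel),
    mat = truth$mat,
    neocen = truth$neocen,
    centromeres = truth$centromere,
    genes = genes
  )
}

#' Truth chromatin-group labels for synthetic windows
#'
#' Labels each window from the planted geometry by direct interval
#' arithmetic (independent of [classify_windows()]), applying the same
#' group definitions: CENP-A core coverage > 6 kb, neocentromere
#' overlap, mating-type majority coverage, heterochromatin majority
#' coverage adjacent to a CENP-A domain, subtelomere proximity.
#'
#' @param windows Window tibble from [make_windows()].
#' @param truth Geometry list from [synth_genome()].
#' @param telomere_proximity,cenpa_cov_min,half_cov,adjacency_gap As
#'   in [classify_windows()].
#' @return `windows` with an added `truth_group` factor column.
#' @export
synth_truth_labels <- function(windows, truth, telomere_proximity = 1e5,
                               cenpa_cov_min = 6000, half_cov = 0.5,
                               adjacency_gap = 1) {
  n <- nrow(windows)
  width <- windows$end - windows$start
  # plain per-window overlap sums (planted intervals never overlap)
  ovl_sum <- function(regions) {
    out <- numeric(n)
    for (j in seq_len(nrow(regions))) {
      same <- windows$chrom == regions$chrom[j]
      o <- pmin(windows$end, regions$end[j]) - pmax(windows$start, regions$start[j])
      out <- out + ifelse(same & o > 0, o, 0)
    }
    out
  }
  cov_core <- ovl_sum(truth$core)
  cov_het <- ovl_sum(bind_rows(truth$flank, truth$subtel))
  cov_mat <- ovl_sum(truth$mat)
  cov_neo <- ovl_sum(truth$neocen)
  is_cenpa <- cov_core > cenpa_cov_min
  # adjacency: gap <= adjacency_gap to a core interval or CENPA window
  anchors <- bind_rows(
    truth$core[, c("chrom", "start", "end")],
    windows[is_cenpa, c("chrom", "start", "end")]
  )
  near <- logical(n)
  for (j in seq_len(nrow(anchors))) {
    same <- windows$chrom == anchors$chrom[j]
    gap <- interval_gap(windows$start, windows$end,
                        anchors$start[j], anchors$end[j])
    near <- near | (same & gap <= adjacency_gap)
  }
  chrlen <- unname(truth$lengths[windows$chrom])
  near_end <- pmin(windows$start, chrlen - windows$end) < telomere_proximity
  lab <- rep("OTHER", n)
  lab[cov_het > half_cov * width & near_end] <- "SUBTEL"
  lab[cov_het > half_cov * width & near] <- "CEN_HET"
  lab[cov_mat > half_cov * width] <- "MAT"
  lab[cov_neo > 0] <- "NEOCEN"
  lab[is_cenpa] <- "CENPA"
  mutate(windows, truth_group = factor(lab, levels = GROUP_LEVELS))
}

#' Binomially sampled colony counts
#'
#' `n_white ~ Binomial(n_transformants, p_establish)` and
#' `n_half_sectored ~ Binomial(n_colonies, p_loss)`.
#'
#' @param p_establish,p_loss Event probabilities in `[0, 1]`.
#' @param n_transformants,n_colonies Trial counts.
#' @param seed Integer seed.
#' @param plasmid Label for the output row.
#' @return One-row tibble compatible with [colony_statistics()].
#' @export
synth_colony_counts <- function(p_establish, p_loss, n_transformants,
                                n_colonies, seed = 1,
                                plasmid = "synthetic") {
  stopifnot(p_establish >= 0, p_establish <= 1, p_loss >= 0, p_loss <= 1)
  set.seed(derive_seed(seed, key = "colonies"))
  tibble(
    plasmid = plasmid,
    n_transformants = as.integer(n_transformants),
    n_white = rbinom(1, n_transformants, p_establish),
    n_checked = NA_integer_, n_integrants = NA_integer_,
    n_colonies = as.integer(n_colonies),
    n_half_sectored = rbinom(1, n_colonies, p_loss)
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: genome, truth geometry, annotation tracks and
#' colony counts from one master seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Master seed.
#' @return List with `genome`, `truth`, `annotations`, `colonies`.
#' @export
synth_dataset <- function(cfg = synth_config(), seed = 1) {
  sg <- synth_genome(cfg, seed = seed)
  ann <- synth_annotations(cfg, sg$truth, seed = seed)
  col <- synth_colony_counts(cfg$p_establish, cfg$p_loss,
                             cfg$n_transformants, cfg$n_colonies,
                             seed = seed)
  list(genome = sg$genome, truth = sg$truth, annotations = ann,
       colonies = col)
}
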