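# Assignment of genome windows to chromatin groups from peak/region
# intervals, plus window selection helpers for the limited-PCA mode.

GROUP_LEVELS <- c("CENPA", "NEOCEN", "MAT", "CEN_HET", "SUBTEL", "OTHER")

#' Classify genome windows into six chromatin groups
#'
#' Each window receives exactly one label, assigned by the first
#' matching rule in priority order:
#'
#' * `CENPA`: CENP-A peak coverage strictly greater than
#'   `cenpa_cov_min` bp (default 6000, i.e. peaks covering >6 kb of a
#'   12 kb window);
#' * `NEOCEN`: the window overlaps a neocentromere region;
#' * `MAT`: more than `half_cov` of the window lies in a mating-type
#'   region;
#' * `CEN_HET`: H3K9me2 coverage greater than `half_cov` of the window
#'   and the window is within `adjacency_gap` bp (default 1; overlap
#'   counts) of a CENPA-labelled window or a CENP-A peak;
#' * `SUBTEL`: H3K9me2 coverage greater than `half_cov` of the window
#'   and the window lies within `telomere_proximity` bp of either
#'   chromosome end;
#' * `OTHER`: everything else.
#'
#' @param windows Window tibble from [make_windows()].
#' @param genome A [genome()] object (for chromosome bounds).
#' @param cenpa_peaks,h3k9_peaks,mat_regions,neocen_regions Interval
#'   tibbles (any may be `NULL`).
#' @param telomere_proximity Distance from a chromosome end below
#'   which a heterochromatic window counts as subtelomeric (bp,
#'   default 1e5).
#' @param cenpa_cov_min CENP-A coverage threshold in bp (strict `>`,
#'   default 6000).
#' @param half_cov Fraction of the window for the "more than half
#'   covered" rules (strict `>`, default 0.5).
#' @param adjacency_gap Maximum gap (bp) to a CENP-A domain for the
#'   `CEN_HET` rule (default 1).
#' @return `windows` with an added factor column `group`.
#' @export
classify_windows <- function(windows, genome,
                             cenpa_peaks = NULL, h3k9_peaks = NULL,
                             mat_regions = NULL, neocen_regions = NULL,
                             telomere_proximity = 1e5,
                             cenpa_cov_min = 6000, half_cov = 0.5,
                             adjacency_gap = 1) {
  for (x in list(cenpa_peaks, h3k9_peaks, mat_regions, neocen_regions)) {
    if (!is.null(x) && nrow(x) > 0) {
      unknown <- setdiff(unique(x$chrom), names(genome$lengths))
      if (length(unknown) > 0) {
        abort(sprintf("unknown chromosome in annotation: %s",
                      paste(unknown, collapse = ", ")))
      }
    }
  }
  n <- nrow(windows)
  width <- windows$end - windows$start
  cov_cenpa <- window_coverage(windows, cenpa_peaks)
  cov_h3k9 <- window_coverage(windows, h3k9_peaks)
  cov_mat <- window_coverage(windows, mat_regions)
  is_cenpa <- cov_cenpa > cenpa_cov_min
  is_neo <- overlaps_any(windows, neocen_regions)
  is_mat <- cov_mat > half_cov * width
  het <- cov_h3k9 > half_cov * width

  # adjacency (gap <= adjacency_gap) to a CENP-A peak or CENPA window
  anchors <- bind_rows(
    if (!is.null(cenpa_peaks)) cenpa_peaks[, c("chrom", "start", "end")],
    windows[is_cenpa, c("chrom", "start", "end")]
  )
  near_cenpa <- logical(n)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    grown <- mutate(anchors,
                    start = pmax(0L, .data$start - as.integer(adjacency_gap)),
                    end = .data$end + as.integer(adjacency_gap))
    near_cenpa <- overlaps_any(windows, grown)
  }

  chrlen <- unname(genome$lengths[windows$chrom])
  near_end <- pmin(windows$start, chrlen - windows$end) < telomere_proximity

  group <- rep("OTHER", n)
  group[het & near_end] <- "SUBTEL"
  group[het & near_cenpa] <- "CEN_HET"
  group[is_mat] <- "MAT"
  group[is_neo] <- "NEOCEN"
  group[is_cenpa] <- "CENPA"
  mutate(windows, group = factor(group, levels = GROUP_LEVELS))
}

#' Select the top-n most enriched windows
#'
#' Returns the `n` highest-scoring windows that do not overlap
#' `exclude`; ties are broken by genomic order (chromosome order of
#' appearance, then start). Used for the limited-PCA mode where the
#' top 11 most highly enriched 12 kb regions stand in for unassembled
#' centromeres.
#'
#' @param windows Window tibble containing a numeric score column.
#' @param n Number of windows to select.
#' @param exclude Optional interval tibble; overlapping windows are
#'   removed before ranking.
#' @param score Name of the score column (default `"score"`).
#' @return The selected rows, highest score first.
#' @export
top_enriched_windows <- function(windows, n, exclude = NULL,
                                 score = "score") {
  if (n < 1) abort("n must be >= 1")
  s <- windows[[score]]
  if (is.null(s)) abort(sprintf("no column `%s` in windows", score))
  if (any(!is.finite(s))) abort("scores must be finite")
  keep <- !overlaps_any(windows, exclude)
  cand <- windows[keep, , drop = FALSE]
  if (n > nrow(cand)) {
    abort(sprintf("requested %d windows but only %d available", n, nrow(cand)))
  }
  chrom_rank <- match(cand$chrom, unique(windows$chrom))
  ord <- order(-cand[[score]], chrom_rank, cand$start)
  cand[ord[seq_len(n)], , drop = FALSE]
}

#' Randomly selected control windows
#'
#' Samples `n` windows uniformly without replacement from the windows
#' not overlapping `exclude` (e.g. randomly selected non-centromeric
#' sequences), returned in genomic order.
#'
#' @inheritParams top_enriched_windows
#' @param seed Optional integer seed.
#' @return A tibble of `n` window rows in genomic order.
#' @export
random_control_windows <- function(windows, n, exclude = NULL, seed = NULL) {
  if (n == 0) return(windows[0, , drop = FALSE])
  keep <- !overlaps_any(windows, exclude)
  cand <- windows[keep, , drop = FALSE]
  if (n > nrow(cand)) {
    abort(sprintf("requested %d windows but only %d eligible", n, nrow(cand)))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(nrow(cand), n))
  cand[idx, , drop = FALSE]
}
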