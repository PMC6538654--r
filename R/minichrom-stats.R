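# Minichromosome establishment-frequency and loss-rate arithmetic
# from colony counts.

#' Centromere establishment frequency from transformant counts
#'
#' `100 * n_white_adjusted / n_transformants`, reported half-up to one
#' decimal. White/pale-pink colonies on replica plating indicate
#' minichromosome retention, i.e. established centromere function.
#' When a sample of white colonies was re-streaked to detect
#' integration events (false-positive whites), the white count is
#' adjusted by the detected integrant fraction:
#' `n_white * (1 - n_integrants_detected / n_white_checked)`.
#'
#' @param n_transformants Total transformants analysed (> 0).
#' @param n_white White/pale-pink colonies on replica plating.
#' @param n_white_checked Number of white colonies re-streaked
#'   (optional).
#' @param n_integrants_detected Integrants found among
#'   `n_white_checked` (optional).
#' @return Establishment frequency in percent, rounded half-up to one
#'   decimal.
#' @examples
#' establishment_frequency(217, 204) # 94.0
#' establishment_frequency(100, 10, 10, 2) # 8.0
#' @export
establishment_frequency <- function(n_transformants, n_white,
                                    n_white_checked = NULL,
                                    n_integrants_detected = NULL) {
  assert_count(n_transformants, "n_transformants", min = 1)
  assert_count(n_white, "n_white")
  if (n_white > n_transformants) abort("n_white exceeds n_transformants")
  adj <- n_white
  if (!is.null(n_white_checked) && !is.null(n_integrants_detected) &&
      !is.na(n_white_checked) && n_white_checked > 0) {
    assert_count(n_white_checked, "n_white_checked", min = 1)
    assert_count(n_integrants_detected, "n_integrants_detected")
    if (n_white_checked > n_white) abort("n_white_checked exceeds n_white")
    if (n_integrants_detected > n_white_checked) {
      abort("n_integrants_detected exceeds n_white_checked")
    }
    adj <- n_white * (1 - n_integrants_detected / n_white_checked)
  }
  round_half_up(100 * adj / n_transformants, 1)
}

#' Minichromosome loss rate per division from the half-sector assay
#'
#' Colonies that are 50% or more red lost the minichromosome at the
#' first division after plating; the loss rate per division is the
#' number of half-sectored colonies as a percentage of all
#' (non-pure-red) colonies, half-up to one decimal.
#'
#' @param n_colonies_total All colonies counted, pure reds excluded
#'   (> 0).
#' @param n_half_sectored Colonies at least half red.
#' @return Loss rate per division in percent, one decimal.
#' @examples
#' loss_rate_per_division(3284, 190) # 5.8
#' @export
loss_rate_per_division <- function(n_colonies_total, n_half_sectored) {
  assert_count(n_colonies_total, "n_colonies_total", min = 1)
  assert_count(n_half_sectored, "n_half_sectored")
  if (n_half_sectored > n_colonies_total) {
    abort("n_half_sectored exceeds n_colonies_total")
  }
  round_half_up(100 * n_half_sectored / n_colonies_total, 1)
}

#' Establishment and loss statistics for a colony-count table
#'
#' Data-frame-in, tibble-out wrapper: for each row computes the
#' establishment frequency (with integrant adjustment when
#' `n_checked`/`n_integrants` are given) and, where colony counts are
#' present, the loss rate per division. The mean loss rate across
#' transformants of one construct is the count-weighted pooled rate
#' (total half-sectored over total colonies).
#'
#' @param counts Tibble with columns `plasmid`, `n_transformants`,
#'   `n_white`, and optionally `n_checked`, `n_integrants`,
#'   `n_colonies`, `n_half_sectored`.
#' @return `counts` with added `establishment_pct` and `loss_pct`
#'   columns (NA where counts are missing).
#' @export
colony_statistics <- function(counts) {
  n <- nrow(counts)
  col <- function(nm) if (nm %in% names(counts)) counts[[nm]] else rep(NA, n)
  n_checked <- col("n_checked")
  n_integrants <- col("n_integrants")
  n_colonies <- col("n_colonies")
  n_half <- col("n_half_sectored")
  est <- rep(NA_real_, n)
  loss <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    chk <- n_checked[[i]]
    est[i] <- establishment_frequency(
      counts$n_transformants[[i]], counts$n_white[[i]],
      if (!is.na(chk)) chk else NULL,
      if (!is.na(chk)) n_integrants[[i]] else NULL
    )
    if (!is.na(n_colonies[[i]]) && n_colonies[[i]] > 0) {
      loss[i] <- loss_rate_per_division(n_colonies[[i]], n_half[[i]])
    }
  }
  mutate(counts, establishment_pct = est, loss_pct = loss)
}

#' Published minichromosome establishment and stability rates
#'
#' The published establishment frequencies and per-division loss rates
#' of chimeric minichromosomes carrying fission-yeast central-core
#' fragments, assayed in *S. pombe* cells over-expressing CENP-A:
#' percent values with the number of transformants (`establishment_n`)
#' or colonies screened (`loss_n`). `NA` loss rates correspond to
#' minichromosomes that never established centromere function.
#'
#' @return A tibble with columns `plasmid`, `establishment_pct`,
#'   `establishment_n`, `loss_pct`, `loss_n`.
#' @export
minichromosome_rates <- function() {
  tibble(
    plasmid = c("pK-Sp-cnt2-8.5kb", "pK-So-cnt2-10kb", "pK-So-cnt3-6.5kb",
                "pK-So-cnt2-6.5kb", "pK-So-cnt2-4.7kb", "pK-So-cnt1-3.2kb",
                "pK-So-cnt3-2.6kb", "pKp-So-cnt3-6.5kb", "pKp-So-cnt3-3.6kb",
                "pKp"),
    establishment_pct = c(94, 36.4, 40.1, 28.1, 5.2, 1.9, 0.3, 6.6, 0, 0),
    establishment_n = c(217L, 88L, 262L, 208L, 973L, 1529L, 1443L, 916L,
                        1538L, 295L),
    loss_pct = c(5.8, 11.2, 5.8, 6.6, 6.8, 11.5, 21.1, 15.9, NA, NA),
    loss_n = c(3284L, 1636L, 3705L, 3621L, 7176L, 2017L, 1237L, 2099L,
               NA, NA)
  )
}

#' Round-trip a published percentage through integer counts
#'
#' Reconstructs the integer event count behind a printed percentage as
#' `round(rate / 100 * n)` (half-up) and recomputes the percentage at
#' one decimal. Used to check the published-table arithmetic.
#'
#' @param rate Printed percentage.
#' @param n Printed denominator.
#' @return One-row tibble with `count` and `recomputed_pct`.
#' @export
reconstruct_rate <- function(rate, n) {
  count <- floor(rate / 100 * n + 0.5)
  tibble(count = as.integer(count),
         recomputed_pct = round_half_up(100 * count / n, 1))
}
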