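# shared low-level helpers: sequence encoding, k-mer naming, seed
# derivation, half-up rounding

# ASCII lookup: A,C,G,T -> 0:3, all other bytes -> -1 (ambiguity codes
# are kept but never counted)
.encode_lut <- local({
  lut <- rep(-1L, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut
})

encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  if (anyNA(v)) abort("sequence contains non-ASCII characters")
  .encode_lut[v]
}

decode_dna <- function(codes) {
  stopifnot(all(codes >= 0L & codes <= 3L))
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

#' All k-mers over ACGT in lexicographic order
#'
#' @param k word length (1--12).
#' @return Character vector of length `4^k`.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1, k <= 12)
  nb <- 4L^k
  idx <- 0:(nb - 1L)
  base <- c("A", "C", "G", "T")
  cols <- lapply(seq_len(k), function(j) base[(idx %/% 4L^(k - j)) %% 4L + 1L])
  do.call(paste0, cols)
}

# fraction of unambiguous letters that are G or C
gc_fraction <- function(codes) {
  ok <- codes >= 0L
  if (!any(ok)) return(NA_real_)
  sum(codes == 1L | codes == 2L) / sum(ok)
}

# deterministic 31-bit substream seed from a master seed and a key
# (integer index and/or string); cheap multiplicative hash, collisions
# irrelevant for RNG-stream separation
derive_seed <- function(master, index = 0L, key = "") {
  h <- 0
  if (nzchar(key)) {
    v <- utf8ToInt(key)
    h <- sum(v * seq_along(v)) %% 2147483647
  }
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + as.numeric(index) * 30269 + h * 131) %% m
  as.integer(s + 1) # avoid 0
}

# round half-up to `digits` decimals (Table-style formatting; round()
# is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# gap between two half-open intervals on the same chromosome:
# negative when they overlap, 0 when abutting
interval_gap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) - pmin(end1, end2)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
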