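# Genome container, FASTA/BED/GFF3 input, windowing and interval
# coverage. Coordinates are 0-based half-open everywhere internally;
# GFF3 (1-based inclusive) is converted on read.

IUPAC_DNA <- "ACGTRYSWKMBDHVN"

#' Construct a genome from named chromosome sequences
#'
#' A genome is an ordered set of chromosome sequences over the IUPAC
#' DNA alphabet. Sequences are upper-cased; chromosome ids must be
#' unique and sequences non-empty.
#'
#' @param chromosomes Named character vector of DNA sequences.
#' @return An object of class `censcape_genome` with elements
#'   `chromosomes` (named character vector) and `lengths` (named
#'   integer vector).
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT", chr2 = "TTTTAAAA"))
#' g$lengths
#' @export
genome <- function(chromosomes) {
  if (length(chromosomes) == 0) abort("no records")
  ids <- names(chromosomes)
  if (is.null(ids) || any(!nzchar(ids))) abort("all chromosomes must be named")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate chromosome id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(chromosomes)
  if (any(!nzchar(seqs))) abort("chromosome sequences must be non-empty")
  bad <- regexpr(sprintf("[^%s]", IUPAC_DNA), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("non-IUPAC character in '%s' at position %d", ids[i], bad[i]))
  }
  structure(
    list(chromosomes = seqs, lengths = setNames(nchar(seqs), ids)),
    class = "censcape_genome"
  )
}

#' @export
print.censcape_genome <- function(x, ...) {
  cat(sprintf("<censcape_genome> %d chromosome(s), %s bp total\n",
              length(x$chromosomes), format(sum(x$lengths), big.mark = ",")))
  for (id in names(x$lengths)) {
    cat(sprintf("  %s: %s bp\n", id, format(x$lengths[[id]], big.mark = ",")))
  }
  invisible(x)
}

#' Read a multi-record FASTA file into a genome
#'
#' Record order is preserved, lower-case letters are upper-cased and
#' headers are parsed up to the first whitespace. Duplicate ids and
#' non-IUPAC characters are errors.
#'
#' @param path Path to a FASTA file.
#' @return A [genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort("no records")
  ids <- sub("\\s.*$", "", names(set))
  genome(setNames(as.character(set), ids))
}

#' Extract the sequence of a half-open interval
#'
#' @param genome A [genome()] object.
#' @param chrom Chromosome id.
#' @param start,end 0-based half-open coordinates.
#' @return A character scalar.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  seq <- genome$chromosomes[[chrom]]
  if (is.null(seq)) abort(sprintf("unknown chromosome: %s", chrom))
  if (start < 0 || end > nchar(seq) || start >= end) {
    abort(sprintf("invalid range %s:%d-%d", chrom, start, end))
  }
  substr(seq, start + 1, end)
}

# standard 6-column interval tibble used throughout
new_intervals <- function(chrom, start, end, name = ".", score = 0L,
                          strand = ".") {
  tibble(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), name = as.character(name),
    score = score, strand = as.character(strand)
  )
}

#' Read genomic intervals from BED or GFF3
#'
#' BED (3--6 tab-separated columns) is read as 0-based half-open
#' unchanged; GFF3 (1-based inclusive) is converted to 0-based
#' half-open (`start - 1`, `end`). The strand column is honoured and
#' `.` is allowed.
#'
#' @param path Path to the interval file.
#' @param format `"bed"` or `"gff3"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "bed") read_bed_impl(path) else read_gff3_impl(path)
}

read_bed_impl <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0) abort("no intervals in file")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("line %d: BED requires at least 3 columns", idx[which(nf < 3)[1]]))
  }
  get_col <- function(j, default) {
    vapply(fields, function(f) if (length(f) >= j) f[[j]] else default, "")
  }
  start <- suppressWarnings(as.integer(get_col(2, NA)))
  end <- suppressWarnings(as.integer(get_col(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad) > 0) abort(sprintf("line %d: invalid coordinates", idx[bad[1]]))
  rev_ <- which(start >= end)
  if (length(rev_) > 0) {
    abort(sprintf("line %d: start >= end (%d >= %d)",
                  idx[rev_[1]], start[rev_[1]], end[rev_[1]]))
  }
  col5 <- get_col(5, "0")
  strand <- get_col(6, ".")
  # tolerate 5-column files that put the strand where the score goes
  misplaced <- col5 %in% c("+", "-") & strand == "."
  strand[misplaced] <- col5[misplaced]
  col5[misplaced] <- "0"
  score <- suppressWarnings(as.numeric(col5))
  score[is.na(score)] <- 0
  new_intervals(
    chrom = get_col(1, "."), start = start, end = end,
    name = get_col(4, "."),
    score = if (all(score == floor(score))) as.integer(score) else score,
    strand = strand
  )
}

read_gff3_impl <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) abort("no intervals in file")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  nm <- rep(".", nrow(df))
  for (col in c("Name", "ID", "type")) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      fill <- nm == "." & !is.na(v) & nzchar(v)
      nm[fill] <- v[fill]
    }
  }
  # GRanges is 1-based inclusive; convert to 0-based half-open
  start0 <- df$start - 1L
  end0 <- df$end
  bad <- which(start0 >= end0)
  if (length(bad) > 0) {
    abort(sprintf("record %d: start >= end after conversion", bad[1]))
  }
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "."
  score <- if ("score" %in% names(df)) df$score else 0L
  score[is.na(score)] <- 0L
  new_intervals(
    chrom = as.character(df$seqnames), start = start0, end = end0,
    name = nm, score = score, strand = strand
  )
}

#' Write intervals as 6-column BED
#'
#' Inverse of `read_intervals(..., format = "bed")` for the six
#' standard columns.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`).
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  x <- tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = intervals$name %||% ".",
    score = intervals$score %||% 0L,
    strand = intervals$strand %||% "."
  )
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Tile a genome into fixed-length overlapping windows
#'
#' Windows of `window_len` bp start at position 0 of each chromosome
#' and advance by `window_len - overlap`; partial terminal windows are
#' dropped, so every window has the full length. The defaults are the
#' 12 kb / 4.5 kb-overlap windows used for 5-mer profiling.
#'
#' @param genome A [genome()] object.
#' @param window_len Window length in bp (default 12000).
#' @param overlap Overlap between consecutive windows in bp (default
#'   4500); the step is `window_len - overlap`.
#' @return A tibble with columns `chrom`, `start`, `end`, `index`
#'   (1-based ordinal within its chromosome) and `window_id`
#'   (`chrom:start-end`), ordered by chromosome then start.
#' @examples
#' g <- genome(c(chr1 = strrep("ACGT", 5000)))
#' make_windows(g)
#' @export
make_windows <- function(genome, window_len = 12000, overlap = 4500) {
  if (overlap < 0 || overlap >= window_len) {
    abort("must have 0 <= overlap < window_len")
  }
  step <- window_len - overlap
  out <- lapply(names(genome$lengths), function(id) {
    L <- genome$lengths[[id]]
    if (L < window_len) return(NULL)
    starts <- seq.int(0L, L - window_len, by = step)
    tibble(
      chrom = id, start = as.integer(starts),
      end = as.integer(starts + window_len),
      index = seq_along(starts)
    )
  })
  out <- bind_rows(out)
  if (nrow(out) > 0) {
    out$window_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  } else {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  index = integer(), window_id = character())
  }
  out
}

#' Covered basepairs of a window by a set of peaks
#'
#' Total bp of the union of the peak intersections with the window;
#' only peaks on the window's chromosome count.
#'
#' @param window A single-row interval tibble or list with `chrom`,
#'   `start`, `end`.
#' @param peaks Interval tibble.
#' @return Covered bp, between 0 and the window length.
#' @export
interval_coverage <- function(window, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(0L)
  p <- peaks[peaks$chrom == window$chrom[[1]], , drop = FALSE]
  if (nrow(p) == 0) return(0L)
  s <- pmax(p$start, window$start[[1]])
  e <- pmin(p$end, window$end[[1]])
  keep <- s < e
  if (!any(keep)) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1L, end = e[keep]))
  sum(IRanges::width(r))
}

# vectorized coverage of many windows by a peak set, per chromosome
# (Rle coverage + viewSums); returns bp per window row
window_coverage <- function(windows, peaks) {
  cov <- integer(nrow(windows))
  if (is.null(peaks) || nrow(peaks) == 0 || nrow(windows) == 0) return(cov)
  for (id in unique(windows$chrom)) {
    wi <- which(windows$chrom == id)
    p <- peaks[peaks$chrom == id, , drop = FALSE]
    if (nrow(p) == 0) next
    maxend <- max(c(windows$end[wi], p$end))
    rle <- IRanges::coverage(
      IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end)),
      width = maxend
    )
    v <- IRanges::Views(rle, start = windows$start[wi] + 1L,
                        end = windows$end[wi])
    cov[wi] <- as.integer(IRanges::viewSums(v))
  }
  cov
}

# does each window overlap any interval in `x` (>= 1 bp)?
overlaps_any <- function(windows, x) {
  hit <- logical(nrow(windows))
  if (is.null(x) || nrow(x) == 0 || nrow(windows) == 0) return(hit)
  for (id in unique(windows$chrom)) {
    wi <- which(windows$chrom == id)
    p <- x[x$chrom == id, , drop = FALSE]
    if (nrow(p) == 0) next
    q <- IRanges::IRanges(start = windows$start[wi] + 1L, end = windows$end[wi])
    s <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    hit[wi] <- IRanges::overlapsAny(q, s)
  }
  hit
}
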