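#' Nx continuity statistic
#'
#' Sorts the lengths descending and returns the length at which the
#' cumulative sum first reaches `x` percent of the total (so `nx(l, 50)` is
#' the N50, `nx(l, 90)` the N90).
#'
#' @param lengths Sequence lengths in bp (non-empty).
#' @param x Percent threshold in `(0, 100]`.
#' @return The Nx length in bp.
#' @examples
#' nx(c(40, 30, 20, 10), 50)
#' @export
nx <- function(lengths, x) {
  if (length(lengths) == 0) stop("`lengths` must be non-empty")
  if (x <= 0 || x > 100) stop("`x` must be in (0, 100]")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= x / 100 * sum(as.numeric(s)))[1]]
}

#' Count sequences at or above a length threshold
#'
#' @param lengths Sequence lengths in bp.
#' @param threshold Minimum length (>= 0).
#' @return Number of lengths `>= threshold`.
#' @export
count_above <- function(lengths, threshold) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  sum(lengths >= threshold)
}

#' Percentage ratio with half-up rounding
#'
#' `100 * numerator / denominator`, half-up rounded to `decimals` — the
#' arithmetic behind every printed assembly/annotation percentage.
#'
#' @param numerator,denominator The ratio terms; `denominator > 0`.
#' @param decimals Decimals to keep.
#' @return The percentage.
#' @examples
#' percent_ratio(28144, 30350, 2)
#' @export
percent_ratio <- function(numerator, denominator, decimals = 2) {
  if (denominator <= 0) stop("`denominator` must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Kosambi map-function conversion
#'
#' Converts a recombination fraction to genetic distance allowing for
#' crossover interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` centiMorgans.
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Genetic distance in centiMorgans.
#' @examples
#' kosambi_cm(0.1)
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("`r` must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Filter predicted gene models
#'
#' Applies the two independent removal rules used after consensus gene
#' prediction: a model is dropped if its coding region is shorter than
#' `min_cds` bp, or if it is supported by ab initio evidence only, hits
#' nothing beyond UniRef, and is expressed below `min_fpkm`. Input order is
#' preserved.
#'
#' @param records Data frame with columns `cds_length`, `ab_initio_only`
#'   (logical), `uniref_only` (logical), `fpkm`; extra columns pass
#'   through.
#' @param min_cds Minimum coding length in bp (default 150).
#' @param min_fpkm Expression floor for ab-initio-only, UniRef-only models
#'   (default 5 FPKM).
#' @return The surviving records as a tibble.
#' @export
filter_gene_models <- function(records, min_cds = 150, min_fpkm = 5) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  short <- records$cds_length < min_cds
  weak <- records$ab_initio_only & records$uniref_only &
    records$fpkm < min_fpkm
  records[!(short | weak), ]
}

#' Summarise assembly continuity
#'
#' @param lengths Scaffold or contig lengths in bp, or the path to a FASTA
#'   file (lengths are taken from the sequences) or to a one-length-per-line
#'   text file.
#' @return An `assembly_metrics` object (list with `lengths`,
#'   `total_length`, `n50`, `n90`, `largest`, `count`, `count_above_n90`).
#' @examples
#' assembly_metrics(c(40, 30, 20, 10))
#' @export
assembly_metrics <- function(lengths) {
  if (is.character(lengths) && length(lengths) == 1) {
    lengths <- if (grepl("\\.f(ast)?a$", lengths, ignore.case = TRUE)) {
      Biostrings::width(Biostrings::readDNAStringSet(lengths))
    } else {
      scan(lengths, what = numeric(), quiet = TRUE)
    }
  }
  if (length(lengths) == 0) stop("no sequence lengths")
  n90 <- nx(lengths, 90)
  structure(list(lengths = lengths,
                 total_length = sum(as.numeric(lengths)),
                 n50 = nx(lengths, 50), n90 = n90,
                 largest = max(lengths), count = length(lengths),
                 count_above_n90 = count_above(lengths, n90)),
            class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0("<assembly_metrics> %d sequences, %s bp total\n",
                     "  N50 %s | N90 %s | largest %s | >= N90: %d\n"),
              x$count, format(x$total_length, big.mark = ","),
              format(x$n50, big.mark = ","), format(x$n90, big.mark = ","),
              format(x$largest, big.mark = ","), x$count_above_n90))
  invisible(x)
}

#' @method tidy assembly_metrics
#' @export
tidy.assembly_metrics <- function(x, ...) {
  tibble::tibble(statistic = c("total_length", "n50", "n90", "largest",
                               "count", "count_above_n90"),
                 value = c(x$total_length, x$n50, x$n90, x$largest,
                           x$count, x$count_above_n90))
}

#' @method glance assembly_metrics
#' @export
glance.assembly_metrics <- function(x, ...) {
  tibble::tibble(total_length = x$total_length, n50 = x$n50, n90 = x$n90,
                 largest = x$largest, count = x$count,
                 count_above_n90 = x$count_above_n90)
}
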