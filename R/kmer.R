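#' Count canonical k-mers and build the depth histogram
#'
#' Splits every read into its k-length windows, counts each k-mer under its
#' canonical form (the lexicographic minimum of the k-mer and its reverse
#' complement), and tabulates how many distinct k-mer species were seen at
#' each depth. Windows containing a non-ACGT character are rejected and
#' tallied in the `rejected_windows` attribute. Counting is exact and
#' in-memory; the histogram is capped at `cap` (deeper species accumulate
#' in the cap bin).
#'
#' @param reads A `read_set`, a character vector of sequences, or the path
#'   to a FASTQ/FASTA file.
#' @param k Odd k-mer size in `[1, 31]`; default 17. Odd k guarantees no
#'   k-mer equals its own reverse complement.
#' @param cap Maximum recorded depth.
#' @return A `kmer_histogram`: a tibble with columns `depth` and `count`
#'   (ascending depth, zero-count depths omitted) and attributes `k`,
#'   `total_instances` (sum of depth x count) and `rejected_windows`.
#' @examples
#' count_kmers("ACGTA", k = 3)
#' @export
count_kmers <- function(reads, k = 17, cap = 10000) {
  if (k %% 2 == 0) stop("`k` must be odd")
  if (k < 1 || k > 31) stop("`k` must be in [1, 31]")
  seqs <- if (inherits(reads, "read_set")) {
    reads$reads$sequence
  } else if (is.character(reads) && length(reads) == 1 &&
             file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads)) "fastq" else "fasta"
    as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  } else if (is.character(reads)) {
    reads
  } else {
    stop("`reads` must be a read_set, character vector, or file path")
  }
  res <- kmer_hist_cpp(seqs, as.integer(k), as.integer(cap))
  new_kmer_histogram(
    tibble::tibble(depth = as.integer(res$depth), count = res$count),
    k = k, rejected_windows = res$rejected_windows)
}

new_kmer_histogram <- function(df, k, rejected_windows = 0) {
  stopifnot(all(df$depth >= 1), all(df$count >= 0))
  df <- dplyr::arrange(df, .data$depth)
  structure(df,
            class = c("kmer_histogram", class(tibble::tibble()))) -> out
  attr(out, "k") <- k
  attr(out, "total_instances") <- sum(as.numeric(df$depth) * df$count)
  attr(out, "rejected_windows") <- rejected_windows
  out
}

#' @export
as.data.frame.kmer_histogram <- function(x, ...) {
  data.frame(depth = x$depth, count = x$count)
}

#' Coerce a depth/count table to a k-mer histogram
#'
#' @param df Data frame with columns `depth` and `count`.
#' @param k The k-mer size the table was computed with.
#' @return A `kmer_histogram`.
#' @export
as_kmer_histogram <- function(df, k) {
  new_kmer_histogram(tibble::as_tibble(df[c("depth", "count")]), k = k)
}

#' Locate the sequencing-error depth cutoff
#'
#' Sequencing errors produce a mass of near-unique k-mers at low depth;
#' genomic k-mers sit in peaks at higher depth. The cutoff is the depth of
#' the first local minimum of the species counts scanning upward from the
#' lowest observed depth (ties broken toward the lower depth). If the
#' histogram is monotone decreasing throughout, 1 is returned.
#'
#' @param hist A `kmer_histogram` (or depth/count data frame).
#' @return The cutoff depth (integer).
#' @export
find_error_cutoff <- function(hist) {
  if (nrow(hist) == 0) stop("empty histogram")
  d <- hist$depth
  n <- hist$count
  m <- length(n)
  if (m == 1) return(1L)
  for (i in seq_len(m)) {
    left_ok <- i == 1 || n[i] <= n[i - 1]
    right_ok <- i < m && n[i] <= n[i + 1]
    if (left_ok && right_ok) return(d[i])
  }
  1L
}

#' Detect the heterozygous and homozygous spectrum peaks
#'
#' Smooths the dense (zero-filled) histogram with a centered moving average
#' and searches for prominent local maxima above the error cutoff. The
#' homozygous peak is the highest-depth prominent maximum; a heterozygous
#' peak is reported if a prominent maximum lies within `het_range` times
#' the homozygous depth (in a diploid read spectrum, k-mers spanning
#' heterozygous sites appear at about half the homozygous depth). Each
#' candidate is refined to the raw-count argmax within one depth unit; ties
#' break toward the lower depth.
#'
#' @param hist A `kmer_histogram`.
#' @param error_cutoff Depth below which species are treated as error;
#'   default [find_error_cutoff()].
#' @param smooth_window Width of the centered moving average (odd).
#' @param het_range Relative depth window searched for the heterozygous
#'   peak, as a fraction of the homozygous depth.
#' @param prominence Minimum smoothed height of a reported maximum, as a
#'   fraction of the tallest smoothed bin above the cutoff.
#' @return A `spectrum_peaks` object: list with `error_cutoff`, `het_peak`
#'   (`NA` if absent), `hom_peak`.
#' @examples
#' h <- as_kmer_histogram(
#'   data.frame(depth = c(13, 14, 15, 27, 28, 29),
#'              count = c(5, 100, 6, 4, 90, 5)), k = 17)
#' detect_peaks(h, error_cutoff = 3)
#' @export
detect_peaks <- function(hist, error_cutoff = find_error_cutoff(hist),
                         smooth_window = 3, het_range = c(0.35, 0.65),
                         prominence = 0.05) {
  keep <- hist$depth > error_cutoff
  if (!any(keep)) stop("no k-mer species above the error cutoff")
  dmin <- min(hist$depth[keep])
  dmax <- max(hist$depth[keep])
  pad <- smooth_window %/% 2
  grid <- (dmin - pad):(dmax + pad)
  dense <- numeric(length(grid))
  dense[match(hist$depth[keep], grid)] <- hist$count[keep]
  sm <- stats::filter(dense, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm[is.na(sm)] <- 0
  interior <- seq(pad + 1, length(grid) - pad)
  # leftmost-of-plateau local maxima of the smoothed signal
  is_max <- vapply(interior, function(i) {
    sm[i] >= sm[i + 1] && (sm[i] > sm[i - 1] ||
      (i == pad + 1 && sm[i] >= sm[i - 1]))
  }, logical(1))
  cand <- grid[interior][is_max]
  heights <- sm[interior][is_max]
  prominent <- heights >= prominence * max(sm)
  if (!any(prominent)) stop("no prominent peak above the error cutoff")
  cand <- cand[prominent]
  heights <- heights[prominent]

  refine <- function(d) {
    nb <- (d - 1):(d + 1)
    raw <- dense[match(nb, grid)]
    raw[is.na(raw)] <- 0
    nb[which.max(raw)]
  }
  hom <- refine(max(cand))
  lo <- het_range[1] * hom
  hi <- het_range[2] * hom
  in_win <- cand >= lo & cand <= hi
  het <- if (any(in_win)) {
    w <- cand[in_win][which.max(heights[in_win])]
    refine(w)
  } else NA_integer_
  structure(list(error_cutoff = as.integer(error_cutoff),
                 het_peak = as.integer(het), hom_peak = as.integer(hom)),
            class = "spectrum_peaks")
}

#' @export
print.spectrum_peaks <- function(x, ...) {
  cat(sprintf("<spectrum_peaks> error cutoff %d | het %s | hom %d\n",
              x$error_cutoff,
              ifelse(is.na(x$het_peak), "absent", x$het_peak), x$hom_peak))
  invisible(x)
}

#' Spectral genome-size estimate
#'
#' Divides the total number of genomic k-mer instances (depth x species
#' summed over depths at or above the error cutoff) by the homozygous peak
#' depth. This is the standard k-mer survey estimate of haploid genome
#' size.
#'
#' @param hist A `kmer_histogram`.
#' @param peaks A `spectrum_peaks` (default: detected from `hist`).
#' @return Estimated haploid genome size in bp (rounded to integer).
#' @export
estimate_genome_size <- function(hist, peaks = detect_peaks(hist)) {
  if (is.null(peaks$hom_peak) || is.na(peaks$hom_peak) ||
      peaks$hom_peak == 0)
    stop("homozygous peak undefined")
  keep <- hist$depth >= peaks$error_cutoff
  total <- sum(as.numeric(hist$depth[keep]) * hist$count[keep])
  if (total == 0) stop("no k-mer instances above the error cutoff")
  round(total / peaks$hom_peak)
}

#' Read / write a k-mer depth histogram TSV
#'
#' Two whitespace-separated columns (`depth`, `count`), no header,
#' ascending depth — the layout common k-mer counters emit.
#'
#' @param path File path.
#' @param k k-mer size to attach on read.
#' @return `read_kmer_histogram` returns a `kmer_histogram`;
#'   `write_kmer_histogram` returns `path` invisibly.
#' @export
read_kmer_histogram <- function(path, k = 17) {
  df <- utils::read.table(path, col.names = c("depth", "count"))
  as_kmer_histogram(df, k = k)
}

#' @param hist A `kmer_histogram`.
#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist[c("depth", "count")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
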