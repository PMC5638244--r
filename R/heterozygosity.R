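#' K-mer heterozygous ratio from the heterozygous species fraction
#'
#' Converts the fraction `a1` of genomic k-mer species assigned to the
#' heterozygous (half-depth) spectrum component into the k-mer heterozygous
#' ratio: `KHR = (a1/2) / (2 - a1/2)`.
#'
#' @param a1 Heterozygous species fraction in `[0, 1]`.
#' @return KHR in `[0, 1/3]`.
#' @examples
#' khr_from_a1(0.8512)
#' @export
khr_from_a1 <- function(a1) {
  if (any(a1 < 0 | a1 > 1)) stop("`a1` must be in [0, 1]")
  (a1 / 2) / (2 - a1 / 2)
}

#' Per-base heterozygosity from KHR
#'
#' `BHR = KHR / k`, under the approximation that each SNP creates k new
#' k-mers.
#'
#' @param khr K-mer heterozygous ratio (>= 0).
#' @param k k-mer size (>= 1).
#' @return Base heterozygous ratio (per-base fraction).
#' @examples
#' bhr_from_khr(khr_from_a1(0.8512), 17)
#' @export
bhr_from_khr <- function(khr, k) {
  if (any(khr < 0)) stop("`khr` must be >= 0")
  if (any(k < 1)) stop("`k` must be >= 1")
  khr / k
}

#' Heterozygous k-mer species fraction from a spectrum
#'
#' Splits the genomic species (depth at or above the error cutoff) at the
#' midpoint of the heterozygous and homozygous peaks (rounded down):
#' `a1` is the fraction of species below that boundary. If no heterozygous
#' peak was detected, returns 0 with attribute `het_peak_absent = TRUE` and
#' a warning.
#'
#' @param hist A `kmer_histogram`.
#' @param peaks A `spectrum_peaks`.
#' @return `a1`, the heterozygous species fraction.
#' @export
estimate_a1 <- function(hist, peaks) {
  if (is.na(peaks$het_peak)) {
    warning("no heterozygous peak detected; a1 = 0")
    return(structure(0, het_peak_absent = TRUE))
  }
  boundary <- (peaks$het_peak + peaks$hom_peak) %/% 2
  genomic <- hist$depth >= peaks$error_cutoff
  het <- genomic & hist$depth < boundary
  total <- sum(hist$count[genomic])
  if (total == 0) stop("no genomic k-mer species above the error cutoff")
  sum(hist$count[het]) / total
}

new_het_estimate <- function(method, bhr, a1 = NA_real_, khr = NA_real_,
                             k = NA_integer_, grid_step = NA_real_,
                             details = list()) {
  structure(c(list(method = method, a1 = a1, khr = khr, bhr = bhr, k = k,
                   grid_step = grid_step), details),
            class = "het_estimate")
}

#' @export
print.het_estimate <- function(x, ...) {
  cat(sprintf("<het_estimate: %s> bhr = %.4g (%.3g%%)\n",
              x$method, x$bhr, 100 * x$bhr))
  if (!is.na(x$a1)) cat(sprintf("  a1 = %.4g, khr = %.4g, k = %d\n",
                                x$a1, x$khr, x$k))
  invisible(x)
}

#' @method tidy het_estimate
#' @export
tidy.het_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, a1 = x$a1, khr = x$khr, bhr = x$bhr,
                 k = x$k, grid_step = x$grid_step)
}

#' @method glance het_estimate
#' @export
glance.het_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, bhr = x$bhr,
                 percent = 100 * x$bhr)
}

#' Formula-based heterozygosity estimate from a k-mer spectrum
#'
#' Composes the whole spectrum route: error cutoff, peak detection, the
#' heterozygous species fraction `a1`, and the KHR/BHR formulas.
#'
#' @param hist A `kmer_histogram`.
#' @param k k-mer size; defaults to the histogram's own.
#' @return A `het_estimate` with `method = "formula"` holding `a1`, `khr`,
#'   `bhr` and the intermediate cutoff/peaks.
#' @export
estimate_het_formula <- function(hist, k = attr(hist, "k")) {
  cutoff <- find_error_cutoff(hist)
  peaks <- detect_peaks(hist, error_cutoff = cutoff)
  a1 <- suppressWarnings(estimate_a1(hist, peaks))
  khr <- khr_from_a1(as.numeric(a1))
  bhr <- bhr_from_khr(khr, k)
  new_het_estimate("formula", bhr, a1 = as.numeric(a1), khr = khr,
                   k = as.integer(k),
                   details = list(error_cutoff = peaks$error_cutoff,
                                  het_peak = peaks$het_peak,
                                  hom_peak = peaks$hom_peak,
                                  het_peak_absent =
                                    isTRUE(attr(a1, "het_peak_absent"))))
}

# species-frequency distribution over depths at or above the histogram's
# own error cutoff
spectrum_distribution <- function(hist) {
  cutoff <- find_error_cutoff(hist)
  keep <- hist$depth >= cutoff
  p <- hist$count[keep] / sum(hist$count[keep])
  stats::setNames(p, hist$depth[keep])
}

l1_spectrum_distance <- function(obs, sim) {
  depths <- union(names(obs), names(sim))
  o <- ifelse(depths %in% names(obs), obs[depths], 0)
  s <- ifelse(depths %in% names(sim), sim[depths], 0)
  o[is.na(o)] <- 0; s[is.na(s)] <- 0
  sum(abs(o - s))
}

#' Heterozygosity by matching simulated k-mer spectra
#'
#' For each candidate heterozygosity on the grid, simulates a diploid
#' genome and a shotgun read set under `sim_params`, builds its k-mer
#' histogram, and compares it with the observed histogram as normalized
#' species-frequency distributions (each over depths at or above its own
#' error cutoff, L1 distance). The grid value whose simulated spectrum fits
#' best is the estimate; ties break toward the lower heterozygosity.
#'
#' @param observed A `kmer_histogram` built from the reads under study.
#' @param h_grid Sorted candidate heterozygosities, each in `[0, 0.1]`.
#' @param sim_params List fixing the simulation conditions:
#'   `genome_length`, `coverage`, `read_length`, `error_rate`, `k`, and
#'   optionally `gc`.
#' @param seed Master integer seed; per-grid-point sub-seeds are derived
#'   from it and recorded.
#' @param replicates Simulations averaged per grid point (default 1).
#' @param grid_spectra Optional precomputed reference spectra from
#'   [simulate_grid_spectra()] (same `h_grid` and `sim_params`); lets
#'   several observed spectra be matched against one set of simulations.
#' @return A `het_estimate` with `method = "matching"`; `bhr` is the best
#'   grid value and the per-point distances are in `$grid` (a tibble with
#'   `h`, `distance`, `seed`).
#' @export
match_simulated_spectra <- function(observed, h_grid, sim_params,
                                    seed = NULL, replicates = 1,
                                    grid_spectra = NULL) {
  if (length(h_grid) == 0 || is.unsorted(h_grid))
    stop("`h_grid` must be non-empty and sorted")
  if (any(h_grid < 0 | h_grid > 0.1))
    stop("grid heterozygosities must be in [0, 0.1]")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(grid_spectra))
    grid_spectra <- simulate_grid_spectra(h_grid, sim_params, seed = seed,
                                          replicates = replicates)
  stopifnot(length(grid_spectra$spectra) == length(h_grid))
  obs_dist <- spectrum_distribution(observed)
  dist_h <- vapply(grid_spectra$spectra, function(sims) {
    mean(vapply(sims, function(sd) l1_spectrum_distance(obs_dist, sd),
                numeric(1)))
  }, numeric(1))
  best <- which.min(dist_h)  # which.min takes the first (lowest h) on ties
  sp <- sim_params
  seeds <- grid_spectra$seeds
  step <- if (length(h_grid) > 1) min(diff(h_grid)) else NA_real_
  new_het_estimate("matching", bhr = h_grid[best], k = sp$k,
                   grid_step = step,
                   details = list(
                     grid = tibble::tibble(h = h_grid, distance = dist_h,
                                           seed = seeds[, 1]),
                     master_seed = seed))
}

#' Simulate the reference spectra for grid matching
#'
#' Builds, for every candidate heterozygosity, `replicates` simulated
#' diploid read sets under `sim_params` and reduces each to its normalized
#' species-frequency distribution. The result can be passed to
#' [match_simulated_spectra()] so that several observed spectra are
#' matched against the same reference simulations.
#'
#' @inheritParams match_simulated_spectra
#' @return A list with `spectra` (per grid h, a list of `replicates`
#'   named distributions), `seeds` (matrix of sub-seeds used), `h_grid`,
#'   `sim_params`.
#' @export
simulate_grid_spectra <- function(h_grid, sim_params, seed = NULL,
                                  replicates = 1) {
  sp <- sim_params
  gc <- if (is.null(sp$gc)) 0.5 else sp$gc
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seeds <- matrix(derive_seeds(seed, 3 * length(h_grid) * replicates),
                  nrow = length(h_grid))
  spectra <- lapply(seq_along(h_grid), function(i) {
    lapply(seq_len(replicates), function(r) {
      s <- seeds[i, (3 * r - 2):(3 * r)]
      ref <- simulate_reference(sp$genome_length, gc = gc, seed = s[1])
      dg <- simulate_diploid(ref, h_grid[i], seed = s[2])
      rs <- simulate_reads(dg, coverage = sp$coverage,
                           read_length = sp$read_length,
                           error_rate = sp$error_rate, seed = s[3])
      spectrum_distribution(count_kmers(rs, k = sp$k))
    })
  })
  list(spectra = spectra, seeds = seeds, h_grid = h_grid,
       sim_params = sim_params)
}

#' Mapping-based heterozygosity percentage
#'
#' Variant density on the assembly: `100 * (n_snp + n_indel) /
#' assembly_length`, half-up rounded. Indel events count as single
#' variants. This route tends to underestimate spectrum-based values
#' because the best-assembled regions are the least heterozygous.
#'
#' @param n_snp,n_indel Variant counts (>= 0).
#' @param assembly_length Assembly length in bp (> 0).
#' @param decimals Decimals to round the percentage to.
#' @return Heterozygosity as a percentage.
#' @examples
#' mapping_heterozygosity(5379554, 486341, 804993085)
#' @export
mapping_heterozygosity <- function(n_snp, n_indel, assembly_length,
                                   decimals = 2) {
  if (n_snp < 0 || n_indel < 0) stop("variant counts must be >= 0")
  if (assembly_length <= 0) stop("`assembly_length` must be positive")
  round_half_up(100 * (n_snp + n_indel) / assembly_length, decimals)
}

#' Combine heterozygosity estimates into one report
#'
#' The three routes measure different things (spectrum matching, the
#' KHR/BHR formula, variant density on the assembly) and are reported side
#' by side without adjudication.
#'
#' @param ... `het_estimate` objects, or bare numbers (interpreted as
#'   per-base fractions for the `mapping` method when named `mapping`).
#' @return A tibble with one row per estimate.
#' @export
het_report <- function(...) {
  ests <- list(...)
  rows <- lapply(seq_along(ests), function(i) {
    e <- ests[[i]]
    if (inherits(e, "het_estimate")) return(tidy(e))
    nm <- names(ests)[i]
    tibble::tibble(method = if (is.null(nm) || nm == "") "value" else nm,
                   a1 = NA_real_, khr = NA_real_, bhr = as.numeric(e),
                   k = NA_integer_, grid_step = NA_real_)
  })
  dplyr::bind_rows(rows)
}
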