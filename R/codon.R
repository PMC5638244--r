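split_codons <- function(cds) {
  L <- nchar(cds)
  if (L %% 3 != 0) stop("CDS length is not a multiple of 3")
  substring(cds, seq(1, L, 3), seq(3, L, 3))
}

validate_cds <- function(cds, tabs = genetic_code_tables()) {
  codons <- split_codons(toupper(cds))
  if (!all(codons %in% names(tabs$code)))
    stop("CDS contains non-ACGT codons")
  internal <- codons[-length(codons)]
  if (any(internal %in% tabs$stops)) stop("internal stop codon")
  codons
}

# counts over the 61 sense codons (terminal stop dropped)
sense_codon_counts <- function(cds, tabs = genetic_code_tables()) {
  codons <- validate_cds(cds, tabs)
  if (codons[length(codons)] %in% tabs$stops)
    codons <- codons[-length(codons)]
  table(factor(codons, levels = names(tabs$sense)))
}

#' Relative synonymous codon usage
#'
#' Per codon: observed count divided by the mean count of its synonymous
#' family (stop codons excluded). Families absent from the gene score 0;
#' single-codon families (Met, Trp) score 1 whenever present.
#'
#' @param cds A coding sequence (length a multiple of 3, no internal
#'   stops; a terminal stop is tolerated and dropped).
#' @return Named numeric vector of RSCU values over the 61 sense codons.
#' @examples
#' rscu(simulate_coding_sequences(1, bias = 0, seed = 1)[[1]])
#' @export
rscu <- function(cds) {
  tabs <- genetic_code_tables()
  cnt <- sense_codon_counts(cds, tabs)
  out <- stats::setNames(numeric(length(cnt)), names(cnt))
  for (fam in tabs$families) {
    tot <- sum(cnt[fam])
    if (tot > 0) out[fam] <- cnt[fam] / (tot / length(fam))
  }
  out
}

#' Relative adaptiveness weights from a reference gene set
#'
#' Pools codon counts over a highly expressed reference set (classically
#' ribosomal-protein genes) and scales each codon by the maximum count in
#' its synonymous family: `w = count / max(family counts)`. Zero counts
#' are replaced by 0.5 before division (the small-sample guard), so no
#' weight is exactly 0.
#'
#' @param reference_cds Character vector of reference coding sequences.
#' @return Named numeric vector `w` over the 61 sense codons.
#' @export
relative_adaptiveness <- function(reference_cds) {
  if (length(reference_cds) == 0) stop("empty reference set")
  tabs <- genetic_code_tables()
  pooled <- Reduce(`+`, lapply(reference_cds, sense_codon_counts,
                               tabs = tabs))
  pooled <- as.numeric(pooled)
  names(pooled) <- names(tabs$sense)
  pooled[pooled == 0] <- 0.5
  w <- pooled
  for (fam in tabs$families) w[fam] <- pooled[fam] / max(pooled[fam])
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over a gene's codons,
#' excluding Met, Trp and stop codons (whose usage carries no synonymous
#' choice).
#'
#' @param cds A coding sequence.
#' @param w Relative adaptiveness weights from [relative_adaptiveness()].
#' @return CAI in `[0, 1]`.
#' @export
cai <- function(cds, w) {
  tabs <- genetic_code_tables()
  cnt <- sense_codon_counts(cds, tabs)
  single <- unlist(tabs$families[lengths(tabs$families) == 1])
  cnt <- cnt[setdiff(names(cnt), single)]
  n <- sum(cnt)
  if (n == 0) stop("no codons with synonymous choice in this gene")
  use <- cnt > 0
  exp(sum(cnt[use] * log(w[names(cnt)[use]])) / n)
}

#' Effective number of codons (Wright's Nc)
#'
#' Within each synonymous family with usage `n > 1`, the codon
#' homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)`; family values are
#' averaged within degeneracy classes and combined as
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to `[20, 61]`. A missing
#' 3-fold class (Ile unused) is imputed as the mean of the 2- and 4-fold
#' class averages; if any other class is empty the statistic is undefined
#' (`NA`).
#'
#' @param cds A coding sequence.
#' @return Nc in `[20, 61]`, or `NA` if undefined.
#' @export
enc <- function(cds) {
  tabs <- genetic_code_tables()
  cnt <- sense_codon_counts(cds, tabs)
  fams <- tabs$families[lengths(tabs$families) > 1]
  deg <- lengths(fams)
  fhat <- vapply(fams, function(fam) {
    n <- sum(cnt[fam])
    if (n <= 1) return(NA_real_)
    p <- cnt[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  class_mean <- vapply(c(2, 3, 4, 6), function(d) {
    v <- fhat[deg == d]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(class_mean) <- c("F2", "F3", "F4", "F6")
  if (is.na(class_mean["F3"]) &&
      !is.na(class_mean["F2"]) && !is.na(class_mean["F4"]))
    class_mean["F3"] <- mean(class_mean[c("F2", "F4")])
  if (anyNA(class_mean)) return(NA_real_)
  if (any(class_mean <= 0)) return(61)
  nc <- 2 + 9 / class_mean["F2"] + 1 / class_mean["F3"] +
    5 / class_mean["F4"] + 3 / class_mean["F6"]
  unname(pmin(61, pmax(20, nc)))
}

#' Per-gene codon usage statistics
#'
#' @param cds_set Named character vector of coding sequences.
#' @param reference_cds Reference set for the CAI weights; defaults to
#'   `cds_set` itself (self-referential CAI).
#' @return Tibble with `gene_id`, `cai`, `nc`.
#' @export
codon_usage_stats <- function(cds_set, reference_cds = cds_set) {
  w <- relative_adaptiveness(reference_cds)
  tibble::tibble(
    gene_id = if (is.null(names(cds_set)))
      sprintf("cds_%03d", seq_along(cds_set)) else names(cds_set),
    cai = vapply(cds_set, cai, numeric(1), w = w),
    nc = vapply(cds_set, enc, numeric(1)))
}

#' Genes-by-codons RSCU matrix
#'
#' @param cds_set Named character vector of coding sequences.
#' @return Numeric matrix, one row per gene, one column per sense codon.
#' @export
rscu_matrix <- function(cds_set) {
  m <- do.call(rbind, lapply(cds_set, rscu))
  rownames(m) <- if (is.null(names(cds_set)))
    sprintf("cds_%03d", seq_along(cds_set)) else names(cds_set)
  m
}

#' Correspondence analysis of a codon-usage matrix
#'
#' Standard correspondence analysis: the matrix is converted to a
#' correspondence matrix, centered by the outer product of row and column
#' masses, scaled by the square-root masses and decomposed by SVD. Row
#' principal coordinates and per-axis inertia shares are returned; axes
#' are ranked by inertia.
#'
#' @param rscu_mat Non-negative genes-by-codons matrix with positive row
#'   sums (all-zero columns are dropped).
#' @param n_axes Number of axes to keep (default 4).
#' @return A `codon_ca` object: list with `row_coords` (genes x axes),
#'   `inertia_share`, `singular_values`, `row_mass`.
#' @export
correspondence_axes <- function(rscu_mat, n_axes = 4) {
  X <- as.matrix(rscu_mat)
  if (nrow(X) < 2) stop("need at least two genes")
  if (any(X < 0)) stop("matrix must be non-negative")
  X <- X[, colSums(X) > 0, drop = FALSE]
  if (any(rowSums(X) == 0)) stop("matrix has all-zero rows")
  P <- X / sum(X)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) {
    return(structure(list(
      row_coords = matrix(0, nrow(X), 0,
                          dimnames = list(rownames(X), NULL)),
      inertia_share = numeric(0), singular_values = numeric(0),
      row_mass = r), class = "codon_ca"))
  }
  keep <- seq_len(min(n_axes, sum(pos)))
  Fc <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = length(keep))
  dimnames(Fc) <- list(rownames(X), paste0("axis", keep))
  structure(list(row_coords = Fc,
                 inertia_share = sv$d[keep]^2 / sum(sv$d[pos]^2),
                 singular_values = sv$d[keep],
                 row_mass = r),
            class = "codon_ca")
}

#' @export
print.codon_ca <- function(x, ...) {
  cat(sprintf("<codon_ca> %d genes, %d axes (inertia shares: %s)\n",
              nrow(x$row_coords), ncol(x$row_coords),
              paste(sprintf("%.3f", x$inertia_share), collapse = ", ")))
  invisible(x)
}

#' @method tidy codon_ca
#' @export
tidy.codon_ca <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(x$row_coords)),
                   tibble::as_tibble(x$row_coords))
}

#' @method glance codon_ca
#' @export
glance.codon_ca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$inertia_share),
                 inertia_share = x$inertia_share,
                 singular_value = x$singular_values)
}

#' Correlation between a CA axis and CAI
#'
#' Pearson correlation between per-gene axis coordinates and CAI values.
#' Because the sign of an SVD axis is arbitrary, the axis is oriented so
#' the correlation is non-negative.
#'
#' @param axis_coordinates Numeric vector of per-gene coordinates.
#' @param cai_values Numeric vector of per-gene CAI, same length (>= 3).
#' @return The (non-negative) Pearson correlation.
#' @export
axis_cai_correlation <- function(axis_coordinates, cai_values) {
  if (length(axis_coordinates) != length(cai_values) ||
      length(cai_values) < 3)
    stop("inputs must have equal length >= 3")
  if (stats::sd(axis_coordinates) == 0 || stats::sd(cai_values) == 0)
    stop("zero-variance input")
  abs(stats::cor(axis_coordinates, cai_values))
}

#' Find the CA axis most correlated with CAI
#'
#' Which axis tracks expression-driven codon bias is data-dependent; this
#' helper labels it explicitly rather than assuming it is axis 2.
#'
#' @param ca A `codon_ca`.
#' @param cai_values Per-gene CAI values in the row order of `ca`.
#' @return Tibble with `axis`, `correlation`, sorted by correlation.
#' @export
cai_axis <- function(ca, cai_values) {
  cors <- vapply(seq_len(ncol(ca$row_coords)), function(i)
    axis_cai_correlation(ca$row_coords[, i], cai_values), numeric(1))
  dplyr::arrange(tibble::tibble(axis = seq_along(cors),
                                correlation = cors),
                 dplyr::desc(.data$correlation))
}
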