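#' FPKM from a fragment count
#'
#' `count * 1e9 / (gene_length * library_size)` — fragments per kilobase of
#' transcript per million mapped reads. Vectorised over all arguments.
#'
#' @param count Assigned fragment count (>= 0).
#' @param gene_length Transcript length in bp (> 0).
#' @param library_size Total mapped fragments in the library (> 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)
#' @export
fpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("`gene_length` must be positive")
  if (any(library_size <= 0)) stop("`library_size` must be positive")
  count * 1e9 / (gene_length * library_size)
}

#' Convert a count matrix to FPKM
#'
#' Applies [fpkm()] per gene and stage using the matrix's gene lengths and
#' per-stage library sizes.
#'
#' @param cm A `count_matrix` (from [simulate_expression()] or
#'   [read_count_matrix()]).
#' @return A wide tibble (`gene_id` plus one FPKM column per stage) with
#'   the stage order preserved; attribute `stages` records it.
#' @export
fpkm_matrix <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  stages <- cm$stages
  out <- cm$counts
  lens <- cm$gene_lengths[out$gene_id]
  for (s in stages) {
    out[[s]] <- fpkm(out[[s]], lens, cm$library_sizes[[s]])
  }
  attr(out, "stages") <- stages
  out
}

stage_cols <- function(mat) {
  st <- attr(mat, "stages")
  if (is.null(st)) st <- setdiff(names(mat), "gene_id")
  st
}

#' Express every gene relative to a housekeeping gene
#'
#' Divides each gene's value at each stage by the housekeeping gene's value
#' at that stage, the usual presentation of developmental expression levels
#' against a stable reference such as tubulin.
#'
#' @param mat Wide expression tibble (`gene_id` + stage columns).
#' @param housekeeping_id Gene id of the reference; must be present and
#'   non-zero at every stage.
#' @return A tibble of ratios with the same shape.
#' @export
relative_to_housekeeping <- function(mat, housekeeping_id) {
  st <- stage_cols(mat)
  hk <- mat[mat$gene_id == housekeeping_id, st]
  if (nrow(hk) != 1) stop("housekeeping gene not found: ", housekeeping_id)
  if (any(hk == 0)) stop("housekeeping gene has value 0 at some stage")
  out <- mat
  for (s in st) out[[s]] <- out[[s]] / hk[[s]]
  attr(out, "stages") <- st
  out
}

#' Per-gene fold change of a stage window over a baseline
#'
#' `fold = (max over window + pseudocount) / (baseline + pseudocount)`. The
#' pseudocount keeps genes silent in the control from producing infinite
#' folds while still letting strong inductions register.
#'
#' @param mat Wide expression tibble (`gene_id` + stage columns; FPKM
#'   scale expected).
#' @param baseline_stage Reference stage (default the noneviscerated
#'   control).
#' @param window_stages Stages whose maximum is compared to the baseline
#'   (default the 0--3 dpe early window).
#' @param pseudocount Added to both terms (default 0.01 FPKM).
#' @return Tibble with `gene_id` and `fold`, in input gene order.
#' @export
fold_change <- function(mat, baseline_stage = "control",
                        window_stages = early_window(),
                        pseudocount = 0.01) {
  st <- stage_cols(mat)
  if (!baseline_stage %in% st) stop("unknown baseline stage: ", baseline_stage)
  if (!all(window_stages %in% st))
    stop("unknown window stage(s): ",
         paste(setdiff(window_stages, st), collapse = ", "))
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  win <- as.matrix(mat[window_stages])
  wmax <- apply(win, 1, max)
  tibble::tibble(gene_id = mat$gene_id,
                 fold = (wmax + pseudocount) /
                   (mat[[baseline_stage]] + pseudocount))
}

#' Screen for early-regeneration up-regulated genes
#'
#' Returns the genes whose window-over-baseline fold change reaches
#' `threshold_fold`, sorted by descending fold.
#'
#' @inheritParams fold_change
#' @param threshold_fold Minimum fold change (default 10000, the scale of
#'   the strongest regeneration induction).
#' @return Tibble (`gene_id`, `fold`) of hits, strongest first.
#' @export
screen_upregulated <- function(mat, threshold_fold = 10000,
                               baseline_stage = "control",
                               window_stages = early_window(),
                               pseudocount = 0.01) {
  fc <- fold_change(mat, baseline_stage, window_stages, pseudocount)
  dplyr::arrange(dplyr::filter(fc, .data$fold >= threshold_fold),
                 dplyr::desc(.data$fold), .data$gene_id)
}

#' Cluster expression profiles (average linkage on log10(FPKM + 1))
#'
#' Transforms every value to `log10(value + 1)`, computes pairwise
#' Euclidean distances between gene profiles, and merges them by
#' average-linkage (UPGMA) agglomeration — the procedure behind the
#' regeneration-cluster heatmap panels. Genes are sorted by id before
#' clustering so the result is independent of input order.
#'
#' @param mat Wide expression tibble (`gene_id` + stage columns), at least
#'   two genes.
#' @return A list of class `profile_clustering`: `hclust` (the stats::hclust
#'   tree), `merges` (tibble with merge heights), `leaf_order` (gene ids in
#'   dendrogram order).
#' @export
hcluster_profiles <- function(mat) {
  if (nrow(mat) < 2) stop("need at least two genes to cluster")
  st <- stage_cols(mat)
  ord <- order(mat$gene_id)
  m <- log10(as.matrix(mat[ord, st]) + 1)
  rownames(m) <- mat$gene_id[ord]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  structure(list(hclust = hc,
                 merges = tibble::tibble(step = seq_len(nrow(hc$merge)),
                                         height = hc$height),
                 leaf_order = hc$labels[hc$order]),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d leaves, %d merges (max height %.4g)\n",
              length(x$leaf_order), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' @method tidy profile_clustering
#' @export
tidy.profile_clustering <- function(x, ...) x$merges
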