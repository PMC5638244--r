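#' Global-alignment protein identity
#'
#' Needleman–Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1, with a deterministic traceback preferring diagonal over
#' vertical over horizontal moves. Identity is the number of matched
#' columns divided by the alignment length.
#'
#' @param protein_a,protein_b Non-empty amino-acid sequences (character).
#' @return The identity fraction in `[0, 1]`, with attributes `matches`
#'   and `alignment_length`.
#' @examples
#' pairwise_identity("ACDE", "ACDF")
#' @export
pairwise_identity <- function(protein_a, protein_b) {
  if (nchar(protein_a) == 0 || nchar(protein_b) == 0)
    stop("empty sequence")
  r <- nw_identity_cpp(protein_a, protein_b)
  structure(r$identity, matches = r$matches,
            alignment_length = r$alignment_length)
}

#' Detect tandem-duplicated gene clusters on scaffolds
#'
#' Scans the genomic gene order of each scaffold and greedily extends a run
#' while the next gene — allowing up to `max_intervening` skipped
#' non-members — aligns at identity `>= min_identity` to any current
#' member. Maximal runs with at least `min_repeats` members are reported;
#' clusters are disjoint and members are listed in genomic order.
#'
#' @param annotation An `annotation_set` (genes tibble plus named protein
#'   vector), e.g. from [simulate_annotation()] or [read_annotation()].
#' @param min_repeats Minimum member count (default 6, i.e. more than 5
#'   repeats).
#' @param min_identity Minimum pairwise identity linking a gene into a run
#'   (default 0.3, the floor of detectable paralogy).
#' @param max_intervening Non-member genes tolerated between consecutive
#'   members (default 1).
#' @return A `tandem_clusters` tibble: `scaffold`, `members` (list column
#'   of gene ids), `repeat_count`, `mean_identity`.
#' @export
detect_tandem_clusters <- function(annotation, min_repeats = 6,
                                   min_identity = 0.3,
                                   max_intervening = 1) {
  genes <- dplyr::arrange(annotation$genes, .data$scaffold, .data$start)
  prot <- annotation$proteins
  out <- list()
  for (scaf in unique(genes$scaffold)) {
    ids <- genes$gene_id[genes$scaffold == scaf]
    n <- length(ids)
    i <- 1L
    while (i <= n) {
      members <- ids[i]
      last <- i
      j <- i + 1L
      while (j <= n && j - last <= max_intervening + 1L) {
        hit <- any(vapply(members, function(m) {
          as.numeric(pairwise_identity(prot[[m]], prot[[ids[j]]])) >=
            min_identity
        }, logical(1)))
        if (hit) {
          members <- c(members, ids[j])
          last <- j
        }
        j <- j + 1L
      }
      if (length(members) >= min_repeats) {
        pairs <- utils::combn(members, 2)
        mpi <- mean(apply(pairs, 2, function(p)
          as.numeric(pairwise_identity(prot[[p[1]]], prot[[p[2]]]))))
        n_members <- length(members)
        out[[length(out) + 1]] <- tibble::tibble(
          scaffold = scaf, members = list(members),
          repeat_count = n_members, mean_identity = mpi)
        i <- last + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(scaffold = character(), members = list(),
                   repeat_count = integer(), mean_identity = numeric())
  class(res) <- c("tandem_clusters", class(res))
  res
}

#' Cluster point features by genomic proximity
#'
#' Single-linkage chaining: features on the same scaffold whose
#' consecutive gaps are at most `max_gap` form one cluster; clusters with
#' at least `min_size` members are returned. This is the criterion for
#' calling physically adjacent miRNA-style feature clusters.
#'
#' @param positions Data frame with columns `scaffold` and `position`
#'   (bp); an optional `name` column is carried through.
#' @param max_gap Maximum gap between consecutive members (bp, > 0).
#' @param min_size Minimum cluster size (>= 2).
#' @return Tibble with `scaffold`, `positions` (list column), `size`,
#'   `span`.
#' @export
cluster_features_by_proximity <- function(positions, max_gap,
                                          min_size = 2) {
  if (max_gap <= 0) stop("`max_gap` must be positive")
  if (min_size < 2) stop("`min_size` must be >= 2")
  positions <- tibble::as_tibble(positions)
  if (nrow(positions) == 0)
    return(tibble::tibble(scaffold = character(), positions = list(),
                          size = integer(), span = numeric()))
  positions <- dplyr::arrange(positions, .data$scaffold, .data$position)
  res <- positions |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::mutate(gap = .data$position - dplyr::lag(.data$position),
                  cluster = cumsum(is.na(.data$gap) |
                                     .data$gap > max_gap)) |>
    dplyr::group_by(.data$scaffold, .data$cluster) |>
    dplyr::summarise(positions = list(.data$position),
                     size = dplyr::n(),
                     span = max(.data$position) - min(.data$position),
                     .groups = "drop") |>
    dplyr::filter(.data$size >= min_size) |>
    dplyr::select(-"cluster")
  res
}

#' Conserved residue columns of an alignment
#'
#' Reports the columns of an equal-length alignment where the frequency of
#' `residue` (gaps excluded from the numerator but included in the
#' denominator) reaches `min_fraction` — e.g. the invariant cysteines of a
#' duplicated protein family.
#'
#' @param alignment Character vector of aligned rows, all the same length
#'   (gaps as `-`).
#' @param residue Single residue character to test.
#' @param min_fraction Required frequency in `(0, 1]`.
#' @return 1-based column indices (integer vector).
#' @export
conserved_columns <- function(alignment, residue, min_fraction = 1) {
  if (length(alignment) == 0) return(integer())
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows must all have the same length")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  freq <- colMeans(m == residue)
  which(freq >= min_fraction)
}

#' Center-star multiple alignment (fixture utility)
#'
#' A quick multiple aligner for building small alignment fixtures: picks
#' the sequence with the highest total pairwise identity as the center and
#' merges the pairwise alignments of all others against it. Not intended
#' for production alignments.
#'
#' @param seqs Named character vector of sequences (>= 2).
#' @return Character vector of aligned rows (same names), equal length.
#' @export
center_star_align <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <- as.numeric(pairwise_identity(seqs[[i]],
                                                           seqs[[j]]))
  }
  center <- which.max(rowSums(idm))
  aligned_center <- strsplit(seqs[[center]], "")[[1]]
  rows <- list()
  rows[[center]] <- aligned_center
  # merge each pairwise alignment into the growing center coordinates
  gapmap <- seq_along(aligned_center)  # center column -> master column
  master_len <- length(aligned_center)
  pair_aln <- lapply(seq_len(n), function(i) {
    if (i == center) return(NULL)
    nw_align_strings(seqs[[center]], seqs[[i]])
  })
  # build master gap structure: for each center position, the max number of
  # insertions after it across all pairwise alignments
  ins_after <- integer(nchar(seqs[[center]]) + 1)  # [0] = before start
  for (al in pair_aln) {
    if (is.null(al)) next
    cpos <- 0L; run <- 0L
    for (kk in seq_along(al$a)) {
      if (al$a[kk] == "-") run <- run + 1L
      else {
        ins_after[cpos + 1L] <- max(ins_after[cpos + 1L], run)
        run <- 0L; cpos <- cpos + 1L
      }
    }
    ins_after[cpos + 1L] <- max(ins_after[cpos + 1L], run)
  }
  place <- function(al) {
    # expand one pairwise alignment onto the master columns
    outv <- character(0)
    cpos <- 0L; buf <- character(0)
    flush <- function(buf, slot) c(buf, rep("-", slot - length(buf)))
    for (kk in seq_along(al$a)) {
      if (al$a[kk] == "-") buf <- c(buf, al$b[kk])
      else {
        outv <- c(outv, flush(buf, ins_after[cpos + 1L]), al$b[kk])
        buf <- character(0); cpos <- cpos + 1L
      }
    }
    c(outv, flush(buf, ins_after[cpos + 1L]))
  }
  center_row <- {
    chars <- strsplit(seqs[[center]], "")[[1]]
    outv <- rep("-", ins_after[1])
    for (p in seq_along(chars))
      outv <- c(outv, chars[p], rep("-", ins_after[p + 1]))
    outv
  }
  res <- character(n)
  res[center] <- paste(center_row, collapse = "")
  for (i in seq_len(n)) {
    if (i == center) next
    res[i] <- paste(place(pair_aln[[i]]), collapse = "")
  }
  names(res) <- names(seqs)
  res
}

# aligned character vectors for a/b under the same NW scheme as
# pairwise_identity (used only by the fixture aligner)
nw_align_strings <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  sc <- matrix(0L, n + 1, m + 1)
  tb <- matrix(0L, n + 1, m + 1)
  sc[1, ] <- -(0:m); sc[, 1] <- -(0:n)
  tb[1, -1] <- 3L; tb[-1, 1] <- 2L
  for (i in 1:n) for (j in 1:m) {
    d <- sc[i, j] + (ac[i] == bc[j])
    u <- sc[i, j + 1] - 1L
    l <- sc[i + 1, j] - 1L
    best <- d; dir <- 1L
    if (u > best) { best <- u; dir <- 2L }
    if (l > best) { best <- l; dir <- 3L }
    sc[i + 1, j + 1] <- best; tb[i + 1, j + 1] <- dir
  }
  i <- n; j <- m; ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    dir <- tb[i + 1, j + 1]
    if (dir == 1L) { ra <- c(ac[i], ra); rb <- c(bc[j], rb); i <- i - 1; j <- j - 1 }
    else if (dir == 2L) { ra <- c(ac[i], ra); rb <- c("-", rb); i <- i - 1 }
    else { ra <- c("-", ra); rb <- c(bc[j], rb); j <- j - 1 }
  }
  list(a = ra, b = rb)
}
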