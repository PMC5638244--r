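#' Simulate a haploid reference sequence
#'
#' Draws an i.i.d. nucleotide sequence with a controlled GC fraction. This is
#' the starting material for the diploid-genome and read simulators used by
#' the spectrum-based heterozygosity estimators.
#'
#' @param length Sequence length in bp (positive integer).
#' @param gc Target GC fraction in `[0, 1]`; G and C (and A and T) are drawn
#'   with equal probability within their class.
#' @param seed Integer seed; the same seed always yields the same sequence.
#'   `NULL` uses the current RNG state.
#' @return A single character string over the alphabet ACGT.
#' @examples
#' s <- simulate_reference(1000, gc = 0.4, seed = 1)
#' @export
simulate_reference <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0) stop("`length` must be a positive number of bases")
  if (gc < 0 || gc > 1) stop("`gc` must be in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")[sample.int(4, length, replace = TRUE, prob = p)]
  intToUtf8(codes)
}

#' Simulate a diploid genome with known heterozygous sites
#'
#' Mutates each position of a reference haplotype independently with
#' probability `het_rate` to a uniformly chosen different base, producing an
#' alternate haplotype and a full list of planted variants. The default model
#' is substitution-only, matching the SNP-style k-mer splitting that the
#' spectrum heterozygosity formulas assume; `indel_fraction` converts that
#' fraction of variant sites into 1-bp insertions or deletions.
#'
#' @param reference Haploid reference sequence (character string, ACGT).
#' @param het_rate Per-base heterozygosity in `[0, 0.1]`.
#' @param seed Integer seed (or `NULL`).
#' @param indel_fraction Fraction of variant sites realised as 1-bp indels
#'   rather than substitutions; default 0.
#' @return An object of class `diploid_genome`: a list with `reference`,
#'   `alt_haplotype`, a `variants` tibble (`position` 1-based on the
#'   reference, `ref`, `alt`), `true_het_rate`, and `seed`.
#' @examples
#' dg <- simulate_diploid(simulate_reference(1e4, seed = 1), 0.02, seed = 2)
#' nrow(dg$variants)
#' @export
simulate_diploid <- function(reference, het_rate, seed = NULL,
                             indel_fraction = 0) {
  if (het_rate < 0 || het_rate > 0.1)
    stop("`het_rate` must be in [0, 0.1]")
  if (!is.null(seed)) withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- nchar(reference)
  pos <- which(runif(L) < het_rate)
  if (length(pos) == 0) {
    variants <- tibble::tibble(position = integer(), ref = character(),
                               alt = character())
    alt_seq <- reference
  } else {
    ref_codes <- utf8ToInt(reference)
    base_codes <- utf8ToInt("ACGT")
    ref_idx <- match(ref_codes[pos], base_codes)
    is_indel <- runif(length(pos)) < indel_fraction
    ref_at <- bases[ref_idx]
    # substitution: uniformly one of the three other bases, vectorised as
    # a cyclic offset 1..3 from the reference base
    alt_idx <- 1L + (ref_idx - 1L + sample.int(3, length(pos),
                                               replace = TRUE)) %% 4L
    alt_at <- bases[alt_idx]
    if (any(is_indel)) {
      ins <- is_indel & (runif(length(pos)) < 0.5)
      del <- is_indel & !ins
      alt_at[ins] <- paste0(ref_at[ins], sample(bases, sum(ins), TRUE))
      alt_at[del] <- ""
    }
    variants <- tibble::tibble(position = pos, ref = ref_at, alt = alt_at)
    if (any(is_indel)) {
      alt_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
      alt_chars[pos] <- alt_at
      alt_seq <- paste(alt_chars, collapse = "")
    } else {
      alt_codes <- ref_codes
      alt_codes[pos] <- base_codes[alt_idx]
      alt_seq <- intToUtf8(alt_codes)
    }
  }
  structure(
    list(reference = reference, alt_haplotype = alt_seq,
         variants = variants, true_het_rate = het_rate, seed = seed),
    class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf(
    "<diploid_genome> %s bp, %s planted variants (rate %.4g, target %.4g)\n",
    format(nchar(x$reference), big.mark = ","), nrow(x$variants),
    nrow(x$variants) / nchar(x$reference), x$true_het_rate))
  invisible(x)
}

#' Simulate single-end shotgun reads from a diploid genome
#'
#' Places reads uniformly on a haplotype chosen with probability 1/2 per
#' read, and substitutes each base independently with probability
#' `error_rate`. Enough reads are drawn that the total base count is at
#' least `coverage` times the haploid length (the last read counts in full).
#' Qualities are a constant Sanger+33 'I' column; no attempt is made to
#' model machine error profiles.
#'
#' @param dg A `diploid_genome` (or a single character string, treated as a
#'   homozygous genome).
#' @param coverage Target haploid fold-coverage (> 0).
#' @param read_length Read length in bp; must not exceed the genome length.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed (or `NULL`).
#' @return An object of class `read_set`: list with a `reads` tibble (`id`,
#'   `sequence`, `quality`), `read_length`, `target_coverage`, `error_rate`,
#'   `seed`.
#' @examples
#' dg <- simulate_diploid(simulate_reference(5e3, seed = 1), 0.01, seed = 2)
#' rs <- simulate_reads(dg, coverage = 5, read_length = 100, seed = 3)
#' @export
simulate_reads <- function(dg, coverage, read_length, error_rate = 0,
                           seed = NULL) {
  if (is.character(dg)) dg <- structure(
    list(reference = dg, alt_haplotype = dg,
         variants = tibble::tibble(), true_het_rate = 0, seed = NULL),
    class = "diploid_genome")
  L <- nchar(dg$reference)
  if (read_length > min(L, nchar(dg$alt_haplotype)))
    stop("`read_length` exceeds the genome length")
  if (coverage <= 0) stop("`coverage` must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  n_reads <- ceiling(coverage * L / read_length)
  hap <- sample(c(1L, 2L), n_reads, replace = TRUE)
  seqs <- character(n_reads)
  for (h in 1:2) {
    src <- if (h == 1) dg$reference else dg$alt_haplotype
    idx <- which(hap == h)
    if (!length(idx)) next
    start <- sample.int(nchar(src) - read_length + 1L, length(idx),
                        replace = TRUE)
    seqs[idx] <- substring(src, start, start + read_length - 1L)
  }
  if (error_rate > 0) {
    # flip bases jointly over the concatenated reads: equivalent to an
    # i.i.d. per-base error, but vectorised
    big <- paste(seqs, collapse = "")
    codes <- utf8ToInt(big)
    n_err <- rbinom(1, length(codes), error_rate)
    if (n_err > 0) {
      p <- sample.int(length(codes), n_err)
      base_codes <- utf8ToInt("ACGT")
      idx <- match(codes[p], base_codes)
      codes[p] <- base_codes[1L + (idx - 1L +
                                     sample.int(3, n_err, TRUE)) %% 4L]
      big <- intToUtf8(codes)
    }
    starts <- (seq_len(n_reads) - 1L) * read_length + 1L
    seqs <- substring(big, starts, starts + read_length - 1L)
  }
  reads <- tibble::tibble(
    id = sprintf("read_%07d", seq_len(n_reads)),
    sequence = seqs,
    quality = strrep("I", read_length))
  structure(
    list(reads = reads, read_length = as.integer(read_length),
         target_coverage = coverage, error_rate = error_rate, seed = seed),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s reads x %d bp (target %gx, error %g)\n",
              format(nrow(x$reads), big.mark = ","), x$read_length,
              x$target_coverage, x$error_rate))
  invisible(x)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Mutate exactly round(L * (1 - identity) / 2) residues (sampled without
# replacement) so that two copies derived from the same template differ at
# no more than L * (1 - identity) positions: pairwise identity is
# guaranteed >= `identity`, and is typically slightly above it.
mutate_protein <- function(protein, identity) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  m <- round(length(chars) * (1 - identity) / 2)
  if (m > 0) {
    hit <- sample.int(length(chars), m)
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1), "")
  }
  paste(chars, collapse = "")
}

#' Simulate a gene annotation with planted tandem-duplicated clusters
#'
#' Builds `n_scaffolds` scaffolds of non-overlapping, start-sorted gene
#' models with random protein products, then plants each requested cluster
#' as a run of adjacent genes whose proteins are mutated copies of one
#' template. Each cluster goes on its own scaffold. Copies are mutated at
#' per-residue rate `(1 - identity) / 2` so the expected pairwise identity
#' between members is about `identity`.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param genes_per_scaffold Genes per scaffold.
#' @param cluster_specs A data frame (or list of 2-vectors) with columns
#'   `size` (>= 2) and `identity`; one planted cluster per row.
#' @param seed Integer seed (or `NULL`).
#' @param protein_length Mean background protein length (residues).
#' @return An object of class `annotation_set`: list with a `genes` tibble
#'   (`gene_id`, `scaffold`, `start`, `end`, `strand`), a named character
#'   vector `proteins`, and `planted_clusters` (list of gene-id vectors).
#' @examples
#' ann <- simulate_annotation(3, 30, data.frame(size = 11, identity = 0.95),
#'                            seed = 7)
#' lengths(ann$planted_clusters)
#' @export
simulate_annotation <- function(n_scaffolds, genes_per_scaffold,
                                cluster_specs = NULL, seed = NULL,
                                protein_length = 120) {
  if (!is.null(cluster_specs) && !is.data.frame(cluster_specs))
    cluster_specs <- as.data.frame(do.call(rbind, cluster_specs))
  n_clusters <- if (is.null(cluster_specs)) 0L else nrow(cluster_specs)
  if (n_clusters > n_scaffolds)
    stop("more planted clusters than scaffolds")
  if (n_clusters > 0) {
    if (any(cluster_specs$size < 2)) stop("cluster size must be >= 2")
    if (any(cluster_specs$size > genes_per_scaffold))
      stop("cluster larger than `genes_per_scaffold`")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  genes <- vector("list", n_scaffolds)
  proteins <- character(0)
  planted <- vector("list", n_clusters)
  cluster_scaffold <- if (n_clusters)
    sample.int(n_scaffolds, n_clusters) else integer(0)

  for (s in seq_len(n_scaffolds)) {
    scaf <- sprintf("scaffold%03d", s)
    ids <- sprintf("%s.g%03d", scaf, seq_len(genes_per_scaffold))
    glen <- sample(900:2400, genes_per_scaffold, replace = TRUE)
    gap <- sample(200:3000, genes_per_scaffold, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0L, glen[-genes_per_scaffold]))
    genes[[s]] <- tibble::tibble(
      gene_id = ids, scaffold = scaf,
      start = start, end = start + glen - 1L,
      strand = sample(c("+", "-"), genes_per_scaffold, replace = TRUE))
    plen <- pmax(30L, round(rlnorm(genes_per_scaffold,
                                   log(protein_length), 0.25)))
    prot <- vapply(plen, random_protein, "")
    names(prot) <- ids

    ci <- which(cluster_scaffold == s)
    if (length(ci) == 1) {
      size <- as.integer(cluster_specs$size[ci])
      identity <- cluster_specs$identity[ci]
      at <- sample.int(genes_per_scaffold - size + 1L, 1)
      template <- random_protein(protein_length)
      members <- ids[at:(at + size - 1L)]
      prot[members] <- vapply(members,
        function(g) mutate_protein(template, identity), "")
      planted[[ci]] <- members
    }
    proteins <- c(proteins, prot)
  }
  structure(
    list(genes = dplyr::bind_rows(genes), proteins = proteins,
         planted_clusters = planted, seed = seed),
    class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes on %d scaffolds, %d planted cluster(s)\n",
              nrow(x$genes), dplyr::n_distinct(x$genes$scaffold),
              length(x$planted_clusters)))
  invisible(x)
}

#' Stage labels of the intestinal-regeneration time course
#'
#' The nine stages sampled across intestinal regeneration: a noneviscerated
#' control followed by 0.5 h, 2 h and 6 h, then 3, 5, 7, 14 and 21 days
#' post evisceration (dpe).
#'
#' @return Character vector of nine ordered stage labels.
#' @export
regeneration_stages <- function() {
  c("control", "0.5h", "2h", "6h", "3d", "5d", "7d", "14d", "21d")
}

#' Early-regeneration stage window (0--3 dpe)
#'
#' @return The stage labels between evisceration and 3 dpe inclusive.
#' @export
early_window <- function() c("0.5h", "2h", "6h", "3d")

#' Simulate a regeneration time-course count matrix
#'
#' Draws a genes-by-stages matrix of negative-binomial counts around
#' per-gene log-normal baseline means, multiplying the mean of each planted
#' up-regulated gene by `fold` inside the early-stage window. Library sizes
#' are the realised per-stage totals. `dispersion = 0` degenerates to
#' rounded expected means.
#'
#' @param annotation An `annotation_set`, or a character vector of gene ids.
#' @param stages Ordered stage labels; default [regeneration_stages()].
#' @param upregulated Gene ids to up-regulate (must exist).
#' @param fold Mean multiplier in the window (>= 1).
#' @param dispersion Negative-binomial overdispersion (0 = deterministic).
#' @param seed Integer seed (or `NULL`).
#' @param window Stage labels forming the up-regulation window; default the
#'   0--3 dpe early window.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean counts. The default mean scale (about 2000 fragments per
#'   gene) emulates a realistically deep RNA-seq library, so that expressed
#'   genes essentially never draw a zero baseline count.
#' @param upregulated_baseline_mean Baseline mean count of the planted
#'   genes (default 100): regeneration-induced genes are near-silent in the
#'   control, which is what makes four-digit FPKM fold changes reachable
#'   without the planted genes swamping the window libraries.
#' @return An object of class `count_matrix`: list with `counts` (wide
#'   tibble: `gene_id` plus one column per stage), `gene_lengths` (named,
#'   bp), `library_sizes` (named per-stage totals), `stages`, and `planted`
#'   (tibble `gene_id`, `fold`, `window`).
#' @examples
#' cm <- simulate_expression(sprintf("g%02d", 1:20),
#'                           upregulated = c("g01", "g02"),
#'                           fold = 1000, seed = 5)
#' @export
simulate_expression <- function(annotation, stages = regeneration_stages(),
                                upregulated = character(), fold = 1,
                                dispersion = 0.1, seed = NULL,
                                window = early_window(),
                                baseline_meanlog = log(2000),
                                baseline_sdlog = 1,
                                upregulated_baseline_mean = 100) {
  if (fold < 1) stop("`fold` must be >= 1")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (inherits(annotation, "annotation_set")) {
    ids <- annotation$genes$gene_id
    lens <- annotation$genes$end - annotation$genes$start + 1L
  } else {
    ids <- annotation
    lens <- NULL
  }
  if (!all(upregulated %in% ids))
    stop("unknown gene ids in `upregulated`: ",
         paste(setdiff(upregulated, ids), collapse = ", "))
  if (!all(window %in% stages)) stop("`window` stages must be in `stages`")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(ids)
  if (is.null(lens)) lens <- sample(600:3000, n, replace = TRUE)
  names(lens) <- ids
  mu0 <- rlnorm(n, baseline_meanlog, baseline_sdlog)
  names(mu0) <- ids
  if (fold > 1) mu0[upregulated] <- upregulated_baseline_mean
  mu <- matrix(mu0, nrow = n, ncol = length(stages),
               dimnames = list(ids, stages))
  mu[upregulated, window] <- mu[upregulated, window] * fold
  counts <- if (dispersion == 0) {
    matrix(round(mu), nrow = n, dimnames = dimnames(mu))
  } else {
    matrix(rnbinom(n * length(stages), mu = as.vector(mu),
                   size = 1 / dispersion),
           nrow = n, dimnames = dimnames(mu))
  }
  wide <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                           tibble::as_tibble(counts))
  structure(
    list(counts = wide,
         gene_lengths = lens,
         library_sizes = colSums(counts),
         stages = stages,
         planted = tibble::tibble(
           gene_id = upregulated, fold = fold,
           window = list(window))[seq_along(upregulated), ],
         dispersion = dispersion, seed = seed),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d stages, %d planted up-regulated\n",
              nrow(x$counts), length(x$stages), nrow(x$planted)))
  invisible(x)
}

# ---- codon-biased coding sequences ------------------------------------------

genetic_code_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  fam <- split(names(sense), sense)            # amino acid -> codons
  fam <- lapply(fam, sort)
  optimal <- vapply(fam, `[`, "", 1)           # designated optimal codon
  list(code = gc, sense = sense, families = fam, optimal = optimal,
       stops = names(gc)[gc == "*"])
}

#' Simulate coding sequences with controlled codon-usage bias
#'
#' Generates CDS with a tunable preference for one designated optimal codon
#' per amino acid. At `bias = 1` only optimal codons are used (maximal
#' bias); at `bias = 0` synonymous codons are used uniformly. Every CDS
#' starts with ATG, ends with a stop codon, contains no internal stops, and
#' has length a multiple of 3.
#'
#' @param n Number of sequences.
#' @param bias A single bias in `[0, 1]` or one value per sequence.
#' @param n_codons Number of internal codons per CDS (excluding the start
#'   and stop); scalar or per-sequence.
#' @param seed Integer seed (or `NULL`).
#' @return Named character vector of CDS (names `cds_001`, ...), with the
#'   per-sequence bias attached as attribute `bias`.
#' @examples
#' cds <- simulate_coding_sequences(5, bias = c(0, .25, .5, .75, 1), seed = 2)
#' @export
simulate_coding_sequences <- function(n, bias = 0, n_codons = 300,
                                      seed = NULL) {
  if (any(bias < 0 | bias > 1)) stop("`bias` must be in [0, 1]")
  bias <- rep_len(bias, n)
  n_codons <- rep_len(n_codons, n)
  if (!is.null(seed)) withr::local_seed(seed)
  tabs <- genetic_code_tables()
  out <- character(n)
  for (i in seq_len(n)) {
    aas <- sample(names(tabs$families), n_codons[i], replace = TRUE)
    codons <- vapply(aas, function(a) {
      fam <- tabs$families[[a]]
      f <- length(fam)
      if (f == 1) return(fam)
      p <- rep((1 - (1 / f + bias[i] * (1 - 1 / f))) / (f - 1), f)
      p[fam == tabs$optimal[[a]]] <- 1 / f + bias[i] * (1 - 1 / f)
      sample(fam, 1, prob = p)
    }, "")
    out[i] <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  }
  names(out) <- sprintf("cds_%03d", seq_len(n))
  attr(out, "bias") <- bias
  out
}
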