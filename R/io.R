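#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences, a `diploid_genome`
#'   (haplotypes written as two records), or a CDS set.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (inherits(x, "diploid_genome"))
    x <- c(hap1 = x$reference, hap2 = x$alt_haplotype)
  if (is.null(names(x))) names(x) <- sprintf("seq_%03d", seq_along(x))
  set <- if (type == "dna") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write a read set to FASTQ (Sanger +33 qualities)
#'
#' @param rs A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  dna <- Biostrings::DNAStringSet(stats::setNames(rs$reads$sequence,
                                                  rs$reads$id))
  qual <- Biostrings::BStringSet(rs$reads$quality)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @return A `read_set` (target coverage and error rate unknown: `NA`).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  reads <- tibble::tibble(
    id = names(seqs),
    sequence = unname(as.character(seqs)),
    quality = unname(as.character(S4Vectors::mcols(seqs)$qualities)))
  structure(list(reads = reads,
                 read_length = if (nrow(reads)) nchar(reads$sequence[1])
                               else NA_integer_,
                 target_coverage = NA_real_, error_rate = NA_real_,
                 seed = NULL),
            class = "read_set")
}

#' Write an annotation set to GFF3 (+ protein FASTA)
#'
#' Genes are written as `gene` features with `ID` attributes, 1-based
#' inclusive coordinates.
#'
#' @param ann An `annotation_set`.
#' @param gff_path GFF3 output path.
#' @param protein_path Optional protein FASTA output path.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(ann, gff_path, protein_path = NULL) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$scaffold,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$source <- "genomesurvey"
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(protein_path))
    write_fasta(ann$proteins, protein_path, type = "protein")
  invisible(gff_path)
}

#' Read a GFF3 gene annotation (+ protein FASTA) into an annotation set
#'
#' @param gff_path GFF3 path; `gene` features with `ID` attributes are
#'   used.
#' @param protein_path Optional protein FASTA keyed by gene `ID`.
#' @return An `annotation_set` (with no planted-cluster ground truth).
#' @export
read_annotation <- function(gff_path, protein_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  genes <- tibble::tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  genes <- dplyr::arrange(genes, .data$scaffold, .data$start)
  proteins <- if (is.null(protein_path)) character(0)
              else read_fasta(protein_path, type = "protein")
  structure(list(genes = genes, proteins = proteins,
                 planted_clusters = list(), seed = NULL),
            class = "annotation_set")
}

#' Write / read a count (or FPKM) matrix TSV
#'
#' Tab-separated, header row of stage labels, first column `gene_id`.
#'
#' @param cm A `count_matrix`, or a wide tibble (`gene_id` + stage
#'   columns).
#' @param path File path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `count_matrix` (gene lengths and
#'   library sizes are taken from the optional sidecar columns or
#'   reconstructed: lengths `NA`, library sizes = column sums).
#' @export
write_count_matrix <- function(cm, path) {
  df <- if (inherits(cm, "count_matrix")) cm$counts else cm
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param gene_lengths Optional named lengths to attach on read.
#' @export
read_count_matrix <- function(path, gene_lengths = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stages <- setdiff(names(df), "gene_id")
  counts <- as.matrix(df[stages])
  lens <- if (is.null(gene_lengths))
    stats::setNames(rep(NA_real_, nrow(df)), df$gene_id)
  else gene_lengths[df$gene_id]
  structure(list(counts = df,
                 gene_lengths = lens,
                 library_sizes = colSums(counts),
                 stages = stages,
                 planted = tibble::tibble(gene_id = character(),
                                          fold = numeric(),
                                          window = list()),
                 dispersion = NA_real_, seed = NULL),
            class = "count_matrix")
}

#' Write the ground-truth sidecar of a simulation
#'
#' Records planted variants, clusters, folds and seeds as JSON next to the
#' generated data files, so every synthetic data set carries its own
#' truth.
#'
#' @param truth A list of ground-truth components (e.g. `variants`,
#'   `planted_clusters`, `planted`, `seed`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
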