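test_that("reference simulation honours length, GC and seed", {
  expect_error(simulate_reference(0), "positive")
  expect_error(simulate_reference(100, gc = 1.2), "gc")
  expect_identical(simulate_reference(10000, 0.5, seed = 1),
                   simulate_reference(10000, 0.5, seed = 1))
  s <- simulate_reference(100000, gc = 0.37, seed = 7)
  gcf <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.37), 0.01)
})

test_that("diploid simulation plants substitutions at the requested rate", {
  ref <- simulate_reference(5000, seed = 11)
  dg0 <- simulate_diploid(ref, 0, seed = 12)
  expect_identical(dg0$alt_haplotype, ref)
  expect_identical(nrow(dg0$variants), 0L)
  expect_error(simulate_diploid(ref, 0.5), "het_rate")

  dg <- simulate_diploid(simulate_reference(1e6, seed = 2), 0.02, seed = 3)
  expect_lt(abs(nrow(dg$variants) - 20000), 4 * sqrt(1e6 * 0.02 * 0.98))

  dg2 <- simulate_diploid(simulate_reference(1e6, seed = 4), 0.0159, seed = 5)
  expect_lt(abs(nrow(dg2$variants) / 1e6 - 0.0159), 0.0005)
})

test_that("every listed variant position differs and unlisted positions match", {
  ref <- simulate_reference(3000, seed = 21)
  dg <- simulate_diploid(ref, 0.03, seed = 22)
  r <- strsplit(dg$reference, "")[[1]]
  a <- strsplit(dg$alt_haplotype, "")[[1]]
  expect_equal(length(r), length(a))          # substitution-only default
  differing <- which(r != a)
  expect_setequal(differing, dg$variants$position)
  expect_identical(r[dg$variants$position], dg$variants$ref)
  expect_identical(a[dg$variants$position], dg$variants$alt)
})

test_that("read simulation covers the genome and respects its contracts", {
  ref <- simulate_reference(1e5, seed = 31)
  dg <- simulate_diploid(ref, 0.01, seed = 32)
  expect_error(simulate_reads(dg, 5, 2e5), "read_length")

  rs <- simulate_reads(dg, coverage = 5, read_length = 100, seed = 33)
  total <- sum(nchar(rs$reads$sequence))
  expect_gte(total, 5 * 1e5)
  expect_lt(total, 5 * 1e5 + 100)

  # error-free reads are exact substrings of one of the two haplotypes
  sub <- rs$reads$sequence[1:50]
  hit <- vapply(sub, function(s)
    grepl(s, dg$reference, fixed = TRUE) ||
      grepl(s, dg$alt_haplotype, fixed = TRUE), logical(1))
  expect_true(all(hit))

  # both haplotypes are sampled
  only_alt <- vapply(rs$reads$sequence[1:500], function(s)
    !grepl(s, dg$reference, fixed = TRUE), logical(1))
  expect_gt(mean(only_alt), 0.1)
})

test_that("a fixed seed reproduces the FASTQ byte for byte", {
  dg <- simulate_diploid(simulate_reference(2e4, seed = 41), 0.01, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(dg, 3, 80, error_rate = 0.01, seed = 43), f1)
  write_fastq(simulate_reads(dg, 3, 80, error_rate = 0.01, seed = 43), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annotations are sorted, non-overlapping and clusters are planted adjacently", {
  spec <- data.frame(size = 11, identity = 0.95)
  ann <- simulate_annotation(3, 40, spec, seed = 7)
  for (scaf in unique(ann$genes$scaffold)) {
    g <- ann$genes[ann$genes$scaffold == scaf, ]
    expect_true(!is.unsorted(g$start))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  expect_length(ann$planted_clusters, 1)
  members <- ann$planted_clusters[[1]]
  expect_length(members, 11)
  g <- ann$genes[ann$genes$scaffold == sub("\\.g.*", "", members[1]), ]
  expect_identical(members, g$gene_id[match(members[1], g$gene_id) + 0:10])
  ids <- utils::combn(members, 2)
  pid <- apply(ids, 2, function(p)
    as.numeric(pairwise_identity(ann$proteins[[p[1]]], ann$proteins[[p[2]]])))
  expect_true(all(pid >= 0.9))
})

test_that("cluster placement respects scaffold boundaries and size limits", {
  ann0 <- simulate_annotation(2, 10, NULL, seed = 1)
  expect_length(ann0$planted_clusters, 0)
  expect_error(simulate_annotation(2, 10, data.frame(size = 11, identity = .9)),
               "larger")
  ann2 <- simulate_annotation(2, 20,
                              data.frame(size = c(5, 6),
                                         identity = c(0.9, 0.9)), seed = 5)
  scafs <- vapply(ann2$planted_clusters,
                  function(m) sub("\\.g.*", "", m[1]), "")
  expect_length(unique(scafs), 2)
})

test_that("expression matrices respect library sizes and the planted fold", {
  ids <- sprintf("g%03d", 1:300)
  cm <- simulate_expression(ids, upregulated = ids[1:5], fold = 10000,
                            dispersion = 0.1, seed = 9)
  mat <- as.matrix(cm$counts[cm$stages])
  expect_equal(unname(colSums(mat)), unname(cm$library_sizes))
  base <- mat[1:5, "control"] + 1
  win <- rowMeans(mat[1:5, early_window()])
  expect_true(all(win / base >= 1000))
  expect_error(simulate_expression(ids, upregulated = "nope"), "unknown")
})

test_that("dispersion zero degenerates to rounded expected means", {
  ids <- sprintf("g%03d", 1:50)
  cm <- simulate_expression(ids, upregulated = ids[1], fold = 100,
                            dispersion = 0, seed = 10)
  mat <- as.matrix(cm$counts[cm$stages])
  # background genes: identical counts at every stage
  expect_true(all(apply(mat[-1, ], 1, function(x) length(unique(x)) == 1)))
  # planted gene: window exactly fold x baseline (both rounded from means)
  expect_equal(unname(mat[1, "2h"]), unname(round(100 * 100)))
})

test_that("a unit fold leaves planted genes indistinguishable from background", {
  ids <- sprintf("g%03d", 1:500)
  cm <- simulate_expression(ids, upregulated = ids[1:50], fold = 1,
                            dispersion = 0.1, seed = 13)
  mat <- as.matrix(cm$counts[cm$stages])
  # per-gene mean log-counts are i.i.d. across genes under the null
  gene_level <- rowMeans(log1p(mat))
  ks <- suppressWarnings(stats::ks.test(gene_level[1:50],
                                        gene_level[-(1:50)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("coding-sequence simulation is structurally valid and deterministic", {
  cds <- simulate_coding_sequences(10, bias = 0.5, n_codons = 100, seed = 2)
  expect_identical(cds,
                   simulate_coding_sequences(10, bias = 0.5, n_codons = 100,
                                             seed = 2))
  for (s in cds) {
    expect_equal(nchar(s) %% 3, 0)
    expect_identical(substr(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(simulate_coding_sequences(2, bias = 2), "bias")
})
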