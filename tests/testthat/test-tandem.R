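test_that("pairwise identity matches hand examples and stays symmetric", {
  expect_equal(as.numeric(pairwise_identity("ACDE", "ACDE")), 1)
  expect_equal(as.numeric(pairwise_identity("ACDE", "ACDF")), 0.75)
  expect_equal(as.numeric(pairwise_identity("AAAA", "CCCC")), 0)
  expect_error(pairwise_identity("", "ACD"), "empty")
  set.seed(121)
  for (i in 1:20) {
    a <- random_aa_seq(sample(5:30, 1))
    b <- random_aa_seq(sample(5:30, 1))
    expect_equal(as.numeric(pairwise_identity(a, b)),
                 as.numeric(pairwise_identity(b, a)))
  }
})

test_that("identity equals 1 iff the sequences are identical", {
  set.seed(122)
  for (i in 1:20) {
    a <- random_aa_seq(15)
    b <- a
    substr(b, 8, 8) <- ifelse(substr(a, 8, 8) == "A", "C", "A")
    expect_lt(as.numeric(pairwise_identity(a, b)), 1)
  }
})

test_that("identity agrees with the brute-force dynamic-programming oracle", {
  set.seed(123)
  for (i in 1:50) {
    a <- random_aa_seq(sample(3:30, 1))
    b <- random_aa_seq(sample(3:30, 1))
    expect_equal(as.numeric(pairwise_identity(a, b)),
                 brute_nw_identity(a, b))
  }
})

test_that("a planted 11-copy cluster is recovered exactly", {
  ann <- simulate_annotation(3, 60, data.frame(size = 11, identity = 0.95),
                             seed = 7)
  tc <- detect_tandem_clusters(ann)
  expect_identical(nrow(tc), 1L)
  expect_identical(tc$repeat_count, 11L)
  expect_setequal(tc$members[[1]], ann$planted_clusters[[1]])
  expect_gte(tc$mean_identity, 0.9)
})

test_that("clusters never span scaffolds and disperse under shuffling", {
  ann <- simulate_annotation(2, 30,
                             data.frame(size = c(6, 8),
                                        identity = c(0.9, 0.9)), seed = 31)
  tc <- detect_tandem_clusters(ann)
  expect_identical(nrow(tc), 2L)
  expect_identical(length(unique(tc$scaffold)), 2L)
  expect_identical(sort(tc$repeat_count), c(6L, 8L))
  # members listed in genomic order
  for (i in 1:2) {
    g <- ann$genes[ann$genes$scaffold == tc$scaffold[i], ]
    expect_false(is.unsorted(match(tc$members[[i]], g$gene_id)))
  }

  # shuffle the gene order on a large scaffold: adjacency is destroyed
  ann2 <- simulate_annotation(1, 200, data.frame(size = 11, identity = 0.95),
                              seed = 32)
  perm <- withr::with_seed(33, sample(nrow(ann2$genes)))
  shuffled <- ann2
  # reassign gene ids to new coordinates, keeping starts sorted
  shuffled$genes$gene_id <- ann2$genes$gene_id[perm]
  shuffled$proteins <- ann2$proteins
  expect_identical(nrow(detect_tandem_clusters(shuffled)), 0L)
})

test_that("an empty annotation yields no clusters", {
  ann <- simulate_annotation(1, 8, NULL, seed = 41)
  tc <- detect_tandem_clusters(ann)
  expect_identical(nrow(tc), 0L)
  expect_s3_class(tc, "tandem_clusters")
})

test_that("a single intervening gene does not split a cluster", {
  prot <- c(rep(random_aa_seq(80), 3), random_aa_seq(80),
            rep(random_aa_seq(80), 3))
  set.seed(42)
  base <- random_aa_seq(80)
  prot <- c(base, base, base, random_aa_seq(80), base, base, base)
  ids <- sprintf("s1.g%02d", 1:7)
  ann <- structure(list(
    genes = tibble::tibble(gene_id = ids, scaffold = "s1",
                           start = (1:7) * 1000, end = (1:7) * 1000 + 500,
                           strand = "+"),
    proteins = stats::setNames(prot, ids),
    planted_clusters = list()), class = "annotation_set")
  tc <- detect_tandem_clusters(ann, min_repeats = 6, max_intervening = 1)
  expect_identical(nrow(tc), 1L)
  expect_identical(tc$members[[1]], ids[-4])
  tc0 <- detect_tandem_clusters(ann, min_repeats = 6, max_intervening = 0)
  expect_identical(nrow(tc0), 0L)
})

test_that("proximity clustering chains nearby features", {
  pos <- tibble::tibble(scaffold = "s1",
                        position = c(100, 5000, 9000, 500000))
  cl <- cluster_features_by_proximity(pos, max_gap = 10000, min_size = 2)
  expect_identical(nrow(cl), 1L)
  expect_setequal(cl$positions[[1]], c(100, 5000, 9000))
  expect_identical(
    nrow(cluster_features_by_proximity(pos[0, ], 1000)), 0L)
  far <- tibble::tibble(scaffold = "s1", position = c(0, 1e6, 2e6))
  expect_identical(nrow(cluster_features_by_proximity(far, 1000)), 0L)
})

test_that("conserved columns honour the frequency threshold with gaps counted", {
  aln <- c("AC-E", "ACDE", "ACDE", "TCDE")
  expect_identical(conserved_columns(aln, "C", 1), 2L)
  # column 3: D in 3 of 4 rows (one gap)
  expect_identical(conserved_columns(aln, "D", 0.75), 3L)
  expect_identical(conserved_columns(aln, "D", 0.8), integer(0))
  expect_identical(conserved_columns(character(), "C"), integer())
  expect_error(conserved_columns(c("AB", "ABC"), "A"), "same length")
})

test_that("the center-star utility aligns related sequences consistently", {
  seqs <- c(a = "ACDEFG", b = "ACDEG", c = "ACDEFG")
  aln <- center_star_align(seqs)
  expect_identical(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln[["b"]]), "ACDEG")
  expect_identical(aln[["a"]], aln[["c"]])
})
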