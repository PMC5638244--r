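codon_seq <- function(...) paste0("ATG", paste0(...), "TAA")

test_that("RSCU matches hand-constructed usage patterns", {
  # every sense codon exactly once: uniform usage in every family
  tabs <- genomesurvey:::genetic_code_tables()
  all61 <- codon_seq(paste(names(tabs$sense), collapse = ""))
  r <- rscu(all61)
  expect_true(all(abs(r[r > 0] - 1) < 1e-12))
  # Lys family (AAA/AAG) at counts 3:1
  r2 <- rscu(codon_seq("AAAAAAAAAAAG"))
  expect_equal(unname(r2["AAA"]), 1.5)
  expect_equal(unname(r2["AAG"]), 0.5)
  # absent families score 0
  expect_equal(unname(r2["GGG"]), 0)
  expect_error(rscu("ATGA"), "multiple of 3")
  expect_error(rscu(codon_seq("TAAAAA")), "internal stop")
})

test_that("relative adaptiveness scales by the family maximum with the 0.5 guard", {
  # Lys AAA x30, AAG x10 -> w = 1, 1/3
  ref <- codon_seq(strrep("AAA", 30), strrep("AAG", 10))
  w <- relative_adaptiveness(ref)
  expect_equal(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3, tolerance = 1e-12)
  # absent codon with family max 20 -> 0.5 / 20
  ref2 <- codon_seq(strrep("AAA", 20))
  w2 <- relative_adaptiveness(ref2)
  expect_equal(unname(w2["AAG"]), 0.025)
  expect_error(relative_adaptiveness(character()), "empty")
})

test_that("CAI is the geometric mean over codons with synonymous choice", {
  tabs <- genomesurvey:::genetic_code_tables()
  w1 <- stats::setNames(rep(1, length(tabs$sense)), names(tabs$sense))
  expect_equal(cai(codon_seq("AAAGGGTTC"), w1), 1)
  w <- w1
  w["TTC"] <- 0.25
  # two w=1 and two w=0.25 codons -> (0.0625)^(1/4) = 0.5
  expect_equal(cai(codon_seq("AAAAAATTCTTC"), w), 0.5)
  # Met/Trp excluded: adding them leaves CAI unchanged
  expect_equal(cai(codon_seq("ATGTGGAAAAAATTCTTC"), w), 0.5)
})

test_that("CAI is order invariant and length-weighted under concatenation", {
  cds <- simulate_coding_sequences(2, bias = c(0.3, 0.8), n_codons = 200,
                                   seed = 130)
  w <- relative_adaptiveness(simulate_coding_sequences(3, 1, seed = 131))
  body <- function(s) substr(s, 4, nchar(s) - 3)
  a <- cds[[1]]; b <- cds[[2]]
  # shuffle codons of a
  cods <- substring(body(a), seq(1, nchar(body(a)), 3),
                    seq(3, nchar(body(a)), 3))
  shuf <- codon_seq(paste(withr::with_seed(9, sample(cods)), collapse = ""))
  expect_equal(cai(a, w), cai(shuf, w))
  concat <- codon_seq(body(a), body(b))
  countable <- function(s) {
    cods <- substring(body(s), seq(1, nchar(body(s)), 3),
                      seq(3, nchar(body(s)), 3))
    sum(!cods %in% c("ATG", "TGG"))
  }
  na <- countable(a); nb <- countable(b)
  expected <- exp((na * log(cai(a, w)) + nb * log(cai(b, w))) / (na + nb))
  expect_equal(cai(concat, w), expected, tolerance = 1e-6)
})

test_that("maximal bias forces CAI = 1 under matching reference weights", {
  cds <- simulate_coding_sequences(4, bias = 1, n_codons = 150, seed = 132)
  w <- relative_adaptiveness(cds)
  expect_true(all(vapply(cds, cai, numeric(1), w = w) == 1))
})

test_that("Nc hits the Wright limits at the bias extremes", {
  one_per_aa <- simulate_coding_sequences(1, bias = 1, n_codons = 600,
                                          seed = 133)
  expect_equal(enc(one_per_aa[[1]]), 20)
  uniform <- simulate_coding_sequences(1, bias = 0, n_codons = 3000,
                                       seed = 134)
  expect_lte(abs(enc(uniform[[1]]) - 61), 2)
})

test_that("Nc equals the direct-formula oracle on random genes", {
  cds <- simulate_coding_sequences(10, bias = runif(10), n_codons = 300,
                                   seed = 135)
  for (s in cds) expect_equal(enc(s), brute_enc(s))
})

test_that("Nc decreases monotonically along the bias gradient", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  ncs <- matrix(NA_real_, 10, length(grid))
  for (r in 1:10) {
    cds <- simulate_coding_sequences(length(grid), bias = grid,
                                     n_codons = 500, seed = 140 + r)
    ncs[r, ] <- vapply(cds, enc, numeric(1))
  }
  expect_true(all(diff(colMeans(ncs)) < 0))
})

test_that("correspondence analysis has the expected geometry", {
  cds <- simulate_coding_sequences(30, bias = seq(0, 1, length.out = 30),
                                   n_codons = 300, seed = 150)
  m <- rscu_matrix(cds)
  ca <- correspondence_axes(m, n_axes = 4)
  # identical rows -> identical coordinates
  m2 <- rbind(m, m[1, , drop = FALSE])
  rownames(m2)[31] <- "dup"
  ca2 <- correspondence_axes(m2, n_axes = 2)
  expect_equal(ca2$row_coords[1, ], ca2$row_coords[31, ])
  # row-mass-weighted orthogonality of principal coordinates
  G <- t(ca$row_coords) %*% diag(ca$row_mass) %*% ca$row_coords
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8)
  # inertia shares are a non-increasing sub-unit decomposition
  expect_lte(sum(ca$inertia_share), 1 + 1e-9)
  expect_true(all(diff(ca$inertia_share) <= 1e-12))
})

test_that("a rank-one usage contrast yields a single informative axis", {
  m <- rbind(g1 = c(4, 0, 1, 1), g2 = c(0, 4, 1, 1), g3 = c(2, 2, 1, 1))
  ca <- correspondence_axes(m, n_axes = 3)
  expect_identical(ncol(ca$row_coords), 1L)
  expect_gt(ca$inertia_share[1], 0.99)
})

test_that("axis-CAI correlation is sign-corrected and null-calibrated", {
  x <- seq_len(50)
  expect_equal(axis_cai_correlation(x, 0.2 + 0.001 * x), 1)
  expect_equal(axis_cai_correlation(-x, 0.2 + 0.001 * x), 1)
  set.seed(151)
  r <- axis_cai_correlation(rnorm(1000), runif(1000))
  expect_lte(r, 0.1)
  expect_error(axis_cai_correlation(1:2, 1:2), "length")
  expect_error(axis_cai_correlation(rep(1, 5), 1:5), "variance")
})

test_that("the bias gradient drives a CA axis strongly correlated with CAI", {
  biases <- seq(0, 1, length.out = 40)
  cds <- simulate_coding_sequences(40, bias = biases, n_codons = 400,
                                   seed = 152)
  st <- codon_usage_stats(cds, reference_cds = cds[biases > 0.9])
  ca <- correspondence_axes(rscu_matrix(cds))
  best <- cai_axis(ca, st$cai)
  expect_gte(best$correlation[1], 0.8)
})
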