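# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
           ""))
}

# direct map accumulation over every k-window of every read
brute_kmer_hist <- function(reads, k) {
  acc <- new.env(hash = TRUE)
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      canon <- min(w, revcomp(w))
      acc[[canon]] <- (if (is.null(acc[[canon]])) 0 else acc[[canon]]) + 1
    }
  }
  depths <- unlist(as.list(acc), use.names = FALSE)
  tab <- table(depths)
  data.frame(depth = as.integer(names(tab)), count = as.numeric(tab))
}

# cumulative-scan Nx
brute_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * sum(s))[1]]
}

# full-matrix Needleman-Wunsch identity (match +1 / mismatch 0 / gap -1,
# diagonal-preferring traceback), kept in plain R
brute_nw_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  sc <- matrix(0, n + 1, m + 1); tb <- matrix(0L, n + 1, m + 1)
  sc[1, ] <- -(0:m); sc[, 1] <- -(0:n)
  tb[1, -1] <- 3L; tb[-1, 1] <- 2L
  for (i in 1:n) for (j in 1:m) {
    cand <- c(sc[i, j] + (ac[i] == bc[j]), sc[i, j + 1] - 1, sc[i + 1, j] - 1)
    dir <- which.max(cand)              # ties -> diagonal first
    sc[i + 1, j + 1] <- cand[dir]; tb[i + 1, j + 1] <- dir
  }
  i <- n; j <- m; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    dir <- tb[i + 1, j + 1]
    if (dir == 1L) { matches <- matches + (ac[i] == bc[j]); i <- i - 1; j <- j - 1 }
    else if (dir == 2L) i <- i - 1 else j <- j - 1
    len <- len + 1
  }
  matches / len
}

# Wright's Nc recomputed directly from a codon-count vector
brute_enc <- function(cds) {
  gcod <- Biostrings::GENETIC_CODE
  sense <- gcod[gcod != "*"]
  codons <- substring(toupper(cds), seq(1, nchar(cds), 3),
                      seq(3, nchar(cds), 3))
  codons <- codons[codons %in% names(sense)]
  fam <- split(names(sense), sense)
  fam <- fam[lengths(fam) > 1]
  fhat <- sapply(fam, function(f) {
    nn <- sum(codons %in% f)
    if (nn <= 1) return(NA_real_)
    p <- sapply(f, function(cd) sum(codons == cd)) / nn
    (nn * sum(p^2) - 1) / (nn - 1)
  })
  deg <- lengths(fam)
  fbar <- sapply(c(2, 3, 4, 6), function(d) mean(fhat[deg == d], na.rm = TRUE))
  if (is.nan(fbar[2])) fbar[2] <- mean(fbar[c(1, 3)])
  min(61, max(20, 2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4]))
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# a small diploid read simulation + spectrum, shared by several tests
small_spectrum <- function(h, seed, L = 2e5, coverage = 30,
                           read_length = 100, error_rate = 0, k = 17) {
  ref <- simulate_reference(L, seed = seed)
  dg <- simulate_diploid(ref, h, seed = seed + 1)
  rs <- simulate_reads(dg, coverage = coverage, read_length = read_length,
                       error_rate = error_rate, seed = seed + 2)
  count_kmers(rs, k = k)
}
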