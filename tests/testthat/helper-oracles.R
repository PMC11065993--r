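# Independent oracles used across the suite. These deliberately avoid
# the package's own computation paths.

BASES <- c("A", "C", "G", "T")

# Random PWM built from random sites through the public constructor.
rand_pwm <- function(W, n_sites = 6, pseudocount = 0.5,
                     background = NULL) {
  if (is.null(background)) {
    b <- runif(4, 0.5, 2)
    background <- setNames(b / sum(b), BASES)
  }
  sites <- replicate(n_sites, paste(sample(BASES, W, replace = TRUE),
                                    collapse = ""))
  build_pwm(sites, background = background, pseudocount = pseudocount)
}

# Enumerate all 4^W words: per-word background probability and score.
# Scores are accumulated column by column with plain double additions,
# the same association order as a left-to-right sum.
enumerate_words <- function(pwm) {
  W <- pwm$width
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  idx <- as.matrix(expand.grid(rep(list(1:4), W)))
  score <- numeric(nrow(idx))
  prob <- rep(1, nrow(idx))
  for (k in seq_len(W)) {
    score <- score + unname(lo[k, idx[, k]])
    prob <- prob * unname(pwm$background[idx[, k]])
  }
  list(score = score, prob = prob, logodds = lo)
}

# Brute-force tail probability over all words.
brute_pvalue <- function(pwm, threshold) {
  e <- enumerate_words(pwm)
  sum(e$prob[e$score >= threshold])
}

# TATA mismatch count by minimum Hamming distance over the two concrete
# expansions of the degenerate consensus.
tata_mm_oracle <- function(word8) {
  v <- strsplit(word8, "")[[1]]
  ref <- list(strsplit("TTTAAATA", "")[[1]], strsplit("TTTATATA", "")[[1]])
  min(vapply(ref, function(r) sum(v != r), numeric(1)))
}

# Quadratic-DP Smith-Waterman score with affine gaps (open 11, extend
# 1; a length-L gap costs 11 + L), BLOSUM62.
sw_score_oracle <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[x[i - 1], y[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - 12, Ix[i - 1, j] - 1)
      Iy[i, j] <- max(M[i, j - 1] - 12, Iy[i, j - 1] - 1)
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_dna <- function(len, probs = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
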