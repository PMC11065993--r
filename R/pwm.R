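#' Order-0 background model from upstream regions
#'
#' Empirical base frequencies with +1 smoothing across the four bases;
#' ambiguous bases are ignored.
#'
#' @param regions named character vector of sequences or a region
#'   data.frame (see [upstream_regions()]).
#' @return named probability vector over A, C, G, T.
#' @export
build_background <- function(regions) {
  seqs <- as_region_seqs(regions)
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0)
    stop("cannot build a background from empty input")
  v <- strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE)[[1]]
  counts <- vapply(DNA_BASES, function(b) sum(v == b), numeric(1))
  if (sum(counts) == 0) stop("no unambiguous bases in input")
  (counts + 1) / (sum(counts) + 4)
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount * bg) / (n_sites +
#' pseudocount)`: the pseudocount is distributed according to the
#' background, MEME-style. The IUPAC consensus covers, per column, every
#' base holding at least 25% probability.
#'
#' @param sites character vector of equal-length DNA strings (>= 2,
#'   A/C/G/T only).
#' @param background named base-probability vector.
#' @param pseudocount nonnegative total pseudocount.
#' @param motif_id identifier carried into outputs.
#' @return an object of class `PWM`.
#' @export
build_pwm <- function(sites, background = c(A = .25, C = .25, G = .25, T = .25),
                      pseudocount = 0.25, motif_id = "motif_1") {
  if (length(sites) < 2) stop("need at least 2 sites")
  W <- unique(nchar(sites))
  if (length(W) != 1) stop("sites must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  if (!all(mat %in% DNA_BASES))
    stop("sites must contain only A/C/G/T (drop N-containing sites upstream)")
  counts <- t(apply(mat, 2, function(col)
    vapply(DNA_BASES, function(b) sum(col == b), numeric(1))))
  counts <- matrix(counts, nrow = W, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  new_pwm(counts = counts, n_sites = length(sites),
          background = background[DNA_BASES], pseudocount = pseudocount,
          motif_id = motif_id,
          source_site_ids = names(sites) %||% as.character(seq_along(sites)))
}

# shared constructor: probs derived from counts + pseudocount*bg
new_pwm <- function(counts, n_sites, background, pseudocount, motif_id,
                    source_site_ids = character()) {
  probs <- sweep(counts, 2, background * pseudocount, "+") /
    (rowSums(counts) + pseudocount)
  structure(list(
    motif_id = motif_id, width = nrow(counts), counts = counts,
    probs = probs, background = background, pseudocount = pseudocount,
    n_sites = n_sites, source_site_ids = source_site_ids,
    consensus = pwm_consensus(probs)), class = "PWM")
}

pwm_consensus <- function(probs) {
  paste(apply(probs, 1, function(p)
    iupac_code(DNA_BASES[p >= 0.25])), collapse = "")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("<PWM> %s: width %d, %s sites, consensus %s\n", x$motif_id,
              x$width, format(x$n_sites), x$consensus))
  invisible(x)
}

pwm_logodds <- function(pwm) {
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  dimnames(lo) <- list(NULL, DNA_BASES)
  lo
}

#' Average information content (bits/column)
#' @param pwm a `PWM`.
#' @export
pwm_ic <- function(pwm) {
  p <- pwm$probs
  mean(rowSums(ifelse(p > 0, p * log2(p), 0)) + 2)
}

#' Log-likelihood-ratio score of a word
#'
#' Sum over columns of `log2(p[i, base] / background[base])`, in bits.
#' With a zero pseudocount an unseen base scores `-Inf`.
#'
#' @param pwm a `PWM`.
#' @param word DNA string of length `pwm$width` over A/C/G/T.
#' @export
score_word <- function(pwm, word) {
  idx <- encode_dna(word)
  if (length(idx) != pwm$width)
    stop("word length ", length(idx), " != PWM width ", pwm$width)
  if (any(idx > 3)) stop("word must be over A/C/G/T")
  lo <- pwm_logodds(pwm)
  sum(lo[cbind(seq_len(pwm$width), idx + 1L)])
}

#' Distribution of PWM scores under the background
#'
#' Dynamic program over the score distribution of a background-drawn
#' word. `"exact"` convolves the exact per-column score values (feasible
#' for widths up to ~8); `"lattice"` rounds scores to a fixed bin width
#' first, which scales linearly for wide discovery motifs. `"auto"`
#' picks exact when the full word space is small (width <= 8).
#'
#' @param pwm a `PWM`.
#' @param granularity lattice bin width (bits); must be > 0 for the
#'   lattice method.
#' @param method `"auto"`, `"exact"` or `"lattice"`.
#' @return `ScoreDistribution`: sorted `support`, `pmf`, `granularity`
#'   (0 for exact).
#' @export
score_distribution <- function(pwm, granularity = 1e-3,
                               method = c("auto", "exact", "lattice")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (pwm$width <= 8) "exact" else "lattice"
  lo <- pwm_logodds(pwm)
  bg <- pwm$background
  if (method == "lattice") {
    if (granularity <= 0) stop("granularity must be > 0")
    d <- cpp_score_dist_lattice(lo, unname(bg), granularity)
    return(structure(list(support = d$support, pmf = d$pmf,
                          granularity = granularity),
                     class = "ScoreDistribution"))
  }
  if (!all(is.finite(lo)))
    stop("exact distribution requires finite scores (positive pseudocount)")
  support <- 0; pmf <- 1
  for (w in seq_len(pwm$width)) {
    sv <- rep(support, times = 4) + rep(lo[w, ], each = length(support))
    pv <- rep(pmf, times = 4) * rep(unname(bg), each = length(pmf))
    u <- unique(sv)
    pmf <- as.vector(rowsum(pv, match(sv, u)))
    support <- u
    if (length(support) > 2e5)
      stop("exact score distribution too large; use method = \"lattice\"")
  }
  o <- order(support)
  structure(list(support = support[o], pmf = pmf[o], granularity = 0),
            class = "ScoreDistribution")
}

# Survival-function lookup: P(score >= s) for each s.
pvalue_from_dist <- function(dist, scores) {
  sf <- rev(cumsum(rev(dist$pmf)))
  tol <- if (dist$granularity > 0) dist$granularity / 2 else 0
  vapply(scores, function(s) {
    if (!is.finite(s)) return(if (s > 0) 0 else 1)
    i <- findInterval(s - tol, dist$support, left.open = TRUE) + 1L
    if (i > length(sf)) 0 else sf[i]
  }, numeric(1))
}

#' Exact p-value of a PWM score threshold
#'
#' `P(score of a background-distributed word >= threshold)`.
#'
#' @param pwm a `PWM`.
#' @param threshold score threshold (bits).
#' @param dist optional precomputed [score_distribution()].
#' @param ... passed to [score_distribution()].
#' @export
score_pvalue <- function(pwm, threshold, dist = NULL, ...) {
  stopifnot(is.finite(threshold))
  if (is.null(dist)) dist <- score_distribution(pwm, ...)
  pvalue_from_dist(dist, threshold)
}

# ---- MEME minimal motif format -------------------------------------------

#' Write motifs in MEME minimal text format
#'
#' @param pwms a `PWM` or list of them.
#' @param path output file.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), "")
  for (pwm in pwms) {
    out <- c(out, sprintf("MOTIF %s", pwm$motif_id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
                     pwm$width, pwm$n_sites),
             apply(pwm$probs, 1, function(p)
               paste(sprintf("%.6f", p), collapse = "  ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path MEME-format motif file.
#' @param pseudocount pseudocount recorded on the returned `PWM`s (the
#'   probabilities are taken as stored).
#' @return list of `PWM` objects.
#' @export
read_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])
    bg <- bg[DNA_BASES]
  }
  motif_at <- grep("^MOTIF ", lines)
  pwms <- list()
  for (m in motif_at) {
    motif_id <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr <- lines[m + 1]
    W <- as.integer(sub(".* w= *([0-9]+).*", "\\1", hdr))
    nsites <- as.numeric(sub(".* nsites= *([0-9.eE+-]+).*", "\\1", hdr))
    rows <- lines[(m + 2):(m + 1 + W)]
    probs <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                   as.numeric))
    colnames(probs) <- DNA_BASES
    # reconstruct counts consistent with the stored probabilities
    counts <- probs * nsites
    pwm <- structure(list(
      motif_id = motif_id, width = W, counts = counts, probs = probs,
      background = bg, pseudocount = pseudocount, n_sites = nsites,
      source_site_ids = character(), consensus = pwm_consensus(probs)),
      class = "PWM")
    pwms[[motif_id]] <- pwm
  }
  pwms
}
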