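#' Motif discovery configuration
#'
#' Defaults mirror the scale of archaeal early-promoter regulatory
#' sequences: wide motifs (30-100 nt) holding a BRE + TATA core plus
#' conserved flanks, discovered in 100-nt upstream windows.
#'
#' @param W_min,W_max motif width bounds (nt); widths are explored on a
#'   grid `W_min, W_min + width_step, ...`.
#' @param width_step width grid step (nt).
#' @param n_motifs maximum motifs extracted per region set (iterative
#'   masking between rounds).
#' @param site_p_threshold exact site p-value below which a site counts
#'   as significant.
#' @param em_tol relative change in the EM objective declaring
#'   convergence.
#' @param em_max_iter EM iteration cap.
#' @param min_sequences minimum usable regions required.
#' @param pseudocount total Dirichlet pseudocount, spread by background.
#' @param granularity score-lattice bin width (bits) for site p-values.
#' @export
discovery_config <- function(W_min = 30L, W_max = 100L, width_step = 10L,
                             n_motifs = 3L, site_p_threshold = 1e-8,
                             em_tol = 1e-6, em_max_iter = 200L,
                             min_sequences = 5L, pseudocount = 0.25,
                             granularity = 1e-3) {
  stopifnot(W_min >= 1, W_min <= W_max, site_p_threshold > 0,
            site_p_threshold < 1, em_tol > 0, pseudocount >= 0)
  list(W_min = as.integer(W_min), W_max = as.integer(W_max),
       width_step = as.integer(width_step), n_motifs = as.integer(n_motifs),
       site_p_threshold = site_p_threshold, em_tol = em_tol,
       em_max_iter = as.integer(em_max_iter),
       min_sequences = as.integer(min_sequences),
       pseudocount = pseudocount, granularity = granularity)
}

# Soft seed model used for exhaustive-substring seeding: the seed base
# gets probability 0.55, the others 0.15 (vs a uniform reference), so
# seed ranking is a monotone function of per-window match counts.
SEED_MATCH_LOD <- log2(0.55 / 0.25)
SEED_MISMATCH_LOD <- log2(0.15 / 0.25)

#' One ZOOPS expectation-maximization step
#'
#' E-step: per-offset site posteriors under the zero-or-one-occurrence
#' model; M-step: background-weighted Dirichlet-smoothed column
#' probabilities and the site prior. The returned `log_likelihood` is
#' the EM objective (data log-likelihood relative to the all-background
#' model, plus the Dirichlet smoothing term, base 2) evaluated at the
#' *input* parameters; it is nondecreasing over successive calls.
#'
#' @param pwm a `PWM`.
#' @param lambda site prior in (0, 1).
#' @param regions named character vector of region sequences (masked
#'   bases as N) or pre-encoded integer list.
#' @param background named base-probability vector.
#' @return list: updated `pwm`, `lambda`, `log_likelihood`, plus the
#'   per-region posterior matrix pieces (`z`, `scores`).
#' @export
em_step <- function(pwm, lambda, regions, background = pwm$background) {
  stopifnot(lambda > 0, lambda < 1)
  enc <- if (is.list(regions) && is.integer(regions[[1]])) regions
         else lapply(as_region_seqs(regions), encode_dna)
  W <- pwm$width
  lo <- pwm_logodds(pwm)
  scores <- cpp_window_scores(enc, lo)
  n_used <- 0L
  obj_data <- 0
  z <- vector("list", length(enc))
  zsum <- numeric(length(enc))
  for (i in seq_along(enc)) {
    sc <- scores[[i]]
    ok <- is.finite(sc)
    m <- sum(ok)
    if (m == 0) { z[[i]] <- numeric(length(sc)); next }
    n_used <- n_used + 1L
    lw <- log2(lambda / m) + sc
    denom <- logsumexp2(c(log2(1 - lambda), lw[ok]))
    zi <- numeric(length(sc))
    zi[ok] <- 2^(lw[ok] - denom)
    z[[i]] <- zi
    zsum[i] <- sum(zi)
    obj_data <- obj_data + denom
  }
  if (n_used == 0) stop("no region offers a valid window of width ", W)
  prior <- pwm$pseudocount *
    sum(sweep(log2(pwm$probs), 2, pwm$background, "*"))
  cnt <- cpp_weighted_counts(enc, z, W)
  dimnames(cnt) <- list(NULL, DNA_BASES)
  new_lambda <- min(max(mean(zsum[vapply(z, length, 1L) > 0]), 1e-6),
                    1 - 1e-6)
  new <- new_pwm(cnt, n_sites = sum(zsum), background = pwm$background,
                 pseudocount = pwm$pseudocount, motif_id = pwm$motif_id,
                 source_site_ids = pwm$source_site_ids)
  list(pwm = new, lambda = new_lambda,
       log_likelihood = obj_data + prior, data_log_likelihood = obj_data,
       z = z, scores = scores, n_regions_used = n_used)
}

# EM to convergence from a given starting PWM.
run_em <- function(pwm, lambda, enc, config) {
  prev <- -Inf
  state <- list(pwm = pwm, lambda = lambda)
  for (it in seq_len(config$em_max_iter)) {
    state <- em_step(state$pwm, state$lambda, enc)
    obj <- state$log_likelihood
    if (is.finite(prev) &&
        abs(obj - prev) <= config$em_tol * max(1, abs(prev))) break
    prev <- obj
  }
  state
}

seed_pwm <- function(enc, region, offset, W, background, pseudocount,
                     motif_id) {
  codes <- enc[[region]][offset:(offset + W - 1L)]
  probs <- matrix(0.15, nrow = W, ncol = 4, dimnames = list(NULL, DNA_BASES))
  probs[cbind(seq_len(W), codes + 1L)] <- 0.55
  structure(list(motif_id = motif_id, width = W, counts = probs,
                 probs = probs, background = background[DNA_BASES],
                 pseudocount = pseudocount, n_sites = 1,
                 source_site_ids = character(),
                 consensus = pwm_consensus(probs)), class = "PWM")
}

#' Discover conserved motifs in a set of upstream regions
#'
#' Deterministic per-genome ZOOPS discovery: every width-W substring is
#' screened as a one-site seed (exhaustive-substring seeding, so no
#' random restarts), the best seed is refined by EM to convergence, the
#' width grid is compared by BIC-penalized converged likelihood, sites
#' are kept when their exact score p-value clears `site_p_threshold`,
#' and retained sites are masked before the next motif round.
#'
#' @param regions named character vector or region data.frame; regions
#'   flagged unusable (column `usable`) are dropped.
#' @param config a [discovery_config()].
#' @param background optional base-probability vector; estimated from
#'   the regions by default.
#' @return list of motif results: `pwm`, `sites` (data.frame sorted by
#'   p-value with a `passing` flag), `zoops_lambda`, `log_likelihood`,
#'   `passed_threshold`, `width`.
#' @export
discover_motifs <- function(regions, config = discovery_config(),
                            background = NULL) {
  if (is.data.frame(regions) && "usable" %in% names(regions))
    regions <- regions[regions$usable, , drop = FALSE]
  seqs <- as_region_seqs(regions)
  seqs <- seqs[nchar(seqs) >= config$W_min]
  if (length(seqs) < config$min_sequences)
    stop(sprintf(
      "too few usable regions: %d < min_sequences = %d (of length >= W_min = %d)",
      length(seqs), config$min_sequences, config$W_min))
  if (is.null(background)) background <- build_background(seqs)
  background <- background[DNA_BASES]
  enc <- lapply(seqs, encode_dna)
  widths <- seq(config$W_min, config$W_max, by = config$width_step)
  widths <- widths[widths <= max(nchar(seqs))]
  results <- list()
  for (round in seq_len(config$n_motifs)) {
    best <- NULL
    for (W in widths) {
      seed <- cpp_seed_screen(enc, W, SEED_MATCH_LOD, SEED_MISMATCH_LOD, 0.5)
      if (seed$region < 1) next
      init <- seed_pwm(enc, seed$region, seed$offset, W, background,
                       config$pseudocount,
                       motif_id = sprintf("motif_%d", round))
      state <- run_em(init, 0.5, enc, config)
      # widths are compared by AIC-penalized converged likelihood:
      # raw likelihood grows monotonically with width (3 free
      # parameters per added column), so an unpenalized comparison
      # always degenerates to W_max
      crit <- state$data_log_likelihood * log(2) - (3 * W + 1)
      if (is.null(best) || crit > best$crit) {
        best <- state
        best$crit <- crit
        best$width <- W
      }
    }
    if (is.null(best)) break
    res <- finalize_motif(best, enc, seqs, config)
    results[[length(results) + 1]] <- res
    if (!res$passed_threshold) break
    # mask retained sites before the next round
    for (k in which(res$sites$passing)) {
      i <- match(res$sites$region_id[k], names(enc))
      span <- res$sites$offset[k]:(res$sites$offset[k] + res$width - 1L)
      enc[[i]][span] <- 4L
    }
  }
  results
}

finalize_motif <- function(state, enc, seqs, config) {
  W <- state$width
  dist <- score_distribution(state$pwm, granularity = config$granularity,
                             method = "lattice")
  cnt <- state$pwm$counts
  bg <- state$pwm$background
  pc <- state$pwm$pseudocount
  rows <- list()
  for (i in seq_along(enc)) {
    zi <- state$z[[i]]
    if (length(zi) == 0 || sum(zi) < 0.5) next
    j <- which.max(zi)
    sc <- state$scores[[i]][j]
    if (!is.finite(sc)) next
    # Site significance is computed on the leave-one-out score: the
    # site rescored under the PWM re-estimated without its own
    # region's posterior mass. This removes the self-inclusion bias
    # that otherwise makes EM-aligned sites in pure-noise region sets
    # look significant.
    cnt_i <- cpp_weighted_counts(enc[i], state$z[i], W)
    loo <- pmax(cnt - cnt_i, 0)
    # Jeffreys (+0.5/base) smoothing for the held-out predictive
    # probabilities: with few sites, the sharper estimation
    # pseudocount would price a base unseen in the remaining sites at
    # nearly -log2(n_sites/bg) bits, over-penalizing natural site
    # degeneracy
    probs_loo <- (loo + 0.5) / (rowSums(loo) + 2)
    lo_loo <- log2(sweep(probs_loo, 2, bg, "/"))
    codes <- enc[[i]][j:(j + W - 1L)]
    sc_loo <- sum(lo_loo[cbind(seq_len(W), codes + 1L)])
    rows[[length(rows) + 1]] <- data.frame(
      region_id = names(enc)[i], offset = j, score = sc,
      score_loo = sc_loo,
      p_value = pvalue_from_dist(dist, sc_loo),
      site = substr(seqs[[i]], j, j + W - 1L),
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(), offset = integer(),
               score = numeric(), score_loo = numeric(),
               p_value = numeric(), site = character())
  sites$passing <- sites$p_value < config$site_p_threshold
  sites <- sites[order(sites$p_value, sites$region_id), , drop = FALSE]
  rownames(sites) <- NULL
  pwm <- state$pwm
  pwm$source_site_ids <- sites$region_id[sites$passing]
  list(pwm = pwm, width = W, sites = sites,
       zoops_lambda = state$lambda,
       log_likelihood = state$log_likelihood,
       score_dist = dist,
       passed_threshold = sum(sites$passing) >= 2)
}
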