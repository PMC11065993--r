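# 12 upstream-like regions, n_implant of them carrying a site sampled
# from a sharp implant PWM at a random offset. Returns the ground truth.
implant_fixture <- function(seed, n_regions = 12, n_implant = 10,
                            implant_ic = 1.2, L = 100) {
  set.seed(seed)
  sp <- sim_spec(seed = seed, implant_ic = implant_ic)
  pwm <- adgscan:::make_implant_pwm(sp)
  regions <- setNames(replicate(n_regions, random_dna(L)),
                      sprintf("r%02d", 1:n_regions))
  truth <- data.frame(region = names(regions)[seq_len(n_implant)],
                      offset = NA_integer_, site = NA_character_)
  for (i in seq_len(n_implant)) {
    site <- adgscan:::sample_site(pwm)
    at <- sample(seq_len(L - pwm$width + 1), 1)
    substr(regions[i], at, at + pwm$width - 1) <- site
    truth$offset[i] <- at
    truth$site[i] <- site
  }
  list(regions = regions, truth = truth, pwm = pwm)
}

iupac_contains <- function(code, base) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
            W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG",
            H = "ACT", D = "AGT", B = "CGT", N = "ACGT")
  grepl(base, sets[code], fixed = TRUE)
}

test_that("one EM step matches the hand-computed two-offset posterior", {
  # width-2 PWM: column 1 = (.7,.1,.1,.1) on A, column 2 on C
  sites <- c(rep("AC", 7), "CA", "GG", "TT")
  pwm <- build_pwm(sites, pseudocount = 0)
  expect_equal(unname(pwm$probs[1, "A"]), 0.7)
  region <- c(r1 = "ACG")  # offsets: AC, CG
  s1 <- 2 * log2(0.7 / 0.25)
  s2 <- 2 * log2(0.1 / 0.25)
  lambda <- 0.5
  denom <- (1 - lambda) + (lambda / 2) * (2^s1 + 2^s2)
  z1 <- (lambda / 2) * 2^s1 / denom
  z2 <- (lambda / 2) * 2^s2 / denom
  st <- em_step(pwm, lambda, region)
  expect_equal(st$z[[1]], c(z1, z2), tolerance = 1e-12)
  # of the site mass, nearly all concentrates on the true offset
  expect_gt(z1 / (z1 + z2), 0.95)
  expect_gt(st$z[[1]][1] / sum(st$z[[1]]), 0.95)
  expect_equal(st$lambda, z1 + z2, tolerance = 1e-12)
})

test_that("the EM objective is nondecreasing and reaches a fixed point", {
  set.seed(61)
  for (fixture in 1:20) {
    regions <- setNames(replicate(6, random_dna(60)), paste0("r", 1:6))
    pwm <- rand_pwm(8, n_sites = 4, pseudocount = 0.25,
                    background = c(A = .25, C = .25, G = .25, T = .25))
    st <- list(pwm = pwm, lambda = 0.3)
    objs <- numeric(10)
    for (it in 1:10) {
      st <- em_step(st$pwm, st$lambda, regions)
      objs[it] <- st$log_likelihood
    }
    expect_true(all(diff(objs) >= -1e-8))
  }
  # converged state moves less than the tolerance
  cfg <- discovery_config()
  regions <- setNames(replicate(8, random_dna(60)), paste0("r", 1:8))
  set.seed(62)
  st <- adgscan:::run_em(rand_pwm(8, background = build_background(regions)),
                         0.4, regions, cfg)
  again <- em_step(st$pwm, st$lambda, regions)
  final <- em_step(again$pwm, again$lambda, regions)
  expect_lt(abs(final$log_likelihood - again$log_likelihood),
            cfg$em_tol * max(1, abs(again$log_likelihood)))
})

test_that("an implanted motif is recovered with its carrier regions", {
  fx <- implant_fixture(seed = 71)
  res <- discover_motifs(fx$regions)
  expect_gte(length(res), 1)
  top <- res[[1]]
  expect_true(top$passed_threshold)
  hits <- top$sites[top$sites$passing, ]
  expect_gte(length(intersect(hits$region_id, fx$truth$region)), 9)

  # consensus agreement over the implant's 20 most informative columns:
  # align by the modal (site offset - true offset) shift
  common <- intersect(hits$region_id, fx$truth$region)
  shifts <- hits$offset[match(common, hits$region_id)] -
    fx$truth$offset[match(common, fx$truth$region)]
  shift <- as.integer(names(sort(table(shifts), decreasing = TRUE))[1])
  imp_cons <- strsplit(fx$pwm$consensus, "")[[1]]
  got_cons <- strsplit(top$pwm$consensus, "")[[1]]
  ic <- rowSums(ifelse(fx$pwm$probs > 0, fx$pwm$probs * log2(fx$pwm$probs), 0)) + 2
  top20 <- order(ic, decreasing = TRUE)[1:20]
  mm <- 0
  for (k in top20) {
    kd <- k - shift  # implant column k sits at discovered column kd
    if (kd < 1 || kd > top$width) next
    if (!iupac_contains(got_cons[kd], imp_cons[k])) mm <- mm + 1
  }
  expect_lte(mm, 2)
})

test_that("identical regions give one site per region at the tail minimum", {
  set.seed(81)
  r <- random_dna(100)
  regions <- setNames(rep(r, 12), paste0("r", 1:12))
  res <- discover_motifs(regions)
  top <- res[[1]]
  expect_true(top$passed_threshold)
  expect_equal(anyDuplicated(top$sites$region_id), 0L)  # ZOOPS
  expect_lte(nrow(top$sites), 12)
  expect_true(all(top$sites$p_value < 1e-8))
})

test_that("pure-noise regions never pass the site threshold", {
  set.seed(91)
  regions <- setNames(replicate(12, random_dna(100)), paste0("r", 1:12))
  res <- discover_motifs(regions)
  expect_false(any(vapply(res, `[[`, logical(1), "passed_threshold")))
})

test_that("discovery refuses undersized region sets", {
  regions <- setNames(replicate(3, random_dna(100)), paste0("r", 1:3))
  expect_error(discover_motifs(regions), "min_sequences")
  shorties <- setNames(replicate(8, random_dna(20)), paste0("r", 1:8))
  expect_error(discover_motifs(shorties), "min_sequences")
})

test_that("discovery is deterministic and masks previous sites", {
  fx <- implant_fixture(seed = 72)
  cfg <- discovery_config(n_motifs = 2)
  res1 <- discover_motifs(fx$regions, cfg)
  res2 <- discover_motifs(fx$regions, cfg)
  expect_identical(res1, res2)
  if (length(res1) >= 2 && res1[[2]]$passed_threshold) {
    s1 <- res1[[1]]$sites[res1[[1]]$sites$passing, ]
    s2 <- res1[[2]]$sites[res1[[2]]$sites$passing, ]
    for (i in seq_len(nrow(s2))) {
      j <- match(s2$region_id[i], s1$region_id)
      if (is.na(j)) next
      # intervals [offset, offset + W) must not overlap
      expect_true(s2$offset[i] + res1[[2]]$width <= s1$offset[j] ||
                  s1$offset[j] + res1[[1]]$width <= s2$offset[i])
    }
  }
})

test_that("implant recovery rises with implant information content", {
  levels <- c(0.5, 0.8, 1.1, 1.4)
  cfg <- discovery_config(W_max = 50, n_motifs = 1)
  rate <- numeric(length(levels))
  for (li in seq_along(levels)) {
    rec <- 0; tot <- 0
    for (rep in 1:6) {
      fx <- implant_fixture(seed = 7000 + 100 * li + rep,
                            implant_ic = levels[li])
      res <- tryCatch(discover_motifs(fx$regions, cfg),
                      error = function(e) list())
      hit <- character()
      for (m in res) if (m$passed_threshold)
        hit <- union(hit, m$sites$region_id[m$sites$passing])
      rec <- rec + length(intersect(hit, fx$truth$region))
      tot <- tot + nrow(fx$truth)
    }
    rate[li] <- rec / tot
  }
  expect_gte(cor(levels, rate, method = "spearman"), 0.9)
  expect_gte(rate[4], 0.9)
})
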