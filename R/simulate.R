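#' Specification for a synthetic genome
#'
#' Defines the simulated study conditions: a small viral-genome-sized
#' replicon with random ORFs, same-strand operons, and a regulatory
#' motif implanted upstream of designated ADG genes. The implant always
#' embeds a strong promoter core -- a purine-rich BRE (G at -6, A at -3)
#' directly 5' of a TTTAWATA-compatible TATA-box -- inside informative
#' flanks whose sharpness is tuned so the whole implant averages
#' `implant_ic` bits/column.
#'
#' @param seed integer; the same spec always yields the same genome.
#' @param n_genes number of CDS features.
#' @param topology `"linear"` or `"circular"`.
#' @param gc genomic GC content in (0, 1).
#' @param operon_fraction probability a gene extends the previous
#'   transcription unit.
#' @param n_adg number of implanted ADG genes.
#' @param implant_ic target mean information content (bits/column).
#' @param implant_width implant width (nt).
#' @param adg_positions placement of ADG units: `"uniform"`,
#'   `"termini_biased"` (rudivirus-like), `"one_end"`
#'   (lipothrixvirus-like).
#' @param L_up upstream window length the implant must fit into.
#' @param gene_len_range ORF length bounds (nt, multiple-of-3 enforced).
#' @param shared_adg_orfs optional character vector of ORF sequences
#'   (multiples of 3 nt) used verbatim for the ADG genes, recycled in
#'   order. Supplying the same vector to several specs makes the ADG
#'   proteins homologous across simulated genomes, emulating a shared
#'   anti-defense family.
#' @export
sim_spec <- function(seed, n_genes = 40L, topology = "linear", gc = 0.5,
                     operon_fraction = 0.3, n_adg = 8L, implant_ic = 1.0,
                     implant_width = 40L, adg_positions = "uniform",
                     L_up = 100L, gene_len_range = c(300L, 900L),
                     shared_adg_orfs = NULL) {
  stopifnot(n_adg <= n_genes, gc > 0, gc < 1,
            adg_positions %in% c("uniform", "termini_biased", "one_end"),
            implant_width >= 27, implant_width <= L_up - 20)
  if (!is.null(shared_adg_orfs))
    stopifnot(all(nchar(shared_adg_orfs) %% 3 == 0))
  structure(as.list(environment()), class = "sim_spec")
}

sim_background_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Column IC (bits) of a 1-dominant-base column at probability p
col_ic <- function(p) {
  q <- (1 - p) / 3
  2 + p * log2(p) + ifelse(q > 0, 3 * q * log2(q), 0)
}

# Implant PWM: 6-nt BRE + 8-nt TATA core at probability 0.95, flanks
# sharpened so the average column IC hits the target.
make_implant_pwm <- function(spec) {
  W <- spec$implant_width
  n_flank2 <- W - 13L - 14L
  bre <- c("G", sample(c("A", "G"), 1), sample(c("A", "G"), 1), "A",
           sample(c("A", "G"), 1), sample(c("A", "G"), 1))
  tata <- c("T", "T", "T", "A", sample(c("A", "T"), 1), "A", "T", "A")
  flank1 <- sample(DNA_BASES, 13L, replace = TRUE)
  flank2 <- sample(DNA_BASES, n_flank2, replace = TRUE)
  consensus <- c(flank1, bre, tata, flank2)
  core <- seq(14L, 27L)  # BRE+TATA columns
  ic_core <- col_ic(0.95)
  target_flank <- (W * spec$implant_ic - length(core) * ic_core) /
    (W - length(core))
  target_flank <- min(max(target_flank, 0.05), 1.95)
  p_flank <- uniroot(function(p) col_ic(p) - target_flank,
                     c(0.2500001, 0.999999), tol = 1e-12)$root
  probs <- matrix(NA_real_, W, 4, dimnames = list(NULL, DNA_BASES))
  for (k in seq_len(W)) {
    p <- if (k %in% core) 0.95 else p_flank
    probs[k, ] <- (1 - p) / 3
    probs[k, consensus[k]] <- p
  }
  structure(list(motif_id = "implant", width = W, counts = probs,
                 probs = probs,
                 background = c(A = .25, C = .25, G = .25, T = .25),
                 pseudocount = 0, n_sites = 0,
                 source_site_ids = character(),
                 consensus = pwm_consensus(probs)), class = "PWM")
}

sample_site <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(k)
    sample(DNA_BASES, 1, prob = pwm$probs[k, ]), character(1)),
    collapse = "")
}

random_orf <- function(len_nt, bg) {
  n_codons <- len_nt %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (i in 2:(n_codons - 1L)) {
    repeat {
      cd <- paste(sample(DNA_BASES, 3, replace = TRUE, prob = bg),
                  collapse = "")
      if (!(cd %in% stops)) break
    }
    codons[i] <- cd
  }
  codons[n_codons] <- sample(stops, 1)
  paste(codons, collapse = "")
}

str_assign <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

#' Simulate a ground-truth-labeled genome
#'
#' Builds an i.i.d. background genome at the requested GC, lays out
#' ORFs in transcription units (every unit is preceded by at least
#' `L_up + 20` nt of intergenic sequence so promoter windows are clean),
#' picks `n_adg` unit-lead genes and implants one sampled motif site in
#' each of their upstream windows, ending 5-15 nt before the window end
#' so the TATA-to-start-codon gap always exceeds the TSS-proximity
#' rule.
#'
#' @param spec a [sim_spec()].
#' @return list: `genome` (a [Genome] with translations), `truth`
#'   (per-gene data.frame with `is_adg`, implant window offset and
#'   site), `implant_pwm`, `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  bg <- sim_background_probs(spec$gc)
  pwm <- make_implant_pwm(spec)

  n <- spec$n_genes
  lens <- 3L * (sample(spec$gene_len_range[1]:spec$gene_len_range[2],
                       n, replace = TRUE) %/% 3L)
  new_unit <- c(TRUE, runif(n - 1) > spec$operon_fraction)
  unit_id <- cumsum(new_unit)
  strand <- character(n)
  for (i in seq_len(n))
    strand[i] <- if (new_unit[i]) sample(c("+", "-"), 1)
                 else strand[i - 1L]

  # choose ADG genes among unit leads (5'-most gene of each unit);
  # positional bias uses the unit's rank along the replicon
  leads <- vapply(split(seq_len(n), unit_id), function(idx)
    if (strand[idx[1]] == "-") idx[length(idx)] else idx[1], integer(1))
  if (length(leads) < spec$n_adg)
    stop("infeasible: fewer transcription units than requested ADGs")
  relpos <- seq_along(leads) / length(leads)
  w <- switch(spec$adg_positions,
              uniform = rep(1, length(leads)),
              termini_biased = exp(-6 * pmin(relpos, 1 - relpos)),
              one_end = exp(-6 * relpos))
  adg_idx <- sort(sample(leads, spec$n_adg, prob = w))
  shared <- spec$shared_adg_orfs
  if (!is.null(shared))
    lens[adg_idx] <- nchar(rep_len(shared, spec$n_adg))

  starts <- ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    gap <- if (new_unit[i]) spec$L_up + sample(20:80, 1)
           else sample(3:25, 1)
    starts[i] <- pos + gap + 1L
    ends[i] <- starts[i] + lens[i] - 1L
    pos <- ends[i]
  }
  glen <- pos + spec$L_up + sample(20:80, 1)

  seq <- paste(sample(DNA_BASES, glen, replace = TRUE, prob = bg),
               collapse = "")
  proteins <- character(n)
  for (i in seq_len(n)) {
    orf <- if (!is.null(shared) && i %in% adg_idx)
      rep_len(shared, spec$n_adg)[match(i, adg_idx)]
    else random_orf(lens[i], bg)
    proteins[i] <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(orf))))
    placed <- if (strand[i] == "+") orf else revcomp(orf)
    seq <- str_assign(seq, starts[i], placed)
  }

  truth <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), is_adg = FALSE,
    implant_offset = NA_integer_, implant_site = NA_character_,
    stringsAsFactors = FALSE)
  for (i in adg_idx) {
    site <- sample_site(pwm)
    g <- sample(5:15, 1)  # implant end .. start codon distance
    if (strand[i] == "+") {
      at <- starts[i] - g - pwm$width
      seq <- str_assign(seq, at, site)
    } else {
      at <- ends[i] + g + 1L
      seq <- str_assign(seq, at, revcomp(site))
    }
    truth$is_adg[i] <- TRUE
    truth$implant_offset[i] <- spec$L_up - g - pwm$width + 1L
    truth$implant_site[i] <- site
  }

  genes <- data.frame(
    gene_id = truth$gene_id, start = starts, end = ends, strand = strand,
    product = "hypothetical protein", protein = proteins,
    stringsAsFactors = FALSE)
  genome <- Genome(sprintf("SIMV%05d", spec$seed), seq, genes,
                   topology = spec$topology, source_format = "synthetic")
  list(genome = genome, truth = truth, implant_pwm = pwm, spec = spec)
}

#' Simulate protein families by ancestor mutation
#'
#' Each family descends from one random ancestor; members substitute
#' every site independently with probability `divergence` (to a uniform
#' different residue).
#'
#' @param seed RNG seed.
#' @param n_families number of families.
#' @param sizes member counts (recycled to `n_families`).
#' @param divergence per-site substitution probability in `[0, 1)`.
#' @param len_range ancestor length bounds (aa).
#' @return list: `proteins` (named character vector), `truth`
#'   (data.frame member -> family).
#' @export
simulate_protein_families <- function(seed, n_families = 2L,
                                      sizes = 5L, divergence = 0.3,
                                      len_range = c(80L, 200L)) {
  stopifnot(divergence >= 0, divergence < 1)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sizes <- rep_len(sizes, n_families)
  prots <- character(0)
  truth <- list()
  for (f in seq_len(n_families)) {
    len <- sample(len_range[1]:len_range[2], 1)
    anc <- sample(aa, len, replace = TRUE)
    for (m in seq_len(sizes[f])) {
      mem <- anc
      mut <- runif(len) < divergence
      if (any(mut))
        mem[mut] <- vapply(anc[mut], function(x)
          sample(setdiff(aa, x), 1), character(1))
      nm <- sprintf("fam%02d_m%02d", f, m)
      prots[nm] <- paste(mem, collapse = "")
      truth[[length(truth) + 1]] <- data.frame(member = nm,
                                               family = f)
    }
  }
  list(proteins = prots, truth = do.call(rbind, truth))
}

#' Write a simulated genome as on-disk fixtures
#'
#' GenBank, GFF3 + FASTA and the ground-truth TSV.
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if missing).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$genome$id
  write_genbank(sim$genome, file.path(dir, paste0(id, ".gbk")))
  write_gff3_fasta(sim$genome, file.path(dir, paste0(id, ".gff3")),
                   file.path(dir, paste0(id, ".fna")))
  write.table(sim$truth, file.path(dir, paste0(id, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
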