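# Constructed fixtures for caller-level tests.

# A bare genome whose sequence content is irrelevant (coordinates and
# strands drive the logic under test).
make_test_genome <- function(genes, len = NULL, topology = "linear",
                             id = "TESTV1") {
  if (is.null(len)) len <- max(genes$end, genes$start) + 200L
  set.seed(424242)
  Genome(id, random_dna(len), genes, topology = topology)
}

# Evenly spaced plus-strand genes, far enough apart to all be "single".
spaced_genes <- function(n, gene_len = 300L, gap = 200L, strand = "+") {
  starts <- (0:(n - 1)) * (gene_len + gap) + gap + 1L
  data.frame(gene_id = sprintf("g%02d", 1:n), start = starts,
             end = starts + gene_len - 1L,
             strand = rep_len(strand, n),
             product = "hypothetical protein",
             stringsAsFactors = FALSE)
}

# A strong-promoter site: BRE (GAGAGA) + TATA (TTTAAATA) at a fixed
# offset, padded to `width`.
strong_site <- function(width = 30L, lead = 3L) {
  core <- paste0("GAGAGA", "TTTAAATA")
  pad_n <- width - lead - nchar(core)
  paste0(strrep("C", lead), core, strrep("G", pad_n))
}

# Minimal motif-result object as produced by discover_motifs().
make_motif_fixture <- function(gene_ids, motif_id = "motif_1",
                               strong = TRUE, width = 30L) {
  site <- if (strong) strong_site(width) else strrep("C", width)
  sites <- data.frame(
    region_id = gene_ids, offset = 1L, score = 50, score_loo = 48,
    p_value = 1e-12, site = site, passing = TRUE,
    stringsAsFactors = FALSE)
  pwm <- structure(list(motif_id = motif_id, width = width,
                        consensus = site), class = "PWM")
  list(pwm = pwm, width = width, sites = sites, zoops_lambda = 0.3,
       log_likelihood = 0, passed_threshold = TRUE)
}

# Hit rows shaped like scan_regions() output.
make_hits <- function(gene_ids, motif_id = "motif_1", site = NULL,
                      offset = 40L, p = 1e-12, n_pos = 1000L,
                      region_length = 100L, genome_id = "TESTV1") {
  if (is.null(site)) site <- strong_site()
  data.frame(
    genome_id = genome_id, gene_id = gene_ids, motif_id = motif_id,
    offset = offset, score = 50, p_value = p, e_value = p * n_pos,
    site = site, region_length = region_length,
    n_positions_scanned = n_pos, passed = TRUE,
    stringsAsFactors = FALSE)
}
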