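minimal_gbk <- function(seq, cds_lines, circular = FALSE) {
  f <- tempfile(fileext = ".gbk")
  top <- if (circular) "circular" else "linear"
  lines <- c(
    sprintf("LOCUS       TESTACC          %d bp    DNA     %s   UNA",
            nchar(seq), top),
    "FEATURES             Location/Qualifiers",
    cds_lines, "ORIGIN")
  for (p in seq(1, nchar(seq), by = 60))
    lines <- c(lines, sprintf("%9d %s", p,
                              tolower(substr(seq, p, p + 59))))
  writeLines(c(lines, "//"), f)
  f
}

test_that("GenBank CDS locations parse with strand and qualifiers", {
  set.seed(1)
  seq <- random_dna(500)
  f <- minimal_gbk(seq, c(
    "     CDS             101..220",
    '                     /locus_tag="gene1"',
    '                     /product="anti-CRISPR protein"',
    "     CDS             complement(300..420)",
    '                     /locus_tag="gene2"'))
  g <- read_genome(f, format = "genbank")
  expect_equal(g$id, "TESTACC")
  expect_equal(g$topology, "linear")
  expect_equal(g$genes$start, c(101L, 300L))
  expect_equal(g$genes$end, c(220L, 420L))
  expect_equal(g$genes$strand, c("+", "-"))
  expect_equal(g$genes$product[1], "anti-CRISPR protein")
  expect_equal(nchar(g$genes$gene_id), c(5L, 5L))
  expect_equal(gene_sequence(g, "gene1"), substr(seq, 101, 220))
  expect_equal(gene_sequence(g, "gene2"),
               rc_oracle(substr(seq, 300, 420)))
})

test_that("GenBank parse errors name the offending content", {
  f <- tempfile()
  writeLines(c("LOCUS       X 10 bp DNA linear",
               "FEATURES             Location/Qualifiers",
               "     CDS             banana..7",
               "ORIGIN", "        1 acgtacgtac", "//"), f)
  expect_error(read_genome(f, format = "genbank"), "banana")
  f2 <- minimal_gbk(strrep("ACGT", 10), character())
  expect_error(read_genome(f2, format = "genbank"), "no CDS")
})

test_that("origin-spanning CDS on circular genomes wrap correctly", {
  set.seed(2)
  seq <- random_dna(2050)
  f <- minimal_gbk(seq, c(
    "     CDS             join(2001..2050,1..40)",
    '                     /locus_tag="wrap1"'), circular = TRUE)
  g <- read_genome(f, format = "genbank")
  expect_equal(g$topology, "circular")
  expect_equal(g$genes$start, 2001L)
  expect_equal(g$genes$end, 40L)
  # manual string concatenation oracle
  expect_equal(gene_sequence(g, "wrap1"),
               paste0(substr(seq, 2001, 2050), substr(seq, 1, 40)))
  # survives a GenBank round trip
  f2 <- tempfile(fileext = ".gbk")
  write_genbank(g, f2)
  g2 <- read_genome(f2, format = "genbank")
  expect_equal(g2$genes[, c("start", "end", "strand")],
               g$genes[, c("start", "end", "strand")])
  expect_equal(g2$sequence, g$sequence)
})

test_that("GenBank -> GFF3+FASTA -> internal round trip is lossless", {
  sim <- simulate_genome(sim_spec(seed = 11, n_genes = 12, n_adg = 3))
  g <- sim$genome
  gbk <- tempfile(fileext = ".gbk")
  write_genbank(g, gbk)
  g_gbk <- read_genome(gbk, format = "genbank")
  gff <- tempfile(fileext = ".gff3"); fna <- tempfile(fileext = ".fna")
  write_gff3_fasta(g_gbk, gff, fna)
  g_gff <- read_genome(gff, format = "gff3", fasta = fna)
  for (col in c("gene_id", "start", "end", "strand"))
    expect_equal(g_gff$genes[[col]], g$genes[[col]])
  expect_equal(g_gff$sequence, g$sequence)
  expect_equal(g_gbk$genes$protein, g$genes$protein)
})

test_that("upstream extraction is strand-aware and truncates at ends", {
  set.seed(3)
  seq <- random_dna(3000)
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    start = c(1001L, 1L, 2500L), end = c(1600L, 90L, 2800L),
    strand = c("+", "+", "-"))
  g <- Genome("T", seq, genes)
  up <- extract_upstream(g, "gA", 100L)
  expect_equal(up$sequence, substr(seq, 901, 1000))
  expect_false(up$truncated)
  expect_equal(c(up$win_start, up$win_end), c(901L, 1000L))

  # gene starting at position 1: nothing upstream
  up0 <- extract_upstream(g, "gB", 100L)
  expect_equal(up0$length, 0L)
  expect_true(up0$truncated)

  # minus-strand gene: window 3' of the end, reverse-complemented
  upm <- extract_upstream(g, "gC", 100L)
  expect_equal(upm$sequence, rc_oracle(substr(seq, 2801, 2900)))

  expect_error(extract_upstream(g, "nope", 100L), "not found")
})

test_that("circular upstream windows match the doubled-sequence oracle", {
  set.seed(4)
  seq <- random_dna(2050)
  genes <- data.frame(gene_id = c("gM", "gP"),
                      start = c(1500L, 30L), end = c(2000L, 500L),
                      strand = c("-", "+"))
  g <- Genome("C", seq, genes, topology = "circular")
  doubled <- paste0(seq, seq)
  upm <- extract_upstream(g, "gM", 100L)
  expect_equal(upm$sequence, rc_oracle(substr(doubled, 2001, 2100)))
  expect_false(upm$truncated)
  # plus-strand window wrapping the origin leftwards
  upp <- extract_upstream(g, "gP", 100L)
  expect_equal(upp$sequence, substr(doubled, 2050 + 30 - 100, 2050 + 29))
})

test_that("re-embedding upstream windows reproduces the genome substring", {
  sim <- simulate_genome(sim_spec(seed = 12, n_genes = 15, n_adg = 3))
  g <- classify_loci(sim$genome)
  regs <- upstream_regions(g, L_up = 80L)
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    if (r$length == 0) next
    emb <- substr(g$sequence, r$win_start, r$win_end)
    if (r$strand == "-") emb <- rc_oracle(emb)
    expect_equal(r$sequence, emb)
  }
})

test_that("locus classification follows the strand-aware gap rule", {
  seq_len_tot <- 5000L
  mk <- function(starts, ends, strands) {
    Genome("L", strrep("A", seq_len_tot),
           data.frame(gene_id = sprintf("g%d", seq_along(starts)),
                      start = starts, end = ends, strand = strands))
  }
  # single-gene genome
  g1 <- classify_loci(mk(100L, 400L, "+"))
  expect_equal(g1$genes$locus_class, "single")

  # two plus-strand genes, 10-nt gap, max_gap 30
  g2 <- classify_loci(mk(c(100L, 511L), c(500L, 900L), c("+", "+")),
                      max_gap = 30L)
  expect_equal(g2$genes$locus_class, c("operon_lead", "operon_internal"))

  # convergent pair never forms an operon
  g3 <- classify_loci(mk(c(100L, 511L), c(500L, 900L), c("+", "-")),
                      max_gap = 30L)
  expect_equal(g3$genes$locus_class, c("single", "single"))

  # minus-strand operon: the 5'-most (rightmost) gene leads
  g4 <- classify_loci(mk(c(100L, 511L), c(500L, 900L), c("-", "-")),
                      max_gap = 30L)
  expect_equal(g4$genes$locus_class, c("operon_internal", "operon_lead"))

  # gap above threshold splits the operon
  g5 <- classify_loci(mk(c(100L, 601L), c(500L, 900L), c("+", "+")),
                      max_gap = 30L)
  expect_equal(g5$genes$locus_class, c("single", "single"))
})

test_that("locus classification is idempotent and leaves nothing unset", {
  sim <- simulate_genome(sim_spec(seed = 13, n_genes = 30, n_adg = 5,
                                  operon_fraction = 0.5))
  g1 <- classify_loci(sim$genome)
  expect_true(all(g1$genes$locus_class %in%
                    c("single", "operon_lead", "operon_internal")))
  g2 <- classify_loci(g1)
  expect_identical(g1$genes, g2$genes)
  # every operon_internal follows a same-strand gene
  idx <- which(g1$genes$locus_class == "operon_internal")
  for (i in idx) expect_gt(i, 1)
})

test_that("upstream FASTA and BED writers emit the documented shapes", {
  sim <- simulate_genome(sim_spec(seed = 14, n_genes = 10, n_adg = 2))
  g <- classify_loci(sim$genome)
  regs <- upstream_regions(g, L_up = 100L)
  fa <- tempfile(fileext = ".fa")
  write_upstream_fasta(regs, g$id, fa, L_up = 100L)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_true(all(grepl(sprintf("^%s\\|g[0-9]+\\|upstream100$", g$id),
                        names(seqs))))
  bed <- tempfile(fileext = ".bed")
  write_upstream_bed(regs, g, bed)
  tab <- read.table(bed, sep = "\t")
  expect_equal(ncol(tab), 6)
  expect_true(all(tab$V3 > tab$V2))
  expect_true(all(tab$V6 %in% c("+", "-")))
})
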