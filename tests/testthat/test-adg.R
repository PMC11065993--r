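test_that("dual criteria drive ADG status and the audit reasons", {
  genome <- make_test_genome(spaced_genes(6))
  cfg <- pipeline_config(min_shared = 3)

  strong <- make_motif_fixture(c("g01", "g02", "g03"), "motif_1",
                               strong = TRUE)
  weak <- make_motif_fixture(c("g04", "g05"), "motif_2", strong = FALSE)
  hits <- rbind(make_hits(c("g01", "g02", "g03"), "motif_1"),
                make_hits("g04", "motif_2"))
  calls <- call_adgs(genome, list(strong, weak), hits, cfg)

  expect_equal(calls$status[calls$gene_id %in% c("g01", "g02", "g03")],
               rep("adg", 3))
  # passing hit on a motif without a strong promoter core
  expect_equal(calls$status[calls$gene_id == "g04"], "low_probability")
  expect_equal(calls$reasons[calls$gene_id == "g04"],
               "no_strong_promoter")
  # no hit at all
  expect_equal(calls$status[calls$gene_id == "g06"], "negative")
  # statuses partition the genes
  expect_true(all(calls$status %in%
                    c("adg", "low_probability", "negative")))
  # every ADG call carries both a passing hit and a strong promoter
  adg <- calls[calls$status == "adg", ]
  expect_true(all(!is.na(adg$e_value)))
  expect_true(all(adg$promoter_strong))
  # deterministic rerun
  expect_identical(calls, call_adgs(genome, list(strong, weak), hits, cfg))
})

test_that("a motif shared by too few genes is demoted, not called", {
  genome <- make_test_genome(spaced_genes(4))
  strong <- make_motif_fixture(c("g01", "g02"), "motif_1", strong = TRUE)
  hits <- make_hits(c("g01", "g02"), "motif_1")
  calls <- call_adgs(genome, list(strong), hits,
                     pipeline_config(min_shared = 3))
  expect_equal(calls$status[calls$gene_id %in% c("g01", "g02")],
               rep("low_probability", 2))
  expect_equal(calls$reasons[calls$gene_id == "g01"], "motif_not_shared")
  # with min_shared = 2 the same evidence yields ADGs
  calls2 <- call_adgs(genome, list(strong), hits,
                      pipeline_config(min_shared = 2))
  expect_equal(calls2$status[calls2$gene_id %in% c("g01", "g02")],
               rep("adg", 2))
})

test_that("TSS proximity and core-protein keywords demote candidates", {
  genes <- spaced_genes(4)
  genes$product[2] <- "major capsid protein"
  genome <- make_test_genome(genes)
  cfg <- pipeline_config(min_shared = 3)
  strong <- make_motif_fixture(c("g01", "g02", "g03", "g04"), "motif_1",
                               strong = TRUE)
  # g04's TATA box ends 4 nt before the start codon: the transcription
  # start would sit inside the ORF. Site layout: TATA at site offset 9
  # (CCT + GAGAGA + TTTAAATA...), so with region length 100 and width
  # 30 an offset of 74 leaves 100 - (74 + 9 + 6) = 11 nt; offset 81
  # leaves 4 nt.
  hits <- rbind(make_hits(c("g01", "g02", "g03"), "motif_1", offset = 40L),
                make_hits("g04", "motif_1", offset = 81L))
  calls <- call_adgs(genome, list(strong), hits, cfg)
  expect_equal(calls$status[calls$gene_id == "g04"], "low_probability")
  expect_equal(calls$reasons[calls$gene_id == "g04"], "tss_too_close")
  expect_equal(calls$status[calls$gene_id == "g02"], "low_probability")
  expect_equal(calls$reasons[calls$gene_id == "g02"], "core_protein")
  expect_equal(calls$status[calls$gene_id == "g01"], "adg")
  # 11 nt of TATA-to-start gap is acceptable
  hits_ok <- rbind(make_hits(c("g01", "g03", "g04"), "motif_1",
                             offset = 40L),
                   make_hits("g04b", "motif_1", offset = 74L))
  hits_ok$gene_id[4] <- "g04"
  hits_ok <- hits_ok[-3, ]
  calls_ok <- call_adgs(genome, list(strong), hits_ok, cfg)
  expect_equal(calls_ok$status[calls_ok$gene_id == "g04"], "adg")
})

test_that("operon-internal genes behind an ADG lead join the audit list", {
  # g1 (+) leads g2 (+, 10-nt gap); g3 is a distant single gene
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    start = c(201L, 511L, 1500L), end = c(500L, 800L, 1800L),
    strand = "+", product = "hypothetical protein")
  genome <- make_test_genome(genes)
  cfg <- pipeline_config(min_shared = 2)
  strong <- make_motif_fixture(c("g1", "g3"), "motif_1", strong = TRUE)
  hits <- make_hits(c("g1", "g3"), "motif_1")
  calls <- call_adgs(genome, list(strong), hits, cfg)
  expect_equal(calls$status[calls$gene_id == "g1"], "adg")
  expect_equal(calls$status[calls$gene_id == "g2"], "low_probability")
  expect_equal(calls$reasons[calls$gene_id == "g2"],
               "downstream_in_operon")
  expect_equal(calls$status[calls$gene_id == "g3"], "adg")
})

# Build a genome holding one plus-strand ORF with a controlled codon
# layout: filler codons contain no start/stop, with an optional
# in-frame ATG at codon index `atg_codon` (1-based; codon 1 is the
# annotated start).
orf_genome <- function(n_codons, atg_codon = NULL) {
  codons <- rep("CCA", n_codons - 1L)
  if (!is.null(atg_codon)) codons[atg_codon - 1L] <- "ATG"
  cds <- paste0("ATG", paste(codons[-length(codons)], collapse = ""),
                "TAA")
  stopifnot(nchar(cds) == 3 * n_codons)
  seq <- paste0(strrep("G", 150), cds, strrep("G", 50))
  Genome("RE1", seq, data.frame(gene_id = "orf1", start = 151L,
                                end = 150L + nchar(cds), strand = "+"))
}

test_that("start re-annotation finds the first in-frame start past the promoter", {
  # 84-codon CDS (83 aa product) with the promoter buried in its 5'
  # end and an in-frame ATG 84 nt downstream -> 55-aa product
  g <- orf_genome(84L, atg_codon = 29L)
  re <- reannotate_start(g, "orf1", promoter_end_cds = 30L)
  expect_equal(re$offset_nt, 84L)
  expect_equal(re$new_protein_length, 55L)
  expect_equal(re$new_start, 151L + 84L)

  # promoter entirely upstream of the annotated start: no change
  expect_null(reannotate_start(g, "orf1", promoter_end_cds = 0L))

  # no in-frame alternative start in the first half of the ORF
  g2 <- orf_genome(84L)
  expect_null(reannotate_start(g2, "orf1", promoter_end_cds = 30L))

  # an in-frame start beyond the halfway point is rejected
  g3 <- orf_genome(84L, atg_codon = 60L)
  expect_null(reannotate_start(g3, "orf1", promoter_end_cds = 30L))
})

test_that("re-annotation respects strand orientation", {
  # same CDS on the minus strand
  n_codons <- 60L
  codons <- rep("CCA", n_codons - 1L)
  codons[14L] <- "ATG"
  cds <- paste0("ATG", paste(codons[-length(codons)], collapse = ""),
                "TAA")
  seq <- paste0(strrep("G", 100), rc_oracle(cds), strrep("G", 100))
  g <- Genome("RE2", seq,
              data.frame(gene_id = "orf1", start = 101L,
                         end = 100L + nchar(cds), strand = "-"))
  re <- reannotate_start(g, "orf1", promoter_end_cds = 20L)
  expect_equal(re$offset_nt, 42L)
  expect_equal(re$new_start, 100L + nchar(cds) - 42L)
})
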