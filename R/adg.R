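#' Pipeline configuration
#'
#' Central home of the numeric operating points: 100-nt upstream
#' windows, motif widths 30-100, site p-value and scan e-value cutoffs
#' of 1e-8, family clustering at e 1e-3, host homolog screen at e 1e-10
#' with a 150-aa small-protein bound and a 5-gene viral-context rule.
#' The whole configuration is echoed into every report.
#'
#' @param L_up upstream window length (nt).
#' @param W_min,W_max,width_step,n_motifs,min_sequences,pseudocount,granularity
#'   motif discovery settings (see [discovery_config()]).
#' @param site_p_threshold site p-value cutoff in discovery.
#' @param e_threshold scan e-value cutoff.
#' @param min_shared minimum genes sharing a motif for ADG status.
#' @param max_mm TATA mismatch tolerance.
#' @param purine_min minimum BRE purine fraction.
#' @param max_gap operon gap threshold (nt).
#' @param min_tss_gap minimum distance (nt) between the TATA-box end and
#'   the start codon; closer promoters imply a transcription start
#'   inside the ORF.
#' @param core_keywords product keywords marking conserved viral core
#'   genes (editable).
#' @param family_evalue e-value for protein family clustering.
#' @param host_screen_evalue e-value for the viral-vs-host screen.
#' @param small_protein_max small-protein bound (aa) in the host screen.
#' @param viral_context_min_hits viral-hit genes in a host neighborhood
#'   marking an integrated virus.
#' @param max_n_frac maximum N fraction tolerated in upstream windows.
#' @export
pipeline_config <- function(L_up = 100L, W_min = 30L, W_max = 100L,
                            width_step = 10L, n_motifs = 3L,
                            min_sequences = 5L, pseudocount = 0.25,
                            granularity = 1e-3,
                            site_p_threshold = 1e-8, e_threshold = 1e-8,
                            min_shared = 3L, max_mm = 1L,
                            purine_min = 2 / 3, max_gap = 30L,
                            min_tss_gap = 10L,
                            core_keywords = c("capsid", "polymerase",
                                              "terminase", "portal",
                                              "tail", "integrase",
                                              "primase", "helicase"),
                            family_evalue = 1e-3,
                            host_screen_evalue = 1e-10,
                            small_protein_max = 150L,
                            viral_context_min_hits = 5L,
                            max_n_frac = 0.1) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("site_p_threshold", "e_threshold",
                             "family_evalue", "host_screen_evalue")],
                       function(x) x > 0, logical(1))))
  cfg
}

as_discovery_config <- function(cfg) {
  discovery_config(W_min = cfg$W_min, W_max = cfg$W_max,
                   width_step = cfg$width_step, n_motifs = cfg$n_motifs,
                   site_p_threshold = cfg$site_p_threshold,
                   min_sequences = cfg$min_sequences,
                   pseudocount = cfg$pseudocount,
                   granularity = cfg$granularity)
}

#' Call anti-defense genes in one genome
#'
#' Applies the dual criteria: a gene is a putative ADG when (1) its
#' regulatory motif carries a predicted strong promoter core and (2) the
#' motif is shared by at least `min_shared` genes of the same genome
#' (both with significance thresholds already applied in the scan).
#' Genes failing a criterion, or caught by a low-probability rule
#' ([flag_low_probability()], applied last), go to the low-probability
#' list with machine-readable reasons; everything else is negative.
#'
#' @param genome an annotated [Genome].
#' @param motifs list of motif results from [discover_motifs()].
#' @param hits combined hit table from [scan_regions()] over the same
#'   genome's upstream set (one scan per motif, rbind-ed).
#' @param config a [pipeline_config()].
#' @return data.frame: one row per gene with `status`
#'   (adg/low_probability/negative), `reasons`, motif/hit/promoter
#'   evidence columns.
#' @export
call_adgs <- function(genome, motifs, hits, config = pipeline_config()) {
  if (!nrow(genome$genes)) stop("genome has no genes")
  if (any(genome$genes$locus_class == "unset"))
    genome <- classify_loci(genome, max_gap = config$max_gap)
  if (nrow(hits) && !all(hits$gene_id %in% genome$genes$gene_id))
    stop("hits refer to genes absent from this genome")

  strong <- vapply(motifs, classify_motif, logical(1),
                   max_mm = config$max_mm, purine_min = config$purine_min)
  names(strong) <- vapply(motifs, function(m) m$pwm$motif_id, character(1))
  shared_tab <- if (nrow(hits)) table(hits$motif_id[hits$passed])
                else table(character())
  shared <- function(id) {
    v <- shared_tab[id]
    ifelse(is.na(v), 0L, as.integer(v))
  }

  g <- genome$genes
  calls <- data.frame(
    genome_id = genome$id, gene_id = g$gene_id, status = "negative",
    reasons = "", motif_id = NA_character_, offset = NA_integer_,
    score = NA_real_, p_value = NA_real_, e_value = NA_real_,
    region_length = NA_integer_,
    tata_offset = NA_integer_, tata_mismatches = NA_integer_,
    bre_purine = NA_real_, promoter_strong = NA,
    locus_class = g$locus_class, product = g$product,
    reannotated_start = NA_integer_, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(calls))) {
    gh <- hits[hits$gene_id == calls$gene_id[i] & hits$passed, ,
               drop = FALSE]
    if (!nrow(gh)) next
    gh <- gh[order(gh$e_value), , drop = FALSE]
    eligible <- strong[gh$motif_id] & shared(gh$motif_id) >= config$min_shared
    eligible[is.na(eligible)] <- FALSE
    best <- if (any(eligible)) gh[which(eligible)[1], ] else gh[1, ]
    calls$motif_id[i] <- best$motif_id
    calls$offset[i] <- best$offset
    calls$score[i] <- best$score
    calls$p_value[i] <- best$p_value
    calls$e_value[i] <- best$e_value
    calls$region_length[i] <- best$region_length
    pc <- call_promoter(best$site, config$max_mm, config$purine_min)
    if (!is.null(pc)) {
      calls$tata_offset[i] <- pc$tata_offset
      calls$tata_mismatches[i] <- pc$tata_mismatches
      calls$bre_purine[i] <- pc$bre_purine_fraction
      calls$promoter_strong[i] <- pc$is_strong
    } else {
      calls$promoter_strong[i] <- FALSE
    }
    if (!isTRUE(unname(strong[best$motif_id]))) {
      calls$status[i] <- "low_probability"
      calls$reasons[i] <- "no_strong_promoter"
    } else if (shared(best$motif_id) < config$min_shared) {
      calls$status[i] <- "low_probability"
      calls$reasons[i] <- "motif_not_shared"
    } else {
      calls$status[i] <- "adg"
    }
  }
  flag_low_probability(calls, genome, config)
}

add_reason <- function(reasons, tag) {
  ifelse(nzchar(reasons), paste(reasons, tag, sep = ","), tag)
}

#' Apply the low-probability demotion rules
#'
#' Demotes ADG candidates (and annotates others) that match the
#' enumerated audit rules: `core_protein` (product matches a conserved
#' viral core-gene keyword), `tss_too_close` (the TATA-box ends fewer
#' than `min_tss_gap` nt before the start codon, putting the likely
#' transcription start inside the ORF), and `downstream_in_operon`
#' (operon-internal genes co-transcribed behind a called ADG lead).
#'
#' @param calls data.frame from [call_adgs()].
#' @param genome the source [Genome].
#' @param config a [pipeline_config()].
#' @export
flag_low_probability <- function(calls, genome, config = pipeline_config()) {
  kw <- paste(config$core_keywords, collapse = "|")
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] != "adg") next
    prod <- calls$product[i]
    if (!is.na(prod) && nzchar(kw) &&
        grepl(kw, prod, ignore.case = TRUE)) {
      calls$status[i] <- "low_probability"
      calls$reasons[i] <- add_reason(calls$reasons[i], "core_protein")
    }
    if (!is.na(calls$tata_offset[i]) && !is.na(calls$region_length[i])) {
      tata_end <- calls$offset[i] + calls$tata_offset[i] + 6L
      gap <- calls$region_length[i] - tata_end
      if (gap < config$min_tss_gap) {
        calls$status[i] <- "low_probability"
        calls$reasons[i] <- add_reason(calls$reasons[i], "tss_too_close")
      }
    }
  }
  # operon-internal genes behind an ADG lead
  runs <- operon_runs(genome, config$max_gap, TRUE)
  adg_ids <- calls$gene_id[calls$status == "adg"]
  for (r in runs) {
    if (length(r$members) < 2) next
    if (!(r$lead %in% adg_ids)) next
    for (m in setdiff(r$members, r$lead)) {
      i <- match(m, calls$gene_id)
      if (is.na(i) || calls$status[i] == "adg") next
      calls$status[i] <- "low_probability"
      calls$reasons[i] <- add_reason(calls$reasons[i],
                                     "downstream_in_operon")
    }
  }
  calls
}

#' Re-annotate a start codon hidden under a promoter
#'
#' When the regulatory motif lies inside the annotated 5' coding region
#' of an ORF, the true translation start is downstream. Returns the
#' first in-frame ATG/GTG/TTG after the promoter core such that the
#' motif becomes fully upstream of the new start, or `NULL` when no such
#' start exists before half the ORF is consumed.
#'
#' @param genome a [Genome].
#' @param gene_id the annotated gene.
#' @param promoter_end_cds 1-based position, within the annotated coding
#'   sequence, of the last base of the promoter/motif occurrence.
#' @param config a [pipeline_config()].
#' @return list with `new_start` (genomic coordinate of the re-annotated
#'   start on the coding strand), `offset_nt` (downstream shift) and
#'   `new_protein_length` (aa), or `NULL`.
#' @export
reannotate_start <- function(genome, gene_id, promoter_end_cds,
                             config = pipeline_config()) {
  if (promoter_end_cds < 1) return(NULL)  # promoter entirely upstream
  g <- gene_row(genome, gene_id)
  cds <- gene_sequence(genome, gene_id)
  orf_len <- nchar(cds)
  max_shift <- floor(orf_len / 2)
  starts <- c("ATG", "GTG", "TTG")
  for (k in 2:(orf_len %/% 3)) {
    d <- 3L * (k - 1L)
    if (d > max_shift) break
    if (d + 1L <= promoter_end_cds) next  # motif not yet fully upstream
    codon <- substr(cds, d + 1L, d + 3L)
    if (codon %in% starts) {
      new_start <- if (g$strand == "+") g$start + d else g$end - d
      if (genome$topology == "circular")
        new_start <- norm_pos(new_start, nchar(genome$sequence))
      return(list(new_start = as.integer(new_start), offset_nt = d,
                  new_protein_length = (orf_len - d) %/% 3L - 1L))
    }
  }
  NULL
}

#' Write ADG calls as TSV
#' @param calls data.frame from [call_adgs()].
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called ADG features as GFF3
#' @param calls data.frame from [call_adgs()].
#' @param genome the source [Genome].
#' @param path output file.
#' @export
write_adg_gff3 <- function(calls, genome, path) {
  adg <- calls[calls$status == "adg", , drop = FALSE]
  g <- genome$genes[match(adg$gene_id, genome$genes$gene_id), , drop = FALSE]
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(adg))) {
    lines <- c(lines, paste(
      genome$id, "adgscan", "CDS", g$start[i], g$end[i], ".",
      g$strand[i], "0",
      sprintf("ID=%s;adg_status=adg;motif=%s;e_value=%g",
              adg$gene_id[i], adg$motif_id[i], adg$e_value[i]),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
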