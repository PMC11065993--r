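#' Scan upstream regions with a PWM
#'
#' One best-scoring hit per region (ties broken toward the smallest
#' offset), consistent with the one-promoter-per-gene model. Each hit
#' carries its exact score p-value and a Bonferroni e-value over all
#' positions actually scanned in this call; `passed` applies the
#' e-value threshold.
#'
#' @param pwm a `PWM`.
#' @param regions named character vector or region data.frame.
#' @param e_threshold scan e-value cutoff (the study's operating point
#'   is 1e-8).
#' @param genome_id recorded on the hits.
#' @param dist optional precomputed [score_distribution()].
#' @param granularity lattice bin width when `dist` is computed here.
#' @return data.frame of hits: `genome_id`, `gene_id`, `motif_id`,
#'   `offset` (1-based within the region), `score`, `p_value`,
#'   `e_value`, `passed`, `n_positions_scanned`, `site`.
#' @export
scan_regions <- function(pwm, regions, e_threshold = 1e-8,
                         genome_id = NA_character_, dist = NULL,
                         granularity = 1e-3) {
  seqs <- as_region_seqs(regions)
  if (length(seqs) == 0) stop("no regions to scan")
  W <- pwm$width
  if (max(nchar(seqs)) < W)
    stop("PWM width ", W, " exceeds every region length")
  enc <- lapply(seqs, encode_dna)
  scores <- cpp_window_scores(enc, pwm_logodds(pwm))
  n_pos <- sum(vapply(scores, function(s) sum(is.finite(s)), numeric(1)))
  if (is.null(dist))
    dist <- score_distribution(pwm, granularity = granularity)
  rows <- list()
  for (i in seq_along(enc)) {
    sc <- scores[[i]]
    if (length(sc) == 0 || !any(is.finite(sc))) next
    j <- which.max(sc)   # which.max returns the first (smallest offset) tie
    p <- pvalue_from_dist(dist, sc[j])
    rows[[length(rows) + 1]] <- data.frame(
      genome_id = genome_id, gene_id = names(enc)[i],
      motif_id = pwm$motif_id, offset = j, score = sc[j], p_value = p,
      e_value = p * n_pos, site = substr(seqs[[i]], j, j + W - 1L),
      region_length = nchar(seqs[[i]]), stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(genome_id = character(), gene_id = character(),
                       motif_id = character(), offset = integer(),
                       score = numeric(), p_value = numeric(),
                       e_value = numeric(), site = character(),
                       region_length = integer())
  hits$n_positions_scanned <- n_pos
  hits$passed <- hits$e_value < e_threshold
  rownames(hits) <- NULL
  hits
}

#' Scan a whole annotated genome's promoter-owning genes
#'
#' Applies [scan_regions()] to the upstream windows of every single and
#' operon-lead gene of `genome` -- the host-regulon use case (finding
#' the viral early motif in front of host genes).
#'
#' @param pwm a `PWM`.
#' @param genome an annotated [Genome].
#' @param L_up upstream window length (nt).
#' @param e_threshold scan e-value cutoff.
#' @param ... passed to [scan_regions()].
#' @export
scan_host_geneset <- function(pwm, genome, L_up = 100L, e_threshold = 1e-8,
                              ...) {
  regions <- upstream_regions(genome, L_up = L_up)
  regions <- regions[regions$usable, , drop = FALSE]
  scan_regions(pwm, regions, e_threshold = e_threshold,
               genome_id = genome$id, ...)
}

#' Write motif hits as TSV
#' @param hits data.frame from [scan_regions()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6 in genome coordinates
#'
#' Recovers genome coordinates through the upstream-window table.
#' @param hits data.frame from [scan_regions()].
#' @param regions region data.frame (with window coordinates) the scan
#'   used.
#' @param genome the source [Genome].
#' @param width motif width.
#' @param path output file.
#' @export
write_hits_bed <- function(hits, regions, genome, width, path) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    r <- regions[match(h$gene_id, regions$gene_id), ]
    if (is.na(r$win_start)) next
    if (r$strand == "+") {
      gs <- r$win_start + h$offset - 1L
      ge <- gs + width - 1L
    } else {
      ge <- r$win_end - h$offset + 1L
      gs <- ge - width + 1L
    }
    rows[[length(rows) + 1]] <- data.frame(
      chrom = genome$id, start = gs - 1L, end = ge,
      name = paste0(h$gene_id, "|", h$motif_id),
      score = round(h$score, 3), strand = r$strand)
  }
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
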