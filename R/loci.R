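#' Classify genes as single, operon-lead or operon-internal
#'
#' Only single genes and the 5'-most gene of an operon own a promoter, so
#' only their upstream regions enter motif discovery. Two consecutive
#' genes are placed in the same operon when they lie on the same strand
#' and the intergenic gap does not exceed `max_gap`; on circular genomes
#' the last/first gene pair is also considered. Within a run, the
#' 5'-most gene (leftmost on "+", rightmost on "-") is the operon lead.
#'
#' @param genome a [Genome] with genes sorted by start.
#' @param max_gap maximum intergenic distance (nt) within an operon.
#' @param require_same_strand operons never span strand switches
#'   (disabling this links across strands; kept for auditability).
#' @return the genome with `locus_class` filled for every gene.
#' @export
classify_loci <- function(genome, max_gap = 30L, require_same_strand = TRUE) {
  stopifnot(inherits(genome, "Genome"), max_gap >= 0)
  if (!genome$topology %in% c("linear", "circular"))
    stop("genome topology is unset")
  if (nrow(genome$genes) == 0) return(genome)
  runs <- operon_runs(genome, max_gap, require_same_strand)
  cls <- setNames(rep("single", nrow(genome$genes)), genome$genes$gene_id)
  for (r in runs) {
    if (length(r$members) < 2) next
    cls[r$members] <- "operon_internal"
    cls[r$lead] <- "operon_lead"
  }
  genome$genes$locus_class <- unname(cls[genome$genes$gene_id])
  genome
}

# Maximal same-strand gene runs with intergenic gaps <= max_gap,
# cyclic on circular genomes. Returns a list of runs, each holding the
# member gene ids in chain order and the 5'-most member as `lead`.
operon_runs <- function(genome, max_gap = 30L, require_same_strand = TRUE) {
  g <- genome$genes
  n <- nrow(g)
  if (n == 0) return(list())
  len <- nchar(genome$sequence)
  linked <- rep(FALSE, n)  # linked[i]: gene i joined to gene i+1 (cyclic)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      gap <- g$start[i + 1L] - g$end[i] - 1L
      same <- g$strand[i + 1L] == g$strand[i]
      linked[i] <- (same || !require_same_strand) && gap <= max_gap
    }
    if (genome$topology == "circular") {
      gap <- g$start[1L] + len - g$end[n] - 1L
      same <- g$strand[1L] == g$strand[n]
      linked[n] <- (same || !require_same_strand) && gap <= max_gap
    }
  }
  if (all(linked) && n > 1) linked[n] <- FALSE  # fully circular chain
  start_at <- if (genome$topology == "circular" && n > 1 && linked[n]) {
    which(!linked)[1] %% n + 1L  # begin at the first break
  } else 1L
  ord <- ((start_at - 1L + 0:(n - 1L)) %% n) + 1L
  runs <- list()
  cur <- integer()
  for (i in ord) {
    cur <- c(cur, i)
    if (!linked[i]) {
      lead <- if (g$strand[cur[1]] == "-") cur[length(cur)] else cur[1]
      runs[[length(runs) + 1]] <- list(members = g$gene_id[cur],
                                       lead = g$gene_id[lead])
      cur <- integer()
    }
  }
  runs
}

#' Extract the upstream region of a gene
#'
#' Returns the `L_up` bases immediately 5' of the annotated start codon
#' on the coding strand (reverse-complemented for minus-strand genes).
#' Linear genomes truncate at the ends; circular genomes wrap.
#'
#' @param genome a [Genome].
#' @param gene_id gene identifier.
#' @param L_up window length in nt (>= 1).
#' @return one-row data.frame: `gene_id`, `sequence`, `length`,
#'   `truncated`, plus the genome-coordinate window (`win_start`,
#'   `win_end`, `strand`; `win_start > win_end` marks an origin-wrapping
#'   window on a circular genome, and an empty window has
#'   `win_start = win_end = NA`).
#' @export
extract_upstream <- function(genome, gene_id, L_up = 100L) {
  stopifnot(L_up >= 1)
  g <- gene_row(genome, gene_id)
  len <- nchar(genome$sequence)
  truncated <- FALSE
  if (g$strand == "+") {
    from <- g$start - L_up; to <- g$start - 1L
    if (genome$topology == "linear") {
      if (from < 1L) { from <- 1L; truncated <- TRUE }
      seq <- if (to < 1L) "" else substr(genome$sequence, from, to)
    } else {
      seq <- genome_substr(genome, from, to)
    }
  } else {
    from <- g$end + 1L; to <- g$end + L_up
    if (genome$topology == "linear") {
      if (to > len) { to <- len; truncated <- TRUE }
      seq <- if (from > len) "" else substr(genome$sequence, from, to)
    } else {
      seq <- genome_substr(genome, from, to)
    }
    if (nzchar(seq)) seq <- revcomp(seq)
  }
  empty <- !nzchar(seq)
  if (genome$topology == "circular" && !empty) {
    from <- norm_pos(from, len); to <- norm_pos(to, len)
  }
  data.frame(
    gene_id = g$gene_id, sequence = seq, length = nchar(seq),
    truncated = truncated,
    win_start = if (empty) NA_integer_ else as.integer(from),
    win_end = if (empty) NA_integer_ else as.integer(to),
    strand = g$strand, stringsAsFactors = FALSE)
}

#' Upstream regions of all promoter-owning genes
#'
#' Convenience wrapper: classifies loci if still unset, then extracts
#' upstream windows for every single and operon-lead gene. Windows with
#' more than `max_n_frac` ambiguous bases are flagged unusable for motif
#' discovery.
#'
#' @param genome a [Genome].
#' @param L_up window length (nt).
#' @param max_gap operon gap used if loci are still unclassified.
#' @param max_n_frac maximum tolerated N fraction per window.
#' @return data.frame of regions with a `usable` column.
#' @export
upstream_regions <- function(genome, L_up = 100L, max_gap = 30L,
                             max_n_frac = 0.1) {
  if (any(genome$genes$locus_class == "unset"))
    genome <- classify_loci(genome, max_gap = max_gap)
  keep <- genome$genes$locus_class %in% c("single", "operon_lead")
  ids <- genome$genes$gene_id[keep]
  out <- do.call(rbind, lapply(ids, function(id)
    extract_upstream(genome, id, L_up)))
  if (is.null(out))
    return(data.frame(gene_id = character(), sequence = character(),
                      length = integer(), truncated = logical(),
                      win_start = integer(), win_end = integer(),
                      strand = character(), usable = logical()))
  out$usable <- out$length > 0 &
    vapply(out$sequence, fraction_n, numeric(1)) <= max_n_frac
  rownames(out) <- NULL
  out
}

#' Write upstream regions as FASTA
#'
#' Headers follow `<genome_id>|<gene_id>|upstream<L_up>`.
#' @param regions data.frame from [upstream_regions()].
#' @param genome_id genome identifier used in headers.
#' @param path output file.
#' @param L_up window length recorded in the header.
#' @export
write_upstream_fasta <- function(regions, genome_id, path, L_up = 100L) {
  keep <- regions$length > 0
  seqs <- Biostrings::DNAStringSet(regions$sequence[keep])
  names(seqs) <- sprintf("%s|%s|upstream%d", genome_id,
                         regions$gene_id[keep], L_up)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write upstream windows as BED6
#'
#' Genome coordinates, 0-based half-open as BED requires. Windows that
#' wrap a circular origin are split into two records.
#' @inheritParams write_upstream_fasta
#' @param genome the source [Genome] (for its length).
#' @export
write_upstream_bed <- function(regions, genome, path) {
  len <- nchar(genome$sequence)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$length == 0 || is.na(r$win_start)) next
    name <- paste0(genome$id, "|", r$gene_id)
    if (r$win_start <= r$win_end) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = genome$id, start = r$win_start - 1L, end = r$win_end,
        name = name, score = 0L, strand = r$strand)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = genome$id, start = r$win_start - 1L, end = len,
        name = name, score = 0L, strand = r$strand)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = genome$id, start = 0L, end = r$win_end,
        name = name, score = 0L, strand = r$strand)
    }
  }
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
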