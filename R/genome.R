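#' Construct a Genome object
#'
#' The internal genome model used throughout the pipeline: a single DNA
#' sequence plus an ordered table of CDS features. Coordinates are
#' 1-based and closed (the GRanges/Biostrings convention). On a circular
#' genome a gene may wrap the origin, in which case `start > end` and the
#' feature covers `start..length` followed by `1..end`.
#'
#' @param id accession-like identifier (nonempty string).
#' @param sequence DNA string over A/C/G/T/N.
#' @param genes data.frame with columns `gene_id`, `start`, `end`,
#'   `strand` ("+"/"-"), and optionally `product`, `protein`,
#'   `locus_class`.
#' @param topology `"linear"` or `"circular"`.
#' @param source_format provenance tag (`"genbank"`, `"gff3+fasta"`,
#'   `"synthetic"`).
#' @return an object of class `Genome`.
#' @export
Genome <- function(id, sequence, genes, topology = c("linear", "circular"),
                   source_format = "synthetic") {
  topology <- match.arg(topology)
  stopifnot(is.character(id), nzchar(id), is.character(sequence))
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  if (is.null(genes$product)) genes$product <- NA_character_
  if (is.null(genes$protein)) genes$protein <- NA_character_
  if (is.null(genes$locus_class)) genes$locus_class <- "unset"
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    bad <- genes$start < 1 | genes$end < 1 | genes$start > len | genes$end > len
    if (any(bad))
      stop("gene coordinates outside [1, genome length] for: ",
           paste(genes$gene_id[bad], collapse = ", "))
    wrapped <- genes$start > genes$end
    if (any(wrapped) && topology != "circular")
      stop("start > end only allowed on circular genomes: ",
           paste(genes$gene_id[wrapped], collapse = ", "))
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(
    list(id = id, sequence = sequence, topology = topology,
         genes = genes, source_format = source_format),
    class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s: %d bp (%s), %d CDS [%s]\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$genes),
              x$source_format))
  invisible(x)
}

#' @export
length.Genome <- function(x) nchar(x$sequence)

# 1-based position normalized onto a circular genome
norm_pos <- function(p, len) ((p - 1L) %% len) + 1L

# Substring of the genome sequence; `from` may be < 1 or > len and
# `from > to` spans the origin -- both only on circular genomes.
genome_substr <- function(genome, from, to) {
  len <- nchar(genome$sequence)
  if (genome$topology == "linear") {
    stopifnot(from >= 1, to <= len, from <= to + 1)
    if (from > to) return("")
    return(substr(genome$sequence, from, to))
  }
  from <- norm_pos(from, len); to <- norm_pos(to, len)
  if (from <= to) return(substr(genome$sequence, from, to))
  paste0(substr(genome$sequence, from, len), substr(genome$sequence, 1, to))
}

gene_row <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("gene not found in genome: ", gene_id)
  genome$genes[i, , drop = FALSE]
}

gene_length_nt <- function(genome, g) {
  len <- nchar(genome$sequence)
  ifelse(g$start <= g$end, g$end - g$start + 1L,
         len - g$start + 1L + g$end)
}

#' Coding-strand nucleotide sequence of a gene
#'
#' @param genome a [Genome].
#' @param gene_id gene identifier.
#' @return DNA string on the coding strand (reverse-complemented for
#'   minus-strand genes), wrapping the origin where needed.
#' @export
gene_sequence <- function(genome, gene_id) {
  g <- gene_row(genome, gene_id)
  s <- genome_substr(genome, g$start, g$end)
  if (g$strand == "-") s <- revcomp(s)
  s
}
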