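#' Read an annotated genome
#'
#' Supports GenBank flat files and GFF3 + FASTA pairs. All CDS features
#' become gene records with 1-based closed coordinates; annotated
#' translations and products are retained. Topology is taken from the
#' GenBank LOCUS line; GFF3 input defaults to linear unless overridden.
#'
#' @param path GenBank file, or GFF3 file when `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta FASTA file with the genome sequence (GFF3 input only).
#' @param topology override for GFF3 input (`"linear"`/`"circular"`).
#' @return a [Genome].
#' @export
read_genome <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                        topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") read_genbank(path)
  else read_gff3_fasta(path, fasta, topology %||% "linear")
}

# ---- GenBank flat file ----------------------------------------------------
# Minimal parser for the feature subset this pipeline needs: LOCUS
# (length + topology), CDS locations incl. complement() and two-segment
# origin-spanning join(), qualifiers locus_tag/product/translation, and
# the ORIGIN sequence block.

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("parse error: no LOCUS line in ", path)
  topology <- if (grepl("\\bcircular\\b", locus[1])) "circular" else "linear"
  id_field <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]]
  id <- id_field[1]

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("parse error: no ORIGIN section in ", path)
  endl <- grep("^//", lines)
  endl <- endl[endl > ori[1]][1]
  if (is.na(endl)) endl <- length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1):(endl - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat0 <- grep("^FEATURES", lines)
  if (length(feat0) == 0) stop("parse error: no FEATURES table in ", path)
  flines <- lines[(feat0[1] + 1):(ori[1] - 1)]
  # a feature header has a non-blank key in columns 6-20
  keys <- substr(flines, 6, 20)
  is_head <- trimws(keys) != "" & substr(flines, 1, 5) == "     "
  heads <- which(is_head)
  genes <- list()
  n_cds <- 0L
  for (h in seq_along(heads)) {
    key <- trimws(keys[heads[h]])
    if (key != "CDS") next
    block_end <- if (h < length(heads)) heads[h + 1] - 1L else length(flines)
    block <- flines[heads[h]:block_end]
    body <- trimws(substr(block, 22, nchar(block)))
    # location may continue over lines until the first qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    loc <- paste(body[1:loc_end], collapse = "")
    parsed <- tryCatch(parse_gb_location(loc, nchar(sequence)),
                       error = function(e)
                         stop("parse error in CDS location '", loc, "': ",
                              conditionMessage(e)))
    quals <- parse_gb_qualifiers(body[seq_along(body) > loc_end])
    n_cds <- n_cds + 1L
    genes[[n_cds]] <- data.frame(
      gene_id = quals[["locus_tag"]] %||% sprintf("cds_%03d", n_cds),
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      product = quals[["product"]] %||% NA_character_,
      protein = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_cds == 0L) stop("empty annotation: no CDS features in ", path)
  Genome(id, sequence, do.call(rbind, genes), topology,
         source_format = "genbank")
}

parse_gb_location <- function(loc, genome_len) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(segs) != 2) stop("only two-segment joins supported")
    s1 <- parse_gb_span(segs[1]); s2 <- parse_gb_span(segs[2])
    if (s1[2] != genome_len || s2[1] != 1)
      stop("join does not span the origin")
    return(list(start = s1[1], end = s2[2], strand = strand))
  }
  s <- parse_gb_span(loc)
  list(start = s[1], end = s[2], strand = strand)
}

parse_gb_span <- function(x) {
  x <- gsub("[<>]", "", x)
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) != 3) stop("unsupported span: ", x)
  as.integer(m[2:3])
}

parse_gb_qualifiers <- function(body) {
  quals <- list()
  cur_key <- NULL; cur_val <- character()
  flush <- function() {
    if (!is.null(cur_key))
      quals[[cur_key]] <<- paste(cur_val, collapse = "")
  }
  for (ln in body) {
    if (grepl("^/", ln)) {
      flush()
      m <- regmatches(ln, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', ln))[[1]]
      cur_key <- m[2]; cur_val <- m[3]
    } else if (!is.null(cur_key)) {
      cur_val <- c(cur_val, gsub('"', "", ln))
    }
  }
  flush()
  quals
}

#' Write a Genome as a GenBank flat file
#'
#' @param genome a [Genome].
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  len <- nchar(genome$sequence)
  top <- if (genome$topology == "circular") "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   UNA",
                   genome$id, len, top),
           sprintf("DEFINITION  %s.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", len))
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    loc <- if (g$start <= g$end) sprintf("%d..%d", g$start, g$end)
           else sprintf("join(%d..%d,1..%d)", g$start, len, g$end)
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf('                     /locus_tag="%s"', g$gene_id))
    if (!is.na(g$product))
      out <- c(out, sprintf('                     /product="%s"', g$product))
    if (!is.na(g$protein))
      out <- c(out, wrap_qualifier("translation", g$protein))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

wrap_qualifier <- function(key, value) {
  full <- sprintf('/%s="%s"', key, value)
  chunks <- substring(full, seq(1, nchar(full), 58),
                      pmin(seq(58, nchar(full) + 57, 58), nchar(full)))
  paste0(strrep(" ", 21), chunks)
}

# ---- GFF3 + FASTA ---------------------------------------------------------

read_gff3_fasta <- function(path, fasta, topology) {
  if (is.null(fasta)) stop("GFF3 input requires a FASTA file")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("empty annotation: no CDS features in ", path)
  seqs <- Biostrings::readDNAStringSet(fasta)
  id <- sub("\\s.*$", "", names(seqs)[1])
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]])
         else rep(NA_character_, length(gr))
  gene_id <- pick("ID")
  if (all(is.na(gene_id))) gene_id <- pick("locus_tag")
  if (all(is.na(gene_id))) gene_id <- sprintf("cds_%03d", seq_along(gr))
  genes <- data.frame(
    gene_id = gene_id,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = pick("product"), protein = pick("translation"),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  Genome(id, as.character(seqs[[1]]), genes, topology,
         source_format = "gff3+fasta")
}

#' Write a Genome as a GFF3 + FASTA pair
#'
#' Origin-wrapping genes cannot be represented in GFF3 ranges; use
#' [write_genbank()] for those genomes.
#'
#' @param genome a [Genome].
#' @param gff_path,fasta_path output files.
#' @export
write_gff3_fasta <- function(genome, gff_path, fasta_path) {
  g <- genome$genes
  if (any(g$start > g$end))
    stop("origin-wrapping genes cannot be written as GFF3")
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- g$gene_id
  gr$product <- g$product
  gr$translation <- g$protein
  rtracklayer::export(gr, gff_path, format = "gff3")
  seq <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(seq, fasta_path)
  invisible(gff_path)
}
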