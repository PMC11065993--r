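DNA_BASES <- c("A", "C", "G", "T")

# A=0 C=1 G=2 T=3, anything else (N, masked) = 4
encode_dna <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  code <- match(v, DNA_BASES) - 1L
  code[is.na(code)] <- 4L
  code
}

decode_dna <- function(code) {
  paste(c(DNA_BASES, "N")[code + 1L], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# base-2 log-sum-exp
logsumexp2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC degenerate code for a set of bases
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  unname(IUPAC_MAP[key])
}

# Coerce either a named character vector of sequences or an
# upstream-region data.frame into a named character vector.
as_region_seqs <- function(regions) {
  if (is.data.frame(regions)) {
    stopifnot(all(c("gene_id", "sequence") %in% names(regions)))
    setNames(as.character(regions$sequence), regions$gene_id)
  } else if (is.character(regions)) {
    if (is.null(names(regions)) && length(regions))
      names(regions) <- paste0("region", seq_along(regions))
    regions
  } else {
    stop("regions must be a data.frame or a named character vector")
  }
}

fraction_n <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(v) == 0) return(0)
  mean(!(v %in% DNA_BASES))
}
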