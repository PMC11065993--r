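TATA_CONSENSUS <- c("T", "T", "T", "A", "W", "A", "T", "A")
TATA_ALLOWED <- list("T", "T", "T", "A", c("A", "T"), "A", "T", "A")

#' Find TATA-box candidates
#'
#' All offsets where an 8-mer matches the archaeal TATA consensus
#' TTTAWATA (W = A or T) with at most `max_mm` mismatches, sorted by
#' (mismatches, offset). Offsets are 1-based.
#'
#' @param sequence DNA string.
#' @param max_mm maximum mismatches tolerated.
#' @return data.frame with `offset` and `mismatches` (zero rows when the
#'   sequence is shorter than 8).
#' @export
find_tata <- function(sequence, max_mm = 1L) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(v)
  if (L < 8)
    return(data.frame(offset = integer(), mismatches = integer()))
  n <- L - 7L
  mm <- integer(n)
  for (k in 1:8) {
    bad <- !(v[k:(k + n - 1L)] %in% TATA_ALLOWED[[k]])
    mm <- mm + bad
  }
  keep <- which(mm <= max_mm)
  out <- data.frame(offset = keep, mismatches = mm[keep])
  out[order(out$mismatches, out$offset), , drop = FALSE]
}

#' Call a strong early-promoter core
#'
#' Looks for the strong archaeal promoter core: a TTTAWATA TATA-box
#' directly preceded by a 6-nt purine-rich BRE (TFB recognition
#' element). Position -1 is the base immediately 5' of the TATA start;
#' the preferred strong-BRE bases G at -6 and A at -3 are reported as
#' flags but not required. `is_strong` requires `mismatches <= max_mm`
#' and BRE purine fraction `>= purine_min`.
#'
#' @param sequence DNA string to examine.
#' @param max_mm TATA mismatch tolerance.
#' @param purine_min minimum BRE purine (A/G) fraction.
#' @return a `PromoterCall` list, or `NULL` when no TATA candidate has a
#'   complete BRE window.
#' @export
call_promoter <- function(sequence, max_mm = 1L, purine_min = 2 / 3) {
  cand <- find_tata(sequence, max_mm)
  cand <- cand[cand$offset >= 7L, , drop = FALSE]  # room for the BRE
  if (nrow(cand) == 0) return(NULL)
  best <- cand[1, ]  # already sorted by (mismatches, offset)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  tata_offset <- best$offset
  bre <- v[(tata_offset - 6L):(tata_offset - 1L)]  # positions -6 .. -1
  purine <- mean(bre %in% c("A", "G"))
  structure(list(
    tata_offset = tata_offset,
    tata_seq = paste(v[tata_offset:(tata_offset + 7L)], collapse = ""),
    tata_mismatches = best$mismatches,
    bre_seq = paste(bre, collapse = ""),
    bre_purine_fraction = purine,
    bre_G_minus6 = bre[1] == "G",
    bre_A_minus3 = bre[4] == "A",
    is_strong = best$mismatches <= max_mm && purine >= purine_min),
    class = "PromoterCall")
}

#' @export
print.PromoterCall <- function(x, ...) {
  cat(sprintf("<PromoterCall> BRE %s | TATA %s @%d (%d mm), purine %.2f%s\n",
              x$bre_seq, x$tata_seq, x$tata_offset, x$tata_mismatches,
              x$bre_purine_fraction, if (x$is_strong) ", strong" else ""))
  invisible(x)
}

#' Classify a motif as a strong-promoter motif
#'
#' TRUE when the strong promoter core is called on the motif consensus
#' and on at least half of the individual site sequences at a consistent
#' TATA offset (within +/- 2 nt of the consensus call).
#'
#' @param motif a motif result from [discover_motifs()] (needs `pwm`
#'   and `sites` with >= 2 rows).
#' @param max_mm TATA mismatch tolerance.
#' @param purine_min minimum BRE purine fraction.
#' @export
classify_motif <- function(motif, max_mm = 1L, purine_min = 2 / 3) {
  sites <- motif$sites
  if (!is.null(sites$passing)) sites <- sites[sites$passing, , drop = FALSE]
  if (nrow(sites) < 2) return(FALSE)
  consensus_call <- call_promoter(motif$pwm$consensus, max_mm, purine_min)
  if (is.null(consensus_call) || !consensus_call$is_strong) return(FALSE)
  ref <- consensus_call$tata_offset
  ok <- vapply(sites$site, function(s) {
    pc <- call_promoter(s, max_mm, purine_min)
    !is.null(pc) && pc$is_strong && abs(pc$tata_offset - ref) <= 2
  }, logical(1))
  mean(ok) >= 0.5
}

#' Promoter calls for a motif and its sites, as a table
#'
#' One row for the consensus plus one per site; handy audit output.
#' @inheritParams classify_motif
#' @export
promoter_table <- function(motif, max_mm = 1L, purine_min = 2 / 3) {
  seqs <- c(consensus = motif$pwm$consensus,
            setNames(motif$sites$site, motif$sites$region_id))
  rows <- lapply(names(seqs), function(nm) {
    pc <- call_promoter(seqs[[nm]], max_mm, purine_min)
    if (is.null(pc))
      return(data.frame(id = nm, tata_offset = NA_integer_,
                        tata_seq = NA_character_, mismatches = NA_integer_,
                        bre_seq = NA_character_, purine = NA_real_,
                        G_minus6 = NA, A_minus3 = NA, is_strong = FALSE))
    data.frame(id = nm, tata_offset = pc$tata_offset,
               tata_seq = pc$tata_seq, mismatches = pc$tata_mismatches,
               bre_seq = pc$bre_seq, purine = pc$bre_purine_fraction,
               G_minus6 = pc$bre_G_minus6, A_minus3 = pc$bre_A_minus3,
               is_strong = pc$is_strong)
  })
  do.call(rbind, rows)
}
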