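#' Local pairwise protein alignment with an e-value proxy
#'
#' Smith-Waterman via BLOSUM62 with gap open 11 / extend 1 (the BLAST
#' protein defaults). Percent identity is identities over aligned
#' columns; coverage is the aligned span of the shorter sequence over
#' its length. The e-value proxy uses Karlin-Altschul scaling with the
#' published gapped BLOSUM62-11-1 constants (lambda = 0.267, K = 0.041)
#' on the two sequence lengths; it calibrates a single-pass search, so
#' family counts can differ from an iterative profile search at the same
#' nominal threshold.
#'
#' @param a,b amino-acid strings (>= 1 aa; >= 10 aa for a meaningful
#'   e-value).
#' @return list: `score`, `pid`, `coverage` (percent), `evalue`.
#' @export
pairwise_align <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  score <- Biostrings::score(aln)
  pid <- Biostrings::pid(aln, type = "PID1")
  shorter_is_a <- nchar(a) <= nchar(b)
  al <- if (shorter_is_a) Biostrings::pattern(aln) else
    Biostrings::subject(aln)
  span <- Biostrings::end(al) - Biostrings::start(al) + 1L
  coverage <- 100 * span / min(nchar(a), nchar(b))
  list(score = score, pid = pid, coverage = coverage,
       evalue = ka_evalue(score, nchar(a), nchar(b)))
}

KA_LAMBDA <- 0.267
KA_K <- 0.041

ka_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

# All-vs-all local alignment scores (upper triangle), vectorized
# one-vs-many through Biostrings.
align_score_matrix <- function(prots) {
  n <- length(prots)
  S <- matrix(0, n, n, dimnames = list(names(prots), names(prots)))
  if (n < 2) return(S)
  set <- Biostrings::AAStringSet(prots)
  for (i in seq_len(n - 1)) {
    sc <- Biostrings::pairwiseAlignment(
      set[(i + 1):n], set[[i]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    S[i, (i + 1):n] <- sc
    S[(i + 1):n, i] <- sc
  }
  S
}

#' Cluster proteins into families by single linkage
#'
#' Edges connect pairs whose e-value proxy clears `threshold_evalue`;
#' connected components are the families (so A~B and B~C put A and C in
#' one family even without a direct A~C link). Families are named by
#' provenance prefix (`viral_single` -> ADG, `mag` -> mADG,
#' `ssv_operon` -> ADGSSV) and numbered by descending size, ties broken
#' by the lexicographically first member. Input order never changes the
#' result: members are canonically sorted first.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param threshold_evalue clustering cutoff (study operating point
#'   1e-3).
#' @param provenance optional named vector mapping protein names to
#'   `"viral_single"`, `"mag"` or `"ssv_operon"`.
#' @return list of families: `family_id`, `members`, `n_members`,
#'   `singleton`, `min_pid`, `min_coverage`.
#' @export
cluster_families <- function(proteins, threshold_evalue = 1e-3,
                             provenance = NULL) {
  if (length(proteins) == 0) stop("empty protein set")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("prot", seq_along(proteins))
  proteins <- proteins[order(names(proteins))]
  n <- length(proteins)
  S <- align_score_matrix(proteins)
  lens <- nchar(proteins)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ka_evalue(S[i, j], lens[i], lens[j]) <= threshold_evalue) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(names(proteins), comp)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) sort(g)[1], character(1)))
  groups <- groups[ord]
  counters <- c(ADG = 0L, mADG = 0L, ADGSSV = 0L)
  fams <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    members <- sort(groups[[k]])
    prefix <- family_prefix(members, provenance)
    counters[prefix] <- counters[prefix] + 1L
    stats <- family_stats(proteins[members])
    fams[[k]] <- list(
      family_id = sprintf("%s.%02d", prefix, counters[prefix]),
      members = members, n_members = length(members),
      singleton = length(members) == 1L,
      min_pid = stats$min_pid, min_coverage = stats$min_coverage)
  }
  fams
}

family_prefix <- function(members, provenance) {
  if (is.null(provenance)) return("ADG")
  prov <- provenance[members]
  prov[is.na(prov)] <- "viral_single"
  top <- names(sort(table(prov), decreasing = TRUE))[1]
  switch(top, mag = "mADG", ssv_operon = "ADGSSV", "ADG")
}

family_stats <- function(prots) {
  n <- length(prots)
  if (n < 2) return(list(min_pid = 100, min_coverage = 100))
  pid <- cov <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- pairwise_align(prots[[i]], prots[[j]])
    pid <- c(pid, al$pid); cov <- c(cov, al$coverage)
  }
  list(min_pid = min(pid), min_coverage = min(cov))
}

#' Motif prevalence of a protein family
#'
#' The fraction of a family's homologous genes whose upstream region
#' carries the genome-specific regulatory motif. A prevalence of 1
#' means every homolog sits behind the early promoter; values near 0
#' mark families recruited into the ADG set through one unusual member.
#'
#' @param family one element of [cluster_families()] output.
#' @param adg_flags named logical vector: does this gene carry the
#'   motif? Every family member must be present.
#' @return list: `family_id`, `n_homologs`, `n_with_motif`,
#'   `prevalence`.
#' @export
motif_prevalence <- function(family, adg_flags) {
  members <- family$members
  if (length(members) == 0) stop("empty family")
  if (!all(members %in% names(adg_flags)))
    stop("adg_flags missing entries for: ",
         paste(setdiff(members, names(adg_flags)), collapse = ", "))
  nm <- sum(adg_flags[members])
  list(family_id = family$family_id, n_homologs = length(members),
       n_with_motif = as.integer(nm),
       prevalence = nm / length(members))
}

#' Screen viral small proteins for host homologs (antitoxin candidates)
#'
#' Viral proteins shorter than `small_protein_max` are compared against
#' all host proteins; hits at `host_screen_evalue` or better are kept.
#' A host hit whose +/-5-gene neighborhood contains
#' `viral_context_min_hits` or more genes with viral homologs is
#' discarded as an integrated virus. Remaining candidates are annotated
#' with adjacent-small-gene context: a neighbor that is itself small and
#' convergently oriented (head-to-head 3' ends) is flagged as a putative
#' toxin partner, the Phd-Doc-like arrangement.
#'
#' @param viral_proteins named character vector of viral protein
#'   sequences.
#' @param hosts list of annotated host [Genome]s with `protein` filled.
#' @param config a [pipeline_config()].
#' @return data.frame of candidates with exclusion and partner flags.
#' @export
screen_host_homologs <- function(viral_proteins, hosts,
                                 config = pipeline_config()) {
  if (inherits(hosts, "Genome")) hosts <- list(hosts)
  rows <- list()
  for (host in hosts) {
    hp <- setNames(host$genes$protein, host$genes$gene_id)
    hp <- hp[!is.na(hp) & nzchar(hp)]
    if (!length(hp)) next
    # viral hits per host gene (any viral protein, screening threshold)
    hit_mat <- matrix(FALSE, length(hp), length(viral_proteins),
                      dimnames = list(names(hp), names(viral_proteins)))
    best <- list()
    for (v in names(viral_proteins)) {
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(hp), viral_proteins[[v]], type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11,
        gapExtension = 1, scoreOnly = TRUE)
      ev <- ka_evalue(sc, nchar(hp), nchar(viral_proteins[[v]]))
      hit_mat[, v] <- ev <= config$host_screen_evalue
    }
    host_has_hit <- rowSums(hit_mat) > 0
    gene_order <- host$genes$gene_id
    for (v in names(viral_proteins)) {
      if (nchar(viral_proteins[[v]]) >= config$small_protein_max) next
      for (hg in names(hp)[hit_mat[, v]]) {
        idx <- match(hg, gene_order)
        nb <- gene_order[max(1, idx - 5):min(length(gene_order), idx + 5)]
        nb <- setdiff(nb, hg)
        n_ctx <- sum(host_has_hit[intersect(nb, names(host_has_hit))])
        excluded <- n_ctx >= config$viral_context_min_hits
        partner <- find_toxin_partner(host, idx, config)
        al <- pairwise_align(viral_proteins[[v]], hp[[hg]])
        rows[[length(rows) + 1]] <- data.frame(
          viral_id = v, host_genome = host$id, host_gene = hg,
          evalue = al$evalue, pid = al$pid, coverage = al$coverage,
          viral_context_hits = n_ctx, excluded_integrated = excluded,
          toxin_partner = !is.null(partner),
          partner_gene = partner %||% NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(viral_id = character(), host_genome = character(),
                      host_gene = character(), evalue = numeric(),
                      pid = numeric(), coverage = numeric(),
                      viral_context_hits = integer(),
                      excluded_integrated = logical(),
                      toxin_partner = logical(),
                      partner_gene = character())
  out
}

# Adjacent small gene convergently oriented with gene `idx` (their 3'
# ends face each other: + then - along the genome).
find_toxin_partner <- function(host, idx, config) {
  g <- host$genes
  for (j in c(idx - 1L, idx + 1L)) {
    if (j < 1 || j > nrow(g)) next
    plen <- nchar(g$protein[j])
    if (is.na(plen) || plen >= config$small_protein_max) next
    left <- min(idx, j); right <- max(idx, j)
    if (g$strand[left] == "+" && g$strand[right] == "-")
      return(g$gene_id[j])
  }
  NULL
}
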