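#' Run the full ADG discovery pipeline
#'
#' Per genome, independently: classify loci, extract upstream windows of
#' single/operon-lead genes, discover per-genome motifs (motifs are
#' never pooled across genomes -- each virus follows its own
#' evolutionary path, so the regulatory sequence is conserved within,
#' not between, genomes), scan the genome's own upstream set with every
#' significant motif, and call ADGs by the dual criteria. Then, across
#' genomes: cluster the proteins of all promoter-owning genes into
#' families and compute motif prevalence for every family containing an
#' ADG.
#'
#' A genome whose stages cannot run (e.g. too few usable upstream
#' regions) is skipped with a recorded reason; the run continues.
#'
#' @param genomes list of [Genome] objects and/or GenBank file paths.
#' @param config a [pipeline_config()].
#' @param outdir optional directory for the report files (TSV/JSON/
#'   MEME); nothing is written when `NULL`.
#' @return list: `manifest`, `per_genome` (motifs, hits, calls, counts
#'   or skip reason), `calls` (combined), `families`, `prevalence`.
#' @export
run_pipeline <- function(genomes, config = pipeline_config(),
                         outdir = NULL) {
  if (length(genomes) == 0) stop("need at least one genome")
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  inputs <- list()
  objs <- list()
  for (g in genomes) {
    if (is.character(g)) {
      inputs[[length(inputs) + 1]] <-
        list(path = g, md5 = unname(tools::md5sum(g)))
      g <- read_genome(g, format = "genbank")
    } else {
      inputs[[length(inputs) + 1]] <- list(path = NA_character_,
                                           md5 = NA_character_)
    }
    objs[[g$id]] <- g
  }
  per_genome <- lapply(objs, analyze_genome, config = config)
  names(per_genome) <- names(objs)

  ok <- !vapply(per_genome, function(x) is.null(x$calls), logical(1))
  calls <- if (any(ok))
    do.call(rbind, lapply(per_genome[ok], `[[`, "calls")) else NULL
  if (!is.null(calls)) rownames(calls) <- NULL

  fam_res <- cross_genome_families(objs[ok], per_genome[ok], config)

  counts <- lapply(per_genome, function(x) x$counts %||%
                     list(skipped = x$skip_reason))
  manifest <- list(
    tool = "adgscan", version = as.character(utils::packageVersion("adgscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[order(names(config))],
    inputs = inputs,
    per_genome_counts = counts,
    n_genomes = length(objs), n_genomes_analyzed = sum(ok),
    n_families = length(fam_res$families),
    n_adg_total = if (is.null(calls)) 0L else sum(calls$status == "adg"),
    calls_md5 = df_md5(calls))
  res <- list(manifest = manifest, per_genome = per_genome,
              calls = calls, families = fam_res$families,
              prevalence = fam_res$prevalence)
  if (!is.null(outdir)) write_pipeline_reports(res, objs, outdir)
  res
}

# content checksum of a data.frame (via a canonical TSV rendering)
df_md5 <- function(df) {
  if (is.null(df)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Analyze one genome end to end
#'
#' Regions -> per-genome motif discovery -> promoter-aware scan -> ADG
#' calls, without the cross-genome family stage. [run_pipeline()] calls
#' this per genome.
#'
#' @param genome an annotated [Genome].
#' @param config a [pipeline_config()].
#' @return list with `regions`, `motifs`, `hits`, `calls` and stage
#'   `counts`, or a `skip_reason` when the genome cannot be analyzed.
#' @export
analyze_genome <- function(genome, config = pipeline_config()) {
  genome <- classify_loci(genome, max_gap = config$max_gap)
  regions <- upstream_regions(genome, L_up = config$L_up,
                              max_gap = config$max_gap,
                              max_n_frac = config$max_n_frac)
  usable <- regions[regions$usable & regions$length >= config$W_min, ,
                    drop = FALSE]
  if (nrow(usable) < config$min_sequences)
    return(list(skip_reason = "too_few_regions", genome_id = genome$id))
  motifs <- tryCatch(
    discover_motifs(usable, as_discovery_config(config)),
    error = function(e) NULL)
  if (is.null(motifs))
    return(list(skip_reason = "discovery_failed", genome_id = genome$id))
  passing <- Filter(function(m) m$passed_threshold, motifs)
  hits <- if (length(passing)) do.call(rbind, lapply(passing, function(m)
    scan_regions(m$pwm, usable, e_threshold = config$e_threshold,
                 genome_id = genome$id, dist = m$score_dist)))
    else empty_hits()
  # A gene carries the motif when either significance route clears the
  # cutoff: the discovery site p-value or the scan e-value.
  for (m in passing) {
    ok_genes <- m$sites$region_id[m$sites$passing]
    sel <- hits$motif_id == m$pwm$motif_id & hits$gene_id %in% ok_genes
    hits$passed[sel] <- TRUE
  }
  calls <- call_adgs(genome, motifs, hits, config)
  list(genome_id = genome$id, regions = regions, motifs = motifs,
       hits = hits, calls = calls,
       counts = list(n_genes = nrow(genome$genes),
                     n_regions = nrow(usable),
                     n_motifs = length(motifs),
                     n_motifs_passing = length(passing),
                     n_hits_passed = sum(hits$passed),
                     n_adg = sum(calls$status == "adg")))
}

empty_hits <- function() {
  data.frame(genome_id = character(), gene_id = character(),
             motif_id = character(), offset = integer(),
             score = numeric(), p_value = numeric(), e_value = numeric(),
             site = character(), region_length = integer(),
             n_positions_scanned = integer(), passed = logical())
}

# Cluster proteins of all promoter-owning genes across genomes and
# attach motif prevalence to every family containing an ADG call.
cross_genome_families <- function(genomes, per_genome, config) {
  prots <- character(0)
  flags <- logical(0)
  is_adg <- character(0)
  for (id in names(genomes)) {
    res <- per_genome[[id]]
    g <- genomes[[id]]$genes
    keep <- g$gene_id %in% res$regions$gene_id &
      !is.na(g$protein) & nzchar(g$protein)
    nm <- paste(id, g$gene_id[keep], sep = "|")
    prots[nm] <- g$protein[keep]
    hit_genes <- res$hits$gene_id[res$hits$passed]
    flags[nm] <- g$gene_id[keep] %in% hit_genes
    adg_genes <- res$calls$gene_id[res$calls$status == "adg"]
    is_adg <- c(is_adg, paste(id, adg_genes, sep = "|"))
  }
  if (length(prots) < 2 || length(is_adg) == 0)
    return(list(families = list(), prevalence = NULL))
  fams <- cluster_families(prots, threshold_evalue = config$family_evalue)
  fams <- Filter(function(f) any(f$members %in% is_adg), fams)
  prev <- do.call(rbind, lapply(fams, function(f)
    as.data.frame(motif_prevalence(f, flags), stringsAsFactors = FALSE)))
  list(families = fams, prevalence = prev)
}

write_pipeline_reports <- function(res, genomes, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$calls))
    write_calls_tsv(res$calls, file.path(outdir, "adg_calls.tsv"))
  for (id in names(res$per_genome)) {
    pg <- res$per_genome[[id]]
    if (is.null(pg$calls)) next
    gdir <- file.path(outdir, id)
    dir.create(gdir, showWarnings = FALSE)
    if (length(pg$motifs))
      write_meme(lapply(pg$motifs, `[[`, "pwm"),
                 file.path(gdir, "motifs.meme"))
    write_hits_tsv(pg$hits, file.path(gdir, "hits.tsv"))
    write_calls_tsv(pg$calls, file.path(gdir, "calls.tsv"))
    write_adg_gff3(pg$calls, genomes[[id]], file.path(gdir, "adg.gff3"))
  }
  if (!is.null(res$prevalence))
    write.table(res$prevalence, file.path(outdir, "prevalence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  fam_rows <- do.call(rbind, lapply(res$families, function(f)
    data.frame(family_id = f$family_id, n_members = f$n_members,
               members = paste(f$members, collapse = ","))))
  if (!is.null(fam_rows))
    write.table(fam_rows, file.path(outdir, "families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}
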