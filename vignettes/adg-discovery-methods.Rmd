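---
title: "Finding anti-defense genes from their early promoters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding anti-defense genes from their early promoters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgscan)
```

## The biological problem

Archaeal viruses of the Sulfolobales face CRISPR-Cas, toxin–antitoxin and
other defense systems the moment they inject their DNA. Their counter-weapons
— anti-CRISPR proteins (Acrs), Acr-associated regulators (Aca), antitoxin
mimics — must be expressed *immediately* after infection, before any other
viral gene. These anti-defense genes (ADGs) evolve fast and share almost no
sequence similarity, which defeats homology-based annotation. What they do
share, within any one virus, is the *cis* signal that makes them early: a
highly conserved upstream regulatory sequence built around a strong archaeal
core promoter — a purine-rich TFB-recognition element (BRE) directly 5' of a
TATA-box matching `TTTAWATA`. `adgscan` operationalizes that observation:
instead of asking "what does this protein look like?" it asks "is this gene
wired to fire first?".

## Pipeline overview

For each genome independently (regulatory sequences are conserved *within*,
not between, viruses — each lineage followed its own evolutionary path):

1. **Upstream regions** (`upstream_regions()`): classify genes into single /
   operon-lead / operon-internal, then take the 100 nt upstream of the start
   codon of every promoter-owning (single or lead) gene on the coding strand.
2. **Motif discovery** (`discover_motifs()`): deterministic ZOOPS
   expectation-maximization over a width grid of 30–100 nt.
3. **Promoter verification** (`classify_motif()`): the motif must contain the
   BRE + TATA core, on its consensus and on at least half of its sites.
4. **Scanning** (`scan_regions()`): the per-genome matrix rescans the same
   upstream set; hits carry exact p-values and Bonferroni e-values.
5. **Dual-criteria calling** (`call_adgs()`): a gene is a putative ADG when
   its motif (i) carries a predicted strong promoter and (ii) is shared by at
   least `min_shared` genes in that genome. Genes failing a criterion or
   matching an audit rule are kept on a low-probability list with
   machine-readable reasons rather than silently dropped.
6. **Families and prevalence** (`cluster_families()`,
   `motif_prevalence()`): ADG proteins are clustered across genomes by
   single-linkage local alignment, and each family is annotated with its
   motif prevalence — the fraction of homologs that actually sit behind the
   early promoter.

## The statistical core

### PWM scores and exact p-values

Motifs are position weight matrices scored as summed log-likelihood ratios
(bits) against an order-0 background. Site significance requires the tail
probability `P(score >= s)` for a background-drawn word, which
`score_distribution()` computes by dynamic programming in two modes:

* **exact** — convolves the per-column score values themselves, merging equal
  partial sums. Because additions run column-by-column in the same order a
  direct word-score sum would use, the resulting support atoms are
  bit-identical to enumerating all `4^W` words. Feasible up to width ~8, and
  used to validate the machinery against exhaustive enumeration.
* **lattice** — rounds each column's scores to the nearest multiple of a
  granularity (default `1e-3` bits) and convolves on the integer lattice.
  This is linear in width × score range and is what the 30–100-column
  discovery motifs use. The induced error is bounded by `W × granularity / 2`
  bits of score displacement; for thresholds that do not sit within that
  distance of a score atom the lattice result is exactly the exact-mode
  result, which is how the convergence tests are constructed.

### ZOOPS EM, deterministic seeding, width selection

Each upstream region carries zero or one site (one promoter per gene), the
classic ZOOPS model. Rather than random restarts, every substring of the
requested width is evaluated as a candidate seed under a two-parameter
match/mismatch model and the seed with the best ZOOPS likelihood initializes
EM — the pipeline is therefore fully deterministic with no seed parameter.
The E/M updates carry a Dirichlet pseudocount (0.25, spread by background),
so the monitored objective is the penalized log-likelihood, which is
provably nondecreasing.

Widths are explored on a grid (30, 40, …, 100 nt) and compared by
**AIC-penalized** converged likelihood. Raw likelihood cannot be compared
across widths: every added column contributes three free parameters, so the
unpenalized maximum always sits at the widest model (which, at 100-nt
regions, degenerates to a single-offset per region). BIC
(`0.5 · k · log n`) was evaluated and systematically under-shot the width of
the conserved region, trimming informative flanking columns; AIC retains
them while still rejecting pure-noise width growth.

### Leave-one-out site significance

A subtlety that matters in practice: after EM, the sites *are* the training
data of the PWM, so their scores are biased upward — severely enough that on
pure-noise region sets EM-aligned sites can clear any fixed p-value cutoff.
`discover_motifs()` therefore scores each site under the PWM re-estimated
**without that region's posterior mass** (leave-one-out), and converts that
score to a p-value under the exact null distribution. Held-out
probabilities use Jeffreys (+0.5 per base) smoothing: with few sites, the
sharper estimation pseudocount would price a base unseen in the remaining
sites at close to its pseudocount floor, over-penalizing the natural
degeneracy of real sites. With this correction, motif-free control genomes
produce no passing motifs while implanted regulons are essentially
unaffected.

### Significance operating point

A gene counts as motif-positive when **either** its discovery site p-value
**or** its scan e-value (Bonferroni over all positions scanned in that
genome's run) clears `1e-8`. The two routes deliberately have different
multiplicity behavior — the site p-value is per-occurrence, the e-value is
per-scan — and the disjunction is the documented operating point of the
calling criteria.

## Promoter-core model

`call_promoter()` searches for the degenerate octamer `TTTAWATA`
(default tolerance: 1 mismatch) and reads the 6 nt immediately 5' of the
TATA start as the BRE, with position −1 adjacent to the TATA. A call is
*strong* when the TATA matches within tolerance and the BRE purine (A/G)
fraction reaches 2/3. The literature's preferred strong-BRE bases — G at −6
and A at −3 — are surfaced as flags but not required, so either policy can
be audited downstream; requiring them would be a one-line configuration
for a stricter reading. `classify_motif()` lifts the per-sequence call to
the motif level: the consensus must call strong, and at least half the
sites must call strong at a consistent offset (±2 nt).

## Calling rules and the audit list

Beyond the dual criteria, three demotion rules populate the
low-probability list (never silently discarding a candidate):

* `tss_too_close` — the TATA box ends fewer than 10 nt before the start
  codon. The transcription start sits ~20+ nt downstream of the TATA start,
  so such a "promoter" would transcribe from inside the ORF. (The rule is
  applied to the TATA *end*; a box ending 4 nt before the start codon is
  the canonical firing example.)
* `core_protein` — the product matches a configurable keyword list of
  conserved viral core genes (capsid, polymerase, terminase, …), which are
  never early genes.
* `downstream_in_operon` — operon-internal genes co-transcribed behind a
  called ADG lead: expressed early, but without their own promoter
  evidence.

`reannotate_start()` handles the inverse situation — a strong promoter
*inside* the annotated 5' coding region — by finding the first in-frame
ATG/GTG/TTG that places the motif fully upstream, refusing if more than
half the ORF would be consumed. An 83-codon ORF with an in-frame start
84 nt downstream re-annotates to a 55-aa product.

## Protein families and motif prevalence

ADG proteins are clustered by single-linkage over local alignments
(BLOSUM62, gap 11/1) with a Karlin–Altschul e-value proxy
(λ = 0.267, K = 0.041 — the published gapped BLOSUM62-11-1 constants) at a
1e-3 threshold. This single-pass search replaces an iterative profile
search; family boundaries at the same nominal threshold may therefore be
somewhat more conservative, which is documented rather than hidden.
Coverage is computed over the shorter sequence. Prevalence denominators
count homologs within the analyzed genome set.

The small-protein host screen (`screen_host_homologs()`) compares viral
proteins < 150 aa against host proteomes at e ≤ 1e-10, discards host hits
whose ±5-gene neighborhood contains ≥ 5 genes with viral homologs
(integrated proviruses), and flags candidates whose adjacent small gene is
convergently oriented — the Phd–Doc-like antitoxin/toxin arrangement.

## The synthetic-genome generator

`simulate_genome()` produces the ground truth everything is tested
against: an i.i.d. background at a requested GC, 30–80 random ORFs in
same-strand transcription units (every unit preceded by ≥ 120 nt of clean
intergenic sequence so upstream windows are well defined), and `n_adg`
unit-lead genes receiving one implant each, sampled from a PWM that embeds
a near-deterministic BRE (G at −6, A at −3) + `TTTAWATA` core inside
flanks tuned so the implant averages a target information content
(default 1.0 bit/column — the regime where recovery is expected but not
trivial). Implants end 5–15 nt before the window end, so the
TSS-proximity rule never fires on true positives. ADG placement can be
uniform, biased to both termini (rudivirus-like) or to one end
(lipothrixvirus-like).

What the generator does **not** emulate: real codon usage and amino-acid
composition, shared gene content between genomes (unless shared ADG ORFs
are supplied explicitly), dinucleotide or regional compositional
heterogeneity (the background is strictly order-0, matching the scanning
statistics), overlapping genes, and non-early promoters of ordinary
genes. Passing the benchmark therefore demonstrates
the statistical machinery under the stated model, not performance on any
particular natural genome.

```{r example, eval = FALSE}
sim <- simulate_genome(sim_spec(seed = 1))
res <- run_pipeline(list(sim$genome), outdir = "adgscan_out")
res$calls[res$calls$status == "adg", c("gene_id", "motif_id", "e_value")]
```

## Numerical and design choices

* Coordinates are 1-based closed throughout (the Biostrings/GenomicRanges
  convention); GenBank's 1-based inclusive locations map directly and GFF3
  via `rtracklayer`. Origin-wrapping genes are represented as
  `start > end` on circular genomes.
* The operon heuristic (same strand, gap ≤ 30 nt) is a documented default,
  configurable and echoed into every report; no claim is made that it
  reproduces any particular operon predictor.
* Upstream windows are coding-strand only — the promoter is directional.
  Windows with > 10% ambiguous bases are excluded from discovery.
* Scan ties at the best offset break toward the smallest offset; one hit
  per region, matching the per-gene presence/absence semantics downstream.
* `min_shared = 3` genes is the smallest count making "a shared regulatory
  sequence" meaningful; it is configurable.
* Benchmarks in the test suite run 50 simulated genomes of 40 genes with
  8 implants plus 10 motif-free controls, and smaller fixtures elsewhere;
  these sizes were chosen as the smallest that exercise every code path
  with stable statistics.

## Known limitations

* The e-value proxy is calibrated for, not identical to, an iterative
  profile search; family counts on real data will differ from PSI-BLAST's.
* Only order-0 backgrounds are modeled; strongly skewed dinucleotide
  composition would mis-calibrate p-values.
* GenBank parsing covers the CDS/locus_tag/product/translation subset
  with simple and two-segment origin-spanning locations; exotic location
  operators are rejected loudly rather than guessed at.
* Motif comparison across genomes is by promoter-core identity and
  protein homology, not PWM alignment.
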