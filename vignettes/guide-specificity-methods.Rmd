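---
title: "Guide specificity scoring and off-target diagnostics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide specificity scoring and off-target diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidespec)
```

## The problem

Pooled CRISPR growth screens for *non-coding* elements — transcription
factor motifs, enhancers, promoters, CTCF sites — are structurally more
vulnerable to off-target artefacts than gene-knockout screens. A coding
exon offers a wide window of equivalent sgRNAs, so designers can afford to
keep only highly specific guides. A 19-bp motif does not: the nuclease
must cut *inside* the element, and often every available spacer has
marginal specificity. When a low-specificity guide depletes in a growth
screen, the signal is easily mistaken for evidence that its target element
is essential, when in reality the fitness cost comes from cutting (or, for
dCas9 effectors, binding and silencing) dozens of off-target loci.

`guidespec` implements the off-target-aware design and diagnosis workflow
for this setting: enumerate candidate spacers, find and weigh their
off-target sites, aggregate the weights into a per-guide specificity
score, filter libraries on that score, and — for completed screens —
quantify how much of the depletion signal is attributable to
low-specificity guides.

## The specificity model

### Off-target search

For a 20-nt spacer, every window on either strand of the genome whose
adjacent 3-nt PAM matches the allowed set and whose protospacer is within
a Hamming distance budget of the spacer is an off-target site
(`find_offtarget_sites()`). Defaults:

* mismatch budget 3 (sites at 4+ mismatches contribute negligibly to
  cleavage and are not searched);
* PAM set `{NGG, NAG}` — NGG is the canonical SpCas9 PAM and NAG its main
  tolerated alternate. Published off-target search tools differ in whether
  alternate PAMs enter the aggregate; we therefore expose the set as a
  parameter everywhere rather than hard-coding a guess.
* windows containing N never match: base-pairing (and hence any mismatch
  weight) is undefined against an ambiguous base.

Mismatch positions are numbered 1..20 from the spacer 5' end, so position
20 is PAM-proximal — the convention of published mismatch-weight tables.
The contract is *set-exactness*: the implementation (seeded candidate
generation via `Biostrings::matchPattern`) is tested for set equality
against a naive all-window Hamming scan on genomes up to 200 kb.

### Searchability

Trie-based off-target search tools only index sufficiently unique
spacers. We mirror that eligibility rule (`is_searchable()`): a guide is
*searchable* iff it has exactly one perfect genomic match (its on-target)
and zero 1-mismatch sites. Unsearchable guides get **no** score (`NA`),
not a score of zero — analyses exclude them, matching how such guides are
excluded from webtool output. A separate, older count-based rule
(`legacy_count_filter()`; at most 2/10/50/200 sites at 0/1/2/3
mismatches, strictly-greater fails) reflects alignment-based library
design pipelines and is kept as an independent predicate.

### CFD site scores and the aggregate

Each off-target site's relative cleavage propensity is its Cutting
Frequency Determination (CFD) score: the product over its mismatches of a
(position, guide base, target base) weight, times a PAM weight
(`cfd_site_score()`). The per-guide aggregate (`aggregate_specificity()`)
sums CFD over all 2–3-mismatch sites (1-mismatch sites cannot occur for a
searchable guide; the one 0-mismatch site is the on-target) and maps it to

$$ S \;=\; \frac{1}{1 + \sum_{\text{sites}} \mathrm{CFD}} \in (0, 1], $$

so a perfectly specific guide scores 1 and promiscuous guides approach 0.
The class set `{2, 3}` is configurable for sensitivity analyses.

**Weight table provenance.** The package defines a TSV format for the
weight table (`read_cfd_weights()`), keyed by guide-versus-target base on
the protospacer strand with position 20 PAM-proximal; tables shipped in
other conventions must be normalised at load (covered by a round-trip
test). The table vendored under `inst/extdata/` is **synthetic**
(`synthetic_cfd_weights()`): deterministic weights with the qualitative
structure of empirical CFD tables (tolerance decaying toward the
PAM-proximal end, identity-dependent factors, PAM suffix weights
GG = 1 > AG > GA > rest). All algebraic properties of the aggregate —
`score = 1/(1 + sum)`, strict monotonicity under site addition,
permutation invariance, the all-ones closed form `1/(1 + n)` — are
independent of the numeric weights, which is what the test suite
verifies. For scoring real designs, load the published empirical CFD
table into the same format.

## Library design rules

`sequence_filters()` evaluates independent predicates per spacer:

* GC in [0.20, 0.80] — failing *strictly* outside the bounds; whether the
  boundary itself passes is not standardised in the field, so exactly 20%
  or 80% passes here (configurable).
* no `TTTT` substring (Pol III terminator), no `GGGGG` 3' suffix
  (expression/PCR artefacts) — the suffix rule reads the 20-nt spacer's
  3' end, since the stated concern is the transcribed guide;
* no restriction recognition sites (`CTGCAG`, `GAAGAC`, `GTCTTC`,
  `CCANNNNNNTGG`, `GCTNAGC`, IUPAC-expanded) on **either strand** of the
  spacer. Restriction recognition is double-stranded; listing both BbsI
  orientations but checking one strand would silently miss the
  palindromic sites, so both-strand matching is made explicit.

`exclusion_overlap_filter()` drops guides with exact or 1-mismatch sites
overlapping (≥ 1 shared base, half-open intervals) exclusion regions such
as exons or DNase-hypersensitive sites. `select_motif_guides()` keeps
guides cutting inside the motif, at most 5 per site, ranked by
specificity with ties broken by distance of the cut from the motif center
and then guide id — a fully deterministic ordering, so designs are
byte-stable. Motifs with fewer than 2 surviving guides are flagged
under-covered, since element-level calls need concordant evidence.

Coordinates are 0-based half-open (BED convention) throughout; the cut
site is the standard SpCas9 blunt cut between spacer positions 17 and 18
(3 nt 5' of the PAM), recorded as the 0-based coordinate of the base
immediately 3' of the cut on the plus strand. Cas9 targetability
(`targetability_summary(mode = "cas9")`) requires the cut inside the
element; CRISPRi/a targetability requires the protospacer within the
element window (default ± 100 bp), reflecting the wider reach of
epigenome editors.

## Screen diagnostics

`guide_enrichment()` computes the guide-level log2 fold-change of
endpoint versus plasmid counts with explicit counts-per-million
normalisation and a pseudocount (default 1) added *after* CPM; replicates
are summarised by the arithmetic mean with standard error
`sd/sqrt(k)`. Screen-analysis suites embed enrichment in larger
maximum-likelihood machinery with unspecified internal normalisation; we
keep the quantity elementary and expose both knobs instead.

`quadrant_association()` cross-tabulates guides by depletion
(`mean log2FC <= -2` by default) and low specificity (`score <= 0.2`) and
tests independence with an exact Fisher test. The thresholds are the
screen-level conventions for "strong fitness effect" and "confounded";
for tiling screens with different dynamic range they are required
parameters, not silent defaults. `fisher_exact_2x2()` implements the
two-sided minimum-likelihood rule directly on the hypergeometric mass
with a 1e-12 relative tie tolerance (and p = 1 with a warning for
zero-margin tables); it is verified against exhaustive fixed-margin
enumeration for all tables up to N = 60. The odds ratio is reported
exactly, with infinity allowed on zero cells; a Haldane–Anscombe 0.5
correction is optional.

`call_elements()` calls an element essential when ≥ 2 of its guides are
depleted; single-guide evidence is reported separately because
concordance across independent guides is precisely what off-target
toxicity cannot fake. `specificity_filter_screen()` removes guides with
score ≤ 0.2, absent score, or unsearchable status, and reports the
removed fraction — re-calling elements after this filter is the
package's core diagnostic.

## Coverage rescaling

To compare ChIP coverage between experiments of different strength, each
track (RPM units) is multiplied by `max(FRiP)/FRiP_D`
(`rescale_coverage()`), so the strongest experiment is the anchor and all
scale factors are ≥ 1. FRiP (`compute_frip()`) is the fraction of reads
sharing ≥ 1 base with a merged consensus peak — the overlap rule is a
package choice, as is treating RPM conversion as a loader responsibility
(alignment and peak calling are consumed as inputs, not reimplemented).

## The synthetic-data model

The simulation module exists so every claim above is testable offline.

* `random_genome()` draws i.i.d. bases at a given GC content (default
  0.41, human-like).
* `implant_sites()` plants protospacer copies with controlled mismatch
  positions and PAMs, pre-scanning the background and mutating away
  chance near-matches, so the planted truth is *exactly* what a correct
  search must return — the cross-module oracle.
* `simulate_screen()` generates a pooled growth screen: plasmid
  abundances Dirichlet-uniform; endpoint abundance proportional to
  `plasmid * 2^(g * (e_on + e_tox * confounded))`; counts negative
  binomial with shared dispersion (the standard count-noise model for
  pooled screens, which have no published noise model of their own).
  Off-target toxicity enters as an additive per-doubling fitness term on
  the confounded (low-specificity) guides, reflecting the observation
  that confounded guides deplete like essential-gene guides.

Default study conditions: 1000 guides in elements of 5, 10% of elements
essential with `e_on = -0.6`/doubling, 30% of guides confounded with
`e_tox = -1.5`/doubling, 7 doublings, 500× per-guide depth, dispersion
0.05, 2 replicates. All randomness flows through one seeded generator
whose state is restored afterwards; count matrices are bit-identical per
seed.

What the simulation does *not* emulate: compositional copy-number
effects, chromatin-state-dependent off-target toxicity, guide cloning
biases, replicate batch structure, and the correlation between a guide's
true specificity score and its off-target *phenotype* (in the simulation
the confounded flag and score are drawn jointly by construction). Passing
the simulation tests therefore demonstrates correctness of the
statistical machinery under the stated generative model, not accuracy of
any biological prediction.

## Numerical and scale choices

* Spacer enumeration and site search are deterministic, sorted by
  (chrom, start, strand).
* Oracle-equivalence tests run 50 random spacers against a 200 kb planted
  genome (both PAM sets); simulation calibration uses 200 null seeds and
  100 confounded seeds; Fisher enumeration covers > 10^4 tables at
  N ≤ 60. These sizes give stable medians and full coverage of the
  boundary cases while keeping the default suite fast.
* Parameter-recovery checks regress observed mean log2FC on planted
  `g*e`; effects are kept within the count dynamic range, because
  near-total dropout saturates at the pseudocount floor and attenuates
  any estimator — a real phenomenon, not a simulation artefact.
* Degenerate inputs: empty site lists score 1; empty peak sets give
  FRiP 0; zero-margin Fisher tables return p = 1 with a warning;
  all-zero samples are an error, not a silent NaN.

## Worked example

```{r example, eval = FALSE}
# a confounded screen, simulated at the default study conditions
sim <- simulate_screen(screen_sim_config(seed = 1))
enrich <- guide_enrichment(sim$counts)

# is depletion associated with low specificity?
quadrant_association(enrich, sim$truth)

# element calls before and after specificity filtering
gmap <- sim$truth[, c("guide_id", "element_id")]
pre  <- call_elements(enrich, gmap)
post <- call_elements(specificity_filter_screen(enrich, sim$truth), gmap)
c(pre = sum(pre$called), post = sum(post$called))
```

## Known limitations

* Bulge/indel off-targets and on-target activity scores are out of
  scope; the search is Hamming-distance only.
* The aggregate score requires the vendored weight table to be meaningful
  for ranking; with the synthetic table, scores order guides sensibly but
  are not calibrated to cleavage measurements.
* Genome-scale search is designed for desk-scale genomes (up to a few
  Mb); indexing a full mammalian genome is a different engineering
  problem (trie/FM-index) deliberately not attempted here.
* Elements are treated independently; no multiple-testing correction is
  applied to element calls, which are threshold rules rather than
  hypothesis tests.
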