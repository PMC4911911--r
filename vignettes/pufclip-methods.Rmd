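---
title: "Peak calling and crosslink-site analysis for PUF iCLIP: models and design"
author: "pufclip maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak calling and crosslink-site analysis for PUF iCLIP: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufclip)
```

# The problem

iCLIP maps where an RNA-binding protein touches the transcriptome. UV light
covalently links the protein to RNA in vivo; after immunoprecipitation and
reverse transcription, most cDNAs *truncate* at the crosslinked nucleotide
and a minority read through it, frequently acquiring a deletion at the
crosslink. Sequenced reads therefore carry two single-nucleotide signals —
5'-end pile-ups (CITS) and deletion hotspots (CIMS) — on top of a peak-scale
signal of read density. The hard part is separating genuine binding from
background: iCLIP background is itself crosslinked and abundance-coupled, so
highly expressed transcripts produce read piles with no specific binding.

`pufclip` implements the full analysis for PUF-family proteins such as the
*C. elegans* germline regulators FBF-1/FBF-2: candidate peak discovery, six
peak-calling strategies that differ in their background model, enrichment
and reproducibility filters, binding-element (FBE) motif analysis, CIMS/CITS
crosslink inference, and binding-landscape statistics. A seeded synthetic
data generator provides a ground-truth world on which every step is
validated.

# Peak calling

**Candidates.** Local coverage maxima of at least `minHeight` reads
(default 10; the upstream peak-finder's exact parameters are not published,
so this is configurable) are extended until coverage falls below 20% of the
peak height (`borderFrac = 0.2`), and overlapping spans are merged, keeping
the maximum height.

**The test.** Read 5' ends are placed in 50-nt bins. For each candidate, the
tallest bin *within the candidate span* is tested against a background
distribution fitted to bins over a surrounding region — either the 500-bp
window centered on the peak maximum ("local") or all exons of the containing
transcript ("whole gene"). Three backgrounds x two regions give six methods:

| method | background | region |
|---|---|---|
| 1 | RNA-seq | whole gene |
| 2 | RNA-seq | local 500 bp |
| 3 | negative-control iCLIP | whole gene |
| 4 | negative-control iCLIP | local 500 bp |
| 5 | iCLIP signal itself | whole gene |
| 6 | iCLIP signal itself | local 500 bp |

Methods 1–4 fit a Gaussian by default (Poisson and method-of-moments
negative binomial are available; the negative binomial falls back to
Poisson when the variance does not exceed the mean). Methods 5/6 always use
a Poisson on the assumption that true peaks are sharp while background is
flat. Two numerical guards keep the fits defined on count data: the
Gaussian standard deviation is floored at 1 read, and an empty background
region gets a Poisson rate of one read spread over the region's bins.

**Depth normalization.** Negative-control libraries are routinely much
shallower than experimental ones (in the motivating data set, roughly 13–21
fold). A background fit on raw control counts cannot absorb a background
pile-up across that asymmetry, so `callPeaks()` scales background bin
counts by the ratio of total experimental to total background reads before
fitting (`depthNormalize = TRUE`, identity for the self background).
Without it, background pile-ups in a deep experiment dwarf their raw-count
image in a shallow control and pass the test as false calls.

**Correction.** Each peak's p-value is Bonferroni-multiplied by the number
of bins its background was modelled on; Benjamini–Hochberg is then applied
across the full candidate set (we read the two corrections as sequential)
and calls at q <= 1% FDR are kept. `bhAdjust()` is the package's own
step-up implementation, oracle-tested against the textbook definition.

**Filters.** The secondary filter keeps a peak only if experimental reads
in the 500-bp window centered on its maximum are at least fivefold the
negative-control reads there, with an empty control floored at one read
and an inclusive boundary. (The window, rather than the bare peak span, is
our reading of "within local (500 bp) peak region".) Replicate consensus
clusters peaks across replicates by single-linkage span overlap on the same
strand; a consensus peak needs support from `kRequired` replicates (3-of-3
per protein; 5-of-6 for a combined two-protein list). Heights can be
normalized to RNA abundance (RNA-seq reads per nucleotide of mature
transcript per million mapped, floored at 0.1 to keep unexpressed genes
finite).

# Motifs

The canonical FBE is `UGUNNNAU`; an upstream cytosine at -1 or -2 marks
high-affinity sites, and the in-vivo consensus is a -1/-2 C followed by
`UGURCCAUR`. `scanMotif()` does exact IUPAC matching (T read as U) with
upstream-context flags; `consensusMismatches()` anchors the consensus at a
site's UGU and counts violations over core positions 4–9 plus the
upstream-C requirement. `maskFBE()` blanks canonical matches with `X` (a
character that matches nothing) so alternate motifs can be scored
"exclusive of the canonical FBE", and `shuffleEnrichment()` computes an
empirical enrichment p-value against mononucleotide-shuffled sequences with
the add-one estimator `(1 + #{shuffle >= observed}) / (n + 1)`. We use
mononucleotide rather than dinucleotide shuffles because nothing stronger
is specified; dinucleotide content of peak windows is thus not preserved,
which slightly flatters U/G-rich motifs. The bundled motif table includes
the FBE-like 7-mer `UGURNAU`, its refined form `UGUGAAUR`, UGU/CUGU
half-mers and four U/G-rich "in-vitro-style" alternate elements. The exact
published alternate strings appear only in a figure, so the bundled
patterns are synthetic placeholders; the table is plain TSV and meant to be
edited.

# Crosslink sites

CIMS: for each position carrying deletions, the deletion count is tested
against Binomial(depth, r) with r the global deletion rate; CITS: the
crosslink is taken one base 5' of the read start (reverse transcriptase
stops one base 3' of the crosslinked nucleotide), and start counts are
tested against a Poisson whose rate is the containing gene's mean start
rate (reads outside annotation pool into a per-strand genome rate). The
upstream pipelines this emulates do not publish their exact nulls; the
binomial and Poisson forms were chosen because they are deterministic,
match the published P < 0.001 interface, and control type I error in null
simulations. P-values are left uncorrected, mirroring the published raw
threshold; sites must recur at the identical base in at least 2 replicates.
`crosslinkProfile()` aggregates sites by strand-aware offset from FBE
starts (U1 = 0) and normalizes to sum one.

# The synthetic world

`simConfig()` states the simulated world; `makeTranscriptome()`,
`simulateIclip()` and `simulateControls()` realize it deterministically
from one seed. Defaults: 200 single-exon transcripts of 0.8–3 kb laid out
with 150-nt spacers on both strands of one chromosome; log-normal
abundance (sdlog 0.5); 35% of transcripts carry one planted site
(canonical FBE with -1/-2C context, plain FBE, 7-mer, or an alternate
element, with mean specific-molecule rates 80/60/45/35 per unit abundance —
free parameters chosen for clear signal at desk scale, in the stated
affinity order). Sites sit mostly in 3'UTRs with a Beta(3,1) bias toward
the 3' end. Each site carries two crosslink positions drawn from a skewed
distribution on -10..+8 with mode -2, emulating predominantly upstream
crosslinking. Reads are 35 nt; cDNAs truncate at the crosslink with
probability 0.8, otherwise read through and delete the crosslinked base
with probability 0.6; each molecule gets a 7-nt random barcode and
1 + Poisson(1) PCR copies.

Background is the part of the world that decides which peak-calling methods
can work, and it is deliberately structured: each transcript receives
Poisson(2) "hotspot" positions shared between experiment and negative
control, and 40% of nonspecific reads truncate at a hotspot rather than
starting uniformly. This mimics crosslinked background binding — the reason
RNA-seq and self backgrounds underperform a negative-control iCLIP.
Hotspots are kept >= 60 nt away from planted sites (they model independent
background contacts). Hotspot piles scale like ~6x abundance versus
~40–60x for specific sites, so nonspecific enrichment ratios sit near 3
(below the fivefold cutoff) while genuine sites sit far above — the
separation that motivates the published cutoff of 5. The negative control
uses the same hotspots at a third of the background depth (shallower
control libraries, as in the motivating data); RNA-seq is uniform along
transcripts at rate 100 per unit abundance.

What the generator does **not** emulate: splice junctions (reads never span
exon boundaries and simulated transcripts are single-exon), sequencing
substitution errors, mappability structure, isoform mixtures, and
transcript-end effects beyond hard clipping. A green test on this world
shows the pipeline's statistics behave as designed under the stated
assumptions; it does not certify performance on real libraries.

On the default world, method 4 plus the fivefold filter and 3-of-3
consensus recovers at least 90% of planted sites with an empirical
false-call rate within 5%, and CIMS+CITS recover over 80% of planted
crosslink positions within 1 nt — the acceptance tests compute these
quantities fresh on every run.

# Numerical and design choices

* Coordinates are 1-based, closed (GRanges convention) everywhere; GFF3 and
  SAM need no conversion, BED output is converted on write.
* Duplicate collapse keys on (chromosome, strand, 5'-end, barcode) — an
  iCLIP molecule is defined by its truncation point — keeping the longest
  read, ties broken by read name. The cited EM-based collapse is
  unspecified in the source; exact collapse is deterministic and testable.
* Bonferroni's "number of bins used for modeling" is read as the bins of
  the candidate's own background region, not genome-wide bins.
* Self-background rates (methods 5/6) include the peak bin itself —
  the conservative reading of "background will uniformly look like flat
  coverage".
* Un-merging splits two maxima only when the valley between them is
  strictly below 20% of the smaller height; a valley exactly at threshold
  keeps one peak.
* Peaks map to genes by the transcript whose exons contain the peak
  maximum; among isoforms the longest mature transcript wins; region labels
  (5'UTR/CDS/3'UTR/ncRNA/intergenic) follow the maximum position, not span
  majority.
* Spearman p-values use the exact permutation distribution for n <= 9 and
  the t-approximation otherwise; Fisher tests are two-sided exact.
* Degenerate inputs: empty coverage yields no candidates; an empty
  background errors; `x_max = 0` always gives p = 1; empty RNA-seq yields
  zero density (floored); sub-bin-width candidate spans are padded to one
  bin around the maximum.

# Known limitations

The shallow-control + raw-count fivefold filter interaction means a single
unlucky control draw at a background hotspot can let a false peak through
both filters at once; at desk scale this keeps the empirical false-call
rate above zero, though within the five-percent criterion. The 7-mer and alternate-motif
tables necessarily contain placeholder patterns (see above). CITS
resolution is one base and assumes complete truncation at the crosslink;
partial-readthrough chemistry shifts a fraction of signal one base
upstream, which the +-1-nt recovery criterion absorbs.
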