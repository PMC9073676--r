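---
title: "Mapping meganuclease-mediated transgene integrations from WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meganuclease-mediated transgene integrations from WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

I-SceI-mediated transgenesis inserts a linearized plasmid cassette
(promoter + reporter + vector backbone, flanked by remnants of the 18-bp
I-SceI recognition site) into a host genome. Characterising the resulting
line requires three things that short-read whole-genome sequencing can
deliver at once: *where* the cassette landed (to base-pair resolution),
*how many copies* went in, and *what the junctions look like* — the last
being the footprint of the repair pathway that captured the transgene.
`isceimap` implements that analysis as a reusable, tested package, driven
by a synthetic-data generator that reproduces the geometry of a hemizygous
transgenic line so the whole pipeline runs and is verified at desk scale.

# The combined-reference strategy

The construct sequence is appended to the host assembly as an extra contig
(`build_combined_reference()`). Read pairs are then mapped **twice**:

* **end-to-end** — every read base must align. Fragments spanning an
  integration junction cannot align this way; their pairs surface as
  *discordant*, with one mate on the host and the other on the transgene
  contig ("junction pairs"). These bracket each site to within a fragment
  length.
* **local** — read ends may be soft-clipped. A read crossing a junction
  aligns its longer side and clips the rest; realigning the clipped
  substring to the other side of the reference ("split reads") places the
  breakpoint exactly.

The built-in aligner is a seed-and-extend design: exact k-mer seeds
(default k = 21, sampled every 5 read positions) vote for candidate loci,
which are scored with a three-state affine-gap dynamic program (match +1,
mismatch −4, gap of length *g* costs 6 + *g*; minimum reported score 20).
An alignment is *unique* when it beats the best alternative locus by at
least 2. These values are declared stand-ins: the original analysis used a
production aligner whose parameters are not printed, and any SAM produced
by such an aligner can be substituted through `read_sam()`. Ties between
equal-scoring placements break to the lexicographically smallest
(contig, position, strand) — deterministic, and it reproduces the
practically important case of a promoter shared between the genome and the
cassette: such reads all land on the host copy, flagged non-unique.

# Boundary calling and lesion classification

A *left* boundary is the last host base before inserted DNA, a *right*
boundary the first host base after it. Split-read breakpoints are
**leftmost-normalised** before clustering: microhomology between the host
flank and the construct terminus makes the split position non-unique, and
every valid representation is slid as far left as the sequences allow
(`normalize_breakpoint()`); the residual slide range is reported with each
boundary. Breakpoints within 10 bp then cluster to their modal position.
A boundary is reported when it has ≥ 3 split reads, or ≥ 1 split read plus
≥ 2 corroborating junction pairs — no call without evidence.

Left and right boundaries pair into sites when their construct termini are
opposite ends of the cassette, within 10 kb, minimising the summed
|left − right| offset. The relative order of the paired boundaries then
*is* the lesion:

* `right == left + 1` — blunt join;
* `right > left + 1` — target-site **deletion** of `left+1 .. right-1`;
* `right <= left` — target-site **duplication** of `right .. left`
  (the duplicated host stretch flanks the insert on both sides).

The site-to-site distance is the closest-boundary gap, the convention that
makes two adjacent insertions "108 bp apart" when one's right boundary is
at offset 212 and the other's closest boundary at offset 320.

# Copy number from coverage ratios

Under a Poisson sequencing model, read depth is proportional to how often a
region is present in the sample. For a hemizygous diploid with background
(pile-up) coverage *B*, a region present at *c* copies per diploid genome
shows *c·B/2*, so

```
copies_from_transgene = ploidy * region_depth / background_depth - endogenous_copies
```

with `endogenous_copies = 2` for a promoter the host already carries on
both chromosomes and 0 for cassette-only features. At a 20x background
this reproduces the worked figures: a shared promoter at 80x and a
cassette-only reporter at 60x both give 6 copies. The promoter must be
measured at its **host** locus — the shared reads all pile up there under
the tie-break rule above — while cassette-only features are measured on the
transgene contig, with non-unique reads retained inside the declared
promoter-homology regions (dropping them would carve a hole exactly where
the signal is).

Depth is GC-corrected with a deliberately simplified binned-ratio model
(1000-bp bins; mean binned depth per GC tenth over the global mean; classes
with < 3 bins inherit ratio 1). This replaces fragment-level GC correction
used in production pipelines; on desk-scale simulations without GC bias the
ratios are ≈ 1, and a planted multiplicative bias is removed to within 10%
(tested). Multi-copy regions (the transgene contig, shared promoter,
called-site vicinity) are masked from model *fitting* — otherwise they drag
their GC class upward and deflate their own corrected depth — but are still
corrected. The background is the median of binned corrected host depth
outside the mask.

**Precision.** The uncertainty of a feature's mean depth is set by its
length: roughly `depth / sqrt(depth * length / read_length)`, inflated
further because the two reads of one fragment are correlated. For a
3,900-bp promoter at 80x this is well under one copy after rounding; for a
700-bp reporter at 60x the fractional estimate has a standard deviation
approaching half a copy, so integer rounding can land on 5 or 7 in a
noticeable minority of simulations. This is a property of the study design
(region length × depth), not of the estimator; the reported Poisson
interval makes it visible. Tests therefore pin the promoter estimate
exactly and treat the reporter's as what it is — an estimate with
single-copy-scale uncertainty on a short feature.

# Junction microhomology and the MMEJ signature

The cleavage model (`cleavage_model()`) encodes the canonical 18-bp I-SceI
recognition sequence TAGGGATAACAGGGTAAT cut at top-strand offsets 9/5,
leaving the 4-nt 3′ overhang 5′-ATAA-3′ (the site sequence itself is an
external constant; the overhang is the printed anchor). Around each called
boundary, `mmej_report()` scans a 30-bp genomic flank against the construct
terminus joined there for maximal exact matches ≥ 3 bp (exact-only by
design — the motifs are a handful of bases, and fuzzy matching would flood
the report). Matches covering the terminal overhang bases and sitting
within 5 bp of the junction are labelled *overhang*; matches overlapping a
recognition-site remnant feature are labelled *recognition*. For each pair
of sites the upstream flanks are scanned against each other: ≥ 4 bp of
shared flank homology together with a target-site duplication at one site
flags the tandem-duplication signature — the configuration expected when an
initial MMEJ-mediated insertion is followed by homology-mediated
realignment that duplicates the insert and the intervening host bases.

# What the generator emulates — and what it does not

`study_scenario()` is the one-call study fixture. Its defaults are the
study conditions, not tuning knobs: 2×101 bp pairs from Normal(350, 35)
fragments; pile-up coverage 20x (each haplotype at 10x — hemizygosity is
modelled explicitly as one transgenic plus one wild-type haplotype);
substitution errors at 0.001/base; a ~7.6-kb construct
(13-bp left site remnant, 3,900-bp promoter, 700-bp reporter CDS, 3,000-bp
vector, 9-bp right remnant); six construct copies split 3 + 3 head-to-tail
across two sites whose boundary offsets encode an 11-bp deletion, a 15-bp
duplication and a 108-bp inter-site gap; the endogenous promoter planted
half a chromosome away; and planted junction microhomology (a
recognition-site motif upstream of site 1, genomic ATAA immediately
downstream of site 2, an 8-bp motif shared by both upstream flanks). The
copy arrangement (3 + 3, head-to-tail) is an assumption recorded in the
truth object — the real line's arrangement is not printed, only that
copy–copy boundaries exist.

Deliberately **not** modelled: indel sequencing errors (rate parameter
exists, defaults to 0 — substitutions suffice to stress the soft-clip
logic), PCR/optical duplicates, quality-score profiles, adapter
read-through, mappability structure of a real 1.4-Gb genome, and
structural variation beyond the insertions. Passing tests therefore show
the *method logic* is right at realistic depth/noise, not that a real
genome's repeat landscape is handled; on real data the aligner is expected
to be replaced by a production mapper via SAM import.

# Numerical choices

* Internal coordinates are 0-based half-open; everything printed is 1-based
  inclusive.
* Head-to-tail tandem junctions in a concatemer are sequence-identical, so
  they are reported once with pooled support — read evidence cannot count
  them separately (the copy number comes from coverage, not junction
  counts).
* Boundary clustering uses the modal position (ties to the smallest);
  degenerate inputs (empty alignment sets, empty site lists, wild-type
  genomes) return empty-but-typed results, tested as negative controls.
* Split-read remapping requires the clip's junction-proximal end to align
  exactly; clips failing this are silently dropped (counted in the
  dropped-candidates table).
* Thresholds (min_clip 20, window 10, min_support 3, min_pair_support 2,
  max_span 10 kb) are declared defaults, all configurable via
  `pipeline_config()`.

# Problem sizes

The package's own test and acceptance runs use a 1-Mb toy chromosome
(≈ 100k read pairs, both alignment modes, ≈ 1–2 min end to end) for the
full-recovery checks, and a 150-kb variant with identical locus geometry
for unit-level fixtures. These sizes were chosen so that every stage,
including the quadratic-oracle comparisons, runs comfortably on a laptop
while keeping per-boundary split-read support in the range reported for real lines
(a handful to a dozen reads).

# Known limitations

* The toy aligner indexes the forward strand only and evaluates at most 8
  candidate loci per strand; it is not a substitute for a production
  mapper on repeat-rich genomes.
* GC correction is binned, not fragment-level; strong bias coupled with
  short features would leave residual error.
* Boundary pairing enumerates matchings exhaustively only up to 6 × 6
  boundaries, then falls back to a greedy assignment.
* Orientation-mixed concatemers are typed junction-by-junction; full
  reconstruction of an arbitrary copy arrangement from short reads alone is
  underdetermined and out of scope.
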