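---
title: "Resolving dyad methylation from MspJI cut-edge geometry"
author: "hemidyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving dyad methylation from MspJI cut-edge geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(hemidyad)
  library(GenomicRanges)
})
```

## The measurement model

A CpG (or CHG) dyad is the pair of cytosines facing each other on the two
DNA strands. Bisulfite-free dyad resolution exploits the
methylation-dependent restriction enzyme MspJI: it recognizes a methylated
CNNR motif (R = A/G) and cleaves 9 nt downstream on the methylated strand
and 13 nt downstream on the other, leaving a 4 nt 5&prime; overhang. When
a dyad sits in a palindromic YNCGNR context (Y = C/T), *each* strand
carries its own CNNR motif, so the enzyme reads the two methyl marks
independently:

* **fully methylated** — cuts on both sides release a characteristic
  32 bp fragment whose YNCGNR 6-mer sits at the center;
* **hemi-methylated** — a single cut; one fragment edge matches that
  strand's cut site and the fragment runs past the other;
* **unmethylated** — no cut; fragments span the dyad with neither edge
  at a cut site.

`hemidyad` models fragment boundaries at the far (13 nt) cut only; the
overhang is bookkeeping exposed through `mspjiCutModel()`. With the
Watson-strand cytosine at 0-based position $p$ and its partner at $q$
($q = p+1$ for CpG, $p+2$ for CWG), the boundaries are $p + 17$ and
$q - 16$ (0-based half-open offsets). This single convention reproduces
the validated construct digests exactly — 57/32/57 bp for full
methylation, 89/57 bp for Watson-only — and places every cut-created
fragment edge 13 bp beyond the motif. A CWG dyad under the same
arithmetic yields a 31 bp doubly-cut product; that length follows from
the geometry rather than from any published measurement.

In-memory containers are Bioconductor-native (1-based, closed
`GRanges`); cut offsets and all on-disk BED/bedGraph coordinates are
0-based half-open. Crick-strand sites are always indexed by the Watson
coordinate of the paired base, so the package uses one coordinate system
throughout.

```{r construct}
g <- plantConstruct()
m <- uniformDyadMethylome(g, "me")
mol <- sampleMolecules(m, 1, seed = 1)
bp <- breakpointsForMolecule(g, mol,
                             DigestionParams(efficiencyByR = c(A = 1, G = 1)))
width(digestMolecule(146, bp$construct))
```

## Calling dyads from fragment edges

`countDyadStatuses()` classifies every deduplicated fragment against
every overlapping resolvable dyad by exact edge matching: `me` needs both
edges at the cut sites, `hemiW`/`hemiC` one matching edge with the
fragment extending past the partner cut, `unme` a strict span of both cut
sites. Exact integer matching (no slop window) is deliberate: the
simulator is exact, and tolerance windows for real-data wobble are a
mapping-layer concern outside this package's scope. Two further choices:

* Fragments whose matching edge is real but whose other end falls short
  of the partner cut site carry **single-strand evidence only**
  (`strandOnlyW`/`strandOnlyC`). The partner strand's state is
  unobservable on such a molecule, so these tallies feed strand-level
  cytosine calls but never dyad coverage.
* Fragments shorter than the inter-cut interval with no matching edge
  are `no_call`.

Dyads need **more than four** classified fragments (default
`minDyadCoverage = 5`) to enter analysis; the hairpin-side
predominant-status rule uses its own threshold of 3. Both surface as
configuration. Deduplication collapses records by (chrom, start, end,
UMI), keeping the first occurrence after a stable sort — UMIs are
necessary because 32 bp fragments are positionally degenerate.

## Count normalization

Digestion efficiency depends on the motif's downstream R base: methylated
CGNG-type sites are cut near-completely (~97%) while CGNA-type sites
reach only ~80%. A truly fully-methylated dyad therefore leaks into the
observed hemi and unme classes. With true counts $M, W, C, U$, strand
efficiencies $E_W, E_C$, and 32 bp purification efficiency $E_{pu}$:

$$M_{exp} = M\,E_W E_C E_{pu}$$
$$W_{exp} = W + M\,E_W (1 - E_C)$$
$$C_{exp} = C + M\,(1 - E_W) E_C$$
$$U_{exp} = U + M\,(1 - E_W)(1 - E_C)$$

`forwardExpected()` implements these equations exactly as stated, in
which the true hemi counts carry no efficiency factor of their own.
Whether that omission is intentional is not documented, so the package
does not guess: an optional `mode = "extended"` additionally scales hemi
counts by their single cut's efficiency ($W E_W$, $C E_C$), and the
stated form stays the default. `invertObserved()` solves the system the
other way; small-count noise can push estimates below zero, and such
values are clamped to 0 with a per-dyad flag (negatives within 1e-9 are
treated as float jitter and clamped silently). Efficiencies are assigned
per dyad from its own R bases (`assignEfficiencies()`), never from
genome-wide averages. $E_{pu}$ is treated as a known instrument
parameter applying sharply to 32 bp fragments — the form the equations
imply — not as a smooth size-bias curve.

The forward equations double as the empirical oracle for the simulator:
at $10^4$ molecules over an always-methylated dyad with mixed
efficiencies, the observed multinomial matches the predictions within
3 standard errors, and the inversion recovers the pure full-methylation
composition within 2% (this is asserted in the test suite).

## The hairpin-bisulfite oracle

`simulateHairpinReads()` emulates the orthogonal readout in which both
strands of one molecule are sequenced after hairpin ligation: each
cytosine reads C if methylated and T if converted, with
`conversionRate` (default 0.99) for unmethylated and `failureRate`
(default 0) for methylated cytosines. Reads are generated directly as
per-strand base strings over windows — no FASTQ round-trip and no
aligner, because the oracle's job is cross-validation of the fragment
caller, not read mapping. The linker carries known unmethylated
cytosines from which `estimateConversionRate()` recovers the conversion
rate by counting. Per-dyad statuses aggregate by the
**predominant-status rule**: at least 3 observations, unique maximum
wins, ties are excluded (there is no canonical convention for ties, so
the package excludes and flags rather than guessing).

Concordance between the two routes is asserted at `conversionRate = 1`:
with deterministic per-dyad states the two instruments must agree on
100% of co-covered dyads, and any disagreement is a bug. Conversion
noise is tested separately: at `conversionRate = 0.9` an unmethylated
dyad leaks into hemi/me at the analytic rates
$(0.81, 0.09, 0.09, 0.01)$ within 3 SE.

## Downstream statistics

* `assignRegionCluster()` maps a designated dyad's predominant status to
  the four motif clusters (1 unme, 2 motif-strand hemi, 3 opposite-strand
  hemi, 4 me). Orientation comes from the region's strand column; on
  `-` regions hemiW/hemiC swap roles and offsets count along the motif
  strand from its 5&prime; end.
* `orientedHemiProfile()` bins dyads by signed offset from region
  centers (sign flipped for `-` regions) and averages same-strand and
  opposite-strand hemi fractions; flipping every orientation mirrors the
  profile exactly, which the tests assert.
* `binomialBiasTest()` tests SNPs with coverage strictly greater than 10
  (i.e. `minCoverage = 11`) two-sided against 0.5 with the exact
  binomial test and adjusts with Benjamini–Hochberg, the standard FDR
  default (the adjustment procedure is configurable). Regions owning at
  least one bias-SNP are flagged allele-specific.

## What the synthetic generator does and does not emulate

`makeGenome()` draws i.i.d. bases at a chosen GC content; at
`gc = 0.5` the YNCGNR constraint is met by 1/4 of CpG dyads in
expectation (independent Y and R, each probability 1/2), which the
1 Mb acceptance check measures. `makeMethylome()` assigns each selected
dyad a fixed true status (default mix 25/25/25/25) and writes a truth
table; `makeAlleleModel()` draws balanced SNPs at proportion 0.5 and
imprinted SNPs at 0.95.

Two generator decisions deserve emphasis:

* **Designed dyads are isolated** (`minGap = 50` bp). MspJI cuts land up
  to 17 bp from the cytosine, so two methylated sites within ~33 bp can
  split each other's diagnostic fragments or, worse, drop a breakpoint
  exactly onto a neighbour's cut offset, creating a false edge match.
  Per-dyad statuses are then not geometrically identifiable from
  fragment edges — a property of the assay, not of this implementation.
  Round-trip scoring therefore runs against the emitted truth table of
  designed, spaced dyads; dense real methylomes will contain ambiguous
  configurations that these tests deliberately do not cover.
* **The 146 bp construct uses a `TTCGAA` motif.** The validation
  geometry requires exactly one CNNR site per strand; placing any G at
  the motif's N/R positions creates an extra Crick-strand CNNR site, so
  TTCG{A/T}A on an A/T background is the only context satisfying the
  constraint. The construct is generated programmatically from this
  geometric constraint; the digest lengths depend only on the cut
  arithmetic, not on the oligo's exact sequence. Tests that need
  distinct strand efficiencies use a `TTCGGG` variant and tolerate its
  two extra — always unmethylated, hence inert — strand-level sites.

Also note: multinomial-consistency checks run with deduplication off.
At $10^4$ molecules over a single 146 bp construct, every doubly-cut
fragment shares coordinates, and the 8 nt UMI space ($4^8$) would lose
~7% of genuinely distinct molecules to birthday collisions; with
`duplicateRate = 0` there is nothing to deduplicate, so switching it off
removes a pure artifact of the fixture geometry.

Not modelled at all: sequencing errors and quality scores, alignment and
mapping-quality filtering, UMI sequencing errors, smooth size-selection
curves, chromatin tracks beyond arbitrary numeric signals, and 5hmC
(treated as 5mC throughout).

## Problem sizes and runtime posture

The test and acceptance workloads are sized for a laptop-class single
core: 1 Mb genomes for motif statistics, 100 kb genomes with 50
molecules for round-trip calling, $10^4$ molecules for multinomial
convergence, $10^5$ cut sites for the in-silico digest length
distribution, and 1000 SNPs for error-rate and power checks of the
allele tests. All generators are deterministic under a seed; stochastic
assertions use 3-standard-error bands at those sizes.

## Known limitations

* Exact edge matching means real libraries with end-repair wobble need
  upstream normalization of fragment ends before calling.
* The efficiency model is per-R-base Bernoulli with independence across
  sites and strands; processivity or steric interference between nearby
  cut sites is not modelled (duplicate breakpoints simply collapse).
* `CNNR` strand-level calls within 3 bp of a contig end are dropped,
  since the motif cannot be completed; they are not padded.
* Star activity (off-target cutting of unmethylated sites) defaults to
  0, matching the observation that unmethylated templates are barely
  digested; it is exposed for robustness experiments only.
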