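# hemidyad

Most of what is known about DNA methylation treats a CpG site as a single
unit, yet the two cytosines of a CpG (or CHG) dyad can disagree:
hemi-methylated dyads arise during replication and de-novo methylation,
are heritable, and repress transcription-factor binding much like full
methylation. Resolving the three states — unmethylated, hemi-methylated
on either strand, fully methylated — normally requires hairpin bisulfite
sequencing, with all the degradation and base-conversion artifacts
bisulfite brings.

`hemidyad` implements the computational core of a bisulfite-free
alternative built on the methylation-dependent restriction enzyme MspJI.
MspJI cuts 9/13 bp downstream of a methylated CNNR site, leaving a 4 nt
5′ overhang. Inside a palindromic **YNCGNR** motif each strand of a dyad
carries its own CNNR motif, so the enzyme reads the two strands
independently and the *fragment edges* encode the dyad state:

* both cuts → a characteristic **32 bp** fragment (fully methylated),
* one cut → one fragment edge exactly 13 bp past the motif
  (hemi-methylated, strand given by which edge matches),
* no cut → fragments span the dyad (unmethylated).

The package provides, for R / Bioconductor users (GRanges, Biostrings,
S4 classes throughout):

* a seeded **digestion & library simulator** (`simulateLibrary`,
  `insilicoDigestLengths`) with per-motif cutting efficiencies,
  size selection, 32 bp purification efficiency, UMIs and PCR duplicates;
* the **dyad caller** (`countDyadStatuses`, `callCytosineLevels`) mapping
  deduplicated fragment records (BED + UMI) to per-dyad status counts and
  strand-level methylation;
* the **count normalization** for incomplete digestion — with
  efficiencies `E_W`, `E_C` and 32-mer purification `E_pu`,
  `M_exp = M·E_W·E_C·E_pu`, `W_exp = W + M·E_W·(1−E_C)`,
  `C_exp = C + M·(1−E_W)·E_C`, `U_exp = U + M·(1−E_W)·(1−E_C)` — and its
  inversion (`forwardExpected`, `invertObserved`);
* a **hairpin-bisulfite oracle** (`simulateHairpinReads`,
  `hairpinDyadCalls`) that re-measures the same synthetic molecules by an
  independent route, plus linker-based conversion-rate estimation;
* **downstream statistics**: motif cluster assignment
  (unme / motif-strand hemi / opposite hemi / me), orientation-aware
  hemi-methylation profiles, window signal annotation, and
  allele-specific methylation tests (exact binomial, BH-FDR);
* **synthetic data generators** for genomes, designed methylomes with
  truth tables, allele models, and the 146 bp single-dyad validation
  construct.

## Worked example

The validation construct is a 146 bp duplex with one resolvable CpG dyad
(Watson-strand C at 0-based 72). Digesting it fully methylated at unit
efficiency:

```r
library(hemidyad)
library(GenomicRanges)

g   <- plantConstruct()
m   <- uniformDyadMethylome(g, "me")
mol <- sampleMolecules(m, 1, seed = 1)
bp  <- breakpointsForMolecule(g, mol,
            DigestionParams(efficiencyByR = c(A = 1, G = 1)))
bp
#> $construct
#> [1] 57 89
width(digestMolecule(146, bp$construct))
#> [1] 57 32 57
```

The two cuts at offsets 57 and 89 release the central 32-mer — the
doubly-cut signature — flanked by two 57 bp fragments; Watson-only
methylation instead gives 89 + 57. Simulating a library at the realistic
efficiencies (~97% for CGNG-type motifs, ~80% for CGNA-type; both strands
of this construct are CGNA-type) and calling it back:

```r
frags <- simulateLibrary(g, m, DigestionParams(),
                         LibraryParams(nMolecules = 2000), seed = 42)
calls <- countDyadStatuses(frags, scanDyads(g, "CpG"),
                           CallerConfig(dedup = FALSE))
dyadCounts(calls)
#>      unme hemiW hemiC   me
#> [1,]   82   310   303 1305
```

Although every molecule is truly fully methylated, incomplete digestion
(0.80 per strand here) makes ~15% of molecules look hemi-methylated and
~4% unmethylated — exactly the leakage the normalization equations
describe (expected 80/320/320/1280). Inverting them recovers the truth:

```r
corr <- normalizeDyadCalls(calls)
#> Warning: 1 dyad(s) produced negative estimates; clamped to 0
as.data.frame(mcols(corr))[, c("corrUnme","corrHemiW","corrHemiC","corrMe")]
#>   corrUnme corrHemiW corrHemiC corrMe
#> 1      0.4         0         0 2039.1
```

The corrected composition is ~100% fully methylated (2039 vs 2000 true
molecules, within sampling noise; the slightly overshooting hemi
subtractions clamp at zero and are flagged).

A thin CLI over the same functions ships at
`inst/scripts/hemidyad-cli.R` with subcommands `make-fixtures`,
`simulate`, `call` and `analyze`.

## Scope

Read trimming, alignment, BAM handling and real-genome annotation are
out of scope: the caller starts from fragment coordinates (the product
of a bamToBed-style conversion) and the simulators generate everything
else. See `vignettes/hemidyad-methods.Rmd` for the model, parameter
choices, and what the synthetic tests do and do not demonstrate about
real libraries.
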