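---
title: "Quantifying 5'-end GC gradients, amino-acid cost and start-codon mRNA structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 5'-end GC gradients, amino-acid cost and start-codon mRNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcgradient)
```

## The problem

Eukaryotic coding regions carry a characteristic compositional signature at
their 5' ends: GC content is elevated near the start codon and decays along
the direction of translation, with the decline setting in only after roughly
the 25th codon. Because the genetic code couples nucleotide composition to
amino-acid identity differently at different codon positions, this gradient
can be decomposed by site degeneracy. At nonsynonymous (ns) sites — positions
where every substitution changes the encoded residue — higher GC content
implies energetically cheaper amino acids, so a 5'-elevated ns-site GC
gradient is read as selection for cheap residues at protein N-termini. At
two-fold (2s) and four-fold (4s) synonymous sites the gradient reflects
other forces (transcription efficiency, local mRNA structure) and varies
between lineages. Elevated start-region GC has a cost of its own: it
stabilises local mRNA secondary structure around the start codon, which
impedes translation initiation.

`gcgradient` implements this entire analysis as a reusable pipeline —
degeneracy classification, positional profiling, the gradient slope
statistic, biosynthetic-cost profiles with the saved-ATP estimate,
sliding-window folding scans, expression stratification — together with a
synthetic genome generator that provides ground-truth data for every stage.

## Site classification

Every position of every sense codon is classified by counting, against the
standard genetic code (NCBI table 1), the alternative nucleotides whose
substitution preserves the encoded amino acid: 3 synonymous alternatives
make a 4s site, 1 or 2 a 2s site, and 0 an ns site. Substitutions that
create a stop codon count as nonsynonymous. Two conventions were genuinely
open and are settled as follows, both configurable where meaningful:

* Three-fold degenerate third positions (isoleucine ATT/ATC/ATA) fold into
  the 2s class by default (`threefold = "separate"` reports them apart).
  Only the named 4s/2s/ns trichotomy is used downstream.
* Partially synonymous first positions (leucine TTR/CTR, arginine CGR/AGR)
  classify by their synonymous-alternative count, which makes some first
  positions 2s. This follows the substitution-counting rule literally
  rather than special-casing six-codon families.

Under these rules the 61 sense codons contribute 183 site slots: 116 ns
(63.4%), 35 2s and 32 4s — the familiar "about 60% of codon sites are
nonsynonymous". The test suite checks the full 64-codon table against an
independent brute-force enumerator built on a different translation engine.

## Positional profiles and the slope statistic

```{r profiles, eval = FALSE}
sim <- generate_genome(synthetic_spec(seed = 1))
genome <- filter_valid(sim$genome)
prof <- positional_mean(genome, fragment = "START", site_class = "NS")
fit_gradient(prof)
```

Genomes are reduced to one representative transcript per gene (the longest
cDNA; ties broken by smallest transcript id) and filtered: the annotated
CDS must be at least 900 nt (threshold applied before stop-codon stripping,
matching annotation-level lengths), a multiple of 3, and ATG-initiated
(configurable — non-standard starts are rare enough not to affect profiles,
but the check keeps codon 1 interpretable). Records with internal stops are
retained but flagged rather than silently dropped.

Three non-overlapping 100-codon fragments are cut from each CDS after
removing the terminal stop (stops encode nothing and would distort class
profiles): `START` is codons 1–100, `END` the last 100, and `MIDDLE` is
centred deterministically at `floor((L-100)/2)+1` so reruns are exactly
reproducible. Per-position values are averaged per gene first and then
across genes, never pooled by site count, and masked codons (e.g. the
positively charged residues K/R/H plus proline, or the essential-residue
set) leave holes without renumbering positions.

The gradient statistic is an ordinary least-squares fit of the per-position
mean GC (in percent) on the raw codon index over codons 26–100 — the first
25 codons are excluded because they sit under distinct initiation-related
constraints. The per-codon coefficient is reported ×100, so a slope of −5
means GC falls five percentage points per 100 codons. The fit range is a
parameter (extending to codon 150 on longer fragments is supported); no
weighting by per-position gene counts is applied.

## Costs and the saved-ATP estimate

Amino-acid costs (ATP equivalents, i.e. high-energy phosphate bonds per
residue, aerobic values of the Akashi type) are bundled as an editable TSV;
they are configuration, not code. The bundled nucleotide cost file is a
constructed stand-in (named `_synthetic` accordingly) that preserves only
the ordering that matters conceptually — G and C cost more than A and T —
and is carried as metadata: no computation consumes it. Positional cost
profiles average the cost of the encoded residue per codon position; the
cost gradient is fitted over the same 26–100 window but reported on the raw
per-codon scale, because the saved-ATP statistic

\[ \text{saved ATP} = \text{slope} \times \frac{n}{2} \times 100 \]

consumes it directly, with `n` the number of regression codons. With the
default fit range, `n = 75`; a human-like slope of 0.0082 then gives 30.75
ATP equivalents saved per protein over the first 100 codons — the package's
default `n` because it reproduces the ~30-ATP figure that the 26–100
regression window implies (with `n = 100` the same slope would give 41).

## Folding windows

Local secondary-structure propensity around the start codon is scanned with
39-nt windows — one codon at the centre plus 18-nt flanks — advancing 3 nt
per codon. Windows for the first codons extend into the 3' end of the
5'-UTR; when the UTR is too short the window is truncated at the transcript
end, recorded as such, and excluded from cross-gene means by default (a
26-nt window is not comparable to a 39-nt one).

Folding engines are pluggable. When the ViennaRNA `RNAfold` executable is
on the `PATH`, `vienna_engine()` (the `default_engine()` in that case)
provides thermodynamic minimum free energies with default parameters. The
package also ships `bundled_fold()`: a Nussinov-style base-pair
maximisation dynamic program with stated constants — pair scores GC = −3,
AU = −2, GU = −1, minimum hairpin loop of 3 unpaired nucleotides. Its
values are kcal/mol-like but are not free energies; every analysis herein
therefore uses folding scores only comparatively (between codon positions
or expression bins), never as absolute energies, and the test suite
verifies the bundled engine against exhaustive enumeration of nested
pairings on short sequences.

Expression stratification uses rank-based equal-sized bins (1 = lowest to
4 = highest by default). Ties break deterministically by gene id, earlier
bins absorb the remainder when sizes cannot be equal, and zero-abundance
genes stay in the lowest bin; these choices are arbitrary but documented
and stable.

## The synthetic generator

`generate_genome()` emulates the statistical structure the pipeline is
meant to detect: per-codon-position expected GC at ns/2s/4s sites following
linear gradients over the first 100 codons (ns starting from
`gc_start_ns`, the synonymous classes from `baseline_gc`), a flat baseline
elsewhere, optional fixed-length 5'-UTRs at baseline composition,
lognormal expression abundances, and an optional coupling that raises
start-fragment GC targets by a fixed step per expression bin. Codon 1 is
always ATG, stops are never sampled internally, and a terminal stop is
appended, so every generated gene passes the default validity filter.

The generator's defaults are the tetrapod-like condition: 2000 genes of
300 coding codons, ns-site GC 60% at the start falling 5 points per 100
codons, flat synonymous classes at a 50% baseline, 50-nt UTRs, and
lognormal(meanlog 2, sdlog 1.5) abundances — TPM-like in scale. These are
fixed study conditions, not tuning knobs.

Two design points deserve explanation:

* **Exponential tilting.** For each position (and expression stratum) the
  sense-codon distribution is reweighted as
  \(w(c) \propto q(c)\,e^{\alpha g_{ns}(c) + \beta g_{2s}(c) + \gamma g_{4s}(c)}\),
  where \(g_k(c)\) counts G/C nucleotides at class-\(k\) sites of codon
  \(c\) and \(q\) is the usage prior (uniform by default; a human-like
  per-thousand table is bundled). The three tilting parameters are solved
  numerically so the *conditional* per-class GC expectations — exactly the
  quantity the profiler averages — hit their targets; solutions are cached
  by target. Because amino-acid identity and degeneracy composition co-vary
  with the tilt, targets are met in expectation rather than per codon.
* **Balanced sampling.** At each position, codon counts are allocated as
  `floor(n·w)` plus a multinomial draw on the fractional remainders (the
  expectation is exactly `n·w`), then permuted randomly across genes.
  Compared with i.i.d. sampling this suppresses the between-replicate
  variance of per-position means, so realized profiles track their targets
  to within a fraction of a GC point at every position and slope recovery
  is tight. The cost is realism: gene-to-gene compositional heterogeneity
  is far smaller than in real genomes, positions are independent (no
  codon-pair or amino-acid autocorrelation), UTRs are i.i.d. nucleotides,
  and expression is independent of everything except the explicit GC
  coupling. Passing recovery tests therefore demonstrates correctness of
  the estimators, not their power on noisy biological data.

## Numerical choices and degenerate inputs

* OLS fits require at least 3 defined positions; missing positions are
  dropped, never imputed. A constant profile has slope 0 and undefined
  R² (reported `NA` rather than `NaN`).
* The cross-genome regression refuses a constant GC predictor, and its
  zero-crossing (`gc_threshold_crossing()`) is `NA` with a warning for a
  zero slope.
* GC targets outside [5, 95] are clamped with a warning; the tilting solver
  warns if its residual exceeds 1e-4 in GC-fraction units.
* N-containing codons are unclassifiable: they are kept in masks but drop
  out of every average; `coding_gc()` excludes N from both numerator and
  denominator and errors when nothing countable remains.
* Filtering an already-filtered genome is a no-op; profiles are invariant
  to gene order.

## Problem sizes

The shipped tests and examples run on deliberately small instances chosen
to exercise every code path at interactive speeds: recovery experiments use
2000 genes × 300 codons per genome across 20 seeds, folding comparisons use
a few hundred genes over the first 10–15 codon centres with the bundled
engine, and cross-genome panels use a handful of synthetic species. All
sizes scale up linearly through the same interfaces.

## Known limitations

* Only the standard genetic code is supported; organisms with variant
  codes would need a different classification table.
* GFF3 handling targets transcript-relative annotations with `CDS` and
  `five_prime_UTR` features grouped by `Parent` (the layout the bundled
  writer emits and typical cDNA-coordinate exports use); GTF is not read.
* The bundled folding surrogate ignores stacking, loop entropies and
  pseudoknots; absolute values are not comparable across engines.
* Cross-genome regressions are plain OLS within groups; no phylogenetic
  correction is attempted.
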