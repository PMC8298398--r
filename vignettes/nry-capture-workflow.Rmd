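---
title: "Ancient-DNA NRY capture analysis: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancient-DNA NRY capture analysis: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrykit)
```

## The scientific problem

The non-recombining region of the Y chromosome (NRY) is inherited as a
single haploid locus, so its history is strictly tree-like: every male
lineage carries the derived alleles of all SNPs on its root-to-tip path and
the ancestral alleles of every other branch. The ~10.4 Mb "mappable" subset
of the NRY — regions where the short reads typical of ancient DNA map
uniquely — is long enough that, despite a substitution rate around
`8e-10`/site/year, a single lineage picks up a new substitution roughly
every century:

```{r waiting}
expected_waiting_years(7.77e-10, 10445000)   # slow NRY rate, mappable NRY
expected_waiting_years(1.95e-8, 16569)       # fast mitogenome rate
```

That ~25-fold advantage in temporal resolution over the mitogenome is the
motivation for capture assays that target the whole mappable NRY rather
than a fixed panel of known Y SNPs. This package implements the analysis
side of such a workflow: assay coverage comparison, pileup-based
haplogroup assignment, contamination screening, consensus/alignment
construction, diagnostic-SNP discovery, and calibrated pairwise TMRCA
estimation — plus a simulator that generates all inputs with known truth.

## Coordinate conventions

BED target intervals are 0-based half-open; SNP catalogues are 1-based.
The two conventions meet in exactly one place, `in_regions()`: a SNP at
1-based position `p` lies in `[start, end)` iff `start <= p - 1 < end`.
Coordinates are interpreted in a single fixed reference build (the hs37d5
chrY space of the catalogues); no liftover is attempted. Pileups are
strand-folded on input because haplogroup SNP tables are strandless;
deamination orientation is handled separately via the allele pair.

## Assay coverage comparison

`coverage_fraction()` scores a SNP catalogue against an assay's target
regions; `expand_windows()` models the extra flanking sequence a tiled
probe recovers around a panel SNP. The window default is 120 bp total
(60 bp on either side, window length 121 including the SNP base itself).
The probe literature also suggests 52 bp flanks; the width is therefore an
argument, not a constant. `haplogroup_snp_set()` collects the SNPs of a
clade plus its descendants up to a branch depth (default 3), which is how
per-haplogroup assay resolution is scored.

Per-library counts are comparable only after normalizing by sequencing
effort (`normalize_per_unit()`, default per five million quality-filtered
mapped reads). Enrichment between modes is tested with a one-sample t-test
on log fold-changes (`enrichment_tests()`); the log scale makes "no
enrichment" symmetric around zero, and the test is exact under lognormal
folds. No particular test is canonical for this design; the t-test on logs
is the conventional choice and its size/power are verified by simulation
in the test suite. Preservation dependence is checked with a
product-moment correlation (`endogenous_correlation()`; rank correlation
available). Empirical comparisons should first drop libraries with
shotgun endogenous DNA ≤ 0.1% (`filter_library_stats()`).

## Haplogroup assignment

`tally_snp_calls()` reduces a pileup to one row per covered catalogue SNP:
derived reads, ancestral reads, other reads, and the *difference*
(derived − ancestral). The sign convention is: positive difference =
evidence for the derived allele, which is what makes the set of
positive-difference SNPs trace the root-to-terminal path.
`call_haplogroup()` aggregates differences per branch and walks the tree
from the root, descending only into branches whose aggregate support
reaches `min_support` (default 1 read); the call is the deepest node
reached. An uncovered branch therefore blocks automated descent — the
exported reports (`export_reports()`: positive-only CSV and all-SNPs CSV)
exist precisely so a reviewer can distinguish "basal branch uncovered"
from "basal branch contradicted". Branches carrying both positive and
negative SNP differences are reported as conflicts but do not abort the
call, mirroring a manual-review workflow.

Deamination shows up as C→T (and, strand-folded, G→A) derived calls.
These are flagged at tally time from the allele pair alone;
`flag_damage_suspects()` additionally selects the calls worth manual
inspection — damage-type pairs supported by a single read close to a read
end (`min_reads = 2`, `min_offset = 5` bp by default).

## Contamination screening

On a haploid locus, any site showing two bases in one sample is evidence
of contamination (or damage/error). `heterozygosity()` reports the
fraction of covered sites with ≥ 2 distinct bases; the default pass
threshold is 0.1%. The literal criterion counts a single minor read as
heterozygous, which on heavily damaged, well-covered samples can fail
uncontaminated libraries; `min_minor_reads = 2` is the practical strict
mode that damps single-read deamination. The default stays literal
(`min_minor_reads = 1`, `min_depth = 1`) and the knobs are exposed.

## Consensus and alignment

`consensus_call()` emits a base only when a site has ≥ 2 reads and the
minor-allele fraction is strictly below 10% (a 9:1 site is masked — the
strict reading is the conservative one; ties are masked too). The
comparison is done in integer arithmetic so the 9:1 boundary cannot slip
through floating point. `build_alignment()` keeps segregating sites
(≥ 2 distinct called bases), requires each sample to cover at least
`min_seg_sites` of them (production default 1100; the threshold counts
sites *after* the ≥ 2-sample site filter) and each site to be called in
≥ 2 samples. The two filters can invalidate each other, so they are
iterated to a fixed point. The exported FASTA (`write_alignment()`, with
a column→position sidecar) is the input for external maximum-likelihood
tree software; model selection, bootstrap and ML search are deliberately
out of scope. `pairwise_distance_tree()` provides an internal
neighbour-joining sanity check on mismatch distances.

## Diagnostic-SNP discovery

Given a three-state genotype matrix (ancestral/derived/missing, polarized
against the reference), a site is diagnostic for a candidate clade when
(1) no ingroup sample is ancestral, (2) > 1 ingroup sample is covered,
(3) no outgroup sample is derived, and (4) > 1 outgroup sample is
covered. "More than one" is read literally as ≥ 2. Novel candidates whose
allele pair is C→T or G→A are excluded (deamination can fake them) unless
they match a previously known catalogue SNP by exact position and allele
pair. Reports use the "x/N derived, rest missing" convention: rule (1)
guarantees the N−x remainder is uncovered, never ancestral. The
implementation is vectorized and is verified in the tests against a
brute-force per-site oracle on hundreds of random matrices.

## Pairwise TMRCA

For two consensus haplotypes, `pairwise_differences()` returns the
jointly called site count `n` and mismatch count `d`; the relative
divergence `d/(2n)` is proportional to TMRCA because both lineages
accumulate substitutions independently since their split. Rather than
assuming a substitution rate for the filtered consensus site set, the
proportionality constant is fitted (`calibrate()`) so that the mean
TMRCA of anchor pairs — an outgroup lineage such as A0 against all others
— equals a published anchor age (default 161,300 years; ~163 kya is also
quoted for the same split, and the anchor is an argument). Confidence
intervals treat `d` as Poisson and map the exact (Garwood) interval
through the linear estimator, so sparser overlap automatically widens the
interval. Exact Poisson intervals over-cover slightly at small counts
(~96–98% observed for nominal 95% in the validation suite) — a known,
conservative property. An option excludes C/T and G/A mismatches (and
their sites) from the counts as a damage sensitivity analysis.

Panels that target known segregating sites would inflate `d/(2n)`;
`tmrca_pairs()` therefore refuses consensuses tagged `mode = "snp-panel"`
unless explicitly overridden. `clade_summary()` averages cross-clade
pairs after excluding pairs from the same sampling site (close kin and
shared local history depress divergence).

## The simulator and what it does (and does not) emulate

`simulate_tree()` draws a random bifurcating genealogy with the root at a
chosen depth and leaves at the present. Internal node times are laid out
by tree level in disjoint jittered bands, so every branch is guaranteed a
duration of at least half a level width. This is a deliberate departure
from a plain coalescent: named haplogroup branches in real Y phylogenies
carry several defining SNPs each, and testing haplogroup recovery is only
meaningful when every branch can carry SNPs. A coalescent would routinely
produce near-zero terminal branches that no SNP could tag, making perfect
recovery impossible for any method.

`place_mutations()` is infinite-sites: per-branch Poisson counts with
mean `mu * L * duration`, positions uniform without replacement. This
matches how SNP catalogues treat each haplogroup SNP as a single
ancestral→derived event; back mutation and saturation — rare on the NRY —
are not modelled. `emit_pileups()` adds per-site Poisson depth, whole-site
dropout, orientation-symmetric per-read deamination (C→T / G→A), and
optional contamination by another leaf's haplotype. Contaminant reads are
modelled as present-day (undamaged) DNA, the classic contamination
signal. Not modelled: sequencing error beyond deamination, fragment-length
structure, reference bias, and the position-dependence of damage along
the read (end offsets are drawn uniformly). Passing tests on these
simulations therefore validates the statistical logic of the pipeline,
not robustness to every artefact of real ancient-DNA libraries.

## Default parameters at a glance

| Parameter | Default | Where | Why |
|---|---|---|---|
| substitution rate `mu` | 8e-10 /site/yr | `place_mutations()` | midpoint of published NRY estimates |
| sequence length `L` | 10,445,000 bp | `place_mutations()` | mappable NRY |
| normalization unit | 5e6 reads | `normalize_per_unit()` | field convention |
| probe window | 120 bp | `expand_windows()` | 60 bp flanks, configurable |
| branch depth | 3 | `haplogroup_snp_set()` | near-terminal resolution metric |
| het threshold | 0.1% | `heterozygosity()` | haploid contamination screen |
| consensus depth / minor fraction | 2 reads / <10% | `consensus_call()` | low-coverage majority rule |
| segregating-site minimum | 1100 | `build_alignment()` | production alignment filter |
| anchor age | 161,300 yr | `calibrate()` | deepest Y split (A0) |
| `min_support` | 1 read | `call_haplogroup()` | permissive default, reports carry the evidence |

## Validation scales

The test suite and the acceptance script run everything on reduced
problem sizes chosen so the full validation completes in minutes on one
core while keeping expected counts large enough for the closed-form
checks: haplogroup-recovery accuracy uses 200 leaves with `mu = 8e-9`
over `L = 1e6` bp (the same `mu * L` mutation supply per year as the
paper-scale `8e-10` over 10.4 Mb, i.e. ~125 years per substitution);
TMRCA coverage uses 300 two-leaf replicates per split depth (10, 50,
150 ky) at `L = 5e4` with an anchor pair simulated at `L = 2e6`;
diagnostic-SNP equivalence uses 200 random 20×200 matrices; interval
unions use 500 random instances. All stochastic steps take explicit
seeds.

## Known limitations

- The haplogroup caller requires support on every traversed branch; on
  sparse data it stops at the last covered branch rather than guessing
  past gaps. The exported reports are the intended recovery path.
- Heterozygosity mixes damage and contamination at depth; use the strict
  minor-read mode on heavily damaged libraries.
- TMRCA calibration absorbs all rate uncertainty into one constant; CIs
  reflect only Poisson counting error, not calibration error.
- ML phylogenetics (model selection, bootstrap) is delegated to external
  tools via the exported FASTA.
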