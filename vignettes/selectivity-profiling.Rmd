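---
title: "Ligand-based selectivity profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based selectivity profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selprof)
```

## The problem

Enzyme families such as the human carbonic anhydrases (hCA I--XIV) share a
catalytic mechanism but differ in tissue distribution, so a therapeutically
useful inhibitor must hit its intended isoform (say, the tumour-associated
hCA IX) while sparing ubiquitous off-targets (hCA II). Decades of medicinal
chemistry have left thousands of published Ki values for sulfonamide-type
inhibitors across these isoforms. `selprof` mines such multi-target
bioactivity tables for *structure--selectivity relationships*: groups of
structurally related ligands (chemotypes) that are consistently selective
for an on-target over an off-target. The approach is purely ligand-based —
no protein structure or binding-mode information enters at any point.

## The model

**Per-ligand selectivity.** For on-target $t_\mathrm{on}$ and off-target
$t_\mathrm{off}$, a ligand's selectivity index is

$$\mathrm{SI} = \frac{K_i(t_\mathrm{off})}{K_i(t_\mathrm{on})},$$

so SI = 10 means ten-fold preference for the on-target. Ligands are
classified as $L_\mathrm{on}$ (SI > 5), $L_\mathrm{off}$ (SI < 0.2) or
$L_\mathrm{ns}$ otherwise. Both inequalities are strict; a ligand sitting
exactly at a threshold is non-selective. For two ligands, the selectivity
ratio $\mathrm{SR} = \log_{10}\mathrm{SI}_a - \log_{10}\mathrm{SI}_b$
measures how much their selectivity profiles differ; base 10 is used so
that SR spans about $[-8, 8]$ over realistic Ki ranges.

**Structural similarity.** Structures are encoded as binary fingerprints
and compared with the Tanimoto index
$T_i = |A \cap B| / |A \cup B|$ over set bits, with $T_d = 1 - T_i$ the
corresponding distance. A pair of all-zero fingerprints is assigned
$T_i = 0$ rather than NaN so similarity matrices are total. Two schemes are
implemented:

* `keys` (default): the public 166-key MACCS SMARTS set, shipped verbatim
  in `inst/extdata/maccs_keys.tsv`. Bit $k$ is set when the molecule has
  strictly more than the key's minimum count of unique matches of SMARTS
  $k$, evaluated with OpenBabel's SMARTS engine. Three keys (isotope,
  more-than-one-aromatic-ring, more-than-one-fragment) are not expressible
  as a single SMARTS and are never set, which matches the reference
  OpenBabel implementation bit for bit — the test suite asserts exact
  equality on a 50-molecule panel.
* `path`: all simple linear paths of 1--7 heavy atoms are enumerated from
  the molecular graph, written as canonical token strings over element
  symbols (lower-case when aromatic) and bond orders, taking the
  lexicographically smaller direction, then hashed with 32-bit FNV-1a and
  folded onto 1024 bits by xoring 10-bit chunks. Unlike the classical FP2
  fingerprint this scheme indexes single-atom paths for every element; the
  hash function is fixed and versioned (`fp_hash_version()`) so matrices
  are reproducible across platforms. Every input SMILES is canonicalised
  with OpenBabel before graph extraction, which is what guarantees that
  atom-order permutations of the same molecule produce identical bits.

**Clustering and scoring.** Ligands are clustered by single-linkage on the
$T_d$ matrix (inter-cluster distance = minimum member-pair distance). The
dendrogram is cut at a *height ratio*: threshold = ratio × root merge
height (default 0.30), and clusters are the connected components joined by
merges strictly below it. An absolute $T_d$ cutoff mode is available as an
alternative. Clusters with at least 5 members are scored by

$$S_\mathrm{score} = 100\,\frac{L_\mathrm{on} - L_\mathrm{off}}
{L_\mathrm{on} + L_\mathrm{off} + L_\mathrm{ns}} \in [-100, +100],$$

and clusters with $S_\mathrm{score} > 70$ (strict) are reported as
selective chemotypes. In double-selectivity mode the score is computed
independently against two on-targets sharing one off-target and their sum
(the double $S_\mathrm{score}$, in $[-200, 200]$) is filtered at strictly
above twice the single-mode cutoff — the double-mode filter is this
package's convention, chosen so that a cluster must be convincingly
selective for both targets.

## Data curation

Raw bioactivity tables mix assay metrics, laboratories and replicates.
`curate()` applies, in a fixed order: (1) metric filter (keep Ki only by
default — IC50/Kd/Km/EC50 values are not comparable with Ki); (2) optional
PMID whitelist, the practical proxy for restricting to one laboratory's
assay protocol; (3) per-(compound, isoform) replicate aggregation;
(4) merge to one wide row per compound; (5) zinc-binding-group substructure
filter with SMARTS `[#16](=[OX1])(=[OX1])[NX3]`, which matches
sulfonamides and also sulfamates and sulfamides. The order matters for the
audit trail (a compound removed by the substructure filter still
contributes replicates to aggregation counts), so the audit records
survivors of every stage and each stage's input count equals the previous
stage's output.

Replicate aggregation removes outliers by the modified z-score
($0.6745\,(x - \mathrm{med})/\mathrm{MAD}$, with the conventional
mean-absolute-deviation fallback when the MAD is zero) computed on
$\log_{10} K_i$ — Ki error is multiplicative, so a gross error is additive
on the log scale — at threshold 3.5, then takes the arithmetic mean of the
surviving raw nM values. The median is kept if removal would empty the
set. Both the rule (`none`, `modified-z`, `trim-fraction`) and the mean
(`arithmetic`, `geometric`) are configurable, because the log/linear
averaging choice is genuinely open for this kind of data; the defaults
reflect the most common practice. Compounds whose records carry
conflicting canonical SMILES are not silently resolved: the first record
wins and the CIDs are flagged in the `smiles_conflicts` attribute.

## The synthetic-data generator

`sim_scenario()` / `simulate_bioactivity()` emulate the structure of a
PubChem-derived inhibition table without any download: a few sulfonamide
scaffold families (benzenesulfonamide, ureido-phenyl-sulfamate,
acetazolamide-like, biphenyl-, benzyl- and thiophene-sulfonamides), each
decorated with up to 12 small R-groups, each family carrying a planted
selectivity class. On the log10 Ki scale:

$$\log_{10} K_i(\ell, t) = b_{s(\ell)} + \Delta_{s(\ell)}(t) + u_\ell +
\varepsilon,$$

with scaffold base potency $b_s \sim U(1, 2)$ (10--100 nM), planted offset
$\Delta = -1.5$ on the on-target(s) for on-selective scaffolds ($+1.5$ for
off-selective, 0 for promiscuous — a true SI of $10^{\pm 1.5} \approx
31.6$ or its reciprocal), ligand jitter $u \sim N(0, 0.1)$ and replicate
noise $\varepsilon \sim N(0, 0.15)$. Each (ligand, isoform) receives 3--6
replicates; a replicate is multiplied by 100 with probability 0.05
(gross-error outliers, sized so the modified-z rule removes them at
typical replicate counts); decoy records — sulfonamides reported as IC50,
and non-sulfonamide carboxylic acids with Ki — are appended at 10% of the
core record count. Everything is deterministic given the scenario seed,
and the generator restores the caller's RNG state.

What the generator does *not* emulate: activity cliffs inside a scaffold
family, correlated assay batch effects, heavy-tailed Ki error, tautomer and
salt ambiguity, or the very unbalanced isoform coverage of real PubChem
exports. Passing the planted-recovery tests therefore shows the pipeline's
machinery is correct, not that real data will cluster this cleanly.

## Numerical and design choices

* Tanimoto uses the union denominator (the only reading under which
  $T_i \in [0, 1]$).
* The dendrogram cut is strictly below threshold, so an all-equidistant
  set at or above the threshold stays as singletons; a height ratio of 1 is
  defined as the whole-tree cut. Ties in merge order are resolved
  deterministically, and cluster IDs are assigned by decreasing size then
  lowest member index, so reports are reproducible byte for byte.
* Ki values are normalised to nM at ingestion (an optional `units` column
  triggers conversion); malformed rows are rejected individually with
  row-indexed diagnostics rather than aborting the load.
* Ligands lacking a Ki for either target of an analysis are excluded at
  profiling time (`select_pair_subset()`), not during curation, so one
  curated table serves every target pair.
* Problem sizes in the test-suite and acceptance runs use the default
  scenario (3 scaffolds × 8 ligands, ~230 records) over 20 seeds, which is
  ample to exercise every stage while keeping brute-force oracles
  (recursive path enumeration, naive $O(n^3)$ single linkage) cheap.

## Known limitations

* The `keys` scheme inherits OpenBabel's aromaticity model; SMARTS
  dialects differ across toolkits, so bit-level agreement is claimed only
  against OpenBabel's MACCS, not against other MACCS implementations.
* The `path` scheme hashes into 1024 bits; distinct paths can collide, so
  Tanimoto values computed from hashed bits can differ slightly from the
  collision-free path-set Tanimoto for large molecules. The tests compare
  enumerated path *sets* against an independent oracle exactly, and hashed
  Ti on small molecules where no collision occurs.
* Shared-substructure summaries of reported clusters are by member
  inspection (the report lists SMILES); maximum-common-substructure
  extraction is out of scope.
* No error propagation from replicate scatter to SI: a ligand near a class
  threshold may flip class under resampling, which is visible in the
  planted-class recovery rate (about 90% per-ligand at the default noise)
  but is not quantified per ligand.
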