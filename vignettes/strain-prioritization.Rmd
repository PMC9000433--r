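---
title: "Automated strain prioritization from MALDI-TOF fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated strain prioritization from MALDI-TOF fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpick)
```

## The problem

Natural-product drug discovery from environmental bacteria suffers from a
front-end redundancy problem: a field expedition yields hundreds to
thousands of culturable isolates, many of which are near-identical taxa
producing near-identical chemistry, and every redundant isolate carried into
a library multiplies downstream costs (fermentation, extraction,
fractionation, screening, dereplication). MALDI-TOF mass spectrometry of
intact colony material offers a cheap per-isolate readout of both
dimensions of redundancy at once: the 2--15 kDa region fingerprints small
ribosomal and housekeeping proteins and so tracks taxonomy, while the
200--2000 Da region records the small-molecule (natural product, "np") ions
the isolate secretes.

`strainpick` turns these two fingerprints into an automated library
selection. Isolates are clustered on protein-fingerprint similarity into
*pseudo-phylogenetic groups* (clusters that approximate species-level
relatedness without sequencing); within each group, a bipartite *metabolite
association network* (MAN) links isolates to their distinct small-molecule
mass features; and a greedy rule selects, per group, a minimal ordered set
of isolates that jointly carry at least a user-chosen fraction of the
group's features. Replacing manual MAN inspection with this rule removes
curator-to-curator variation and reduces hours of manual triage to seconds.

## The selection rule

Let a group have members $i = 1..m$ with feature sets
$F_i \subseteq U$, where $U$ is the union of the group's distinct np
features, and let $t \in (0, 1]$ be the capture threshold. The rule is:

1. Among unselected members, pick the isolate with the most features; since
   a selected isolate *and its features* are removed from the group before
   iterating, "most features" at every step counts features not yet
   captured. The first pick therefore coincides with the raw-count maximum.
2. Ties are broken by the lexicographically smallest isolate id.
3. Stop as soon as $|{\rm captured}| / |U| \ge t$ (inclusive, so $t = 1$
   terminates exactly at full coverage).

Three consequences are guaranteed by construction and tested as
properties:

* **Coverage**: every group with $|U| > 0$ ends at or above $t$.
* **Overshoot**: features accumulate isolate-by-isolate, not one at a time,
  so the final fraction typically exceeds $t$; with an 0.75 threshold the
  per-group average lands near 0.8 on the synthetic collections below.
* **Stopping-rule minimality**: removing the last selected isolate of any
  group drops coverage strictly below $t$.

Members that would contribute no uncovered feature are never selected, even
at $t = 1$ — they add nothing and the goal is minimization. A group whose
members carry no np features at all selects nothing by default
(`captured_fraction` is 1 by convention); `min_select = 1` instead forces
one representative (the lexicographically smallest id) when taxonomic
coverage matters more than parsimony. Greedy maximum coverage is not
globally optimal set cover; the per-group, threshold-stopped greedy *is*
the method, and the package deliberately does not attempt cross-group joint
optimization.

## From spectra to the selection

**Input.** Centroided peaks per isolate per technical replicate, either as
mzML (read through `mzR`) or as delimited two-column peak tables
(comma/tab/semicolon auto-detected). Spectrum ids map to isolate and
replicate via a `"{isolate}_{replicate}"` naming pattern — a convention of
this package, since acquisition software ties spectra to target-plate
positions in vendor-specific ways. `pick_peaks()` is available for
profile-mode input (local maxima over a ±`halfwindow`-point window, 101-point
rolling-median baseline, MAD-based noise).

**Replicate consensus.** `merge_replicates()` matches peaks across the
(typically three) technical replicates by single-linkage grouping of m/z
values with gap ≤ `tol`, averages each matched cluster (intensity-weighted
m/z, mean intensity) and keeps clusters present in at least `min_presence`
of the replicates. The default 2/3 requires a peak in two of three
replicates: spurious, replicate-private peaks (and the generator's planted
noise peaks) are removed in expectation, while a single dropped-out
replicate does not lose a real peak.

**Regions.** Peaks split at the documented bounds: np = [200, 2000) Da,
protein = [2000, 15000] Da, the 2000.0 Da boundary belonging to protein
only so each peak has exactly one region; peaks outside 200--15,000 Da are
dropped with a logged count.

**Feature binning.** `bin_features()` pools all isolates' consensus peaks
per region and splits the sorted m/z values wherever a gap exceeds `tol` —
one-dimensional single-linkage clustering. This is deterministic,
order-independent, and free of the phase artifacts of fixed-width grids. A
bin is a *mass feature*; incidence is binary because the method counts
features and never weights them by intensity. Isotopologues are *not*
collapsed and isobars are not resolved: multiple features can represent one
chemical entity, a known limitation retained deliberately.

**Clustering and the cut.** `distance_matrix()` compares binary protein
fingerprints (cosine by default; Jaccard and Dice available — all three are
standard for MALDI biotyping presence/absence data), and
`build_dendrogram()` runs agglomerative clustering (UPGMA by default)
through `stats::hclust`. The dendrogram cut — by height or by group count
`k` — is a deliberate manual/configured choice: automatic selection of a
species-level cut is a long-standing open problem in bacterial MALDI-TOF
typing, and the package does not pretend to solve it.

**MANs and reports.** One MAN per group, with features defined
collection-wide and restricted per group (so the 6624-style collection
totals and cross-selection comparisons are well defined in one shared
feature space). After selection, `annotate_man()` flags selected isolates
and captured vs missed features, and the writers emit Newick (branch
lengths equal merge-height differences), GraphML with the four node
classes, delimited tables, and a JSON selection report.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `threshold` | 0.75 | working default for the capture fraction; tune per dataset until the selected count matches downstream capacity |
| `min_presence` | 2/3 | peak must appear in 2 of 3 technical replicates |
| `tol_rep_protein`, `tol_bin_protein` | 2.0 Da | linear-mode TOF mass accuracy above 2 kDa |
| `tol_rep_np`, `tol_bin_np` | 0.2 Da | reflectron-quality accuracy below 2 kDa |
| `snr_min_protein`, `snr_min_np` | 4, 10 | picking thresholds for profile input; np region is denser and noisier |
| `metric`, `linkage` | cosine, average | common MALDI biotyping practice |
| `cut_mode`, `cut_value` | — | user-supplied; never auto-selected |
| `min_per_group` | 0 | no forced representative for chemistry-free groups |

The processing settings behind any particular published dataset live in the
original acquisition pipelines; the defaults above are this package's own
declared, fully configurable choices, not a claim about any specific prior
run.

## The synthetic generator

`simulate_collection()` plants the structure the method assumes so that
every stage can be scored against ground truth: `n_groups` groups of
isolates, each group owning a pool of 30 protein marker masses that members
carry with probability 0.9 (cross-group leakage 0.05) — giving
within-group cosine distances well below between-group ones — and an np
universe made of a 10-mass group core shared by all members plus 5 private
accessory masses per isolate, giving the partial within-group chemical
overlap the greedy rule exploits. Replicates drop each true peak with
probability 0.1, jitter m/z (SD 0.3 Da protein / 0.03 Da np, scaled to the
matching tolerances), and add 3 replicate-private uniform noise peaks. True
masses are drawn uniformly in their regions with a minimum separation of 5×
the default binning tolerance, so noise-free runs bin unambiguously;
intensities are lognormal (median 50, ±20% replicate scatter) — intensity
plays no role downstream, it only exercises the weighted-mean consensus.
Everything is reproducible from a single integer seed, and the caller's RNG
state is left untouched.

What the generator does **not** emulate: isotope envelopes and adducts,
detector saturation, mass-calibration drift, correlated (matrix-derived)
noise, and profile-mode baselines. Passing tests on synthetic collections
therefore demonstrate the pipeline's logic — consensus, binning,
clustering, selection — under controlled conditions, not instrument-level
robustness on real spectra.

## Numerical and design choices

* **Determinism.** Every stage is deterministic given its input: gap
  clustering has no initialization; `hclust` resolves ties by its fixed
  scan order; greedy ties resolve lexicographically. Identical inputs give
  bit-identical selection reports.
* **Percentages** are rounded half-up to integers (base `round()` is
  round-half-even), matching the printed precision of collection-level
  summaries.
* **Duplicate m/z** within one replicate collapses to the maximum
  intensity — deterministic and conservative.
* **Empty-fingerprint isolates** sit at distance 1 from everything so they
  fall out as singleton groups rather than poisoning a cluster.
* **Newick branch lengths** are merge-height differences (tips at height
  0), so tip depth equals the root merge height and cophenetic distances
  are twice the merge heights.
* **Matrix-blank subtraction** is available (`blank_paths`) but off by
  default; it removes consensus peaks within `blank_tol` of any blank
  peak.
* Problem sizes in the shipped tests — collections of 5 groups × 8
  isolates × 3 replicates, 20-seed sweeps, and exhaustive greedy-oracle
  enumeration at 3 isolates × 3 features with randomized sweeps up to 6 ×
  8 — were chosen as the smallest scales at which every claimed property
  is exercised with headroom.

## Limitations

Beyond the generator's idealizations above: no deisotoping or isobar
separation (features overcount chemical entities); absolute-Da tolerances
rather than ppm (adequate over these narrow ranges); no bootstrap support
on the dendrogram; and the dendrogram cut remains the analyst's
responsibility. Reading vendor raw directories is out of scope — convert
to mzML externally.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_collection(synth_params(seed = 1))
cfg <- run_config(cut_mode = "k", cut_value = 5, threshold = 0.75,
                  out_dir = "run1")
res <- run_pipeline(cfg, peaklists = sim$peaklists)
res
summary(res$selection)
```

The `run1/` directory then holds the dendrogram (Newick), the group table,
both feature matrices, one annotated GraphML MAN per group, the JSON
selection report, the flat selected-isolate list, and a manifest from which
the run can be reproduced identically.
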