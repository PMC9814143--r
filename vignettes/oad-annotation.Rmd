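---
title: "Resolving lipid C=C positions from OAD-MS/MS: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving lipid C=C positions from OAD-MS/MS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidoad)
```

## The annotation problem

Untargeted lipidomics pipelines built on collision-induced dissociation
(CID) stop at the molecular species level: `PC 18:1_22:6` names the head
group and the carbon/double-bond count of each acyl chain, but not where
the double bonds are. Oxygen attachment dissociation (OAD) adds that
information: atomic oxygen or hydroxyl radicals add to each C=C and the
backbone cleaves at the carbons around it, so every double bond leaves a
small set of neutral losses whose masses encode its position counted from
the methyl terminus (the *n*-position; the delta-position counts from the
carboxyl end, delta = C − n).

`lipidoad` turns a molecular-species annotation plus its OAD-MS/MS
spectrum into a C=C-resolved structure in four steps: candidate
enumeration, in-silico spectrum generation, diagnostic-ion verification,
and reverse dot-product ranking.

## Fragmentation model

For a double bond at n-x, cleavage can occur at three bonds: n-(x−1)\_n-x
(methyl side), n-x\_n-(x+1) (the C=C itself), and n-(x+1)\_n-(x+2)
(carboxyl side). The charged fragment always retains the head group; the
neutral lost spans the methyl terminus through the cleaved bond. A loss of
k carbons containing u complete double bonds is the radical C_k H_(2k+1−2u),
modified by the rule's hydrogen delta; oxygen-retaining rules keep one O on
the charged fragment (so the net loss is lighter by one O), and dehydrated
variants lose a further H2O.

The packaged rule set (`oad_rule_table()`) formalizes twenty ion types per
double bond across these three sites, including the hydrogen-shifted,
oxygen-retaining and dehydrated variants, plus two vinyl-ether entries.
Two rules are flagged as the *essential diagnostic pair*: the
oxygen-retaining methyl-side cleavage and the carboxyl-side
hydrocarbon-radical cleavage. For 18:1(n-9) these give neutral losses of
97.1381 Da (C8H17 − O) and 139.1487 Da (C10H19); shifting the double bond
one carbon toward the methyl end shifts both by one CH2 (14.0157 Da).
Only the diagnostic pair is anchored by well-characterized masses; the
other eighteen entries are structurally plausible companions whose H/O
deltas and relative intensities are heuristic and fully replaceable via a
user rule table — the verification and ranking logic depends only on the
pair being correct, the rest shape the reference spectrum.

Special contexts (`special_case_rules()`):

* **Sphingoid delta-4** (n-(C−4) on the long-chain base): fragments are
  systematically low-abundance. The engine applies a reduced rule subset
  at 0.2× intensity and verifies the pair against the lower 0.005 %
  intensity floor.
* **Sphingoid delta-8 and deeper**: behaves like an ordinary acyl chain;
  the standard rules apply unchanged.
* **Vinyl ether (plasmalogen, P- chains)**: the implicit delta-1' double
  bond at n-(C−1) yields its own cleavage ions (near *m/z* 521.31/522.32
  for PE P-18:0/18:1), generated from two dedicated rule entries.

Head-group ions come from the subclass registry
(`subclass_registry()`): a standalone product ion for choline-containing
classes (protonated phosphocholine, *m/z* 184.0733) or a head-group
neutral loss (e.g. C2H8NO4P for PE, C3H9O6P for PG, with NH3 added for
ammoniated precursors). Masses use IUPAC monoisotopic values pinned in the
package; charged species subtract one electron mass per positive charge,
which reproduces printed reference *m/z* values to within 0.0005.

## Candidate enumeration

Biological fatty acyl chains are methylene-interrupted: the first double
bond sits at n-3 or deeper, the last no closer than two carbons to the
carboxyl end, and two double bonds are separated by at least two bonds.
Under these constraints (`min_pos = 3`, `max_offset = 2`, `min_gap = 2`,
all configurable, e.g. to admit conjugated systems) the candidate count is
`choose(C − 3 − d, d)`:

```{r}
nrow(enumerate_positions(18, 1))
nrow(enumerate_positions(22, 6))
```

Chains are evaluated in decreasing double-bond-count order (ties: longer
chain first, then input order); saturated chains contribute nothing to
search.

## Verification and scoring

A candidate survives only if, for **every** double bond, both diagnostic
pair ions are found within 15 ppm and at ≥ 0.01 % of the base peak
(≥ 0.005 % for sphingoid delta-4). Thresholds are fractions of the base
peak because spectra are compared in relative intensity; both the
tolerance and the floors are `oad_config()` settings, and
`require_pair_all_bonds = FALSE` relaxes the all-bonds rule to
at-least-one for exploratory use.

Survivors are ranked by the reverse dot product with square-root
intensities, summed over reference peaks only: unmatched reference peaks
contribute zero, measured-only peaks are ignored. The score is in [0, 1],
is exactly 1 for a perfect copy, and is invariant under uniform intensity
scaling.

Two numerical choices matter here:

* **Colliding reference peaks are summed, not maximum-pooled.** Fragment
  masses depend only on the n-position and the bond index, not on which
  chain carries the bond, so different chains routinely emit identical
  fragments. Summing their contributions (then renormalizing to the base
  peak) preserves the quantitative evidence that distinguishes "two chains
  emit this ion" from "one does"; with maximum-pooling, any candidate that
  duplicates a position already assigned to another chain would tie the
  true assignment exactly and every such lipid would come out ambiguous.
* **Per-chain screening is followed by joint re-scoring.** Each chain's
  candidates are first screened and scored against the head-group/precursor
  context alone. Because one chain's ions can alias a candidate of another
  chain, the top candidates per chain (within `joint_delta = 0.05` of the
  chain-stage top, at most `joint_pool = 8`) are then re-scored jointly on
  the full in-silico spectrum, and the best joint assignment wins. The
  cross product is capped at 512 combinations; beyond that the union of
  tied positions is reported as ambiguous rather than silently truncated.

Ties within `tie_epsilon = 1e-6` of the top joint score are genuine
ambiguity. If the tied assignments differ only by which equal-DBE chain
carries which position set — spectrally indistinguishable swaps such as
16:1(n-7)/18:1(n-9) vs 16:1(n-9)/18:1(n-7) — one assignment is reported
with status `chain-unresolved`. Otherwise the differing slots are reported
with `&` notation (`22:6(n-3&4,6,...)`) and status `ambiguous`. Records
whose every candidate fails verification are `unresolved`; records with no
matching spectrum are `no-spectrum`.

## Pipeline

`read_alignment_table()` consumes tab-delimited molecular-species tables
in the MS-DIAL export dialect through a configurable header-synonym map;
unparseable names are skipped with a count. `read_spectra()` reads MGF
natively and mzML through `mzR`; RT is carried in minutes. CID records and
OAD spectra are paired by nearest precursor within 0.01 Da and 0.15 min
(`join_cid_oad()`). `annotate_batch()` captures per-record errors and is
deterministic: repeated runs write byte-identical result tables.

## Synthetic data and what it shows

`simulate_spectrum()` perturbs the noise-free in-silico reference with
log-normal intensity jitter (sdlog 0.3), Gaussian *m/z* error (3 ppm,
about a fifth of the matching window), and chemical noise (peak count ~
Poisson(20), *m/z* uniform over the scan range, intensity exponential
below 5 % of the base peak). These defaults emulate a well-behaved
high-resolution QTOF acquisition; they are deliberately conservative and
all adjustable. `make_truthset()` draws random C=C-resolved species
(chain lengths 14–22, up to six double bonds, positions uniform over the
enumerable set) and emits the MGF/alignment/truth trio the pipeline
consumes, with retention times spaced wider than the join window so
records pair with their own spectra unless co-elution is simulated
explicitly (`simulate_spectrum(..., coeluting = )`).

The evaluation harness (`evaluate_ppv()`) counts a record correct when
the top-ranked name equals the truth; ambiguous results count only when
the truth is among the reported alternatives, and chain-unresolved results
when the position multiset matches at the species level. PPV is reported
with both the annotated-only and the all-attempted denominator, overall
and stratified by single vs multiple unsaturated chains;
`threshold_sweep()` traces PPV against the minimum-intensity floor.

Because the simulator and the annotation engine share the fragmentation
rules, a 100 % PPV on noise-free simulations is a round-trip consistency
check of enumeration, spectrum generation, verification and ranking — it
does not certify the rule table against real instrument behaviour, nor
cover deconvolution of co-eluting isomers, isotope envelopes, or
chromatographic effects. The noisy-simulation results (accuracy decaying
as mass error grows past the 15 ppm window) probe the matching logic, not
instrument reality. Test-suite problem sizes — 50-species truth sets for
the round-trip check, 30-species sets at three mass-error levels for the
degradation check, brute-force enumeration cross-checks up to C30 with
the closed form covering C ≤ 44 — were chosen to exercise every code path
at desk scale.

## Known limitations

* Chain-specific assignment of equal-DBE chains is impossible from the
  spectrum alone; such records are flagged, not guessed.
* Lipids whose multiple unsaturated chains alias one another's fragments
  (same n-position at the same bond index on different chains) can be
  genuinely indistinguishable; they surface as `ambiguous` with `&` sets.
* Cardiolipins and other four-chain lipids, negative-ion OAD, and
  quantitative intensity prediction are out of scope.
* The eighteen non-diagnostic rule intensities are heuristics; replace the
  packaged table with instrument-calibrated values where available.
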