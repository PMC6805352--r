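---
title: "Models and methods behind spiralineage"
author: "spiralineage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiralineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralineage)
```

# Scope

spiralineage analyses developmental cell lineages of the annelid larval
episphere — the apical hemisphere of the trochophore larva that forms
the head and brain.  Early development follows spiral cleavage: quartets
of micromeres arise by oblique divisions alternately rotated clockwise
and counter-clockwise, so that the embryo is fourfold rotationally
symmetric about the animal–vegetal axis, with four lineage quadrants A,
B, C and D.  Over larval stages the episphere converts to bilateral
symmetry.  The package provides the computational tools of that
analysis: the spiralian nomenclature, a lineage-tree container with
track-table I/O, a synthetic embryo generator, cross-embryo
corresponding-cell identification with difference quantification and
consensus trees, bilateral-founder detection with symmetry
classification, and lineage metrics.

All positions live in a fixed frame: the apical (animal) pole is $+z$,
the dorsal (D-quadrant) azimuth is $+y$, the sagittal mirror plane is
$\{x = 0\}$, and the right body side ($+x$) carries the C quadrant (the
right larval eye derives from 1c, the left from 1a).  Times are hours
post fertilization (hpf) throughout; spatial units are opaque and
conventionally micrometres, with the hemisphere radius normalised to 1
in simulated data.

# The synthetic episphere embryo

## Canonical program

`canonicalProgram()` scripts the stereotypic phase of episphere
development from the first micromere quartet (2 hpf) to roughly 16 hpf:

* the spiral divisions of the 1m quartet producing the 1m-1 and 1m-2
  tiers and their descendants;
* the primary prototroch — per quadrant the three non-dividing cells
  1m-212, 1m-221, 1m-222, arranged as a rotationally symmetric ring,
  leaving the cycle at 6.5–7 hpf;
* the accessory prototroch — per quadrant 1m-211, 1m-122 and 1m-1212,
  except for the D quadrant which contributes only two accessory cells
  (1d-211 and 1d-1221) because the 1d-121 clone and 1d-1222 migrate out
  of the episphere through the prototroch gap;
* the apical organ from the rosette cells 1m-111: the ampullary-cell
  division of 1c-111 at ~9 hpf, the division of 1d-111 into the large
  dorsal apical cell and a flask-shaped cell at ~10 hpf, the budding of
  1a-1112 from 1a-111 at ~9 hpf followed by the division of 1a-1111 at
  ~12 hpf, and the variable ventral rosette cell 1b-111;
* the first bilateral divisions: 1m-112 at 6.0 hpf (producing 1m-1121
  and 1m-1122) and 1m-1121 at 8 hpf;
* a registry of the 11 bilateral founder pairs, with the lateral pairs
  from the 1m-1122 quartet, a left–right pair drawn from the 1a-12 and
  1c-12 clones (A|C symmetry), two single-quadrant pairs
  (1a-1121121/1a-1121211 and 1b-12111aa/1b-121121b), and medial pairs of
  non-corresponding lineage assembled from the 1cd-1121x and 1ab-1121x
  sublineages.  Registry identities that are not fully constrained by
  published material carry `verified = FALSE`; they are consistent
  placeholders, not biological claims.

Late development (towards 32 hpf) is not scripted cell-by-cell; each
founder clone proliferates parametrically with a clone-specific cell
cycle and division depth.  Lateral clones cycle fastest (3.4–3.6 h) and
medial clones more slowly (4.6–5.8 h), which reproduces the
qualitative pattern that the lateral territory reaches the greatest
lineage depth with the shortest cycles, and brings the canonical embryo
to 594 cells at 32 hpf — above the 500-cell mark a real recording
passes at that stage.

## Geometry

Daughters are placed by `placeDaughters()`.  Spiral divisions separate
daughters along the meridian rotated $\pm45^\circ$ about the local
surface normal (sign alternating between tiers) plus a constant
handedness twist of $-12^\circ$; the twist accumulates the rotational
offset of the spiral pattern, so the early scaffold is fourfold
rotationally symmetric but *not* mirror symmetric — as in a real
spirally cleaving embryo, where bilateral symmetry has to be built
later.  Radial divisions separate daughters along the meridian, and
bilateral divisions along the direction towards the sagittal plane,
which makes them mirror-equivariant.  Bilateral founders and a small
set of asymmetric medial cells carry scripted positions (the regulative
phase of development is positional, not lineage-driven); each founder
clone is laid out deterministically around its founder with
separations near the late-stage internuclear distance (0.07–0.09 R)
and mirrored exactly onto the partner side, without crossing the
midline.

A known consequence of this design is that the canonical embryo's
mirror symmetry is carried almost entirely by the founder clones:
fitting the sagittal plane with `estimateMirrorPlane()` is reliable
from late stages (when clones dominate the cell count) but not at 12
hpf, when most cells still sit in the rotationally offset scaffold.

## Variability model

`variabilityModel()` adds inter-embryo variability on top of the
canonical program.  All parameters are exposed; the defaults are the
package's study conditions:

* **Division-time jitter.** Each division time is perturbed by a normal
  deviate with SD $0.060\,(t-2)$ hours (clamped so daughters follow
  mothers).  The slope is calibrated so the mean max-minus-min time of
  corresponding divisions across a 3-embryo cohort reaches ≈2.5 h in
  the 30–34 hpf window; the naive order-statistics value
  ($2.5/1.693/30 \approx 0.049$) is corrected upwards because clamping
  and window selection shrink the realised range.
* **Lineage deviations.** After a 16 hpf onset, terminal-fated cells
  may undergo an extra division (probability rate/2, time skewed
  towards the onset, the deviant daughters re-entering the cycle with a
  4.5 h period) and final (leaf-producing) divisions may be skipped
  (probability rate/2).  Restricting skips to leaf divisions reflects
  that observed inter-embryo differences are local missing or extra
  terminal divisions, not the wholesale loss of clones.  The default
  rate of 0.40 is calibrated so that the end-to-end analysis —
  pairwise matching at 30 hpf with a 3 h guard and the
  "absent from both other embryos" counting rule — reports ≈10% of
  cells as differences.  The nominal rate is much larger than the
  reported percentage because only deviations that are private to one
  embryo, established before the comparison point, and reachable
  through a matched ancestor chain are counted.
* **Positional noise.** Gaussian noise with SD 2% of the hemisphere
  radius is applied per recorded timepoint, emulating nucleus-centroid
  measurement error.
* **1b-111.** The ventral rosette cell divides not at all (p = 3/6),
  once (2/6) or twice (1/6), with its first division uniform on the
  characteristic 12–24 hpf window clipped at the deviation onset.  The
  clipping resolves a tension between the printed window and the
  observation that embryos are indistinguishable before 16 hpf; with a
  lower onset the full window applies.  1b-111 is excluded from the
  generic deviation channel since its variability is already fully
  described.

All stochastic draws are namespaced per embryo and per event (a
31-bit stream seed derived by hashing the master seed with the embryo
id and event tag), so extending the program does not shift unrelated
draws, and a fixed seed reproduces an embryo bitwise.

## What the generator does and does not emulate

The generator reproduces: hemispherical geometry with fourfold
rotational then bilateral symmetry, the stereotypic division program to
~16 hpf, growth past 500 cells by 32 hpf, inter-embryo variability
with a 16 hpf onset calibrated to the observed difference fraction,
and growing division asynchrony.  It does not emulate: cell movements
and intercalation (positions are essentially static per cell),
hyposphere lineages (2d, 4d), mechanics or signalling, imaging
artefacts beyond Gaussian centroid noise, or realistic cell density
inside clones.  Tests passing on synthetic cohorts therefore establish
the correctness and calibration of the algorithms, not the biology of
any real recording.

# Corresponding cells across embryos

`matchLineages()` implements the recursive corresponding-cell
procedure.  Roots are assigned (by name, or explicitly); at each
matched pair whose members both divide before the comparison point
$t_c$ (default 30 hpf), the divisions are compared through three
features per daughter: the unit displacement from the mother at
division, the subsequent cell-cycle length, and the number of
descendant divisions within the horizon $t_c + g$.  Both daughter
assignments are scored as

$$s = \frac{w_p \sum \frac{1+\cos\theta}{2} + w_c \sum e^{-|\Delta
c|/\tau} + w_d \sum \left(1 - \frac{|n_1-n_2|}{\max(n_1,n_2,1)}\right)}
{2\,(w_p + w_c + w_d)},$$

with equal default weights and $\tau = 2$ h (the original weighting
coefficients were chosen arbitrarily and never published; equal weights
reproduce the behaviour class).  A daughter that has not divided by the
end of the recording contributes a censored cycle with lower bound
(recording end − birth); censored terms score $e^{-\max(0,\,
\text{bound} - \text{observed})/\tau}$.  The higher-scoring assignment
provides the new rooting points; exact ties prefer the assignment with
smaller summed angular offset distance, then the index-preserving one.
The recursion is greedy with no backtracking — an early mistake
propagates down its subtree, as in the original procedure.

Recordings end around 33–34 hpf while divisions continue, so
comparisons are made at 30 hpf and the remaining frames serve as
"known divisions to come": when only one member divides before $t_c$,
the partner's frames up to $t_c + g$ (default $g = 3$ h) are searched;
if the recording ends first the subtree is *censored*, otherwise it is
a *real difference*.  `countDifferences()` counts a cell as differing
at time $t$ only when it (or its originating division) is flagged as a
real difference against **both** other cohort members; censored
subtrees never count.

`buildConsensus()` groups cells across the cohort by correspondence
(union–find over the pairwise maps, applied in descending score order;
a pairing that would place two cells of one embryo in one cluster — an
inconsistent correspondence triangle, which occurs occasionally with
noisy features — is dropped, or raised as an error in strict mode).
Divisions supported by more than half the cohort are retained with
their support count, the minimal and maximal member division time, a
low-support flag (e.g. 2 of 3), and a deterministic breadth-first
reference ID (`r1`, `r2`, …).  `maxTimingAsynchrony()` averages the
max-minus-min member time over corresponding divisions whose mean time
falls in a window.

# Bilateral founders

A bilateral founder pair must (i) have a positional mirror counterpart,
(ii) produce bilaterally symmetrical clones with similar lineage-tree
topology, and (iii) arise at roughly the same developmental time.
`detectBilateralFounders()` operationalises the three criteria with
explicit tolerances: mirror distance at birth (positions averaged over
the first 30 min) at most 0.10 R, clone-topology score at least 0.8,
and birth times within 1.0 h.  The topology score is the package's own
formula — the source material states the criterion only qualitatively:
divisions of the two clones match recursively when their clone-relative
times differ by at most 1 h, and the score is $2m/(d_u + d_v)$; two
terminal cells score 1.  Candidate pairs are pruned to the earliest
qualifying generation (without pruning, every descendant pair of a
founder also qualifies), and each cell joins at most one pair (greedy
by topology score, then mirror distance, then uid).  The defaults were
chosen once so that the canonical embryo yields exactly its
founder registry; all thresholds are arguments and are reported in the
output.

`classifyFounderPair()` assigns the symmetry class from the lineage
names: identical index under the A↔B/C↔D swap (quadrant homologs),
identical index under the A↔C swap, same quadrant (single-quadrant
symmetry), otherwise non-corresponding lineages.

# Annotations and metrics

The packaged annotation fixture transcribes the 62 differentiated cell
types of the 30 hpf episphere with lineage, observation support,
approximate cycle-exit time, reference ID and expression markers; the
markers were extracted into an explicit column at transcription time to
avoid fragile runtime text parsing.  One printed row covers two
anterior prototroch cells and is stored once with multiplicity 2.  One
printed lineage contains placeholder characters for a division that
differed between recordings; it is stored truncated to its resolved
prefix, and a double reference ID is kept verbatim.

Lineage depth counts divisions from the zygote; trees rooted at the
first micromeres add a root offset of 3 (zygote → AB/CD → quadrants →
first quartet).  Cell age is time since the last division.
`projectClone()` propagates a labelled cell set (e.g. an expression
pattern mapped at 12 hpf) to its theoretical clonal offspring at a
later stage, and `clonalityScore()` compares observation with
projection by the Jaccard index — 1 for perfectly clonal inheritance,
lower when expression switches on or off between cycles.

# Numerical choices and problem sizes

* Track tables are TSV with 3-decimal times; rebuilt trees snap
  daughter births to the parent division within 0.01 h.
* The mirror-plane fit scans azimuths at 1° and refines by
  golden-section search; the brute-force check uses a 0.1° grid.
* Simulated recordings sample positions every 0.5 h plus at each
  cell's end time.
* The test suite and the acceptance analysis use 3-embryo cohorts to
  33–34 hpf (roughly 600 cells each), 10 cohort replicates for the
  stochastic calibrations, five seeds for the growth check, 200
  random instances for the matcher-versus-brute-force property and 50
  planted instances for the founder-detector property.  These sizes
  keep every analysis deterministic and reproducible on a single CPU
  while leaving the statistics well inside their tolerance bands.

# Known limitations

* Positions are static per cell (plus noise); analyses that depend on
  migration trajectories cannot be exercised against the generator.
* The late-phase program is parametric; real clone topologies at
  20–32 hpf are richer than synchronous binary growth with a depth
  cap.
* The matcher's features become uninformative when daughter
  separations fall below the positional noise; the generator keeps
  separations at realistic internuclear distances, but very dense real
  data may mis-pair deviant cells (two independent deviations can
  absorb each other), which biases difference counts downwards.
* The difference metric follows the strict two-other-embryos rule, so
  a division skipped in one embryo contributes no counted cells; only
  private extra lineage is counted.
* The expression-label registry carries user-supplied content; no gene
  atlas is shipped.
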