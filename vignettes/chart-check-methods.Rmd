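---
title: "Automated initial chart checks: models, tolerances and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated initial chart checks: models, tolerances and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartcheckr)
```

## What the package models

Before the first treatment fraction of an external-beam radiotherapy (EBRT)
course, a physicist reviews the chart: does the plan in the record-and-verify
system (OIS) match what the planning system (TPS) produced, is the
prescription arithmetic consistent, is the CT usable, are the required
workflow sign-offs in place? `chartcheckr` implements this review as three
cooperating layers:

1. a **comparison engine** that diffs the full parameter set of a TPS plan
   export against its OIS counterpart under per-field tolerances;
2. a battery of **rule checks** that go beyond field equality
   (fractionation arithmetic, isocenter geometry, CT Hounsfield screening,
   hotspot burden, couch-shift policy, attestations);
3. a **benefit model** that, given a checklist whose items carry automation
   feasibility classes, estimates how much manual review time and how many
   residual detectable errors remain at a given level of automation.

A fourth layer, the **synthetic fixture generator**, produces paired
TPS/OIS exports with deliberately injected errors so that all of the above
is testable without clinical data.

## The comparison engine

A `plan_snapshot` carries the comparable content of one plan export:
identity (patient, plan, course, approval status), prescription, technique,
machine, and per-beam geometry down to the control-point level (gantry /
collimator / couch angles, jaws, MLC leaf banks, cumulative meterset
weights, wedge / bolus / applicator accessories). Snapshots are read from a
JSON dialect or from DICOM RT Plan files; both dialects restore identical
snapshots.

`compare_plans()` walks the two snapshots in a fixed field order and emits
one discrepancy per flagged field:

* **numeric** fields are flagged when `|tps - ois|` exceeds the applicable
  tolerance; angles are first reduced to the circle (`angle_difference()`),
  so 359.8° vs 0.1° is a 0.3° difference, not 359.7°;
* **categorical** fields (energy label, wedge id, machine name, patient
  position, approval status, ...) use exact string equality after trimming
  whitespace, case-sensitive, because these are system identifiers;
* **structure** (beam sets, control-point and leaf counts, presence of
  optional attributes) is compared first; a structural mismatch suppresses
  element-wise comparison of the affected branch instead of producing a
  cascade of spurious per-element findings.

Beams are matched by `beam_name`, not list position, because OIS exports
may reorder beams; a name present on one side only, or duplicated, is a
structural discrepancy.

The default tolerance profile is **zero everywhere**: any difference is
flagged. In clinical use a handful of fields need nonzero tolerances purely
to absorb import/export rounding between systems; the packaged
`tolerances_example.yaml` shows the shape of such overrides (0.01 MU,
0.1 mm, 0.1°) without promoting them to defaults. Tolerances are matched to
fields by glob (`beams[*].mu`), last match wins, and raising any tolerance
can only shrink the set of findings — a property the test suite checks.

An absent optional attribute is kept as *absent*, never silently defaulted
to zero: absent-vs-present is itself a reportable discrepancy.

## Rule checks and their thresholds

Each rule check returns `pass`, `fail` or `not_applicable` with a detail
string naming the computed quantity and threshold. Missing inputs (no CT,
no dose grid, no target structure) degrade the affected check to
`not_applicable`; the battery never aborts on a missing optional input.

The thresholds live in `policy_config()` and are deliberately
institution-tunable — published guidance does not fix them:

| parameter | default | unit | meaning |
|---|---|---|---|
| `slice_thickness_max_mm` | 1.25 (SRS/SBRT), 3 (others) | mm | max CT slice thickness per technique |
| `hu_high_z_threshold` | 2000 | HU | inside-External HU above which density-override review is required |
| `iso_target_offset_max_mm` | 50 | mm | advisory isocenter-to-target-centroid distance |
| `mono_iso_tol_mm` | 0.1 | mm | max pairwise isocenter spread |
| `srs_jaw_mlc_gap_mm` | [0, 5] | mm | allowed jaw-to-open-leaf-tip gap band for SRS |
| `localization_tol_mm` | 1 | mm | BB/user-origin vs localization point |

The one fixed number is the hotspot threshold: a hotspot voxel is dose
**strictly greater than 110%** of the total prescription dose, so a voxel
at exactly 110.0% does not count. "Delta couch cleared" is interpreted as
*absent or exactly zero*; SRS/SBRT plans conversely require a stored couch
shift. Checks whose clinical implementation queries an electronic medical
record (peer review, billing approval, consent) are modeled as boolean
attestations carried in the OIS snapshot and verified for presence and
truth — verifying the *content* of such documents is out of scope.

## Geometry and voxel labeling

Structure summaries use the area-weighted mean of per-slice polygon
centroids (shoelace formula), so two equal disjoint parts average
symmetrically, and bounding boxes over all contour points. Voxel membership
against the External contour is decided by testing the **voxel center**
with an even-odd ray cast; points exactly on the contour count as inside,
which makes labeling deterministic when contours pass through voxel
centers. Contours are matched to the nearest slice within half a slice
thickness. The suite cross-checks this labeling against an independent
point-in-polygon implementation (`mgcv::in.out`) and against brute-force
voxel scans on grids up to 20x20x6.

## The benefit model

Checklist items carry an automation feasibility class per scenario:
`Full` (fully automatable), `Partial` (automation can verify presence but
not correctness), `Full/Partial` (full automation attainable under stated
practice changes), `No` (manual only). The manual-burden weight is 0, 0.5,
1 for Full/Partial/No, and classes between two levels are averaged —
`Full/Partial` scores (0 + 0.5)/2 = 0.25.

Residual manual time under a scenario is the weight-scaled sum of per-item
times. Published time data give only checklist totals, so the default
allocates the total **uniformly** across items; a per-item minutes mapping
can be supplied when a clinic has one. Consequently scenario-level *time
fractions* are exact under the model, while reconstructing any specific
published per-figure reduction would require the unpublished per-item
times — those figures are treated as context, not as test targets.

Residual detectable errors per workflow step scale the step's baseline
percentage (patient assessment 7.7, simulation 28.2, treatment planning
49.2 — the packaged incident-learning baseline) by the step's non-automated
burden. "Proportional to the number of items that cannot be automated" is
ambiguous between counting items and weighting them; the default
`error_model = "weighted"` uses the mean weight (partial automation earns
partial credit, consistent with the time model), and `"count"` treats any
nonzero weight as fully manual for sensitivity analysis. Scenario `none`
maps every item to `No` by definition and reproduces the baseline exactly;
a fully automated list drives every step to zero.

The packaged 60-item checklist encodes the printed expert re-evaluation
table: per item, the survey class and the expert class, with categories
synthesized as stable ids (`PA-*`, `SIM-*`, `TP-*`) because the source
prints descriptions, not identifiers. On this table the expert classes
dominate the survey classes item by item, so residual time is ordered
`none >= auto_tg275 >= auto_umms_exp` — an invariant the suite asserts.
The published survey also derives a priority list by keeping items with
RPN > 100 **and** use > 60%; both inequalities are strict in
`filter_priority()` to match that wording. A companion 44-item skeleton
(36 recommended + 8 optional) exercises list mechanics for the minimum
checklist without reproducing its text.

## The synthetic fixture generator

`generate_plan_pair()` builds one plausible clean plan — 60 MLC leaf pairs
of 5 mm (a common linac head layout; plausible but arbitrary), 10 control
points for dynamic techniques and 2 for static, prescriptions drawn from
common fraction schemes with consistent totals, all values rounded so the
decimal DICOM encoding round-trips exactly — and exports it twice. Errors
from an 18-type taxonomy (MU delta, energy swap, angle deltas, isocenter
and leaf and jaw shifts, fractionation mismatch, removed accessories,
identity changes, cleared approvals, injected couch shifts, localization
offsets, dose-grid hotspots) mutate the OIS copy; every mutation is
recorded in a manifest with its resolved field paths and before/after
values. The generator runs on a private seeded RNG stream and leaves the
global RNG untouched; identical seeds give byte-identical output.

Two properties tie the layers together and are the backbone of the test
suite: **identity** (any snapshot is clean against itself under any
tolerance profile) and **injection completeness** (for every snapshot
error type, zero-tolerance comparison flags exactly the manifest's field
paths — no misses, no collateral findings). The suite checks the latter
over 112 seeded fixtures (2 beams, 4 control points, 20 leaf pairs; small
enough that the full battery runs in seconds) plus an independent generic
tree-diff of the snapshots. `hotspot_injected` is the one taxon that does
not touch the snapshot: it parameterizes `generate_dose_grid()`, which
raises exactly `round(fraction x n_voxels)` seeded voxels to 115% of
prescription, and is verified through `check_hotspot()` instead.

What the generator does **not** emulate: anatomically realistic CT or
deliverable MLC sequences, correlated multi-field errors, or export
rounding noise. Passing tests therefore demonstrate the engine's detection
semantics, not performance on any vendor's real exports.

## DICOM encoding

No installed R package reads DICOM, so the package carries its own minimal
RT Plan codec: explicit VR little endian, defined-length sequences on
write, defined or undefined lengths accepted on read. Beam geometry,
control points, MLC banks, metersets, wedges, applicators, tolerance
tables and patient setup use their standard attributes; snapshot fields
with no standard RT Plan home (user origin, couch delta, prescription
details, attestations) travel in one private element (creator
`CHARTCHECKR`) as compact JSON — the same pattern vendors use for private
extensions. Generated files are validated in the suite with pydicom as an
independent reader. One representational restriction: per-control-point
jaw positions on the *first* control point must agree with the beam-level
jaws (the writer refuses otherwise rather than silently losing data).

## Numerical choices and degenerate inputs

* Coordinates are DICOM patient-system millimetres as stored, angles IEC
  61217 degrees, doses centigray; nothing is resampled.
* Zero tolerance means `|difference| > 0` flags — values differing only in
  storage precision are flagged on purpose; absorbing rounding is what
  nonzero overrides are for.
* Leaf banks must not cross (A ≤ B within 1e-9); cumulative meterset
  weights must be nondecreasing in [0, 1]; violations are validation
  errors, not findings.
* A structure with no contour points is flagged degenerate and excluded
  from geometric checks rather than contributing NaN centroids.
* An empty outside region (External covering the whole grid) reports the
  outside maximum as absent, not as -Inf.
* Ties in tolerance-glob matching resolve to the last listed override.

## Problem sizes

The shipped tests run the property battery on 112 single-error fixtures
plus multi-error and reversed-argument cases, compare grids up to 64³-sized
equivalents (20x20x6 CT, 12x12x8 dose) against brute-force scans, and
finish in well under a minute on one CPU. These sizes were chosen as the
smallest that still exercise every code path (multiple beams, dynamic
control points, both MLC banks, all error types).

## Known limitations

* Published figure-level outcomes (per-checklist percentage reductions,
  step-wise residual-error columns) depend on unpublished per-item check
  times and a full 151-item classification; the package reproduces the
  *model* and its printed inputs, and treats those outputs as
  non-reproducible references.
* The 60-item table is the printed subset of a larger re-evaluated list;
  tallies are exact for the printed rows.
* Dose recomputation, DVH analysis, EMR/OIS live connectivity and natural-
  language document parsing are out of scope by design; document checks
  reduce to presence/attestation booleans.
* The comparison engine reports findings; it does not judge clinical
  significance. A zero-tolerance run on real exports will flag benign
  rounding unless overrides are configured.
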