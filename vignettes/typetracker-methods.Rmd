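---
title: "Inferring cell-type histories from end-point staining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-type histories from end-point staining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typetracker)
```

## The problem

Time-lapse microscopy of intestinal organoids yields complete lineage trees
of tracked nuclei, but live imaging alone cannot tell what type each cell
is. Antibody staining identifies types, but only once, after fixation at
the movie end point. `typetracker` joins the two: it calls a type for every
stained end-point cell, matches those cells one-to-one to the tracked cells
in the last frame, and then propagates the types backward along the lineage
trees, producing a per-frame type for every tracked cell together with the
moment and position at which each lineage committed to a new type.

The package also quantifies the resulting differentiation program:
positions along the crypt-villus axis, migration speeds, neighbor-graph
persistence, sister-type symmetry, divisions and cycle durations per type,
and a census of two-type subtrees. A seeded synthetic-crypt generator with
ground-truth commitment events underpins the test suite.

## End-point typing

Each stained cell carries six markers: Olfm4, Cga, Aldob (aldolase beta),
KRT20, WGA and Lyz. The decision table in `call_type()` is:

| pattern                      | type       |
|------------------------------|------------|
| Olfm4+ only                  | STEM       |
| Cga+ only                    | EEC        |
| Aldob+ (KRT20 either way)    | ENTEROCYTE |
| WGA+ Lyz+                    | PANETH     |
| WGA+ KRT20+ Lyz−             | GOBLET     |
| WGA+ only                    | IMPC       |
| all six negative             | TA         |
| anything else                | UNKNOWN    |

The mapping is total: every one of the 64 patterns yields exactly one
label, with `UNKNOWN` as the sink for contradictory panels (these are also
reported as conflicts). Positivity is `intensity > threshold`, strictly: a
cell exactly at the threshold is negative. Because visual positivity
assessment is not reproducible, thresholds are explicitly user-governed;
when none are given, a per-marker Otsu threshold over the staining table is
used, with the plateau midpoint taken when the Otsu criterion is flat
across an empty intensity gap.

## Matching stained to tracked cells

Fixation and repeated staining deform the tissue, so stained cells are
linked to tracked end-point cells by a one-to-one assignment minimising
total Euclidean distance, subject to a hard gate: no matched pair may be
farther apart than `max_match_distance` (default 10 μm, about one nucleus
diameter). Among gate-satisfying assignments the solver returns the one of
maximal cardinality with minimal cost. The gate plus the exported
unmatched/ambiguity report replaces interactive manual correction of the
linking; an optional rigid (centroid translation) pre-registration is
available but off by default.

The solver is a dense Jonker–Volgenant shortest-augmenting-path assignment
on a padded square matrix (real pair cost `d − K` with `K` large enough
that cardinality dominates; forbidden pairs effectively infinite). Cost
ties are broken toward lexicographically smallest (track, stain) pairs via
an epsilon perturbation of 1e-9 relative scale — far below micrometre
distances, so optimality is unaffected at any realistic precision. The
tests verify optimality against an exhaustive bitmask-DP oracle on
instances up to 8×8, with and without the gate.

## Backpropagation rules

Types flow from the leaves to the roots. Along a track the type is
unchanged; at each division fork, in order:

1. **R2 (symmetric fate).** Both daughters share an inferred type → the
   mother is that type.
2. **R3 (stem).** Exactly one daughter is STEM → the mother is STEM (stem
   cells come from stem cells).
3. **R4 (TA).** One daughter is TA and the other is not STEM → the mother
   is TA (TA cells are proliferative intermediates).

A dead daughter does not constrain the fork: the mother takes the living
daughter's type. Daughters with `UNKNOWN` type (lost tracks, unmatched end
points) are handled the same way, but the mother is flagged low-confidence,
since the missing subtree could in principle have contradicted the
inheritance; with both daughters unknown the mother stays `UNKNOWN`. Two
daughters with distinct terminally differentiated types cannot be resolved
by the rules; the mother becomes `UNKNOWN` and the fork is recorded as a
conflict. The rule precedence R2→R3→R4 never actually needs a tie-break —
the one overlapping case, a (STEM, TA) fork, gives STEM under both R3 and
the ordering — but it is fixed and tested.

Whenever a daughter's type differs from its mother's (both known), a
transition event is placed at the floor midpoint of the daughter's observed
lifetime, `floor((first + last)/2)` frames, with the cell's position at
that frame. For tracks already present at the movie start the observed span
stands in for the full cycle. Per-track types are piecewise constant:
before the event frame the track carries the mother's type, from the event
frame on its own.

## Crypt-villus axis geometry

The per-frame axis is a natural cubic spline through 3–6 annotated control
points (crypt bottom first), reparameterised to arc length by dense
sampling at 0.25 μm. Projection of a cell minimises its distance to the
curve: nearest dense sample followed by a three-point parabolic refinement
of the squared distance (also applied at the curve ends, with the vertex
clamped to the sampled span). The tests require agreement within 0.1 μm of
a 0.01 μm brute-force grid and a quarter-circle arc length within 1% of
the analytic value.

Within each frame the bottom-most cell defines position zero and positions
are divided by the zeroed arc-length of the annotated crypt neck, which
therefore sits at normalised position 1 in every frame. Migration speed is
the zeroed-position difference between a track's last and first observed
frames divided by the elapsed time; a least-squares slope over all frames
is available (`method = "regression"`) but the two-point definition is the
default. Frames lacking their own annotation reuse the nearest annotated
frame within ±5 frames; farther gaps are an error. Projection uses all
three coordinates by default (`use_z = FALSE` switches to in-plane
distance, for annotations drawn in a single z-plane).

## Neighbor graphs and separation rates

Two cells A and B are neighbors when no third cell lies between them,
operationalised by the neighbor score `(dAS + dBS)/dAB` minimised over all
other cells S in the frame: the pair are neighbors iff that minimum is
strictly greater than 2 and B is among A's twenty nearest cells. Candidate
pairs from either endpoint are pooled, so the graph is symmetric by
construction. The blocking set is deliberately *all* other cells, not just
the twenty candidates — restricting S could only add spurious edges at the
tissue boundary.

The strict cutoff has a knife-edge consequence worth knowing: on a perfect
triangular lattice every adjacent pair has two equidistant common
neighbors forming equilateral triangles, so its minimal score is exactly 2
and the pair is *not* adjacent under the strict rule. Real epithelia are
disordered, which breaks the degeneracy; on a unit square lattice the rule
gives interior cells exactly their four axis-aligned neighbors
(min score 1 + √2 ≈ 2.414), with diagonal pairs blocked (2/√2 ≈ 1.414).

Separation rates follow pairs over time. For each newly born cell, partners
are its graph neighbors one hour after the division (when nuclei have
returned to the basal surface). Each pair is then checked at each horizon
(defaults 2 h and 10 h after selection) in the graph of the single frame
nearest the horizon. If a member of a pair divides during follow-up, one
daughter — chosen uniformly with the run's seeded RNG — is followed
instead; we apply this substitution to both members, not only the selected
partner, since the rationale (do not cut follow-up short by division)
applies equally to the focal cell. Pairs whose horizon falls beyond the
movie are excluded and counted; pairs whose lineage dies or is lost count
as separated. Sister separation applies the same protocol to same-type
sister pairs, stratified by type.

## Lineage statistics

* **Sister-type histogram** — over sister pairs both alive at the movie
  end: for each type column, pairs with at least one member of that type
  are counted, same-type pairs counting twice in their own column, and each
  column is normalised by its sum. Pairs with an `UNKNOWN` member are
  excluded and reported.
* **End-point ages** — time since birth; tracks present from the first
  frame get the movie length.
* **Divisions per type** — fork counts within maximal same-type connected
  lineage segments (a daughter extends its mother's segment iff it has no
  transition and shares the mother's type).
* **Cycle durations** — fork-to-fork times of complete cycles only,
  attributed to the type at division.
* **Two-type subtree census** — maximal subtrees whose cells comprise
  exactly two distinct types. "Maximal" is not formally defined in the
  literature this implements; we define it as: the root's parent subtree
  (if any) contains a third type. `UNKNOWN` never counts as a type, and
  subtrees in which more than half of the cells died or were lost are
  excluded and counted. The definition is verified against brute-force
  enumeration on randomized trees.

## The synthetic crypt generator

`simulate_crypt()` emulates the statistical structure the inference
assumes: cells live on the surface of a cylinder (radius 12 μm, crypt
60 μm + villus 80 μm), imaged every 0.2 h for 60 h, starting from 24 cells
with a mixed composition (half stem, a third TA, the rest differentiated)
placed by type along the axis. Cycle times are lognormal with per-type
means of 12.5 h (enterocyte), 14.1 h (TA), 15.5 h (stem) and 15 h for the
secretory types, CV 0.15, truncated below at 4 h. Motion is advection
proportional to the number of proliferative cells below (0.012 μm/h per
cell) plus isotropic per-frame jitter (0.25 μm), which yields villus-bound
cells outrunning crypt residents. Paneth and IMPC daughters receive a
one-off tangential sister-scatter displacement (8 and 6 μm, with
probability 0.8 and 0.6) so sister-separation stratification has a planted
signal.

Differentiation follows a commit-then-divide model: at each division of a
proliferative mother, with probability 0.35 one daughter is scheduled to
commit; if that daughter later divides, the commitment is realised at a
uniform time within its lifetime and both of its daughters inherit the new
type (stem commits mostly to TA, rarely directly to secretory fates; TA
commits to enterocyte, goblet or EEC). Committed terminal daughters draw a
small division budget (up to 5 further divisions for enterocytes, 0–2 for
secretory types).

Three constraints make the planted events *identifiable by design*, which
is the point of a ground-truth benchmark:

1. Commitment is realised only in cells that subsequently divide, so a
   cell's end-point type always equals its birth type and end-point sisters
   are same-type by construction.
2. At most one daughter per fork is scheduled to commit, so the sister
   subtree of every committing cell provably retains a leaf of the old
   type — which is exactly the condition under which the backpropagation
   rules place the inferred transition in the committing track.
3. Terminal commitments, and all divisions inside terminal clones, are
   realised only before `movie_length − maturation_delay`, so every
   differentiated end-point cell is marker-mature.

Under these conditions, noiseless staining gives an end-point sister
same-type fraction of exactly 1.0 and 100% recovery of planted commitments
in the correct track, and the tests assert both. Real recordings satisfy
none of the three constraints exactly — commitments can strike both
sisters, late commitments are invisible to end-point staining, and sister
symmetry is high but not perfect — so passing these tests demonstrates
correctness of the inference machinery, not that real data would be this
clean.

Marker maturation runs from the later of commitment and the cell's last
division (default delay 20 h): marker proteins take time to accumulate and
signal rises in the daughters after a division. A differentiated cell
younger than the delay appears unstained and is typed TA, exactly the
failure mode end-point staining has in reality; the generator's
deadline constraint keeps this out of the default benchmark but the
behaviour is exercised when configurations are varied. `degrade_dataset()`
adds staining-position jitter, marker-call flips and track truncation;
flips use common random numbers so that the flipped set at a lower rate is
nested in the flipped set at a higher rate, making noise-sweep recovery
curves directly comparable (and monotone).

## Numerical and scale choices

* Frames are the primitive time unit; hours are derived via
  `frame_interval_h` (default 0.2 h). Division timing is resolved at frame
  granularity; a daughter's first frame is its mother's last frame plus
  one.
* Tracks ending early without daughters and without an explicit death flag
  default to `lost` — conservative, since lost cells cannot anchor types.
* Spline sampling at 0.25 μm and 0.01 μm for the brute-force oracle;
  projection tolerance 0.1 μm; arc-length tolerance 1% on the
  quarter-circle.
* The test suite runs the full simulated benchmark at its default size
  (about 300 end-point cells over 60 h) once, plus a three-level label-noise
  sweep; the remaining tests use smaller crypts (6–40 h, 6–20 initial
  cells) and randomized trees of at most five generations.

## Known limitations

* Typing consumes a single merged staining table; registration of raw
  multi-round images is out of scope, as is segmentation and tracking
  itself.
* The brightness of the nuclear marker, which can assist pre/post-fixation
  linking, is not modelled; matching is position-only.
* No probabilistic typing: a lineage is one type per interval, transitions
  are point events, and conflicting evidence collapses to `UNKNOWN` rather
  than a posterior.
* The fork rules are strictly local; no global consistency pass
  reconsiders a fork in the light of cousins.
* The generator is not a mechanical model of the epithelium: no cell-cell
  forces, no Notch-style signaling, a straight tube rather than a budding
  organoid, and commitment hazards are per-division rather than
  niche-position-dependent.
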