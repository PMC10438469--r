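# typetracker

Live imaging of intestinal organoids tracks every nucleus through space,
time and division — but says nothing about cell type. Antibody staining
identifies types — but only once, at the movie end point, after fixation.
`typetracker` is an R package for researchers who have both: it maps the
stained identities onto the tracked cells of the last frame and propagates
them backward along the lineage trees, so that every cell in the recording
acquires a type history, including the moment and the position at which
each lineage committed to a new fate.

## What it computes

**End-point typing.** Each stained cell carries six markers (Olfm4, Cga,
Aldob, KRT20, WGA, Lyz). `call_type()` applies the typing table — Olfm4+ →
stem; Cga+ → enteroendocrine (EEC); Aldob+ → enterocyte; WGA+Lyz+ → Paneth;
WGA+KRT20+ → goblet; WGA+ only → immature mucus-producing cell (IMPC); all
negative → transit-amplifying (TA); contradictory panels → UNKNOWN.
Stained cells are matched one-to-one to tracked end-point cells by a
min-cost assignment with a hard distance gate (default 10 μm).

**Backpropagation.** Types flow from leaves to roots under the fork rules:
if both daughters share a type, the mother is that type; if one daughter is
a stem cell, the mother is a stem cell; if one daughter is TA and the other
is not stem, the mother is TA. A mother that differs from a daughter
implies a type transition, marked halfway through the daughter's lifetime.

**Quantification.** Arc-length positions along a spline-fitted crypt-villus
axis (zeroed at the bottom-most cell, normalised by the neck distance),
migration speeds, neighbor graphs under the neighbor score
*(d*<sub>AS</sub> *+ d*<sub>BS</sub>*)/d*<sub>AB</sub> with strict cutoff 2,
neighbor/sister separation rates over 2 h and 10 h horizons, sister-type
histograms, per-type ages, divisions and cycle durations, and a census of
maximal two-type subtrees.

**Synthetic benchmark.** `simulate_crypt()` generates seeded crypt-villus
recordings with ground-truth commitment events, staining tables and axis
annotations; `degrade_dataset()` adds staining jitter, marker-call noise
and track loss. The methods vignette
(`vignettes/typetracker-methods.Rmd`) documents every model choice.

## Worked example

```r
library(typetracker)

ds     <- simulate_crypt(sim_config(), seed = 17)   # tracked crypt + staining
typing <- assign_endpoint_types(ds$forest, ds$stain, max_match_distance = 10)
typed  <- backpropagate(ds$forest, typing)
typed
#> Typed lineage forest: 506 tracks, 20 type transitions, 0 conflicts
#>
#> ENTEROCYTE     GOBLET       IMPC     PANETH       STEM         TA
#>         26          6          3          3        165        303

sister_type_histogram(typed)
#> End-point sister pairs: 124 (0 excluded), same-type fraction 1
#>            STEM TA ENTEROCYTE GOBLET IMPC
#> STEM          1  0          0      0    0
#> TA            0  1          0      0    0
#> ENTEROCYTE    0  0          1      0    0
#> GOBLET        0  0          0      1    0
#> IMPC          0  0          0      0    1

round(sapply(cycle_durations(typed)[c("STEM", "TA", "ENTEROCYTE")], mean), 1)
#>       STEM         TA ENTEROCYTE
#>       15.4       13.9       12.3

two_type_subtrees(typed)
#> Two-type subtree census: 13 subtrees (0 excluded)
#>   STEM|TA                   8  (61.5%)
#>   ENTEROCYTE|TA             3  (23.1%)
#>   GOBLET|TA                 2  (15.4%)

mean(ds$truth$transitions$track_id %in% typed$transitions$track_id)
#> [1] 1
```

Because the simulated staining is noiseless and commitments are planted
identifiably, every end-point sister pair shares a type (the identity
histogram), all 20 planted commitment events are recovered in the correct
track, and the recovered mean cycle durations sit at the configured
per-type means (15.5/14.1/12.5 h for stem/TA/enterocyte). The subtree
census shows the expected structure: most two-type subtrees pair TA with
either stem or a differentiated type. `plot(typed)` draws the lineage trees
coloured by inferred type with transition markers.

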