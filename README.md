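# vesselfc

Seeded segmentation of hepatic vessels in contrast-enhanced 3D CT by
**adaptive-threshold fuzzy connectedness**, with a refined region-growing
comparator, a synthetic vascular phantom generator, and volumetric
evaluation tools. The package is aimed at medical-image-analysis
researchers who need a reproducible, scriptable implementation of the
method and a fully synthetic test bed that requires no patient data.

## The method

Given a scene *C* (a 3D volume windowed to 0–255) and one seed voxel
inside a vessel:

1. **Affinity.** Adjacent voxels (6-adjacency) are related by a Gaussian
   of their pair-mean intensity around the vessel mean,
   μ<sub>k</sub>(c,d) = μ<sub>α</sub>(c,d) · exp(−½[((f(c)+f(d))/2 − m)/s]²).
2. **Seed-robust parameters.** *m* and *s* come from Otsu-splitting a
   20³ cube around the seed and taking the brighter class; the seed's
   intensity is replaced by *m*, so results do not depend on whether the
   user clicked the vessel centre or its blurred edge.
3. **Connectivity scene.** The fuzzy connectedness
   μ<sub>K</sub>(seed, d) — the max over paths of the min link affinity —
   is computed for all voxels by Dijkstra-style max-min propagation, with
   all 65,536 possible affinities pre-tabulated in a 256×256 lookup table
   (bit-identical to direct evaluation, roughly half the runtime).
4. **Adaptive threshold.** On the histogram of the connectivity scene, a
   watershed-like search finds the endpoint EP where the cumulative
   segmented volume ∫<sub>h</sub>¹ H(x)dx reaches the physiological cap
   (50 ml for whole-liver vasculature), then takes EP — or the next
   histogram peak toward 1.0 — as the threshold *T*. The mask is
   CS ≥ *T*.

A descending-threshold, 26-adjacent refined region-growing baseline
(`rrg()`), a branching/two-system phantom generator with analytic ground
truth, and Dice/difference-set/volumetry utilities round out the package.

## Worked example

```r
library(vesselfc)

ph   <- default_phantom(rng_seed = 42)        # 64^3, 7-segment vessel tree
seed <- seed_in_trunk(ph)                     # (33, 33, 19)
cap  <- 1.5 * mask_volume(ph$truth)$volume_ml # phantom-scale volume cap

fit <- fuzzycon(ph$scene, seed, max_volume_ml = cap, bins = 64)
summary(fit)
#> Fuzzy-connectedness segmentation summary
#>   seed:            (33, 33, 19)
#>   vessel class:    m = 152.633, s = 12.601 (Otsu cut 116)
#>   threshold:       T = 0.4219, EP = 0.01562, EP is not a peak
#>   reached voxels:  262144 (100.0% of scene)
#>   segmentation:    1541 voxels, 1.541 ml
dice(fit$mask, ph$truth)
#> [1] 0.9896171
```

The estimated vessel class (m ≈ 152.6, s ≈ 12.6) sits close to the
generator's nominal 160 ± 10 after blur; the adaptive search walks from
EP = 0.016 (where the cumulative volume exceeds the cap) up to the vessel
mode at T = 0.42, and the resulting 1,541-voxel mask overlaps the
1,541-voxel analytic truth at Dice 0.99. The comparator on the same
phantom:

```r
base <- rrg(ph$scene, seed, theta_end = 100, strategy = "absolute")
dice(base$mask, ph$truth)
#> [1] 0.9137267
mask_volume(difference_set(fit$mask, base$mask))   # edge voxels FC adds
```

`plot(fit)` draws the connectivity histogram with EP and T marked;
`plot(base)` draws the region-growth trace. A thin command-line front end
(`exec/vesselfc`) exposes `segment-fc`, `segment-rrg`, `phantom`,
`evaluate` and `histogram` subcommands over NIfTI/MetaImage/raw volumes
and writes a provenance JSON with every run.

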