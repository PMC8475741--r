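# agephantom

Retrospective dose reconstruction for childhood cancer survivors needs a
body model that can be scaled to the patient's age at radiotherapy — often
an age for which no CT exists and no fixed-age reference phantom is
available. `agephantom` implements such an age-scalable 3-D computational
phantom pipeline in R, for medical physicists and late-effects
epidemiologists: a generic adult phantom of body-region cuboids and organ
point grids is scaled to any age from 0.1 to 18 years and exported as a
DICOM RT Structure Set (optionally with a synthetic water-equivalent CT
series) that any treatment planning system can ingest.

## The model

Body-region sizes $S(d, r, a)$ are tabulated per direction
$d \in \{x, y, z\}$ and region
$r \in \{\mathrm{uh}, \mathrm{lh}, \mathrm{n}, \mathrm{tr}, \mathrm{ar}, \mathrm{lg}\}$
at ages $a \in \{0.1, 1, 3, 5, 10, 15, 18\}$ y. Scaling factors are

$$F_{dis}(d,r,a) = S(d,r,a)\,/\,S(d,r,18),$$

interpolated piecewise-linearly in age ($F_{cont}$), clamped to 1 above
age 18. Points transform per region as

$$x_t = x\,F_{cont}(x,r,a), \qquad
  y_t = \sum_{r'=\mathrm{uh}}^{r} l_{r'\!,y}\,F_{cont}(y,r',a), \qquad
  z_t = (z - z_{abr,r})\,F_{cont}(z,r,a) + z_{shift,r},$$

where the $y$ sum telescopes scaled region lengths from the top of the head
down (keeping regions exactly contiguous at every age) and $z_{shift,r}$
centres each region on the head's scaled mid-plane. Organs scale with their
containing region. Validation metrics include percent differences, the
normalized mean square distance between corresponding organ points
(implemented as RMS distance, mm), height comparison against
50th-percentile population tables, and organ masses as ICRU-46-style
densities × voxelized convex-hull volumes.

The true generic-phantom coordinates are proprietary, so the package ships
a seeded synthetic fixture with the documented structural properties
(adult height 176 cm; head fraction 1/4 of height at age 0.1 falling to
1/7 at 18; a 55-point heart, 15-point kidneys, one-point pituitary). See
`vignettes/agephantom-methods.Rmd` for assumptions and design choices.

## Worked example

```r
library(agephantom)

fx <- generate_fixture_phantom(seed = 7)
fx$phantom
#> Generic phantom (age 18 y): 5 chained regions, 2 arm cuboid(s), 20 organs, height 176.0 cm

scaled <- scale_phantom(fx$phantom, fx$growth, age = 3.9)
scaled$factors
#> Scaling factors at age 3.9 y (interval [3, 5]):
#>       uh     lh      n     tr     ar     lg
#> x 0.8635 0.8635 0.7025 0.6025 0.6025 0.6025
#> y 0.7480 0.7480 0.6760 0.5800 0.5800 0.5224
#> z 0.8635 0.8635 0.7025 0.6025 0.6025 0.6025
```

At 3.9 years every region has shrunk anisotropically (legs to 52% of adult
length, head to 75%), giving a 101.8 cm phantom. Export to DICOM:

```r
dicom <- reorient_to_dicom(scaled)          # head-first supine, mm, LPS
rois  <- phantom_roi_set(dicom, slice_spacing = 2.5)
#> Warning: non-contourable organ(s) exported as POINT ROIs: pituitary
write_rtstruct(rois, "phantom_3.9y.dcm", metadata = list(age_years = 3.9))
stopifnot(length(check_rtstruct("phantom_3.9y.dcm")) == 0)
```

27 ROIs are written: 7 body-region boxes, 19 convex-hull organs, and the
single-point pituitary (too few points for a hull) as a POINT structure.
Heights track a 50th-percentile population table:

```r
heights <- data.frame(age = c(1, 5, 10, 18), height_cm = sapply(
  c(1, 5, 10, 18),
  function(a) phantom_height(scale_phantom(fx$phantom, fx$growth, a))))
pop <- read.csv(system.file("extdata", "heights_50th_example.csv",
                            package = "agephantom"))
compare_heights(heights, pop)
#>   age reference_cm phantom_cm percent_difference
#> 1   1         75.7         75         0.92470277
#> 2   5        109.2        109         0.18315018
#> 3  10        138.4        138         0.28901734
#> 4  18        176.1        176         0.05678592
```

The percent differences (< 1% here) are |reference − phantom| / reference;
the adult heart's mass from its voxelized hull at 1 mm voxels and
1.05 g/cm³ is `organ_mass(heart, 1.05, voxel = 1)` → 1100.5 g (a convex
hull over a coarse point grid — an upper envelope of the organ shape, not
an anatomical mass).

A command-line wrapper is installed at
`system.file("cli", "agephantom.R", package = "agephantom")`:

```sh
Rscript inst/cli/agephantom.R generate --age 3.9 --out-dir out --ct
Rscript inst/cli/agephantom.R validate --out-dir out --heights inst/extdata/heights_50th_example.csv
```

`generate` writes the RT-STRUCT (plus CT series with `--ct`) and a JSON
manifest recording the exact scaling factors, ROI list and warnings;
`validate` emits height, per-region volume percent-difference, NMSD and
(given reference files) mass tables. Exit codes: 0 success, 2 usage error,
3 validation error.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — fixture generation, scaling to the 3.9-year worked
example, RT-STRUCT write / independent read-back / conformance check,
dual-path self-consistency at the ten standard validation ages, and the
height and mass metrics — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
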