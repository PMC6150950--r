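# megres — spatial resolution of MEG beamformer source imaging

`megres` is an R package for quantifying, in simulation, how finely a
linearly constrained minimum variance (LCMV) beamformer can spatially
separate two nearby cortical sources in magnetoencephalography (MEG) — and
for showing how much that resolution improves when the experimental design
lets the sources be separated *in time*.

An LCMV beamformer estimates source activity at a location/orientation
θ as `q(t) = w' m(t)`, with weights

    w' = l' C⁻¹ / (l' C⁻¹ l)

(`l` the forward field, `C` the sensor covariance), imaged as the
noise-normalised pseudo-z statistic `z = w'Cw / (υ² w'w)`. The weights
place spatial nulls on every other source represented in `C`. When two
sources are active in disjoint time windows, computing separate segment
covariances `C₁` and `C₂` — and separate weights from each — removes the
other source from each filter's minimisation problem and sharpens both
images. The package implements the three reconstruction strategies
(single weights/single image, single weights/two images, two weights/two
images), an 80%-dip two-peak resolvability criterion, a
minimum-resolvable-distance search over randomly placed source pairs on a
shrunken brain-surface ellipsoid, closed-form infinite-data images as an
analytic oracle, and a volumetric pseudo-t mapping pipeline for
post-movement beta rebound (PMBR) responses with peak-coordinate
statistics.

Everything is simulated from first principles: a parametric 275-channel
helmet, a Sarvas closed-form dipole forward model with a multiple local
spheres conductor, boxcar-gated stochastic dipole timecourses (31 ± 3 nAm
across trials), Gaussian sensor noise at three SNR levels (36/21/8 fT
in-band), and a multivariate phase-randomised surrogate generator for
recycling measured interference records. No external data are required.

## Worked example

```r
library(megres)

## two sources 12 mm apart on the shrunken ellipsoid, medium SNR
geo <- default_geometry()                      # helmet, head, source surface
cfg <- study_config(n_repeats = 2, methods = c(1, 3), seed = 1)
res <- resolution_study(cfg)
res
#> <resolution_result> 2 repeats, medium SNR
#>  method mean_mm     sd_mm n
#>       1    9.50 8.4852814 2
#>       3    1.25 0.3535534 2

## the headline 20-repeat study (~1 minute)
res20 <- resolution_study(study_config(n_repeats = 20, methods = c(1, 3),
                                       seed = 1))
res20$summary
#>   method mean_mm    sd_mm  n
#> 1      1  11.475 6.831573 20
#> 3      3   1.925 0.977039 20
res20$tests$p_one_sided_a_greater
#> [1] 1.230362e-06
```

With a single weights vector computed from all data (method 1), the mean
minimum resolvable separation under medium sensor noise is ~11.5 mm;
deriving separate weights from the two half-trial covariances (method 3)
sharpens that to ~1.9 mm, a ~6× improvement whose per-repeat dominance is
significant at p ≈ 10⁻⁶ (one-sided paired t-test over shared placements
and noise realisations). The corresponding measurements with a real
275-channel system and its (unpublished) helmet geometry are 16.5 mm and
2.8 mm — the same ratio at a ~40% larger absolute scale, consistent with
the parametric helmet's larger source–sensor distances.

A command-line front-end over the same functions ships in
`inst/cli/megres.R`:

```sh
Rscript inst/cli/megres.R simulate --config cfg.yaml --out ds.rds --d 0.012
Rscript inst/cli/megres.R profile  --config cfg.yaml --dataset ds.rds --method 3 --out prof.tsv
Rscript inst/cli/megres.R study    --config cfg.yaml --out-tsv study.tsv --out-json study.json
Rscript inst/cli/megres.R map      --config cfg.yaml --datasets r1.rds,r2.rds --out-dir pmbr/
```

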