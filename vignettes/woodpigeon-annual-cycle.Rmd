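---
title: "Methods: annual-cycle segmentation, home ranges and recovery mapping for partial migrants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annual-cycle segmentation, home ranges and recovery mapping for partial migrants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palumbus)
```

## The scientific problem

Common Woodpigeons (*Columba palumbus*) breeding in Central Europe are
facultative partial migrants: within one urban breeding population, some
individuals winter on site, some shift a few tens of kilometres, and some
migrate several hundred kilometres along the East Atlantic flyway to
south-western France — and an individual can switch strategy between years.
Quantifying this requires a chain of fairly standard but fiddly analyses on
satellite (Argos) and GPS tracking data and on ringing-scheme
mark-recovery records. `palumbus` implements that chain as reusable,
tested functions:

1. location-quality filtering (Argos location classes; a 30 m/s speed sweep),
2. segmentation of tracks into breeding / migration / stopover / wintering
   phases and migration phenology,
3. kernel utilization distributions (KUD), home-range areas and land-cover
   composition,
4. circular statistics of city-to-farmland foraging flights,
5. ANOVA-based repeatability (intraclass correlation) of site use,
6. ring-recovery filtering, line-density and recovery-position kernels.

Because raw tracking archives of this kind are typically not public, the
package ships a ground-truthed simulator of the whole data-generating
process; every analysis stage is tested against the simulator's exact truth
records and against closed-form oracles.

## Filtering

Argos fixes are kept only for location classes 3, 2 and 1 (nominal errors
of roughly 250, 500 and 1500 m; worse classes carry kilometre-scale errors
with no stated bound). Both Argos and GPS tracks then pass a deterministic
speed sweep: walking forward in time, a fix whose great-circle speed from
the last *retained* fix exceeds 30 m/s — a generous ceiling for sustained
pigeon flight — is dropped, so an isolated displaced fix costs exactly one
location. The sweep is idempotent and order-stable, and replaces any manual
outlier screening, which cannot be reproduced. All distances use the
haversine formula on a sphere of radius 6,378,137 m (the WGS84 equatorial
radius); the radius is recorded in exported metadata.

## Annual-cycle segmentation

The segmentation is deliberately rule-based rather than model-based
(no hidden-state inference), so that every boundary is auditable:

* **Stationary runs.** A greedy forward pass grows a run while each new fix
  stays within 20 km of the run's running centroid. Runs spanning at least
  5 days are site candidates; the 20 km radius is the "spatial overlap"
  scale and is configurable.
* **Sites and phases.** Site-candidate runs are clustered (same site when
  centres are within the run radius); the breeding site is the cluster
  holding the most April–August fixes. Other sites are wintering sites when
  at least 100 km from the breeding site, or when occupied in late autumn
  and winter.
* **Migration.** A transition between site occupancies at least 100 km
  apart is a migration: it opens at the first fix 100 km or more from the
  previous site centre and closes at the last fix before the next occupancy
  begins. The 100 km displacement is the only quantitative ingredient of
  the published "clear switch" definition, and determinism argues for using
  it alone. Movements between distinct sites under 100 km are recorded as
  *site shifts* (the within-Germany 10–40 km movers), never as migration.
* **Stopovers.** Stationary runs of at least 3 days inside a migration
  interval are stopovers. Because runs of 5 days or more become site
  candidates, the two rules disambiguate stopovers from wintering sites by
  duration; a real 10-day stopover would be mis-promoted to a site, a known
  limitation of the purely temporal rule (the simulator's stated world uses
  3–4 day stopovers).

A track that ends mid-migration yields an interval flagged
`complete = FALSE`.

## Phenology: the midpoint rule

Transmission is not continuous (daylight GPS schedules; Argos duty cycles
of 10 h ON / 24–48 h OFF), so a phase boundary falls between a last signal
on one side and a first signal on the other. `boundaryDate()` takes the
calendar midpoint, allowing fractional days, and *excludes* the event when
the gap exceeds 14 days — beyond that the midpoint is no longer a
defensible estimate.

Averaging dates across individuals tracked in different years needs a
common scale. `doy365()` maps every date onto a non-leap day-of-year scale
(29 February maps to 59.5, so 1 March is day 60 in every year), the mean is
taken there, and the result is rounded to the nearest whole day with 0.5
rounding up. Phase *durations*, by contrast, are exact calendar-day
differences in the event's own year and are therefore leap-aware; their
dispersion is the sample standard deviation (n−1), reported to one
decimal. Published reports print event *ranges* from raw signals while the
means follow midpoints; `phenologySummary()` therefore returns both the
stationary-side and the migration-side raw ranges alongside the midpoint
mean. Where a printed mean could only be matched by rounding each event
before averaging (one autumn mean differs by one day between conventions),
the package keeps the single un-rounded-until-the-end convention rather
than switching rules per event.

## Kernel home ranges

Relocations are projected onto a Lambert azimuthal equal-area plane centred
on their centroid before any density estimation, so cell counts are true
areas; at the 10–1000 km scales involved, projection distortion is
negligible. The utilization distribution is

$$\hat f(c) = \frac{1}{n}\sum_i K_h(c - x_i),\qquad
K(u) = \frac{2}{\pi}(1 - u^\top u)\ \text{for}\ \lVert u\rVert \le 1,$$

the bivariate Epanechnikov kernel (a bivariate normal kernel is available,
and is used for ring-recovery position densities). The bandwidth is the
ad-hoc reference value $h_\mathrm{ref} = 0.5\,(s_x + s_y)\,n^{-1/6}$,
multiplied by 1.77 for the Epanechnikov kernel — the conventional rescaling
that matches its support to the Gaussian bandwidth the formula was derived
for. The grid has 100 (default) or 500 cells per side and covers the point
bounding box padded by 0.5 times the range per side; mass is renormalized
to 1 *over the grid* (renormalization over infinite support is not
attempted; with the default padding the truncated mass is far below the
1e-6 validity tolerance). Home ranges are volume contours: cells are
accumulated in descending density order — ties broken deterministically in
linear cell order — until the cumulative mass reaches the level (0.95 for
the home range, 0.50 for the core area). Areas are cell count times cell
area. On a seeded isotropic Gaussian sample (n = 500, sd = 1 km) the 95%
contour area lands within 15% of the analytic highest-density region
$\pi\,\chi^2_{2,0.95}\,\sigma^2 \approx 18.8\ \mathrm{km^2}$; the residual
upward bias is the usual bandwidth inflation.

Monthly home ranges use `monthlySplit()`: a calendar month enters the
analysis only when tracking spanned it fully, with a 1-day tolerance at
each end (a judgment call, configurable), so capture months and
transmitter-failure months drop out.

## Habitat use and foraging vectors

Land cover is a categorical raster in the three-level CORINE numbering
(leading digit = level-1 class; 1 artificial, 2 agricultural). Composition
of a home range is cell-in-polygon area weighting on the contour's own
cells; classes under 1% can be displayed as "Others". The city footprint
is *defined by the raster's artificial-surface classes*, not by an
administrative boundary, keeping the package self-contained. Each
rook-connected part of a monthly 95% contour is assigned its majority
level-1 class; the foraging vector runs from the area-weighted centroid of
the city parts to that of the farmland parts, with great-circle distance
and initial bearing (at commuting distances the difference from a planar
bearing is negligible, but the convention is fixed). Months with no
farmland part contribute no vector but stay in the denominator of the
"left the city" proportion. Pooled monthly bearings feed the Rayleigh
test: $\bar R = r$, $Z = n r^2$, with the standard series approximation for
the p-value, clamped into (0, 1]; its type-I error at n = 20 is 0.05 within
Monte-Carlo accuracy. Monthly vectors are pooled across individuals
(one data point per bird-month), matching how the published rose diagrams
are captioned; a per-individual pre-averaging variant would be a one-line
change.

## Site-fidelity repeatability

Fidelity is the intraclass correlation of site longitude with individuals
as groups, in the Lessells & Boag formulation for unbalanced one-way
ANOVA: $s^2_A = (MS_A - MS_W)/n_0$ with
$n_0 = (N - \sum n_i^2/N)/(a-1)$ and $r = s^2_A/(MS_W + s^2_A)$. A negative
among-group component is *retained* (finite-sample ICCs can be negative,
and published wintering-site values are). For winters with several distinct
sites only the first-occupied site enters, avoiding overrepresentation of
multi-site birds. Longitude is the fidelity axis because the flyway runs
mainly east–west; latitude is available behind the same function.

## Ring recoveries

The filter keeps records ringed in Germany during the breeding season
(1 April – 30 September) and recovered in the wintering season — within
Germany 1 November to the end of February (the published "30 February" is
read as month end), abroad 1 October – 30 March (literal) — plus the
reverse direction (winter-ringed anywhere, recovered in Germany in the
breeding window). Records spanning more than five years or with a date
accuracy worse than six weeks (42 days; accuracy is taken as a day count,
since no ringing-scheme code mapping is published) are discarded. Every
dropped record carries exactly one reason with priority
`malformed > season > span > accuracy`, and verdicts are order-independent.
Country assignment comes from the record fields — no political boundaries
are bundled. Kept records become densified great-circle lines; line
density is the standard "total line length within a search radius of the
cell centre over the disc area" statistic, computed with exact
segment-circle chords on the shared equal-area plane. Recovery positions
abroad get a bivariate-normal KUD with 50%/95% contours.

## The synthetic world

`simConfig()` fixes the simulated world once; its defaults are the
conditions the analysis assumes, chosen from the study system where stated
and from field realism otherwise:

| parameter | default | rationale |
|---|---|---|
| breeding centre / radius | (8.68 E, 50.58 N), 5 km | an urban Central-German breeding population |
| `p_migrate_per_winter` | 0.4 | between the observed 42% and 13% migrant fractions; redrawn per winter (facultative switching) |
| wintering quarter | (0.5 E, 44.3 N) ± 150 km | south-western France along the East Atlantic flyway |
| winter sites per winter | 1–3, shifts 25–60 km | published multi-site winters; shifts must exceed the 20 km site radius to be distinct |
| migration legs | 110–160 km/day | crosses the 100 km displacement threshold within the first travel day, with ~1000 km covered in about a week of travel |
| stopovers | 1–3 per leg, 3–4 d | at least the 3-day stopover minimum and below the 5-day site-candidacy span |
| departure days | autumn ~N(doy 295, 8), spring ~N(doy 82, 8) | late-October departures, late-March returns |
| foraging commutes | p = 0.3/day, 5.7 ± 2.0 km, direction 225° (von Mises, kappa 4) | the published mean commute distance and a concentrated south-westerly direction |
| GPS schedule | every 60 min, 06:00–20:00, error 10 m | a mid-battery duty point of the real schedule (5 min at full battery is computationally gratuitous here); fixed local-hour daylight window instead of solar geometry |
| Argos schedule | 10 h ON / 48 h OFF, LC errors 250/500/1500 m | the published duty cycle; LC error magnitudes are nominal Argos accuracy conventions, flagged as such |

Movement is discrete daily waypoints with within-day great-circle
interpolation (simplicity over behavioural realism — enough to exercise
every downstream rule). Positional error is 2-D Gaussian *truncated
radially at 3 sd*, so every fix is within 3 error-sd of its true position
by construction; the residency random walk (0.3 km/day, clamped to the
site radius) and the commutes mean that fixes during stationary phases are
*not* all near the site centre — truth checks therefore compare fixes to
true positions, not site centres. Outlier fixes are displaced by at least
45 m/s times the preceding gap, guaranteeing a speed-ceiling violation.
Identical configurations (including the seed) give bit-identical output,
and the generator restores the global RNG state.

What a green test does *not* establish: the simulator has no wind, no
battery dynamics, no solar geometry, no behavioural heterogeneity beyond
the stated parameters, and its stopovers never exceed 4 days; recovery of
boundaries at ±1 day on this world says nothing about change-point quality
on noisier real schedules.

## Numerical choices and degenerate inputs

* UD mass must equal 1 within 1e-6 (object validity); contour ties are
  resolved in deterministic linear cell order.
* `href` requires at least 5 points and errors on a zero-variance cloud.
* The Rayleigh p-value is clamped into (0, 1]; n = 0 bearings is an error,
  coincident city/farm centroids give an undefined bearing that is flagged
  and excluded from circular statistics.
* Repeatability requires at least two groups and one group of size ≥ 2.
* Zero-length recovery lines are kept; a home range extending beyond the
  land-cover raster is an error naming the gap.
* All timestamps are UTC (explicitly, because the host timezone database
  cannot be assumed); dates are Gregorian with leap years.

## Worked arithmetic on the bundled tables

The bundled annual-schedule table reproduces the published phenology
exactly — this is also the package's acceptance arithmetic:

```{r}
ph <- woodpigeonPhases()
gps <- ph[ph$data_type == "GPS", ]
fr <- gps[gps$individual_id %in% franceMigrants(gps), ]
unlist(phenologyDurations(fr, "autumn_migration")[c("mean", "sd")])
phenologySummary(fr, "autumn_departure")$mean_date
phenologySummary(ph[ph$data_type == "Argos", ], "spring_departure")$mean_date
migrationIncidence(woodpigeonDeployments(), ph)
```

## Known limitations

* Stopovers longer than the site-candidacy span are promoted to sites
  (see above); real data with week-long stopovers needs a larger
  `site_min_days`.
* The running-centroid run detector is sequential and can split a site
  visited with a long excursion in between; episodes of the same site are
  re-merged, but the run table itself keeps the split.
* Line density and KUD grids are planar in one shared equal-area
  projection; continental extents beyond a few thousand kilometres would
  need zone handling.
* Mean dates mix years on the non-leap day-of-year scale; sub-daily event
  timing is not modelled anywhere.
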