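---
title: "Methods: geographic embedding and spatial cytometry analysis in geocyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic embedding and spatial cytometry analysis in geocyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geocyto)
```

## The embedding model

Segmented-cell tables place each cell at a pixel centroid
$(x, y)$ in an image frame of width $W$ and height $H$ pixels, with a
physical pitch $p$ micrometres per pixel (0.65 µm/px for the melanoma
whole-slide data this package mirrors). Geodesic GIS functions operate
on latitude/longitude, so `geocyto` maps pixels to the geographic
coordinate system linearly and isotropically:

$$\mathrm{lon} = x / s, \qquad \mathrm{lat} = y / s,$$

with one scale $s$ (pixels per degree) and the image's lower-left
corner anchored at $(0^\circ\mathrm{N}, 0^\circ\mathrm{E})$. The pixel
origin is the lower-left corner with $y$ increasing upward; tables
using the top-left imaging convention are flipped on read
(`read_cell_table(flip_y = TRUE)`).

Distances are then computed on a sphere of radius $R = 6{,}371{,}000$ m,
so one degree of arc is $R\pi/180 = 111{,}194.93$ m. The sphere (rather
than a geodetic spheroid) makes the haversine formula exact and
reproduces all the printed dimension-table values to within 0.5 %; the
residual discrepancy in the 20-µm neighborhood radius (13.26 m on this
sphere) is the price of not knowing a GIS backend's exact earth model,
and is irrelevant at the tolerances of any analysis here.

### Curvature distortion

Meridians converge away from the equator: an east–west step embedded at
latitude $\varphi$ is stretched by $\sec\varphi$ relative to the same
step at the equator (`ew_scale_factor()`). Because the factor grows
with latitude, the worst case sits on the image's top edge, giving a
maximum east–west length error of

$$\Delta = W\,(\sec\varphi_{\mathrm{top}} - 1) \ \text{pixels}$$

(`max_distortion_px()`). The two mappings of interest for a
$36{,}857 \times 25{,}808$ px slide:

```{r distortion}
fr <- image_frame(36857, 25808, microns_per_pixel = 0.65)
low  <- make_embedding(fr, top_latitude_deg = 0.1)     # 258,080 px per degree
naive <- make_embedding(fr, pixels_per_degree = 1000)  # top at 25.808 N
c(sec_low = ew_scale_factor(low$top_latitude_deg),
  sec_naive = ew_scale_factor(naive$top_latitude_deg))
c(px_low = max_distortion_px(low), px_naive = max_distortion_px(naive))
```

The low-latitude mapping keeps the whole slide under a tenth of a pixel
of distortion; the naive 1,000 px/° mapping stretches the top of the
image by more than 10 %. Anchoring the top edge at 0.1°N is therefore
the default, and `top_latitude_deg` is the single knob that trades
latitude headroom against distortion. Longitude and latitude share one
scale because the source tables scale both centroid coordinates by one
factor; anisotropic scaling would silently change every distance.

## Geodesic neighborhood operations

`haversine_m()` is the metric for all geodesic operations.
`pairs_within()` enumerates unordered cell pairs at most `radius_m`
apart using a latitude/longitude grid with bucket size equal to the
radius (longitude buckets widened by $\sec$ of the extreme latitude),
so only neighboring buckets are compared; the brute-force $O(n^2)$
enumeration survives as the test oracle. Two conventions are fixed and
tested rather than left implicit:

- **Closed ball.** A pair exactly at the radius is kept
  ($d \le r$), the conventional inclusive DWithin predicate.
- **Canonical pair order.** Each pair is stored once with
  `cell_id_a < cell_id_b` under the ids' natural ordering, rows sorted.

`neighbor_counts()` tallies, per cell of a target phenotype, its paired
cells of the same phenotype (so the sum over cells equals twice the
same-phenotype pair count), and `geo_dbscan()` implements DBSCAN under
the geodesic metric. DBSCAN choices, each deterministic and
documented because GIS implementations differ: the core test is
self-inclusive (a point counts toward its own `min_points`), border
points reachable from several clusters join the cluster of their
lowest-ordered core neighbor, noise is `NA`, and cluster ids are
renumbered `1..K` by smallest member id so results are invariant to
input order. At the latitudes the default embedding uses, geodesic
clustering agrees exactly (adjusted Rand index 1) with planar DBSCAN on
the pixel coordinates once `eps` is converted with `px_to_earth_m()` —
which is the point of bounding the distortion.

## Phenotyping

Gates threshold marker intensities. A `quantile` gate resolves its
threshold on the cohort being classified — deliberately, so a gate
applied after `region_filter()` reflects the region's intensity
distribution, matching the practice of thresholding the distribution
one actually plots. The quantile is the linear interpolation between
closest order statistics (`stats::quantile` type 7); raw intensities
are used, with no log transform. Cells must **strictly exceed** every
rule's threshold ("positivity" at the boundary is excluded; with the
type-7 Q3 of integers 1..8 at 6.25, cells 7 and 8 gate positive).
Multi-marker gates are conjunctive. Absolute thresholds (as for
manually calibrated SOX10/S100B/CD63 tumor gates) are required
configuration with no defaults, since no defensible universal values
exist. `region_filter()` uses closed bounds so boundary cells are
retained.

## Planar spatial statistics

`knn()` returns each cell's $k$ Euclidean nearest neighbors in pixel
space, self excluded, with equal-distance ties broken by ascending cell
id (the kd-tree backends this mirrors leave tie order unspecified;
tests require determinism). `spatial_correlation()` operationalizes the
k-NN marker correlation $C_{AB}(k)$: the Pearson correlation across
cells between marker $A$ and the $k$-NN neighborhood mean of marker
$B$. A zero-variance input raises an explicit undefined-correlation
error rather than returning `NaN`. Only the k-NN variant is provided —
distance-binned correlation curves over a range of radii are a
different estimator and out of scope.

## The tidy expression store

Long-format tables hold one `(cell_barcode, feature, value)`
observation per row. Zeros are not materialized: ingest stores exactly
the nonzero matrix entries and pivot zero-fills, so the row count
equals the matrix's nonzero count and the round trip is exact. Whether
production tidy stores materialize zeros is a storage-engine choice;
the sparse convention is adopted here explicitly.
`normalize_log1p()` scales each cell to a 10,000-count total (the
single-cell ecosystem's convention, configurable) and applies natural
`log1p`; per-cell feature ranks are preserved and
$\sum \mathrm{expm1}(v) = \texttt{target\_sum}$ per cell to $10^{-6}$
relative, which the tests assert. Centers shipping
$\log_2(x+1)$-transformed values are handled by
`input_transform = "log2p1"`, which inverts that transform first —
a flag, not the default.

## Provenance and cohort queries

Identifiers follow the `HTA<center>_<participant>[_<suffix>]` grammar,
so any biospecimen or file id recovers its participant by prefix. The
provenance graph is a DAG with child→parent edges; construction
validates acyclicity and that every file descends from at least one
biospecimen and exactly one participant.

The precancer cohort is a union of four queries, because no single
field is comprehensively annotated:

1. age-at-diagnosis equal to a sentinel at a precancer-designated
   center — the sentinel marks "no cancer diagnosis" and defaults to 0,
   config-exposed; by default this conjointly requires primary
   diagnosis "Not Reported", since that is how such cases are recorded,
   and the requirement can be relaxed in config;
2. primary diagnosis in an explicitly precancerous value set (ductal
   carcinoma in situ, familial adenomatous polyposis);
3. biospecimen tumor tissue type in {Premalignant, Atypia -
   hyperplasia, Premalignant - in situ};
4. canonicalized histologic morphology code in {8211/0, 8213/0,
   8263/0, 8220/0} — tubular, serrated and tubulovillous adenoma and
   adenomatous polyposis coli. Codes are accepted as `dddd/d` or as
   five contiguous digits with an optional leading `M`; other dialects
   are rejected as typed `NA`s, never silently dropped. The morphology
   criterion is not restricted to precancer-designated centers.

All vocabulary matching is exact after whitespace squeezing and case
folding — the queries are literal value matches, and fuzzy matching
would manufacture cohort members. Participant-level and
biospecimen-level criteria can select the same participant; the report
keeps one row per participant with per-criterion flags and attaches the
biospecimen-granularity hits, so neither tier shadows the other.
Cross-modal matching keeps biospecimens with released files of both
requested assay types within a center; manifests validate
`drs://prefix:object-id` locators and report rejects in a separate
table. Manifest output is sorted by file id, making it byte-stable.

## Synthetic data: what it emulates, and what it does not

The generators produce every schema the analysis consumes, with
planted ground truth and full determinism under a root seed (streamed
to per-table sub-seeds, so extending a scenario does not perturb
earlier tables).

- `gen_spatial_cells()`: Gaussian blobs (isotropic spread, truncated to
  the frame by resampling) over a uniform background. Marker
  intensities are log-normal per phenotype — nonnegative and
  right-skewed like imaging intensities — with the default tumor
  marker one decade above background (meanlog $\log 600$ vs
  $\log 60$, sdlog 0.35/0.5): clearly separable in the mean but with
  overlapping tails, so quartile gates are exercised rather than
  trivialized.
- `gen_metadata()`: clinical/biospecimen/file tables planted by
  criterion-overlap cell (e.g. `c(A = 7, B = 5, AB = 3, none = 10)`),
  with morphology codes alternating dialects to exercise scrubbing,
  and a per-biospecimen modality plan including both-modalities cases
  with a null data release (which must *not* match).
- `gen_tidy_counts()`: negative-binomial counts (size 2, mean 5) at a
  requested sparsity, positive where observed.

Realism is structural — schemas, sparsity, clustering, provenance
shape — not biological. Passing tests therefore demonstrate that the
operations recover *planted* structure under separable regimes; they do
not certify marker distributions, segmentation noise, or the marginal
statistics of any real release, and dataset-dependent observations
(cell counts, pair counts, modal neighbor numbers) are reproduced only
on plants constructed to have them.

## Numerical choices and degenerate inputs

- Inverse-embedding round trip is exact to well below $10^{-9}$ px
  inside any frame; the tests assert that bound.
- Empty inputs: empty point sets cluster to an empty assignment;
  empty tidy tables pivot to zero matrices; an empty gate-rule list
  labels every cell (vacuous conjunction). Empty intensity vectors,
  zero-total cells, inverted rectangles, duplicate ids and malformed
  ids raise typed validation errors naming the offender.
- All file outputs carry a header comment with the tool version and a
  location-independent config hash; reruns with the same config and
  seed are byte-identical.

## Problem sizes

The test suite runs the heavy property checks at the scales the design
targets: 100 random within-radius instances up to $n = 2000$ against
the brute-force oracle, k-NN at $n = 1000, k = 10$ against the
all-pairs sort, 200 permutation replicates of the k-NN correlation
null at $n = 2000$ (neighbor structure computed once, since positions
are fixed under permutation), and ten multi-blob DBSCAN recoveries.
Desk-scale analyses up to a few hundred thousand cells are in scope;
distributed or out-of-core execution is not.

## Known limitations

- Sphere only: no spheroid/datum support and no map projections; the
  embedding is a measurement device, not cartography.
- Longitude wrap-around is not handled — images span fractions of a
  degree by construction.
- No automatic threshold learning (Otsu, mixture models) and no cell
  type hierarchies; gates are explicit configuration.
- The tidy store is an analysis-scale container, not a database: no
  indices, no persistence beyond CSV/TSV/MTX.
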