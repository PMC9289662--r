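---
title: "parkflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{parkflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkflux)
```

## The model

`parkflux` quantifies how a city's residents are exposed to its parks through
their daily activity patterns, and how that exposure connects neighborhoods.
The core object is a weighted bipartite network between census tracts and
parks. A daily trajectory $u_a$ consists of one *home* location and
$n^o_a \ge 0$ *other*-type activity locations (work activities behave
differently — they are dominated by commuting — and are excluded). Each
activity location carries spatial uncertainty of roughly half the 400 m grid
resolution of the underlying mobility model, represented as a circle of
radius $r = 200$ m. An activity is *exposed* to every park intersecting that
circle, equivalently every park polygon within euclidean distance $r$ of the
activity point.

The incidence matrix counts potential visits:
$$X_{ij} = \sum_a \sum_{q=1}^{n^o_a} \mathbf{1}\{p_j \in P^q_a\}\,
\mathbf{1}\{\mathrm{home}(a) \in t_i\},$$
where $P^q_a$ is the exposed park set of activity $q$ of agent $a$. Row sums
$s^T_i$ measure a tract's *park exposure*; column sums $s^P_j$ measure a
park's *demand* (its potential visits). Visit-weighted neighbor averages
$\hat\beta_i = \frac{1}{s^T_i}\sum_j X_{ij}\beta_j$ transport any park
attribute onto tracts (and vice versa): with $\beta_j$ the park area this is
the mean area of a potentially visited park; with $\alpha_i$ a tract's group
fraction it estimates a park's visitor composition.

Tracts are labeled by their predominant racial/ethnic group (argmax of
census counts over White, Black, Asian, Hispanic, Other); parks by the
argmax of their estimated visitor composition over the four named groups
(the Other share is carried but never wins a label). *Homophily*
$h^T_i = \frac{1}{s^T_i} \sum_j X_{ij}\,\delta_{g^T_i, g^P_j}$ is the
weighted fraction of a node's cross-side neighbors sharing its label.

Community structure is scored with Barber's bipartite modularity
$$Q = \frac{1}{m}\sum_{ij}\Bigl(X_{ij} - \frac{s^T_i s^P_j}{m}\Bigr)
\delta_{c^T_i, c^P_j}, \qquad m = \sum_{ij} X_{ij},$$
and optimized by leading-eigenvector spectral bisection (below). The
association between group labels and community labels is measured by
plug-in mutual information in bits, referenced against a permutation null
(default 5000 uniform shuffles of the community labels, tracts and parks
shuffled separately, summarized as mean ± sd).

## Parameters that matter

* `radius_m` (default **200 m**): the exposure radius; it is the half-side
  of the 400 m activity grid cell, i.e. the locational uncertainty, not a
  behavioral "willingness to walk" parameter. Exposure counts are monotone
  non-decreasing in it.
* `urban_park_threshold_km2` (default **1 km²**): separates
  neighborhood-scale "urban parks" from large reserves in area summaries.
* `n_permutations` (default **5000**): permutation-null sample size; the
  Monte-Carlo standard error of the null mean scales as
  $\mathrm{sd}/\sqrt{n}$.
* `tol` (default **1e-10** on $\Delta Q$): a community split is accepted
  only if it increases modularity by more than this.

## Geometry engine

No polygon-clipping library is assumed. Regions are simple polygons
(optionally with holes, even-odd rule) in planar meter coordinates;
projection from geographic coordinates is the data producer's
responsibility, since a 200 m buffer is only meaningful in a metric system.
Areas of unions and intersections are computed by slab decomposition: the
x-axis is cut at every vertex and every pairwise edge crossing, making the
covered y-measure linear within each slab, so midpoint (or two-point Gauss,
for centroids) evaluation integrates it exactly up to floating point. This
also gives a principled meaning to invalid self-intersecting rings (they
are measured even-odd rather than repaired or rejected); rings that cannot
be interpreted at all raise an error naming the polygon.

Merging overlapping park polygons is implemented as connected components of
the positive-area pairwise-overlap graph followed by a union: equivalent to
iterated pairwise merging but deterministic and order-independent. A merged
park keeps its member polygons as parts; its area is the measure of their
union, so containment ("the merge is only the bigger polygon") and partial
overlap are handled without constructing new boundary rings. Parks touching
only along a boundary (zero-area intersection) are not merged — this is
exactly what makes the output interior-disjoint.

Deterministic tie-breaks: a point on a shared tract boundary is assigned to
the lexicographically smallest tract id; label ties resolve to the earliest
group in the fixed order White, Black, Asian, Hispanic, Other, with an
explicit tie flag.

## Community detection

The bipartite modularity matrix $B_{ij} = X_{ij} - s^T_i s^P_j / m$ is used
directly over both node sets jointly (no one-mode projection): each
candidate split of a community is the sign pattern of the leading
eigenvector of the symmetric matrix $\begin{pmatrix}0 & B_g\\ B_g' &
0\end{pmatrix}$, refined by a Kernighan–Lin pass (every node flipped once
per pass, best intermediate state kept), and accepted only if $\Delta Q >$
`tol`. Recursion over accepted halves yields the partition tree.

Bisection alone provably cannot reach some optimal multiway partitions, and
on small sparse instances it measurably misses the global optimum a few
percent of the time. The default therefore adds a multiway Kernighan–Lin
refinement stage (single-node moves between communities, a fresh community
always being a candidate), plus ten deterministically seeded random
restarts on networks with at most 64 connected nodes, where the modularity
landscape is most rugged and restarts are essentially free. With this
default the detector matched exhaustive enumeration on every one of 500
random ≤ 8-node instances across five seed sets. `refine = FALSE` recovers
the bare bisection tree. The eigensolver is dense and deterministic;
networks beyond 5000 connected nodes are rejected rather than silently
approximated. Zero-strength nodes are left unassigned (`NA`) and excluded
from modularity and label summaries.

## The synthetic city

Real call-detail-record trajectories are private, so validation runs on a
generator that reproduces the *shapes* the analysis consumes, not the
mechanics of human mobility:

* square grid tracts (default 6 × 6 at 1 km side) with ~4000 residents each
  (metropolitan tracts average roughly 4500);
* per-tract group mixtures drawn from a Dirichlet distribution concentrated
  around a city-wide mixture — small `segregation_alpha` gives segregated
  cities. The Other share stays fixed at its small global value, so no
  tract is Other-predominant, matching the expected data shape;
* log-normal park areas (default median 0.05 km², $\sigma_{\log} = 1$),
  placed uniformly ("even", Boston-like) or around three Gaussian centers
  ("clustered", Los-Angeles-like);
* one home per agent, Poisson other-activity counts (default mean 1,
  matching the observed roughly one other-activity per daily trajectory),
  isotropic exponential-tailed displacements, snapped to a 400 m grid and
  jittered within ±200 m to mimic the mobility model's resolution.

What a green test on this generator establishes is *computational*
correctness — the indexed network construction equals a brute-force
geometric double loop, metrics equal their defining sums, detection
recovers planted blocks. It does not establish behavioral realism: there is
no temporal scheduling, no road network, no destination choice model, and
displacement lengths are an assumption, not an inference.

## Numerical choices

* Exposure is a point-to-polygon distance test, not a discretized buffer
  polygon: exactly equivalent and free of circle-discretization error.
  Points inside a park have distance 0 and are exposed.
* Overlap detection uses a relative area threshold ($10^{-9}$ of the
  smaller polygon, floored at 1 mm²) so boundary-touching polygons never
  merge through float noise.
* The log-normal fit is maximum likelihood on $\ln v$ (the $1/n$ variance
  estimator); both the distribution mean
  $\exp(\mu_{\log} + \sigma_{\log}^2/2)$ and the geometric mean
  $\exp(\mu_{\log})$ are reported, because "natural scale" summaries are
  used ambiguously in the literature.
* Log-binned histograms use geometric bins, left-closed and right-open with
  the final bin closed; zeros are excluded and counted, and densities
  normalize so the integral equals the included fraction.
* Travel distance is euclidean; each trajectory contributes the median of
  its home-to-other distances, each tract the median over its trajectories,
  and city-level values are reported as mean ± sd over tracts.
* Published summary tables mix truncation and rounding-to-nearest when
  printing ratios; `render_summary()` exposes both renderings explicitly.

## Known limitations

* Pure-R geometry: fine for thousands of polygons at test scale, but a
  metropolitan OSM extract (10⁵ polygons) would want a compiled spatial
  index.
* Park polygons are not clipped to the study-region boundary before area
  computation; areas are those of the full polygons.
* Exposure is instantaneous and unweighted by duration; co-presence,
  time-of-day structure and work activities are out of scope.
* The plug-in mutual-information estimator is biased upward on finite
  samples; the permutation null quantifies exactly that bias, which is why
  observed values are always read against it rather than against zero.
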