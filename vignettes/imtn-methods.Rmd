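---
title: "Methods: construction and analysis of daily intermunicipal travel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and analysis of daily intermunicipal travel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imtn)
```

## The model

`imtn` builds one directed, weighted travel network per calendar day from
anonymized device-location pings. Nodes are localities — municipalities, or
metropolitan zones collapsed to a single node, since movement between the
municipalities of one conurbation is urban traffic rather than travel between
places. A device *moves* from node $i$ to node $j$ when it is observed in $i$
and its next ping of the same day falls in $j$. Edge weights are
device-normalized flows:

$$W_{ij} = \frac{|D_{ij}|}{|D|},$$

where $|D_{ij}|$ is the number of unique devices observed to move from $i$ to
$j$ that day and $|D|$ is the size of the day's *device panel* — every unique
device observed, movers or not. Two consequences matter:

* $W_{ij} \in (0, 1]$: the weight is the fraction of the whole observed
  panel making that trip; it reaches 1 only if every observed device made it.
* Because the denominator is the full panel, weights are comparable across
  days even when the number of observed devices fluctuates — the panel size
  acts as the day's exposure.

A device contributes at most once per directed pair per day (weights count
devices, not trips), but one device can contribute to several distinct pairs.
Consecutive pings at the same node — including two municipalities of the same
metropolitan zone — contribute nothing, and self-loops never exist.

The day boundary is a fixed UTC offset (default $-6$ h, central Mexico).
Construction is strictly per-day, so cross-midnight ping pairs are never
joined into a transition. Ties in a device's timestamps are broken by zone id
so the construction is a pure function of the ping multiset; shuffling row
order cannot change the network.

## The synthetic mobility generator

Real ping feeds are proprietary, so the package ships a seeded generator
whose output exercises every downstream stage:

* **Zone registry.** Zones sit on a planar grid. States occupy disjoint
  compact blocks on a coarser state-level grid, so intra-state distances are
  short and inter-state distances longer; this block structure is what makes
  state-aligned communities recoverable by community detection. A subset of
  adjacent same-state zones is paired into metropolitan zones (every metro
  has at least two member municipalities). Populations are i.i.d. log-normal
  (default `meanlog = log(2e4)`, `sdlog = 1.5`): a median municipality of
  20,000 inhabitants with a heavy upper tail, the typical shape of national
  municipal registers.
* **Device panel.** Home zones are sampled proportional to population.
* **Daily travel.** Each device, each day, makes one round trip
  (home → destination → home) with probability
  `p_move × intensity(date)`; the destination is drawn with probability
  proportional to $\mathrm{pop}_j / \max(d_{ij}, 1)^{\gamma}$ — a gravity
  kernel with Euclidean centroid distance, floored at 1 so coincident
  centroids cannot produce infinite rates. Non-movers emit all pings at
  home. The `intensity` map (per-date multiplier in $[0,1]$) is the lockdown
  dial: stepping it down reproduces, qualitatively, the pandemic mobility
  collapse in the weight-sum series.

Defaults were fixed once: `p_move = 0.25` (about a quarter of devices
leave their municipality on a given day), `gravity_gamma = 1` (a decay in
the low range of empirical intercity gravity fits; at this value the daily
networks develop the mesoscale signature observed in national travel data —
one dominant community holding half or more of the localities plus smaller
regional ones, some of them crossing state lines), and 4 pings per device
per day (the fewest that resolve a full round trip with a little slack).
Larger `gravity_gamma` (around 4) confines travel to nearby zones and makes
the planted state blocks sharply recoverable; the community-recovery tests
use that regime.

Every generator is a pure function of its inputs and a seed. Per-day seeds
are derived from the scenario seed and the ISO date by an exact integer hash
(`derive_seed`), so any single day can be regenerated without replaying the
stream.

**What the generator does not emulate.** One round trip per mover per day is
an assumption, not an observed property of the source data (the empirical
trips-per-device distribution is not public); there are no road networks, no
intra-day schedules, no multi-day trips, and no calibration to a real
census. Log-normal populations give nearly log-normal node strengths, so
with default parameters the synthetic networks do *not* reproduce the
positive excess kurtosis and decisive log-normality rejections seen in the
real collection; the distribution-analysis tests therefore exercise that
regime with a heavier-tailed population configuration (`pop_sdlog = 2.5`).
Passing tests show the machinery is correct under controlled conditions,
not that the generator is a statistical twin of the source feed.

## Feature analysis

* **Global movement** is the edge-weight sum $S_G = \sum_i w_i$ per day,
  smoothed with a trailing 30-day moving average whose window shrinks at the
  start of the series (day $t$ averages the most recent $\min(30, t)$ days).
  A trailing window was chosen because the average must be computable on the
  day it refers to.
* **Centralities**: degree, strength (in / out / total) and directed
  betweenness. Betweenness uses unweighted shortest paths by default; since
  a weight-to-distance convention is a genuine modelling choice, the
  `bc_distance = "inverse-weight"` option provides the $1/W$ alternative
  rather than baking either in silently. Nodes absent from a day's network
  (no observed travel) contribute 0 to that day, so every observed locality
  has a complete series.
* **Variability** is the coefficient of variation
  $\mathrm{cv} = 100\,\sigma/\mu$ (percent), with the sample standard
  deviation ($n-1$ denominator); cv is flagged undefined when the mean is 0
  rather than reported as 0 or infinity. cv is invariant to rescaling all
  values, so it compares nodes of very different size.
* **Population scaling** is ordinary least squares on
  $(\log_{10} x, \log_{10} y)$; nonpositive pairs are excluded before the
  transform and counted in the output.
* **Rank turnover** of the daily top-$N$ list: $F(t)$ is the number of
  distinct nodes ever to enter the top-$N$ through day $t$, divided by $N$.
  Ranking ties are broken by node id so the measure is deterministic. The
  comparison curve is the closed-form expectation under independent uniform
  daily rankings, $E[F(t)] = (M/N)(1 - (1 - N/M)^t)$ with $M$ the node
  count; stable empirical rankings sit far below it.

## Distribution analysis

Daily node-strength distributions are characterized three ways:

* **Log-normality**: Shapiro–Wilk on the natural log of positive total
  strengths. Zero-strength nodes are excluded and counted. Days with fewer
  than 4 positive strengths, zero variance, or more than 5000 values (the
  test's implementation range; the real networks have ~2.5k nodes) are
  flagged, not tested.
* **Tail extremity**: excess kurtosis $g_2 = m_4/m_2^2 - 3$ with population
  moments (Fisher convention; a bias-corrected $G_2$ is available by
  option). $g_2$ is affine-invariant, so it measures shape only.
* **Rank-size structure**: the Beta Rank Function
  $X(r) = A\,(N+1-r)^b / r^a$, the two-exponent (discrete generalized beta)
  rank-size law with independent Paretian exponents for the two tails. The
  commonly printed shorthand $(1-r)^b/r^a$ is read as $(N+1-r)^b$: the
  literal form is negative for $r \ge 2$ and cannot be a size. Fitting is
  ordinary least squares of $\ln X$ on $\{\ln r, \ln(N+1-r)\}$ — exact on
  noiseless profiles (the parameter-recovery tests require agreement to
  $10^{-6}$) and the standard approach for this family; nonlinear least
  squares would add iteration without improving the noiseless fixed points.
  The $r = N$ point, where $\ln(N+1-r) = 0$, is retained: it still informs
  $A$ and $a$. A zero-variance profile is reported as $a = b = 0$,
  $R^2 = 1$ (the flat profile is fit exactly).

QQ data against the standard normal use plotting positions $(i - 0.5)/n$;
standardization uses the sample mean and standard deviation and can be
disabled when the input is already on the standard scale.

## Community dynamics

Communities are detected per day by **label propagation** on the symmetrized
graph (undirected weight $W_{ij} + W_{ji}$; the reference algorithm is
defined for undirected graphs, and direction handling is otherwise an open
choice). The variant implemented is asynchronous and weighted: nodes are
visited in a seeded random order; each adopts the label with the largest
summed incident edge weight, ties broken uniformly at random from the same
seeded generator; sweeps repeat until no label changes (or `max_iter`).
Partitions are therefore deterministic given the seed — the seed is recorded
in the result — and a single run per day is performed, matching a
proof-of-concept framing; consensus across seeds is left to the caller.
Labels are canonicalized (0, 1, 2, … by decreasing size, ties by smallest
member id) so partitions are comparable across days, which is what makes
the alluvial flow tables well defined.

Partition statistics resolve each node to a state; a metropolitan node takes
the state of its most populous member municipality, since metros can
straddle state lines. The interstate fraction is the share of communities
whose members span at least two states.

## Problem sizes and numerical checks

The test suite builds everything it needs at run time. Representative sizes,
chosen to keep each property statistically decisive at interactive runtimes:
construction is verified against a brute-force enumeration oracle on 200
random instances of up to 20 devices and 5 zones; betweenness against
exhaustive path enumeration on graphs of up to 8 nodes; gravity-kernel
recovery on 25 zones × 10,000 devices × 100 days (Spearman correlation
against the closed-form trip expectation); planted-state-block recovery on
48 zones, 4 states, 4,000 devices at `gravity_gamma = 4`; the calendar
check runs the full 2020-01-01..2021-12-31 range (731 days) with a 3-device
panel. The acceptance script simulates the full two-year range at 60 zones,
6 states and an 800-device panel with a stepped lockdown intensity profile.

## Known limitations

* The edge-list CSV cannot represent isolated nodes; a round trip through
  disk keeps all edges and weights exact (weights are re-derived from the
  integer counts) but drops ping-observed, non-travelling nodes.
* Label propagation on near-tied structures is sensitive to the seed by
  design; cross-seed stability is the caller's responsibility.
* The generator's simplifications listed above mean distribution-shape
  results on synthetic data should be read as functional checks, not as
  reproductions of empirical values.
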