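---
title: "Timetrees of protein domains from abundance censuses: models and methods"
author: "domClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timetrees of protein domains from abundance censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domClock)
```

## The data and the idea

A genomic census of protein domain structure counts how many times each
domain type — usually a SCOP fold superfamily (FSF) such as `c.37.1` —
occurs in each of a set of proteomes. Such a census is a single matrix that
can be read as phylogenetic data in two orientations. With proteomes as
taxa and domains as characters it supports a tree of life (ToL). With
domains as taxa and proteomes as characters (the transpose) it supports a
tree of domains (ToD), whose branching order is interpreted as the order in
which domain structures were discovered by evolution.

Three assumptions make a chronology out of the ToD:

1. **Polarization.** Genomic abundances grow as genes duplicate and
   diverge, so the most abundant, most widely distributed domains are the
   oldest. High states are therefore ancestral, and trees can be rooted
   without an outgroup by attaching a *hypothetical ancestor* carrying, per
   character, the maximum observed state (the Lundberg method: the ancestor
   is attached to an optimal unrooted tree on the edge that adds the least
   parsimony length).
2. **Pectinate trees carry time.** When change is semi-punctuated the
   trees are highly unbalanced, and the *node distance* of a leaf — the
   number of internal nodes between root and leaf, rescaled to `[0, 1]` —
   ranks leaves by relative age. `domClock` warns when a tree's normalized
   Colless imbalance falls below a threshold (default 0.3), because nd is
   meaningless on trees that look like a balanced, null branching process.
3. **A linear clock.** Calibration points tying particular domains (or nd
   values) to geological ages are fitted by ordinary least squares,
   `age ~ nd`, turning node distances into ages in Gy.

## Character coding

Abundances are coded into 24 linearly ordered, reversible states written
`0`–`9`, `A`–`N`. The default is logarithmic:

$$G = \mathrm{round}\!\left(23\,\frac{\ln(g+1)}{\ln(g_{\max}+1)}\right),$$

with half-away-from-zero rounding, fixed so encodings are identical on
every platform. The log scale is the only sensible default because census
abundances span four orders of magnitude (maxima above $10^4$); a linear
rescaling (`scheme = "linear"`) is available but collapses almost all cells
onto the lowest states, so any nonzero count that would round to state 0 is
clamped to state 1 to preserve presence/absence. `gmax` is the matrix-wide
maximum — one colour scale for the whole heat map — rather than a
per-column maximum; per-column scaling would erase the global abundance
differences the polarization argument rests on. State 0 is reserved for
absence in both schemes.

Decoding (needed to report an urancestral repertoire in copies rather than
states) is necessarily approximate: each state is mapped to the geometric
midpoint of its abundance bin, $(g_{\max}+1)^{s/23}-1$, so state 23 decodes
exactly to `gmax` and state 0 to 0.

## Parsimony engine

Characters transform along ordered, reversible pathways with cost
$|i-j|$ (Wagner parsimony), all equally weighted. Tree length is computed
by the interval (Farris) down-pass — for ordered characters the set of
optimal states at any node is a contiguous interval, and merging two child
intervals costs their gap — which agrees with Sankoff dynamic programming
under the L1 cost matrix but runs in constant time per node and character.
The inner loop is in C++; everything above it is R.

The heuristic search is a parsimony ratchet over unrooted binary
topologies:

* starting trees by random-addition-sequence stepwise addition
  (`restarts` of them, default 5);
* steepest-descent branch swapping; the neighbourhood is NNI, SPR, or NNI
  until a local optimum followed by SPR scans (default);
* ratchet iterations (default 50): reweight a random 25% of characters by
  a factor of 2, re-search, restore unit weights, re-search, and accept
  the result when not worse. The original description of the ratchet
  leaves these parameters open; the defaults here follow common practice
  and are all exposed in `SearchParams()`.

All distinct topologies at the best length are retained (up to
`maxTrees`), and every run is exactly reproducible from its seed. When
several equally parsimonious trees survive, downstream chronology uses the
first best tree under the run seed — nd is undefined at the polytomies a
consensus would introduce — and the choice is recorded in the search
result.

Rooting attaches the polarization ancestor (`max-state` by default;
`zero-state` gives the gain-polarized alternative) on every edge in turn
and keeps an edge of minimum added length; ties are reported. Both the ToD
and the ToL are rooted with the same `max-state` model by default: the
generality argument for abundance polarization applies to proteomes as
repertoires just as it does to domains, and the package treats the shared
default as a configuration choice (`polarization` in the pipeline config).

## Chronology and clock

Node distance counts the internal nodes on the root-to-leaf path with the
root included, then rescales: $nd = (d-1)/(d_{\max}-1)$, so the
earliest-diverging leaf sits at exactly 0 and the deepest at exactly 1.
Whether the root itself is counted is a convention with no observable
consequence after rescaling; it is fixed here and documented. A two-leaf
tree has no internal structure and all its leaves get nd 0.

`fitClock()` is unweighted OLS of age on nd — the assumed relationship is
simply linear — reporting slope, intercept, $R^2$ and residual standard
deviation. `buildChronology()` applies a fitted clock to every leaf,
refuses a positive slope unless explicitly overridden (ages must decrease
toward the present), clamps negative extrapolations to 0 Gy with a
warning, and attaches the imbalance diagnostic described above.

## Urancestral reconstruction

On the rooted ToL the same down-pass yields, per domain, the interval of
root states attaining the minimum length. The urancestral repertoire is
then read off under a stringency sweep: a domain is present at threshold
$\tau$ when its interval midpoint (rounded down) reaches
$\max(1, \tau)$. Sweeping $\tau$ from permissive to strict produces a
(liberal, conservative) range of repertoire sizes — this package's
realization of iterative reconstruction at multiple stringencies, which in
the source literature yields ranges such as "303–507 domains in 70–152
FSFs". The exact stringency schedule behind published ranges is not
restated here; the sweep is the transparent surrogate. Reproducing the
published numbers themselves is out of scope: they require the original
420-proteome census, which was never deposited.

## Comparative layer

Venn distribution groups classify each domain by the set of superkingdoms
where it occurs at all (`A`, `B`, `E`, `AB`, `AE`, `BE`, `ABE`); presence
means one copy in one member proteome, with an optional occupancy-fraction
threshold for noisy annotations. Group emergence times are the oldest
member ages. Whole-superkingdom losses are flagged for domains absent from
every proteome of one superkingdom, present in both others, and older than
that superkingdom's oldest clade-specific domain — the age filter that
separates ancient losses from domains simply born elsewhere after the
split. The flagged domain's own nd-derived age is reported with the event;
because complete loss is most likely soon after origin, that age is a
lower bound on the loss time and is documented as an approximation.

The heat-map ordering reproduces the canonical figure layout: rows in
ladderized ToL order (children by decreasing subtree size, ties by label —
deterministic and idempotent), columns by ascending nd, with gray for
absence and a red-to-blue ramp for states 1–23.

## The synthetic census generator

No census accompanies the source analysis, so validation rests on
`simulateCensus()`, which generates censuses with the structure the method
assumes, plus full ground truth (birth steps, lineage tree, loss events,
the stem repertoire at the first split). The model and its frozen
defaults:

* **Timeline and lineages.** 100 discrete steps. A stem line spawns the
  Archaea ancestor at step 24 and splits into Bacteria and Eukarya at step
  26 — the positions of ~2.9 Gy and ~2.8 Gy on a 3.8-Gy clock, matching
  the split order the analysis is meant to recover. Each clade then
  bifurcates at uniformly drawn times into 5 terminal proteomes.
* **Births.** 50 domain types arise at steps drawn with gamma-distributed
  weights damped by $e^{-3t/T}$: discovery is burst-prone
  (semi-punctuated) and front-loaded, so a universal core of early domains
  seeds all three superkingdoms while later births are clade-specific.
  The damping constant was chosen so that the ubiquitous Venn class (ABE)
  robustly outnumbers every clade-unique class, the nested structure the
  real census shows.
* **Duplication.** Per-copy Bernoulli duplication at 0.1 per step:
  geometric-like growth spanning abundances 1 to $\sim 10^4$
  ($1.1^{100} \approx 1.4\times 10^4$, the scale of the real census
  maximum).
* **Loss.** Complete loss of a domain from a lineage with probability
  $0.02 \times 0.3^{\,n-1}$ per step for $n$ copies: loss is concentrated
  on domains with one or two copies, i.e. soon after origin, and abundant
  domains are effectively immortal.

What the generator does **not** emulate: sequence evolution, lateral
transfer, viruses, annotation error, and any correlation between domain
function and abundance. Passing recovery tests on these censuses shows
the inference chain is faithful to its own model assumptions at desk
scale; it does not certify performance on real, much larger censuses with
horizontal transfer and annotation noise.

## Problem sizes, test configuration and known limitations

The validation suite runs the full chain on censuses of 50 domain types
across 15 proteomes over 25 replicate seeds, with a deliberately light
search configuration (ratchet of 5 iterations, single restart, NNI+SPR),
recorded here as the package's choice for its simulation studies: at
these matrix sizes the strongly nested abundance structure leaves little
for longer searches to improve, and anyone can raise `SearchParams()`
and compare. `assessRecovery()` exposes exactly this experiment.

Two intrinsic limits are worth knowing. First, the temporal resolution of
an abundance chronology is bounded by duplication stochasticity: a domain
born with one copy stays at one copy for $t$ steps with probability
$0.9^t$, so log-abundance carries noise of order one natural-log unit,
while the whole 3.8-Gy range spans only $\ln(g_{\max}) \approx 9.6$ units
— birth-time differences much below a tenth of the timeline are not
resolvable from abundance, in any analysis. Second, a domain lost by a
whole superkingdom acquires a strongly correlated absence profile;
parsimony places such domains in derived side clades, so their nd dates
the loss rather than the birth. Both effects depress the rank agreement
between true birth order and inferred nd on small censuses; the recovery
experiment reports the agreement honestly rather than selecting domains
that behave well.

Numerical conventions, for reproducibility: half-up rounding in the
coding; steepest-descent swapping with first-found tie-breaking in the
search; first-edge tie-breaking (with all ties reported) in Lundberg
rooting; all simulation and search randomness flows from explicit seeds,
and rerunning a pipeline configuration reproduces every output file byte
for byte.
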