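# domClock

Time-calibrated phylogenomic trees of protein domain structure, built from
genomic abundance censuses.

## The problem

A census of protein domain structure counts the occurrences of each domain
type — typically a SCOP fold superfamily (FSF) like `c.37.1` — in each of a
set of proteomes spanning Archaea, Bacteria and Eukarya. Because genomic
abundances grow as genes duplicate and diverge, the most abundant and most
widely distributed domains are the oldest, and the census supports two
phylogenies at once: a tree of proteomes (ToL, taxa = organisms) and, from
the transposed matrix, a tree of domains (ToD, taxa = domain structures)
whose branching order is a chronology of biochemical innovation. `domClock`
is for molecular evolutionists who want to run, probe or extend this
analysis with tested, reproducible code.

The method, end to end:

* abundances `g` are coded into 24 linearly ordered, reversible character
  states (alphabet `0`–`9`, `A`–`N`),
  `G = round(23 · ln(g+1) / ln(gmax+1))`;
* trees are sought by ordered (Wagner) maximum parsimony — character cost
  `|i − j|`, interval/Farris down-pass — with a parsimony-ratchet heuristic
  search (random-addition starts, NNI/SPR swapping, iterated character
  reweighting);
* trees are rooted without outgroups by the Lundberg method: a hypothetical
  ancestor carrying per-character maximum states (the abundance
  polarization model) is attached on the edge of minimum added length;
* each leaf gets a node distance `nd = (d−1)/(dmax−1)` (internal nodes from
  root to leaf, rescaled to [0, 1]), a relative age on the pectinate trees
  the process produces;
* a linear molecular clock `age = a + b · nd` is calibrated by OLS on
  geological calibration points and turns the ToD into a timetree;
* the rooted ToL's root states give the urancestral domain repertoire under
  a stringency sweep; superkingdom Venn groups, group emergence times and
  whole-superkingdom domain losses are mapped onto the chronology; rows and
  columns of the census are ordered for the canonical heat-map figure.

Because published censuses of this kind are not deposited alongside the
analyses, the package ships a synthetic census generator
(`simulateCensus()`) with recorded ground truth — domain birth times, the
true organismal tree, loss events, the stem-line repertoire — so every
stage is testable. See the vignette (`vignettes/domain-timetrees.Rmd`) for
the models, parameter choices and known limitations.

## Worked example

```r
library(domClock)

sim  <- simulateCensus(SimParams(seed = 42L))   # census + ground truth
sim$census
#> AbundanceCensus: 38 domains x 15 proteomes, gmax = 29962
#>   superkingdoms: Archaea=5, Bacteria=5, Eukarya=5

todM <- t(encodeCensus(sim$census, scheme = "log"))  # ToD orientation
fit  <- searchTrees(todM, SearchParams(ratchetIterations = 5L,
                                       restarts = 1L, seed = 1L))
fit$length                                       # best tree length: 694

rooted <- lundbergRoot(fit$trees[[1]],
                       polarizedAncestor(todM, "max-state"), todM)
nd  <- nodeDistances(rooted)
cal <- simulateCalibrations(sim$truth, clock = c(3.8, 3.8), nPoints = 10L,
                            noiseSd = 0.1, seed = 7L, domains = names(nd))
clk <- fitClock(cal, nd)
clk
#> ClockModel: age = 4.173 -1.691 * nd  (R^2 = 0.6952, n = 10, sd = 0.3 Gy)

chron <- buildChronology(rooted, clk, treeId = "ToD")
head(as.data.frame(chron), 3)
#>     leaf         nd   age_Gy
#> 4  g.2.1 0.00000000 4.173271
#> 10 c.1.1 0.03225806 4.118734
#> 9  d.1.1 0.09677419 4.009662

table(vennAssign(sim$census))
#>   A  AB ABE   B  BE   E
#>   8   2  20   3   1   4

detectSuperkingdomLosses(sim$census, chron = chron)
#>   domain superkingdom   age_Gy        presentIn firstLoss
#> 1  a.4.1      Eukarya 3.246153 Archaea+Bacteria      TRUE
#> 2  f.4.1      Eukarya 3.246153 Archaea+Bacteria     FALSE
#> 3  c.3.1      Archaea 3.191617 Bacteria+Eukarya      TRUE

round(cor(birthTimes(sim$truth)[names(nd)], nd, method = "spearman"), 3)
#> [1] 0.832
```

Reading the output: the leaf at `nd = 0` (`g.2.1`) is the most ancient
domain in the inferred chronology and is dated near the clock intercept
(~4.2 Gy here — the fitted intercept overshoots the true 3.8-Gy origin
because the calibration points are noisy); the Venn table shows the nested
structure (20 ubiquitous `ABE` domains against at most 8 unique to one
superkingdom); the loss table flags domains absent from one entire
superkingdom, present in both others, and older than that superkingdom's
own first endemic domain — `c.3.1` is the inferred first complete loss in
Archaea, dated by its own nd-derived age (a lower bound for the loss
time). The final line scores the run against the generator's truth: the
Spearman correlation between true birth steps and inferred nd is 0.83.

`runPipeline(pipelineConfig(...))` chains all stages (simulation or file
input → coding → ToD/ToL searches → rooting → chronology/clock →
urancestor → Venn/losses/heat-map order) into one seeded, fully
reproducible run that writes every intermediate plus a JSON manifest.

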