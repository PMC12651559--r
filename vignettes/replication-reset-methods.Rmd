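---
title: "Models and methods behind replireset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replireset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replireset)
```

`replireset` packages the quantitative procedures used to study *replication
reset* in fast-growing bacteria — the resolution of transcription–replication
collisions by fork rear-ending and RecBCD-mediated degradation of an entire
nascent replicore — together with seeded generators that emulate each
experimental readout with known ground truth. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not demonstrate about real data.

## CRISPRi screen statistics

Pooled CRISPRi screens read gene fitness out of guide-plasmid abundances
sequenced before and after an outgrowth. The count model is deliberately a
*simplified* negative-binomial pipeline:

* **Size factors** are classic median-of-ratios: for sample $j$,
  $\hat s_j = \operatorname{median}_i\, c_{ij}/(\prod_j c_{ij})^{1/m}$ over
  guides with nonzero counts everywhere, rescaled to geometric mean 1. This
  is exactly the estimator used by mainstream RNA-seq count modelling, and a
  test cross-checks it against that implementation.
* **Dispersions** are per-guide method-of-moments values
  $\hat\alpha_i = \max\{0, (s_i^2-\bar\mu_i)/\bar\mu_i^2\}$ on normalized
  counts within replicate groups, pooled by degrees of freedom, with a robust
  least-squares mean trend $\alpha(\mu) = a_0 + a_1/\mu$. The trend value is
  used as-is: there is **no** empirical-Bayes shrinkage of individual guides
  toward the trend, and no fold-change shrinkage. These would add power for
  small designs but are not part of the procedure being modelled.
* **Fold changes** are $\log_2$ ratios of mean normalized counts
  (post + c)/(pre + c) with pseudocount $c = 0.5$ normalized counts. The
  pseudocount bounds fold changes for guides that drop to zero, at the price
  of compressing extreme depletions; with 5 doublings a fully dead guide
  would ideally read ≈ −10, but the pseudocount floors it near
  $\log_2(c/\mu_{pre})$.
* **Gene values** are medians across the gene's guides (robust to a dead or
  mistargeting guide), with a MAD-based standard error. Guides with
  pre-induction normalized mean below 10 are flagged low-coverage and
  excluded; the threshold is configurable and was chosen as the depth below
  which a single-count fluctuation moves the guide's fold change by more
  than ~15%.

**Interaction calling.** Experimental gene fold changes are regressed on the
control condition's. "Removing the gene significantly improves the fit" is
operationalized as the externally studentized deleted residual
$t_i = e_i/(s_{(i)}\sqrt{1-h_{ii}})$, referred to $t_{G-3}$, two-sided, with
Holm correction at $\alpha = 0.05$. This is *identical in decisions* to the
leave-one-out F test on the residual-sum-of-squares reduction
($t_i^2 = F_i$), which the test suite verifies by brute-force refitting.
Calling is single-pass: each gene is tested against the full-fit baseline,
with no iterative removal, because each candidate is judged relative to the
bulk trend of all genes. Two numerical guards matter in degenerate inputs: a
globally perfect fit (all residuals ~0) carries no outlier signal and yields
no calls, while a perfect *leave-one-out* fit around one displaced gene makes
the deleted variance vanish and is treated as infinite evidence for that
gene.

## Fluctuation analysis

The mutant-count distribution is the Lea–Coulson formulation with mutant
relative fitness fixed at 1: mutation events per culture are
Poisson($m$) and each event founds a clone whose final size has the law
$P(\text{size}=k) = 1/(k(k+1))$. The generator draws clone sizes as
$\lfloor 1/U \rfloor$, $U\sim\mathrm{Uniform}(0,1)$, which realizes that law
exactly, so the generator and the Ma–Sandri–Sarkar (MSS) recursion

$$p_0 = e^{-m},\qquad p_k = \frac{m}{k}\sum_{j=0}^{k-1}\frac{p_j}{k-j+1}$$

describe the same process; a total-variation test at $m \in \{0.5, 1, 2\}$
with $10^6$ cultures holds them to within 0.01.

$\hat m$ maximizes the MSS likelihood by bounded 1-D search on
$[10^{-6}, 10(\bar x + 1)]$ with tolerance $10^{-6}$; the recursion is
truncated at the maximum observed count, capped at 5000 with astronomical
jackpot counts scored against the censored tail mass (the recursion is
$O(K^2)$). The standard error is the inverse square root of the numerical
observed information. The per-generation rate is $\hat\mu = \hat m / N_t$
with $N_t$ the final population per culture — the convention that one
saturated culture represents about $N_t$ cell divisions; $\hat m/(N_t\ln 2)$
is exposed as an option (`per_division = FALSE`) since both denominators are
in circulation. Rates are compared with a one-sided normal test on
$(\hat\mu_a - \hat\mu_b)/\sqrt{se_a^2+se_b^2}$.

Partial plating ($z < 1$, e.g. 100 µl plated of a 3 ml culture) is simulated
by binomial thinning, but the estimator deliberately assumes $z = 1$ and
warns otherwise: the exact $z$-corrected pmf is out of scope, and estimates
from thinned counts refer to *plated* mutants. All-zero counts sit on the
likelihood boundary and return $\hat m = 0$ with no standard error.

## Flow-cytometry DNA content

Peaks in the DAPI intensity distribution are located on a Gaussian-kernel
density (Silverman bandwidth by default) as points where the first
derivative crosses from positive to negative — the second-derivative sign
rule — filtered by topographic prominence (default 5% of the density
maximum, which suppresses shoulder artifacts of overlapping peaks).
Calibration regresses *signal on assigned chromosome number*, matching how
control peaks are plotted, and inverts the line for conversion; regressing
count on signal would minimize errors in the wrong variable.

Chromosome fractions count events whose calibrated estimate lies within a
window (default ±0.35 chromosomes) of the target integer; windows of 0.5 or
more would make neighbouring integers ambiguous and are rejected. At an
optical CV of 10% a 2-chromosome peak has a spread of ±0.2 chromosomes, so
the default window clips about 8% of the peak's mass; fraction summaries at
that noise level should widen the window toward 0.45 (as the acceptance
simulations do) or accept the undercount.

## Replication run-out and the reset signature

A cell in steady exponential growth has age $a$ with density
$2\ln 2\cdot 2^{-a}$ on $[0,1)$. With $G$ cohabiting fork generations
(`generations_overlap` $= G-1$), round $j$ (oldest $j=1$) sits at replichore
fraction $(a+G-j)/G$ and runs on $2^{j-1}$ sister structures, which
reproduces the classic marker-frequency facts: per-locus copy number
$2^{\#\text{rounds past the locus}}$, origin:terminus ratio $2^G$, and a
completed run-out (initiation and division blocked, forks finish) leaving
exactly $2^G$ chromosomes.

The collision model is event-based with deterministic geometry. The oldest
round still behind a blockage stalls there with probability `p_stall`; its
trailing round — one initiation interval ($1/G$ replichore) behind — closes
the gap and rear-ends with `p_rearend_given_stall`, during which the stalled
round's sister replisome advances that same interval. The *sister-fork
locus* is therefore pinned at the stall fraction plus $1/G$ on the sister
replichore, and the degradation tract runs from the rear-end site through
*oriC* to that locus. Consequences of an event:

* **Reset (degradation competent):** one full replication round is reverted
  — a cell headed for $2^G$ chromosomes ends the run-out with $2^{G-1}$,
  the flow-cytometry signature of reset (e.g. 4 → 2).
* **Gam mode (ends protected):** nothing is degraded; the rear-ended round
  is frozen at its collision extent and the blockage persists, leaving
  non-integer chromosome equivalents — stabilized replication
  intermediates.

Two epochs of this one event history are rendered, mirroring the two assays.
Flow cytometry reads the **end of the run-out**. Sequencing of
degradation-delayed populations is a **mid-run-out snapshot** taken at each
cell's stall-resolution epoch; there the tract is rendered as fully resected
nascent DNA (parental copy 1, never less — the parental duplex is not
broken), which carries sharp, planted boundaries at the rear-end and
sister-fork loci. This is a stylized population-level bookkeeping, not a
molecule-resolved simulation: its purpose is a ground truth that the
coverage analytics must recover, and its end-state and snapshot are not
required to interpolate into one another.

Two limitations follow from the deterministic fork ladder. First, a barrier
closer to the origin than one initiation interval ($1/G$ of a replichore) is
only ever reached by the youngest round, which has no trailer — so
rear-ending at origin-proximal loci requires the shorter initiation
intervals of hyper-initiating strains, which this generator does not model;
demonstration analyses therefore place the barrier mid-replichore. Second,
snapshot profiles are piecewise-constant (ages cancel out of the
event-relative epoch), so flanks are steps rather than the smooth pyramids
of asynchronous real populations.

## Coverage analytics on a circular genome

Coordinates are 0-based half-open and wrap at the chromosome length; all
reference coordinates (length, *oriC*, terminus window, loci) live in a
config — NC_000913.3 values ship as `inst/extdata/NC_000913.3.conf` — and
nothing is hard-coded in logic. Binning accumulates bedGraph-style per-base
signal into fixed-width bins (1 kb by default) with length-weighted partial
overlaps and circular wrap, conserving total signal exactly. CPM
normalization scales the track to $10^6$; terminus correction further
divides by the mean over the terminus window so terminus copy number reads
1. Replicate averaging → rolling-MAD outlier trimming ($k = 5$ robust SDs
against a 25-bin rolling median, spikes imputed from neighbours) → circular
loess (degree 1, default span 2% of the genome) is the smoothing order; the
trimming rule and the order are choices of this package, as is the
pure-spike fallback (when the MAD is zero the residual SD takes over).

**Plateau detection** looks for the degradation-tract signature: maximal
runs of bins whose relative slope on a 21-bin rolling median stays within
`flatness_tol` (default 10% per bin), kept only if the run level lies at
least 10% below the linear trend extrapolated from both flanking windows.
Each flank is fitted separately so a truncated pyramid apex (flanks rising
toward the run) is recognized; flank slopes are used only when statistically
clear ($|t|\ge 2$) and frozen beyond four flank-lengths, because a 50-bin
fit extrapolated over thousands of bins otherwise amplifies noise into
nonsense. Runs covering more than 90% of the genome (a flat completed
run-out) are never plateaus, and — because a degradation tract by mechanism
crosses the origin — only runs containing *oriC* are reported by default.
Boundaries are refined to the half-height crossing on the *raw* track, which
localizes a clean step to about one bin; the wide rolling median only
stabilizes run detection.

**Orientation.** For stranded DNA-end tracks, the per-bin orientation index
is $(R-L)/(R+L)$ and the genome-wide `away_fraction` is the share of signal
facing away from *oriC* along its replichore (forward strand on the
clockwise replichore, reverse on the other). One-ended collision ends all
face away, two-ended breaks split evenly, so the away-fraction is linear in
the one-ended fraction: $f_1 + (1-f_1)/2$. Poisson background dilutes this
toward 0.5; the generator's default background (0.1 reads/bin/strand against
2000 reads per site) keeps the dilution below one percentage point.

## Simulation scale and what the tests show

Default test and acceptance scales — $10^6$ cultures for distributional
agreement, 200 replicates of 30-culture assays (the design scale of the
mutation-rate experiments), 100 null screens of 2000 genes × 5 guides,
populations of a few hundred to a few thousand cells, 1 kb bins on the
4.64 Mb chromosome — were chosen so each check resolves its tolerance with
comfortable Monte-Carlo margin. Passing them shows the estimators invert
their own generative models correctly and with calibrated error control; it
does not certify behaviour under real-data pathologies the generators omit:
sequence-composition bias, mappability, guide off-target structure,
replicate batch effects, cytometer gating artifacts, or hyper-initiation
age structures. The interfaces accept real count tables, event exports, and
bedGraphs so those properties can be examined directly when such data are
in hand.
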