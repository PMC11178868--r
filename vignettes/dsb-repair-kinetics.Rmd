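---
title: "Quantifying CRISPR-Cas9 cutting and repair kinetics with dsbflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR-Cas9 cutting and repair kinetics with dsbflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbflow)
```

## The problem

When Cas9 ribonucleoproteins (RNPs) are delivered into cells, target loci
move through a cycle of states: intact DNA is cut into a double-strand break
(DSB); broken ends may be processed (resected, extended, filled); and breaks
are resolved either precisely — restoring the original sequence — or with
error, leaving an indel. Amplicon sequencing sees only the endpoint
(indels), so it confounds cutting efficiency with repair fidelity: a locus
with few indels may be cut rarely, or cut often and repaired precisely.

Single-molecule (UMI-consensus) capture assays that ligate adaptors directly
onto broken ends observe the DSB intermediates *alongside* intact and
indel-bearing molecules, over a sampled time course. `dsbflow` implements
the computational half of such an experiment:

1. **Classification** of consensus reads into intact, indel (NHEJ) and
   unrepaired-DSB states, with indel footprint naming, microhomology
   annotation, and positional typing of captured DSB ends.
2. **Kinetic modeling** of the per-category counts with 3-state and 4-state
   compartment models under a time-varying RNP activity curve, fitted by
   exact multinomial maximum likelihood, with stratified-bootstrap
   uncertainty, AIC model comparison, and cumulative-flow integration.
3. **Simulation** of both category counts and raw reads with planted
   footprints, so every step can be validated against known truth.

## Read classification

All classification happens inside a 100 bp reference window (`wt_ref`)
centred on the expected blunt cut (SpCas9 cuts 3 bp upstream of the PAM).
Coordinates are 0-based and half-open; "position 50" means a molecule whose
captured end abuts the boundary between offsets 49 and 50 — the expected
cut. Targets whose PAM lies left of the cut in the amplicon's written
orientation are reverse-complemented internally (reads included), so the
captured, primer-proximal side is always on the left.

The outermost 12 bp of the window act as *indicators*. A read is:

* **INTACT** — both indicators align with score at least 10 of 12
  (ungapped +1/−1 scoring, so one mismatch passes; a gapped fallback through
  `Biostrings::pairwiseAlignment` with gap cost 2 per position rescues
  indicators carrying a single indel);
* **DSB** — only the left (captured-side) indicator aligns;
* **NA** — neither rule applies, the read has more than 4 `N`s, or it ends
  in the target primer (allowing one mismatch), which marks a PCR
  contamination artifact rather than a captured end.

Ties at the maximal indicator score resolve to the leftmost hit for the left
indicator and the rightmost for the right indicator, maximizing the spanned
window deterministically.

Intact reads are globally aligned to `wt_ref`; gaps in the reference are
insertions (`+` + bases), gaps in the read deletions (`-` + bases), and any
non-WT footprint promotes the read to state NHEJ. Indels are left-normalized
before naming, which makes microhomology detection independent of where the
aligner happens to place the gap. A deletion whose flank repeats at least
`mh_min_len` (default 2) bp of the deleted sequence is annotated `MH_Del`
with the repeat reported. Reads containing both an insertion and a deletion
are named by concatenating the events in reference order and typed by the
net length change; the simple cases are the scientifically meaningful ones
and the composite naming merely keeps every read's footprint unique and
parsable.

DSB reads are typed by where the captured molecule ends: at `50 + delta`
for `delta` in the target's `direct_positions` they are **direct**
(nuclease-made) breaks; short of every direct position, **guide**-side
(resection or deletion intermediates); past the cut with reference-matching
bases, **PAM**-side; past it with non-reference bases, **extended** (filler
DNA). Dual-cleavage targets — loci where the nuclease leaves blunt ends at
both −3 and −4 from the PAM — set `direct_positions = c(0, -1)` so both
ends count as direct. Trailing `N`s are trimmed before measuring the end
(adaptor fill-in is not end evidence; internal `N`s are consensus ambiguity
and are left alone).

```{r classify-demo}
sheet <- system.file("extdata", "synthetic_samplesheet.csv",
                     package = "dsbflow")
target <- read_sample_sheet(sheet)$synthetic_psy1_like
gr <- generate_reads(target,
                     c(WT = 0.6, "del:8@44" = 0.2, "dsb@50" = 0.2),
                     n_reads = 50, seed = 1)
mols <- classify_molecules(gr$reads, target)
table(mols$state)
unique(mols[mols$state == "NHEJ",
            c("footprint_type", "footprint_name", "microhomology")])
```

The bundled sample sheet is synthetic: the amplicons are constructed
sequences that embed the features of interest (a 4 bp `TGTT` microhomology
spanning the cut of the first target, a dual-cleavage second target), not
the sequences of any real locus.

## The kinetic models

Latent states are fractions of the molecule pool. The **3-state model**
tracks intact, indel and DSB pools:

$$
\begin{aligned}
\frac{d[\mathrm{intact}]}{dt} &= -K_\mathrm{cut}\,\mathrm{RNP}(t) + P\,[\mathrm{DSB}]\\
\frac{d[\mathrm{indel}]}{dt} &= E\,[\mathrm{DSB}]\\
\frac{d[\mathrm{DSB}]}{dt} &= K_\mathrm{cut}\,\mathrm{RNP}(t) - (P+E)\,[\mathrm{DSB}]
\end{aligned}
$$

with cutting rate $K_\mathrm{cut}$, precise-repair rate $P$ (DSB back to
intact — the unobservable flux this machinery exists to estimate) and
error-repair rate $E$ (DSB to indel), all per hour. Observed DSBs split
into direct and processed ends with a constant observation probability $e$:
processed ends are treated as a reporting phenomenon, not a distinct
kinetic pool. The **4-state model** promotes processed DSBs to a real pool
fed from direct DSBs at rate $K_\mathrm{processing}$, each pool with its
own precise and error repair rates; with $K_\mathrm{processing}=0$ it
collapses exactly onto the 3-state model (a nesting the test suite checks
to $10^{-8}$). A `3state_no_precise` variant fixes $P = 0$ for model
comparison.

### The induction curve

RNP activity is not constant: RNPs must enter cells and their activity
decays. The activity is modeled as

$$
\mathrm{RNP}(t) = \max\!\Big(0,\; (1-U)\, 2^{-d t}\,
\mathrm{logistic}\big(r (t - t_0)\big) - \big(1 - [\mathrm{intact}]\big)\Big),
\qquad t_0 = \frac{\ln 10^6}{r + 10^{-12}},
$$

where $U$ is the fraction of molecules that can never be cut (e.g. in
untransfected cells), $r$ the induction speed, and $d$ the decay rate
(half-life $1/d$). The anchor $t_0$ forces activity $\approx 10^{-6}$ at
$t = 0$; the $10^{-12}$ is a division guard, and the logarithm is natural
(forced by the $10^{-6}$ anchor). The subtraction of $1-[\mathrm{intact}]$
makes $\mathrm{RNP}(t)$ the fraction of the pool currently accessible to
active RNPs, so the model's cutting term is $K_\mathrm{cut}\,\mathrm{RNP}(t)$
directly: at saturation with $d=0$ this equals
$K_\mathrm{cut}([\mathrm{intact}]-U)$, i.e. cutting acts on the cuttable
intact excess over the untransfected fraction. We verified this form
(rather than an additional multiplication by $[\mathrm{intact}]$) by
checking that integrating previously reported rate estimates reproduces the
corresponding reported 72 h and 24 h flows to within a fraction of a
percent — the extra multiplication underestimates them by 10–20%. An
optional `t_offset` (default 0, with 0.5 h the documented alternative)
shifts the induction clock to account for handling time between
transfection and the nominal time 0; it shifts the clock, never the
observation times.

### Observation model and likelihood

Control time courses (no guide) contain only intact molecules, so their
pooled category frequencies estimate the probability that an intact
molecule is recorded in each category. The resulting 4×4 error matrix
assumes indel-bearing molecules misread at the same rates (roles swapped)
and that a broken molecule is never read as intact. Counts in each
(time point, replicate) sample are multinomial over
`{intact, indel, dsb_direct, dsb_processed}` with probabilities given by
the integrated model passed through this matrix, and the log-likelihood is
computed exactly (the package's own `lgamma` form; `stats::dmultinom`
serves as an independent oracle in the tests).

### Optimization

Rates live in the box $[0, 10]$ per hour (10 cuts/hour comfortably exceeds
any reported CRISPR cutting rate), $e, U \in [0, 1]$, $d \in [0, 10]$, and
$r$ is optimized as $\log_{10} r \in [-2, 5]$ because its plausible values
span seven orders of magnitude and raw-scale quasi-Newton steps cannot
traverse that. Multi-start search draws `n_starts` (default 5000) points
from an exponential distribution with mean 0.01 (log-uniform for $r$),
evaluates the likelihood at all of them, and runs box-constrained L-BFGS-B
from the best `n_refine` (default 25). Screening before refining preserves
the global-search intent of optimizing from every start at a fraction of
the cost: most draws land in one basin of attraction, and refining the 25
best screened points in practice recovers the same optimum as refining all
of them. Fits are deterministic given `seed`.

Integration uses fixed-step classical RK4. The clipped activity curve makes
the right-hand side non-smooth, where fixed steps are more reproducible
than adaptive error control. Flow integration and the acceptance surface
use 500 steps/hour; the likelihood inside the optimizer defaults to 50
steps/hour, which changes log-likelihoods by well under 0.1 for realistic
rates while cutting fit time an order of magnitude (both are
`steps_per_hour` arguments). Mass conservation holds to $10^{-8}$ at every
step.

### Uncertainty and model comparison

`stratified_bootstrap()` resamples molecules with replacement within each
(time point, replicate) stratum — operationally a multinomial redraw of
each sample's counts at its own total, which is the resampling scheme
implied by the multinomial likelihood — and refits each resample, warm
starting from the original estimate plus a small random screen. Confidence
intervals are the 1% and 99% percentiles of the re-estimates; the one-sided
p-value per parameter is the proportion of re-estimates at the zero bound,
reported as `<1/B` when none (with $B = 100$, `<0.01`). Refits that fail
are dropped and counted; more than 10% failures flags the intervals
unreliable. `aic_compare()` reports AIC, ΔAIC and relative likelihood
$\exp((\mathrm{AIC}_{\min}-\mathrm{AIC})/2)$; `bootstrap_compare()` refits
two nested models on shared resamples and reports the proportion
preferring the more complex model, with >95% as the stability threshold.

### Flows

`compute_flows()` integrates each rate term over the time course: e.g.
cutting flow $= \int_0^T K_\mathrm{cut}\,\mathrm{RNP}(t)\,dt$, in units of
the initial molecule pool. Flows can exceed 1 because precisely repaired
molecules re-enter the cuttable pool and can be cut again. Repair accuracy
is precise flow over total repair flow; in the 3-state model the
error-to-precise flow ratio equals $E/P$ exactly (both integrate the same
DSB trajectory), an identity the tests verify to machine precision.

```{r flows-demo}
fl <- compute_flows("3state", rates3(0.0092, 0.0791, 0.0335, 0.2052),
                    induction_params(U = 0, r = 9402.089, d = 0), T = 72)
fl
```

## What the simulator emulates — and what it does not

`simulate_counts()` draws per-sample multinomial counts from the integrated
model (per-sample substream seeds derived from `(seed, time, replicate)`,
so draws are reproducible regardless of evaluation order);
`generate_reads()` builds raw reads from a target's amplicon with planted
footprints: WT, insertions, deletions, truncations at any window boundary,
and extended ends with non-reference filler. Per-base `N` noise exercises
the NA rule. The simulator deliberately omits substitution sequencing
errors, UMI collisions and PCR duplication: the classification rules are
indel- and end-driven, and consensus building (which would absorb
substitution errors) is upstream of this package's scope. Passing the
round-trip and recovery tests therefore demonstrates correctness of the
rules and estimators under the stated noise model, not robustness to every
artifact of a real sequencing run.

Default simulated study conditions mirror a realistic protoplast time
course: 7 time points over 72 h (0, 6, 12, 24, 36, 48, 72), 2 replicates,
$10^4$ molecules per sample, near-step induction ($r = 10^4$, $U = 0$,
$d = 0$). The recovery tests use 20 such simulations with 200 screened
starts per fit (10 refined); the false-positive tests use bootstrap
$B = 50$. These sizes are scaled-down but statistically adequate: at
$10^4$ molecules the multinomial noise on each category proportion is
below 0.5%, and the recovery criterion (median relative error below 15%)
is met with a wide margin.

## Numerical choices and degenerate inputs

* Requested output times are snapped to the RK4 step grid (exact for the
  usual integer-hour sampling).
* Likelihood evaluations that integrate to non-finite states, or put zero
  probability on an observed count, contribute $-\infty$ (the optimizer
  treats them as a large finite penalty).
* All-intact data with a free induction curve is ridge-degenerate
  ($K_\mathrm{cut} = 0$, $U = 1$ and $r \to 0$ all fit perfectly); fixing
  the induction curve resolves the ridge when that matters.
* Empty control sets yield an identity error matrix with a warning; an
  all-zero control total does the same.
* FACS-based induction fitting (`fit_induction_from_facs()`) maximizes the
  binomial likelihood of positive-cell counts under the uncoupled activity
  curve; all-zero or all-one data produce boundary estimates with a
  warning. Because activity at the sorting clock's zero is anchored at
  $10^{-6}$, a fraction of 1 at $t=0$ is only approachable through the
  handling-time offset (default 0.5 h for FACS).

## Known limitations

* Per-read concordance with any particular upstream pipeline is rule-level,
  not implementation-level: local-alignment scoring of the original
  tooling is not published, so reads balanced exactly at the 10/12
  indicator boundary may be called differently.
* The error matrix is estimated from controls pooled across time; a
  time-varying artifact rate is not modeled.
* The 4-state model's identifiability is data-limited: with few processed
  DSBs, $P_\mathrm{processed}$ and $E_\mathrm{processed}$ have wide
  bootstrap intervals; compare models before interpreting them.
* Reported confidence intervals are percentile bootstrap intervals; for
  parameters pinned at a box bound they are one-sided by construction.
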