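---
title: "Decay-corrected reactivity estimation: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decay-corrected reactivity estimation: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeseqr)
```

## The experiment and the generative model

A two-channel probing experiment treats one RNA pool with an acylating
reagent ((+) channel) and mock-treats another ((−) channel). Reverse
transcription initiated from a universal 3′ linker then converts each
molecule into a cDNA whose length records where RT terminated: at a chemical
adduct, or by spontaneous drop-off. `shapeseqr` models this process
explicitly.

RT processes positions $L, L-1, \dots, 1$ in order. The model has three
parameter groups:

* $\gamma_k \in [0, 1)$ — the natural drop-off hazard: the probability RT
  terminates at position $k$ given that it reached $k$, in the absence of
  modification. The (−) channel measures exactly this.
* $p_{\mathrm{mod}} \in [0, 1]$ — the probability a (+)-channel molecule
  carries a modification at all.
* $\theta = (\theta_1, \dots, \theta_L)$ — the distribution of the
  modification position among modified molecules, $\sum_i \theta_i = 1$.
  This is the reactivity spectrum the pipeline exists to estimate.

The **single-hit assumption**: each molecule carries at most one adduct, and
RT stops with certainty upon reaching it. This is the low-modification
regime the θ-distribution formalism presumes; a multi-hit (Poisson ladder)
correction is deliberately out of scope. A stop at index $k$ means the last
synthesized cDNA base was $k+1$ (the blocking lesion sits one nucleotide 5′
of it); $k = 0$ is a full-length read-through. Stop probabilities follow by
summing over the adduct site; `dropoff_loglik()` evaluates the resulting
two-channel log-likelihood and the test suite pins it to an independent
enumeration.

## The estimator and why it carries a survival product

Write $X_k, Y_k$ for the (+)/(−) stop counts and
$\alpha_k = X_k / \sum_{j \le k} X_j$,
$\beta_k = Y_k / \sum_{j \le k} Y_j$ for the empirical per-position stop
hazards (the denominator counts molecules that *reached* $k$, i.e. stopped
at $k$ or read through further). $\beta$ is the hazard MLE of $\gamma$ from
the control channel alone — the (−) channel carries no information about
θ, so γ is profiled there rather than estimated jointly.

In the (+) channel the combined stop hazard at $k$ factorizes as
$h_k = 1 - (1-\gamma_k)(1-\mu_k)$, where
$\mu_k = P(\text{adduct at } k \mid \text{reached } k)$. The likelihood is a
product of independent hazard terms in the $\mu_k$, so the MLE is
$\hat\mu_k = r_k$ with

$$ r_k \;=\; \frac{\alpha_k - \beta_k}{1 - \beta_k}, $$

clamped below at zero (sampling noise can push $\alpha_k$ under $\beta_k$;
with γ profiled at β, the clamp *is* the constrained MLE, and the unclamped
value is kept in the diagnostics). Mapping back from conditional hazards to
the unconditional site distribution introduces a survival product:

$$ \hat\theta_k \;\propto\; r_k \prod_{j > k} (1 - r_j),
   \qquad
   \hat p_{\mathrm{mod}} = 1 - \prod_j (1 - r_j). $$

The product term matters: a position can only host the (single) adduct if no
position 3′ of it did. Normalizing $r_k$ alone — without the survival
product — looks natural but does **not** maximize the stated likelihood
except in the limit of small $p_{\mathrm{mod}}$. We verified this during
design on a two-position instance (counts $X = (40, 20, 40)$,
$Y = (90, 0, 10)$): grid search plus local refinement of the likelihood
gives $\hat\theta = (0.4, 0.6)$ and $\hat p_{\mathrm{mod}} = 5/9$, exactly
the survival-product closed form, whereas plain normalization of $r$ gives
$(0.5, 0.5)$ with a strictly lower likelihood. The test suite keeps the
estimator honest by comparing it against numeric maximization (grid over
the simplex plus Nelder-Mead polishing) on seeded random instances with
$L \le 4$ and counts $\le 100$, at a per-coordinate tolerance of $10^{-3}$
(the granularity of the numeric optimizer, not of the closed form).

Edge cases are explicit rather than silent: positions never reached in
either channel are unestimable (flagged, contributing 0); a saturated
control position ($\beta_k = 1$) is flagged and excluded from
normalization; and an instance with no signal anywhere ($r \equiv 0$, e.g.
identical channels) yields a *degenerate* profile — all-zero θ with a flag —
rather than an error, since downstream code must distinguish "no signal"
from "no data".

## Coordinate conventions (load-bearing)

* Positions are 1-based and inclusive throughout; the full-length bin is
  index 0.
* Stop attribution: a fragment whose 5′-most aligned position is $p$ yields
  stop index $k = p - 1$. Changing this convention shifts every spectrum by
  one; it is the convention under which the simulator's planted reactive
  sites recover at their planted positions.
* The 3′-terminal position $k = L$ is excluded from scoring by default
  (`exclude_3prime = TRUE`, scored length $L' = L - 1$): a molecule modified
  there yields a linker-only fragment with zero target nucleotides, which
  identifies no target and cannot be aligned. The aligner therefore refuses
  such candidates and the $k = L$ count bin is structurally zero in real
  (aligned) data. For simulated count tables, where the bin can be
  populated, the estimator simply ignores it; the survival factor
  $(1 - r_L)$ is common to every scored position and cancels in the
  normalization.
* θ is reported over the scored range and sums to 1 there;
  $\rho_k = L' \theta_k$ so that $\bar\rho = 1$ exactly.

## Read processing choices

Alignment is exact-substring matching of the handle-stripped R1 against
`target[p..L] + linker`, with two deliberate twists:

* **Adapter-aware overhang matching.** When the read is longer than the
  candidate fragment+linker, the overhang must match the adapter prefix.
  Suffix-trimming with a minimum overlap (provided as `trim_adapter()`,
  default minimum 4) cannot remove a 1–3-nt read-through remnant; folding
  read-through into the aligner is what makes exact end-to-end count
  recovery possible. Including the linker in the match also anchors very
  short fragments (even a single target nucleotide) that would otherwise be
  unalignable.
* **Mate verification.** R2 must equal the reverse complement of the full
  insert (observed handle + fragment + linker, adapter-padded) within the
  same mismatch budget. The default budget is 0 mismatches per mate, with a
  Hamming-distance option (no indels — indel-tolerant alignment is out of
  scope, matching the substitution-only error model of the simulator).
* **Ambiguity.** A read consistent with more than one (target, position) is
  discarded and counted, never assigned at random: random assignment would
  bias hazard estimates at sequence repeats. The run statistics account for
  every input pair (aligned + unaligned + ambiguous + handle-unassigned),
  so nothing is dropped silently.

Base qualities are carried but unused by default; an optional
minimum-mean-quality filter exists and is off.

## The simulator: what it emulates and what it does not

`simulate_stop_counts()` draws the per-channel stop counts in a single
multinomial step from the analytic stop distribution — distributionally
identical to simulating each molecule's walk, exactly reproducible from the
seed, and fast enough to run the full study sizes inside the test suite.
`emit_fastq()` expands the counts into per-molecule read pairs: concrete
handle instantiation (e.g. RRRY → one of A/G,A/G,A/G,C/T per molecule),
fragment + linker, adapter read-through padding to the read length,
optional iid substitution errors, uniform qualities. Byte-identical output
under identical parameters is asserted in the tests.

Defaults were chosen once as the simulated study conditions: 35-nt reads,
RRRY/YYYR handles, the standard 18-nt linker `CACTCGGGCACCAAGGAC`, a 33-nt
sequencing-adapter read-through, substitution error rate 0, natural
drop-off $\gamma = 0.02$ per position, and $p_{\mathrm{mod}} = 0.5$ — a
single-adduct-bearing fraction of one half, high enough that the (+)
channel carries signal at realistic depths while honouring the single-hit
regime. The default ground-truth θ (`structured_theta()`) mimics real
spectra as a mixture of sparse high-reactivity sites (every 5th position,
15-fold over background) on a near-zero floor, with the unobservable
3′-terminal position fixed at zero.

The simulator does *not* emulate: PCR duplication or amplification bias,
ligation bias, quality-score realism, indel errors, or multi-adduct
molecules. Passing the recovery tests therefore shows the estimator inverts
the modelled RT-stop process correctly — not that real libraries are free
of the unmodelled effects.

## Numerical choices and problem sizes

* Normalization is asserted to $10^{-9}$ on every estimator call.
* Oracle-equivalence suites use $L \le 4$, counts $\le 100$ (25 seeded
  instances), the scale at which grid + refinement maximization is cheap
  and reliable.
* Parameter recovery runs at $L = 50$ with $10^5$ molecules per channel and
  $\gamma \sim U[0, 0.05]$, asserting per-position absolute error
  $\le 0.005$ and Pearson $r \ge 0.99$ against the (renormalized) truth;
  replicate reproducibility uses two independent seeds at the same size.
* The end-to-end identity test emits 50,000 read pairs at error rate 0 and
  requires the recovered count table to equal the simulator's internal
  tallies *exactly* over $k = 0..L-1$, with the $k = L$ molecules
  reconciled against the unaligned counter.
* The structure scorer uses exact maximum bipartite matching
  (augmenting paths) for slippage credit — each accepted pair creditable at
  most once — and is checked against an exhaustive matching oracle on
  random structures up to 30 nt. Slippage defaults on; both modes are
  first-class.
* Folding-constraint presets: slope/intercept $(1.1, -0.3)$ kcal/mol tuned
  for the ρ scale (the package default), and $(1.8, -0.6)$ kcal/mol for
  traditional SHAPE reactivity scales. The thermodynamic folding engine
  itself is out of scope — the package writes the constraint files and
  scores the output of whatever engine the user runs.

## Known limitations

* Single-target-per-read alignment with exact/Hamming matching: no indels,
  no splicing, no partial-target reads from degraded RNA.
* The estimator treats replicates independently; replicate comparison (not
  pooling) is the supported workflow (`compare_profiles()`,
  `compare_distributions()` — the latter excludes the $k = 0$ bin by
  default so correlations reflect reactivity-bearing positions).
* Degenerate handles other than R/Y mixtures are accepted but the two
  handles must be mutually exclusive for assignment to work; overlapping
  handle designs route reads to `unassigned`.
* External reactivity scales are mapped to θ by masked renormalization
  (`normalize_to_theta()`: clamp negatives, divide by the sum over
  positions with data) — no attempt is made to undo the original scale's
  outlier-trimmed normalization.
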