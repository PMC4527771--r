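---
title: "Isolation-with-migration inference with imcoal: model, sampler, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolation-with-migration inference with imcoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoal)
```

## The model

`imcoal` fits the two-population isolation-with-migration (IM) model to
multi-locus DNA sequence alignments. An ancestral population of scaled size
$\theta_A = 4 N_A u$ splits at scaled time $t$ (measured in expected
mutations) into two descendant populations of sizes $\theta_1 = 4 N_1 u$ and
$\theta_2 = 4 N_2 u$ that afterwards exchange migrants at scaled rates $m_1$
and $m_2$ ($m_p$ is the backward-in-time rate at which a lineage currently
in population $p$ moves to the other population). All six parameters are
scaled by the neutral mutation rate $u$, so time and branch lengths are in
expected-mutations units.

The latent variable for each locus is a *genealogy with migration events*:
a timed binary coalescent tree whose lineages carry population labels that
flip at migration events. Under the structured coalescent, going backward in
time from the present, while $k_1$ and $k_2$ lineages are in the two
populations (below $t$) each within-population pair coalesces at rate
$2/\theta_p$ and each lineage in population $p$ migrates at rate $m_p$;
above $t$ all surviving lineages form one pool with pair rate $2/\theta_A$.
The log-density of a genealogy is the usual interval scan
$\sum_{\text{events}} \log(\text{rate of realized event}) -
 \sum_{\text{intervals}} \Delta t \cdot (\text{total rate})$.
This density is log-linear in
$\{\log\theta_p^{-1}, \theta_p^{-1}, \log m_p, m_p\}$ given ten sufficient
statistics of the genealogy (event counts and rate exposures), which the
sampler caches per locus.

The joint posterior sampled is
$$
P(\theta, G_{1:L} \mid D) \propto P(\theta)\,
\prod_{\ell} P(G_\ell \mid \theta)\, P(D_\ell \mid G_\ell),
$$
with independent Uniform$(0,\mathrm{bound})$ priors (bounds default to 10
for every parameter, matching the standard configuration of this analysis).

## Sequence likelihoods

Two per-locus likelihood engines are provided; the model tag of each locus
selects one.

**HKY85 by Felsenstein pruning.** Conditional likelihood vectors are
propagated to the root in postorder; leaf children select a column of the
closed-form HKY transition matrix and internal children contribute a
matrix–vector product. The rate matrix is normalized to mean rate 1, so a
branch of genealogical length $\tau$ contributes $\tau u_\ell$ expected
substitutions per site, where $u_\ell$ is the locus's relative rate
multiplier (default 1). Per-site scaling guards against underflow at large
sample sizes. Base frequencies default to the empirical alignment
frequencies with a $+1$ pseudocount per base (the model requires
$\pi_i > 0$); $\kappa$ is by default sampled per locus as a nuisance
parameter with a Uniform$(0, 100)$ prior and a reflected sliding-window
move, or can be fixed. The total log-likelihood supports a chunked
("blocked") reduction whose result is invariant to the block size up to
floating-point reassociation; this invariance is asserted in the test suite.

**Infinite sites by mutation mapping.** Sites are polarized against the
locus's ancestral designation (an explicit ancestral sequence or a
designated alignment row; an `either`-polarity fallback accepts a site if
either orientation maps). Each biallelic site's derived carriers must equal
the leaf set subtended by exactly one branch; that site contributes one
mutation to that branch. A site whose carriers are non-monophyletic on the
current genealogy, carry three or more alleles, or span all leaves makes
the likelihood exactly zero, which the sampler sees as $-\infty$ and
rejects — the infinite-sites "break-off" behaviour falls out of ordinary
Metropolis–Hastings rejection. Otherwise the likelihood is the per-branch
Poisson product
$$
\log L = -\mathrm{BT}\,u_\ell + \sum_b \big[m_b \log(B_b u_\ell) -
\log m_b!\big],
$$
with $\mathrm{BT}$ the total branch length, $B_b$ a branch length, and
$m_b$ the number of mapped mutations on branch $b$. We use this
normalizable Poisson form deliberately: informal renderings of the
infinite-sites likelihood sometimes drop the factorial or flip the sign of
the exposure term, but those variants do not integrate to one. Note the
exposure is per locus, not per site: $u_\ell$ plays the role of the whole
locus's mutation intensity.

## The sampler

Each generation of one chain cycles:

1. one reflected sliding-window move per demographic parameter (window
   defaults to bound/5; reflection at 0 and at the bound keeps the proposal
   symmetric);
2. exact Gibbs draws of $m_1, m_2$ and, when their conditional is proper,
   of $\theta_1, \theta_2, \theta_A$ from the closed-form full conditionals
   implied by the cached sufficient statistics (truncated Gamma for the
   rates; truncated inverse-Gamma for the $\theta$s, skipped when fewer
   than two coalescences fall in that class), plus a shrinkage
   slice-sampling update of $t$ from its full conditional on
   $[0, \mathrm{bound}]$ (each slice evaluation is one
   sufficient-statistic sweep per locus, so the update is cheap and
   tuning-free);
3. two joint rescaling attempts (one local, one wide) that multiply $t$,
   every genealogy node time, and every migration time by a common
   log-uniform factor $\varepsilon = e^{U(-\delta, \delta)}$, accepted with
   the Jacobian correction $\varepsilon^{D}$ where $D$ is the number of
   scaled coordinates ($\delta = 0.3$ and $3\delta$ by default), plus one
   *split-shift* attempt that translates $t$ together with every event
   time above it by a uniform offset (a symmetric move once shifts whose
   reverse would capture additional coordinates are rejected) — the
   rescalings move the whole time scale, the shift moves the divergence
   time relative to the data-constrained below-split structure;
4. one move per sampled $\kappa$;
5. an occasional per-locus independence refresh (probability
   `refresh_prob`, default 0.15) that redraws the genealogy from the
   structured coalescent at the current parameters — the coalescent
   densities cancel against the proposal, leaving a pure likelihood-ratio
   acceptance (an exact conditional refresh whenever the likelihood is
   flat);
6. one genealogy move per locus, chosen uniformly among three families:
   node-time slides (the root height instead rescales by a log-uniform
   multiplier), subtree regrafts (attachment uniform by length over the
   time-compatible edges of the pruned tree; the pruned configuration is
   identical forward and reverse, so the Hastings ratio is 0), and
   migration birth/death moves;
7. for Metropolis-coupled runs, one swap attempt between a random adjacent
   temperature pair, with heating $\beta_k = 1/(1 + \lambda (k-1))$
   ($\lambda = 0.05$) applied by default to the full posterior
   (likelihood-only tempering is a switch).

Two design points deserve comment because they were forced by validation
failures of simpler designs:

* **Why a joint rescaling move.** The divergence time and the genealogy
  heights are rigidly coupled: lowering $t$ alone leaves inter-population
  coalescences stranded, and the conditional density of $t$ given the
  current genealogies is sharply peaked just below the oldest constraint.
  Chains without the rescaling move sat wherever they started. Scaling $t$
  and all event times together moves the whole history coherently and
  mixes the time scale well.

* **Why two kinds of migration moves.** A reversible
  insert/delete of a flip-and-return *pair* of migration events on one
  edge keeps lineage labels consistent everywhere, but it changes the
  migration count by $\pm 2$, so it preserves the count's parity — the
  chain could never cross between odd and even totals (a defect we
  caught because the sampled migration-count distribution retained only
  every other value). The second family inserts or deletes a *single*
  event on the below-split portion of an edge whose parent lies above
  $t$: there the edge-top label is unconstrained, a lone flip stays
  consistent, and the parity barrier disappears. With both families the
  sampled migration-count distribution matches direct simulation.

Genealogy updates run through a compiled (Rcpp) path that proposes,
evaluates the density via the sufficient-statistic sweep, evaluates the
locus likelihood, and applies the accept step in one call; the identical
moves are also implemented in plain R and serve as the reference
implementation. A periodic audit (`audit_every`, default 2500 generations)
recomputes every cached term through the R reference path and stops the run
on any disagreement beyond $10^{-8}$, so the two routes continuously
cross-check each other during every run, including the test suite's.

**Initialization.** Parameters start from a prior draw. Genealogies for HKY
loci start from a structured-coalescent simulation at those parameters. For
infinite-sites loci a prior-drawn genealogy is almost surely incompatible
with the data (likelihood zero), so the starting tree is built from the
data's perfect phylogeny: every derived carrier set becomes a clade, and
clades mixing the two populations are placed above $t$ so no migration
events are needed. This is an initialization heuristic only; it does not
enter the target distribution. A bounded number of prior draws is attempted
before giving up.

**Reproducibility.** Every source of randomness derives from the run seed;
each chain owns an independent stream derived from the seed and its index,
so adding chains does not desynchronize the cold chain's stream, and
identical seeds give bit-identical traces.

## The simulator

`simulate_genealogy()` draws from the same structured coalescent the
density describes (exponential waiting times, event class proportional to
rate, pooling at $t$); `simulate_sequences_hky()` draws root states from
$\pi$ and propagates them down the tree; `simulate_sequences_is()` draws a
Poisson$(\mathrm{BT}\,u_\ell)$ total mutation count, places each mutation
on a branch with probability proportional to its length, and gives each its
own site — so simulated IS data are compatible by construction and return
their true site-to-branch mapping for oracle tests.

`simulate_benchmark_suite()` reproduces the benchmark experimental design:
single-locus datasets of 150 + 40 sequences at lengths 1000, 6000, 11000
and 16000 for both mutation models, plus multi-locus combinations of 1, 2,
4 and 8 loci at length 1000. The truth point for all emitted datasets is
$(\theta_1, \theta_2, \theta_A, m_1, m_2, t) = (2, 2, 2, 0.5, 0.5, 1)$ —
moderate diversity, symmetric moderate migration, and a divergence old
enough to structure the sample, values we consider typical of two-population
divergence studies; the original benchmark's generating parameters beyond
the sample sizes and lengths are not recoverable, so these are this
package's own documented defaults, not a reproduction. HKY loci use
$u = 0.01$ (giving realistic per-site divergence around 1–2%), IS loci
$u = 1$ (giving on the order of ten segregating sites per locus).

## What the validation does and does not show

The test suite validates, among other things:

* pruning likelihoods against brute-force enumeration over all internal
  state assignments (trees to 4 leaves), transition matrices against
  matrix exponentials, and pattern-sum normalization;
* the IS likelihood against an independent per-branch Poisson oracle and
  the break-off rule on non-monophyletic sites;
* forward/reverse Hastings cancellation for every move family, and the
  genealogy-only sampler against direct simulation (TMRCA and
  migration-count distributions);
* prior recovery of the full sampler with the likelihood disabled;
* parameter recovery: 20 replicate datasets at the truth point above
  (5 infinite-sites loci, 10 + 10 sequences, 500 sites), each fitted with
  5,000 burn-in + 15,000 sampling generations, requiring the 90% central
  interval to cover the truth for each parameter in at least 14 of 20
  replicates.

Because all test data come from the package's own simulator, passing these
tests shows internal consistency of model, simulator and sampler — it does
not certify behaviour on real data, which violate the model through
recombination, selection, sequencing error, back-mutation (for IS loci) and
rate variation (for HKY loci), none of which are modeled.

Statistical checks on MCMC output use heavy thinning (chosen from measured
autocorrelation times: the slow modes are the divergence time and the
migration rates, with integrated autocorrelation times near $10^3$
generations on small datasets) so that Kolmogorov–Smirnov levels are
honest; with mild thinning the KS test rejects correct samplers.

## Numerical choices and degenerate inputs

* Conditional-likelihood vectors are rescaled per site when their maximum
  drops below $10^{-200}$; the log of the scale accumulates separately.
* Zero-length branches, $\kappa \to$ Jukes–Cantor, and stationarity at
  long branches are exact limits of the closed-form transition matrix.
* Exact event-time ties have probability zero under the model; the
  validator rejects them, and proposals cannot create them.
* $\theta_p = 0$ with a realized coalescence in that class, or $m_p = 0$
  with a realized migration, give density $-\infty$ (state rejected), not
  an error.
* The histogram mode in posterior summaries is the midpoint of the
  highest-count bin among `bins` equal-width bins over $[0,
  \mathrm{bound}]$; means and central 90% intervals come directly from the
  thinned draws.

## Known limitations

* Two populations only; no recombination within loci; no population growth
  or founding-proportion parameter (the size change at $t$ is the
  $\theta$ change alone).
* The infinite-sites engine requires a polarization source; the
  `either`-polarity fallback resolves ambiguous sites toward the smaller
  derived set, which slightly favours singleton interpretations.
* Migration-rate and divergence-time posteriors mix on a $10^3$-generation
  scale on small data; runs shorter than a few tens of thousands of
  generations under-explore them. The per-parameter acceptance rates and
  the trace plots from `plot()` are the first diagnostics to check.
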