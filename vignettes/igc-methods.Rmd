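---
title: "Quantifying interlocus gene conversion between paralogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interlocus gene conversion between paralogs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcodon)
```

## The problem

After a gene or whole-genome duplication, the two resulting paralogs do
not evolve independently. Interlocus gene conversion (IGC) — a mutation
that overwrites a stretch of one paralog with the corresponding sequence
of the other — homogenizes the copies, and natural selection can favor or
disfavor amino-acid homogenization on top of that. Ignoring IGC, as
conventional single-locus codon models must, biases branch lengths,
divergence times and selection estimates for any gene family with a
duplicated history.

`igcodon` fits a joint substitution model to *ordered pairs* of codons
occupying corresponding positions in two paralogs, on a rooted species
tree with an explicitly annotated duplication node. It estimates how much
of the post-duplication substitution history is attributable to IGC
rather than point mutation, and whether homogenizing nonsynonymous changes
are favored over nonhomogenizing ones.

## The point-mutation model

Within one locus, codon substitution follows a Muse–Gaut-style
F1×4 + κ + ω parameterization: a single-nucleotide change to nucleotide
$h$ has rate

$$ Q_{ij} = u\,\pi_h\,\kappa^{[\text{transition}]}\,
            \omega^{[\text{nonsynonymous}]} , $$

with stop codons excluded and multi-nucleotide point changes impossible.
The sense-codon stationary distribution is the product of position-wise
nucleotide frequencies restricted to sense codons and renormalized
(`codon_freqs()`). The constant $u$ (`normalize_u()`) makes the expected
number of point-mutation substitutions per codon per unit time equal 1 at
stationarity, so branch lengths are in expected point substitutions per
codon.

## The pair process and IGC

The joint state is the ordered codon pair $(i, i')$; for the standard
code that is $61^2 = 3721$ states. Only one locus can change at a time.
A change of the first locus from $i$ to $j$ with the partner at $i'$ has
rate

$$ Q_{(i,i'),(j,i')} = Q_{ij} + \nu\,[\,j = i'\,], $$

where the IGC increment $\nu$ applies only when the change copies the
partner's codon: $\nu = \tau$ for a synonymous copy and
$\nu = \omega\tau$ (or $\omega_H \tau$, below) for a nonsynonymous copy.
Because IGC replaces the whole codon, it can cross multi-nucleotide
differences in one event — the only transitions that reach the identical
pair diagonal from such states, which also makes the pair chain
non-reversible for $\tau > 0$; nothing in the package assumes pair-chain
reversibility. Both paralogs share one point process ($Q_{ij} = Q_{i'j'}$
when the triplets agree). Normalization is performed once, at $\tau = 0$,
and is *not* recomputed as $\tau$ varies: with that convention $\tau = 1$
means that, at a site where the paralogs differ, homogenization by IGC
runs at roughly the rate of point substitution.

## Homogenizing vs nonhomogenizing selection: ωH and ωN

The single ω is replaced by two factors: $\omega_H$ when a nonsynonymous
change makes the changed codon encode the *same* amino acid as its
partner (homogenizing), $\omega_N$ otherwise. All nonsynonymous IGC is
homogenizing by construction, so its rate is $\omega_H \tau$. The rate at
one locus now depends on the partner's amino acid, so normalization uses
the $61^2$-state chain at its $\tau = 0$ stationary distribution, with
the total pair flux halved because a pair state spans two codons. That
stationary distribution has the closed form

$$ \pi(i,i') \propto f(i)\,f(i')\,
   (\omega_H/\omega_N)^{[\,\mathrm{aa}(i) = \mathrm{aa}(i')\,]} , $$

which we verified analytically (detailed balance of the $\tau = 0$ chain)
and numerically against a null-space solve (`stationary_tau0(method =
"solve")`), on toy codes and on the full standard-code chain.

On branches where only one gene copy exists — before the duplication and
on the outgroup lineage — there is no partner, and $\omega_N$ is used as
the nonsynonymous factor, with those intervals normalized on their own to
one expected point substitution per codon per time unit.

Crossing the two choices (one ω vs ωH/ωN; τ free vs τ = 0) gives four
models: `omega-IGC`, `omega+IGC`, `omegaHN-IGC`, `omegaHN+IGC`.

## Likelihood on a duplication tree

`log_likelihood()` runs Felsenstein pruning in two regimes: pair-state
partial vectors (length $n^2$) below the duplication node, and
single-copy vectors above it. The duplication itself is deterministic —
state $i$ becomes the identical pair $(i,i)$ — so the pair partial vector
at the duplication node is mapped to a single-copy vector by reading the
diagonal entries (`map_duplication()`). The root sits at the outgroup
divergence with the single-copy stationary distribution; since the
single-copy segment is reversible and the non-reversible pair segment is
always evaluated tipward of the duplication, root placement within the
single-copy region does not affect the value. Sites are treated as
independent. Real IGC tracts span adjacent codons, so under low
recombination the product over sites is a *composite* likelihood; we
follow the convention of assuming recombination is high enough for the
distinction not to matter, and the limitation is inherited by the tests
below.

Columns are compressed to unique patterns; missing or ambiguous codons
become all-ones partial vectors; per-node rescaling guards against
underflow. Transition operators use dense matrix exponentials for small
state spaces and uniformization (Poisson-weighted powers of
$I + Q/\lambda$, truncated at tail mass $10^{-13}$) for the sparse
3721-state chain.

## Fitting and model comparison

`fit_igc()` maximizes the likelihood over κ, the ω factor(s), τ (natural
scale, lower bound exactly 0 so the boundary is attainable) and all
branch lengths (log scale), with L-BFGS-B and deterministic multistart
jitter. Nucleotide frequencies default to empirical F1×4 counts from the
alignment (all sequences pooled); they can also be fixed or ML-estimated
through a softmax transform — the original analyses' convention is not
recorded, so both are provided and neither is claimed canonical. ωH is
capped at $10^3$ with a boundary flag: effectively infinite homogenizing
rates do occur in real data (identical amino acids within species,
different between), and a flagged cap is the only finite representation.

`lrt_igc()` computes $\Lambda = 2(\ell_1 - \ell_0)$ and selects the null
reference automatically: releasing ωH = ωN alone gives $\chi^2_1$;
releasing τ = 0 alone gives the equiprobable mixture of a point mass at 0
and $\chi^2_1$, because τ = 0 is on the boundary; releasing both gives
the equiprobable $\chi^2_1$/$\chi^2_2$ mixture, whose 0.05 critical value
is 5.14. Small negative statistics (optimizer noise, clamping threshold
$10^{-6}$) are set to 0 and flagged. The two decomposition paths from the
simplest to the richest model telescope to the same total, which the
tests assert on every fixture.

Two data screens mirror common practice for paralog data sets:
`branch_length_screen()` fails a fit whose estimated branch length
exceeds 1.5 codon substitutions per codon, and `paralog_swap_check()`
refits the simplest model with one taxon's paralog labels exchanged,
flagging the data set when the swapped orthology fits better (ties favor
the given labels).

## Expected labeled counts and the IGC proportion

Every off-diagonal pair rate is stored as an additive point + IGC split,
further classed into five labels (IGC synonymous, IGC nonsynonymous,
point synonymous, point nonsynonymous homogenizing/nonhomogenizing).
Expected counts of label-$L$ transitions over a branch of length $t$ use
the matrix-of-exponentials identity: $\int_0^t e^{Qs} L e^{Q(t-s)}\,ds$
is the upper-right block of $\exp\!\big(\begin{smallmatrix} Q & L \\ 0 &
Q\end{smallmatrix}\big)t$ (`joint_integral()`); in the large-state case
the block operator is applied to partial-vector matrices by
uniformization rather than materialized.

`expected_counts()` combines that kernel with inside (tipward) and
outside (rootward) partial vectors to give posterior expected counts per
branch conditional on the alignment; an unconditional mode is exposed for
diagnostics. Mixed transitions (rate $Q_{ij} + \nu$ into the diagonal)
are attributed by the stored additive split — never proportionally
re-weighted — because the generator literally is that sum. Only
*countable* branches enter the reported proportion: branches subsequent
to the first post-duplication speciation. Immediately after duplication
the paralogs are identical, so IGC on the initial segment leaves no
signature and estimates there are unstable; the default excludes that
segment, with an override for diagnostics only. Whether the original
proportion estimates conditioned on the data is not printed; conditional
(posterior) expectations are the default here and the switch is
documented.

An identical-paralog start also implies a hard pathwise bound: every IGC
substitution requires a prior point substitution to have created a
difference to copy, so IGC can account for at most 50% of realized
substitutions over the post-duplication history — a useful end-to-end
check on both the simulator and the counting machinery.

## The simulator

`simulate_igc()` is an exact Gillespie simulation of the same generator:
root codon from the single-copy stationary distribution, single-copy
evolution to the duplication, deterministic copy to $(i,i)$, then the
labeled pair process on each branch. Sites are independent — matching
the inference model's per-codon IGC assumption; IGC *tracts* are
deliberately not simulated, so simulation-based tests validate the
machinery under the model's own assumptions and say nothing about
tract-induced dependence in real data. Every event is logged (branch,
site, time, states, origin, synonymy, homogenization); when a state
change is admissible as either a point mutation or an IGC copy, the
origin label is sampled proportionally to the two rate components, making
realized labeled counts estimators of the same quantities as the
expectation machinery. Each site gets its own seed derived from the
master seed, so output is bit-reproducible and independent of iteration
order. Replaying the log from the logged root states must reproduce the
tip alignment exactly, and the tests assert it does.

Bundled scenarios (`make_fixture()`): `teleost-like` — an outgroup plus a
duplication and a four-taxon post-duplication clade with teleost-like
truth (κ = 3, ωN = 0.1, ωH = 0.5, τ = 0.2, slightly AT-rich
frequencies); `two-tip-minimal` — a 4-"codon" toy alphabet small enough
for exhaustive enumeration oracles; `yeast-like-high-tau` — the high-IGC,
high-ωH regime reported for duplicated ribosomal protein genes (τ = 2.3,
ωH = 5.7, ωN = 0.08).

## Toy codes, oracles, and what the tests show

Reduced genetic codes (`toy_code()`) make the full pair space small
enough to check everything against independent oracles: pruning against
exhaustive summation over all ancestral states (relative error
$10^{-10}$), total probability 1 over all possible columns, the
block-matrix integral against Gauss–Legendre quadrature ($10^{-6}$), the
τ = 0 operator against the Kronecker product of single-locus operators
($10^{-8}$), and the closed-form stationary distribution against a
null-space solve. The standard-code machinery is checked where it is
cheap and exact: normalization flux (within $10^{-8}$ of 1 for both
modes), the generator's Kronecker-sum identity, and the ωH = ωN collapse,
entrywise.

Two simulation studies are scaled down from the full-codon setting so
that they run routinely; the scientist-facing claims are unchanged but
the problem sizes are the package's own choices:

* **Parameter recovery** uses a 9-codon toy alphabet over {A, C, G}
  (chosen so transitions exist and κ is identifiable, with several
  amino-acid classes so homogenization is meaningful), the four-taxon
  post-duplication topology with countable branch lengths 0.3, 2000
  codons and 20 replicates at truth κ = 3, ωN = 0.1, ωH = 0.5, τ = 0.2.
  The pooled median absolute relative error of (ωN, ωH, τ) must be at
  most 15%. Pilot medians were about 3%, 4% and 13%: τ is the weakly
  identified parameter, as expected — its information comes only from
  homogenization given standing differences on countable branches.

* **Type-I calibration** of the τ = 0 boundary test uses the minimal
  4-codon code with two paired tips, 200 null replicates at level 0.05,
  asserting the empirical rate inside a 99% binomial band. A caveat worth
  recording: on this minimal code at 2000 codons the boundary-mixture
  reference is visibly anticonservative (empirical rejection ≈ 0.13)
  even though simulator and likelihood agree exactly on the full joint
  column distribution — the score for τ is strongly skewed and its
  normal regime needs more data. At 6000 codons the half-and-half mixture
  is accurate (pilot rejection 5%, half the statistic mass at zero), so
  the study uses 6000 codons. Users applying the boundary test to short
  alignments with few post-duplication taxa should expect the same
  anticonservatism.

## Numerical choices and degenerate inputs

Row sums of all generators are zero to $10^{-10}$; label matrices sum to
the off-diagonal generator exactly. Zero-length branches yield identity
operators; an all-zero-diagonal pair partial at the duplication
correctly yields likelihood 0 (data impossible); a tree with all lengths
0 returns the stationary log-frequency of the observed codon. A zero
total expected count makes the IGC proportion undefined and it is
reported as `NA` with a warning, never silently 0. Optimizer defaults:
3 multistart points (1 in the simulation studies, which start near
plausible values), relative function tolerance `factr = 1e7`, τ and
branch lengths bounded below, all seeds recorded in the fit object.

## Known limitations

Per-codon IGC only (no tract lengths); two paralogs per genome; no
paralog deletion; F1×4 frequencies only (no F3×4, no among-site rate
variation); composite-likelihood uncertainty (standard errors for τ and
ω̂H under low recombination) is out of scope. Full-codon ML fits are
supported but computation-heavy in pure R at 3721 states; the simulation
studies in the test suite therefore run at toy-code scale, and full-scale
fits are practical mainly for single data sets rather than replicate
studies.
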