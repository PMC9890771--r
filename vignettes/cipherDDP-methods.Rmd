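---
title: "Solving the double digest problem over ciphertexts: model, scheme and solver"
author: "cipherDDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving the double digest problem over ciphertexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipherDDP)
```

## The problem

A double digest experiment cuts one DNA molecule three ways — with
restriction enzyme α, with enzyme β, and with both at once — and reads
the fragment lengths of each digest off a gel. That yields three
multisets of positive integers, `A` (p fragments), `B` (q fragments) and
`C` (t fragments), with `sum(A) = sum(B) = sum(C)` equal to the molecule
length. The double digest problem (DDP) asks for orderings of the
fragments of `A` and of `B` — two permutations, the *mapping sequences*
μ and ν — whose combined cut sites reproduce `C`. It is strongly
NP-complete, and the fragment lengths themselves are commercially
sensitive: they take months of bench work to measure and identify the
molecule uniquely.

This package solves the DDP *without showing the fragment lengths to the
machine doing the work*. The data owner encodes each length with an
order-preserving homomorphic index (OPHI); a compute server runs a
quantum-inspired genetic algorithm (QIGA) entirely on the encoded
values and returns only μ and ν, which carry no length information; the
owner verifies the answer against the plaintext instance. There is no
decryption anywhere — the scheme does not define one.

## Plaintext model

Order the fragments of `A` by μ and take running prefix sums
(*accumulative summation*): these are the α cut-site coordinates. Do the
same for `B` with ν. Merge the two site lists, sort, prepend 0, and take
consecutive differences (*step differences*): the gaps between adjacent
sites are the fragment lengths a simultaneous digest would produce.
Both site lists end at the molecule length, so the merged list always
contains a duplicated terminal site, and any interior site shared by
both enzymes is duplicated too. Those duplications contribute
zero-length artifacts; since the merged list has `p + q` sites while `C`
has `t` values, exactly `p + q - t ≥ 1` artifacts exist, and the model
drops the `p + q - t` smallest step differences. This rule is
deterministic, needs no magnitude threshold, and — crucially — transfers
to the ciphertext domain, where "smallest" is decided by order alone.

The quality of a candidate `(μ, ν)` is the L1 distance between the
ascending implied spectrum and `C`:

    D(μ, ν) = Σ_i | sort(C_implied)[i] − C[i] |,   f(μ, ν) = 1 / (1 + D).

`f = 1` certifies an exact reconstruction. The distance interpretation
of the fitness follows the optimisation objective `min Σ |C' − C|`; a
count-of-mismatches reading would coarsen the search signal without
changing the optimum. The package implements the error-free acceptance
rule (`D = 0`); for noisy gels it reports `D` but fits no error model.

DDP solutions are never unique: reversing the whole arrangement always
solves, duplicate lengths are interchangeable, and internal blocks
bounded by coincident partial sums can be exchanged (the classical
cassette equivalences). `bruteForceSolve()` therefore returns *all*
maximisers (for small p, q) and the verification accepts any exact
mapping, not one designated truth.

## The OPHI scheme

A plaintext `m` becomes an n-vector (n = 3 by default)

    c[i] = k[i] * m + r[i]   (i ≤ n−1),      c[n] = k[n] * R,

with secret positive keys `k[i] ≤ 2^10` drawn from a truncated
Normal(512, 170²), fresh positive noise `r`, and `R = Σ r[i]`. Adding
two ciphertexts componentwise encrypts the sum of the plaintexts with
the noises added — the additive homomorphism the cut-site sums need.
Comparing the first `n−1` components (all strictly greater / all
strictly smaller) decides the plaintext order of *distinct* plaintexts
exactly, provided the noise is budgeted; the n-th component is a noise
checksum and is never compared.

Equal plaintexts deserve a caveat: their comparison is decided by the
fresh noises, which about half the time dominate coordinatewise, so two
encryptions of the same value may compare strictly. No sorter can
recover input order for them — and none needs to: swapping equal
fragment lengths never changes a multiset, so every downstream quantity
is unaffected. The compiled pipeline sorts ciphertext lists by the first
sub-ciphertext, which agrees with the full comparison rule on every
distinct-plaintext pair and is a proper strict weak ordering.

### Noise budget

Let `p_min` be the minimum distance between distinct plaintexts (1 for
integer lengths) and `min_k = min(k[1..n])`. Fresh noise is rejected
until `0 < R < R_bound` with

    R_bound = min_k * p_min / (2 * L_max).

`encryptInstance()` sets `L_max = 4 t (p + q)`. Writing `M = max(p, q)`,
every cut site is a sum of at most `M` fresh ciphertexts (noise in
`(0, M·R_bound)` per coordinate), every step difference a difference of
two such sites (noise magnitude `< 2M·R_bound`), and every residual a
sum over `t` spectrum positions and `n−1` coordinates of step-difference
minus `C`-ciphertext terms (noise magnitude `< (2M+1)·R_bound` each).
Three guarantees follow by strict inequalities:

1. *Sorting is exact.* Distinct site (or step-difference) plaintexts
   differ by at least 1, while comparison noise stays below
   `4M·R_bound ≤ min_k / (2t) < min_k ≤ k[i]`.
2. *Solutions are recognisable without the key.* The public threshold

       T = (n−1) · t · (2·max(p,q) + 1) · R_bound

   bounds the accumulated residual noise of *any* mapping, so a mapping
   with `D = 0` has residual `≤ T`, and one with `D ≥ 1` has residual
   `≥ K − T > T`, where `K = Σ_{i≤n−1} k[i]`. `T` is shipped in the
   public parameters; it reveals a noise-scale bound, nothing else.
3. *Equal distances cluster.* Two mappings with the same `D` have
   residuals within `2T` of each other, while distinct `D` separate by
   more than `2T` (this needs `K > 4T`, which the `L_max` above
   guarantees for every `p, q ≥ 1`, `t ≥ 3`). The solver can therefore
   compare candidates over ciphertexts with a `2T` tie band and make
   *exactly* the decisions a plaintext solver would make.

Guarantee 3 is the package's headline correctness property: on any
budget-respecting instance, the encrypted-domain fitness ordering of all
`p!·q!` mappings equals the plaintext ordering (checked exhaustively in
the test suite for p, q ≤ 5), and the ciphertext and plaintext solver
arms follow identical trajectories seed for seed.

All arithmetic is double precision; with keys below 2^10 and molecule
lengths below 10^7 every quantity stays far below 2^53 and the rounding
error (≤ 10^-8 absolute) is orders of magnitude below both `R_bound`
and all comparison margins, so the inequalities above are exact in
floating point too. Files serialise numbers at full precision.

## The QIGA solver

Candidate mappings are held in superposition: each of the `p + q` map
positions carries `b = ceil(log2(max(p, q))) + 3` qubits, each qubit an
amplitude pair `(α, β) = (cos θ, sin θ)`. Measurement collapses qubit j
to 1 with probability `β_j²`; the b-bit string of a position, read as a
reflected-Gray-coded integer, is that position's *random key*, and the
permutation is the rank order of the keys (ties by position index — any
bit pattern yields a valid mapping pair). Gray decoding is a deliberate
choice: consecutive key values differ in one bit, so a single quantum
NOT can move a fragment by exactly one rank, giving the search a fine
relocation move that plain binary coding lacks.

Per generation, with population `N`:

1. measure every chromosome and evaluate its mapping (ciphertext
   residual, compared with the `2T` tie band; plaintext `D` in the
   comparison arm);
2. stop if a measurement is exact (residual ≤ `T`);
3. *select*: the chromosome that produced the best measurement of the
   current epoch survives (elitism), the other `N − 1` slots are filled
   by binary tournament;
4. *rotate* every non-elite qubit by `Δθ` toward the bit value the
   epoch-best measurement took, clamped so `β²` stays in
   `[0.001, 0.999]` (the saturation guard keeps a residual flip alive);
5. *crossover*: random pairing, with probability `pc` a single-point
   suffix exchange of amplitude pairs;
6. *mutate*: with probability `pm` per chromosome, one uniformly chosen
   qubit undergoes a quantum NOT (amplitude swap).

Rotation toward a single attractor converges the population within tens
of generations, after which progress relies on mutation and the clamp's
residual flips — a stochastic local search around the attractor. To
escape its basin the solver uses a *stagnation catastrophe*: after
`restartAfter` generations without improvement the whole population
collapses back to the uniform superposition and the epoch attractor is
forgotten. The all-time best record survives outside the population, is
monotone by construction, and is what the solver returns; termination is
fitness 1 or `g_max` generations, and the final authority on success is
always the owner's plaintext verification.

Defaults: `N = 50`, `g_max = 10000`, `pc = 0.85`, `pm = 0.5` (midpoint
of the conventional 0.45–0.55 band), `Δθ = 0.025π` rad,
`restartAfter = 100`. All randomness flows through R's RNG, so a seeded
run is fully reproducible, and the compiled loop consumes draws
identically in both fitness domains — which is what makes the paired
arms' trajectories coincide.

## What the generator emulates — and what it does not

`generateInstance(t, length)` plants `t − 1` distinct integer cut sites
uniformly on a molecule of the given length, attributes each site to one
enzyme (or to both, behind a flag), and reads the three gap multisets
off the site sets. Every instance is valid by construction and the
generating order is retained as a known exact solution. The generator
does not emulate measurement error, partial digestion, or missing small
fragments — fragment lengths are exact integers, which is also what the
error-free acceptance rule assumes.

The default molecule length is `100·t` (mean fragment length 100).
This choice controls the single strongest driver of problem difficulty:
*duplicate fragment lengths*. DDP solution counts grow with length
collisions; at mean length 3 the test suite solves `|C| = 40` instances
in a few hundred generations, while at the default scale lengths are
mostly distinct, exact solutions are a vanishing fraction of the
`p!·q!` search space, and no fixed-budget stochastic search — the QIGA
included, but equally a dedicated permutation-space hill climber —
reliably reaches `D = 0` beyond `|C| ≈ 15`. The package's success-rate
experiments (`successRateExperiment()`, and the acceptance script)
therefore show rates near 1 for `|C| = 10` and near 0 from `|C| = 20`
at the default scale: a property of the instance distribution at that
length scale, not of the privacy layer, as the paired-arm experiment
(`compareWithPlaintext()`) demonstrates by producing identical
encrypted and plaintext decisions run for run. Passing tests on
generator instances accordingly validate the protocol's correctness and
the privacy layer's zero cost — they do not certify that any
fixed-budget solver conquers long, duplicate-free spectra.

Experiment sizes in the test suite (|C| up to 40, 25 runs per group)
were chosen as desk-scale versions of the protocol's natural operating
range; the same runners accept larger sizes and run counts.

## Security evaluation

`exhaustiveSearchBounds()` turns the one-wayness argument into
arithmetic: the ciphertext of one fragment hides it among `k·|M|`
possibilities (`2^17` at the scheme's `k = 2^10` and the minimal
plaintext space `|M| = 2^7` consistent with that figure), and a whole
instance of `m + n + k ≥ 7` fragments is protected by the bound raised
to that power (`≤ 2^-110`). `|M|` is exposed as a parameter rather than
hard-coded because only its lower bound is determined.

`lazyServerProbability()` gives `1/(p!·q!)`, the chance a server that
returns a random mapping pair hits one *designated* solution. Because
DDP solutions come in classes (reversal at minimum), the owner's
acceptance rate of random mappings is a small multiple of this figure —
the toy 5-unit instance accepts at exactly `2/(2!·2!) = 1/2` — and the
verification-and-retry loop defeats the lazy server either way.

`ciphertextSample()` and `qqStatistic()` reproduce the distribution
indistinguishability experiment: 50 000 first-coordinate ciphertexts of
a fixed plaintext under keys and noise drawn from a named family,
compared against that family's quantiles after standardisation. The
acceptance constants (Pearson correlation of the QQ pairs ≥ 0.999 and
maximum deviation from y = x over the central 99% of quantile levels
≤ 0.12) were calibrated by simulation at n = 50 000: the normal family
(a sum of two range-truncated normals) lands at correlation ≥ 0.9997
and deviation ≤ 0.08, the uniform family (a trapezoid) at correlation
≈ 0.998 and deviation ≈ 0.3, so the criterion separates the families
with margin on both sides. The extreme half-percents are excluded
because extreme order statistics fluctuate by several tenths of a
standard deviation even for samples truly drawn from the reference.

## Numerical and design choices, in brief

* Zero-artifact removal: drop the `p + q − t` smallest step
  differences; order-based, threshold-free, ciphertext-compatible.
* Merged-site ties: plaintext sorting is stable with α-derived sites
  first; ciphertext sorting orders coincident sites by noise. Both
  choices are outcome-neutral (the dropped-artifact rule absorbs them).
* Mapping indices are 1-based in files and user-facing objects,
  0-based inside the compiled core.
* `p_min` is fixed at 1: gel read-outs are integer lengths, and all
  partial-sum comparisons the solver performs are between integers.
* Forced-noise encryption (`ophiEncrypt(key, m, r = ...)`) exists so
  tests can pin exact ciphertexts; it bypasses the budget rejection and
  is not part of the protocol.
* The solver accepts only the `EncryptedInstance` payload — the server
  role cannot read keys or plaintexts by construction, and the test
  suite runs it from a directory containing nothing else.

## Limitations

* The error-free model: measurement noise in fragment lengths is
  reported as a nonzero `D` but not modelled probabilistically.
* Solution classes are reported as raw mapping pairs; cassette
  equivalence classes are not enumerated.
* The scheme's known weakness under duplicate plaintexts is documented
  (equal values sort by noise) and is harmless for multiset targets,
  but the package makes no IND-style claims — only the one-wayness
  arithmetic above.
* Success rates on long spectra depend overwhelmingly on the
  instance distribution's duplicate richness; see the generator section.
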