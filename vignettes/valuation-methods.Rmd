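---
title: "Methods: the LifePound valuation model and marketplace simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LifePound valuation model and marketplace simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifepound)
```

This vignette documents the model implemented by `lifepound`, the meaning
and defaults of every parameter, the numerical choices, and the design
decisions made where the underlying method leaves room for interpretation.

## 1. The record model

A biomedical record is a triplet *(type, time, quality)*:

- **type** — a categorical key into a registry of record types
  (`record_type_spec()`), each with a positive base value and a half-life;
- **time** — the owner's age in years when the record was sampled;
- **quality** — a nonnegative score; 0 marks unusable data.

A dataset (`lp_dataset()`) is a table of such records with unique
`record_id`s and an `owner_id` per record. Users (`lp_users()`) may carry a
positive `base_value_modifier` (default 1) scaling all their base values.

## 2. Time value

Data loses value as it ages. Each type has a kernel `w` and a half-life
`T`; the default kernel is `w(u) = 2^(-|u|)`, so a record exactly one
half-life old retains one half of its value. Alternatives: `exp2_onesided`
(no value before the sampling age, useful for forecast-only uses) and
`rect` (full value within one half-life, zero outside). An infinite
half-life (the genome) makes the time value constantly 1 — static data.

For a single record valued at age `t_v` the time value is
`w((t_v - time)/T)`. For a combination of `k >= 2` records it is the best
jointly achievable overlap

```
TV = max over t in [min time, t_v] of min over m of w_m((t - time_m)/T_m),
```

i.e. the analysis time `t` is chosen where the *stalest* member of the
combination is least stale. Two records with `T = 1` sampled two years
apart overlap best at the midpoint, each one year old there:

```{r}
cfg <- valuation_config(types = list(
  t1 = record_type_spec("t1", base_value = 1, half_life = 1)))
time_value(data.frame(type = c("t1", "t1"), time = c(10, 12)), cfg, 15)
```

**Optimizer.** When every finite-half-life member uses the default
exponential kernel, the inner minimum is piecewise log-linear and the
maximum lies at a kernel peak or at a pairwise crossing
`(a_i T_j + a_j T_i)/(T_i + T_j)`; the implementation evaluates this closed
candidate set, so the result is exact to double precision. For other
kernels it falls back to a 4096-point grid plus golden-section refinement
with tolerance `1e-8`. The test suite compares both paths against an
independent grid-search oracle.

Valuing records sampled *after* the valuation time is an error, not a
quiet extrapolation.

## 3. Quality aggregation and combinations

A combination of `k >= 2` records from one user has value only if its type
multiset appears in the config's synergy table (`Ψ_k`). Its quality
aggregate is the reciprocal sum `v_k = (Σ 1/q_m)^{-1}` — monotone in each
argument, dominated by the worst member, and zero as soon as any member's
quality is zero. Two perfect-quality records give `v_2 = 1/2`:

```{r}
quality_aggregate(c(1, 1), default_valuation_config())
```

The per-user cost sums `f_1` over all records and `f_k` over all subsets
up to `max_combination_order` (default 4). Because undeclared multisets
contribute nothing, the implementation enumerates only singles plus
subsets matching a synergy entry; a brute-force enumeration over all
`2^n − 1` subsets serves as the test oracle. Users with more than
`record_cap` records (default 20) raise an error rather than silently
truncating — callers with genuinely larger portfolios must raise the cap
explicitly (the marketplace uses 100).

## 4. Group value

For each record type held (with positive best quality) by `K >= 2`
distinct users, the dataset gains `γ(K) · mean(best qualities)` with
`γ(K) = C·K·ln K` by default, or `C·K^{3/2}`. Both are superlinear:
doubling the cohort more than doubles the group term, reflecting the
statistical value of pooled cohorts. Design decisions:

- a type held by a single user generates **no** group term (`K ln K` is 0
  at `K = 1` anyway; the `K^{3/2}` form is gated to `K >= 2` for
  consistency);
- zero-quality records are excluded before computing `K` and the best
  qualities, which preserves the global invariant that adding a
  zero-quality record never changes any cost;
- the group term is attributed to users in proportion to their best
  quality for the type, and within each user to the record achieving that
  best quality.

## 5. Family relationships

Close relatives' data is partially redundant, so a user's cost is scaled
by `1 + λ`, where `λ` sums the coefficient of relationship `r` between the
user and every other enrolled cohort member (`cohort_lambda()`). `λ` is
deliberately uncapped: a fully enrolled large family legitimately inflates
it past 1.

`r` is computed by path enumeration on the pedigree
(`relationship_coefficient()`): `r = Σ 2^{-L}` over all paths climbing
from one individual to a single common ancestor and descending to the
other without repeated individuals. Monozygotic (MZ) twins are merged into
one genetic node first, so a twin pair has `r = 1` — an enrolled identical
twin exactly doubles a user's cost — and paths may run through either twin.

The default `"simplified"` method sets all inbreeding coefficients to
zero, the right choice for random-bred human cohorts. The `"wright"`
method implements the classical inbreeding-adjusted coefficient
`r = Σ 2^{-L}(1 + f_A)/sqrt((1 + f_B)(1 + f_C))`, with each `f` obtained
from the pedigree by the kinship recursion; the two methods agree exactly
on any pedigree without consanguinity.

Pedigrees are exchanged in the 6-column PLINK PED format with `"0"` for
unknown parents; MZ pairs, which PED cannot express, live in a two-id-per-
line sidecar file.

## 6. Marginal pricing and payment attribution

`marginal_cost(D, owned, ...) = Cost(D ∪ owned) − Cost(owned)` is the
price a customer pays given their history; it is nonnegative because
dataset cost is monotone under adding records, and path-independent: any
split of a dataset into sequential purchases sums to the full cost (tested
over random splits to `1e-9`).

`attribute_payments()` takes the data-validator share off the top
(`dv_share`, a marketplace-wide parameter, default 0.1) and splits the
remainder among submitters in proportion to their newly paid per-user
terms. The floating-point residual is folded into the largest share until
the payout vector re-sums to the payment bit-exactly.

## 7. The ledger

Blocks are hash-linked via SHA-256 over a canonical serialization
(key-sorted maps, length-prefixed strings, `%.17g` numbers — injective and
platform-independent). Each block commits to a Merkle root over its
transaction ids and to a Merkle root over the sorted balance map. The odd
node at any tree level is promoted unchanged; this dialect is fixed and
re-implemented independently in the test oracle.

Two proof types are supported against a trusted root alone:

- **inclusion** — standard audit path for a transaction leaf;
- **absence** — each state leaf commits to `(index, n, key, value)`, so
  exhibiting the two adjacent leaves bracketing a key (or one boundary
  leaf) proves no leaf with that key exists.

`verify_chain()` replays every block's balance `deltas` from the genesis
allocation and re-derives all digests, reporting the first bad height and
a reason. Chain digests never include wall-clock time, so runs are
reproducible; an append-only JSON-Lines anchor log (`anchor_digest()`,
`check_anchors()`) detects retroactive rewrites and rollbacks. Chains
round-trip through JSON Lines with 17 significant digits — `%.17g` is the
smallest precision that restores every double bit-exactly, and a sloppier
export would break digest verification on re-import.

## 8. Threshold secret sharing

Record keys are split with Shamir's scheme over the prime field
`p = 94906249`, chosen because `p^2 < 2^53`: all field products stay exact
in double arithmetic, so no big-integer dependency is needed. The
marketplace requires `K > round(N/3)` (Byzantine fault-tolerance bound);
the default is the minimal admissible `K = round(N/3) + 1`. Shares embed a
random split id so shares of different splits cannot be mixed silently,
and reconstruction refuses fewer than `K` shares. The payload "cipher" is
a keyed XOR stand-in: the simulator's claims concern protocol logic, not
cipher strength.

## 9. Marketplace workflows

- **Upload**: the record key is split among the `N` keepers, the payload
  encrypted into mock storage, and an upload transaction appended carrying
  digests and ids only — a record's sampling age and quality never reach
  the chain. Minting on upload is off by default; with it off, the genesis
  allocation is the only source of tokens and total supply is conserved
  across arbitrary runs.
- **Validation**: a data validator (DV) escrows the batch's full model
  price. Keepers deliver shares; below `K` available keepers decryption is
  blocked and the contract can only time out. On settlement each valid
  record's portion (its share of the batch valuation) is paid to its
  submitter and the record is listed; invalid portions are refunded.
  `disbursed + refunded = locked` exactly. A timeout deems the whole batch
  valid. No DV cut is taken at validation — the DV's revenue is the
  `dv_share` of later purchases of records they validated.
- **Purchase**: price is the marginal cost against the customer's history
  (re-buying is free), the DV share is routed to the validators of the
  batch in proportion to the value each validated, and the rest goes to
  submitters. Underfunded validators and customers cause a logged
  rejection and no state change.

Every operation is one block; `run_scenario()` drives all three workflows
from a single seed and returns the event log, final balances and the full
chain, which replays bit-identically.

## 10. Synthetic data generator

`gen_pedigree()` builds families of configurable depth and sibship with
optional MZ twins; `gen_records()` samples static types once per user and
dynamic types as Poisson processes at configurable rates over each user's
age span, with uniform qualities and an optional zero-quality spike;
`gen_scenario()` bundles pedigree, users, records, config and scenario
description, optionally writing everything to disk in the package's file
formats. All generators are deterministic under their seed; none attempt
realistic clinical values — payloads stay opaque.

The default type registry spans the interesting regimes: genome (base 10,
static), cholesterol panel (1, 5-year half-life), blood test (1, 0.5 yr),
transcriptome (3, 1 yr), MRI (5, 2 yr), with a small synergy table among
them.

## 11. Problem sizes and performance

The package targets desk scale: hundreds of users, thousands of records,
hundreds of blocks. The full test suite — including a 1000-dataset
zero-quality sweep, 200 purchase-split trials, exhaustive Shamir subsets
for `N <= 8`, 1000 fuzzed proofs and a 50-user end-to-end scenario — runs
in a few minutes on one CPU. The combinatorial guard (`record_cap`) keeps
per-user subset enumeration bounded; Merkle proofs stay logarithmic in the
leaf count (verified up to `2^16` leaves).
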