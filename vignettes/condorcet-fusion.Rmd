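---
title: "Electing a similarity coefficient: Borda/Condorcet fusion for virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electing a similarity coefficient: Borda/Condorcet fusion for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condorcetfusion)
```

## The problem

Ligand-based virtual screening ranks a compound database by structural
similarity to a known-active reference molecule, hoping that actives
concentrate at the top of the list. No single similarity coefficient is best
for every activity class: the continuous Tanimoto coefficient is the de facto
standard, but classes exist where Cosine, Canberra or Bray/Curtis retrieve
actives better. Similarity fusion addresses this by running the same search
under many coefficients and combining the outputs.

This package implements a social-choice approach to similarity fusion over
count fingerprints (ECFC-style, folded to a fixed length, typically 1024).
Eleven coefficients each search the database from a single reference
structure; the top-n retrieved structures act as a voter committee; each
voter awards points to the coefficients (m points to the best of m, 1 to the
worst); and an activity class elects its "winner" coefficient by Borda count
with Condorcet pairwise comparison. The search is then re-run with the
winner alone, and standard screening metrics evaluate the result.

## The eleven coefficients

For count vectors $a, b$ of length $M$, write $A=\sum a_j^2$,
$B=\sum b_j^2$, $C=\sum a_j b_j$. The seven association coefficients
(higher = more similar) are

| id | form |
|----|------|
| `tanimoto` | $C/(A+B-C)$ |
| `cosine` | $C/\sqrt{AB}$ |
| `sokal_sneath1` | $C/(2A+2B-3C)$ |
| `kulczynski2` | $C(A+B)/(2AB)$ |
| `forbes` | $MC/(AB)$ |
| `fossum` | $M(C-\tfrac12)^2/(AB)$ |
| `simpson` | $C/\min(A,B)$ |

and the four distance coefficients (lower = more similar) are

| id | form |
|----|------|
| `mean_euclidean` | $\sqrt{\sum (a_j-b_j)^2 / M}$ |
| `mean_canberra` | $\frac1M \sum |a_j-b_j|/(a_j+b_j)$ |
| `divergence` | $\frac1M \sum (a_j-b_j)^2/(a_j+b_j)^2$ |
| `bray_curtis` | $\sum|a_j-b_j| / \sum(a_j+b_j)$ |

Numerical conventions: features absent from both molecules contribute 0 to
the Canberra and Divergence sums (the 0/0 convention that keeps all values
finite); zero fingerprints are a domain error; the continuous Forbes/Fossum
normalization constant varies across the literature — here it is the single
factor $M$, which, being a positive per-search constant, never affects a
ranking.

Two structural facts shape everything downstream:

* **Sokal/Sneath(1) is a strictly monotone transform of Tanimoto**:
  $SS_1 = T/(2-T)$. The two coefficients therefore induce *identical*
  database rankings, always. Neither can strictly beat the other in a
  pairwise contest, so a profile containing both never has a Condorcet
  winner, their Borda totals tie exactly, and the tie resolves by the
  canonical listing order (Tanimoto first).
* **Several "association" forms are not self-maximal on counts.** For
  example $kulczynski2(p, 3p) = 5/3 > 1 = kulczynski2(p,p)$ and
  $simpson(p, 3p) = 3$. Self-similarity is therefore tested as
  *self-identity* (the closed-form value at $(x,x)$: 1 for the normalized
  coefficients, $M/A$ for Forbes, $M(A-\tfrac12)^2/A^2$ for Fossum, 0 for
  distances), not as a global maximum, which would be mathematically false.

## Voting profiles and the election

For one reference structure, every configured coefficient ranks the
database (the reference itself is excluded from its own search — standard
practice, and it prevents the trivial self-vote). Two readings of "the top
retrieved structures are the voters" are implemented because the raw
similarity values of different coefficients are not on a common scale:

* **`rank` basis (default).** The voters are the molecules in the union of
  the per-coefficient top-n lists. Each voter orders the coefficients by the
  rank position they assign it; the best coefficient receives m points, the
  worst 1, ties share averaged points (the same averaging convention used
  for Kendall ranks). This reading is scale-free and needs no normalization.
* **`value` basis.** The voters are the retrieval positions 1..n; each
  coefficient contributes the min–max-normalized score of its position-i
  structure (normalized within its own top-n, distances reversed). This
  mirrors the literal "maximum similarity value" wording but depends on the
  normalization choice.

Every profile row sums to $m(m+1)/2$ — the conserved mass that the
validation enforces. The Borda total of a coefficient is its column sum; the
Condorcet winner is the coefficient that beats every other in pairwise
voter-majority contests. When no Condorcet winner exists (a cycle, or the
guaranteed Tanimoto/Sokal–Sneath tie), the Borda argmax is used, with
remaining ties resolved by the canonical coefficient order. A worked 3 × 11
profile ships with the package:

```{r}
prof <- example_voting_profile()
select_winner(prof)
```

Per activity class, the election evidence (Borda totals and pairwise-win
matrices) is *summed over all reference searches* of the class before the
winner is declared; a `per_reference` mode that elects per reference and
takes the modal winner is available. Summation is the natural pooling of an
election repeated under every class member as reference, and it smooths the
considerable voter noise of any single search.

## Metrics

* `recall_at_percent`: share of a class's actives inside the top x% of the
  ranking; the cutoff count is $\lceil pN/100 \rceil$ with a floor of 1.
* `enrichment_factor` (default 1%): active rate in the cutoff over the
  database-wide active rate.
* `bedroc` (default $\alpha = 20$): exponentially early-weighted enrichment
  via the RIE; at $\alpha=20$ roughly 80% of the weight falls on the first
  8% of the ranking.
* `roc_auc`: rank-sum (Mann–Whitney) area under the ROC curve.
* `mean_pairwise_similarity`: class structural diversity as the mean
  pairwise continuous Tanimoto (lower = more heterogeneous).
* `kendall_w`: concordance among activity classes (judges) ranking search
  methods (objects), with the tie correction $T_j = \sum_i (t_i^3 - t_i)$
  and significance from the $\chi^2 = k(n-1)W$ approximation on $n-1$
  degrees of freedom.
* `friedman_test`: computed through the identity $\chi^2_F = k(n-1)W$, so
  Friedman and Kendall are mutually consistent including ties (the identity
  is cross-checked against `stats::friedman.test` in the test suite). A
  seeded within-judge permutation p-value is available for small tables,
  where the $\chi^2$ approximation is weakest.

## The synthetic generator

No public count-fingerprint screening benchmark is redistributable here, so
the package generates its own data, seeded and reproducible (one RNG
substream per class, one for the background).

An activity class grows from a sparse prototype (nonzero density 0.1 by
default, counts $1+\mathrm{Geom}(0.6)$ capped at 9, emulating ECFC count
sparsity). Members are copies of the prototype with each feature resampled
with probability $\mu$; $\mu$ is calibrated by bisection (≤ 30 iterations)
until the realized mean pairwise Tanimoto lands within ±0.05 of the target
diversity. The mutation mask and the replacement values are drawn *once* and
reused across bisection iterations, so the realized diversity is a
deterministic monotone step function of $\mu$ and the bisection converges
without resampling noise. Targets between roughly 0.25 and 1.0 are
reachable at the default density; lower targets error as unreachable.

Two class geometries are provided. `"mutation"` (default) varies members by
feature substitution — the regime where overlap-normalized coefficients
such as Tanimoto excel. `"scaled"` additionally spreads members across a
0.5–3× magnitude range (a series of analogues of varying size) — the regime
where direction-based coefficients such as Cosine excel, and where a
per-class election genuinely pays off.

The background is independent sparse noise by default. Because real
screening databases contain inactive structural neighbours of the actives,
`background_related_frac` of the background can instead be drawn as
high-mutation derivatives (resampling rate 0.25–0.7) of class members; this
is what makes 5%-cutoff retrieval imperfect and gives the metric suite
something to measure.

### The planted-winner construction

The dominant-measure recovery property needs datasets in which one
coefficient is, by construction, the right answer. The construction plants
**Tanimoto**: actives are low-mutation copies ($\mu = 0.10$) of an
even-count prototype, and three decoy families are tuned to the
sensitivities of the other coefficients:

* *scaled-down* decoys (half-magnitude copies): Cosine, Kulczynski(2),
  Forbes, Fossum and Simpson score them at or above genuine actives (for a
  scaled copy $kp$, cosine is ≈ 1 for any $k$, Kulczynski(2) scores
  $(k + 1/k)/2 \ge 1$, Simpson $1/k$), and they sit closer than actives
  under Mean Euclidean and Divergence;
* *scaled-up* decoys (3× copies) reinforce the deception of the
  scale-sensitive quartet;
* *boost* decoys (prototype with one feature count massively inflated)
  deceive Mean Canberra and Bray/Curtis, which penalize support changes far
  more than magnitude changes.

Tanimoto ranks every decoy family below the actives but above the random
background, which is what makes its Borda totals dominate: it collects top
points from active voters and mid-range points from decoy voters, while
each deceived measure collects top points only from its own decoy family.
Family sizes (6/4/3) and magnitudes were fixed during development of the
construction; with 14-active classes, M = 512 and a top-10 committee the
election recovers Tanimoto in every tested seed.

Plantings for the other ten coefficients are not offered: Sokal/Sneath(1)
can never strictly win (rank-equal to Tanimoto, above), and the remaining
coefficients come in near-rank-equivalent pairs on generic count data
(Fossum ≈ Cosine$^2$ whenever $C \gg \tfrac12$) that this decoy geometry
cannot separate reliably. `generate_planted_winner` errors, with an
explanation, rather than producing a construction that recovers its target
only sometimes.

## What the synthetic experiments do and do not show

The acceptance script (`scripts/acceptance.R`) screens a six-class mixed
benchmark — four mutation classes spanning diversity 0.75 to 0.35 and two
scaled classes, each with 24 actives, over a 1600-molecule background of
which 80% are related decoys — with committees of 10, 20, 50 and 100, and
runs the Kendall/Friedman concordance analyses over the resulting
classes × methods recall table.

Three regularities emerge, and they say as much about the regime as about
the method:

* On *scaled* classes the election reliably picks a direction-based
  coefficient and the fused recall beats the Tanimoto baseline by a wide
  margin — the intended payoff of per-class election.
* On *mutation* classes Tanimoto is already the right answer, so fusion can
  at best match it; elections occasionally pick a nearby measure at small
  committee sizes and give up a little recall.
* Very large committees degrade: with only ~23 actives per reference, a
  top-100 committee is dominated by decoys, and decoy voters reward
  whatever measures agree on ranking decoys highly. Committee sizes should
  be commensurate with the expected number of retrievable actives; studies
  on databases of 10^5 molecules with hundreds of actives per class sit in
  exactly that regime, a 2500-molecule synthetic benchmark with 24-active
  classes does not.

Passing the suite therefore demonstrates the correctness of the machinery
(coefficients, elections, metrics, calibration), not that fusion beats a
Tanimoto baseline on real chemistry; the synthetic generator does not model
scaffold hopping, feature correlation from real substructure counting, or
activity cliffs.

## Problem sizes and defaults

| parameter | default | notes |
|-----------|---------|-------|
| fingerprint length M | 1024 | folded ECFC-style; tests use 256–1024 |
| committee size top-n | 100 | study design values 10/20/50/100; any ≥ 1 |
| recall cutoff | 5% | `cutoff_percent` in `run_config()` |
| EF cutoff | 1% | |
| BEDROC α | 20 | |
| voting basis | rank | `value` available |
| diversity tolerance | ±0.05 | bisection stop, ≤ 30 iterations |
| planted-winner suite | 20 seeds, 14 actives, M = 512, top-10 | |

All stochastic steps take explicit integer seeds; identical seeds reproduce
datasets molecule-for-molecule, and screening itself is fully deterministic
(ranking ties break by database row index, Borda ties by the canonical
coefficient order).

## Known limitations

* Single-reference similarity fusion only: group fusion (multiple
  references under one measure), weighted voters and other rank-fusion
  rules (RKP, Z-score, MAX/SUM) are out of scope.
* The `value` voting basis depends on min–max normalization within the
  top-n; a coefficient with constant top-n scores contributes a neutral
  0.5 at every position.
* Count fingerprints are taken as given; fingerprint generation from
  structures is not included.
* The Kendall/Friedman p-values use the χ² approximation, which is rough
  for few judges; prefer `friedman_test(..., exact = TRUE)` below ~10
  classes.
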