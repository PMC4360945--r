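---
title: "Methods: consensus-voted virtual-screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-voted virtual-screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsfunnel)
```

## The problem

Structure-based virtual screening docks a purchasable library of millions
of compounds into a target pocket and must then triage the results down to
a shortlist that can actually be bought and assayed. Single docking scores
are noisy and program-specific, so a common remedy is a *funnel*: a
sequence of increasingly stringent filters, ending in a *consensus* step
that only trusts compounds on which several independent scoring criteria
agree. `vsfunnel` implements one widely used funnel design:

1. a first docking-score threshold (Glide-style score, keep `< 5.0`),
2. a second, independent docking-score threshold (eHiTS-style score,
   keep `< 3.0`),
3. a *pose-consistency* filter: the two programs' poses of the same
   molecule, in the common receptor frame, must agree to within 2.0 Å
   heavy-atom RMSD (strict `<`),
4. a consensus vote: each compound receives one binary vote per scoring
   criterion on which it ranks in the top 10%, the votes are summed
   (maximum 5 with the default five criteria), and the cumulative vote
   selects a 5,000-compound shortlist.

The docking engines themselves are out of scope — scores and poses arrive
as a CSV table and paired SDF V2000 files — and a synthetic library
generator stands in for them so every stage is testable at desk scale.

## Pose-consistency RMSD

Given poses $x$ and $y$ of the same molecule with $n$ heavy atoms, and an
atom correspondence $\sigma$,

$$\mathrm{RMSD}(x, y; \sigma) =
  \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}\lVert x_i - y_{\sigma(i)}\rVert^2}.$$

Two choices deserve justification because the protocol this mirrors does
not state them:

* **In place, no superposition.** Both programs dock into the same
  prepared receptor, so the displacement between the two poses *is* the
  disagreement in predicted binding mode. Kabsch superposition would
  erase exactly that signal; it is available as `superposed_rmsd()` (and
  `symmetry_min_rmsd(..., superpose = TRUE)`) for diagnostics only.
* **Symmetry correction.** Atom numbering differs between programs, and
  topologically equivalent atoms (a benzene ring's 12 automorphisms, the
  24 of a neopentane-like branch) make naive ordered RMSD ill-defined:
  a hexagon "rotated" by one ring position is geometrically identical
  but has naive RMSD equal to the ring radius. `symmetry_min_rmsd()`
  therefore minimises over *every* element- and adjacency-preserving
  correspondence, found by VF2 with element vertex colours. The test
  suite checks this against a full-factorial permutation oracle on
  graphs up to 8 heavy atoms.

Further conventions: hydrogens are dropped at read time (programs
protonate differently); bond orders are ignored during matching by
default (aromatic-bond encodings disagree across exports), with an
order-sensitive mode available; non-isomorphic pairs (tautomer or
protonation divergence) are reported *not comparable* and dropped with
that reason, never silently passed; the automorphism enumeration is
capped (default 10,000) and errs beyond the cap rather than stalling.
The cutoff is applied strictly (`rmsd < 2.0` passes, `rmsd == 2.0`
fails), reading the protocol's "<2.0 Å" literally.

## Consensus vote

Per criterion, compounds are ranked by *competition* ("min") ranking —
rank 1 means no strictly better compound, ties share the minimum rank —
under the criterion's declared direction (`lower_better` for docking
scores and RMSD, `higher_better` for predicted pKi; the direction must be
declared, there is no default). The top-fraction rule is
$m = \max(1, \lfloor f N \rfloor)$ over the $N$ ranked compounds, with
every compound tied across the $m$-th position included: the rule is then
deterministic, order-independent, and exact (no tie inflation) whenever
scores are distinct and $N$ is a multiple of $1/f$. Votes are the integer
sum of the binary memberships. Compounds missing any criterion are
excluded from the vote with a warning rather than treated as non-members;
in a faithful funnel every voted compound has passed all upstream stages
and carries all values.

The protocol being mirrored resolved the shortlist boundary by human
visual inspection, which cannot be reproduced. `select_top_voted()`
replaces it with a stated tie-break chain: cumulative vote (descending),
then mean normalised rank $\overline{r_k / N_k}$ (ascending), then
compound id in C-locale lexicographic order. The whole pipeline is
therefore a deterministic function of its inputs — two runs produce
byte-identical hit-list CSVs.

Whether pose RMSD is *both* the hard 2.0 Å filter and the fifth voting
criterion is ambiguous in the source protocol (its methods list five
procedures including RMSD and a vote maximum of 5; its results name four
score criteria). The default treats RMSD as both — the consistency stage
records each survivor's RMSD as a `lower_better` criterion — and
`default_funnel_config(include_rmsd = FALSE)` gives the four-criterion
reading.

## The synthetic library: what it emulates, and what a green test means

`generate_scores()` draws, per compound $i$, a latent affinity
$a_i \sim \mathcal N(0, 1)$, shifted by $-\delta$ for the planted binders
(lower = more favourable), and per criterion $k$

$$s_{ik} = \sqrt{\rho}\, a_i + \sqrt{1 - \rho}\, \varepsilon_{ik},
  \qquad \varepsilon_{ik} \sim \mathcal N(0,1) \text{ i.i.d.}$$

One shared factor is the simplest structure that reproduces the salient
feature of real consensus criteria — they are all computed from the same
poses and are therefore correlated — while leaving $\rho$ sweepable.
Higher-better criteria are emulated by negation, keeping one code path.
Note a consequence of placing the binder shift on the latent factor: the
per-criterion separation is $\sqrt{\rho}\,\delta$, so at $\rho = 0$
planted binders are indistinguishable by construction.

Defaults (chosen once, stated here, not revisited): $n = 10{,}000$
compounds at desk scale; four score criteria (`glide`, `ehits`, `ligx`
lower-better, `pki` higher-better) with the fifth criterion supplied by
the funnel's RMSD stage; $\rho = 0.5$ (real docking/rescoring criteria
are substantially but far from perfectly correlated); prevalence
$\pi = 0.02$ (a generous but not absurd true-binder rate for a focused
purchasable library); $\delta = 1$ (one latent standard deviation —
detectable, far from trivial); pose noise $\sigma_\text{pose} = 0.15$ Å
per coordinate (redocking jitter well inside the 2.0 Å cutoff);
inconsistent-pose probability $0.1$ with gross displacement $5$ Å
(unambiguously outside the cutoff, as the config invariant requires).

Pose pairs are built from four hard-coded templates (linear C4 chain,
benzene-like C6 ring, neopentane-like C5, O–C–C hetero chain) with fixed
idealised coordinates — dyadic values where closed-form boundary
arithmetic matters, so "translate by exactly 2.0 Å" is exact in floating
point. Pose B adds per-atom Gaussian noise, scrambles atom order by a
random automorphism (exercising the symmetry machinery on every
template), and applies the gross displacement with probability
$p_\text{inconsistent}$. All randomness flows from the single config
seed; regeneration is bit-identical, and the generator restores the
caller's RNG state.

What the generator does *not* emulate: real docking-score distributions
(Glide's empirical range and skew), chemistry-dependent score structure,
receptor-dependent pose multimodality, or correlated failures between
programs. A green enrichment test therefore establishes that the funnel
*machinery* concentrates planted signal as designed — not that any real
screen would enjoy the same enrichment.

## Null model and statistical checks

With $K$ independent continuous criteria and no boundary ties, each
compound's vote is $\mathrm{Binomial}(K, f)$
(`expected_vote_distribution()`). The acceptance suite checks the
empirical vote histogram at $n = 20{,}000$, $K = 5$, $f = 0.1$, $\rho = 0$
against this law by a $\chi^2$ goodness-of-fit test at $\alpha = 0.01$
(upper tail pooled so expected counts stay above ~5), plus the closed
form $P(\text{vote} \ge 1) = 1 - 0.9^5 = 0.40951$ within three Monte
Carlo standard errors. Enrichment of planted binders in the final hit
list is tested at $\delta \in \{0, 0.5, 1, 2\}$ under fixed seeds:
above-prevalence for every $\delta > 0$ and non-decreasing in $\delta$.

## Numerical and design choices

* Strict `lt` at both score-threshold stages. The source protocol writes
  `<5.0` in its methods and `≤5.0` in its results; the methods wording
  is followed, and the comparator is configurable per stage. Thresholds
  apply to raw stored values — no sign convention is imposed on docking
  scores.
* Missing scores are explicit (`NA`), never imputed; threshold stages
  drop them (counted separately), the vote excludes them with a warning.
* Compound identity across files is the exact whitespace-stripped,
  case-sensitive title/id string.
* SDF dialect is fixed to V2000; V3000 records are rejected loudly.
  Multiple records per title are surfaced by the reader; the funnel uses
  the first and tallies the rest as `duplicate`.
* Stage order (score A → score B → RMSD → vote) follows the source
  narrative; stages are freely composable, and threshold stages on
  different criteria provably commute (asserted as a test, not assumed).
* Every drop is tallied by reason (`missing`, `threshold`, `unpaired`,
  `not_comparable`, `cutoff`) in the stage report for auditability.

## Known limitations

* No maximum-common-substructure partial matching: non-isomorphic pose
  pairs are reported, not aligned.
* The automorphism cap makes worst-case symmetric graphs an error, not a
  slow answer; raise the cap deliberately if needed.
* The brute-force oracle equivalence is only feasible to ~8 heavy atoms;
  beyond that, correctness rests on VF2 plus the invariance properties
  (translation, symmetry, self-RMSD zero).
* The published funnel's real-data counts (4 × 10⁶ → … → 100) require a
  commercial library and engines and are not reproduced here; the tests
  establish operational fidelity of every printed constant, not the
  historical screen.
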