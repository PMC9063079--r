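---
title: "Covariation-guided RNA structure prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation-guided RNA structure prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covfold)
```

## The problem and the approach

Homologous RNAs conserve structure through compensatory mutations: when one
base of a pair mutates, its partner tends to mutate so that pairing ability
is preserved. Across a multiple sequence alignment this leaves a detectable
statistical dependence (*covariation*) between the two alignment columns of
a conserved pair. Pure comparative methods exploit this but predict only a
consensus and need a good alignment; pure thermodynamic methods predict a
minimum free energy (MFE) structure for one sequence but suffer from
imperfect energy parameters and ignore the family signal.

covfold combines the two: the alignment's covariation is distilled into a
*guide structure* — columns forced to pair (intermediary base pairs) and
columns forced unpaired (restricted unpaired bases) — which is projected
onto each individual sequence and handed to a *restricted* free-energy
minimization that is free to add pairs around the guide, including a
pseudoknotted layer. Every sequence of the alignment gets its own,
possibly pseudoknotted, structure.

## Covariation scores

For columns $a,b$, mutual information is

$$MI(a,b) = \sum_{x,y} f_{a,b}(x,y)\,\log_2
  \frac{f_{a,b}(x,y)}{f_a(x)\,f_b(y)},$$

with the joint sum restricted to the six canonical pairs
(A·U, U·A, G·C, C·G, G·U, U·G). Rows where either column holds a gap are
excluded. The joint frequencies are normalized by the number of non-gap
rows, and the marginals $f_a, f_b$ are the ordinary per-column base
frequencies over those same rows. This last choice matters: if the
marginals were instead conditioned on the canonical-pair rows, *any* two
independent uniformly-varying columns would condition to the uniform
distribution over the six canonical combinations and score
$MI \approx 1.25$ bits — exactly like a perfectly covarying pair — and
pair selection would be noise. With unconditional marginals, independent
columns score $\approx 0$ and covarying columns score high, which is what
the statistic is for. The truncated (canonical-only) sum can dip
marginally below zero; values are clipped to the score's documented range
$[0, 2]$ bits.

Raw MI is contaminated by background signal shared across many columns
(random noise and phylogeny). The average product correction removes it:

$$APC(a,b) = \frac{MI(a,\bar z)\, MI(b,\bar z)}{MI_{avg}},
 \qquad MIp(a,b) = MI(a,b) - APC(a,b),$$

where $MI(a,\bar z)$ is the average of $MI(a,z)$ over all $z$ with
$|a - z| > 3$ (near-diagonal terms enter as zeros, and the divisor stays
$n_a - 1$), and $MI_{avg}$ is the mean of the same zero-substituted MI
over unordered column pairs. The unordered-pair mean is the convention
under which a flat MI surface satisfies $APC = MI$ and $MIp \approx 0$,
the defining sanity property of the correction; reading the grand average
over both index orders instead would double it and leave
$MIp \approx MI/2$ on flat surfaces. $MIp$ may be negative.

## Guide construction

* **Intermediary pairs.** All column pairs with $MIp > \theta$ (default
  threshold $\theta = 0.4$, chosen as a conservative high-precision
  cutoff; configurable) and span $b - a \ge 4$ are sorted by score, ties
  broken by $(a, b)$, and accepted greedily when both columns are still
  free. The span floor mirrors the 3-base minimal hairpin loop. Because
  the downstream restricted minimization requires a pseudoknot-free
  guide, crossing conflicts among accepted pairs are resolved by keeping
  the higher-scoring pair (a maximum non-crossing-weight alternative
  would also be defensible; the greedy rule is simpler and deterministic).
* **Restricted unpaired columns.** Columns whose maximum raw MI against
  any other column is below $MI_{avg}$ are considered unlikely to pair
  and are marked `x` (forced unpaired). Raw MI is used, not MIp; a flag
  switches to MIp maxima. A restriction on a column that is also an
  accepted pair endpoint is dropped with a warning — a selected pair
  carries direct evidence, a failed restriction only its absence.
* **Projection.** For each aligned row, gap columns are deleted from the
  sequence and the guide; a pair losing an endpoint is removed entirely,
  and pairs whose hairpin loop shrinks below 3 unpaired bases after gap
  removal are removed iteratively. Projected guides therefore always
  satisfy the structure invariants.

## Energy model

Structures are scored by a nearest-neighbor model: a $6 \times 6$ stack
table, hairpin/bulge/internal-loop length tables for sizes up to 30 with
the logarithmic (Jacobson–Stockmayer) extension
$E(L) = E(30) + c\,\ln(L/30)$ beyond, a capped linear (Ninio) asymmetry
term for internal loops, and an affine multiloop cost
$a + b\cdot\text{branches} + c\cdot\text{unpaired}$ in which the closing
helix counts as a branch. All energies are kcal/mol at 37&nbsp;°C, 1&nbsp;M
NaCl. Dangling ends and coaxial stacking are omitted. The shipped
defaults are a Turner-style subset; the entire table round-trips through
a plain-text file (`read_energy_parameters()` /
`write_energy_parameters()`), so published pseudoknot parameter sets can
be substituted without touching code. Disallowed geometry (hairpin loop
< 3, non-canonical pair) is the `Inf` sentinel, never `NaN`.

For a crossing (pseudoknotted) structure the pair set is first split into
two pseudoknot-free layers by a deterministic first-fit sweep ordered by
opening position. When a structure is built as a pseudoknot-free base
layer plus an added layer whose every pair crosses the base layer — the
only crossing class this package produces — the sweep provably recovers
exactly that split. The base layer is scored with the nested loop model,
treating bases paired in the added layer as unpaired; the added layer's
pairs form pseudoknot *bands* (maximal stacked runs) and are scored by
their stacking terms alone; and an affine pseudoknot term is added:
initiation $P_s$ per crossing component (default 9.6), $P_b$ per band
(default 0.2), and $P_{up}$ per unpaired base under a band span (default
0; the added-layer search assumes this term is zero). Charging the added
layer full hairpin initiation instead would make even strongly stacked
H-type pseudoknots energetically unreachable, which is why band loops are
absorbed into the affine penalty, as pseudoknot energy models generally
do. The H-type toy decomposition therefore carries exactly one initiation
and two band terms.

## Restricted minimization

`restricted_pkfree_mfe()` is a Zuker-style $W/V/M$ dynamic program over
one sequence with hard constraints: `x` positions never pair, and guide
pairs must appear (positions with a forced partner cannot remain unpaired
or pair elsewhere, and loop closures may not swallow a forced position).
It runs in $O(n^3)$ time and $O(n^2)$ space — the tables are three
$(n+2)^2$ arrays — with interior loops capped at 30 unpaired bases
(standard). Traceback prefers, in order: unpaired end, pairing, then
bifurcation at the smallest split point, so results are deterministic.
Guide pairs that are non-canonical on a particular sequence are dropped
with a warning; a guide that is still infeasible falls back to the
empty-guide fold, keeping the `x` constraints.

`restricted_pk_mfe()` adds a disjoint pseudoknot-free layer to the
(pseudoknot-free) guide so that the union is a density-2 structure — no
index sits under more than two band spans, the class containing H-type
pseudoknots and kissing hairpins. Three relaxations are evaluated and
compared by `structure_energy()`, the authoritative score:

1. the purely nested completion (the DP above);
2. a layer of span-disjoint perfect crossing helices over the guide
   (candidates are maximal helices over free bases that cross at least
   one guide band, scored by stacking plus their share of the affine
   penalty, selected by weighted interval scheduling), followed by a
   nested re-completion of the remaining free bases;
3. the same helix layer added hierarchically on top of the nested
   completion — the hierarchical-folding picture in which the nested
   scaffold forms first and crossing pairs after.

Any candidate failing the density-2 check is discarded, so the
postcondition holds by construction. Because the added layer is
pseudoknot-free, the whole step keeps the $O(n^3)/O(n^2)$ profile. On
small instances the result is validated against exhaustive enumeration
over *all* pseudoknot-free added layers; the admissible-space narrowing
to disjoint perfect helices is a real restriction in principle, but under
the affine band model interrupted or nested crossing helices pay extra
band penalties and were never optimal in any enumerated instance.

A brute-force oracle (`brute_force_mfe()`) enumerates every admissible
structure (crossing or not) for $n \le 18$ and evaluates each with
`structure_energy()`; it shares no code with the DP beyond the energy
tables and is the reference in the test suite.

## The four relaxation paths

For each sequence the projected guide is relaxed four ways, and the
lowest-energy result wins (ties to the earlier path):

* **P5** — restricted pseudoknotted minimization of the guide as-is.
* **P6** — predicted pairs that cross a guide pair are kept (with the
  original `x` marks) as a new guide and re-minimized, letting competing
  crossing pairs form. When no crossing pair is identified the path
  contributes nothing new; treating it as an unconstrained fold instead
  would always win the energy comparison and silently discard the
  covariation evidence.
* **P7** — pseudoknot-free restricted fold, then only *relaxed stable
  stems* (helices of ≥ 3 pairs, allowing interruptions of ≤ 2 unpaired
  bases per side; both configurable) are kept and re-minimized — nested
  competition.
* **P8** — the outermost pair of each disjoint guide substructure is
  opened first, then as P7 — releases structures blocked by a wrongly
  forced enclosing pair.

Paths are pure functions of their inputs and run sequentially; running
them in parallel would change nothing but wall time.

## Evaluation

Sensitivity TP/(TP+FN), PPV TP/(TP+FP) and their harmonic mean
(F-measure) over exact base-pair identity; F is 0 when either factor is
0, and the empty-vs-empty comparison is vacuously perfect (1). Before
scoring, non-canonical reference pairs and reference hairpins shorter
than 3 are dropped. In *adjusted* mode a predicted pair absent from the
reference but contradicting none of its pairs (neither endpoint paired
elsewhere) is *compatible* and excluded from FP — appropriate when
reference structures from comparative analysis leave large segments
undetermined.

The significance test is implemented exactly as printed in its source:
$t_s = \bar f_1 - \bar f_2$; each of 10,000 repetitions resamples each
vector *with replacement* to its own size and recounts
$t'_s \ge t_s$. That is a bootstrap, not a permutation: on two constant
vectors every $t'_s$ equals $t_s$ and $p = 1$ regardless of the
difference. The degenerate case is documented rather than silently
"fixed"; a conventional pooled label-permutation two-sided test is
available behind `method = "permutation"`.

## Synthetic data

`synthesize_alignment()` plants a consensus structure (dot-bracket, a
crossing layer allowed up to density-2) and evolves a consistent root
sequence: paired columns substitute *jointly* with probability
`compensatory`, drawing uniformly from the six canonical pairs (the
simplest model that saturates covariation); unpaired columns and
non-compensatory events mutate independently at `background`; gaps are
independent single-cell deletions at `gap_rate`, and each row's truth is
the planted structure projected through its own gaps. Defaults (50
sequences, compensatory 1.0, background 0.05, no gaps) correspond to a
well-conserved family with saturated covariation signal.

What the generator does *not* emulate: phylogenetic correlation between
rows (all rows descend independently from one root, so the APC's main
real-world noise source is only crudely present), realistic indel
processes (no multi-column or phylogenetically shared gaps), non-canonical
interactions, and base-composition bias. Passing the end-to-end tests
therefore shows the machinery is correct and the signal path works; it
does not certify accuracy on real families, where alignment quality and
phylogenetic structure dominate.

The bundled `trna_like_fixture()` is a 76-column, four-stem cloverleaf
(acceptor, D, anticodon, T stems) generated the same way.

## Numerical choices and problem sizes

Energies are doubles in kcal/mol; the DP's infeasible sentinel is
$10^9$ with all comparisons guarded, and traceback matches cases within
$10^{-7}$. DP results agree with the independent decomposition
(`structure_energy()`) to well below $10^{-6}$. The test suite verifies
the pseudoknot-free DP against exhaustive enumeration on 500 random
constrained instances at $n \le 14$, the pseudoknotted search against
exhaustive added-layer enumeration at $n \le 16$, covariation against a
naive per-definition oracle at $10^{-12}$, and end-to-end recovery on
50-sequence, 77-column planted alignments — sizes chosen so the whole
suite completes in well under a minute while the enumeration spaces stay
exhaustive. Empirical runtime scaling is measured over
$n \in \{50, 100, 200, 400\}$; note that at these sizes the bounded
interior-loop scan (an $n^2$ term with a 30×30 constant) still carries
substantial weight next to the $n^3$ multiloop/exterior scans, so the
measured log-log slope sits near the lower edge of the cubic band and
approaches 3 from below as $n$ grows.

## Known limitations

* The default energy constants are a plausible Turner-style subset, not a
  fitted or published pseudoknot set; absolute free energies should not
  be interpreted, only compared within a run (the parameter file exists
  precisely so users can substitute measured sets).
* The added crossing layer is searched over disjoint perfect helices;
  bulged crossing helices and multi-band interleavings beyond density-2
  are not considered.
* Guide quality degrades with shallow alignments (few sequences) exactly
  as the underlying statistic does; with no covariation signal the
  pipeline reduces to (x-constrained) MFE prediction.
* The per-unpaired pseudoknot penalty $P_{up}$ is honored by
  `structure_energy()` but ignored by the layer search; leave it 0 unless
  you accept the search scoring bands slightly optimistically.
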