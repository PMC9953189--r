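---
title: "Predicting H-type pseudoknots with bulges and internal loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting H-type pseudoknots with bulges and internal loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpknot)
```

## The problem

An H-type pseudoknot is the simplest crossing topology in RNA secondary
structure: bases of a hairpin loop pair with bases outside the hairpin,
producing two helices (stems) whose base pairs cross, connected by two
loops. Crossing pairs place pseudoknots outside the reach of standard
nested dynamic programming, and exact thermodynamic folding with
pseudoknots is intractable in general, so practical predictors restrict
the topology they search. `hpknot` searches H-type pseudoknots
exhaustively and allows each stem to continue across one bulge or internal
loop, writing results in extended dot-bracket notation with two bracket
layers: the 5'-opening stem and its extensions in `[ ]`, the other stem in
`( )`.

## The pipeline

**1. Core-stem enumeration.** A candidate pseudoknot is seeded by a
*core-stem quadruple* `(i, j, k, l)` with `i < j < k < l`: the left core
pair `(i, k)` and the right core pair `(j, l)`, which cross. A quadruple is
admissible when both pairs are complementary (A–U and C–G; G–U wobble
pairs opt-in via `allow_gu`) and both connecting loops meet a minimum size
(default 1: each loop nonempty, as in the worked example below; `k = j +
1` is allowed). `enumerate_core_stems()` returns exactly this set by
direct enumeration. A grammar-based parser over the same pattern would
yield the same parse forest; the candidate set, not the parsing mechanism,
is the contract, and the test suite pins it to a brute-force scan of all
position quadruples on short random sequences.

**2. Decoration.** Each stem is grown outward from its core pair to
maximality with strictly complementary stacked pairs: the right stem adds
`(j - t, l + t)` drawing on left-loop and 3'-tail bases, the left stem
adds `(i - t, k + t)` drawing on 5'-head and right-loop bases. The two
stems consume disjoint position sets, so the result is independent of
extension order. When contiguous extension stalls, each stem may continue
across one *gap event*: for gap lengths `(b_inner, b_outer)` in
`[0, B]^2` minus `(0, 0)` — `B` is `maximum_bulge_size`, default 3 — the
pair across the gap is attempted and, if complementary and in range,
stacking continues to maximality. A gap on one side is a bulge, on both an
internal loop. Candidates are the Cartesian product of the per-side
choices (including "no gap"); gap-mediated pairs are flagged.

**3. Selection.** Two stages: first keep the candidates with the maximum
number of *non-gap* pairs (pairs formed after a bulge or internal loop are
deliberately excluded from this count so that speculative gap extensions
cannot crowd out better stems); then pick the minimum-energy candidate.
The energy is the pseudoknot penalty

$$G_{pseudo} = \beta_1 + \beta_2 B_p + \beta_3 U_p,$$

with defaults $\beta_1 = 9.6$, $\beta_2 = \beta_3 = 0.1$ kcal/mol, where
$B_p$ counts the non-gap stem pairs and $U_p$ the unpaired bases strictly
inside the span of the structure's outermost pairs. The phrase "number of
core stems" is ambiguous for an H-type topology (it would be the constant
2); counting the stem pairs makes the term discriminative, and $U_p$ over
the pseudoknot span rewards compact, well-paired structures. Energies are
compared with an absolute tolerance of 1e-9 kcal/mol; residual ties fall
deterministically to the larger total pair count and then the
lexicographically smallest quadruple, so the selection is invariant under
permutation of the candidate list.

### Why the default energy is the penalty alone

A full thermodynamic engine is out of scope here; the package instead
ships two scores. The default ranks candidates by $G_{pseudo}$ alone —
the relation the method's description actually states — and this default
reproduces the worked example below exactly. The optional backend
(`use_stacking = TRUE`) adds Turner-style nearest-neighbor stack free
energies (37 °C, 0.1 kcal/mol precision, bundled as a checksummed
plain-text table covering all 36 ordered Watson–Crick/wobble stacks)
summed within each bracket layer. Stacking rewards G–C-rich short helices
heavily, and on the worked example it flips the stage-2 choice between
two stem families that tie at five contiguous pairs; we therefore treat
it as a refinement for users who want sequence-dependent discrimination,
not as the default. The backend is pluggable: any named stack table can be
passed to `energy_params()`.

## The worked 22-nt example

```{r worked}
seq <- "ACAUCCGCCUGAUUUGAGCACA"
p <- predict_pseudoknot(seq, trace = TRUE)
```

The parser-equivalent enumeration finds the core stems C5–G11 and
U10–A17; the loops they delimit are 6..9 (left) and 12..16 (right). The
right stem extends contiguously by C9–G18 and stops (bases 8 and 19 are
both C); the left stem gains U4–A12 and A3–U13 and stops (C2/U14). Gap
search then finds two continuations for the left pair of sets (G7–C19
after a bulge at 8, G7–C21 after an internal loop) and three for the
right (A1–U14, A1–U15, C2–G16), and the selected structure takes G7–C19
and C2–G16 at penalty `r p$candidate$total_energy` kcal/mol. Note that
strict complementarity is enforced throughout: a published trace of this
example lists an eighth pair 8–19, which is C–C on the printed sequence
and is not emitted here.

## The synthetic generator

`generate_pseudoknot()` plants a ground-truth pseudoknot with known
geometry: `head | stem A | loop | stem B | A' | loop | B' | tail`, stems
≥ 2 bp, loops ≥ 1 nt, optionally one bulge/internal-loop continuation
with gap-flagged pairs. Stem bases are sampled uniformly with exact
complements. Unpaired regions are filled uniformly and then *repaired*:
any antiparallel run of three or more complementary pairs that is not a
run of planted pairs, and any complementary (or wobble) pair that would
extend a planted helix outward, triggers resampling of a random involved
base (planted pairs move both ends together). The repair target is chosen
at random because a single position can be pinned by several overlapping
constraints. This makes the planted helices the unique maximal crossing
stems, so the default pipeline should recover both core stems; the
acceptance suite requires recovery (slip-tolerant, see below) on at least
95% of 200 seeded instances with the default geometry (4+4 bp stems, 4/5
nt loops, 2 nt head and tail, about 29 nt total — sizes chosen to sit in
the short range where exhaustive enumeration is the method's natural
regime).

What the generator does *not* emulate: realistic base composition,
structured loops (hairpins inside loops are not predicted by this method
by design), kissing interactions, or non-H topologies. Passing the
recovery suite therefore shows the pipeline is sound on its own model
class, not that it matches experimental accuracy on natural RNAs.

## Evaluation conventions

`confusion_counts()` scores per position, so `tp + tn + fp + fn` equals
the sequence length: `tp` same partner in prediction and reference, `tn`
unpaired in both, `fn` missed reference pairing, `fp` spurious or
wrong-partner pairing (a wrong partner counts once, as `fp`, preserving
the partition). PPV, recall, F1 and MCC follow the standard formulas;
zero denominators give `NaN` with a warning rather than a silent 0, and
MCC on mismatch-free structures equals the Pearson correlation of the
paired/unpaired indicators (a property the tests exercise). Display
rounding is 3 decimals; internal values stay at full precision.

Core-stem matching is slip-tolerant: a pair `(k, l)` matches `(k ± 1, l)`
or `(k, l ± 1)` — one coordinate, not both. Because decoration grows
outward, the selected quadruple is always the innermost crossing pair of
its helices, while a planted ground truth is most naturally summarized by
its outermost pairs; comparing seeds to outermost pairs would make every
match fail by the stem length. Structures are therefore summarized for
matching by the outermost non-gap pair of each bracket layer
(`core_pairs()`), on both sides of the comparison, and the slip rule
absorbs single-base differences in helix extent.

## Numerical and degenerate-input choices

* Sequences with no admissible quadruple (e.g. `AAAA`, or anything
  shorter than 6 nt with nonempty loops) predict all-unpaired with a
  warning, not an error.
* `T` is silently read as `U`; any other non-ACGU letter is an error with
  its position — the method has no ambiguity handling.
* Gap search deduplicates gap-length combinations that land on the same
  pair set, and attempts at most one gap event per side.
* The stage-1 count never changes with gap choices, so the pipeline only
  runs the gap search for quadruples that already achieve the maximal
  contiguous pairing; the result is provably identical to decorating
  everything.
* Energy ties use an absolute 1e-9 tolerance before the deterministic
  tie-breaks engage.

## Limitations

One pseudoknot per sequence; two bracket layers only; no K/L/M-type
topologies; no motif prediction inside loops; the optional stacking
backend has no dangling ends, coaxial stacking, or loop-entropy terms.
Whole-benchmark accuracy tables from the literature require the external
260-sequence dataset and competing predictors, and are deliberately not
reproduced here.
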