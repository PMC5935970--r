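---
title: "Topology strings from secondary-structure contact graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology strings from secondary-structure contact graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topostrings)
```

## The model

A protein chain's topology, at the coarsest level that still determines its
fold, is the identity of its secondary-structure elements (SSEs), which pairs
of them touch in space, and whether touching pairs run parallel or
antiparallel. `topostrings` reduces a chain to exactly this information and
serialises it as a canonical one-dimensional string:

```
COMP | i-jO, i-jO, ...
```

where `COMP` is the SSE composition over the alphabet `H` (α-helix) and `E`
(β-strand) in N→C order, each `i-jO` records a spatial contact between the
`i`-th and `j`-th SSE (`1 ≤ i < j`, sorted ascending), and `O ∈ {P, A}` is
the orientation class. A β-hairpin is `"EE|1-2A"`; a chain with no SSE
contacts is `"COMP|"`. Because the string is canonical, topology comparison
is string equality, and a topology database is a hash of strings — this is
what makes large-scale scanning of topology space cheap.

The pipeline has four stages:

1. **Secondary structure.** Per-residue labels come either from an existing
   DSSP output file or from the built-in assigner, a simplified
   Kabsch–Sander implementation. The amide hydrogen is placed 1 Å from N
   opposite the preceding carbonyl; a donor–acceptor pair is scored with the
   electrostatic model
   \(E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\)
   kcal/mol and bonded when \(E < -0.5\). α-helices arise from two
   consecutive i→i+4 turns (3₁₀ and π analogously from i→i+3 and i→i+5),
   strands from parallel/antiparallel bridge patterns chained into ladders;
   isolated bridges are `B` and are ignored by segmentation. Sheet
   lettering, β-bulge merging and solvent accessibility are deliberately out
   of scope; for exact-DSSP workflows import the DSSP file instead.
2. **Segmentation.** Maximal runs of `H` (≥ 4 residues) and `E` (≥ 3)
   become SSEs. Each SSE gets a centroid (mean CA) and an axis — the
   leading singular vector of its centered CA coordinates, sign-fixed to
   point N→C.
3. **Contacts.** Residues are in contact when their Cβ atoms (Cα for
   glycine) lie within 8 Å and are at least 3 positions apart in sequence.
   An SSE pair is in contact when at least 3 residue contacts support it.
   Orientation is the angle between the two axes: ≤ 90° is `P`, otherwise
   `A`; the raw angle is retained so finer binning can be layered on.
4. **Encoding.** Contacts are sorted by `(i, j)` and serialised; `parse` and
   `encode` are exact inverses on valid strings.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff_A` | 8.0 Å | residue contact distance (Cβ–Cβ) |
| `atom_rule` | `CB` | contact atom; `CA` and `heavy` available |
| `min_seq_sep` | 3 | excludes sequence-local contacts |
| `min_pairs` | 3 | residue pairs needed for an SSE contact |
| `min_helix` / `min_strand` | 4 / 3 | shortest segment kept |
| `count_310` | off | count 3₁₀ (G) runs as helices |
| `parallel_max_deg` | 90° | P/A boundary (90° itself is P) |
| `alpha` / `fdr_max` | 0.001 / 0.001 | significance and FDR thresholds |

The contact thresholds are standard contact-map conventions rather than
values with a single canonical source, so all of them are exposed as
arguments (and CLI flags) and recorded in every output's provenance block.
3₁₀ helices are excluded from the composition by default: on the
reaction-centre-like test architecture this is exactly the 7-helix versus
9-helix difference between the α-only and 3₁₀-inclusive counting
conventions, and `count_310 = TRUE` reproduces the inclusive one. Helices
interrupted by kinks are not merged.

## Topological modules

For a chain with *n* SSEs the module search fixes a window at the N
terminus and grows it one SSE at a time, yielding the *n − 1* prefix
windows (1,2), (1,3), …, (1,*n*); each module is the induced sub-topology
of its window (contacts wholly inside it, re-indexed from 1), and the last
module is the chain's full topology. We read the stepwise N→C description
as prefix growth because it is the only contiguous-window scheme that
produces exactly *n − 1* modules; an `all-contiguous` mode that enumerates
every window (a, b) is provided for exploration. Chains with n ≤ 3 return
no modules by default (`allow_small` overrides).

```{r modules}
t <- parse_topology("EEHH|1-2A,1-3P,3-4P")
vapply(extract_modules(t), function(m) encode_topology(m$sub_topology), "")
```

## Occurrence statistics and the Prevalent class

A topology database groups chains (and, separately counted, domains) by
canonical string. Statistical enrichment of a topology with count *k* among
*N* chains and *T* distinct topologies is measured by the upper binomial
tail \(P(X \ge k)\), \(X \sim \mathrm{Binomial}(N, 1/T)\) — the uniform
null is a declared modelling choice, kept behind `classify_prevalence()` so
a class-conditional null would be a local swap. Benjamini–Hochberg
adjustment across records controls the FDR. A topology is **Prevalent**
when p < 0.001, q < 0.001 *and* its count exceeds the uniform expectation
N/T; the last condition is a deliberate conjunction so that
depleted-but-significant topologies cannot be called Prevalent. On the
package's canonical toy database (counts 70/10/8/7/5 over 100 chains) one
of five topologies is Prevalent — 20% of topology space covering 70% of
the chains, the qualitative small-fraction/most-proteins pattern such
databases show.

```{r prevalence}
db <- build_db(data.frame(
  source_id = paste0("s", 1:100),
  topology = rep(c("HHH|1-2A,2-3A", "EE|1-2A", "EEH|1-2A", "HH|1-2P",
                   "EEEE|1-2A,2-3A,3-4A"), c(70, 10, 8, 7, 5)),
  kind = "chain"))
db <- classify_prevalence(db)
unlist(coverage_summary(db))
```

Curation of the input set (non-redundancy culling and the like) is the
caller's responsibility; the database records what it was given.

## What the synthetic generator emulates — and what it does not

Every stage is testable without downloading structures because the package
generates chains of ideal elements with known ground-truth strings:

* **Helices** are grown from internal coordinates (standard bond
  lengths/angles, φ = −57°, ψ = −47°; φ = −49°, ψ = −26° for 3₁₀), which
  reproduces the textbook ~1.5 Å rise, ~100° twist and ~2.3 Å CA radius
  and, crucially, real i→i+4 hydrogen bonds that the assigner must detect.
* **Strands** use a flat two-residue-repeat model: CA every 3.3 Å along the
  axis, amide and carbonyl groups alternating sides. Antiparallel partners
  are the 180°-rotated copy at 4.8 Å; parallel partners additionally slant
  their carbonyls toward the C terminus (sine 0.36) and shift registry by
  one rise — the inclined-bond geometry real parallel sheets use, solved
  exactly for this model.
* **Loops** between elements are short glycine CA traces. CA-only residues
  cannot donate or accept hydrogen bonds, so loops can never create
  spurious secondary structure; the one exception is the loop residue
  immediately before a strand, which carries a carbonyl oriented as the
  strand's virtual predecessor so that the strand's first amide hydrogen is
  placed as in a continuing sheet (otherwise the terminal bridge of every
  N-terminal strand would be lost).
* Every generated fixture is validated: the generator runs the full
  pipeline and *refuses* to emit a chain whose recovered topology differs
  from the declared ground truth, so a spec whose geometry creates
  ambiguous unintended contacts fails loudly.

The generator does **not** emulate real data's irregularities: no side
chains beyond Cβ, no strand twist or β-bulges, no bent helices, no
physically realistic loops, no alternate conformations, no experimental
noise. Passing the recovery suite therefore demonstrates that the pipeline
is internally consistent and that each stage implements its stated
definition — it does not demonstrate agreement with DSSP on real,
irregular structures, which is what the DSSP-file import path is for.

## Numerical choices and degenerate inputs

* Chain breaks: consecutive CA–CA > 4.5 Å terminates all hydrogen-bond
  patterns; SSEs never span breaks.
* Donor clash (< 0.5 Å between bond atoms) is assigned the −9.9 kcal/mol
  sentinel (treated as bonded), matching common practice.
* Axis fitting needs ≥ 3 CA positions; the sign convention (positive
  projection on CA_last − CA_first) makes the axis orientation-stable, and
  the 90° orientation boundary is assigned to P so the classification is a
  closed half-interval.
* Terminal residues cannot be bridge partners (their three-residue stretch
  is incomplete), so strands lose up to two residues at each end relative
  to the generator's element spans; segment-boundary tests allow ±2.
* Altloc resolution: highest occupancy, ties by alphabetical identifier;
  multi-model files use the first model; MSE is read as MET; other
  non-standard residues are skipped with a warning.
* Drawing is deterministic by construction (circular cartoon layout, no
  timestamps), so re-rendering is byte-identical.

## Problem sizes

The test-suite and the acceptance script work at desk scale by design:
synthetic chains of 10–130 residues, 200 random topologies for the module
law, a 4 × 5 × (N+1) grid for the binomial oracle and 100 random vectors
for the FDR oracle, all completing in seconds on one CPU. The worked
database examples use 100 chains over 5 topologies; the pipeline itself is
O(n²) in residues per chain and linear in the number of chains, and the
same code path regenerates the analysis on any user-supplied structure set.

## Known limitations

* The built-in assigner is intentionally simplified; for publication-grade
  per-residue labels on real structures, run DSSP and import its output.
* Orientation is binary P/A at 90°; contacts near the boundary are
  sensitive to axis noise (the stored raw angle lets callers re-bin).
* Only intra-chain contacts are considered — no ligands, no inter-chain
  interfaces, no domain decomposition.
* Module matching is exact string equality; there is no approximate or
  subgraph search beyond the module windows themselves.
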