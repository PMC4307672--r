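---
title: "Detecting tandem ankyrin repeats from contact-network spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem ankyrin repeats from contact-network spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ankrep)
```

## The problem

Ankyrin (ANK) repeats are ~30–34-residue structural motifs: two antiparallel
α-helices followed by a loop that ends in a β-hairpin. Four to six copies
typically stack into an elongated solenoid. Because individual copies drift in
sequence while keeping their shape, sequence profiles often miss terminal or
degenerate copies; a structure-based detector does not. `ankrep` detects
tandem ANK repeats directly from the Cα geometry of a chain, with no sequence
model and no side-chain information.

## Model

**Contact network.** The chain's Cα atoms become the nodes of an undirected
graph; residues $i \ne j$ are joined when their Euclidean distance satisfies
$d_{ij} \le R_c$, with $R_c = 7.0$ Å (inclusive). At this cutoff the graph
captures both the chain backbone and the tertiary packing between stacked
repeat units, while staying sparse enough that packing differences show up in
the spectrum. The adjacency matrix $A$ is binary, symmetric, zero-diagonal.

**Centrality profile.** The principal eigenpair $AX = \lambda X$ gives a
per-residue profile: the component $X_i$ (returned as `levc`) is the
eigenvector centrality of residue $i$. For a connected network all components
can be taken nonnegative (Perron–Frobenius); `principal_eigenvector()` fixes
the sign so the component sum is positive, normalizes to unit Euclidean norm,
and rejects eigenpairs whose residual exceeds $10^{-8}\max(1, \lambda)$.
Components peak inside densely packed secondary-structure elements, and —
crucially for this fold — the *inner* helix of each repeat, which packs
against the neighbouring copies, scores higher than the *outer* helix.

**Secondary structure.** Detection needs a per-residue assignment pooled into
four classes: HELIX (α, 3₁₀ and π states), STRAND, TURN, COIL. Parsers are
provided for STRIDE output (`parse_stride()`) and classic DSSP output
(`parse_dssp()`), reconciled against the chain by author residue number plus
insertion code. When neither is available, `assign_internal()` assigns from
Cα geometry alone: residue $i$ is helical when $d_{i,i+3} \in [4.5, 6.5]$ Å
and $d_{i,i+4} \in [5.0, 7.0]$ Å (runs of ≥ 4), extended when
$d_{i,i+2} \in [6.4, 7.4]$ Å (runs of ≥ 3), and up to four unassigned
residues after a helix are labelled TURN. These windows bracket the ideal
α-helix (d₃ ≈ 5.0–5.5 Å, d₄ ≈ 6.2 Å) and fully extended chain (d₂ ≈ 6.7–7.0 Å)
with allowance for real-structure distortion.

## Detection rule set

Candidates are every pair of consecutive HELIX segments separated only by
TURN/COIL. A candidate (H1, turn, H2) is accepted as an ANK motif when all
four criteria hold:

1. **Antiparallel helices** (strict): $d(S_1, E_2) < d(E_1, E_2)$, where
   $S_1$/$E_1$ are the first helix's start/end and $E_2$ the second helix's
   end. In an antiparallel hairpin the second helix runs back toward the
   first helix's start.
2. **Buried first helix** (strict): mean `levc` over H1 exceeds the mean over
   H2. The arithmetic mean is used — it is the simplest statistic and both
   helices are short enough that robustness refinements change nothing.
3. **Peak spacing**: the signed distance between the profile peak of H2 and
   of H1 lies in $[5, 15]$ residues (inclusive; ties in a peak break toward
   the lower index).
4. **Core length**: the H1–turn–H2 core spans at least 13 residues.

The scan over candidates is greedy and left-to-right: an accepted motif
consumes both of its helices (repeats never share a helix) and scanning
resumes at the next helix after its H2; a rejected candidate advances by one
helix.

**Boundaries.** Each repeat starts 4 residues before H1 (clamped at residue
1, which flags the copy *terminal*). The end is the lowest-`levc` TURN
residue in the window after H2 — at most 15 residues, truncated at the next
repeat's start; if the window has no TURN its COIL residues are used; a
window that is empty or runs past the chain terminus ends the repeat at the
last residue (`chain_end`, also flagged terminal); an end that would collide
with the next repeat is pulled back to just before it (`clipped`).

**Tandem grouping.** Repeats whose consecutive gaps (residues strictly
between one repeat's end and the next one's start) stay within 17 residues —
about half a motif — form a region; regions with fewer than two repeats are
discarded. A lone helix-turn-helix is not a tandem repeat protein.

## Worked example

The package generates its own test folds, so the whole pipeline runs without
any input file:

```{r example}
spec <- ank_fixture_spec(n_copies = 4, seed = 1)
chain <- build_ank_fixture(spec)
net <- build_contact_network(chain, r_c = 7.0)
profile <- principal_eigenvector(net)
segments <- assign_internal(chain)
result <- detect_ank(chain, segments, profile)
result
```

`verify_detection()` re-checks every reported repeat against the raw inputs,
and `repeat_profile()` / `normalize_profile()` overlay the per-copy profiles
on a common 0–1 scale:

```{r verify}
verify_detection(result, chain, segments, profile)
```

For files on disk, `run_single()` wraps the full pipeline and
`write_outputs()` emits JSON, TSV, repeat-sequence FASTA and a PyMOL
colouring script; `run_batch()` scans many structures, skipping chains under
50 residues and chains with no helix or strand assigned.

## What the synthetic generator emulates

`build_ank_fixture()` stacks congruent helix-turn-helix-loop units on a
curved solenoid. Geometric choices, and why:

- **Copy layout**: 8-residue inner helix, 2-residue turn, 10-residue outer
  helix, 12-residue loop — a 32-residue copy, inside the observed 30–34
  range.
- **`stack_offset = 9.5` Å** between consecutive copies: the packing distance
  of adjacent repeat units. It controls the inter-copy coupling in the
  contact network; much looser stacks decouple the copies, and a nearly
  decoupled stack has near-degenerate top eigenvalues whose eigenvectors
  localize on single copies instead of spreading across the solenoid — real
  solenoids are tight, and so is the fixture.
- **Inner/outer asymmetry**: the inner helices sit on a tighter arc with the
  connecting loop packed against them, while the outer helix leans away at
  its N-terminal end. This reproduces the buried-H1/exposed-H2 contrast that
  criterion 2 reads; it is geometry, not a tuned profile.
- **Hairpin loop**: the loop dives below the copy and returns to just under
  the next copy's first helix, arriving along a vertical kink. Its depth
  grows with `loop_len` so the point spacing stays helix-unlike for long
  loops (used by the gap negative control).
- **Jitter**: seeded Gaussian noise (`jitter_sd = 0.05` Å) avoids exactly
  degenerate coordinates; the builder restores the caller's RNG state. A
  clash check rejects any spec whose non-bonded Cα pairs come closer than
  2.5 Å.

Real structures are messier than the fixture in every way the detector must
tolerate: assigner-dependent helix boundaries, variable copy lengths,
insertion codes, alternate conformations. Those paths are exercised by the
parser-level tests instead.

## Numerical choices and limitations

- Eigenpairs come from a full symmetric `eigen()` — chains are a few hundred
  residues, so dense $O(n^3)$ is cheap and avoids iteration-convergence
  tuning. The residual check guards the result regardless of backend.
- Superposition (`superpose_rmsd()`) is closed-form Kabsch with the
  determinant correction, so reflections are never used; unequal-length sets
  slide the shorter over the longer (ANK copies are near-constant length, so
  a window scan stands in for full fragment alignment).
- Thresholds live in `detection_params()` and every one can be overridden,
  but the defaults are the method: changing them changes what counts as an
  ANK repeat.
- The detector reports per requested chain only; multi-chain proteins are
  scanned one chain at a time.
- Disconnected contact networks (broken chains, far-apart domains) are
  detected and flagged; the profile then concentrates on the dominant
  component, and boundaries in other components should not be trusted.
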