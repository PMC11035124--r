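---
title: "Abundance-aware read re-assignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-aware read re-assignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsort)
```

## The problem

Strain-resolution profiling of a metagenomic sample starts from an
alignment of its reads against a reference database. Closely related
genomes share long identical stretches, so a large fraction of reads
aligns near-equally well to several references. Assigning every read to
its best-scoring alignment ("naive best-score") double-counts the
dominant strain and erases minor ones; discarding multi-mapped reads
throws away most of the signal. `strainsort` instead treats the read
counts a reference may receive as a budget derived from an abundance
estimate, and solves the resulting assignment problem greedily with a
provable local-improvement move.

## Mapping model

For read $r_i$ with alignment score $s_{ij}$ against reference $R_j$,
the mapping probability is the score-normalized

$$p_{ij} = \frac{s_{ij}}{T(r_i)}, \qquad T(r_i) = \sum_j s_{ij},$$

so each read's probabilities sum to 1 over the references it maps to.
Scores must be positive for this to be meaningful; if the score tag can
be non-positive (some aligners emit negative `AS` values), all scores
are shifted affinely by $-\min(s) + 1$ before normalization
(`collapse_multimappings()` does this and records the shift). For
paired-end data the mates' records are collapsed to one entry per
(fragment, reference) pair keeping the maximum score.

## Abundance EM

With abundances $\theta$ the likelihood of the observed reads is the
mixture

$$\ell(\theta) = \sum_{i=1}^{M} \log \sum_j \theta_j \, p_{ij},$$

maximized by the classical EM iteration
$\gamma_{ij} \propto \theta_j p_{ij}$,
$\theta_j' = \frac{1}{M}\sum_i \gamma_{ij}$.

**Equivalence classes.** The update is computed over classes of reads
keyed by their *(reference set, score profile)* pair, with class weight
matrix $W_{cj} = \sum_{i \in c} p_{ij}$. Keying on the reference set
alone — a common shortcut — is *not* exact: two reads mapping to the
same references with different score ratios have different
responsibilities, and averaging them inside one class changes the
trajectory. With the score profile in the key, every read in a class has
identical $p_{i\cdot}$, the class update factorizes exactly, and the
class EM reproduces the read-level EM to machine precision (this is
tested directly against an independent dense implementation).

**Set-cover filter.** Every `setcover_interval` iterations (default 10),
and once more on the final estimate, a greedy weighted set cover over
the equivalence classes is built (references in order of abundance, then
coverage, then id). References outside the cover — i.e. explaining no
class that the cover does not already explain — whose expected read
count $\theta_j M$ falls below one read-equivalent are deactivated
permanently and $\theta$ renormalized. This removes spurious relatives
that would otherwise siphon small amounts of abundance indefinitely.

Convergence is declared when $\max_j |\Delta\theta_j| <$ `tol`
(default $10^{-6}$), checked on the pre-filter update.

## Capacity-constrained re-assignment

Given the estimate $a = \theta$, each reference becomes a bin of
capacity $C_j = a_j + 1/M$ — each read occupies $1/M$, so at most one
read of over-assignment per reference — and contributes
$c_j = \operatorname{round}(a_j M)$ copies (half away from zero) to the
objective

$$F(x) \;=\; \sum_j \sum_{k=1}^{c_j} \prod_i (1 - p_{ij})^{x_{i,(j,k)}},$$

a min-sum variant of the weapon–target assignment problem: each copy is
a "target" that wants at least one confident read, an empty copy costs
1, and diminishing returns discourage piling reads onto one copy.

Reads are placed in three tiers:

1. **Unique mappers** go to their only reference unconditionally (the
   evidence admits no alternative, even if it overfills the bin).
2. **Clear winners** (second-best/best score ratio below `threshold`,
   default 0.5) go to their best reference if it has space, in order of
   best score; otherwise they are relabeled tier 3.
3. **The rest**: all (read, reference-with-space) mappings are pooled,
   sorted by score (ties: read id, then reference id), and walked once,
   placing each still-unplaced read where space remains.

**Open-up-space.** A read $r_i$ left over because every candidate bin is
full can still be placed if some full bin $R_j$ holds an occupant $r_k$
that can move to a non-full $R_l$ in its own mapping list with

$$p_{ij} - p_{kj} \;\ge\; p_{kj} - p_{kl}.$$

Executing such a swap never increases $F$: the copy losing $r_k$ and
gaining $r_i$ changes by a factor bounded using
$(1-p_{kj}) \ge (1-p_{ij}) + (p_{ij}-p_{kj})$, while $r_k$'s new copy
only improves. Occupants are scanned lowest-score first and the
destination maximizing $p_{kl}$ is tried for each. The test suite
verifies the non-increase on every executed swap across hundreds of
random instances. Reads for which no bin can open space are reported as
`UNASSIGNED` rather than forced somewhere misleading.

All stages break ties deterministically (score descending, then read id,
then reference id), so identical inputs give byte-identical outputs.

## The exact oracle

`brute_force_min()` minimizes $F$ exhaustively on instances of at most
8 reads × 4 references: every read-to-(reference or unassigned) map is
enumerated, and within each reference the assigned set is split
optimally across its copies by exhaustive set partition with symmetry
breaking. Note the per-read constraint is "at most one copy", with
multiple reads allowed to share a copy — this is the objective's own
feasible set. A stricter one-read-per-copy oracle would be *above* the
greedy solver on instances where tier-1 reads overfill a bin (two reads
unique to a one-copy reference must share it), so it could not serve as
a lower bound. Against this oracle, the greedy solver is verified never
to go below the minimum, and to attain it exactly whenever all reads map
uniquely (where greedy is trivially optimal).

## Synthetic communities

`community_spec()` / `simulate_alignment()` generate SAM text at the
*score level*: reads are drawn from the truth abundances by multinomial
sampling; an `ambiguity` fraction of reads also maps to the other
references in the source's group, with the source at a high score and
competitors at either the high or a low score (plus integer jitter).
This deliberately skips sequence-level realism (no bases, no errors, no
aligner) — the package's contract starts at scored alignments, and the
generator exercises exactly that interface, including secondary flags,
paired-end mate naming and unmapped records. Consequences: score
distributions are bimodal rather than aligner-shaped, and reference
length plays no role. Conclusions about absolute accuracy on real data
require real alignments; the simulator's job is correctness and
recovery-under-known-truth testing.

Default problem sizes in the tests (hundreds of tiny oracle instances,
communities of $10^3$–$10^4$ reads, 2–4 references) are the package's
own choice: large enough for sampling noise to be well below the
tolerances, small enough for the whole suite to run in well under a
minute.

## Evaluation

With a truth map and an optional taxonomy (`accession, taxid, species,
genus`), each assigned read is labeled TP or FP at strain, species and
genus rank; unassigned and unaligned reads are counted separately and
never as FP. Sensitivity, precision and F1 are reported on a 0–100
scale, along with the L1 distance between the assigned abundance profile
and the truth. TP counts are monotone from strain to genus by
construction.

## Limitations

- Score normalization assumes scores are comparable across references
  for the same read (true for a single aligner run, not across runs).
- Capacities derive from the EM point estimate; no uncertainty is
  propagated into the assignment.
- One open-up-space pass is the default; pathological instances can
  leave reads unassigned that further passes would place
  (`open_space_passes` raises this).
- The greedy solver carries no approximation guarantee relative to the
  global minimum of $F$ — only never-below-oracle, swap monotonicity and
  optimality on unique mappings are certified.
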