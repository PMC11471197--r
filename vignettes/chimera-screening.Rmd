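---
title: "Screening chimeric RNAs with junction probes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chimeric RNAs with junction probes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraScreen)
```

## The problem

Chimeric RNAs are hybrid transcripts that join exonic sequence from two
originally separate genes, arising through chromosomal rearrangement,
trans-splicing, or read-through (cis-SAGe) transcription into a same-strand
downstream neighbour. Callers such as EricScript nominate candidates from
RNA-seq, but raw candidate lists are dominated by events that are not
tissue-specific, not reproducible, or artefactual. chimeraScreen implements
the downstream screening stages that turn a candidate list into a
defensible, quantified marker set for a case/control cohort:

1. **Specificity filtering** against a background panel of chimeras
   observed across normal tissues (a GTEx-style catalog): any candidate
   whose ordered gene pair (5′→3′) appears in the panel is removed.
2. **Classification** of each surviving candidate by parental-gene
   location — *inter-chromosomal*, *intra-chromosomal*, or *read-through* —
   and by junction-site position — `E/E`, `E/M`, `M/E`, `M/M`, where `E`
   means the breakpoint coincides with an annotated exon edge and `M` means
   it falls in the middle of an exon. `M/M` candidates, which cannot use
   canonical splice sites on either side and validate poorly, are removed.
3. **Junction-probe matching**: a fixed-length probe (default 28 nt, 14 nt
   on each side of the breakpoint) is matched against every raw read of
   every sample with an approximate string matcher; the per-sample count of
   probe-bearing reads quantifies support for each chimera.
4. **Cohort comparison**: presence/absence, group-exclusive chimera sets,
   cross-cohort frequency comparison, marker sensitivity/specificity, and
   chromosome-level enrichment of parental genes.

## Coordinates and data contracts

Everything internal is **0-based half-open**. GTF exon records (1-based
closed) and caller breakpoints (1-based) are converted exactly once, at the
file boundary. A chimera call stores `breakpoint5` as the position of the
last transcribed base of the 5′ segment and `breakpoint3` as the first
transcribed base of the 3′ segment. Exon edges are strand-aware: the donor
edge of an exon (relevant for the 5′ side) is its transcription-3′
boundary — the genomic end on `+`, the genomic start on `-` — and the
acceptor edge (3′ side) is the transcription-5′ boundary.

EricScript-style junction sequences do not mark the breakpoint, so the
split index defaults to the midpoint of an even-length sequence; an
explicit `SplitIndex` column is honoured when present, and odd-length
unmarked sequences are rejected with a reported reason rather than
guessed at. This matches the symmetric 28-nt probe design downstream.

## The matcher

The matcher is a bit-parallel **bitap** scan (the algorithm behind agrep),
with two distance models:

* **Hamming** (default): counts alignment offsets where the probe matches a
  length-L read substring with at most *k* substitutions. `N` in a read
  never matches any probe base; probes containing `N` are excluded up
  front.
* **Edit**: Wu–Manber automata with insert/delete/substitute transitions;
  counts end positions within edit distance *k*.

Both orientations are searched by default (unstranded libraries cannot be
assumed away) and the counting unit is **reads with at least one
qualifying occurrence** — a read contributes at most once per probe, which
makes counts robust to tandem repeats, but may support several distinct
probes. Duplicate reads are counted as-is; junction support here is a raw
match count, not a deduplicated molecule count.

Defaults worth knowing:

| parameter | default | why |
|---|---|---|
| `k` | 0 | exact matching is agrep's default and the strictest choice; exposed via `--k` |
| `distance_model` | hamming | substitution-only errors dominate Illumina data; edit model available |
| `probe_length` | 28 nt | 14-base anchors on each side of the junction |
| `min_flank` | 0 | the probe itself already enforces 14-base anchors |
| `search_reverse_complement` | on | library strandedness unknown |

Every probe/read scan has an independent brute-force twin (`naive_count()`:
sliding-window Hamming scan, semi-global DP for edit distance) kept free of
any bitap machinery; the test suite checks exhaustive agreement on a small
alphabet and randomized agreement on 10,000 instances with embedded mutated
probe copies. Probe length is limited to 64 (one machine word); the default
28 is well inside.

## Classification rules

*Location.* Different chromosomes → inter-chromosomal. Same chromosome →
read-through iff the strands agree, the 3′ partner lies downstream of the
5′ partner in the shared transcription direction, and the intergenic gap is
at most `readthrough_gap`. Otherwise intra-chromosomal. The gap threshold
defaults to **50 kb**: read-through/cis-SAGe conventionally means
neighbouring same-strand genes, and a finite default makes the label
decidable; the threshold is configurable, and the read-through set is
provably monotone (non-decreasing) in it.

*Junction site.* `E` requires exact coincidence with a strand-aware splice
edge (`edge_tolerance = 0` by default; small tolerances are supported for
imprecise callers). A breakpoint outside its stated gene is flagged
`outside-gene` and conservatively labelled `M`.

*Filter order.* The background-panel filter runs before classification and
the MM filter, so each removed call has exactly one removal reason and the
accounting identity `n_input = n_retained + n_removed_panel + n_removed_mm`
holds exactly.

*Panel matching* defaults to ordered gene-pair keys (A→B is not B→A);
normal-tissue chimera catalogs are typically gene-pair level. A breakpoint
mode with a coordinate tolerance exists for stricter work.

## Cohort statistics

Presence is `count >= threshold` with threshold 1: any detection counts,
matching the use of junction-read evidence as a presence call. Group
exclusivity is strict — present in at least one sample of one group and in
**zero** samples of the other; the four sets (case-exclusive,
control-exclusive, shared, absent) partition the chimera universe.

Marker performance treats presence as the test and group as truth;
percentages are rounded half away from zero at one decimal, so 11 of 12
positive cases reports a sensitivity of 91.7%.

Chromosome enrichment uses a one-sided binomial test per chromosome —
observed parental-gene count out of all parental genes against the
background proportion of annotated genes on that chromosome — with
Benjamini–Hochberg correction across chromosomes. Parental genes are
deduplicated per side. No specific test is canonical for this question;
the binomial choice is the minimal defensible one and is isolated behind
one function. The cross-cohort frequency comparison is deliberately
descriptive (totals, positive-sample tallies, and a direction-consistency
flag); the package does not invent a significance test where none is
established.

## The synthetic universe

`simulate_dataset()` generates everything the pipeline consumes, with a
truth ledger, so every downstream stage can be tested against a known
answer without external data. The stated world:

* **Cohort**: 4 case + 4 control samples — the smallest realistic
  discovery design for this kind of screen and the default the package
  tests against.
* **Genome**: 4 chromosomes, 40 multi-exon genes (3–6 exons of 80–200 bp,
  introns 100–400 bp), i.i.d. uniform ACGT.
* **Chimeras**: 30 planted, location mix 50% inter / 46% intra / 4%
  read-through and junction mix 55/30/7.5/7.5 over EE/EM/ME/MM — chosen so
  that, as in real placenta screens, ~96% of events are
  inter-/intra-chromosomal and ~85% of 5′ breakpoints sit on exon edges.
  Mixes are met *exactly* via largest-remainder rounding. `E` breakpoints
  sit exactly on exon edges; `M` breakpoints at least 2 bases inside an
  exon.
* **Reads**: length 100, per-base substitution error 0.002 by default
  (Illumina-like; set to 0 for exact-recovery tests), 1000 background reads
  per sample drawn uniformly from normal transcripts, junction-spanning
  reads per expressed chimera per sample ~ Poisson(3) with a ≥14-base
  anchor on each side of the breakpoint, ~50% of reads emitted
  reverse-complemented.
* **Guarantees**: every planted 28-nt junction probe is verified absent
  (at the default mismatch setting, both orientations) from the genome,
  all normal transcripts and all other chimeric transcripts — re-drawn
  otherwise — so with error-free reads the match table equals the realized
  coverage ledger cell-for-cell and decoy probes count exactly zero.
  `ensure_min_coverage` guarantees at least one junction read per
  expressed group, making exclusivity recovery exact rather than
  exact-with-high-probability.

What the generator does **not** emulate: realistic expression
distributions, GC or positional bias, quality-score structure, indels,
fragment-length effects, or caller false positives. A green recovery test
therefore establishes the correctness of the screening arithmetic — not
the sensitivity of the upstream caller, and not performance under indel
error, which the edit-distance model handles but the generator does not
produce by default.

Determinism: `simulate_genome()` seeds the RNG from the config;
the later stages consume the stream that follows, so the staged pipeline
is byte-reproducible under one seed. Two full CLI runs with the same seed
and different `--threads` produce byte-identical data outputs (the
`run_*.json` provenance files record the run's own context, including the
thread count, and are exempt by design).

## Numerical and degenerate-input choices

* Mix proportions must sum to 1 within 1e-9; counts are apportioned by
  largest-remainder rounding with ties broken by position.
* An empty call table is a valid input (header-only outputs, exit 0), as
  is a panel that removes everything (warning, exit 0).
* Rejected call rows (unparseable coordinates, odd unmarked junctions,
  invalid strands) are reported with reasons, never silently dropped.
* `bitap_count` requires `k < L` and `L <= 64`; violations are parameter
  errors, not silent truncation.
* Percentage rounding is half away from zero at one decimal — chosen to
  reproduce standard clinical-sensitivity reporting (11/12 → 91.7%).
* CLI exit codes: 0 success, 1 runtime/validation failure, 2 usage or
  configuration error.

## Known limitations

* Probe construction assumes the caller's junction sequence is centred on
  the breakpoint (or re-extracts from the genome); callers with asymmetric
  junction output need the `SplitIndex` column.
* The matcher is read-level and alignment-free; it cannot distinguish a
  genuine junction read from a read that contains the probe sequence for
  other reasons (the generator's uniqueness guarantee makes this
  impossible *in simulation*, not in real genomes).
* Read-through classification depends on annotation completeness; missing
  parent genes fall back to call coordinates and are flagged.
* `--threads` currently partitions work but executes sequentially; results
  are defined to be identical regardless, so this is a performance
  limitation, not a correctness one.
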