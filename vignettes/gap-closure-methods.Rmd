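---
title: "Gap closure from flanking contig alignments: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap closure from flanking contig alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfillr)
```

## The problem

Scaffolders join assembled contigs into ordered, oriented scaffolds and
represent the unknown sequence between neighbours as runs of `N` sized
by insert estimates. Finishing reduces these gaps. One productive source
of gap sequence is the assembly itself: assemblers routinely emit
contigs that overlap scaffold joins but were not used in them, so a
contig aligning across — or to both flanks of — a gap carries the very
sequence the scaffold is missing. `gapfillr` systematises that
observation: align contigs to scaffolds, search for same-contig
alignments flanking each gap, rank the candidate fills, and apply the
accepted ones under a curator's control or automatically.

Everything internal uses 0-based half-open coordinates; the
user-facing change log and review file use 1-based inclusive
coordinates, matching what BLAST-facing users expect. Conversion
happens only at parse and report boundaries.

## Gap model and accounting

A *gap* is a maximal run of `N` in a scaffold. `find_gaps()` reports
all maximal runs of length at least `min_gap_len`; `gap_stats()` counts
gaps (`n_gaps`) and every `N` character (`n_N`). Two deliberate
asymmetries:

* `n_N` counts all Ns, even in runs below `min_gap_len`, so that the
  before/after difference always equals the total ambiguity removed.
* `min_gap_len` defaults to 1 — the assumption-free reading of an N-run
  count. Assemblers that emit single-N sentinels can be accommodated by
  raising it, which never changes `n_N` and can only lower `n_gaps`.

Gaps touching sequence ends are counted: they are real ambiguity,
although two-sided closure cannot reach them (no second flank exists;
only one-sided reduction can).

## Alignment sources and the internal hit format

Three routes produce the same normalized hit table (query = contig,
subject = scaffold, ascending intervals on forward strands, orientation
in a `strand` column):

1. **BLAST tabular** (`outfmt 6` / legacy `-m 8`), where a descending
   subject interval encodes the minus strand;
2. **nucmer** `show-coords -T` with its standard header, where a
   descending query interval encodes the minus strand — exactly one
   dialect is accepted and anything else is rejected with a message,
   rather than silently misparsed;
3. the **built-in aligner**.

The built-in aligner is a deterministic seed-and-extend scheme: index
every scaffold k-mer not containing `N` (default k = 21), collect exact
seed matches for each contig and its reverse complement, group them by
diagonal, greedily merge co-diagonal seed blocks while the merged
segment's mismatch rate stays within `max_mismatch_rate` (default 0.05)
and no `N` is crossed, then extend each merged segment base by base —
first rightward, then leftward, with the running mismatch rate
accumulated across both phases — stopping at the first position where
the rate would be exceeded or an `N` appears on either sequence.
Segments shorter than `min_hit_len` (default 31) are dropped, as are
hits wholly contained in a higher-scoring hit on the same diagonal.

The aligner is intentionally *ungapped*: closure needs precise
endpoints at gap flanks more than indel tolerance, and an ungapped hit
gives an exact positional map between scaffold and contig coordinates.
Indel-rich data should be aligned externally and ingested through the
parsers; candidates from parsed hits with indels fall back to whole-hit
intervals rather than positional mapping. The right-then-left extension
order is fixed purely for determinism; the two orders differ only in
rare boundary cases near the mismatch-rate limit.

## Candidate definitions

With flank length $F$ (default 11), edge tolerance $d$ (default 10) and
identity threshold $I$ (default 95%), for each gap $[g_s, g_e)$:

* **span**: a hit covering $[g_s - F, g_e + F]$. The replaced interval
  is exactly $[g_s - F, g_e + F)$ for ungapped hits — the gap plus $F$
  aligned flank bases on each side — so the fill's junctions land inside
  trusted, aligned sequence.
* **pair**: hits $L, R$ of one contig and strand with
  $L_{s\_end} \in [g_s - d,\; g_s]$, $R_{s\_start} \in [g_e,\; g_e + d]$,
  each with $\ge F$ aligned bases, and contig intervals ordered
  consistently with the strand. Replaced: $[L_{s\_end}, R_{s\_start})$;
  fill: the contig segment strictly between the inner contig endpoints.
  Any unaligned sliver inside the edge tolerance is consumed by the
  replacement, so no untrusted scaffold base survives adjacent to a
  fill. An empty fill is legal and contracts the join (`delta_len < 0`).
* **extends** (if `allow_reduction`): a one-sided flanking hit whose
  contig overhangs $\ge 1$ base past the gap edge replaces that many Ns
  from one side, clamped at the far gap edge.

Flank length is interpreted as *minimum aligned support immediately
adjacent to the gap on each side*: together with the identity threshold
it is the stringency knob of the method. Candidates whose fill contains
`N` are dropped by default (`reject_ambiguous_fill`), which is what
makes the N count provably non-increasing.

### Ranking, selection, application

Within a gap, candidates sort by kind priority (span = pair before
extends), mean supporting identity (descending), total flank support
(descending), $|{\rm fill} - {\rm gap}|$ length discordance
(ascending), then contig id and strand — a total, deterministic order.
The ranking criteria are declared and fixed rather than learned;
identical inputs always produce byte-identical outputs.

Selection is greedy in gap order: each gap takes its best candidate
whose replaced interval does not overlap an already-accepted one on the
same scaffold, falling back down its ranked list, possibly to none.
Accepted fills are spliced right-to-left per scaffold, so one pass
suffices and no re-alignment between fills is needed — one alignment
round per run. Each splice becomes a change-log event carrying original
coordinates, `delta_N` (signed change in N count; negative when Ns are
removed) and `delta_len`. Candidate tables instead carry
`predicted_delta_N` as the positive count of Ns a fill would remove;
the two conventions match their respective reports (a prediction of
benefit versus a signed ledger delta).

## Curation

The review file replaces an interactive accept/reject step with a
diffable TSV: one row per candidate grouped by gap, with a `decision`
column. Export pre-marks the rows the automatic selector would accept —
including its conflict fallbacks — so an unedited round-trip is
behaviorally identical to the automatic mode (the same events and the
same FASTA, byte for byte; this is asserted in the test suite).
Candidate ids are derived from content (scaffold, gap, contig, strand,
kind, coordinates), not row position, so edited files survive
re-export. Two ACCEPTs on one gap are a hard error; an ACCEPT that
conflicts with an earlier gap's accepted interval is dropped with a
warning, mirroring the automatic selector's resolution rather than
failing a whole curated run.

## The simulator: what it emulates and what it does not

`simulate_dataset()` builds the validation world: an i.i.d. random
reference at a chosen GC (default 0.5), `n_gaps = 10` internal
intervals of 50–500 bp masked with Ns, one spanning contig per gap
(`contig_overhang = 300` bp of true flank on each side,
reverse-complemented with probability 0.5, substituted at `error_rate`)
and 5 decoys drawn from an independent random sequence. The defaults
are sized like a small bacterial finishing problem scaled to desk
runtime: a 50 kb reference with ten sub-kilobase gaps exercises every
code path (both strands, both flanks, decoy rejection) while a full
pipeline run takes well under a second. Masks are length-preserving by
default, as when a scaffolder's insert estimate is exact; `gap_len_bias`
perturbs the N-run length to exercise contracting and expanding fills.

What it deliberately does not emulate: indel sequencing errors (the
built-in aligner is ungapped, so the substitution-only error model
matches the aligner's scope — indel robustness enters via external
alignments, not the simulator), repeats shared between contigs and
distant scaffold loci, chimeric contigs, and coverage-dependent error
profiles. Passing recovery tests therefore demonstrate the *method's*
correctness — flank discovery, coordinate arithmetic, strand handling,
splicing, ledger consistency — not robustness to every artifact of real
draft assemblies; real data additionally depends on the chosen aligner
and thresholds.

`evaluate_recovery()` scores a run without re-alignment: the change
log's coordinate ledger maps each replaced interval into the filled
sequence (cumulative `delta_len` of events to its left), and into the
reference (piecewise-linear map through the masks, exact when the fill
restores reference-length sequence). Masked positions whose fill length
disagrees with the corresponding reference span are compared over the
common prefix and the remainder is counted as evaluated-but-incorrect —
a conservative convention that cannot overstate accuracy. Reported
accuracy is over masked positions actually filled; an untouched run has
no evaluated bases and reports `NA` rather than a misleading 100%.

## Numerical and degenerate-input choices

* Residues are uppercased on input; IUPAC ambiguity codes are accepted
  and treated as non-N, non-matching; `-` characters are rejected to
  surface upstream errors.
* A gap at a sequence end yields only one-sided candidates; a scaffold
  without Ns, an empty hit table, or an all-REJECT review are all valid
  no-op paths.
* Coordinates in hit tables are validated (`c_start < c_end`,
  `s_start < s_end`, identity in [0, 100]) at every module boundary.
* Ties everywhere break on lexicographic ids, then strand (`+` before
  `-`), making every output reproducible across platforms.

## Test and validation problem sizes

The test suite validates candidate discovery against an independent
brute-force enumeration (260 random instances of up to 50 hits across
the unit and acceptance suites), end-to-end recovery on 20 error-free
replicates at the default conditions (100% closure, 100% base
accuracy), ledger conservation and N-monotonicity across fuzzed
conditions including substitution errors and biased mask lengths, and
byte-identity of the curated and automatic routes. The acceptance
script repeats the recovery measurement from scratch — 20 error-free
replicates plus 5 replicates at 1% substitutions — and writes the
measured rates as JSON; at 1% contig errors the filled bases carry the
contigs' own substitutions, so base accuracy settles near 99% while the
closure rate stays at 100%.

## Known limitations

* No iterative re-alignment after filling: a fill that creates a new
  flanking opportunity for a neighbouring gap is only found by running
  the tool again.
* The built-in aligner will not bridge indels; its hits stop at the
  first disagreement cluster exceeding the mismatch-rate budget.
* Paired-read evidence, AGP round-trips and scaffolding itself are out
  of scope; the tool trusts the input scaffold's structure.
* Span fills replace the gap *plus* its trusted flanks; users who need
  strictly-Ns-only edits can reconstruct them from the change log,
  which records exact replaced intervals.
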