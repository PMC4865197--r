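# gapfillr

Headless gap closure for draft genome scaffolds.

Draft assemblies order and orient contigs into scaffolds, bridging the
unknown sequence between neighbouring contigs with runs of `N`. These
N-runs — *gaps* — are an accounting unit of assembly completeness: a
finishing step tries to replace them with real sequence. `gapfillr`
closes gaps from the assembly's own contigs: if the same contig aligns
to both flanks of a gap (or spans it outright), the contig sub-sequence
between the flanking alignments is a candidate replacement for the Ns.

The package is a library plus a command-line tool. It detects gaps,
ingests contig-versus-scaffold alignments (BLAST tabular, nucmer
`show-coords -T`, or a built-in seed-and-extend aligner), proposes and
ranks fill candidates, applies accepted fills with a change log, and
reports the two standard finishing metrics — #Gaps and #N — before and
after. Manual curation is a first-class step: candidates are exported as
a reviewable TSV whose accept/reject decisions drive the final
application, so an automatic run and a curated run share one code path.

## Method

For a scaffold *S* with a gap *g* = [*g.start*, *g.end*) and a set of
local alignments (HSPs) of contigs against *S*, all in 0-based
half-open coordinates with orientation carried by a strand flag:

* **span** — one hit covering [*g.start* − *F*, *g.end* + *F*], where
  *F* is the flank length (default **11**): the replaced interval is the
  gap plus its *F* trusted flank bases, and the fill is the positionally
  mapped contig sub-interval (for ungapped hits; whole-hit intervals
  otherwise).
* **pair** — two hits of the same contig and strand, one ending within
  *d* bases of the left gap edge (default *d* = 10) with ≥ *F* aligned
  bases, one starting within *d* of the right edge likewise, contig
  intervals ordered consistently with the strand. The scaffold between
  the two inner hit ends is replaced by the contig segment between the
  two inner contig endpoints; an empty segment contracts the gap away.
* **left_extend / right_extend** — a one-sided flanking hit whose contig
  overhangs into the gap replaces a prefix or suffix of the Ns (gap
  *reduction* rather than closure).

Every supporting hit must reach a minimum identity (default **95%**).
Candidates are ranked within each gap (full-closure kinds first, then
identity, flank support, fill-versus-gap length concordance, with
deterministic tie-breaks), then selected greedily in gap order under a
no-overlapping-replacements constraint, and spliced right-to-left per
scaffold so coordinates stay valid in a single pass. Every splice is
logged with its original coordinates, `delta_N` and `delta_len`; the
log totals always reconcile with the before/after #Gaps/#N accounting.

A built-in simulator generates ground-truth fixtures — a random
reference, a scaffold with masked intervals, spanning contigs (either
strand, optional substitution errors) and decoy contigs — and
`evaluate_recovery()` scores a closure run base-by-base against the
truth through the change-log coordinate ledger.

## Worked example

```r
library(gapfillr)

truth <- simulate_dataset(seed = 42, genome_len = 20000, n_gaps = 5,
                          gap_len_range = c(50, 200), contig_overhang = 250)
gap_stats(list(truth$scaffold))
#> gap statistics (min gap length 1)
#>   records: 1   #Gaps: 5   #N: 701

hits  <- sort_hits(builtin_align(truth$contigs, list(truth$scaffold)))
gaps  <- find_gaps_all(list(truth$scaffold))
cands <- rank_candidates(find_candidates(gaps, hits, list(truth$scaffold),
                                         truth$contigs))
res   <- apply_fills(list(truth$scaffold), truth$contigs, select_auto(cands))
res$events[, c("gap_index", "action", "contig_id", "strand", "kind", "delta_N")]
#>   gap_index action contig_id strand kind delta_N
#> 1         4 closed  contig_5      - pair    -171
#> 2         3 closed  contig_4      - pair    -195
#> 3         2 closed  contig_3      + pair    -123
#> 4         1 closed  contig_2      - pair    -114
#> 5         0 closed  contig_1      - pair     -98

evaluate_recovery(res$scaffolds, truth, res$events)$totals
#> $n_gaps    [1] 5
#> $closed    [1] 5
#> $reduced   [1] 0
#> $untouched [1] 0
#> $n_removed [1] 701
#> $accuracy_pct [1] 100
```

All five gaps are closed by flanking alignment pairs (four of them from
reverse-complemented contigs), 701 Ns are removed, and every filled base
matches the reference the scaffold was simulated from.

The same pipeline from a shell, with curation in the middle:

```sh
gapfillr simulate   --seed 42 --out sim/
gapfillr candidates --scaffolds sim/scaffold.fasta --contigs sim/contigs.fasta --out review/
# edit review/candidates.tsv: set decision = ACCEPT / REJECT per row
gapfillr apply      --scaffolds sim/scaffold.fasta --contigs sim/contigs.fasta \
                    --review review/candidates.tsv --out filled/
gapfillr stats      --out compare.tsv sim/scaffold.fasta filled/filled.fasta
```

`gapfillr close` runs the automatic route (equivalent to `candidates`
followed by an unedited `apply`); `--aligner blast-tab:FILE` or
`--aligner nucmer-coords:FILE` substitutes a precomputed alignment for
the built-in aligner. The script itself is installed at
`system.file("scripts/gapfillr", package = "gapfillr")`.

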