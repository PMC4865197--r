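# Shared fixtures: tiny records, random closure instances, and a one-call
# closure pipeline used across test files.

rec <- function(id, residues, description = "") {
  seq_record(id, residues, description = description)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run the whole closure pipeline on in-memory records
close_pipeline <- function(scaffolds, contigs, params = closure_params(),
                           hits = NULL) {
  if (is.null(hits)) hits <- builtin_align(contigs, scaffolds)
  hits <- sort_hits(hits)
  gaps <- find_gaps_all(scaffolds, min_gap_len = params$min_gap_len)
  candidates <- rank_candidates(
    find_candidates(gaps, hits, scaffolds, contigs, params))
  accepted <- select_auto(candidates, params)
  res <- apply_fills(scaffolds, contigs, accepted)
  list(gaps = gaps, hits = hits, candidates = candidates,
       accepted = accepted, filled = res$scaffolds, events = res$events,
       before = gap_stats(scaffolds, min_gap_len = params$min_gap_len),
       after = gap_stats(res$scaffolds, min_gap_len = params$min_gap_len))
}

# a random small closure instance: one gapped scaffold, a few contigs, and
# synthetic hits with arbitrary (not sequence-derived) coordinates. Used
# for oracle-equivalence and property checks on candidate discovery.
random_instance <- function(seed, max_hits = 50L) {
  set.seed(seed)
  slen <- sample(300:700, 1)
  sres <- strsplit(random_dna_str(slen), "")[[1]]
  n_runs <- sample(1:3, 1)
  for (r in seq_len(n_runs)) {
    gstart <- sample(30:(slen - 80), 1)
    glen <- sample(5:40, 1)
    sres[gstart:(gstart + glen - 1)] <- "N"
  }
  scaffold <- seq_record("s1", paste(sres, collapse = ""))
  n_contigs <- sample(3:6, 1)
  contigs <- lapply(seq_len(n_contigs), function(i) {
    len <- sample(60:250, 1)
    res <- strsplit(random_dna_str(len), "")[[1]]
    # occasionally salt a contig with an N so ambiguous-fill rejection fires
    if (runif(1) < 0.3) res[sample(len, 1)] <- "N"
    seq_record(sprintf("c%d", i), paste(res, collapse = ""))
  })
  n_hits <- sample(0:max_hits, 1)
  hits <- lapply(seq_len(n_hits), function(i) {
    ctg <- contigs[[sample(n_contigs, 1)]]
    span_s <- sample(12:60, 1)
    positional <- runif(1) < 0.5
    span_c <- if (positional) span_s else sample(12:60, 1)
    span_c <- min(span_c, ctg$length)
    span_s <- min(span_s, scaffold$length)
    s_start <- sample(0:(scaffold$length - span_s), 1)
    c_start <- sample(0:(ctg$length - span_c), 1)
    data.frame(contig_id = ctg$id, scaffold_id = "s1",
               c_start = c_start, c_end = c_start + span_c,
               s_start = s_start, s_end = s_start + span_s,
               strand = sample(c("+", "-"), 1),
               identity = round(runif(1, 85, 100), 2),
               aln_len = max(span_s, span_c),
               score = round(runif(1, 10, 100), 1),
               stringsAsFactors = FALSE)
  })
  hits <- if (n_hits) do.call(rbind, hits) else
    builtin_align(list(), list())
  list(scaffolds = list(scaffold), contigs = contigs,
       hits = sort_hits(hits))
}

# hand-built candidate row for selector/ranking tests
make_candidate <- function(scaffold_id = "s1", gap_index = 0L,
                           gap_start = 10L, gap_end = 20L,
                           contig_id = "c1", strand = "+", kind = "pair",
                           replace_start = gap_start, replace_end = gap_end,
                           fill_c_start = 0L,
                           fill_c_end = replace_end - replace_start,
                           mean_identity = 100,
                           flank_support_left = 20L,
                           flank_support_right = 20L,
                           predicted_delta_N = gap_end - gap_start) {
  data.frame(scaffold_id = scaffold_id, gap_index = gap_index,
             gap_start = gap_start, gap_end = gap_end,
             gap_len = gap_end - gap_start, contig_id = contig_id,
             strand = strand, kind = kind, replace_start = replace_start,
             replace_end = replace_end, fill_c_start = fill_c_start,
             fill_c_end = fill_c_end,
             fill_len = fill_c_end - fill_c_start,
             mean_identity = mean_identity,
             flank_support_left = flank_support_left,
             flank_support_right = flank_support_right,
             predicted_delta_N = predicted_delta_N, status = "proposed",
             stringsAsFactors = FALSE)
}
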