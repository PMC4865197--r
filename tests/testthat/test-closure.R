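test_that("no hits means no candidates; unknown ids are reported", {
  scaffold <- seq_record("s1", "ACGTNNNNACGTACGTACGT")
  contig <- seq_record("c1", "ACGTACGTACGTACGT")
  gaps <- find_gaps_all(list(scaffold))
  empty <- builtin_align(list(), list())
  expect_equal(nrow(find_candidates(gaps, empty, list(scaffold),
                                    list(contig))), 0)

  h <- data.frame(contig_id = "cX", scaffold_id = "s1", c_start = 0L,
                  c_end = 10L, s_start = 0L, s_end = 10L, strand = "+",
                  identity = 100, aln_len = 10L, score = 10,
                  stringsAsFactors = FALSE)
  expect_error(find_candidates(gaps, h, list(scaffold), list(contig)),
               "unknown contig id.*cX")
  h$contig_id <- "c1"; h$scaffold_id <- "sX"
  expect_error(find_candidates(gaps, h, list(scaffold), list(contig)),
               "unknown scaffold id.*sX")
})

test_that("an exact spanning contig yields a candidate that restores truth", {
  set.seed(21)
  ref <- random_dna_str(300)
  masked <- paste0(substr(ref, 1, 100), strrep("N", 20), substr(ref, 121, 300))
  scaffold <- seq_record("s1", masked)
  contig <- seq_record("c1", substr(ref, 61, 160))  # spans the gap
  pipe <- close_pipeline(list(scaffold), list(contig))
  expect_gt(nrow(pipe$candidates), 0)
  expect_equal(nrow(pipe$accepted), 1)
  expect_equal(pipe$accepted$predicted_delta_N, 20)
  expect_identical(pipe$filled[[1]]$residues, ref)
  expect_equal(pipe$events$delta_N, -20)
})

test_that("find_candidates matches brute-force enumeration on random instances", {
  params_pool <- list(
    closure_params(),
    closure_params(flank_len = 5, max_edge_distance = 3),
    closure_params(min_identity = 90, allow_reduction = FALSE),
    closure_params(reject_ambiguous_fill = FALSE))
  for (s in 1:60) {
    inst <- random_instance(seed = 5000 + s, max_hits = 50)
    params <- params_pool[[(s %% length(params_pool)) + 1]]
    gaps <- find_gaps_all(inst$scaffolds, min_gap_len = params$min_gap_len)
    got <- find_candidates(gaps, inst$hits, inst$scaffolds, inst$contigs,
                           params)
    want <- oracle_candidates(gaps, inst$hits, inst$scaffolds,
                              inst$contigs, params)
    expect_identical(canonical_candidates(got), canonical_candidates(want))
  }
})

test_that("ranking follows the declared key and is a total order", {
  a <- make_candidate(contig_id = "c1", mean_identity = 100)
  b <- make_candidate(contig_id = "c2", mean_identity = 96)
  r <- rank_candidates(rbind(b, a))
  expect_equal(r$mean_identity, c(100, 96))
  expect_equal(r$rank, c(1, 2))

  # identical metrics: contig id breaks the tie
  d <- make_candidate(contig_id = "c2")
  r2 <- rank_candidates(rbind(d, make_candidate(contig_id = "c1")))
  expect_equal(r2$contig_id, c("c1", "c2"))

  # extends rank below full-closure kinds regardless of identity
  e <- make_candidate(kind = "left_extend", mean_identity = 100,
                      replace_end = 15, fill_c_end = 5)
  p <- make_candidate(kind = "pair", mean_identity = 95)
  r3 <- rank_candidates(rbind(e, p))
  expect_equal(r3$kind, c("pair", "left_extend"))

  # total order: any permutation sorts to the same list
  set.seed(77)
  pool <- do.call(rbind, lapply(1:8, function(i) {
    make_candidate(contig_id = sample(c("c1", "c2", "c3"), 1),
                   strand = sample(c("+", "-"), 1),
                   kind = sample(c("span", "pair", "left_extend"), 1),
                   mean_identity = sample(c(95, 98, 100), 1),
                   flank_support_left = sample(c(11, 30), 1),
                   fill_c_end = sample(5:15, 1))
  }))
  pool <- unique(pool)
  ranked <- rank_candidates(pool)
  for (i in 1:5) {
    perm <- pool[sample(nrow(pool)), , drop = FALSE]
    rownames(perm) <- NULL
    expect_equal(rank_candidates(perm), ranked)
  }
})

test_that("select_auto takes the top candidate and avoids overlaps", {
  cands <- rank_candidates(rbind(
    make_candidate(contig_id = "c1", mean_identity = 100),
    make_candidate(contig_id = "c2", mean_identity = 98),
    make_candidate(contig_id = "c3", mean_identity = 96)))
  acc <- select_auto(cands)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$contig_id, "c1")
  expect_equal(acc$status, "accepted")

  # two adjacent gaps with conflicting top candidates: the leftmost gap
  # wins; the second falls back to its non-conflicting alternative
  g1_top <- make_candidate(gap_index = 0L, gap_start = 10L, gap_end = 20L,
                           contig_id = "c1", replace_start = 8L,
                           replace_end = 32L, mean_identity = 100)
  g2_top <- make_candidate(gap_index = 1L, gap_start = 30L, gap_end = 40L,
                           contig_id = "c1", replace_start = 28L,
                           replace_end = 42L, mean_identity = 100)
  g2_alt <- make_candidate(gap_index = 1L, gap_start = 30L, gap_end = 40L,
                           contig_id = "c2", replace_start = 32L,
                           replace_end = 42L, mean_identity = 97)
  acc2 <- select_auto(rank_candidates(rbind(g1_top, g2_top, g2_alt)))
  expect_equal(nrow(acc2), 2)
  expect_equal(acc2$contig_id, c("c1", "c2"))

  # property: accepted replaced intervals never overlap
  for (s in 1:20) {
    inst <- random_instance(seed = 7000 + s, max_hits = 40)
    gaps <- find_gaps_all(inst$scaffolds)
    acc <- select_auto(rank_candidates(
      find_candidates(gaps, inst$hits, inst$scaffolds, inst$contigs,
                      closure_params(flank_len = 5, max_edge_distance = 5))))
    if (nrow(acc) > 1) {
      ord <- order(acc$replace_start)
      expect_true(all(acc$replace_end[ord][-nrow(acc)] <=
                        acc$replace_start[ord][-1]))
    }
    # at most one accepted candidate per gap
    expect_false(any(duplicated(paste(acc$scaffold_id, acc$gap_index))))
  }
})

test_that("apply_fills splices replacements and reverse-complements minus fills", {
  scaffold <- seq_record("s", "AACCNNNGGTT")
  cand <- make_candidate(scaffold_id = "s", gap_start = 4L, gap_end = 7L,
                         contig_id = "c", replace_start = 4L,
                         replace_end = 7L, fill_c_start = 0L,
                         fill_c_end = 3L)
  cand$status <- "accepted"
  res <- apply_fills(list(scaffold), list(seq_record("c", "TTT")), cand)
  expect_equal(res$scaffolds[[1]]$residues, "AACCTTTGGTT")
  expect_equal(res$events$delta_N, -3)
  expect_equal(res$events$delta_len, 0)
  expect_equal(res$events$action, "closed")

  cand_m <- cand
  cand_m$strand <- "-"
  res_m <- apply_fills(list(scaffold), list(seq_record("c", "AAA")), cand_m)
  expect_equal(res_m$scaffolds[[1]]$residues, "AACCTTTGGTT")

  # overlapping accepted fills are refused
  two <- rbind(cand, transform(cand, replace_start = 5L, replace_end = 8L,
                               fill_c_end = 3L))
  expect_error(apply_fills(list(scaffold), list(seq_record("c", "TTT")), two),
               "overlapping")

  # out-of-bounds fill interval is refused
  oob <- transform(cand, fill_c_end = 99L)
  expect_error(apply_fills(list(scaffold), list(seq_record("c", "TTT")), oob),
               "out of contig bounds")
})

test_that("full pipeline restores the reference on error-free simulations", {
  truth <- simulate_dataset(seed = 8)
  pipe <- close_pipeline(list(truth$scaffold), truth$contigs)
  expect_identical(pipe$filled[[1]]$residues, truth$reference$residues)
  # conservation: outside replaced intervals bases are unchanged
  ev <- pipe$events[order(pipe$events$replace_start), ]
  shift <- 0L
  pos <- 1L
  for (i in seq_len(nrow(ev))) {
    seg_before <- substr(truth$scaffold$residues, pos, ev$replace_start[i])
    seg_after <- substr(pipe$filled[[1]]$residues, pos + shift,
                        ev$replace_start[i] + shift)
    expect_identical(seg_before, seg_after)
    shift <- shift + ev$delta_len[i]
    pos <- ev$replace_end[i] + 1L
  }
  expect_identical(substr(truth$scaffold$residues, pos, truth$scaffold$length),
                   substr(pipe$filled[[1]]$residues, pos + shift,
                          pipe$filled[[1]]$length))
})

test_that("change log round trips and its totals match the stats deltas", {
  truth <- simulate_dataset(seed = 14, error_rate = 0.005)
  pipe <- close_pipeline(list(truth$scaffold), truth$contigs)
  f <- withr::local_tempfile()
  write_log(pipe$events, f)
  lines <- readLines(f)
  expect_match(lines[1], "^scaffold\tgap_index")
  expect_match(lines[length(lines)], "^# total")
  back <- read_log(f)
  expect_equal(back[, setdiff(names(back), "order")],
               pipe$events[, setdiff(names(pipe$events), "order")])
  expect_equal(sum(pipe$events$delta_N), pipe$after$n_N - pipe$before$n_N)

  # empty log: header plus zero-total footer only
  f2 <- withr::local_tempfile()
  write_log(pipe$events[0, ], f2)
  expect_equal(length(readLines(f2)), 2)
  expect_match(readLines(f2)[2], "events=0\tdelta_N=0\tdelta_len=0")
})

test_that("closure never increases Ns or gaps when ambiguous fills are rejected", {
  set.seed(99)
  cfgs <- list(
    list(seed = 41, error_rate = 0.02),
    list(seed = 42, gap_len_bias = 25L),
    list(seed = 43, gap_len_bias = -15L, error_rate = 0.01),
    list(seed = 44, n_gaps = 3L, genome_len = 8000L, contig_overhang = 120L,
         gap_len_range = c(20L, 80L)))
  for (cfg in cfgs) {
    truth <- do.call(simulate_dataset, cfg)
    pipe <- close_pipeline(list(truth$scaffold), truth$contigs)
    expect_lte(pipe$after$n_N, pipe$before$n_N)
    expect_lte(pipe$after$n_gaps, pipe$before$n_gaps)
  }
  # also under arbitrary synthetic hits
  for (s in 1:10) {
    inst <- random_instance(seed = 8800 + s, max_hits = 40)
    pipe <- close_pipeline(inst$scaffolds, inst$contigs,
                           params = closure_params(flank_len = 5,
                                                   max_edge_distance = 5,
                                                   min_identity = 0),
                           hits = inst$hits)
    expect_lte(pipe$after$n_N, pipe$before$n_N)
    expect_lte(pipe$after$n_gaps, pipe$before$n_gaps)
  }
})
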