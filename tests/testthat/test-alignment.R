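test_that("parse_blast_tabular converts coordinates and strands", {
  f <- withr::local_tempfile(lines = c(
    "# comment line",
    "c1\ts1\t100.000\t50\t0\t0\t1\t50\t101\t150\t1e-20\t93.0",
    "c2\ts1\t97.500\t40\t1\t0\t5\t44\t150\t111\t1e-10\t70.0"))
  hits <- parse_blast_tabular(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$c_start[1], 0)
  expect_equal(hits$c_end[1], 50)
  expect_equal(hits$s_start[1], 100)
  expect_equal(hits$s_end[1], 150)
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$identity[1], 100)
  expect_equal(hits$aln_len[1], 50)
  # descending subject interval means minus strand, stored ascending
  expect_equal(hits$strand[2], "-")
  expect_equal(hits$s_start[2], 110)
  expect_equal(hits$s_end[2], 150)
  expect_equal(hits$c_start[2], 4)
})

test_that("parse_blast_tabular rejects malformed rows with line numbers", {
  short <- withr::local_tempfile(lines = "c1\ts1\t100\t50")
  expect_error(parse_blast_tabular(short), "12.*line 1|line 1.*12")

  nonnum <- withr::local_tempfile(lines =
    "c1\ts1\tabc\t50\t0\t0\t1\t50\t101\t150\t1e-20\t93.0")
  expect_error(parse_blast_tabular(nonnum), "non-numeric")

  swapped <- withr::local_tempfile(lines =
    "c1\ts1\t100\t50\t0\t0\t50\t1\t101\t150\t1e-20\t93.0")
  expect_error(parse_blast_tabular(swapped), "qstart > qend")
})

test_that("blast tabular writer and parser round trip all hits", {
  truth <- simulate_dataset(seed = 2, genome_len = 15000, n_gaps = 4,
                            gap_len_range = c(30, 120),
                            contig_overhang = 150, error_rate = 0.01)
  hits <- builtin_align(truth$contigs, list(truth$scaffold))
  expect_gt(nrow(hits), 0)
  f <- withr::local_tempfile()
  write_blast_tabular(hits, f)
  back <- parse_blast_tabular(f)
  expect_equal(sort_hits(back), sort_hits(hits))
})

test_that("parse_nucmer_coords handles the show-coords -T dialect", {
  f <- withr::local_tempfile(lines = c(
    "/ref.fasta /qry.fasta",
    "NUCMER",
    "",
    "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]",
    "101\t150\t1\t50\t50\t50\t100.00\ts1\tc1",
    "201\t240\t40\t1\t40\t40\t97.50\ts1\tc2"))
  hits <- parse_nucmer_coords(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$s_start[1], 100)
  expect_equal(hits$s_end[1], 150)
  expect_equal(hits$c_start[1], 0)
  expect_equal(hits$c_end[1], 50)
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$identity[1], 100)
  expect_equal(hits$strand[2], "-")
  expect_equal(hits$c_start[2], 0)
  expect_equal(hits$c_end[2], 40)
  expect_equal(hits$score[2], 40 * 97.5 / 100)

  noheader <- withr::local_tempfile(lines = "101\t150\t1\t50")
  expect_error(parse_nucmer_coords(noheader), "show-coords")
})

test_that("builtin_align finds exact substrings on both strands", {
  set.seed(31)
  scaffold <- seq_record("s1", random_dna_str(600))
  fwd <- seq_record("c_fwd", substr(scaffold$residues, 101, 400))
  rev <- seq_record("c_rev",
                    reverse_complement(substr(scaffold$residues, 101, 400)))
  hits <- builtin_align(list(fwd, rev), list(scaffold))
  expect_equal(nrow(hits), 2)
  for (i in 1:2) {
    expect_equal(hits$s_start[i], 100)
    expect_equal(hits$s_end[i], 400)
    expect_equal(hits$c_start[i], 0)
    expect_equal(hits$c_end[i], 300)
    expect_equal(hits$identity[i], 100)
  }
  expect_setequal(hits$strand, c("+", "-"))
  # deterministic: identical inputs give identical output
  expect_identical(hits, builtin_align(list(fwd, rev), list(scaffold)))
})

test_that("builtin_align stops extension at Ns and tolerates mismatches", {
  set.seed(32)
  left <- random_dna_str(200)
  right <- random_dna_str(200)
  scaffold <- seq_record("s1", paste0(left, strrep("N", 50), right))
  contig <- seq_record("c1", paste0(substr(left, 151, 200),
                                    random_dna_str(50),
                                    substr(right, 1, 50)))
  hits <- builtin_align(list(contig), list(scaffold))
  # hits must not cross into the N run
  expect_true(all(hits$s_end <= 200 | hits$s_start >= 250))

  # a single substitution is absorbed by extension at the default rate
  mut <- strsplit(substr(left, 101, 200), "")[[1]]
  mut[50] <- setdiff(c("A", "C", "G", "T"), mut[50])[1]
  contig2 <- seq_record("c2", paste(mut, collapse = ""))
  hits2 <- builtin_align(list(contig2), list(scaffold))
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$s_start, 100)
  expect_equal(hits2$s_end, 200)
  expect_equal(hits2$score, 99)
  expect_equal(hits2$identity, 99)
})

test_that("builtin_align covers simulated source intervals despite errors", {
  truth <- simulate_dataset(seed = 13, error_rate = 0.01)
  hits <- builtin_align(truth$contigs, list(truth$scaffold))
  spanning <- truth$contig_truth[!truth$contig_truth$decoy, ]
  for (i in seq_len(nrow(spanning))) {
    h <- hits[hits$contig_id == spanning$contig_id[i], ]
    expect_gt(nrow(h), 0)
    gap <- truth$gap_truth[truth$gap_truth$contig_id ==
                             spanning$contig_id[i], ]
    # coverage of the alignable flanks (the masked interval itself is N
    # on the scaffold and cannot be covered by any aligner)
    flanks <- rbind(c(spanning$src_start[i], gap$start),
                    c(gap$end, spanning$src_end[i]))
    alignable <- sum(flanks[, 2] - flanks[, 1])
    covered <- 0
    for (f in 1:2) {
      ov <- pmin(h$s_end, flanks[f, 2]) - pmax(h$s_start, flanks[f, 1])
      covered <- covered + sum(pmax(ov, 0))
    }
    expect_gte(covered / alignable, 0.9)
  }
})

test_that("parser and builtin aligner agree on an exact-match fixture", {
  set.seed(33)
  scaffold <- seq_record("s1", random_dna_str(500))
  contig <- seq_record("c1", substr(scaffold$residues, 201, 350))
  builtin <- builtin_align(list(contig), list(scaffold))
  blast_line <- sprintf("c1\ts1\t100.000\t150\t0\t0\t1\t150\t201\t350\t0\t277")
  f <- withr::local_tempfile(lines = blast_line)
  parsed <- parse_blast_tabular(f)
  cols <- c("contig_id", "scaffold_id", "c_start", "c_end", "s_start",
            "s_end", "strand", "identity")
  expect_equal(builtin[, cols], parsed[, cols])
})

test_that("sort_hits orders by scaffold position and is idempotent", {
  h <- data.frame(
    contig_id = c("b", "a"), scaffold_id = "s1",
    c_start = 0L, c_end = 20L,
    s_start = c(50L, 10L), s_end = c(70L, 30L),
    strand = "+", identity = 100, aln_len = 20L, score = 20,
    stringsAsFactors = FALSE)
  s <- sort_hits(h)
  expect_equal(s$s_start, c(10, 50))
  expect_equal(nrow(sort_hits(builtin_align(list(), list()))), 0)

  set.seed(34)
  for (i in 1:5) {
    inst <- random_instance(seed = 100 + i, max_hits = 30)
    once <- sort_hits(inst$hits)
    expect_identical(sort_hits(once), once)
    # a permutation sorts to the same table
    if (nrow(once) > 1) {
      perm <- inst$hits[sample(nrow(inst$hits)), , drop = FALSE]
      expect_equal(sort_hits(perm), once)
    }
  }
})
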