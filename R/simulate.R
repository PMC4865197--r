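#' @title Ground-truth simulation and recovery scoring
#' @name simulate
#' @description Generates fixtures with known truth: a random reference
#'   genome, a scaffold derived from it by masking internal intervals with
#'   Ns, spanning contigs that cover each masked interval (forward or
#'   reverse-complement, with optional substitution errors), and decoy
#'   contigs drawn from an unrelated sequence. Closure runs on these
#'   fixtures can then be scored base-by-base against the truth.
NULL

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a gapped scaffold with ground truth
#'
#' The reference is i.i.d. random DNA at the requested GC content.
#' `n_gaps` non-overlapping internal intervals — at least `contig_overhang`
#' from the sequence ends and from each other — are masked with Ns to form
#' the scaffold. For each gap one spanning contig equal to
#' `reference[gap - contig_overhang, gap + contig_overhang)` is emitted,
#' substituted at `error_rate` per base and reverse-complemented with
#' probability `rc_fraction`; `decoy_count` decoys are drawn from an
#' independently generated sequence, so they share no sequence with the
#' reference and produce no accepted fills at default thresholds. Fully
#' reproducible from `seed`.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_len Reference length (default 50000).
#' @param n_gaps Number of masked intervals (default 10).
#' @param gap_len_range Two-element vector of gap lengths (default
#'   c(50, 500), drawn uniformly).
#' @param contig_overhang Reference bases flanking each gap in its
#'   spanning contig (default 300).
#' @param error_rate Per-base substitution probability in spanning contigs
#'   (default 0).
#' @param decoy_count Number of decoy contigs (default 5).
#' @param rc_fraction Probability a spanning contig is reverse-complemented
#'   (default 0.5).
#' @param gc GC content of the reference (default 0.5).
#' @param gap_len_bias Integer added to each N-run length relative to the
#'   masked length (default 0 = length-preserving masks; non-zero values
#'   exercise contraction/expansion fills).
#' @return An object of class `sim_truth`: list with `reference`,
#'   `scaffold` ([seq_record()]s), `contigs` (list of records, spanning
#'   then decoys), `gap_truth` (data.frame: `start`, `end`, `length`,
#'   `mask_len`, `original`, `contig_id`, `strand`, `n_errors`),
#'   `contig_truth` (provenance data.frame incl. decoys), `seed`, `params`.
#' @export
simulate_dataset <- function(seed, genome_len = 50000L, n_gaps = 10L,
                             gap_len_range = c(50L, 500L),
                             contig_overhang = 300L, error_rate = 0,
                             decoy_count = 5L, rc_fraction = 0.5,
                             gc = 0.5, gap_len_bias = 0L) {
  stopifnot(genome_len > 0L, n_gaps >= 0L, contig_overhang >= 1L,
            error_rate >= 0, error_rate < 1, rc_fraction >= 0,
            rc_fraction <= 1, gc > 0, gc < 1,
            length(gap_len_range) == 2L,
            gap_len_range[1] >= 1L, gap_len_range[1] <= gap_len_range[2])
  .with_seed(seed, {
    lens <- if (n_gaps > 0L) {
      sample(seq.int(gap_len_range[1], gap_len_range[2]), n_gaps,
             replace = TRUE)
    } else integer(0)
    slack <- genome_len - sum(lens) - (n_gaps + 1L) * contig_overhang
    if (slack < 0L) {
      stop("infeasible simulation parameters: ", n_gaps, " gaps totalling ",
           sum(lens), " bp plus ", n_gaps + 1L, " separations of ",
           contig_overhang, " bp exceed genome_len ", genome_len)
    }
    # split the slack into n_gaps + 1 inter-gap spacings
    extra <- if (n_gaps > 0L) {
      cuts <- sort(sample.int(slack + 1L, n_gaps, replace = TRUE) - 1L)
      diff(c(0L, cuts, slack))
    } else slack
    reference <- seq_record("ref", .random_dna(genome_len, gc),
                            description = "simulated reference")
    starts <- integer(n_gaps)
    pos <- 0L
    for (i in seq_len(n_gaps)) {
      pos <- pos + contig_overhang + extra[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    ends <- starts + lens
    original <- substring(reference$residues, starts + 1L, ends)

    # mask (right to left so gap_len_bias length changes keep coordinates)
    scaffold_res <- reference$residues
    mask_len <- pmax(1L, lens + as.integer(gap_len_bias))
    for (i in rev(seq_len(n_gaps))) {
      scaffold_res <- paste0(substr(scaffold_res, 1L, starts[i]),
                             strrep("N", mask_len[i]),
                             substr(scaffold_res, ends[i] + 1L,
                                    nchar(scaffold_res)))
    }
    scaffold <- seq_record("scaffold_1", scaffold_res,
                           description = "simulated gapped scaffold")

    contigs <- list()
    truth_rows <- list()
    strands <- character(n_gaps)
    n_err <- integer(n_gaps)
    for (i in seq_len(n_gaps)) {
      src_start <- starts[i] - contig_overhang
      src_end <- ends[i] + contig_overhang
      seqch <- strsplit(substring(reference$residues, src_start + 1L, src_end),
                        "")[[1]]
      err_pos <- which(stats::runif(length(seqch)) < error_rate)
      for (p in err_pos) {
        seqch[p] <- sample(setdiff(c("A", "C", "G", "T"), seqch[p]), 1L)
      }
      res <- paste(seqch, collapse = "")
      strand <- if (stats::runif(1) < rc_fraction) "-" else "+"
      if (strand == "-") res <- reverse_complement(res)
      id <- sprintf("contig_%d", i)
      contigs[[length(contigs) + 1L]] <- seq_record(
        id, res, description = sprintf("spans gap %d", i - 1L))
      strands[i] <- strand
      n_err[i] <- length(err_pos)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        contig_id = id, src_start = src_start, src_end = src_end,
        strand = strand, n_errors = length(err_pos), decoy = FALSE,
        stringsAsFactors = FALSE)
    }
    if (decoy_count > 0L) {
      decoy_len <- as.integer(mean(gap_len_range) + 2L * contig_overhang)
      decoy_pool <- .random_dna(decoy_count * decoy_len, gc)
      for (d in seq_len(decoy_count)) {
        id <- sprintf("decoy_%d", d)
        res <- substring(decoy_pool, (d - 1L) * decoy_len + 1L, d * decoy_len)
        contigs[[length(contigs) + 1L]] <- seq_record(
          id, res, description = "decoy")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          contig_id = id, src_start = NA_integer_, src_end = NA_integer_,
          strand = NA_character_, n_errors = 0L, decoy = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    gap_truth <- data.frame(
      start = starts, end = ends, length = lens, mask_len = mask_len,
      original = original,
      contig_id = if (n_gaps) sprintf("contig_%d", seq_len(n_gaps)) else character(0),
      strand = strands, n_errors = n_err, stringsAsFactors = FALSE)
    structure(
      list(reference = reference, scaffold = scaffold, contigs = contigs,
           gap_truth = gap_truth,
           contig_truth = do.call(rbind, c(truth_rows,
                                           list(make.row.names = FALSE))),
           seed = seed,
           params = list(genome_len = genome_len, n_gaps = n_gaps,
                         gap_len_range = gap_len_range,
                         contig_overhang = contig_overhang,
                         error_rate = error_rate,
                         decoy_count = decoy_count,
                         rc_fraction = rc_fraction, gc = gc,
                         gap_len_bias = gap_len_bias)),
      class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> seed %d: %d bp reference, %d gap(s), %d contig(s) (%d decoys)\n",
              x$seed, x$reference$length, nrow(x$gap_truth),
              length(x$contigs), sum(x$contig_truth$decoy)))
  invisible(x)
}

#' Write simulation fixtures to a directory
#'
#' Emits reference.fasta, scaffold.fasta, contigs.fasta and truth.tsv
#' (gap intervals and contig provenance).
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(list(truth$reference), file.path(dir, "reference.fasta"))
  write_fasta(list(truth$scaffold), file.path(dir, "scaffold.fasta"))
  write_fasta(truth$contigs, file.path(dir, "contigs.fasta"))
  gt <- truth$gap_truth
  gt$record <- "gap"
  ct <- truth$contig_truth
  ct$record <- "contig"
  utils::write.table(gt, file.path(dir, "truth_gaps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ct, file.path(dir, "truth_contigs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(seed = truth$seed, truth$params[c("genome_len", "n_gaps",
                                              "contig_overhang",
                                              "error_rate", "decoy_count",
                                              "rc_fraction", "gc",
                                              "gap_len_bias")],
            gap_len_min = truth$params$gap_len_range[1],
            gap_len_max = truth$params$gap_len_range[2])
  writeLines(paste(names(meta), unlist(meta), sep = "\t"),
             file.path(dir, "truth_params.tsv"))
  invisible(dir)
}

#' Read simulation fixtures back from a directory
#'
#' @param dir Directory written by [write_sim()].
#' @return A `sim_truth` object.
#' @export
read_sim <- function(dir) {
  need <- c("reference.fasta", "scaffold.fasta", "contigs.fasta",
            "truth_gaps.tsv", "truth_contigs.tsv", "truth_params.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("not a simulation directory (missing ",
         paste(missing, collapse = ", "), "): ", dir)
  }
  gt <- utils::read.delim(file.path(dir, "truth_gaps.tsv"),
                          stringsAsFactors = FALSE)
  gt$record <- NULL
  ct <- utils::read.delim(file.path(dir, "truth_contigs.tsv"),
                          stringsAsFactors = FALSE)
  ct$record <- NULL
  meta_lines <- strsplit(readLines(file.path(dir, "truth_params.tsv")), "\t")
  meta <- stats::setNames(vapply(meta_lines, `[[`, "", 2L),
                          vapply(meta_lines, `[[`, "", 1L))
  structure(
    list(reference = read_fasta(file.path(dir, "reference.fasta"))[[1]],
         scaffold = read_fasta(file.path(dir, "scaffold.fasta"))[[1]],
         contigs = unname(read_fasta(file.path(dir, "contigs.fasta"))),
         gap_truth = gt, contig_truth = ct,
         seed = as.integer(meta[["seed"]]),
         params = list(
           genome_len = as.integer(meta[["genome_len"]]),
           n_gaps = as.integer(meta[["n_gaps"]]),
           gap_len_range = c(as.integer(meta[["gap_len_min"]]),
                             as.integer(meta[["gap_len_max"]])),
           contig_overhang = as.integer(meta[["contig_overhang"]]),
           error_rate = as.numeric(meta[["error_rate"]]),
           decoy_count = as.integer(meta[["decoy_count"]]),
           rc_fraction = as.numeric(meta[["rc_fraction"]]),
           gc = as.numeric(meta[["gc"]]),
           gap_len_bias = as.integer(meta[["gap_len_bias"]]))),
    class = "sim_truth")
}

#' Score a filled scaffold against simulated truth
#'
#' Classifies every simulated gap as closed, reduced or untouched, and
#' measures base accuracy over the originally masked positions. Positions
#' are located alignment-free through the change-log coordinate ledger:
#' each event's replaced interval is mapped into the filled sequence by
#' the cumulative length change of events to its left. Without a ledger
#' (`events = NULL`) coordinates are assumed unshifted, which is exact
#' when no applied fill changed the scaffold length.
#'
#' @param filled List of filled [seq_record()]s (from [apply_fills()]).
#' @param truth A `sim_truth` object the scaffold came from.
#' @param events Optional event data.frame from [apply_fills()] /
#'   [read_log()].
#' @return A list with `per_gap` (data.frame: `start`, `end`, `length`,
#'   `status`, `bases_evaluated`, `bases_correct`) and `totals` (list:
#'   `n_gaps`, `closed`, `reduced`, `untouched`, `n_removed`,
#'   `accuracy_pct` — percent of evaluated filled bases matching the
#'   reference, `NA` when nothing was filled).
#' @export
evaluate_recovery <- function(filled, truth, events = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  ids <- vapply(filled, `[[`, "", "id")
  fi <- match(truth$scaffold$id, ids)
  if (is.na(fi)) {
    stop("filled records do not contain truth scaffold id ",
         truth$scaffold$id)
  }
  fseq <- filled[[fi]]$residues
  ref <- truth$reference$residues
  gt <- truth$gap_truth
  if (is.null(events)) {
    events <- data.frame(scaffold_id = character(0),
                         replace_start = integer(0),
                         replace_end = integer(0), fill_len = integer(0),
                         delta_len = integer(0), stringsAsFactors = FALSE)
  }
  ev <- events[events$scaffold_id == truth$scaffold$id, , drop = FALSE]
  ev <- ev[order(ev$replace_start), , drop = FALSE]
  shift_before <- function(pos) {
    if (nrow(ev) == 0L) return(0L)
    sum(ev$delta_len[ev$replace_end <= pos])
  }
  # scaffold coordinates of each mask: earlier non-length-preserving masks
  # shift everything to their right by their cumulative length bias
  cum_bias <- cumsum(c(0L, gt$mask_len - gt$length))
  sgs <- gt$start + cum_bias[seq_len(nrow(gt))]     # mask start, scaffold
  sge <- sgs + gt$mask_len                          # mask end, scaffold
  # reference coordinate of scaffold position p (clamped inside masks)
  ref_of <- function(p) {
    for (j in seq_len(nrow(gt))) {
      if (p < sgs[j]) return(p - cum_bias[j])
      if (p < sge[j]) return(gt$start[j] + min(p - sgs[j], gt$length[j]))
    }
    p - cum_bias[nrow(gt) + 1L]
  }
  status <- character(nrow(gt))
  n_eval <- integer(nrow(gt))
  n_corr <- integer(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    gs <- sgs[i]; ge <- sge[i]
    touching <- which(ev$replace_start < ge & ev$replace_end > gs)
    if (length(touching) == 0L) {
      status[i] <- "untouched"
      next
    }
    covered <- 0L
    for (t in touching) {
      rs <- ev$replace_start[t]; re <- ev$replace_end[t]
      covered <- covered + (min(re, ge) - max(rs, gs))
      fstart <- rs + shift_before(rs)               # fill start in filled seq
      ra <- ref_of(rs); rb <- ref_of(re)            # reference span replaced
      # masked reference positions this event covers for gap i
      mlo <- max(ra, gt$start[i]); mhi <- min(rb, gt$end[i])
      if (mhi <= mlo) next
      n_eval[i] <- n_eval[i] + (mhi - mlo)
      if (ev$fill_len[t] == rb - ra) {
        # fill is reference-length: ref position q sits at fstart + (q - ra)
        fill_seg <- substr(fseq, fstart + (mlo - ra) + 1L,
                           fstart + (mhi - ra))
        n_corr[i] <- n_corr[i] +
          .count_matches(fill_seg, substr(ref, mlo + 1L, mhi))
      } else {
        # length-discordant fill: compare the common prefix positionally,
        # count the remaining masked positions as evaluated but incorrect
        phi <- min(mhi, ra + min(ev$fill_len[t], rb - ra))
        if (phi > mlo) {
          fill_seg <- substr(fseq, fstart + (mlo - ra) + 1L,
                             fstart + (phi - ra))
          n_corr[i] <- n_corr[i] +
            .count_matches(fill_seg, substr(ref, mlo + 1L, phi))
        }
      }
    }
    fully <- covered >= (ge - gs)
    no_n <- all(vapply(touching, function(t) {
      fstart <- ev$replace_start[t] + shift_before(ev$replace_start[t])
      seg <- substr(fseq, fstart + 1L, fstart + ev$fill_len[t])
      .count_N(seg) == 0L
    }, TRUE))
    status[i] <- if (fully && no_n) "closed" else "reduced"
  }
  per_gap <- data.frame(start = sgs, end = sge,
                        length = gt$mask_len, status = status,
                        bases_evaluated = n_eval, bases_correct = n_corr,
                        stringsAsFactors = FALSE)
  n_removed <- .count_N(truth$scaffold$residues) - .count_N(fseq)
  totals <- list(
    n_gaps = nrow(gt),
    closed = sum(status == "closed"),
    reduced = sum(status == "reduced"),
    untouched = sum(status == "untouched"),
    n_removed = n_removed,
    accuracy_pct = if (sum(n_eval) > 0L) 100 * sum(n_corr) / sum(n_eval)
                   else NA_real_)
  list(per_gap = per_gap, totals = totals)
}

.count_matches <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  sum(charToRaw(substr(a, 1L, n)) == charToRaw(substr(b, 1L, n)))
}
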