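#' @title Gap closure: candidate discovery, ranking, selection, application
#' @name closure
#' @description The core method. For every gap, alignments of the same
#'   contig flanking the gap are combined into fill candidates of three
#'   kinds — a single spanning hit, a pair of flanking hits, or a one-sided
#'   extension that only reduces the gap — then ranked, selected without
#'   overlap conflicts, spliced into the scaffolds, and recorded in a
#'   change log.
NULL

#' Closure parameters
#'
#' @param flank_len Minimum aligned bases required on each side immediately
#'   adjacent to the gap (default 11).
#' @param min_identity Minimum percent identity of every supporting hit
#'   (default 95).
#' @param max_edge_distance Maximum unaligned scaffold bases tolerated
#'   between a supporting hit's inner end and the gap edge (default 10);
#'   these sliver bases are consumed by the replaced interval so no
#'   untrusted scaffold bases survive adjacent to a fill.
#' @param min_gap_len Minimum N-run length treated as a gap (default 1).
#' @param allow_reduction Permit one-sided N trimming when full closure is
#'   impossible (default TRUE).
#' @param reject_ambiguous_fill Drop candidates whose fill sequence
#'   contains N (default TRUE), guaranteeing the total N count never
#'   increases.
#' @return A list of class `closure_params`.
#' @export
closure_params <- function(flank_len = 11L, min_identity = 95,
                           max_edge_distance = 10L, min_gap_len = 1L,
                           allow_reduction = TRUE,
                           reject_ambiguous_fill = TRUE) {
  stopifnot(flank_len >= 1L, min_identity >= 0, min_identity <= 100,
            max_edge_distance >= 0L, min_gap_len >= 1L)
  structure(list(flank_len = as.integer(flank_len),
                 min_identity = min_identity,
                 max_edge_distance = as.integer(max_edge_distance),
                 min_gap_len = as.integer(min_gap_len),
                 allow_reduction = isTRUE(allow_reduction),
                 reject_ambiguous_fill = isTRUE(reject_ambiguous_fill)),
            class = "closure_params")
}

CANDIDATE_COLUMNS <- c("scaffold_id", "gap_index", "gap_start", "gap_end",
                       "gap_len", "contig_id", "strand", "kind",
                       "replace_start", "replace_end", "fill_c_start",
                       "fill_c_end", "fill_len", "mean_identity",
                       "flank_support_left", "flank_support_right",
                       "predicted_delta_N", "status")

.empty_candidates <- function() {
  out <- data.frame(scaffold_id = character(0), gap_index = integer(0),
                    gap_start = integer(0), gap_end = integer(0),
                    gap_len = integer(0), contig_id = character(0),
                    strand = character(0), kind = character(0),
                    replace_start = integer(0), replace_end = integer(0),
                    fill_c_start = integer(0), fill_c_end = integer(0),
                    fill_len = integer(0), mean_identity = numeric(0),
                    flank_support_left = integer(0),
                    flank_support_right = integer(0),
                    predicted_delta_N = integer(0), status = character(0),
                    stringsAsFactors = FALSE)
  out
}

.count_N <- function(s) nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))

#' Find fill candidates for every gap
#'
#' Three candidate kinds per gap (all supporting hits must reach
#' `min_identity`):
#' \describe{
#'   \item{span}{one hit whose scaffold interval covers the gap plus
#'     `flank_len` trusted bases on each side. For ungapped hits
#'     (alignment length equal to both interval widths) the replaced
#'     interval is exactly gap plus flanks and the fill is the positionally
#'     mapped contig sub-interval; for hits with indels the whole hit
#'     intervals are used.}
#'   \item{pair}{two hits of the same contig and strand, one ending within
#'     `max_edge_distance` of the left gap edge with at least `flank_len`
#'     aligned bases, one starting within `max_edge_distance` of the right
#'     edge likewise, with contig intervals ordered consistently with the
#'     strand and non-overlapping. The replaced interval runs between the
#'     two inner hit ends (it contains the gap); the fill is the contig
#'     segment strictly between the hits' inner contig endpoints — an
#'     empty fill is a pure contraction.}
#'   \item{left_extend / right_extend}{(only with `allow_reduction`) a
#'     one-sided flanking hit whose contig extends past the gap edge; the
#'     overhang replaces a prefix/suffix of the gap's Ns, never reaching
#'     past the far gap edge.}
#' }
#'
#' @param gaps Gap table from [find_gaps_all()].
#' @param hits Hit data.frame sorted via [sort_hits()].
#' @param scaffolds,contigs Lists of [seq_record()] objects; every id
#'   referenced by `hits` must be present.
#' @param params A [closure_params()] object.
#' @return Candidate data.frame, one row per candidate, `status`
#'   "proposed".
#' @export
find_candidates <- function(gaps, hits, scaffolds, contigs,
                            params = closure_params()) {
  stopifnot(inherits(params, "closure_params"))
  scaffold_ids <- vapply(scaffolds, `[[`, "", "id")
  contig_ids <- vapply(contigs, `[[`, "", "id")
  if (nrow(hits)) {
    bad <- setdiff(unique(hits$scaffold_id), scaffold_ids)
    if (length(bad)) stop("hits reference unknown scaffold id(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(unique(hits$contig_id), contig_ids)
    if (length(bad)) stop("hits reference unknown contig id(s): ",
                          paste(bad, collapse = ", "))
  }
  hits <- hits[hits$identity >= params$min_identity, , drop = FALSE]
  if (nrow(gaps) == 0L || nrow(hits) == 0L) return(.empty_candidates())

  contig_len <- vapply(contigs, `[[`, 0L, "length")
  names(contig_len) <- contig_ids
  scaffold_seq <- vapply(scaffolds, `[[`, "", "residues")
  names(scaffold_seq) <- scaffold_ids
  contig_seq <- vapply(contigs, `[[`, "", "residues")
  names(contig_seq) <- contig_ids

  out <- list()
  add <- function(gap, contig_id, strand, kind, rs, re, fs, fe,
                  mean_identity, fsl, fsr) {
    fill <- if (fe > fs) substr(contig_seq[[contig_id]], fs + 1L, fe) else ""
    if (params$reject_ambiguous_fill && .count_N(fill) > 0L) return()
    replaced <- substr(scaffold_seq[[gap$scaffold_id]], rs + 1L, re)
    out[[length(out) + 1L]] <<- data.frame(
      scaffold_id = gap$scaffold_id, gap_index = gap$index,
      gap_start = gap$start, gap_end = gap$end, gap_len = gap$length,
      contig_id = contig_id, strand = strand, kind = kind,
      replace_start = as.integer(rs), replace_end = as.integer(re),
      fill_c_start = as.integer(fs), fill_c_end = as.integer(fe),
      fill_len = as.integer(fe - fs), mean_identity = mean_identity,
      flank_support_left = as.integer(fsl),
      flank_support_right = as.integer(fsr),
      predicted_delta_N = as.integer(.count_N(replaced) - .count_N(fill)),
      status = "proposed", stringsAsFactors = FALSE)
  }

  for (g in seq_len(nrow(gaps))) {
    gap <- gaps[g, ]
    h <- hits[hits$scaffold_id == gap$scaffold_id, , drop = FALSE]
    if (nrow(h) == 0L) next

    # span: one hit covering [gap.start - flank_len, gap.end + flank_len]
    span_lo <- gap$start - params$flank_len
    span_hi <- gap$end + params$flank_len
    sp <- which(h$s_start <= span_lo & h$s_end >= span_hi)
    for (i in sp) {
      hi <- h[i, ]
      positional <- hi$aln_len == (hi$s_end - hi$s_start) &&
        hi$aln_len == (hi$c_end - hi$c_start)
      if (positional) {
        rs <- span_lo; re <- span_hi
        if (hi$strand == "+") {
          fs <- hi$c_start + (rs - hi$s_start)
          fe <- hi$c_start + (re - hi$s_start)
        } else {
          fs <- hi$c_start + (hi$s_end - re)
          fe <- hi$c_end - (rs - hi$s_start)
        }
      } else {
        rs <- hi$s_start; re <- hi$s_end
        fs <- hi$c_start; fe <- hi$c_end
      }
      add(gap, hi$contig_id, hi$strand, "span", rs, re, fs, fe,
          hi$identity, gap$start - hi$s_start, hi$s_end - gap$end)
    }

    # flanking hits for pair / extend kinds
    left_ok <- which(h$s_end >= gap$start - params$max_edge_distance &
                     h$s_end <= gap$start &
                     (h$s_end - h$s_start) >= params$flank_len)
    right_ok <- which(h$s_start >= gap$end &
                      h$s_start <= gap$end + params$max_edge_distance &
                      (h$s_end - h$s_start) >= params$flank_len)

    for (i in left_ok) {
      li <- h[i, ]
      for (j in right_ok) {
        ri <- h[j, ]
        if (ri$contig_id != li$contig_id || ri$strand != li$strand) next
        if (li$strand == "+") {
          if (li$c_end > ri$c_start) next
          fs <- li$c_end; fe <- ri$c_start
        } else {
          if (ri$c_end > li$c_start) next
          fs <- ri$c_end; fe <- li$c_start
        }
        add(gap, li$contig_id, li$strand, "pair", li$s_end, ri$s_start,
            fs, fe, (li$identity + ri$identity) / 2,
            li$s_end - li$s_start, ri$s_end - ri$s_start)
      }
    }

    if (params$allow_reduction) {
      for (i in left_ok) {
        li <- h[i, ]
        clen <- contig_len[[li$contig_id]]
        overhang <- if (li$strand == "+") clen - li$c_end else li$c_start
        ext <- min(overhang, gap$end - li$s_end)
        if (ext < 1L || ext <= gap$start - li$s_end) next
        rs <- li$s_end; re <- li$s_end + ext
        if (li$strand == "+") { fs <- li$c_end; fe <- li$c_end + ext }
        else { fs <- li$c_start - ext; fe <- li$c_start }
        add(gap, li$contig_id, li$strand, "left_extend", rs, re, fs, fe,
            li$identity, li$s_end - li$s_start, 0L)
      }
      for (j in right_ok) {
        ri <- h[j, ]
        clen <- contig_len[[ri$contig_id]]
        overhang <- if (ri$strand == "+") ri$c_start else clen - ri$c_end
        ext <- min(overhang, ri$s_start - gap$start)
        if (ext < 1L || ext <= ri$s_start - gap$end) next
        rs <- ri$s_start - ext; re <- ri$s_start
        if (ri$strand == "+") { fs <- ri$c_start - ext; fe <- ri$c_start }
        else { fs <- ri$c_end; fe <- ri$c_end + ext }
        add(gap, ri$contig_id, ri$strand, "right_extend", rs, re, fs, fe,
            ri$identity, 0L, ri$s_end - ri$s_start)
      }
    }
  }
  if (length(out) == 0L) return(.empty_candidates())
  cands <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # distinct hit pairs can induce identical candidates; keep one
  unique(cands)
}

#' Rank candidates within each gap
#'
#' Within each gap, candidates are ordered by: kind priority (span and
#' pair ahead of one-sided extends), mean identity descending, total flank
#' support descending, |fill length - gap length| ascending, then
#' (contig_id, strand) ascending for determinism. Gaps themselves are
#' ordered by (scaffold_id, gap_start). The resulting order is total:
#' sorting any permutation yields the same list.
#'
#' @param candidates Candidate data.frame from [find_candidates()].
#' @return The candidate data.frame sorted, with `rank` (1-based within
#'   gap) and a content-derived `candidate_id` column added.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$rank <- integer(0)
    out$candidate_id <- character(0)
    return(out)
  }
  kind_priority <- ifelse(candidates$kind %in% c("span", "pair"), 0L, 1L)
  support <- candidates$flank_support_left + candidates$flank_support_right
  ord <- order(candidates$scaffold_id, candidates$gap_start,
               kind_priority, -candidates$mean_identity, -support,
               abs(candidates$fill_len - candidates$gap_len),
               candidates$contig_id, candidates$strand, method = "radix")
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  gap_key <- paste(out$scaffold_id, out$gap_index, sep = "\r")
  out$rank <- stats::ave(seq_len(nrow(out)), gap_key,
                         FUN = seq_along)
  out$candidate_id <- sprintf("%s:g%d:%s:%s:%s:%d-%d:%d-%d",
                              out$scaffold_id, out$gap_index, out$contig_id,
                              out$strand, out$kind, out$replace_start,
                              out$replace_end, out$fill_c_start,
                              out$fill_c_end)
  if (anyDuplicated(out$candidate_id)) {
    stop("internal error: candidate ids not unique")
  }
  out
}

.intervals_overlap <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2

#' Automatically select non-conflicting candidates
#'
#' Greedy selection: gaps are visited in (scaffold, position) order; each
#' gap's candidates are tried in rank order and the first whose replaced
#' interval does not overlap an already-accepted candidate's replaced
#' interval on the same scaffold is accepted. Full-closure kinds outrank
#' reduction kinds through the rank order itself.
#'
#' @param candidates Ranked candidate data.frame from [rank_candidates()].
#' @param params A [closure_params()] object (reserved for selection
#'   policy options; the defaults impose none beyond conflict avoidance).
#' @return The accepted subset, `status` set to "accepted", in gap order.
#' @export
select_auto <- function(candidates, params = closure_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  stopifnot("rank" %in% names(candidates))
  acc_idx <- integer(0)
  gap_key <- paste(candidates$scaffold_id, candidates$gap_index, sep = "\r")
  for (key in unique(gap_key)) {
    rows <- which(gap_key == key)
    rows <- rows[order(candidates$rank[rows])]
    for (r in rows) {
      same <- acc_idx[candidates$scaffold_id[acc_idx] ==
                        candidates$scaffold_id[r]]
      clash <- length(same) > 0L &&
        any(.intervals_overlap(candidates$replace_start[r],
                               candidates$replace_end[r],
                               candidates$replace_start[same],
                               candidates$replace_end[same]))
      if (!clash) { acc_idx <- c(acc_idx, r); break }
    }
  }
  out <- candidates[sort(acc_idx), , drop = FALSE]
  out$status <- rep("accepted", nrow(out))
  rownames(out) <- NULL
  out
}

#' Apply accepted fills to the scaffolds
#'
#' Fills are spliced per scaffold in descending `replace_start` order so
#' that earlier coordinates stay valid in one pass; the replacement text is
#' the contig sub-interval, reverse-complemented for minus-strand
#' candidates. Bases outside replaced intervals are unchanged. Events are
#' recorded in application order with the original (pre-fill) coordinates.
#'
#' @param scaffolds,contigs Lists of [seq_record()] objects.
#' @param accepted Accepted candidate data.frame from [select_auto()] or
#'   [import_review()]; replaced intervals must not overlap within a
#'   scaffold.
#' @return A list with `scaffolds` (filled records; descriptions annotated
#'   with the fill count) and `events` (data.frame: the change log —
#'   `delta_N` is the signed change in N count, negative when Ns are
#'   removed; `delta_len` the signed scaffold length change).
#' @export
apply_fills <- function(scaffolds, contigs, accepted) {
  contig_ids <- vapply(contigs, `[[`, "", "id")
  events <- list()
  order_index <- 0L
  out_records <- scaffolds
  for (si in seq_along(scaffolds)) {
    scaf <- scaffolds[[si]]
    rows <- which(accepted$scaffold_id == scaf$id)
    if (length(rows) == 0L) next
    rows <- rows[order(accepted$replace_start[rows], decreasing = TRUE)]
    rs <- accepted$replace_start[rows]; re <- accepted$replace_end[rows]
    if (length(rows) > 1L &&
        any(re[-1] > rs[-length(rows)])) {
      stop("overlapping accepted fills on scaffold ", scaf$id)
    }
    residues <- scaf$residues
    for (r in rows) {
      cand <- accepted[r, ]
      ci <- match(cand$contig_id, contig_ids)
      if (is.na(ci)) stop("unknown contig id in accepted fills: ", cand$contig_id)
      ctg <- contigs[[ci]]
      if (cand$fill_c_end > ctg$length || cand$fill_c_start < 0L) {
        stop("fill interval out of contig bounds for ", cand$contig_id)
      }
      fill <- if (cand$fill_c_end > cand$fill_c_start) {
        substr(ctg$residues, cand$fill_c_start + 1L, cand$fill_c_end)
      } else ""
      if (cand$strand == "-") fill <- reverse_complement(fill)
      replaced <- substr(residues, cand$replace_start + 1L, cand$replace_end)
      residues <- paste0(
        substr(residues, 1L, cand$replace_start),
        fill,
        substr(residues, cand$replace_end + 1L, nchar(residues)))
      order_index <- order_index + 1L
      covers_gap <- cand$replace_start <= cand$gap_start &&
        cand$replace_end >= cand$gap_end
      events[[length(events) + 1L]] <- data.frame(
        scaffold_id = scaf$id, gap_index = cand$gap_index,
        gap_start = cand$gap_start, gap_end = cand$gap_end,
        gap_len = cand$gap_len,
        action = if (covers_gap && .count_N(fill) == 0L) "closed" else "reduced",
        contig_id = cand$contig_id, strand = cand$strand, kind = cand$kind,
        replace_start = cand$replace_start, replace_end = cand$replace_end,
        fill_len = nchar(fill),
        delta_N = .count_N(fill) - .count_N(replaced),
        delta_len = nchar(fill) - nchar(replaced),
        mean_identity = cand$mean_identity,
        order = order_index, stringsAsFactors = FALSE)
    }
    n_fills <- length(rows)
    desc <- scaf$description
    tag <- sprintf("gapfillr_fills=%d", n_fills)
    desc <- if (nzchar(desc)) paste(desc, tag) else tag
    out_records[[si]] <- seq_record(scaf$id, residues, description = desc)
  }
  events <- if (length(events)) {
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  } else {
    data.frame(scaffold_id = character(0), gap_index = integer(0),
               gap_start = integer(0), gap_end = integer(0),
               gap_len = integer(0), action = character(0),
               contig_id = character(0), strand = character(0),
               kind = character(0), replace_start = integer(0),
               replace_end = integer(0), fill_len = integer(0),
               delta_N = integer(0), delta_len = integer(0),
               mean_identity = numeric(0), order = integer(0),
               stringsAsFactors = FALSE)
  }
  list(scaffolds = out_records, events = events)
}

#' Write the change log
#'
#' Tab-separated, one row per applied fill, coordinates 1-based inclusive
#' (user-facing, BLAST-style; internal computation is 0-based half-open).
#' A comment footer line carries the event count and the total delta_N and
#' delta_len, which match the before/after statistics on the affected
#' intervals.
#'
#' @param events Event data.frame from [apply_fills()].
#' @param path Output path.
#' @export
write_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("scaffold", "gap_index", "gap_start", "gap_end", "gap_len",
              "action", "contig", "strand", "kind", "replace_start",
              "replace_end", "fill_len", "delta_N", "delta_len",
              "mean_identity")
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(events)) {
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%.17g",
                       events$scaffold_id, events$gap_index,
                       events$gap_start + 1L, events$gap_end,
                       events$gap_len, events$action, events$contig_id,
                       events$strand, events$kind,
                       events$replace_start + 1L, events$replace_end,
                       events$fill_len, events$delta_N, events$delta_len,
                       events$mean_identity), con)
  }
  writeLines(sprintf("# total\tevents=%d\tdelta_N=%d\tdelta_len=%d",
                     nrow(events), sum(events$delta_N),
                     sum(events$delta_len)), con)
  invisible(NULL)
}

#' Read a change log back into an event table
#'
#' Inverse of [write_log()]; used by recovery evaluation to locate filled
#' positions after coordinate shifts.
#'
#' @param path Path to a change-log TSV.
#' @return Event data.frame in [apply_fills()] layout.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(apply_fills(list(), list(),
                       .empty_candidates())$events)
  }
  data.frame(scaffold_id = as.character(tab$scaffold),
             gap_index = tab$gap_index,
             gap_start = tab$gap_start - 1L, gap_end = tab$gap_end,
             gap_len = tab$gap_len, action = tab$action,
             contig_id = as.character(tab$contig), strand = tab$strand,
             kind = tab$kind,
             replace_start = tab$replace_start - 1L,
             replace_end = tab$replace_end,
             fill_len = tab$fill_len, delta_N = tab$delta_N,
             delta_len = tab$delta_len, mean_identity = tab$mean_identity,
             order = seq_len(nrow(tab)), stringsAsFactors = FALSE)
}
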