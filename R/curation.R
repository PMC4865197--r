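#' @title File-based curation round-trip
#' @name curation
#' @description Candidate fills are exported as a tab-separated review
#'   table, one row per candidate grouped by gap, with a `decision` column.
#'   The rows the automatic selector would accept come pre-marked ACCEPT;
#'   a curator edits decisions (case-insensitive ACCEPT / REJECT / blank)
#'   and the file is imported back to drive [apply_fills()]. An unedited
#'   round-trip is behaviorally identical to [select_auto()].
NULL

REVIEW_COLUMNS <- c("candidate_id", "scaffold", "gap_index", "gap_start",
                    "gap_end", "gap_len", "rank", "kind", "contig",
                    "strand", "replace_start", "replace_end", "fill_len",
                    "mean_identity", "flank_support_left",
                    "flank_support_right", "predicted_delta_N", "decision")

#' Export ranked candidates for review
#'
#' Coordinates in the file are 1-based inclusive (user-facing); the
#' `candidate_id` is derived from candidate content, not row position, so
#' edited files survive re-export. Comment lines start with `#`.
#'
#' @param candidates Ranked candidate data.frame from [rank_candidates()].
#' @param path Output path.
#' @param params A [closure_params()] object used to pre-mark the
#'   automatic selection.
#' @export
export_review <- function(candidates, path, params = closure_params()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(REVIEW_COLUMNS, collapse = "\t"), con)
  if (nrow(candidates)) {
    stopifnot("candidate_id" %in% names(candidates))
    auto <- select_auto(candidates, params)
    decision <- ifelse(candidates$candidate_id %in% auto$candidate_id,
                       "ACCEPT", "")
    writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%d\t%d\t%d\t%.17g\t%d\t%d\t%d\t%s",
                       candidates$candidate_id, candidates$scaffold_id,
                       candidates$gap_index, candidates$gap_start + 1L,
                       candidates$gap_end, candidates$gap_len,
                       candidates$rank, candidates$kind,
                       candidates$contig_id, candidates$strand,
                       candidates$replace_start + 1L,
                       candidates$replace_end, candidates$fill_len,
                       candidates$mean_identity,
                       candidates$flank_support_left,
                       candidates$flank_support_right,
                       candidates$predicted_delta_N, decision), con)
  }
  invisible(NULL)
}

#' Import reviewed decisions
#'
#' Rows marked ACCEPT become the accepted set; REJECT and blank rows are
#' skipped. Decisions parse case-insensitively. Two ACCEPTs for one gap
#' are an error; accepted candidates whose replaced intervals conflict
#' across gaps are resolved by the same rule as [select_auto()] (earlier
#' gap wins), with a warning.
#'
#' @param path Path to an edited review file from [export_review()].
#' @param candidates The same ranked candidate data.frame the file was
#'   exported from (the candidate set must be unchanged).
#' @return Accepted candidate subset, `status` "accepted", in gap order.
#' @export
import_review <- function(path, candidates) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L) stop("empty review file: ", path)
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  id_col <- match("candidate_id", header)
  dec_col <- match("decision", header)
  if (is.na(id_col) || is.na(dec_col)) {
    stop("not a review file (missing candidate_id/decision columns): ", path)
  }
  body <- keep[-1]
  accepted_ids <- character(0)
  seen_ids <- character(0)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    cid <- f[id_col]
    decision <- toupper(trimws(if (length(f) >= dec_col) f[dec_col] else ""))
    if (is.na(cid) || !cid %in% candidates$candidate_id) {
      stop("unknown candidate_id ", sQuote(cid), " at line ", i, " of ", path)
    }
    if (cid %in% seen_ids) {
      stop("duplicate candidate_id ", sQuote(cid), " at line ", i, " of ", path)
    }
    seen_ids <- c(seen_ids, cid)
    if (decision == "ACCEPT") {
      accepted_ids <- c(accepted_ids, cid)
    } else if (decision != "" && decision != "REJECT") {
      stop("invalid decision ", sQuote(decision), " at line ", i, " of ",
           path, " (expected ACCEPT, REJECT or blank)")
    }
  }
  sel <- candidates[candidates$candidate_id %in% accepted_ids, , drop = FALSE]
  gap_key <- paste(sel$scaffold_id, sel$gap_index, sep = "\r")
  dup <- unique(gap_key[duplicated(gap_key)])
  if (length(dup)) {
    stop("multiple ACCEPT decisions for gap(s): ",
         paste(gsub("\r", " gap ", dup, fixed = TRUE), collapse = "; "))
  }
  # re-check select_auto's conflict rule in gap order
  ord <- order(sel$scaffold_id, sel$gap_start, method = "radix")
  sel <- sel[ord, , drop = FALSE]
  keep_row <- rep(TRUE, nrow(sel))
  for (r in seq_len(nrow(sel))) {
    prior <- which(keep_row[seq_len(r - 1L)] &
                     sel$scaffold_id[seq_len(r - 1L)] == sel$scaffold_id[r])
    if (length(prior) &&
        any(.intervals_overlap(sel$replace_start[r], sel$replace_end[r],
                               sel$replace_start[prior], sel$replace_end[prior]))) {
      warning("accepted candidate ", sel$candidate_id[r],
              " conflicts with an earlier accepted fill; dropped")
      keep_row[r] <- FALSE
    }
  }
  out <- sel[keep_row, , drop = FALSE]
  out$status <- rep("accepted", nrow(out))
  rownames(out) <- NULL
  out
}
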