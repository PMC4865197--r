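#' @title Gap detection and #Gaps / #N accounting
#' @name gap_model
#' @description A gap is a maximal run of N characters in a scaffold,
#'   standing in for unknown sequence between ordered contigs. This module
#'   finds gaps, computes per-record and total gap/N statistics, and builds
#'   before/after comparison reports of the kind used to evaluate gap
#'   filling runs.
NULL

#' Find gaps (maximal N-runs) in a sequence record
#'
#' All coordinates are 0-based half-open. Runs shorter than `min_gap_len`
#' are excluded; gaps touching sequence ends are reported (they are
#' detectable, though unfillable by two-sided flank pairing).
#'
#' @param record A [seq_record()].
#' @param min_gap_len Minimum run length to count as a gap (default 1).
#' @return A data.frame with columns `scaffold_id`, `start`, `end`,
#'   `length`, `index` (0-based ordinal within the scaffold, left to
#'   right), sorted by `start`.
#' @examples
#' find_gaps(seq_record("s", "ACNNNGT"))  # one gap, start 2, end 5
#' @export
find_gaps <- function(record, min_gap_len = 1L) {
  stopifnot(inherits(record, "seq_record"), min_gap_len >= 1L)
  m <- gregexpr("N+", record$residues)[[1]]
  empty <- data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      index = integer(0), stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L                 # to 0-based
  len <- attr(m, "match.length")
  keep <- len >= min_gap_len
  if (!any(keep)) return(empty)
  start <- start[keep]; len <- len[keep]
  data.frame(
    scaffold_id = record$id,
    start = start,
    end = start + len,
    length = len,
    index = seq_along(start) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Find gaps across a list of records
#'
#' @param records List of [seq_record()] objects.
#' @inheritParams find_gaps
#' @return Row-bound gap table over all records (see [find_gaps()]).
#' @export
find_gaps_all <- function(records, min_gap_len = 1L) {
  do.call(rbind, c(lapply(records, find_gaps, min_gap_len = min_gap_len),
                   list(make.row.names = FALSE)))
}

#' Gap and N statistics for a set of records
#'
#' `n_gaps` counts maximal N-runs of length at least `min_gap_len`;
#' `n_N` counts every N character regardless of run length, so the
#' difference of `n_N` before and after filling always reflects the total
#' ambiguity removed.
#'
#' @inheritParams find_gaps_all
#' @return An object of class `gap_stats`: a list with `n_gaps`, `n_N`,
#'   `per_record` (data.frame: `id`, `n_gaps`, `n_N`), `gap_lengths`
#'   (integer vector) and `min_gap_len`.
#' @examples
#' recs <- list(seq_record("a", "ACNNNGT"), seq_record("b", "NN"))
#' gap_stats(recs)  # n_gaps 2, n_N 5
#' @export
gap_stats <- function(records, min_gap_len = 1L) {
  per <- lapply(records, function(rec) {
    gaps <- find_gaps(rec, min_gap_len = min_gap_len)
    data.frame(id = rec$id,
               n_gaps = nrow(gaps),
               n_N = nchar(rec$residues) - nchar(gsub("N", "", rec$residues, fixed = TRUE)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  lens <- find_gaps_all(records, min_gap_len = min_gap_len)$length
  structure(
    list(n_gaps = sum(per$n_gaps), n_N = sum(per$n_N), per_record = per,
         gap_lengths = as.integer(lens), min_gap_len = as.integer(min_gap_len)),
    class = "gap_stats"
  )
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf("gap statistics (min gap length %d)\n", x$min_gap_len))
  cat(sprintf("  records: %d   #Gaps: %d   #N: %d\n",
              nrow(x$per_record), x$n_gaps, x$n_N))
  invisible(x)
}

#' Compare gap statistics before and after filling
#'
#' Reproduces the two accounting metrics used to evaluate a filling run:
#' gap count and total N count, before and after, with their deltas,
#' overall and per record. Records absent on one side contribute zero on
#' that side.
#'
#' @param before,after `gap_stats` objects computed with the same
#'   `min_gap_len`.
#' @return A data.frame with columns `id`, `gaps_before`, `n_before`,
#'   `gaps_after`, `n_after`, `delta_gaps`, `delta_N`; the first row
#'   (`id == "TOTAL"`) holds overall totals.
#' @export
compare_stats <- function(before, after) {
  stopifnot(inherits(before, "gap_stats"), inherits(after, "gap_stats"))
  if (before$min_gap_len != after$min_gap_len) {
    stop("gap statistics computed with different min_gap_len (",
         before$min_gap_len, " vs ", after$min_gap_len, ")")
  }
  ids <- union(before$per_record$id, after$per_record$id)
  bi <- match(ids, before$per_record$id)
  ai <- match(ids, after$per_record$id)
  pick <- function(tab, i, col) ifelse(is.na(i), 0L, tab[[col]][i])
  per <- data.frame(
    id = ids,
    gaps_before = pick(before$per_record, bi, "n_gaps"),
    n_before = pick(before$per_record, bi, "n_N"),
    gaps_after = pick(after$per_record, ai, "n_gaps"),
    n_after = pick(after$per_record, ai, "n_N"),
    stringsAsFactors = FALSE
  )
  total <- data.frame(id = "TOTAL",
                      gaps_before = before$n_gaps, n_before = before$n_N,
                      gaps_after = after$n_gaps, n_after = after$n_N,
                      stringsAsFactors = FALSE)
  out <- rbind(total, per)
  out$delta_gaps <- out$gaps_before - out$gaps_after
  out$delta_N <- out$n_before - out$n_after
  out
}

#' Export gaps as 3-column BED
#'
#' BED is 0-based half-open, matching the internal coordinates directly.
#'
#' @param gaps Gap table from [find_gaps_all()].
#' @param path Output path.
#' @export
gaps_to_bed <- function(gaps, path) {
  utils::write.table(gaps[, c("scaffold_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Write a gap-statistics comparison as TSV
#'
#' @param comparison Data.frame from [compare_stats()].
#' @param path Output path.
#' @export
write_compare_tsv <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
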