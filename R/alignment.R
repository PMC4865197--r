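#' @title Contig-versus-scaffold alignment hits
#' @name alignment
#' @description Alignment hits (HSPs) from three sources — BLAST tabular
#'   files, nucmer `show-coords -T` files, and a built-in seed-and-extend
#'   aligner — are normalized into one tabular format: 0-based half-open
#'   intervals on the forward strands of both sequences, with orientation
#'   carried solely by the `strand` column (`-` means the contig's reverse
#'   complement aligns to the scaffold forward strand). Query is always the
#'   contig, subject always the scaffold.
NULL

HIT_COLUMNS <- c("contig_id", "scaffold_id", "c_start", "c_end",
                 "s_start", "s_end", "strand", "identity", "aln_len", "score")

.empty_hits <- function() {
  data.frame(contig_id = character(0), scaffold_id = character(0),
             c_start = integer(0), c_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), identity = numeric(0),
             aln_len = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  if (nrow(hits) == 0L) return(hits)
  stopifnot(all(hits$c_start < hits$c_end), all(hits$s_start < hits$s_end),
            all(hits$strand %in% c("+", "-")), all(hits$aln_len >= 1L),
            all(hits$identity >= 0), all(hits$identity <= 100))
  hits
}

#' Parse 12-column BLAST tabular output (outfmt 6 / legacy -m 8)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore, with query = contig and subject =
#' scaffold. BLAST's 1-based inclusive coordinates are converted to
#' 0-based half-open; a subject interval with sstart > send denotes the
#' minus strand and is swapped to ascending. Comment lines (`#`) are
#' skipped.
#'
#' @param path Path to a BLAST tabular file.
#' @return Hit data.frame (see [sort_hits()] for the column contract).
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(.empty_hits())
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    line_no <- keep[i]
    if (length(f) != 12L) {
      stop("expected 12 tab-separated columns at line ", line_no,
           " of ", path, ", found ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(3, 4, 7, 8, 9, 10, 12)]))
    if (anyNA(num)) {
      stop("non-numeric coordinate or score at line ", line_no, " of ", path)
    }
    qstart <- as.integer(num[3]); qend <- as.integer(num[4])
    sstart <- as.integer(num[5]); send <- as.integer(num[6])
    if (qstart > qend) {
      stop("qstart > qend at line ", line_no, " of ", path,
           " (violates BLAST query convention)")
    }
    strand <- if (sstart > send) "-" else "+"
    if (strand == "-") { tmp <- sstart; sstart <- send; send <- tmp }
    out[[i]] <- data.frame(
      contig_id = f[1], scaffold_id = f[2],
      c_start = qstart - 1L, c_end = qend,
      s_start = sstart - 1L, s_end = send,
      strand = strand, identity = num[1],
      aln_len = as.integer(num[2]), score = num[7],
      stringsAsFactors = FALSE)
  }
  .validate_hits(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Write hits as 12-column BLAST tabular
#'
#' Inverse of [parse_blast_tabular()] up to the columns the hit table does
#' not carry (mismatch, gapopen and evalue are written as 0). Used for
#' round-trip testing and interoperability.
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  .validate_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits)) {
    sstart <- ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end)
    send <- ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L)
    writeLines(sprintf("%s\t%s\t%.17g\t%d\t0\t0\t%d\t%d\t%d\t%d\t0\t%.17g",
                       hits$contig_id, hits$scaffold_id, hits$identity,
                       hits$aln_len, hits$c_start + 1L, hits$c_end,
                       sstart, send, hits$score), con)
  }
  invisible(NULL)
}

#' Parse nucmer `show-coords -T` output
#'
#' Expects the tab-delimited dialect with its standard header (file line,
#' program line, blank line, column-header line): columns S1 E1 S2 E2 LEN1
#' LEN2 %IDY then reference and query tags, with reference = scaffold and
#' query = contig. E2 < S2 denotes the minus strand. Files produced with
#' column-reordering flags (-r/-q with -T are fine; -H, -l, -c change the
#' layout) are rejected.
#'
#' @param path Path to a show-coords -T file.
#' @return Hit data.frame; `score` is `aln_len * identity / 100`.
#' @export
parse_nucmer_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\[S1\\]\t\\[E1\\]\t\\[S2\\]\t\\[E2\\]", lines)
  if (length(hdr) != 1L) {
    stop("not recognized as show-coords -T output (expected the ",
         "tab-delimited dialect with header [S1] [E1] [S2] [E2] [LEN 1] ",
         "[LEN 2] [% IDY] TAGS): ", path)
  }
  body <- lines[seq.int(hdr + 1L, length(lines))]
  if (hdr == length(lines)) body <- character(0)
  body_no <- seq.int(hdr + 1L, length.out = length(body))
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_no <- body_no[keep]
  if (length(body) == 0L) return(.empty_hits())
  rows <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != 9L) {
      stop("expected 9 tab-separated fields at line ", body_no[i], " of ",
           path, ", found ", length(f),
           " (only the default -T column order is supported)")
    }
    num <- suppressWarnings(as.numeric(f[1:7]))
    if (anyNA(num)) stop("non-numeric field at line ", body_no[i], " of ", path)
    s1 <- as.integer(num[1]); e1 <- as.integer(num[2])
    s2 <- as.integer(num[3]); e2 <- as.integer(num[4])
    if (s1 > e1) stop("descending reference interval at line ", body_no[i],
                      " of ", path, " (run show-coords without -r/-o reordering)")
    strand <- if (e2 < s2) "-" else "+"
    if (strand == "-") { tmp <- s2; s2 <- e2; e2 <- tmp }
    aln_len <- max(as.integer(num[5]), as.integer(num[6]))
    out[[i]] <- data.frame(
      contig_id = f[9], scaffold_id = f[8],
      c_start = s2 - 1L, c_end = e2,
      s_start = s1 - 1L, s_end = e1,
      strand = strand, identity = num[7],
      aln_len = aln_len, score = aln_len * num[7] / 100,
      stringsAsFactors = FALSE)
  }
  .validate_hits(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Sort hits by mapping position on the scaffold
#'
#' Stable sort by (scaffold_id, s_start, s_end, contig_id, strand);
#' deterministic across runs and idempotent.
#'
#' @param hits Hit data.frame with columns `contig_id`, `scaffold_id`,
#'   `c_start`, `c_end`, `s_start`, `s_end` (0-based half-open, forward
#'   strand), `strand`, `identity`, `aln_len`, `score`.
#' @return The sorted hit data.frame.
#' @export
sort_hits <- function(hits) {
  .validate_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$scaffold_id, hits$s_start, hits$s_end,
               hits$contig_id, hits$strand, method = "radix")
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align contigs to scaffolds with a built-in seed-and-extend aligner
#'
#' A deterministic, dependency-free aligner for the common case where
#' contigs match scaffolds closely: every scaffold k-mer not containing N
#' is indexed; exact k-mer seed matches of each contig (and its reverse
#' complement) are grouped by diagonal and greedily merged while the
#' merged segment's mismatch rate stays within `max_mismatch_rate` and no
#' N is crossed; each merged segment is then extended base by base (right,
#' then left), stopping when the running mismatch rate would exceed
#' `max_mismatch_rate` or an N is reached on either sequence. Alignments
#' are ungapped, so identity = matches / span * 100 and `score` = match
#' count. Hits wholly contained in a higher-scoring hit of the same
#' contig/scaffold/strand/diagonal are discarded. Indel-rich data should
#' instead be aligned externally and ingested via [parse_blast_tabular()]
#' or [parse_nucmer_coords()].
#'
#' @param contigs,scaffolds Lists of [seq_record()] objects.
#' @param k Seed k-mer size (default 21; must be at least 11).
#' @param min_hit_len Minimum reported alignment span (default 31).
#' @param max_mismatch_rate Maximum running mismatch fraction (default 0.05).
#' @return Hit data.frame, sorted via [sort_hits()].
#' @export
builtin_align <- function(contigs, scaffolds, k = 21L, min_hit_len = 31L,
                          max_mismatch_rate = 0.05) {
  stopifnot(k >= 11L, min_hit_len >= 1L, max_mismatch_rate >= 0)
  k <- as.integer(k)
  N_RAW <- charToRaw("N")
  results <- list()
  for (scaf in scaffolds) {
    s_raw <- charToRaw(scaf$residues)
    s_len <- length(s_raw)
    if (s_len < k) next
    n_kmers <- s_len - k + 1L
    s_kmers <- substring(scaf$residues, seq_len(n_kmers), seq_len(n_kmers) + k - 1L)
    valid <- !grepl("N", s_kmers, fixed = TRUE)
    index <- split(which(valid), s_kmers[valid])    # 1-based start positions
    index_names <- names(index)
    for (ctg in contigs) {
      for (strand in c("+", "-")) {
        query <- if (strand == "+") ctg$residues else reverse_complement(ctg$residues)
        c_raw <- charToRaw(query)
        c_len <- length(c_raw)
        if (c_len < k) next
        nq <- c_len - k + 1L
        q_kmers <- substring(query, seq_len(nq), seq_len(nq) + k - 1L)
        slot <- match(q_kmers, index_names)
        qpos <- which(!is.na(slot))
        if (length(qpos) == 0L) next
        spos_list <- index[slot[qpos]]
        counts <- lengths(spos_list)
        seed_c <- rep.int(qpos, counts)             # 1-based
        seed_s <- unlist(spos_list, use.names = FALSE)
        diag <- seed_s - seed_c
        hits <- .extend_diagonals(seed_c, seed_s, diag, s_raw, c_raw, k,
                                  max_mismatch_rate, N_RAW)
        if (is.null(hits) || nrow(hits) == 0L) next
        hits <- hits[hits$span >= min_hit_len, , drop = FALSE]
        if (nrow(hits) == 0L) next
        hits <- .drop_contained(hits)
        # convert to forward-contig coordinates and 0-based half-open
        cs <- hits$c_start - 1L; ce <- hits$c_start + hits$span - 1L
        if (strand == "-") {
          tmp <- cs
          cs <- c_len - ce
          ce <- c_len - tmp
        }
        results[[length(results) + 1L]] <- data.frame(
          contig_id = ctg$id, scaffold_id = scaf$id,
          c_start = cs, c_end = ce,
          s_start = hits$s_start - 1L, s_end = hits$s_start + hits$span - 1L,
          strand = strand,
          identity = hits$matches / hits$span * 100,
          aln_len = hits$span, score = hits$matches,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(results) == 0L) return(.empty_hits())
  sort_hits(do.call(rbind, c(results, list(make.row.names = FALSE))))
}

# internal: merge co-diagonal seeds and extend; coordinates 1-based here.
# Returns data.frame(c_start, s_start, span, matches, diag).
.extend_diagonals <- function(seed_c, seed_s, diag, s_raw, c_raw, k,
                              max_rate, N_RAW) {
  out <- list()
  for (d in sort(unique(diag))) {
    sel <- which(diag == d)
    cpos <- sort(unique(seed_c[sel]))
    # collapse overlapping/adjacent seed k-mers into covered intervals
    iv_start <- cpos[c(TRUE, cpos[-1] > cpos[-length(cpos)] + k - 1L)]
    brk <- which(cpos[-1] > cpos[-length(cpos)] + k - 1L)
    iv_end <- cpos[c(brk, length(cpos))] + k - 1L    # inclusive end
    # greedy merge of consecutive intervals while mismatch rate holds
    cur_a <- iv_start[1]; cur_b <- iv_end[1]; cur_mm <- 0L
    segs <- list()
    if (length(iv_start) > 1L) {
      for (j in 2:length(iv_start)) {
        a <- cur_a; b <- iv_end[j]
        cseg <- c_raw[a:b]; sseg <- s_raw[(a + d):(b + d)]
        if (any(cseg == N_RAW) || any(sseg == N_RAW)) {
          segs[[length(segs) + 1L]] <- c(cur_a, cur_b, cur_mm)
          cur_a <- iv_start[j]; cur_b <- iv_end[j]; cur_mm <- 0L
          next
        }
        mm <- sum(cseg != sseg)
        if (mm <= max_rate * (b - a + 1L)) {
          cur_b <- b; cur_mm <- mm
        } else {
          segs[[length(segs) + 1L]] <- c(cur_a, cur_b, cur_mm)
          cur_a <- iv_start[j]; cur_b <- iv_end[j]; cur_mm <- 0L
        }
      }
    }
    segs[[length(segs) + 1L]] <- c(cur_a, cur_b, cur_mm)
    for (seg in segs) {
      a <- seg[1]; b <- seg[2]; mm <- seg[3]
      ext <- .extend_segment(a, b, mm, d, s_raw, c_raw, max_rate, N_RAW)
      out[[length(out) + 1L]] <- data.frame(
        c_start = ext[1], s_start = ext[1] + d, span = ext[2],
        matches = ext[2] - ext[3], diag = d)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# internal: ungapped extension of c_raw[a..b] vs s_raw[(a+d)..(b+d)],
# right phase then left phase; running mismatch rate over the whole
# growing alignment must stay <= max_rate, N stops extension.
# Returns c(new_a, span, total_mismatches).
.extend_segment <- function(a, b, mm, d, s_raw, c_raw, max_rate, N_RAW) {
  len <- b - a + 1L
  # right
  room <- min(length(c_raw) - b, length(s_raw) - (b + d))
  if (room > 0L) {
    cseg <- c_raw[(b + 1L):(b + room)]
    sseg <- s_raw[(b + d + 1L):(b + d + room)]
    ext <- .max_extension(cseg, sseg, mm, len, max_rate, N_RAW)
    b <- b + ext$n; mm <- mm + ext$mm; len <- len + ext$n
  }
  # left
  room <- min(a - 1L, a + d - 1L)
  if (room > 0L) {
    cseg <- c_raw[(a - 1L):(a - room)]
    sseg <- s_raw[(a + d - 1L):(a + d - room)]
    ext <- .max_extension(cseg, sseg, mm, len, max_rate, N_RAW)
    a <- a - ext$n; mm <- mm + ext$mm; len <- len + ext$n
  }
  c(a, len, mm)
}

# internal: longest prefix of the candidate extension such that no N is
# crossed and (mm0 + cumulative mismatches) / (len0 + i) <= max_rate at
# every step i.
.max_extension <- function(cseg, sseg, mm0, len0, max_rate, N_RAW) {
  is_n <- cseg == N_RAW | sseg == N_RAW
  lim <- if (any(is_n)) which(is_n)[1] - 1L else length(cseg)
  if (lim == 0L) return(list(n = 0L, mm = 0L))
  mmv <- cumsum(cseg[seq_len(lim)] != sseg[seq_len(lim)])
  ok <- (mm0 + mmv) <= max_rate * (len0 + seq_len(lim))
  n <- if (all(ok)) lim else which(!ok)[1] - 1L
  list(n = n, mm = if (n > 0L) as.integer(mmv[n]) else 0L)
}

# internal: drop hits wholly contained in a higher-scoring hit on the same
# diagonal (hits here share contig/scaffold/strand already).
.drop_contained <- function(hits) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  keep <- rep(TRUE, n)
  a <- hits$c_start; b <- hits$c_start + hits$span
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (hits$diag[i] == hits$diag[j] &&
          a[i] >= a[j] && b[i] <= b[j] &&
          (hits$matches[j] > hits$matches[i] ||
           (hits$matches[j] == hits$matches[i] && j < i))) {
        keep[i] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}
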