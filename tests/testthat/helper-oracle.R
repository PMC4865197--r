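# Brute-force candidate enumeration, written independently of
# find_candidates(): plain nested loops that check every hit and every
# ordered hit pair directly against the candidate definitions. Used as the
# oracle in equivalence tests.

oracle_count_N <- function(s) {
  sum(strsplit(s, "")[[1]] == "N")
}

oracle_candidates <- function(gaps, hits, scaffolds, contigs, params) {
  get_seq <- function(lst, id) {
    for (r in lst) if (r$id == id) return(r)
    stop("missing id ", id)
  }
  rows <- list()
  emit <- function(gap, contig_id, strand, kind, rs, re, fs, fe,
                   mean_identity, fsl, fsr) {
    ctg <- get_seq(contigs, contig_id)
    fill <- if (fe > fs) substr(ctg$residues, fs + 1, fe) else ""
    if (params$reject_ambiguous_fill && oracle_count_N(fill) > 0) return()
    scaf <- get_seq(scaffolds, gap$scaffold_id)
    replaced <- substr(scaf$residues, rs + 1, re)
    rows[[length(rows) + 1]] <<- data.frame(
      scaffold_id = gap$scaffold_id, gap_index = gap$index,
      gap_start = gap$start, gap_end = gap$end, gap_len = gap$length,
      contig_id = contig_id, strand = strand, kind = kind,
      replace_start = as.integer(rs), replace_end = as.integer(re),
      fill_c_start = as.integer(fs), fill_c_end = as.integer(fe),
      fill_len = as.integer(fe - fs), mean_identity = mean_identity,
      flank_support_left = as.integer(fsl),
      flank_support_right = as.integer(fsr),
      predicted_delta_N = as.integer(oracle_count_N(replaced) -
                                       oracle_count_N(fill)),
      status = "proposed", stringsAsFactors = FALSE)
  }
  for (g in seq_len(nrow(gaps))) {
    gap <- gaps[g, ]
    for (i in seq_len(nrow(hits))) {
      hi <- hits[i, ]
      if (hi$scaffold_id != gap$scaffold_id) next
      if (hi$identity < params$min_identity) next
      # span
      if (hi$s_start <= gap$start - params$flank_len &&
          hi$s_end >= gap$end + params$flank_len) {
        ungapped <- hi$aln_len == hi$s_end - hi$s_start &&
          hi$aln_len == hi$c_end - hi$c_start
        if (ungapped) {
          rs <- gap$start - params$flank_len
          re <- gap$end + params$flank_len
          if (hi$strand == "+") {
            fs <- hi$c_start + rs - hi$s_start
            fe <- hi$c_start + re - hi$s_start
          } else {
            fs <- hi$c_start + hi$s_end - re
            fe <- hi$c_end - (rs - hi$s_start)
          }
        } else {
          rs <- hi$s_start; re <- hi$s_end
          fs <- hi$c_start; fe <- hi$c_end
        }
        emit(gap, hi$contig_id, hi$strand, "span", rs, re, fs, fe,
             hi$identity, gap$start - hi$s_start, hi$s_end - gap$end)
      }
      is_left <- hi$s_end <= gap$start &&
        hi$s_end >= gap$start - params$max_edge_distance &&
        hi$s_end - hi$s_start >= params$flank_len
      is_right <- hi$s_start >= gap$end &&
        hi$s_start <= gap$end + params$max_edge_distance &&
        hi$s_end - hi$s_start >= params$flank_len
      # pairs: this hit on the left, every other qualifying hit on the right
      if (is_left) {
        for (j in seq_len(nrow(hits))) {
          hj <- hits[j, ]
          if (hj$scaffold_id != gap$scaffold_id) next
          if (hj$identity < params$min_identity) next
          if (hj$contig_id != hi$contig_id || hj$strand != hi$strand) next
          if (!(hj$s_start >= gap$end &&
                hj$s_start <= gap$end + params$max_edge_distance &&
                hj$s_end - hj$s_start >= params$flank_len)) next
          if (hi$strand == "+") {
            if (hi$c_end > hj$c_start) next
            fs <- hi$c_end; fe <- hj$c_start
          } else {
            if (hj$c_end > hi$c_start) next
            fs <- hj$c_end; fe <- hi$c_start
          }
          emit(gap, hi$contig_id, hi$strand, "pair", hi$s_end, hj$s_start,
               fs, fe, (hi$identity + hj$identity) / 2,
               hi$s_end - hi$s_start, hj$s_end - hj$s_start)
        }
      }
      if (params$allow_reduction && is_left) {
        clen <- get_seq(contigs, hi$contig_id)$length
        over <- if (hi$strand == "+") clen - hi$c_end else hi$c_start
        ext <- min(over, gap$end - hi$s_end)
        if (ext >= 1 && ext > gap$start - hi$s_end) {
          if (hi$strand == "+") { fs <- hi$c_end; fe <- hi$c_end + ext }
          else { fs <- hi$c_start - ext; fe <- hi$c_start }
          emit(gap, hi$contig_id, hi$strand, "left_extend",
               hi$s_end, hi$s_end + ext, fs, fe, hi$identity,
               hi$s_end - hi$s_start, 0)
        }
      }
      if (params$allow_reduction && is_right) {
        clen <- get_seq(contigs, hi$contig_id)$length
        over <- if (hi$strand == "+") hi$c_start else clen - hi$c_end
        ext <- min(over, hi$s_start - gap$start)
        if (ext >= 1 && ext > hi$s_start - gap$end) {
          if (hi$strand == "+") { fs <- hi$c_start - ext; fe <- hi$c_start }
          else { fs <- hi$c_end; fe <- hi$c_end + ext }
          emit(gap, hi$contig_id, hi$strand, "right_extend",
               hi$s_start - ext, hi$s_start, fs, fe, hi$identity,
               0, hi$s_end - hi$s_start)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(NULL)
  }
  unique(do.call(rbind, rows))
}

# canonical form for set comparison of candidate tables
canonical_candidates <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  key <- apply(df[, c("scaffold_id", "gap_index", "contig_id", "strand",
                      "kind", "replace_start", "replace_end",
                      "fill_c_start", "fill_c_end", "mean_identity",
                      "flank_support_left", "flank_support_right",
                      "predicted_delta_N")], 1, paste, collapse = "|")
  sort(unname(key))
}
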