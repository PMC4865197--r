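#' @title FASTA input/output and strand operations
#' @name sequence_io
#' @description Reading and writing multi-record FASTA files, plus the
#'   reverse-complement operation used for minus-strand fills. Every other
#'   module receives sequences through these functions, so the IUPAC
#'   nucleotide alphabet is enforced here once.
NULL

# IUPAC nucleotide codes and their complements. `-` is deliberately absent:
# alignment gap characters in input FASTA indicate an upstream error and are
# rejected rather than silently stripped.
IUPAC_CODES <- "ACGTNRYSWKMBDHV"
IUPAC_COMPLEMENT <- "TGCANYRSWMKVHDB"

#' Create a sequence record
#'
#' A sequence record is one FASTA entry: an identifier (the first
#' whitespace-delimited word of the header), an optional free-text
#' description (the remainder of the header), and uppercase DNA residues
#' over the IUPAC nucleotide alphabet.
#'
#' @param id Record identifier (single token, no whitespace).
#' @param residues DNA residue string; lowercase accepted and uppercased.
#' @param description Free-text description, possibly empty.
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `description`, `residues` and `length`.
#' @examples
#' rec <- seq_record("s1", "acgtn", description = "demo")
#' rec$length  # 5
#' @export
seq_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[[:space:]]", id)) {
    stop("sequence id must not contain whitespace: ", id)
  }
  residues <- toupper(residues)
  bad <- gsub(sprintf("[%s]", IUPAC_CODES), "", residues)
  if (nzchar(bad)) {
    stop(sprintf("invalid residue character(s) %s in sequence '%s'",
                 paste(sQuote(unique(strsplit(bad, "")[[1]])), collapse = ", "),
                 id))
  }
  structure(
    list(id = id, description = description, residues = residues,
         length = nchar(residues)),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s%s (%d bp)\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              x$length))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Residues are uppercased and validated against the IUPAC nucleotide
#' alphabet; original line wrapping is discarded. Duplicate identifiers,
#' residues outside the alphabet, sequence data before the first header,
#' and files with no sequences are all errors.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_idx <- grep("^>", lines)
  if (length(header_idx) == 0L) stop("no sequences in ", path)
  pre <- lines[seq_len(header_idx[1] - 1L)]
  if (any(nzchar(trimws(pre)))) {
    stop("sequence data before first header in ", path,
         " (line ", which(nzchar(trimws(pre)))[1], ")")
  }
  # validate residue lines individually so errors carry a line number
  seq_lines <- setdiff(which(nzchar(trimws(lines))), header_idx)
  for (i in seq_lines) {
    bad <- gsub(sprintf("[%s]", IUPAC_CODES), "", toupper(trimws(lines[i])))
    if (nzchar(bad)) {
      stop(sprintf("invalid residue character %s at line %d of %s",
                   sQuote(substr(bad, 1, 1)), i, path))
    }
  }
  starts <- header_idx
  ends <- c(header_idx[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  ids <- character(length(starts))
  for (j in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[j]])
    id <- sub("[[:space:]].*$", "", header)
    if (!nzchar(id)) stop("empty sequence id at line ", starts[j], " of ", path)
    desc <- trimws(sub("^[^[:space:]]*[[:space:]]*", "", header))
    body <- lines[seq(starts[j] + 1L, ends[j])]
    if (starts[j] == ends[j]) body <- character(0)
    residues <- paste(trimws(body), collapse = "")
    records[[j]] <- seq_record(id, residues, description = desc)
    ids[j] <- id
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  names(records) <- ids
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records Non-empty list of [seq_record()] objects.
#' @param path Output path.
#' @param line_width Residues per line (default 70).
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  if (length(records) == 0L) stop("no records to write")
  stopifnot(line_width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- paste0(">", rec$id,
                     if (nzchar(rec$description)) paste0(" ", rec$description) else "")
    writeLines(header, con)
    if (rec$length > 0L) {
      starts <- seq(1L, rec$length, by = line_width)
      writeLines(substring(rec$residues, starts,
                           pmin(starts + line_width - 1L, rec$length)), con)
    }
  }
  invisible(NULL)
}

#' Reverse complement of a DNA string
#'
#' Complements every residue (including IUPAC ambiguity codes: N-N, R-Y,
#' K-M, B-V, D-H, S and W self-complementary) and reverses the string.
#' An involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param residues Residue string over the IUPAC nucleotide alphabet.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AACN")  # "NGTT"
#' @export
reverse_complement <- function(residues) {
  residues <- toupper(residues)
  bad <- gsub(sprintf("[%s]", IUPAC_CODES), "", residues)
  if (nzchar(bad)) {
    stop("invalid residue character(s) in reverse_complement input: ",
         paste(sQuote(unique(strsplit(bad, "")[[1]])), collapse = ", "))
  }
  comp <- chartr(IUPAC_CODES, IUPAC_COMPLEMENT, residues)
  if (!nzchar(comp)) return(comp)
  intToUtf8(rev(utf8ToInt(comp)))
}

# internal: fetch a record by id with a clear error
.get_record <- function(records, id, what = "sequence") {
  ids <- vapply(records, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown ", what, " id: ", id)
  records[[i]]
}
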