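# Reading and writing FASTA / alignment files and result matrices.
#
# Parsing of the byte formats is delegated to Biostrings; this layer adds
# the validation the analysis depends on: unique ids, a clean amino-acid
# alphabet, no gaps in unaligned input, equal row widths in alignments.

#' A validated protein sequence record
#'
#' @param id Non-empty identifier (full FASTA header up to the newline,
#'   trimmed; internal whitespace is preserved so allergen names like
#'   "Der p 1.0101" survive).
#' @param seq Ungapped amino-acid string, stored uppercased. Allowed
#'   letters are the 20 standard residues plus ambiguity codes
#'   X, B, Z, J, U, O.
#' @param description Optional free text.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, description = NULL) {
  id <- trimws(as.character(id))
  if (length(id) != 1 || !nzchar(id)) {
    stop("sequence id must be non-empty", call. = FALSE)
  }
  seq <- toupper(as.character(seq))
  seq <- sub("\\*+$", "", seq) # trailing stop characters
  if (!nzchar(seq)) {
    stop("empty sequence for record '", id, "'", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  if (any(chars %in% c("-", "."))) {
    pos <- which(chars %in% c("-", "."))[1]
    stop("gap character in unaligned sequence at record ", id,
         ", position ", pos, call. = FALSE)
  }
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad) > 0) {
    stop("invalid amino-acid character '", chars[bad[1]], "' in record ",
         id, " at position ", bad[1], call. = FALSE)
  }
  structure(list(id = id, seq = seq, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$seq), " aa)\n", sep = "")
  invisible(x)
}

#' Read an unaligned protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of `seq_record`, one per entry, input order preserved.
#'   Sequences are uppercased and trailing "*" stop characters stripped.
#'   Duplicate ids (after whitespace trimming), empty sequences, gap
#'   characters and letters outside the amino-acid alphabet are errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- trimws(names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id in ", path, ": '", dup[1], "'",
         call. = FALSE)
  }
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- seq_record(ids[i], as.character(set[[i]]))
  }
  records
}

#' Write sequence records as FASTA
#'
#' @param records List of `seq_record`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    body <- substring(r$seq,
                      seq(1, nchar(r$seq), by = width),
                      pmin(seq(1, nchar(r$seq), by = width) + width - 1L,
                           nchar(r$seq)))
    c(paste0(">", r$id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' A multiple sequence alignment
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of equal-length gapped sequences ("." gaps
#'   are normalized to "-").
#' @return An object of class `msa_alignment` with fields `ids`, `rows`
#'   and `width`.
#' @export
msa_alignment <- function(ids, rows) {
  ids <- trimws(as.character(ids))
  rows <- toupper(gsub(".", "-", as.character(rows), fixed = TRUE))
  stopifnot(length(ids) == length(rows), length(ids) >= 1)
  if (anyDuplicated(ids)) {
    stop("duplicate id in alignment: '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  w <- nchar(rows)
  if (length(unique(w)) != 1) {
    uw <- unique(w)
    stop("ragged alignment: row lengths differ (", uw[1], " vs ", uw[2],
         ")", call. = FALSE)
  }
  if (w[1] < 1) stop("alignment width must be >= 1", call. = FALSE)
  # degapped rows must be valid sequences
  for (i in seq_along(rows)) {
    seq_record(ids[i], gsub("-", "", rows[i], fixed = TRUE))
  }
  structure(list(ids = ids, rows = rows, width = w[1]),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("Alignment: ", length(x$ids), " sequences, width ", x$width, "\n",
      sep = "")
  invisible(x)
}

# Tolerant parser for Clustal-style files: a header line starting with
# "CLUSTAL", then blocks of "<id> <segment>" lines; rows are the
# concatenation of a given id's segments across blocks. Conservation lines
# and trailing residue counters are ignored.
parse_clustal <- function(lines) {
  if (!grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file: missing CLUSTAL header", call. = FALSE)
  }
  body <- lines[-1]
  segs <- list()
  order_seen <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only space, '*', ':', '.'
    if (grepl("^[ *:.]+$", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)(\\s+\\d+)?\\s*$",
                                ln))[[1]]
    if (length(m) == 0) {
      stop("unparseable Clustal line: '", ln, "'", call. = FALSE)
    }
    id <- m[2]; seg <- m[3]
    if (!(id %in% order_seen)) order_seen <- c(order_seen, id)
    segs[[id]] <- paste0(segs[[id]] %||% "", seg)
  }
  if (length(order_seen) == 0) {
    stop("Clustal file contains no sequence rows", call. = FALSE)
  }
  msa_alignment(order_seen, unlist(segs[order_seen], use.names = FALSE))
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal. In `auto` mode the format is sniffed:
#' a first non-blank line starting with "CLUSTAL" means Clustal, a leading
#' ">" means aligned FASTA.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"clustal"`.
#' @return An `msa_alignment`. Ragged rows are a validation error reporting
#'   the differing lengths.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[cumsum(nzchar(trimws(lines))) > 0 | nzchar(trimws(lines))]
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) stop("empty alignment file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- trimws(nonblank[1])
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
              else if (startsWith(first, ">")) "fasta"
              else stop("cannot determine alignment format of ", path,
                        call. = FALSE)
  }
  if (format == "clustal") return(parse_clustal(nonblank))
  set <- Biostrings::readBStringSet(path)
  msa_alignment(names(set), as.character(set))
}

#' Write one field of a family matrix as TSV
#'
#' Produces a square tab-separated table whose first row and first column
#' hold the sequence ids in matrix order. Identity and similarity are
#' written as percentages with one decimal, A-RISC with two decimals,
#' categories as their labels; the diagonal is 100.0 / 1.00 / "high"
#' respectively.
#'
#' @param matrix A `family_matrix` from [build_family_matrix()].
#' @param path Output path.
#' @param field One of `"identity"`, `"similarity"`, `"arisc"`,
#'   `"category"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path,
                         field = c("identity", "similarity", "arisc",
                                   "category")) {
  stopifnot(inherits(matrix, "family_matrix"))
  field <- match.arg(field)
  m <- matrix[[field]]
  cells <- switch(field,
    identity   = ,
    similarity = formatC(100 * m, format = "f", digits = 1),
    arisc      = formatC(m, format = "f", digits = 2),
    category   = m
  )
  dim(cells) <- dim(m)
  out <- cbind(matrix$ids, cells)
  out <- rbind(c("id", matrix$ids), out)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write matrix to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
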