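#' Construct a sequence record
#'
#' A sequence record is the unit of input and output throughout the package:
#' one named nucleotide sequence, as read from a FASTA file. The sequence is
#' sanitized on construction (see [sanitize_sequence()]), so a stored record
#' always holds an uppercase string over `A`, `C`, `G`, `T`, `N`.
#'
#' @param id Record identifier: the first whitespace-delimited token of the
#'   FASTA header. Must be non-empty.
#' @param seq Nucleotide sequence. Sanitized unless `sanitize = FALSE`.
#' @param description Remainder of the FASTA header after the id; may be `""`.
#' @param sanitize Apply [sanitize_sequence()] to `seq` (default `TRUE`).
#'
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `description`, `seq` and `length` (bases).
#' @export
#' @examples
#' r <- seq_record("chr1", "acgtn")
#' r$seq     # "ACGTN"
#' r$length  # 5
seq_record <- function(id, seq, description = "", sanitize = TRUE) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop_format("record id must be a non-empty string")
  if (grepl("[[:space:]]", id))
    stop_format("record id '%s' must not contain whitespace", id)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop_format("seq must be a single string (record '%s')", id)
  if (isTRUE(sanitize)) seq <- sanitize_sequence(seq)
  if (!nzchar(seq))
    stop_format("record '%s' has an empty sequence", id)
  structure(
    list(id = id, description = description, seq = seq, length = nchar(seq)),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  head <- if (x$length > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<seq_record> %s%s  %s bp\n  %s\n", x$id,
              if (nzchar(x$description)) paste0(" (", x$description, ")") else "",
              format(x$length, big.mark = ","), head))
  invisible(x)
}

#' Sanitize a raw nucleotide string
#'
#' Canonicalizes arbitrary FASTA body text to the `A/C/G/T/N` alphabet used
#' by the aligner: whitespace is removed, letters are uppercased, `U` (RNA)
#' is mapped to `T`, gap characters `-` are stripped with a warning, and any
#' IUPAC ambiguity code or other letter becomes `N`. Uncertain bases are kept
#' as `N` rather than dropped so that coordinates stay faithful to the input;
#' the aligner itself never matches through an `N`.
#'
#' @param raw Input string.
#' @return Sanitized string over `{A,C,G,T,N}` (possibly empty).
#' @export
#' @examples
#' sanitize_sequence("acgu")   # "ACGT"
#' sanitize_sequence("ACRGT")  # "ACNGT"
sanitize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop_format("sequence must be a single string")
  s <- gsub("[[:space:]]+", "", raw)
  if (grepl("-", s, fixed = TRUE)) {
    warning("gap characters '-' removed from sequence", call. = FALSE)
    s <- gsub("-", "", s, fixed = TRUE)
  }
  if (!nzchar(s)) return(s)
  if (grepl("[^A-Za-z]", s))
    stop_format("sequence contains non-alphabetic characters")
  s <- toupper(s)
  s <- chartr("U", "T", s)
  # every alphabetic character that is not A/C/G/T becomes N
  gsub("[^ACGT]", "N", s)
}

#' Reverse complement
#'
#' Standard Watson-Crick reverse complement over the `{A,C,G,T,N}` alphabet
#' (`N` maps to `N`). Applying the function twice returns the input.
#'
#' @param seq String over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("AACN")  # "NGTT"
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop_format("seq must be a single string")
  if (grepl("[^ACGTN]", seq))
    stop_format("seq contains characters outside A/C/G/T/N")
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# extensions the field's FASTA files conventionally carry
.fasta_extensions <- c("fasta", "fa", "fsa", "fna")

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file into a list of [seq_record()] objects,
#' in file order. Multi-line sequence bodies are concatenated and sanitized
#' via [sanitize_sequence()]. Accepted extensions are `.fasta`, `.fa`,
#' `.fsa` and `.fna`; other extensions are read with a warning.
#'
#' @param path Path to a FASTA file.
#' @return List of `seq_record` objects.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_io("path must be a single file path")
  if (!file.exists(path))
    stop_io("FASTA file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% .fasta_extensions)
    warning(sprintf("unusual FASTA extension '.%s' for %s", ext, path),
            call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop_format("%s is not FASTA: first line does not start with '>'", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_format("failed to parse FASTA %s: %s",
                                    path, conditionMessage(e))
  )
  headers <- names(set)
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) {
    h <- trimws(headers[i])
    if (!nzchar(h))
      stop_format("record %d in %s has an empty header", i, path)
    id <- sub("[[:space:]].*$", "", h)
    desc <- if (grepl("[[:space:]]", h)) {
      trimws(sub("^[^[:space:]]+[[:space:]]+", "", h))
    } else ""
    if (!nzchar(seqs[i]))
      stop_format("record '%s' in %s has an empty sequence", id, path)
    seq_record(id, seqs[i], description = desc)
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records Non-empty list of [seq_record()] objects.
#' @param path Output path.
#' @param line_width Bases per body line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  records <- as_record_list(records)
  if (length(records) == 0L)
    stop_format("no records to write")
  if (!is.numeric(line_width) || length(line_width) != 1L || line_width < 1)
    stop_param("line_width must be a positive integer")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_io("directory does not exist: %s", dir)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  tryCatch(
    Biostrings::writeXStringSet(set, path, width = as.integer(line_width)),
    error = function(e) stop_io("cannot write %s: %s", path,
                                conditionMessage(e))
  )
  invisible(path)
}

# accept a bare seq_record where a list of records is expected
as_record_list <- function(x) {
  if (inherits(x, "seq_record")) return(list(x))
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "seq_record")))
    stop_usage("expected a seq_record or a list of seq_record objects")
  x
}
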