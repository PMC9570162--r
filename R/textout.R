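#' Write the optimally placed segment listing
#'
#' Text rendering of each query's optimal tiling: one record per tiled
#' segment, in reference order within each query (queries in input order).
#' A record is a header line
#' `>` *query id* `TAB` *initial position* `TAB` *aligned position*
#' followed by the segment's subsequence wrapped at 70 characters. The
#' initial position is the segment's 1-based start on the original query;
#' the aligned position is its 1-based start on the reference.
#' Reverse-strand subsequences are reverse complemented so every record
#' reads in reference orientation.
#'
#' @param results List of `query_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_optimal_text()] for the inverse parse.
#' @export
write_optimal_text <- function(results, path) {
  results <- check_results(results)
  if (!dir.exists(dirname(path)))
    stop_io("directory does not exist: %s", dirname(path))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in results) {
    entries <- assemble_optimal_sequence(r$tiling, r$query)
    for (i in seq_len(nrow(entries))) {
      writeLines(sprintf(">%s\t%d\t%d", r$query$id,
                         entries$query_start[i], entries$ref_start[i]), con)
      writeLines(wrap_sequence(entries$subsequence[i], 70L), con)
    }
  }
  invisible(path)
}

#' Read an optimally placed segment listing
#'
#' Parses a file written by [write_optimal_text()].
#'
#' @param path Input path.
#' @return Data frame with columns `query_id`, `initial_position`,
#'   `aligned_position`, `subsequence`.
#' @export
read_optimal_text <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0L)
    stop_format("%s contains no '>' records", path)
  ends <- c(heads[-1L] - 1L, length(lines))
  fields <- strsplit(sub("^>", "", lines[heads]), "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop_format("malformed header in %s: expected 3 tab-separated fields",
                path)
  data.frame(
    query_id = vapply(fields, `[[`, "", 1L),
    initial_position = as.integer(vapply(fields, `[[`, "", 2L)),
    aligned_position = as.integer(vapply(fields, `[[`, "", 3L)),
    subsequence = vapply(seq_along(heads), function(i) {
      paste(lines[seq.int(heads[i] + 1L, ends[i])], collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Write the similarity-ranked query FASTA
#'
#' Standard FASTA holding the original, full-length query sequences in
#' ranked order (most similar to the reference first, as produced by
#' [rank_queries()]). Each header carries the query id and a
#' `similarity=<percent>` annotation after the original description.
#'
#' @param ranked List of `query_result` objects, already ranked.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rearranged_fasta <- function(ranked, path) {
  ranked <- check_results(ranked)
  records <- lapply(ranked, function(r) {
    rec <- r$query
    rec$description <- trimws(paste(rec$description,
                                    sprintf("similarity=%.3f", r$similarity)))
    rec
  })
  write_fasta(records, path)
}

wrap_sequence <- function(seq, width) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}
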