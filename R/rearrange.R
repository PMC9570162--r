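#' Percent similarity, truncated to three decimals
#'
#' The accuracy measure reported per query and overall: `100 * mapped /
#' total`, truncated (floored, not rounded) to exactly three decimal places.
#' Truncation guarantees the printed figure never overstates the exact
#' ratio. Computed in exact integer arithmetic, so no floating-point
#' round-off can flip the third decimal.
#'
#' @param mapped Mapped bases (`0 <= mapped <= total`).
#' @param total Denominator in bases (`> 0`); the query length for a
#'   per-query figure, the summed query length for an overall figure.
#' @return Numeric percent in `[0, 100]` with three-decimal resolution.
#' @export
#' @examples
#' similarity_percent(72098, 72100)  # 99.997
similarity_percent <- function(mapped, total) {
  if (!is.numeric(mapped) || !is.numeric(total) ||
      length(mapped) != 1L || length(total) != 1L)
    stop_param("mapped and total must be single numbers")
  if (is.na(mapped) || is.na(total) || total <= 0)
    stop_param("total must be a positive number of bases")
  if (mapped < 0)
    stop_param("mapped must be non-negative")
  if (mapped > total)
    stop_consistency("mapped (%s) exceeds total (%s)",
                     format(mapped), format(total))
  ((mapped * 1e5) %/% total) / 1000
}

#' Run the full alignment pipeline over a set of queries
#'
#' Convenience driver tying the stages together: builds the reference k-mer
#' index once, computes each query's basic alignment ([align_query()]),
#' optimal tiling ([select_optimal()]) and percent similarity, and returns
#' one result object per query in input order.
#'
#' @param ref Reference [seq_record()].
#' @param queries List of query [seq_record()]s (or a single record).
#' @param k K-mer size (default 15).
#' @param threshold Minimum segment length to keep (default `k`).
#' @return List of `query_result` objects, each a list with `query`,
#'   `basic_segments`, `tiling`, `mapped_bases`, `similarity`, `ref_id` and
#'   `ref_length`.
#' @export
#' @examples
#' ref <- random_sequence(2000, seed = 1)
#' frag <- shuffle_fragments(split_reference(ref, 4), seed = 2)
#' res <- align_contigs(ref, frag)
#' overall_similarity(res)  # 100
align_contigs <- function(ref, queries, k = 15L, threshold = k) {
  stopifnot(inherits(ref, "seq_record"))
  queries <- as_record_list(queries)
  if (length(queries) == 0L)
    stop_usage("at least one query is required")
  index <- build_kmer_index(ref, k)
  lapply(queries, function(q) {
    segs <- align_query(index, q, threshold)
    til <- select_optimal(segs)
    if (is.na(til$query_id)) til$query_id <- q$id
    structure(
      list(query = q, basic_segments = segs, tiling = til,
           mapped_bases = til$mapped_bases,
           similarity = similarity_percent(til$mapped_bases, q$length),
           ref_id = index$ref_id, ref_length = index$ref_length),
      class = "query_result"
    )
  })
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf(
    "<query_result> %s vs %s: %s/%s bp mapped (%.3f%%), %d tiled segment(s)\n",
    x$query$id, x$ref_id, format(x$mapped_bases, big.mark = ","),
    format(x$query$length, big.mark = ","), x$similarity,
    nrow(x$tiling$segments)))
  invisible(x)
}

#' Rank queries by similarity to the reference
#'
#' Stable sort, most similar first; ties broken by mapped bases (descending)
#' and then by input order. This is the bottom-to-top stacking order of the
#' rearranged dot plot and the record order of the rearranged FASTA.
#'
#' @param results Non-empty list of `query_result` objects.
#' @return The same objects, reordered.
#' @export
rank_queries <- function(results) {
  results <- check_results(results)
  sims <- vapply(results, `[[`, 0, "similarity")
  mapped <- vapply(results, `[[`, 0, "mapped_bases")
  results[order(-sims, -mapped)]  # radix order: stable, preserves input order on ties
}

#' Overall similarity across all queries
#'
#' Pooled figure: total mapped bases over total query length, truncated to
#' three decimals like the per-query values.
#'
#' @param results Non-empty list of `query_result` objects.
#' @return Numeric percent.
#' @export
overall_similarity <- function(results) {
  results <- check_results(results)
  similarity_percent(
    sum(vapply(results, `[[`, 0, "mapped_bases")),
    sum(vapply(results, function(r) r$query$length, 0))
  )
}

check_results <- function(results) {
  if (inherits(results, "query_result")) results <- list(results)
  if (!is.list(results) || length(results) == 0L ||
      !all(vapply(results, inherits, TRUE, "query_result")))
    stop_usage("expected a non-empty list of query_result objects")
  results
}
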