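#' Select an optimal non-overlapping tiling of matched segments
#'
#' Resolves overlaps among one query's basic-alignment segments on the
#' reference axis by a greedy sweep. Walking the reference left to right,
#' the unresolved segment with the smallest `ref_start` opens a conflict;
#' among it and every remaining segment overlapping it, the longest one is
#' kept (ties broken by smallest `ref_start`, then forward strand, then
#' smallest `query_start`) and every segment overlapping the kept one on
#' the reference is discarded whole, never trimmed. The sweep repeats on
#' the remainder, so kept segments are pairwise disjoint on the reference;
#' query-side overlap between kept segments is allowed (a repeated region
#' may legitimately tile two reference copies from one query interval).
#' `mapped_bases` therefore counts the *distinct* query bases covered by
#' the kept segments — the union of their query intervals — so each query
#' base is counted once and percent similarity stays bounded by 100 even in
#' repeat-heavy alignments.
#'
#' @param segments `match_segments` data frame for a single query.
#' @return An object of class `tiling`: list with `query_id`, `segments`
#'   (sorted by `ref_start`, pairwise disjoint on the reference) and
#'   `mapped_bases` (distinct query bases covered by the kept segments).
#' @export
#' @examples
#' ref <- seq_record("r", strrep("ACGTTGCAGGATCCAT", 8))
#' idx <- build_kmer_index(ref, 6)
#' select_optimal(align_query(idx, ref))$mapped_bases
select_optimal <- function(segments) {
  if (!is.data.frame(segments))
    stop_usage("segments must be a match_segments data frame")
  if (nrow(segments) > 0L && length(unique(segments$query_id)) != 1L)
    stop_usage("select_optimal() expects segments of a single query, got: %s",
               paste(unique(segments$query_id), collapse = ", "))
  qid <- if (nrow(segments) > 0L) segments$query_id[1L] else NA_character_
  rem <- segments[order(segments$ref_start, segments$ref_end), , drop = FALSE]
  kept <- vector("list", nrow(rem))
  n_kept <- 0L
  while (nrow(rem) > 0L) {
    opener <- rem[1L, ]
    in_conflict <- rem$ref_start < opener$ref_end &
      rem$ref_end > opener$ref_start
    cluster <- rem[in_conflict, , drop = FALSE]
    pick <- cluster[order(-cluster$length, cluster$ref_start,
                          cluster$strand != "forward",
                          cluster$query_start)[1L], , drop = FALSE]
    n_kept <- n_kept + 1L
    kept[[n_kept]] <- pick
    overlaps_pick <- rem$ref_start < pick$ref_end &
      rem$ref_end > pick$ref_start
    rem <- rem[!overlaps_pick, , drop = FALSE]
  }
  segs <- if (n_kept > 0L) do.call(rbind, kept[seq_len(n_kept)])
          else empty_segments()
  segs <- segs[order(segs$ref_start), , drop = FALSE]
  rownames(segs) <- NULL
  class(segs) <- c("match_segments", "data.frame")
  structure(
    list(query_id = qid, segments = segs,
         mapped_bases = interval_union_length(segs$query_start,
                                              segs$query_end)),
    class = "tiling"
  )
}

# total length of the union of 0-based half-open intervals
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  covered <- 0L
  cur_start <- starts[1L]
  cur_end <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] > cur_end) {
      covered <- covered + (cur_end - cur_start)
      cur_start <- starts[i]
      cur_end <- ends[i]
    } else {
      cur_end <- max(cur_end, ends[i])
    }
  }
  covered + (cur_end - cur_start)
}

#' @export
print.tiling <- function(x, ...) {
  cat(sprintf("<tiling> %s: %d segment(s), %s bp mapped\n",
              x$query_id, nrow(x$segments),
              format(x$mapped_bases, big.mark = ",")))
  invisible(x)
}

#' Assemble the optimally placed query subsequences
#'
#' Emits, in reference order, the query subsequence of each tiling segment.
#' Reverse-strand segments are reverse complemented, so every emitted
#' subsequence reads in reference orientation and their concatenation is the
#' optimally reassembled query. Positions are 1-based.
#'
#' @param tiling A [select_optimal()] result.
#' @param query The [seq_record()] the tiling belongs to.
#' @return Data frame with one row per segment in `ref_start` order:
#'   `ref_start` (1-based position on the reference), `query_start` (1-based
#'   position on the original query) and `subsequence`.
#' @export
assemble_optimal_sequence <- function(tiling, query) {
  stopifnot(inherits(tiling, "tiling"), inherits(query, "seq_record"))
  segs <- tiling$segments
  if (nrow(segs) > 0L && !all(segs$query_id == query$id))
    stop_usage("tiling belongs to query '%s', not '%s'",
               tiling$query_id, query$id)
  if (nrow(segs) > 0L && max(segs$query_end) > query$length)
    stop_consistency("tiling segment extends past the end of query '%s'",
                     query$id)
  subseq <- substring(query$seq, segs$query_start + 1L, segs$query_end)
  rc <- segs$strand == "reverse"
  subseq[rc] <- vapply(subseq[rc], reverse_complement, "", USE.NAMES = FALSE)
  data.frame(
    ref_start = segs$ref_start + 1L,
    query_start = segs$query_start + 1L,
    subsequence = subseq,
    stringsAsFactors = FALSE
  )
}
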