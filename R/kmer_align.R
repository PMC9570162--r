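#' Build a k-mer index of a reference sequence
#'
#' Indexes every k-mer of the reference that contains no `N`, mapping it to
#' the strictly increasing list of its 0-based start positions. Repeated
#' k-mers keep all their positions (no occurrence cap), so repeat regions of
#' the reference remain visible in downstream dot plots. Uncertain bases are
#' never indexed: any k-mer overlapping an `N` is skipped.
#'
#' @param ref A [seq_record()] holding the reference.
#' @param k K-mer size in bases; `1 <= k <= ref$length`. Values outside the
#'   usual working range 10-50 are accepted with a warning.
#' @return An object of class `kmer_index`: list with `k`, `ref_id`,
#'   `ref_length` and `table` (named list, k-mer -> integer positions).
#' @export
#' @examples
#' idx <- build_kmer_index(seq_record("r", "ACGTACGT"), k = 4)
#' idx$table[["ACGT"]]  # 0 4
build_kmer_index <- function(ref, k) {
  stopifnot(inherits(ref, "seq_record"))
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k))
    stop_param("k must be a single integer")
  k <- as.integer(k)
  if (k < 1L || k > ref$length)
    stop_param("k must satisfy 1 <= k <= reference length (%d), got %d",
               ref$length, k)
  if (k < 10L || k > 50L)
    warning(sprintf("k = %d is outside the usual 10-50 range", k),
            call. = FALSE)
  starts <- seq_len(ref$length - k + 1L)
  kmers <- substring(ref$seq, starts, starts + k - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  structure(
    list(k = k, ref_id = ref$id, ref_length = ref$length,
         table = split(starts[valid] - 1L, kmers[valid])),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %s (%s bp), k = %d, %s distinct k-mers\n",
              x$ref_id, format(x$ref_length, big.mark = ","), x$k,
              format(length(x$table), big.mark = ",")))
  invisible(x)
}

#' Scan one query orientation for k-mer anchors
#'
#' An anchor is a single exact k-mer match between a reference position and
#' a position on the scanned orientation of the query. Both strands of a
#' query are handled by scanning twice: the forward sequence and its reverse
#' complement (the caller passes the already reverse-complemented string for
#' `strand = "reverse"`). A query k-mer that occurs at several reference
#' positions yields one anchor per position.
#'
#' @param index A `kmer_index`.
#' @param oriented_query Sanitized sequence of the scanned orientation.
#' @param strand `"forward"` or `"reverse"` (label only; the caller orients
#'   the sequence).
#' @return Data frame with columns `query_pos`, `ref_pos` (0-based starts on
#'   the scanned orientation and the reference) and `strand`, sorted by
#'   `(query_pos, ref_pos)`. Empty if the query is shorter than `k`.
#' @export
scan_anchors <- function(index, oriented_query, strand = c("forward", "reverse")) {
  stopifnot(inherits(index, "kmer_index"))
  strand <- match.arg(strand)
  k <- index$k
  n <- nchar(oriented_query)
  empty <- data.frame(query_pos = integer(), ref_pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n < k) return(empty)
  qs <- seq_len(n - k + 1L)
  qk <- substring(oriented_query, qs, qs + k - 1L)
  ok <- !grepl("N", qk, fixed = TRUE)
  if (!any(ok)) return(empty)
  slot <- match(qk[ok], names(index$table))
  hit <- !is.na(slot)
  if (!any(hit)) return(empty)
  pos_lists <- index$table[slot[hit]]
  counts <- lengths(pos_lists)
  # qs is increasing and each position list is increasing, so the result is
  # already sorted by (query_pos, ref_pos)
  data.frame(
    query_pos = rep.int(qs[ok][hit] - 1L, counts),
    ref_pos = unlist(pos_lists, use.names = FALSE),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Merge co-diagonal anchors into maximal exact-match segments
#'
#' Anchors sharing a diagonal (`ref_pos - query_pos` constant on the scanned
#' orientation) whose query positions step by 1 form a run; a run of `r`
#' anchors is one exact match of `r + k - 1` bases. Each returned segment is
#' maximal: no further anchor on its diagonal extends it. For reverse-strand
#' scans the scanned-orientation coordinates are mapped back to the forward
#' orientation of the query, so a segment always reports forward-query
#' coordinates plus a strand flag.
#'
#' @param anchors Data frame from [scan_anchors()] (one orientation only).
#' @param k K-mer size used for the scan.
#' @param query_length Length of the (forward) query in bases.
#' @param strand Orientation that was scanned.
#' @param query_id Query record id to stamp on the segments.
#' @return Data frame of class `match_segments` with columns `query_id`,
#'   `ref_start`, `ref_end`, `query_start`, `query_end` (0-based half-open),
#'   `strand` and `length`.
#' @export
merge_anchors <- function(anchors, k, query_length,
                          strand = c("forward", "reverse"), query_id) {
  strand <- match.arg(strand)
  if (nrow(anchors) == 0L) return(empty_segments())
  d <- anchors$ref_pos - anchors$query_pos
  o <- order(d, anchors$query_pos)
  qp <- anchors$query_pos[o]
  rp <- anchors$ref_pos[o]
  dd <- d[o]
  run_start <- c(TRUE, diff(dd) != 0L | diff(qp) != 1L)
  first <- which(run_start)
  last <- c(first[-1L] - 1L, length(qp))
  q0 <- qp[first]
  q1 <- qp[last] + k          # half-open end on the scanned orientation
  r0 <- rp[first]
  r1 <- rp[last] + k
  if (strand == "forward") {
    qs <- q0
    qe <- q1
  } else {
    qs <- query_length - q1   # map scanned coords back to the forward query
    qe <- query_length - q0
  }
  segs <- data.frame(
    query_id = query_id,
    ref_start = r0, ref_end = r1,
    query_start = qs, query_end = qe,
    strand = strand,
    length = r1 - r0,
    stringsAsFactors = FALSE
  )
  class(segs) <- c("match_segments", "data.frame")
  segs
}

empty_segments <- function() {
  segs <- data.frame(
    query_id = character(), ref_start = integer(), ref_end = integer(),
    query_start = integer(), query_end = integer(), strand = character(),
    length = integer(), stringsAsFactors = FALSE
  )
  class(segs) <- c("match_segments", "data.frame")
  segs
}

#' Align one query against an indexed reference
#'
#' Runs the basic alignment step: both orientations of the query are scanned
#' for k-mer anchors, co-diagonal anchors are merged into maximal
#' exact-match segments, and segments shorter than `threshold` are dropped.
#' Forward-strand segments match the reference directly; reverse-strand
#' segments match the reverse complement of the reported query interval.
#'
#' @param index A `kmer_index` built from the reference.
#' @param query A [seq_record()].
#' @param threshold Minimum segment length (bp) to keep; must be `>= index$k`.
#'   Defaults to `index$k`.
#' @return `match_segments` data frame sorted by
#'   `(ref_start, ref_end, strand)`.
#' @export
#' @examples
#' ref <- seq_record("r", "ACGTTGCAGGAT")
#' idx <- build_kmer_index(ref, k = 4)
#' align_query(idx, ref)  # one forward segment covering the whole reference
align_query <- function(index, query, threshold = index$k) {
  stopifnot(inherits(index, "kmer_index"), inherits(query, "seq_record"))
  if (!is.numeric(threshold) || length(threshold) != 1L)
    stop_param("threshold must be a single number")
  threshold <- as.integer(threshold)
  if (threshold < index$k)
    stop_param("threshold (%d) must be >= k-mer size (%d)",
               threshold, index$k)
  fwd <- merge_anchors(scan_anchors(index, query$seq, "forward"),
                       index$k, query$length, "forward", query$id)
  rev <- merge_anchors(
    scan_anchors(index, reverse_complement(query$seq), "reverse"),
    index$k, query$length, "reverse", query$id)
  segs <- rbind(fwd, rev)
  segs <- segs[segs$length >= threshold, , drop = FALSE]
  segs <- segs[order(segs$ref_start, segs$ref_end, segs$strand), ,
               drop = FALSE]
  rownames(segs) <- NULL
  class(segs) <- c("match_segments", "data.frame")
  segs
}
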