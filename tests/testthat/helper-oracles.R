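# Independent oracles and small generators used across the suite.
# Deliberately naive implementations, sharing no code with the package
# internals they check.

# All maximal exact matches of length >= min_len between ref and the given
# orientation of the query, by direct O(n*m) per-diagonal base comparison.
# 'N' never matches anything (not even 'N'). Returns 0-based half-open
# scanned-orientation coordinates.
oracle_mems_oriented <- function(ref, oriented_query, min_len) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(oriented_query, "")[[1]]
  m <- length(r)
  n <- length(q)
  out <- list()
  for (d in (-(n - 1L)):(m - 1L)) {
    r0 <- max(0L, d)
    q0 <- r0 - d
    len <- min(m - r0, n - q0)
    if (len < min_len) next
    eq <- r[r0 + seq_len(len)] == q[q0 + seq_len(len)] &
      r[r0 + seq_len(len)] != "N"
    runs <- rle(eq)
    pos <- cumsum(c(0L, runs$lengths))
    for (j in seq_along(runs$values)) {
      if (runs$values[j] && runs$lengths[j] >= min_len) {
        s <- pos[j]  # 0-based offset along this diagonal
        out[[length(out) + 1L]] <- c(ref_start = r0 + s,
                                     q_start = q0 + s,
                                     len = runs$lengths[j])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ref_start = integer(), q_start = integer(),
                      len = integer()))
  as.data.frame(do.call(rbind, out))
}

# Both-strand maximal exact matches in the package's output convention:
# forward-query coordinates, columns ref_start/ref_end/query_start/
# query_end/strand/length, sorted like align_query().
oracle_mems <- function(ref, query, min_len) {
  n <- nchar(query)
  fw <- oracle_mems_oriented(ref, query, min_len)
  fw <- data.frame(ref_start = fw$ref_start, ref_end = fw$ref_start + fw$len,
                   query_start = fw$q_start, query_end = fw$q_start + fw$len,
                   strand = rep("forward", nrow(fw)), length = fw$len)
  rc <- oracle_mems_oriented(ref, reverse_complement(query), min_len)
  rc <- data.frame(ref_start = rc$ref_start, ref_end = rc$ref_start + rc$len,
                   query_start = n - (rc$q_start + rc$len),
                   query_end = n - rc$q_start,
                   strand = rep("reverse", nrow(rc)), length = rc$len)
  out <- rbind(fw, rc)
  out <- out[order(out$ref_start, out$ref_end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive conflict-resolution oracle for the tiling: recompute, from scratch
# each round, the leftmost unresolved segment and the set overlapping it on
# the reference (pairwise O(n^2) checks, no sorting of the pool), extract
# the longest with the documented tie-breaks, then delete everything that
# overlaps the extraction.
oracle_tiling <- function(segs) {
  kept <- segs[0, , drop = FALSE]
  pool <- segs
  ref_overlap <- function(a, b) a["ref_start"] < b["ref_end"] &&
    a["ref_end"] > b["ref_start"]
  while (nrow(pool) > 0L) {
    leftmost <- NULL
    for (i in seq_len(nrow(pool))) {
      cand <- c(ref_start = pool$ref_start[i], ref_end = pool$ref_end[i])
      if (is.null(leftmost) ||
          cand["ref_start"] < leftmost["ref_start"] ||
          (cand["ref_start"] == leftmost["ref_start"] &&
             cand["ref_end"] < leftmost["ref_end"]))
        leftmost <- cand
    }
    in_conflict <- vapply(seq_len(nrow(pool)), function(i) {
      ref_overlap(c(ref_start = pool$ref_start[i], ref_end = pool$ref_end[i]),
                  leftmost)
    }, TRUE)
    cluster <- pool[in_conflict, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(cluster))) {
      cand <- cluster[i, ]
      better <- is.null(best) ||
        cand$length > best$length ||
        (cand$length == best$length && cand$ref_start < best$ref_start) ||
        (cand$length == best$length && cand$ref_start == best$ref_start &&
           cand$strand == "forward" && best$strand == "reverse") ||
        (cand$length == best$length && cand$ref_start == best$ref_start &&
           cand$strand == best$strand && cand$query_start < best$query_start)
      if (better) best <- cand
    }
    kept <- rbind(kept, best)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      ref_overlap(c(ref_start = pool$ref_start[i], ref_end = pool$ref_end[i]),
                  c(ref_start = best$ref_start, ref_end = best$ref_end))
    }, TRUE)
    pool <- pool[!drop, , drop = FALSE]
  }
  kept <- kept[order(kept$ref_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# length of the union of 0-based half-open intervals, by base enumeration
oracle_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  length(unique(unlist(Map(function(s, e) seq.int(s, e - 1L), starts, ends))))
}

# random match_segments-shaped instance for tiling tests
random_segments <- function(n, ref_len = 200L, query_len = 200L) {
  ref_start <- sample.int(ref_len - 20L, n, replace = TRUE) - 1L
  len <- sample(5:60, n, replace = TRUE)
  ref_end <- pmin(ref_start + len, ref_len)
  len <- ref_end - ref_start
  query_start <- sample.int(query_len - 20L, n, replace = TRUE) - 1L
  query_end <- pmin(query_start + len, query_len)
  keep <- query_end - query_start == len
  data.frame(
    query_id = "q", ref_start = ref_start, ref_end = ref_end,
    query_start = query_start, query_end = query_end,
    strand = sample(c("forward", "reverse"), n, replace = TRUE),
    length = len, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

# random sequence with some shared structure so MEMs actually occur:
# a mosaic of reference chunks (possibly reverse complemented) and noise
mosaic_query <- function(ref, n_pieces = 4L, piece = 40L) {
  L <- nchar(ref)
  parts <- vapply(seq_len(n_pieces), function(i) {
    if (runif(1) < 0.25) {
      paste(sample(c("A", "C", "G", "T"), piece, replace = TRUE),
            collapse = "")
    } else {
      s <- sample.int(L - piece, 1L)
      chunk <- substr(ref, s, s + piece - 1L)
      if (runif(1) < 0.5) reverse_complement(chunk) else chunk
    }
  }, "")
  paste(parts, collapse = "")
}

# reference-axis coverage (bp) of a segment set, by sort-and-sweep
ref_coverage <- function(segs) {
  if (nrow(segs) == 0L) return(0)
  o <- order(segs$ref_start, segs$ref_end)
  s <- segs$ref_start[o]
  e <- segs$ref_end[o]
  tot <- 0
  cs <- s[1]
  ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) {
      tot <- tot + (ce - cs)
      cs <- s[i]
      ce <- e[i]
    } else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}
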