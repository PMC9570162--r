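#' Generate a random nucleotide sequence
#'
#' Uniform i.i.d. bases over `{A,C,G,T}` (never `N`), reproducible from the
#' seed. The caller's RNG state is left untouched.
#'
#' @param length Sequence length in bases (`>= 1`).
#' @param seed Integer seed.
#' @param id Record id (default derived from length and seed).
#' @return A [seq_record()].
#' @export
#' @examples
#' random_sequence(12, seed = 42)$seq
random_sequence <- function(length, seed,
                            id = sprintf("random_%dbp_seed%d", length, seed)) {
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stop_param("length must be a positive integer")
  length <- as.integer(length)
  bases <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE))
  seq_record(id, paste(bases, collapse = ""), sanitize = FALSE)
}

#' Split a reference into consecutive fragments
#'
#' Cuts the reference into `n` consecutive fragments whose concatenation is
#' exactly the reference. The first `n - 1` fragments have length
#' `chunk_size` (default `floor(length / n)`); the last fragment carries the
#' remainder. Fragment ids are `<ref id>_T0 ... _T<n-1>` in reference order.
#'
#' @param ref Reference [seq_record()].
#' @param n Number of fragments (`>= 1`).
#' @param chunk_size Optional fixed length (bp) of the first `n - 1`
#'   fragments; must leave at least one base for the last fragment.
#' @return List of `n` [seq_record()] fragments.
#' @export
#' @examples
#' frags <- split_reference(random_sequence(100, 1), n = 4)
#' vapply(frags, `[[`, 0L, "length")  # 25 25 25 25
split_reference <- function(ref, n, chunk_size = NULL) {
  stopifnot(inherits(ref, "seq_record"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    stop_param("n must be a positive integer")
  n <- as.integer(n)
  if (is.null(chunk_size)) chunk_size <- ref$length %/% n
  chunk_size <- as.integer(chunk_size)
  if (n > 1L && chunk_size < 1L)
    stop_param("chunk_size must be >= 1")
  if ((n - 1L) * as.double(chunk_size) >= ref$length)
    stop_param("chunk_size %d too large: %d fragments of that size leave no room for the last fragment of a %d bp reference",
               chunk_size, n - 1L, ref$length)
  starts <- c(if (n > 1L) (0:(n - 2L)) * chunk_size + 1L else 1L[0],
              (n - 1L) * chunk_size + 1L)
  ends <- c(starts[-1L] - 1L, ref$length)
  lapply(seq_len(n), function(i) {
    seq_record(sprintf("%s_T%d", ref$id, i - 1L),
               substring(ref$seq, starts[i], ends[i]),
               sanitize = FALSE)
  })
}

#' Shuffle fragment order
#'
#' Applies a seeded uniform random permutation to a list of fragments.
#' Record contents are unchanged; only the list order moves. The caller's
#' RNG state is left untouched.
#'
#' @param fragments Non-empty list of [seq_record()]s.
#' @param seed Integer seed.
#' @return The permuted list.
#' @export
shuffle_fragments <- function(fragments, seed) {
  fragments <- as_record_list(fragments)
  if (length(fragments) == 0L)
    stop_usage("fragments must be non-empty")
  perm <- withr::with_seed(seed, sample.int(length(fragments)))
  fragments[perm]
}
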