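#' Build a search index over a sequence set
#'
#' The index realises the implicit trie of the lexicographically sorted
#' sequence list: `lcp[i]` is the longest common prefix of lex-adjacent
#' residues `i - 1` and `i` (`lcp[1] = 0`). All sequences start active;
#' deactivating a sequence (after it has been clustered) never changes
#' the lcp structure, only which leaves may be reported.
#'
#' @param seqs a [seq_set()].
#' @return A `search_index`: list with `seqs`, `active` (logical, in
#'   original input order) and `lcp` (integer, in lex order).
#' @export
build_index <- function(seqs) {
  stopifnot(inherits(seqs, "seq_set"))
  lex_seqs <- seqs$seq[seqs$lex_order]
  structure(
    list(seqs = seqs,
         active = rep(TRUE, length(seqs$id)),
         lcp = cpp_lcp(lex_seqs)),
    class = "search_index"
  )
}

#' @export
print.search_index <- function(x, ...) {
  cat("<search_index> ", length(x$seqs$id), " sequences, ",
      sum(x$active), " active\n", sep = "")
  invisible(x)
}

#' Find all active sequences within an edit-distance radius of a query
#'
#' Depth-first traversal of the implicit trie: the lex-sorted list is
#' scanned left to right, one banded DP row is pushed per character and
#' rows are shared across common prefixes, so a prefix is never re-aligned.
#' When the band empties after \eqn{\alpha} characters of a candidate,
#' every following candidate sharing more than \eqn{\alpha} prefix
#' characters is skipped without any work. The result is exact: it contains
#' precisely the eligible candidates whose policy cost against the query is
#' at most their own acceptance radius, with those costs.
#'
#' `band_radius` bounds the DP band during the descent and must be at least
#' every candidate's acceptance radius; `accept_radius` re-checks each leaf
#' against its own (typically length-dependent) radius. Candidates longer
#' than the query are never eligible and are skipped.
#'
#' @param index a [build_index()] result.
#' @param query query sequence (character scalar).
#' @param policy an [alignment_policy()].
#' @param band_radius integer pruning threshold for the shared DP band.
#' @param accept_radius per-candidate acceptance radius: a single integer,
#'   a function of candidate length, or an integer vector along the
#'   original sequence order. Defaults to `band_radius`.
#' @param eligible optional logical vector (original order) further
#'   restricting which active sequences may be reported.
#' @param alignments if `TRUE`, attach the pairwise alignment of every hit.
#' @return A list with `hits` (data.frame: `index`, `id`, `cost`, in
#'   lex-scan order), `alignments` (list of `pairwise_alignment` or NULL)
#'   and `n_advance` (number of DP row advances performed).
#' @export
search_all <- function(index, query, policy = alignment_policy(),
                       band_radius, accept_radius = band_radius,
                       eligible = NULL, alignments = FALSE) {
  stopifnot(inherits(index, "search_index"),
            is.character(query), length(query) == 1L,
            inherits(policy, "alignment_policy"),
            band_radius >= 0)
  seqs <- index$seqs
  n <- length(seqs$id)
  query <- toupper(query)
  acc <- accept_radius_vector(accept_radius, seqs$length, n)
  elig <- index$active
  if (!is.null(eligible)) {
    stopifnot(is.logical(eligible), length(eligible) == n)
    elig <- elig & eligible
  }
  relevant <- elig & seqs$length <= nchar(query)
  if (any(acc[relevant] > band_radius))
    stop("accept_radius may not exceed band_radius for any eligible candidate")
  lex <- seqs$lex_order
  res <- cpp_search(seqs$seq[lex], elig[lex], index$lcp, query,
                    policy$anchor_start, policy$anchor_end,
                    as.integer(band_radius), as.integer(acc[lex]))
  orig <- lex[res$idx]
  hits <- data.frame(index = orig,
                     id = seqs$id[orig],
                     cost = res$cost,
                     stringsAsFactors = FALSE)
  alns <- NULL
  if (alignments && nrow(hits)) {
    alns <- lapply(seq_len(nrow(hits)), function(i) {
      align_pair(query, seqs$seq[hits$index[i]], policy,
                 threshold = band_radius)
    })
  }
  list(hits = hits, alignments = alns, n_advance = res$n_advance)
}

# Normalise the accept_radius argument to an integer vector over the
# original sequence order.
accept_radius_vector <- function(accept_radius, lengths, n) {
  if (is.function(accept_radius)) {
    as.integer(vapply(lengths, accept_radius, numeric(1)))
  } else if (length(accept_radius) == 1L) {
    rep(as.integer(accept_radius), n)
  } else {
    stopifnot(length(accept_radius) == n)
    as.integer(accept_radius)
  }
}
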