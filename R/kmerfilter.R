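#' k-mer spectrum of a sequence
#'
#' Counts every overlapping k-mer of the sequence in a dense vector over
#' the `4^k` possible k-mers (index order: A < C < G < T, first character
#' most significant). A sequence of length `n >= k` without `N` contributes
#' exactly `n - k + 1` counts. k-mers containing `N` are dropped from the
#' spectrum of both query and candidate: projecting the five-letter
#' spectra onto the A/C/G/T subspace can only shrink the positive part of
#' a spectrum difference, so the filter bound below stays conservative.
#'
#' @param seq character scalar.
#' @param k word size (1--8).
#' @return An integer vector of length `4^k` with attribute `k`, class
#'   `kmer_spectrum`.
#' @examples
#' sp <- kmer_spectrum("ACGT", 3)
#' sum(sp)  # 2 == 4 - 3 + 1
#' @export
kmer_spectrum <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1)
  counts <- cpp_spectrum(toupper(seq), as.integer(k))
  structure(counts, k = as.integer(k), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  k <- attr(x, "k")
  nz <- which(x != 0L)
  cat("<kmer_spectrum> k = ", k, ", ", length(nz), " distinct k-mers, ",
      sum(x), " total\n", sep = "")
  if (length(nz)) {
    shown <- head(nz, 12L)
    cat(" ", paste0(kmer_label(shown - 1L, k), ":", x[shown],
                    collapse = " "),
        if (length(nz) > 12L) " ...", "\n", sep = "")
  }
  invisible(x)
}

# 0-based spectrum index -> k-mer string
kmer_label <- function(idx, k) {
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    chars <- character(k)
    for (p in k:1) {
      chars[p] <- bases[i %% 4L + 1L]
      i <- i %/% 4L
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Positive and negative parts of a spectrum difference
#'
#' For two spectra with the same `k`, computes the element-wise difference
#' `a - b` and returns the sum of its positive entries and the sum of its
#' negative entries. If two sequences are within edit distance `d`, each
#' part of their spectrum difference is bounded in magnitude by `k * d`,
#' because a single edit touches at most `k` overlapping k-mers.
#'
#' @param a,b `kmer_spectrum` objects with equal `k`.
#' @return A list with integer elements `pos` (>= 0) and `neg` (<= 0).
#' @export
pos_neg_diff <- function(a, b) {
  stopifnot(inherits(a, "kmer_spectrum"), inherits(b, "kmer_spectrum"))
  if (!identical(attr(a, "k"), attr(b, "k")))
    stop("spectra have different k (", attr(a, "k"), " vs ", attr(b, "k"), ")")
  d <- unclass(a) - unclass(b)
  list(pos = sum(d[d > 0L]), neg = sum(d[d < 0L]))
}

#' Completely sensitive k-mer screen for one candidate
#'
#' Decides whether a candidate could align to (a substring of) the query
#' within edit distance `d`. If the candidate is within `d` edits of a
#' substring of the query, then every candidate k-mer beyond those shared
#' with the query must stem from one of the at most `d` edits, each of
#' which touches at most `k` k-mers; hence
#' `pos(spectrum(candidate) - spectrum(query)) <= k * d` for every true
#' hit. The screen returns `FALSE` only when that bound is violated, so it
#' never discards a candidate whose semi-global distance to the query is
#' at most `d` (zero false negatives); it may pass false positives, which
#' the alignment search then rejects.
#'
#' @param query_spec spectrum of the query (the longer sequence).
#' @param cand_spec spectrum of the candidate (the shorter sequence).
#' @param d distance threshold (non-negative integer).
#' @return Logical: `FALSE` means the pair is provably beyond `d`.
#' @export
may_match <- function(query_spec, cand_spec, d) {
  stopifnot(d >= 0)
  k <- attr(query_spec, "k")
  pos_neg_diff(cand_spec, query_spec)$pos <= k * d
}

#' Build the k-mer filter tree over a search index
#'
#' A balanced binary tree whose nodes cover contiguous intervals of the
#' lexicographic order; each node stores the element-wise minimum and
#' maximum of the covered spectra and the interval's length extremes. The
#' minimum spectrum is a lower bound on every covered spectrum, so the
#' [may_match()] bound applied to it can discard a whole sub-list before
#' any alignment is attempted, without ever discarding a true hit; the
#' maximum spectrum serves the lossy approximate mode.
#'
#' @param index a [build_index()] result.
#' @param k word size (1--6; the node spectra are dense, so small k).
#' @return A `filter_tree` object.
#' @export
build_filter_tree <- function(index, k = 3) {
  stopifnot(inherits(index, "search_index"))
  lex_seqs <- index$seqs$seq[index$seqs$lex_order]
  tr <- cpp_build_tree(lex_seqs, as.integer(k))
  tr$lex_order <- index$seqs$lex_order
  structure(tr, class = "filter_tree")
}

#' @export
print.filter_tree <- function(x, ...) {
  cat("<filter_tree> k = ", x$k, ", ", x$n, " sequences, ",
      if (x$n) length(x$lo) else 0L, " nodes\n", sep = "")
  invisible(x)
}

#' Prune decision for a single tree node
#'
#' Exact mode prunes a subtree only when even the node's element-wise
#' minimum spectrum violates the [may_match()] bound at the loosest radius
#' any covered candidate could need (derived from the node's maximum
#' length), which cannot discard a true hit. Approximate mode instead
#' evaluates the node at the radius of its *shortest* member and adds an
#' optimistic shared-k-mer bound (element-wise minimum of the query
#' spectrum and the node maximum spectrum versus what a shortest member
#' would need). At a leaf this coincides with the exact pair test, but in
#' subtrees that mix lengths across a radius step it can discard true
#' hits, so it is lossy and may split clusters.
#'
#' @param tree a [build_filter_tree()] result.
#' @param node node number (1 = root; children in `tree$left`/`tree$right`).
#' @param query_spec the query's [kmer_spectrum()].
#' @param similarity clustering similarity in (0, 1].
#' @param mult radius multiplier (2 for the well-separated search).
#' @param mode `"exact"` or `"approximate"`.
#' @return Logical: `TRUE` means skip the whole subtree.
#' @export
prune_node <- function(tree, node, query_spec, similarity, mult = 1L,
                       mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "filter_tree"), tree$n > 0L)
  cpp_prune_node(unclass(tree), as.integer(node), as.integer(query_spec),
                 1 - similarity, as.integer(mult), mode == "approximate")
}

#' Screen all candidates for one query through the filter tree
#'
#' @param tree a [build_filter_tree()] result.
#' @param query query sequence (character scalar).
#' @param similarity clustering similarity in (0, 1]; each candidate's
#'   radius is `mult * floor((1 - similarity) * length)`.
#' @param mult radius multiplier (2 for the well-separated search).
#' @param mode `"exact"` (completely sensitive) or `"approximate"` (lossy).
#' @return Logical vector over the *original* sequence order: `TRUE` when
#'   the candidate survives the screen.
#' @export
filter_candidates <- function(tree, query, similarity, mult = 1L,
                              mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "filter_tree"))
  if (tree$n == 0L) return(logical(0))
  qspec <- cpp_spectrum(toupper(query), tree$k)
  pass_lex <- cpp_filter_tree(unclass(tree), qspec, 1 - similarity,
                              as.integer(mult), mode == "approximate")
  pass <- logical(tree$n)
  pass[tree$lex_order] <- pass_lex
  pass
}
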