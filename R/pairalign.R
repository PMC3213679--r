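#' Alignment policy: which end gaps of the shorter sequence are charged
#'
#' The distance between two sequences is the unit-cost edit distance of
#' their best (semi-)global alignment: every mismatch and every charged gap
#' costs 1, matches cost 0. Gaps at the ends of the *shorter* sequence may
#' be left free. The default policy anchors the 5' ends (leading gaps are
#' charged) and leaves 3' end gaps free, which suits reads that start at a
#' common primer but vary in length.
#'
#' `anchor_start = TRUE, anchor_end = TRUE` is a plain global alignment;
#' `FALSE, FALSE` frees both ends. An `N` residue mismatches every
#' character, including another `N`.
#'
#' @param anchor_start charge gaps at the beginning of the shorter sequence?
#' @param anchor_end charge gaps at the end of the shorter sequence?
#' @return An `alignment_policy` object.
#' @examples
#' alignment_policy()               # 5'-anchored semi-global (default)
#' alignment_policy(TRUE, TRUE)     # global
#' @export
alignment_policy <- function(anchor_start = TRUE, anchor_end = FALSE) {
  stopifnot(is.logical(anchor_start), length(anchor_start) == 1L,
            is.logical(anchor_end), length(anchor_end) == 1L)
  structure(list(anchor_start = anchor_start, anchor_end = anchor_end),
            class = "alignment_policy")
}

#' @export
print.alignment_policy <- function(x, ...) {
  lab <- if (x$anchor_start && x$anchor_end) "global"
         else if (!x$anchor_start && !x$anchor_end) "free both ends"
         else if (x$anchor_start) "semi-global (5'-anchored)"
         else "semi-global (3'-anchored)"
  cat("<alignment_policy> ", lab, "\n", sep = "")
  invisible(x)
}

#' Initialise a threshold-banded dynamic-programming row
#'
#' The row holds, for each query prefix length `j`, the best cost of
#' aligning the current vertical (subject) prefix against the first `j`
#' query characters, saturated at `threshold + 1` (the INF sentinel) as
#' soon as a cell provably exceeds the threshold. At depth 0 the row is all
#' zeros when the start is free, or the leading gap costs `0, 1, 2, ...`
#' when anchored. `band` is a covering interval (0-based column indices)
#' of the finite cells; an empty band means no alignment within the
#' threshold can extend this prefix.
#'
#' @param query query sequence (character scalar, horizontal axis).
#' @param policy an [alignment_policy()].
#' @param threshold maximum admissible cost (non-negative integer).
#' @return A `dp_row` object with fields `query`, `policy`, `threshold`,
#'   `depth`, `costs` (length `nchar(query) + 1`) and `band` (`c(lo, hi)`,
#'   or `integer(0)` when dead).
#' @seealso [advance_row()], [semi_global_cost()]
#' @export
init_row <- function(query, policy = alignment_policy(), threshold) {
  stopifnot(is.character(query), length(query) == 1L,
            inherits(policy, "alignment_policy"),
            threshold >= 0)
  query <- toupper(query)
  r <- cpp_row_init(nchar(query), policy$anchor_start, as.integer(threshold))
  structure(
    list(query = query, policy = policy, threshold = as.integer(threshold),
         depth = 0L, costs = r$costs,
         band = c(r$lo, r$hi)),
    class = "dp_row"
  )
}

#' Advance a banded row by one subject character
#'
#' Applies the three-way edit-distance recurrence (diagonal
#' match/mismatch, gap left, gap below) to the whole row, computing only
#' cells that can still be within the threshold; everything else is the
#' INF sentinel. Column 0 (subject prefix versus empty query prefix) is
#' always charged. A row whose band has emptied is absorbing: advancing it
#' returns another dead row.
#'
#' @param row a `dp_row` from [init_row()] or a previous advance.
#' @param ch a single residue (the next subject character).
#' @return The `dp_row` at depth `row$depth + 1`.
#' @export
advance_row <- function(row, ch) {
  stopifnot(inherits(row, "dp_row"), is.character(ch), nchar(ch) == 1L)
  ch <- toupper(ch)
  depth <- row$depth + 1L
  if (row_dead(row)) {
    row$depth <- depth
    row$costs[] <- row$threshold + 1L
    row$band <- integer(0)
    return(row)
  }
  r <- cpp_row_advance(row$costs, row$band[1], row$band[2], row$query, ch,
                       depth, row$threshold)
  row$depth <- depth
  row$costs <- r$costs
  row$band <- if (r$lo > r$hi) integer(0) else c(r$lo, r$hi)
  row
}

#' Is a banded row dead (no cell within the threshold)?
#' @param row a `dp_row`.
#' @return Logical scalar.
#' @export
row_dead <- function(row) length(row$band) == 0L

#' Threshold-limited (semi-)global alignment cost
#'
#' Feeds the subject through [advance_row()] and reads off the final cost:
#' the minimum of the last row when the end is free, or its last cell when
#' anchored. Returns `NA` (REJECT) exactly when the true cost under the
#' policy exceeds the threshold; a finite return value is the exact cost.
#'
#' @param query query sequence (conventionally the longer one).
#' @param subject subject sequence (the shorter; its end gaps are the ones
#'   the policy may free).
#' @param policy an [alignment_policy()].
#' @param threshold maximum admissible cost.
#' @return Integer cost, or `NA_integer_` if the cost exceeds `threshold`.
#' @examples
#' semi_global_cost("ACGTT", "ACG", threshold = 2)  # 0: 3' gaps are free
#' semi_global_cost("ACGTT", "ACG", alignment_policy(TRUE, TRUE), 2)
#' @export
semi_global_cost <- function(query, subject, policy = alignment_policy(),
                             threshold) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(subject), length(subject) == 1L,
            inherits(policy, "alignment_policy"), threshold >= 0)
  res <- cpp_pair_cost(toupper(query), toupper(subject),
                       policy$anchor_start, policy$anchor_end,
                       as.integer(threshold))
  if (res < 0) NA_integer_ else res
}

#' Optimal pairwise alignment with deterministic traceback
#'
#' Recomputes the full dynamic-programming matrix for an accepted pair and
#' returns one optimal-cost alignment. Among co-optimal steps the traceback
#' prefers diagonal (match/mismatch) over a gap in the subject row over a
#' gap in the query row, and with a free end it stops at the leftmost
#' minimum of the final row, so the output is a deterministic function of
#' the inputs.
#'
#' @inheritParams semi_global_cost
#' @return A `pairwise_alignment`: list with `query_row`, `subject_row`
#'   (equal-length gapped strings; `-` is the gap) and `cost` (the charged
#'   column count).
#' @examples
#' align_pair("ACGTT", "ACG", threshold = 2)
#' @export
align_pair <- function(query, subject, policy = alignment_policy(),
                       threshold) {
  cost <- semi_global_cost(query, subject, policy, threshold)
  if (is.na(cost))
    stop("pair exceeds the alignment threshold; no alignment is produced")
  a <- cpp_traceback(toupper(query), toupper(subject),
                     policy$anchor_start, policy$anchor_end)
  structure(list(query_row = a$query_row, subject_row = a$subject_row,
                 cost = a$cost),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> cost ", x$cost, "\n  ", x$query_row, "\n  ",
      x$subject_row, "\n", sep = "")
  invisible(x)
}
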