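#' Edit-distance radius implied by a similarity threshold
#'
#' Similarity between two aligned sequences is
#' `1 - cost / length of the shorter sequence`, with the length taken
#' before alignment (gaps excluded). The radius is therefore the largest
#' integer cost `c` with `1 - c / shorter_len >= similarity`, i.e.
#' `floor((1 - similarity) * shorter_len)`. A tiny additive guard (1e-9)
#' compensates for the binary representation of decimal similarities
#' before flooring.
#'
#' @param similarity fraction in (0, 1].
#' @param shorter_len length (bp) of the shorter sequence of a pair.
#' @return Integer radius (vectorised over `shorter_len`).
#' @examples
#' radius_for(0.99, 231)  # 2
#' radius_for(0.95, 100)  # 5
#' radius_for(1.00, 500)  # 0
#' @export
radius_for <- function(similarity, shorter_len) {
  stopifnot(similarity > 0, similarity <= 1, all(shorter_len >= 1))
  as.integer(floor((1 - similarity) * shorter_len + 1e-9))
}

#' Greedy radius-bounded clustering
#'
#' Sequences are visited in non-increasing length order; each still
#' unclustered sequence becomes the representative (center) of a new
#' cluster and recruits, in a single exact search, every unclustered
#' sequence whose alignment cost against it is within that sequence's own
#' radius (`radius_for(similarity, its length)`). Because centers are
#' always the longest remaining sequences, every member is the shorter
#' sequence of its pair, and the output satisfies, in exact filter mode:
#'
#' * validity — every member cost is within its radius;
#' * exactness — any two centers are farther apart than the threshold
#'   (a closer center would have been recruited earlier).
#'
#' With `separation = "well_separated"` each center searches out to twice
#' the radius: hits within the radius are recruited, hits between once and
#' twice the radius are flagged and can never become centers themselves
#' (though they remain recruitable). Flagged sequences left over at the
#' end form singleton clusters marked `leftover`, preserving the partition
#' property; for all other clusters the closest center to any member is
#' the center of its own cluster.
#'
#' @param seqs a [seq_set()].
#' @param similarity similarity threshold in (0, 1].
#' @param policy an [alignment_policy()].
#' @param k word size for the k-mer filter.
#' @param filter `"exact"` (completely sensitive screen), `"approximate"`
#'   (lossy, faster, may split clusters — never corrupts them) or
#'   `"none"` (no screen; identical output to `"exact"`).
#' @param separation `"standard"` or `"well_separated"`.
#' @param alignments keep the member-versus-representative pairwise
#'   alignments (needed for [build_star_msa()])?
#' @return A `dna_clustering`: list with `clusters` (each a list
#'   `center`, `members`, `costs`, `alignments`, `radius_bound`,
#'   `leftover`), `seqs`, and `params`. Member indices refer to `seqs`;
#'   the center is always the first member with cost 0.
#' @examples
#' ss <- seq_set(c("a", "b", "c"), c("AAAA", "AAAT", "CCCC"))
#' cl <- dna_cluster(ss, similarity = 0.75)
#' length(cl$clusters)  # 2
#' @export
dna_cluster <- function(seqs, similarity, policy = alignment_policy(),
                        k = 3, filter = c("exact", "approximate", "none"),
                        separation = c("standard", "well_separated"),
                        alignments = TRUE) {
  filter <- match.arg(filter)
  separation <- match.arg(separation)
  stopifnot(inherits(seqs, "seq_set"), similarity > 0, similarity <= 1)
  n <- length(seqs$id)
  params <- list(similarity = similarity, policy = policy, k = k,
                 filter = filter, separation = separation)
  if (n == 0L)
    return(new_clustering(list(), seqs, params))

  index <- build_index(seqs)
  tree <- if (filter != "none") build_filter_tree(index, k)
  well_sep <- separation == "well_separated"
  mult <- if (well_sep) 2L else 1L
  acc <- radius_for(similarity, seqs$length)
  clustered <- logical(n)
  flagged <- logical(n)
  clusters <- list()

  for (ci in seqs$len_order) {
    if (clustered[ci] || (well_sep && flagged[ci])) next
    query <- seqs$seq[ci]
    r_center <- radius_for(similarity, seqs$length[ci])
    band <- mult * r_center
    eligible <- !clustered
    if (!is.null(tree)) {
      pass <- filter_candidates(tree, query, similarity, mult = mult,
                                mode = if (filter == "approximate")
                                  "approximate" else "exact")
      pass[ci] <- TRUE # the center always reaches its own leaf
      eligible <- eligible & pass
    }
    res <- search_all(index, query, policy, band_radius = band,
                      accept_radius = mult * acc, eligible = eligible)
    hits <- res$hits
    recruit <- hits$cost <= acc[hits$index]
    members <- hits$index[recruit]
    costs <- hits$cost[recruit]
    # the center leads; remaining members keep lex-scan (recruitment) order
    self <- which(members == ci)
    ord <- c(self, setdiff(seq_along(members), self))
    members <- members[ord]
    costs <- costs[ord]
    alns <- NULL
    if (alignments) {
      alns <- lapply(seq_along(members), function(m) {
        align_pair(query, seqs$seq[members[m]], policy,
                   threshold = max(band, 0L))
      })
    }
    if (well_sep)
      flagged[hits$index[!recruit]] <- TRUE
    clustered[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- list(
      center = ci, members = members, costs = costs, alignments = alns,
      radius_bound = r_center, leftover = FALSE)
  }

  if (well_sep) {
    for (ci in seqs$len_order) {
      if (clustered[ci]) next
      clustered[ci] <- TRUE
      alns <- if (alignments)
        list(align_pair(seqs$seq[ci], seqs$seq[ci], policy, threshold = 0L))
      clusters[[length(clusters) + 1L]] <- list(
        center = ci, members = ci, costs = 0L, alignments = alns,
        radius_bound = radius_for(similarity, seqs$length[ci]),
        leftover = TRUE)
    }
  }
  new_clustering(clusters, seqs, params)
}

new_clustering <- function(clusters, seqs, params) {
  structure(list(clusters = clusters, seqs = seqs, params = params),
            class = "dna_clustering")
}

#' @export
print.dna_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat("<dna_clustering> ", length(x$clusters), " clusters over ",
      length(x$seqs$id), " sequences (similarity ",
      x$params$similarity, ", ", x$params$separation, ", filter ",
      x$params$filter, ")\n", sep = "")
  if (length(sizes))
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Summarise a clustering as a data frame
#'
#' @param object a `dna_clustering`.
#' @param ... unused.
#' @return data.frame with one row per cluster: representative id, size,
#'   maximum member cost (realised radius), radius bound, leftover flag.
#' @export
summary.dna_clustering <- function(object, ...) {
  data.frame(
    representative = object$seqs$id[vapply(object$clusters, `[[`, 1L,
                                           "center")],
    size = vapply(object$clusters, function(cl) length(cl$members),
                  integer(1)),
    radius = vapply(object$clusters, function(cl) max(cl$costs), integer(1)),
    radius_bound = vapply(object$clusters, `[[`, 1L, "radius_bound"),
    leftover = vapply(object$clusters, `[[`, TRUE, "leftover"),
    stringsAsFactors = FALSE
  )
}

#' Cluster membership as a named vector
#'
#' @param clustering a `dna_clustering`.
#' @return Integer vector mapping each sequence id to the index of its
#'   cluster in `clustering$clusters`.
#' @export
cluster_assignments <- function(clustering) {
  stopifnot(inherits(clustering, "dna_clustering"))
  out <- integer(length(clustering$seqs$id))
  names(out) <- clustering$seqs$id
  for (i in seq_along(clustering$clusters))
    out[clustering$clusters[[i]]$members] <- i
  out
}
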