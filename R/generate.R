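#' Generate synthetic read clouds with ground truth
#'
#' Emulates an amplicon read set: a few true template sequences
#' ("centers") each surrounded by a cloud of imperfect copies caused by
#' sequencing error. Centers are drawn uniformly over A/C/G/T and accepted
#' only if every pair is farther apart than twice the maximum cluster
#' radius (rejection sampling), so the planted structure is recoverable.
#' Each cloud consists of the center itself plus `cloud_size - 1` reads:
#' a read is an exact full-length copy when its drawn error count is zero;
#' otherwise it is truncated at the 3' end by at least one base (emulating
#' the quality decay of pyrosequencing reads) and edited with
#' substitutions, insertions and deletions. Erroneous reads are kept
#' strictly shorter than their center and their edit count is capped by
#' `radius_for(similarity, read length)`, so that in exact mode the greedy
#' clustering recovers every cloud intact.
#'
#' @param n_centers number of template sequences.
#' @param cloud_size reads per cloud, center included.
#' @param length_range integer range the center lengths are drawn from,
#'   in bp; the default mirrors a typical pyrosequenced 16S amplicon set
#'   (reads around 230 bp).
#' @param similarity clustering similarity the set is built for; bounds
#'   the per-read error budget.
#' @param mutation_rate per-base error probability used to draw each
#'   read's edit count (binomial, then capped at the read's radius).
#' @param max_trunc maximum 3' truncation of an erroneous read, in bp.
#' @param policy the [alignment_policy()] under which center separation is
#'   verified.
#' @param seed mandatory integer seed; the output is a deterministic
#'   function of the arguments.
#' @param fasta,truth optional paths; when given, the reads are written as
#'   FASTA and the truth table as a tab-separated file.
#' @param max_tries rejection-sampling budget for center separation.
#' @return A list with `seqs` (a [seq_set()] of all reads, cloud by
#'   cloud), `truth` (data.frame: `id`, `center`, `edits`, `length`) and
#'   `params`.
#' @examples
#' g <- generate_clouds(n_centers = 3, cloud_size = 5,
#'                      length_range = c(60, 80), similarity = 0.95,
#'                      seed = 1)
#' table(g$truth$center)
#' @export
generate_clouds <- function(n_centers = 20, cloud_size = 50,
                            length_range = c(220, 240), similarity = 0.99,
                            mutation_rate = 0.005, max_trunc = 20,
                            policy = alignment_policy(), seed,
                            fasta = NULL, truth = NULL, max_tries = 100) {
  if (missing(seed)) stop("a seed is required for reproducible generation")
  stopifnot(n_centers >= 1, cloud_size >= 1, similarity > 0, similarity <= 1,
            mutation_rate >= 0, mutation_rate < 1, max_trunc >= 1,
            length(length_range) == 2L, length_range[1] >= 20)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  d_max <- radius_for(similarity, max(length_range))
  centers <- draw_separated_centers(n_centers, length_range, 2L * d_max,
                                    policy, max_tries)
  center_ids <- sprintf("C%03d", seq_len(n_centers))

  ids <- character(0)
  reads <- character(0)
  truth_center <- character(0)
  truth_edits <- integer(0)
  for (i in seq_len(n_centers)) {
    for (r in seq_len(cloud_size)) {
      id <- if (r == 1L) center_ids[i]
            else sprintf("%s_r%04d", center_ids[i], r - 1L)
      if (r == 1L || mutation_rate == 0) {
        read <- centers[i]
        e <- 0L
      } else {
        len <- nchar(centers[i])
        e <- rbinom(1L, len, mutation_rate)
        if (e == 0L) {
          read <- centers[i]
        } else {
          mut <- mutate_read(centers[i], e, similarity, max_trunc)
          read <- mut$read
          e <- mut$edits
        }
      }
      ids <- c(ids, id)
      reads <- c(reads, read)
      truth_center <- c(truth_center, center_ids[i])
      truth_edits <- c(truth_edits, e)
    }
  }
  seqs <- seq_set(ids, reads)
  truth_df <- data.frame(id = ids, center = truth_center,
                         edits = truth_edits, length = nchar(reads),
                         stringsAsFactors = FALSE)
  if (!is.null(fasta)) write_fasta(seqs, fasta)
  if (!is.null(truth))
    utils::write.table(truth_df, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(seqs = seqs, truth = truth_df,
       params = list(n_centers = n_centers, cloud_size = cloud_size,
                     length_range = length_range, similarity = similarity,
                     mutation_rate = mutation_rate, max_trunc = max_trunc,
                     seed = seed))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

draw_separated_centers <- function(n, length_range, min_dist, policy,
                                   max_tries) {
  centers <- character(0)
  tries <- 0L
  while (length(centers) < n) {
    if (tries >= max_tries)
      stop("could not place ", n, " centers more than ", min_dist,
           " apart; use longer sequences or fewer centers")
    len <- sample(length_range[1]:length_range[2], 1L)
    cand <- random_dna(len)
    ok <- all(vapply(centers, function(prev) {
      long <- if (nchar(prev) >= len) prev else cand
      short <- if (nchar(prev) >= len) cand else prev
      is.na(semi_global_cost(long, short, policy, threshold = min_dist))
    }, logical(1)))
    if (ok) {
      centers <- c(centers, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
    }
  }
  centers
}

# Truncate at the 3' end, then apply up to e edits; the result is strictly
# shorter than the center and its edit budget never exceeds its own radius.
mutate_read <- function(center, e, similarity, max_trunc) {
  len <- nchar(center)
  trunc <- sample(seq_len(max_trunc), 1L)
  chars <- strsplit(substr(center, 1L, len - trunc), "", fixed = TRUE)[[1]]
  # conservative budget: even if every edit were a deletion, the final
  # length still affords e edits within its own radius
  e <- min(e, radius_for(similarity, length(chars)))
  while (e > 0L && e > radius_for(similarity, length(chars) - e))
    e <- e - 1L
  applied <- 0L
  bases <- c("A", "C", "G", "T")
  for (t in seq_len(e)) {
    if (length(chars) <= 1L) break
    # keep the read strictly shorter than its center
    ops <- c("sub", "del", if (length(chars) <= len - 2L) "ins")
    op <- sample(ops, 1L)
    p <- sample(length(chars), 1L)
    if (op == "sub") {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (op == "del") {
      chars <- chars[-p]
    } else {
      chars <- append(chars, sample(bases, 1L), after = p - 1L)
    }
    applied <- applied + 1L
  }
  list(read = paste(chars, collapse = ""), edits = applied)
}

# save/restore the global RNG state so generation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
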