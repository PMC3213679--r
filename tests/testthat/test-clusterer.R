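# recompute every member cost with the reference DP and check the
# radius / exactness / diameter guarantees directly. The twice-the-radius
# diameter bound follows from the triangle inequality, so the direct
# pairwise form is asserted for the metric (global) policy; for semi-global
# policies the bound holds in its star-alignment form (column-wise distance,
# see the star MSA tests) and the direct pairwise distance can exceed it
# when members cover different-length stretches of the representative.
check_clustering <- function(cl, check_exactness = TRUE) {
  seqs <- cl$seqs
  sim <- cl$params$similarity
  pol <- cl$params$policy
  for (cluster in cl$clusters) {
    center_seq <- seqs$seq[cluster$center]
    expect_equal(cluster$members[1], cluster$center)
    expect_equal(cluster$costs[1], 0L)
    for (m in seq_along(cluster$members)) {
      mem <- cluster$members[m]
      expect_lte(seqs$length[mem], seqs$length[cluster$center])
      truth <- ref_cost_policy(center_seq, seqs$seq[mem], pol)
      expect_equal(cluster$costs[m], truth)
      expect_lte(truth, radius_for(sim, seqs$length[mem]))  # validity
    }
    # diameter <= 2 x radius, by direct pairwise computation (metric policy)
    if (pol$anchor_start && pol$anchor_end &&
        length(cluster$members) > 1 && length(cluster$members) <= 12) {
      radius <- max(cluster$costs)
      for (a in cluster$members) for (b in cluster$members) {
        if (a >= b) next
        long <- if (seqs$length[a] >= seqs$length[b]) a else b
        short <- if (seqs$length[a] >= seqs$length[b]) b else a
        expect_lte(ref_cost_policy(seqs$seq[long], seqs$seq[short], pol),
                   2 * radius)
      }
    }
  }
  # partition property
  members <- unlist(lapply(cl$clusters, `[[`, "members"))
  expect_equal(sort(members), seq_along(seqs$id))
  if (check_exactness) {
    centers <- vapply(cl$clusters, `[[`, integer(1), "center")
    for (a in centers) for (b in centers) {
      if (a == b) next
      long <- if (seqs$length[a] >= seqs$length[b]) a else b
      short <- if (seqs$length[a] >= seqs$length[b]) b else a
      expect_gt(ref_cost_policy(seqs$seq[long], seqs$seq[short], pol),
                radius_for(sim, seqs$length[short]))
    }
  }
  invisible(TRUE)
}

test_that("the similarity threshold converts to a radius by flooring", {
  expect_equal(radius_for(0.99, 231), 2L)
  expect_equal(radius_for(0.95, 100), 5L)
  expect_equal(radius_for(1.0, 500), 0L)
  expect_equal(radius_for(0.9, 10), 1L)   # robust to binary representation
  expect_equal(radius_for(0.97, 150), 4L)
  # the defining property: largest c with 1 - c/L >= s
  for (s in c(0.9, 0.95, 0.97, 0.99, 0.995)) {
    for (L in c(10, 77, 100, 231, 499)) {
      c <- radius_for(s, L)
      expect_gte(1 - c / L, s - 1e-12)
      expect_lt(1 - (c + 1) / L, s)
    }
  }
})

test_that("a tiny worked example clusters as the definitions force", {
  ss <- seq_set(c("x", "y", "z"), c("AAAA", "AAAT", "CCCC"))
  cl <- dna_cluster(ss, similarity = 0.75)  # radius 1 at length 4
  expect_length(cl$clusters, 2L)
  expect_setequal(ss$id[cl$clusters[[1]]$members], c("x", "y"))
  expect_equal(ss$id[cl$clusters[[2]]$members], "z")
  check_clustering(cl)
})

test_that("identical copies collapse into one cluster at any similarity", {
  ss <- seq_set(sprintf("c%02d", 1:12), rep("ACGTACGTACGT", 12))
  for (s in c(1.0, 0.99, 0.9)) {
    cl <- dna_cluster(ss, similarity = s, alignments = FALSE)
    expect_length(cl$clusters, 1L)
    expect_length(cl$clusters[[1]]$members, 12L)
  }
})

test_that("empty and singleton inputs are handled", {
  empty <- dna_cluster(seq_set(character(), character()), 0.95)
  expect_length(empty$clusters, 0L)
  one <- dna_cluster(seq_set("a", "ACGT"), 0.95)
  expect_length(one$clusters, 1L)
})

test_that("clustering satisfies validity, exactness and the diameter bound", {
  for (seed in c(3, 91)) {
    g <- generate_clouds(n_centers = 6, cloud_size = 8,
                         length_range = c(60, 90), similarity = 0.95,
                         mutation_rate = 0.02, seed = seed)
    cl <- dna_cluster(g$seqs, 0.95)
    check_clustering(cl)
  }
})

test_that("global-policy clusterings obey the metric diameter bound directly", {
  glob <- alignment_policy(TRUE, TRUE)
  for (seed in c(6, 18)) {
    g <- generate_clouds(n_centers = 5, cloud_size = 7,
                         length_range = c(60, 80), similarity = 0.92,
                         mutation_rate = 0.02, policy = glob, seed = seed)
    cl <- dna_cluster(g$seqs, 0.92, policy = glob)
    check_clustering(cl)
  }
})

test_that("clustering is a deterministic function of its input", {
  g <- generate_clouds(n_centers = 4, cloud_size = 6,
                       length_range = c(50, 70), similarity = 0.95,
                       mutation_rate = 0.03, seed = 8)
  a <- dna_cluster(g$seqs, 0.95)
  b <- dna_cluster(g$seqs, 0.95)
  expect_identical(a$clusters, b$clusters)
  # input order must not matter beyond the documented tie rules:
  perm <- sample(n_seq(g$seqs))
  ss2 <- seq_set(g$seqs$id[perm], g$seqs$seq[perm])
  c2 <- dna_cluster(ss2, 0.95)
  ids_a <- lapply(a$clusters, function(cl) a$seqs$id[cl$members])
  ids_c <- lapply(c2$clusters, function(cl) c2$seqs$id[cl$members])
  expect_identical(ids_a, ids_c)
})

test_that("well-separated mode flags the in-between sequence into a singleton", {
  # costs: d(A,B) = 1 = r, d(B,C) = 1, d(A,C) = 2 = 2r at length 10
  A <- "AAAAAAAAAA"
  B <- "AAAACAAAAA"
  C <- "AAAACAAACA"
  glob <- alignment_policy(TRUE, TRUE)
  expect_equal(ref_cost_policy(A, B, glob), 1L)
  expect_equal(ref_cost_policy(B, C, glob), 1L)
  expect_equal(ref_cost_policy(A, C, glob), 2L)
  ss <- seq_set(c("A", "B", "C"), c(A, B, C))
  cl <- dna_cluster(ss, similarity = 0.9, policy = glob,
                    separation = "well_separated")
  expect_length(cl$clusters, 2L)
  expect_setequal(ss$id[cl$clusters[[1]]$members], c("A", "B"))
  expect_equal(ss$id[cl$clusters[[2]]$members], "C")
  expect_true(cl$clusters[[2]]$leftover)
  # standard mode would have made C a full center recruiting nothing
  std <- dna_cluster(ss, similarity = 0.9, policy = glob)
  expect_length(std$clusters, 2L)
  expect_false(any(vapply(std$clusters, `[[`, TRUE, "leftover")))
})

test_that("when all pairs are far apart, well-separated equals standard", {
  set.seed(71)
  seqs <- vapply(1:10, function(i) rand_dna(40), character(1))
  ss <- seq_set(sprintf("s%02d", 1:10), seqs)
  ws <- dna_cluster(ss, 0.95, separation = "well_separated")
  std <- dna_cluster(ss, 0.95)
  expect_equal(length(ws$clusters), 10L)
  expect_identical(lapply(ws$clusters, `[[`, "members"),
                   lapply(std$clusters, `[[`, "members"))
  expect_false(any(vapply(ws$clusters, `[[`, TRUE, "leftover")))
})

test_that("well-separated clusterings keep every member closest to its own center", {
  for (seed in c(12, 55)) {
    g <- generate_clouds(n_centers = 5, cloud_size = 7,
                         length_range = c(60, 80), similarity = 0.95,
                         mutation_rate = 0.02, seed = seed)
    cl <- dna_cluster(g$seqs, 0.95, separation = "well_separated")
    seqs <- cl$seqs
    pol <- cl$params$policy
    real <- which(!vapply(cl$clusters, `[[`, TRUE, "leftover"))
    centers <- vapply(cl$clusters[real], `[[`, integer(1), "center")
    for (ri in real) {
      cluster <- cl$clusters[[ri]]
      for (m in seq_along(cluster$members)) {
        mem <- cluster$members[m]
        r_mem <- radius_for(0.95, seqs$length[mem])
        expect_lte(cluster$costs[m], r_mem)
        for (other in centers) {
          if (other == cluster$center) next
          if (seqs$length[other] < seqs$length[mem]) next
          expect_gt(ref_cost_policy(seqs$seq[other], seqs$seq[mem], pol),
                    r_mem)
        }
      }
    }
    check_clustering(cl, check_exactness = FALSE)
  }
})

test_that("the lossy screen may split clusters but never corrupts them", {
  for (seed in c(2, 44)) {
    g <- generate_clouds(n_centers = 5, cloud_size = 8,
                         length_range = c(60, 80), similarity = 0.95,
                         mutation_rate = 0.02, seed = seed)
    cl <- dna_cluster(g$seqs, 0.95, filter = "approximate")
    check_clustering(cl, check_exactness = FALSE)
  }
})
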