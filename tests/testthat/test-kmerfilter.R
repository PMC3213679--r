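test_that("spectra count overlapping k-mers", {
  sp <- kmer_spectrum("ACGT", 3)
  expect_equal(sum(sp), 2L)  # n - k + 1
  expect_equal(sum(sp != 0L), 2L)
  sp2 <- kmer_spectrum("AAAA", 3)
  expect_equal(unclass(sp2)[1], 2L)  # AAA counted twice, nothing else
  expect_equal(sum(sp2), 2L)
  expect_equal(sum(kmer_spectrum("AC", 3)), 0L)  # n < k: empty spectrum
  set.seed(61)
  for (rep in 1:10) {
    s <- rand_dna(sample(10:60, 1))
    k <- sample(2:5, 1)
    expect_equal(as.integer(kmer_spectrum(s, k)), ref_spectrum(s, k))
    expect_equal(sum(kmer_spectrum(s, k)), nchar(s) - k + 1L)
  }
})

test_that("k-mers containing N are dropped from the spectrum", {
  sp <- kmer_spectrum("ACGNT", 3)
  expect_equal(sum(sp), 1L)  # only ACG survives
  expect_equal(as.integer(kmer_spectrum("ACGNT", 3)), ref_spectrum("ACGNT", 3))
})

test_that("pos/neg of a spectrum difference follow the definition", {
  a <- kmer_spectrum("AAAA", 3)       # {AAA: 2}
  b <- kmer_spectrum("AAAC", 3)       # {AAA: 1, AAC: 1}
  expect_equal(pos_neg_diff(a, a), list(pos = 0L, neg = 0L))
  expect_equal(pos_neg_diff(a, b), list(pos = 1L, neg = -1L))
  expect_error(pos_neg_diff(a, kmer_spectrum("AAAA", 4)), "different k")
  set.seed(62)
  for (rep in 1:10) {
    s1 <- rand_dna(30); s2 <- rand_dna(25); k <- sample(2:4, 1)
    d <- ref_spectrum(s1, k) - ref_spectrum(s2, k)
    got <- pos_neg_diff(kmer_spectrum(s1, k), kmer_spectrum(s2, k))
    expect_equal(got$pos, sum(d[d > 0]))
    expect_equal(got$neg, sum(d[d < 0]))
  }
})

test_that("the screen accepts identical pairs and rejects disjoint spectra", {
  s <- rand_dna(40)
  expect_true(may_match(kmer_spectrum(s, 3), kmer_spectrum(s, 3), 0))
  q <- kmer_spectrum("AAAAAAAA", 3)
  cand <- kmer_spectrum("CCCCCCCC", 3)
  # pos(cand - q) = 6 > 3 * 1: provably beyond d = 1
  expect_false(may_match(q, cand, 1))
})

test_that("the screen is completely sensitive for mutated, embedded reads", {
  set.seed(63)
  for (k in c(3L, 5L)) {
    for (d in c(0L, 2L, 4L)) {
      for (rep in 1:150) {
        s <- rand_dna(sample(30:60, 1))
        mutated <- apply_edits(s, d)
        q <- paste0(mutated, rand_dna(sample(0:30, 1)))
        expect_true(may_match(kmer_spectrum(q, k), kmer_spectrum(s, k), d))
      }
    }
  }
})

test_that("tree nodes bound every covered spectrum element-wise", {
  ss <- seq_set(c("a", "b"), c("ACGTAC", "TTTACG"))
  idx <- build_index(ss)
  tr <- build_filter_tree(idx, 3)
  spec_a <- ref_spectrum(ss$seq[ss$lex_order][1], 3)
  spec_b <- ref_spectrum(ss$seq[ss$lex_order][2], 3)
  expect_equal(as.integer(tr$minspec[1, ]), pmin(spec_a, spec_b))
  expect_equal(as.integer(tr$maxspec[1, ]), pmax(spec_a, spec_b))
  single <- build_filter_tree(build_index(seq_set("x", "ACGTACG")), 3)
  expect_equal(as.integer(single$minspec[1, ]), ref_spectrum("ACGTACG", 3))
  set.seed(64)
  seqs <- vapply(1:50, function(i) rand_dna(sample(15:40, 1)), character(1))
  ss <- seq_set(sprintf("r%02d", 1:50), seqs)
  idx <- build_index(ss)
  tr <- build_filter_tree(idx, 3)
  lex_specs <- t(vapply(ss$seq[ss$lex_order], ref_spectrum, integer(64), k = 3))
  for (node in seq_along(tr$lo)) {
    covered <- lex_specs[tr$lo[node]:tr$hi[node], , drop = FALSE]
    expect_true(all(sweep(covered, 2, tr$minspec[node, ], `>=`) >= 0))
    expect_true(all(sweep(covered, 2, tr$maxspec[node, ], `<=`) >= 0))
  }
})

test_that("exact pruning never touches the query's own node; disjoint nodes prune", {
  ss <- seq_set(c("q", "far1", "far2"),
                c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "CCCCCCCCCCCG"))
  idx <- build_index(ss)
  tr <- build_filter_tree(idx, 3)
  qspec <- kmer_spectrum("AAAAAAAAAAAA", 3)
  leaf_of_query <- which(tr$left == 0 &
                           ss$lex_order[tr$lo] == 1L)
  expect_false(prune_node(tr, leaf_of_query, qspec, 0.9, mode = "exact"))
  pass <- filter_candidates(tr, "AAAAAAAAAAAA", 0.9, mode = "exact")
  expect_true(pass[1])
  expect_false(pass[2])
  expect_false(pass[3])
  pass_approx <- filter_candidates(tr, "AAAAAAAAAAAA", 0.9,
                                   mode = "approximate")
  expect_true(pass_approx[1])
  expect_false(any(pass_approx[2:3]))
})

test_that("exact-mode screening passes every sequence the search would accept", {
  set.seed(65)
  g <- generate_clouds(n_centers = 6, cloud_size = 10,
                       length_range = c(70, 90), similarity = 0.95,
                       mutation_rate = 0.02, seed = 17)
  ss <- g$seqs
  idx <- build_index(ss)
  tr <- build_filter_tree(idx, 3)
  for (ci in ss$len_order[c(1, 10, 25)]) {
    query <- ss$seq[ci]
    pass <- filter_candidates(tr, query, 0.95)
    res <- search_all(idx, query, band_radius = radius_for(0.95, nchar(query)),
                      accept_radius = function(l) radius_for(0.95, l))
    expect_true(all(pass[res$hits$index]))
  }
})

test_that("clustering with the exact filter tree is identical to clustering without", {
  for (seed in c(5, 23)) {
    g <- generate_clouds(n_centers = 5, cloud_size = 8,
                         length_range = c(60, 80), similarity = 0.96,
                         mutation_rate = 0.015, seed = seed)
    with_tree <- dna_cluster(g$seqs, 0.96, filter = "exact",
                             alignments = FALSE)
    without <- dna_cluster(g$seqs, 0.96, filter = "none",
                           alignments = FALSE)
    expect_identical(with_tree$clusters, without$clusters)
  }
})
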