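test_that("alignment identity behaves on identical and near-identical pairs", {
  set.seed(3)
  a <- rand_seq(100)
  s <- align_identity(a, a)
  expect_equal(s$pide, 100)
  expect_equal(s$length, 100)

  b <- strsplit(a, "")[[1]]
  b[50] <- setdiff(AA, b[50])[1]
  b <- paste(b, collapse = "")
  s <- align_identity(a, b)
  expect_equal(s$pide, 99)
  expect_equal(s$length, 100)

  # symmetry
  c <- rand_seq(80)
  expect_equal(align_identity(a, c), align_identity(c, a))
  expect_error(align_identity("", a), "empty")
})

test_that("the HSSP threshold matches its closed form and plateaus", {
  expect_equal(hssp_threshold(250), 480 * 250^(-0.32 * (1 + exp(-0.25))))
  expect_equal(hssp_threshold(250), 20.7155, tolerance = 1e-4)
  expect_equal(hssp_threshold(5), 100)
  expect_equal(hssp_threshold(11), 100)
  expect_equal(hssp_threshold(10000), 19.5)
  # continuity at the 450-column breakpoint, within 0.1 points
  expect_lt(abs(hssp_threshold(450) - 19.5), 0.1)
  # essentially monotone beyond 11 columns: the closed form rises by under
  # 0.03 points in total approaching the 450 breakpoint, never more
  grid <- hssp_threshold(12:2000)
  expect_true(all(diff(grid) <= 0.002))
  expect_lt(hssp_threshold(450) - min(hssp_threshold(12:450)), 0.03)
  expect_lt(hssp_threshold(450), hssp_threshold(12))
  expect_error(hssp_threshold(0), "positive")
})

test_that("HVAL is identity minus the length threshold", {
  set.seed(4)
  a <- rand_seq(250)
  expect_equal(hval(a, a), 100 - hssp_threshold(250))
  expect_gt(hval(a, a), 79)
  # the 40%-at-250 anchor: identity just above the threshold + 20
  expect_gt(20 + hssp_threshold(250), 40)
  # unrelated random sequences sit far below the similarity cut
  b <- rand_seq(250)
  expect_lt(hval(a, b), 0)
})

test_that("redundancy reduction removes duplicates and shared proteins", {
  set.seed(6)
  prot <- rand_proteome(6, len = 120)
  dup <- make_interactions(
    make_interaction("Q001", "Q002", "m", 9),
    make_interaction("Q001", "Q002", "m", 8))
  red <- reduce_redundancy(dup, prot)
  expect_equal(nrow(red), 1)
  expect_equal(evidence_score(red$evidence[[1]]), 9)  # best evidence kept

  shared <- make_interactions(
    make_interaction("Q001", "Q002", "m", 9),
    make_interaction("Q001", "Q003", "m", 8))
  expect_equal(nrow(reduce_redundancy(shared, prot)), 1)

  unrelated <- make_interactions(
    make_interaction("Q001", "Q002", "m", 9),
    make_interaction("Q003", "Q004", "m", 8),
    make_interaction("Q005", "Q006", "m", 7))
  expect_equal(nrow(reduce_redundancy(unrelated, prot)), 3)

  expect_error(reduce_redundancy(make_interaction("Z1", "Z2", "m", 5), prot),
               "no sequence")
})

test_that("reduction output has disjoint, mutually dissimilar interactions", {
  set.seed(7)
  spec <- synthetic_spec(n_proteins = 40, len_range = c(80, 120),
                         n_families = 6, family_size = 3,
                         n_positive = 12, fraction_failing = 0, seed = 7)
  org <- simulate_organism(spec)
  # plant extra redundancy: interactions reusing family members
  fam <- org$proteome[org$proteome$family > 0, ]
  extra <- do.call(rbind, lapply(1:5, function(i)
    make_interaction(fam$id[2 * i - 1], fam$id[2 * i], "m", 6)))
  ints <- rbind(org$interactions[, c("id_a", "id_b", "self", "evidence")],
                extra)
  red <- reduce_redundancy(ints, org$proteome)
  prots <- c(red$id_a, red$id_b)
  expect_false(anyDuplicated(prots) > 0)
  # the greedy rule constrains proteins of *different* retained interactions;
  # the two partners within one interaction may be similar
  seqs <- stats::setNames(org$proteome$sequence, org$proteome$id)
  interaction_of <- rep(seq_len(nrow(red)), 2)
  for (i in seq_along(prots))
    for (j in seq_len(i - 1))
      if (interaction_of[i] != interaction_of[j])
        expect_lte(hval(seqs[[prots[i]]], seqs[[prots[j]]]), 20)
})

test_that("negative sampling meets count, constraint and determinism", {
  set.seed(8)
  prot <- rand_proteome(40, len = 90)
  pos <- make_interactions(
    make_interaction("Q001", "Q002", "m", 9),
    make_interaction("Q003", "Q004", "m", 9),
    make_interaction("Q005", "Q006", "m", 9))
  cfg <- sampling_config(negative_ratio = 10, seed = 77)
  neg <- sample_negatives(pos, prot, cfg)
  expect_equal(nrow(neg), 30)
  expect_equal(attr(neg, "seed"), 77L)
  # distinct pairs, disjoint from positives, canonical order
  keys <- paste(neg$id_a, neg$id_b)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(neg$id_a < neg$id_b))
  expect_false(any(keys %in% paste(pos$id_a, pos$id_b)))
  # endpoints dissimilar to every positive protein
  pos_ids <- unique(c(pos$id_a, pos$id_b))
  expect_false(any(c(neg$id_a, neg$id_b) %in% pos_ids))
  seqs <- stats::setNames(prot$sequence, prot$id)
  for (p in unique(c(neg$id_a, neg$id_b)))
    for (q in pos_ids)
      expect_lt(hval(seqs[[p]], seqs[[q]]), 20)
  # reproducible from the seed
  neg2 <- sample_negatives(pos, prot, cfg)
  expect_equal(neg, neg2)
  # a different seed gives a different draw
  neg3 <- sample_negatives(pos, prot, sampling_config(seed = 78))
  expect_false(identical(neg[, 1:2], neg3[, 1:2]))
})

test_that("negative sampling errors when the pool is exhausted", {
  set.seed(9)
  base <- rand_seq(100)
  # every protein is a near-copy of a positive protein
  prot <- data.frame(id = sprintf("Q%03d", 1:6),
                     sequence = vapply(1:6, function(i) {
                       s <- strsplit(base, "")[[1]]
                       s[i] <- setdiff(AA, s[i])[1]
                       paste(s, collapse = "")
                     }, character(1)))
  pos <- make_interaction("Q001", "Q002", "m", 9)
  expect_error(sample_negatives(pos, prot, sampling_config(seed = 1)),
               "shortfall")
})

test_that("cached and uncached HVAL agree", {
  set.seed(10)
  prot <- rand_proteome(8, len = 80)
  pos <- make_interaction("Q001", "Q002", "m", 9)
  cache <- hval_cache()
  n1 <- sample_negatives(pos, prot, sampling_config(seed = 3), cache)
  n2 <- sample_negatives(pos, prot, sampling_config(seed = 3))
  expect_equal(n1, n2)
})
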