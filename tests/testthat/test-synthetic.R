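test_that("proteome simulation is reproducible and family-structured", {
  spec <- synthetic_spec(n_proteins = 20, len_range = c(80, 120),
                         n_families = 3, family_size = 3,
                         mutation_rate = 0, seed = 41)
  p1 <- simulate_proteome(spec)
  p2 <- simulate_proteome(spec)
  expect_identical(p1, p2)
  # mutation rate 0: family members identical
  fam1 <- p1$sequence[p1$family == 1]
  expect_equal(length(unique(fam1)), 1)
  expect_gt(hval(fam1[1], fam1[2]), 70)
  # default rate keeps members homologous, strangers dissimilar
  spec2 <- synthetic_spec(n_proteins = 20, len_range = c(150, 250),
                          n_families = 3, family_size = 3, seed = 42)
  p3 <- simulate_proteome(spec2)
  expect_true(kernppi:::verify_family_structure(p3))
  # unrelated random sequences: ~5% identity, HVAL well below 0
  singles <- p3$sequence[p3$family == 0]
  s <- align_identity(singles[1], singles[2])
  expect_lt(s$pide, 25)
  expect_lt(hval(singles[1], singles[2]), 0)
})

test_that("planted positives share their motif pair verbatim", {
  spec <- synthetic_spec(n_proteins = 30, len_range = c(60, 90),
                         n_positive = 8, motif_length = 4,
                         n_motif_pairs = 2, fraction_failing = 0, seed = 43)
  org <- simulate_organism(spec)
  seqs <- stats::setNames(org$proteome$sequence, org$proteome$id)
  found <- vapply(seq_len(nrow(org$interactions)), function(i) {
    a <- seqs[[org$interactions$id_a[i]]]
    b <- seqs[[org$interactions$id_b[i]]]
    any(vapply(seq_len(nrow(org$motifs)), function(m)
      (grepl(org$motifs$m1[m], a, fixed = TRUE) &&
       grepl(org$motifs$m2[m], b, fixed = TRUE)) ||
      (grepl(org$motifs$m1[m], b, fixed = TRUE) &&
       grepl(org$motifs$m2[m], a, fixed = TRUE)), logical(1)))
  }, logical(1))
  expect_true(all(found))
  # no protein participates in two planted positives
  prots <- c(org$interactions$id_a, org$interactions$id_b)
  expect_false(anyDuplicated(prots) > 0)
})

test_that("the evidence model controls the curation failure rate", {
  spec_fail <- synthetic_spec(n_proteins = 30, len_range = c(60, 90),
                              n_positive = 8, fraction_failing = 1, seed = 44)
  org <- simulate_organism(spec_fail)
  expect_equal(nrow(filter_by_evidence(org$interactions)), 0)
  spec_ok <- synthetic_spec(n_proteins = 30, len_range = c(60, 90),
                            n_positive = 8, fraction_failing = 0, seed = 44)
  org2 <- simulate_organism(spec_ok)
  expect_equal(nrow(filter_by_evidence(org2$interactions)), 8)
  expect_equal(filter_by_evidence(org2$interactions)$strong, rep(TRUE, 8))
})

test_that("generated data satisfies the upstream validators", {
  spec <- synthetic_spec(n_proteins = 25, len_range = c(60, 90),
                         n_positive = 6, seed = 45)
  org <- simulate_organism(spec, profile_alpha = 0.2)
  for (pr in org$profiles) {
    expect_equal(rowSums(pr$probs), rep(1, nrow(pr$probs)), tolerance = 1e-9)
    expect_true(all(pr$probs > 0))
  }
  expect_true(all(org$interactions$id_a <= org$interactions$id_b))
  for (ev in org$interactions$evidence) {
    expect_gte(min(ev$score), 1)
    expect_lte(max(ev$score), 10)
  }
})

test_that("one planted interaction per family survives reduction exactly", {
  set.seed(46)
  f <- 5
  spec <- synthetic_spec(n_proteins = 2 * f, len_range = c(100, 150),
                         n_families = f, family_size = 2,
                         n_positive = 0, seed = 46)
  prot <- simulate_proteome(spec)
  # one interaction inside each family (its two members interact)
  ints <- do.call(rbind, lapply(seq_len(f), function(fa) {
    ids <- prot$id[prot$family == fa]
    make_interaction(ids[1], ids[2], "m", 9)
  }))
  red <- reduce_redundancy(ints, prot)
  expect_equal(nrow(red), f)
  # but a second interaction touching any family is removed
  ids1 <- prot$id[prot$family == 1]
  ids2 <- prot$id[prot$family == 2]
  ints2 <- rbind(ints, make_interaction(ids1[2], ids2[2], "m", 1))
  expect_equal(nrow(reduce_redundancy(ints2, prot)), f)
})

test_that("synthetic organisms round-trip through the on-disk formats", {
  spec <- synthetic_spec(n_proteins = 10, len_range = c(40, 60),
                         n_positive = 3, fraction_failing = 0, seed = 47)
  org <- simulate_organism(spec, profile_alpha = 0.3)
  dir <- withr::local_tempdir()
  write_synthetic(org, dir)
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(prot$id, org$proteome$id)
  expect_equal(prot$sequence, org$proteome$sequence)
  st <- read_score_table(file.path(dir, "scores.tsv"))
  expect_equal(sort(names(st)), sort(names(org$scores)))
  ints <- read_interactions(file.path(dir, "interactions.tsv"), "tsv", st)
  expect_equal(ints[, c("id_a", "id_b")],
               org$interactions[order(org$interactions$id_a,
                                      org$interactions$id_b),
                                c("id_a", "id_b")],
               ignore_attr = TRUE)
  pssm <- read_pssm(file.path(dir, "profiles",
                              paste0(org$proteome$id[1], ".pssm")))
  expect_equal(pssm$query, org$proteome$sequence[1])
  prof <- pssm_to_profile(pssm, org$proteome$id[1])
  # integer percentages drop sub-0.5% entries, inflating the rest a little
  expect_lt(max(abs(prof$probs - org$profiles[[1]]$probs)), 0.05)
})
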