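test_that("family generation is deterministic and respects the identity cap", {
  f1 <- generate_family(n_members = 4, length_range = c(50, 80),
                        motif_set = c("QQQPG", "SSYGG"), seed = 5)
  f2 <- generate_family(n_members = 4, length_range = c(50, 80),
                        motif_set = c("QQQPG", "SSYGG"), seed = 5)
  expect_identical(f1$members, f2$members)
  expect_equal(length(f1$members), 4)
  prs <- combn(4, 2)
  for (c in seq_len(ncol(prs)))
    expect_lte(pairwise_identity(f1$members[[prs[1, c]]],
                                 f1$members[[prs[2, c]]]), 0.5)
  expect_true(all(strsplit(paste(f1$members, collapse = ""), "")[[1]] %in%
                  rownames(build_similarity_matrix())))
})

test_that("zero mutation rates cannot satisfy the identity cap", {
  p0 <- mutation_params(substitution_rate = 0, insertion_rate = 0,
                        deletion_rate = 0)
  expect_error(generate_family(n_members = 3, length_range = c(50, 60),
                               params = p0, max_retries = 5, seed = 1),
               class = "shark_generator_error")
  expect_error(mutation_params(substitution_rate = 1.5),
               class = "shark_config_error")
})

test_that("Grantham-biased mutation conserves at least one implanted motif", {
  S <- build_similarity_matrix()
  p <- mutation_params(substitution_rate = 0.3)
  for (seed in 1:3) {
    motifs <- c("QPGQSSYG", "KEEKSPGE", "GYSSQQPG")
    fam <- generate_family(n_members = 5, length_range = c(80, 120),
                           motif_set = motifs, params = p, seed = seed)
    for (m in fam$members) {
      best <- max(vapply(motifs, function(mo)
        max(kmer_similarity_matrix(mo, m, nchar(mo), S)), 1))
      expect_gte(best, 0.8)
    }
  }
})

test_that("pairwise identity follows the global-alignment convention", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1)
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0)
  expect_equal(pairwise_identity("AAAA", "AAAC"), 0.75)
  expect_equal(pairwise_identity("ACDEF", "FEDCA"),
               pairwise_identity("FEDCA", "ACDEF"))
  expect_error(pairwise_identity("", "AAA"), class = "shark_config_error")
})

test_that("dataset generation is deterministic with distinct motif sets", {
  d1 <- generate_dataset(n_families = 5, members_range = c(3, 4),
                         length_range = c(50, 80), seed = 21)
  d2 <- generate_dataset(n_families = 5, members_range = c(3, 4),
                         length_range = c(50, 80), seed = 21)
  expect_identical(lapply(d1, `[[`, "members"), lapply(d2, `[[`, "members"))
  motifs <- lapply(d1, function(f) f$provenance$motif_set)
  expect_equal(anyDuplicated(unlist(motifs)), 0)
  expect_warning(generate_dataset(n_families = 2, members_range = c(2, 2),
                                  length_range = c(50, 60), spread = 0,
                                  seed = 1), "spread")
})

test_that("within-family similarity exceeds cross-family similarity", {
  S <- build_similarity_matrix()
  for (seed in 1:3) {
    fams <- generate_dataset(n_families = 6, members_range = c(3, 3),
                             length_range = c(60, 120), seed = seed)
    seqs <- dataset_sequences(fams)
    fmap <- dataset_family_map(fams)
    fam <- setNames(fmap$family_id, fmap$sequence_id)
    pr <- combn(length(seqs), 2)
    sc <- vapply(seq_len(ncol(pr)), function(c)
      shark_score_best(seqs[[pr[1, c]]], seqs[[pr[2, c]]], 5, S), 1)
    within <- fam[pr[1, ]] == fam[pr[2, ]]
    expect_gt(mean(sc[within]), mean(sc[!within]))
  }
})

test_that("family splits follow largest-remainder rounding and are disjoint", {
  fams <- generate_dataset(n_families = 10, members_range = c(2, 3),
                           length_range = c(50, 60), seed = 31)
  sp <- split_by_family(fams, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 6L, validation = 2L, test = 2L))
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_ids), sort(vapply(fams, `[[`, "", "family_id")))
  expect_equal(anyDuplicated(all_ids), 0)
  expect_identical(sp, split_by_family(fams, c(0.6, 0.2, 0.2), seed = 1))
  expect_error(split_by_family(fams[1:2], seed = 1),
               class = "shark_config_error")
  expect_error(split_by_family(fams, c(0.5, 0.2, 0.2), seed = 1),
               class = "shark_config_error")
})
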