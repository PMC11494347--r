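S <- build_similarity_matrix()

test_that("search returns one ranked hit per database entry", {
  model <- tiny_model()
  fams <- tiny_dataset()
  db <- dataset_sequences(fams)[1:5]
  hits <- shark_search(model, db[1], db)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$rank, 1:5)
  expect_true(all(diff(hits$probability) <= 0))
  expect_error(shark_search(model, db[1], db, threshold = 1.01),
               class = "shark_config_error")
  expect_error(shark_search(model, db[1], character(0)),
               class = "shark_config_error")
  # deterministic re-run
  expect_identical(as.data.frame(hits),
                   as.data.frame(shark_search(model, db[1], db)))
})

test_that("unreadable database entries are skipped into the rejects list", {
  model <- tiny_model()
  fams <- tiny_dataset()
  db <- dataset_sequences(fams)[1:4]
  db["weird"] <- "ACDXXZ"
  expect_warning(hits <- shark_search(model, db[1], db), "skipping")
  expect_equal(nrow(hits), 4)
  expect_equal(attr(hits, "rejects"), "weird")
})

test_that("background distributions are seeded and quantile-monotone", {
  fams <- tiny_dataset()
  seqs <- dataset_sequences(fams)
  fmap <- dataset_family_map(fams)
  bg1 <- build_background(seqs, n_pairs = 50, family_map = fmap, seed = 3)
  bg2 <- build_background(seqs, n_pairs = 50, family_map = fmap, seed = 3)
  expect_identical(bg1$samples, bg2$samples)
  expect_equal(nrow(bg1$samples), 50)
  for (j in seq_len(10))
    expect_lte(quantile(bg1$samples[, j], 0), quantile(bg1$samples[, j], 1))
  expect_warning(build_background(seqs[1:3], n_pairs = 1e6, seed = 1),
                 "capped")
  expect_error(build_background(seqs[1], n_pairs = 5, seed = 1),
               class = "shark_config_error")
})

test_that("score context reports empirical percentiles", {
  fams <- tiny_dataset()
  seqs <- dataset_sequences(fams)
  bg <- build_background(seqs, n_pairs = 40,
                         family_map = dataset_family_map(fams), seed = 7)
  s <- seqs[[1]]
  f_self <- compute_feature_vector(s, s, quiet = TRUE)
  pct <- score_context(f_self, bg)
  expect_equal(unname(pct), rep(1, 10))  # features at the scale maximum
  f_low <- setNames(rep(-1, 10), paste0("k", 1:10))
  expect_equal(unname(score_context(f_low, bg)), rep(0, 10))
  # median feature sits at the 50th percentile (checked on the continuous
  # k = 5 score, where ties are absent)
  med <- setNames(rep(0, 10), paste0("k", 1:10))
  med[["k5"]] <- stats::median(bg$samples[, "k5"])
  expect_equal(unname(score_context(med, bg)[["k5"]]), 0.5,
               tolerance = 1 / 40)
})

test_that("match extraction equals brute-force thresholding and re-derives", {
  set.seed(29)
  s1 <- rand_seq(40); s2 <- rand_seq(35)
  for (k in c(3, 5)) for (T in c(0.6, 0.8, 0.95)) {
    spans <- extract_matches(s1, s2, k, T, S)
    W <- brute_kmer_matrix(s1, s2, k, S)
    expect_equal(nrow(spans), sum(W >= T))
    if (nrow(spans)) {
      expect_equal(substring(s1, spans$query_start + 1, spans$query_start + k),
                   spans$query_kmer)
      expect_equal(substring(s2, spans$target_start + 1, spans$target_start + k),
                   spans$target_kmer)
      expect_true(all(diff(spans$w) <= 1e-12))
      expect_true(all(spans$w >= T))
    }
  }
  # threshold nesting: matches at higher T are a subset
  lo <- extract_matches(s1, s2, 4, 0.6, S)
  hi <- extract_matches(s1, s2, 4, 0.9, S)
  key <- function(d) paste(d$query_start, d$target_start)
  expect_true(all(key(hi) %in% key(lo)))
  # self comparison at T = 1 includes the full diagonal
  d <- extract_matches(s1, s1, 6, 1, S)
  expect_true(all(paste(0:(40 - 6), 0:(40 - 6)) %in% key(d)))
  expect_equal(nrow(extract_matches("CC", "WW", 2, 0.5, S)), 0)
  expect_warning(sp <- extract_matches("AC", rand_seq(20), 8, 0.5, S),
                 "< k")
  expect_equal(nrow(sp), 0)
})

test_that("match reports round-trip through TSV and render panels", {
  set.seed(31)
  s1 <- rand_seq(50); s2 <- rand_seq(45)
  spans <- extract_matches(s1, s2, 5, 0.7, S)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_match_report(spans, f, s1, s2)
  back <- read_match_report(f)
  expect_equal(as.data.frame(back),
               transform(as.data.frame(spans), w = round(w, 6)),
               tolerance = 1e-9)
  # empty report is header-only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_match_report(extract_matches("CC", "WW", 2, 0.9, S), f2)
  expect_length(readLines(f2), 1)
  expect_equal(nrow(read_match_report(f2)), 0)
  # integrity check refuses inconsistent spans
  bad <- spans
  if (nrow(bad)) {
    bad$query_kmer[1] <- strrep("W", 5)
    expect_error(write_match_report(bad, f, s1, s2),
                 class = "shark_integrity_error")
  }
  panel <- render_match_panel(s1, s2, spans)
  expect_true(any(grepl("\\*", panel)) || nrow(spans) == 0)
  expect_match(panel[1], "1-based")
})
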