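test_that("PR curve and auPRC match hand-enumerated cases", {
  # 4 pairs: scores .9/.8/.7/.6, labels 1/0/1/0
  sc <- c(0.9, 0.8, 0.7, 0.6); lb <- c(1, 0, 1, 0)
  cv <- pr_curve(sc, lb)
  expect_equal(cv$threshold, c(0.9, 0.8, 0.7, 0.6))
  expect_equal(cv$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(cv$recall, c(0.5, 0.5, 1, 1))
  expect_equal(auprc(cv), 0.5 * 1 + 0.5 * 2 / 3)
  # perfect separation
  cv2 <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auprc(cv2), 1)
  expect_true(any(cv2$precision == 1 & cv2$recall == 1))
  # constant scorer: single point at precision = prevalence
  cv3 <- pr_curve(rep(0.4, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(nrow(cv3), 1)
  expect_equal(auprc(cv3), 0.3)
  expect_error(pr_curve(c(1, 2), c(1, 1)), class = "shark_config_error")
})

test_that("auPRC is invariant under strictly monotone score transforms", {
  set.seed(37)
  sc <- runif(300); lb <- rbinom(300, 1, 0.4)
  a0 <- auprc(pr_curve(sc, lb))
  for (f in list(function(x) 10 * x - 3, function(x) x^3, plogis))
    expect_equal(auprc(pr_curve(f(sc), lb)), a0, tolerance = 1e-12)
})

test_that("random scores on balanced labels give auPRC near one half", {
  set.seed(41)
  n <- 2000
  lb <- rep(0:1, each = n / 2)
  a <- auprc(pr_curve(runif(n), lb))
  expect_lt(abs(a - 0.5), 0.05)
})

test_that("F1 at threshold and best-F1 scan match enumeration", {
  sc <- c(0.9, 0.8, 0.7, 0.6); lb <- c(1, 0, 1, 0)
  expect_equal(f1_at_threshold(sc, lb, 0.7), 0.8)
  expect_equal(f1_at_threshold(sc, lb, 0.95), 0)  # nothing predicted
  b <- best_f1_threshold(sc, lb)
  expect_equal(b$threshold, 0.7)
  expect_equal(b$f1, 0.8)
  # all-positive predictions: F1 = 2 prev / (1 + prev)
  prev <- 0.25
  expect_equal(f1_at_threshold(rep(1, 8), c(1, 1, rep(0, 6)), 0.5),
               2 * prev / (1 + prev))
  expect_error(f1_at_threshold(sc, c(0, 0, 0, 0), 0.5),
               class = "shark_config_error")
})

test_that("sensitivity by identity bin uses half-open bins, last closed", {
  pid <- c(0.05, 0.15, 0.15, 0.45, 0.5, 0.99)
  det <- c(1, 1, 0, 1, 1, 1)
  out <- sensitivity_by_pid_bin(pid, det)
  expect_equal(sum(out$n_pairs), 6)
  expect_equal(out$sensitivity[out$bin_lo == 0.0], 1)
  expect_equal(out$sensitivity[out$bin_lo == 0.1], 0.5)
  expect_true(is.na(out$sensitivity[out$bin_lo == 0.2]))
  # 0.5 lands in the final closed bin
  expect_equal(out$n_pairs[out$bin_lo == 0.5], 2)
  # all-detected gives 1 in every non-empty bin
  out2 <- sensitivity_by_pid_bin(pid, rep(1, 6))
  expect_true(all(out2$sensitivity[!is.na(out2$sensitivity)] == 1))
  expect_error(sensitivity_by_pid_bin(c(0.2, 1.4), c(1, 1)),
               class = "shark_config_error")
})

test_that("Smith-Waterman equals an independent DP oracle", {
  ap <- alignment_params("BLOSUM62", 11, 1)
  expect_equal(smith_waterman("AAA", "AAA", ap), 12)  # 3 x BLOSUM62[A,A]
  expect_equal(smith_waterman("A", "", ap), 0)
  expect_equal(smith_waterman("", "ACD", ap), 0)
  set.seed(43)
  for (r in 1:40) {
    s1 <- rand_seq(sample(1:20, 1)); s2 <- rand_seq(sample(1:20, 1))
    expect_equal(smith_waterman(s1, s2, ap),
                 brute_sw(s1, s2, ap$matrix, 11, 1))
  }
  # gapped case exercised explicitly: deletion bridged by the affine gap
  s <- "MKVLAWYE"
  expect_equal(smith_waterman(s, "MKVLYE", ap),
               brute_sw(s, "MKVLYE", ap$matrix, 11, 1))
  expect_error(alignment_params("BLOSUM62", 1, 5), class = "shark_config_error")
  expect_error(smith_waterman("ABX", "ACD", ap), class = "shark_invalid_residue")
})

test_that("the benchmark harness evaluates methods all-vs-all on test families", {
  fams <- tiny_dataset()
  sp <- split_by_family(fams, seed = 2)
  model <- tiny_model()
  S <- build_similarity_matrix()
  res <- run_benchmark(list(
    dive = model,
    best5 = function(a, b) shark_score_best(a, b, 5, S),
    best5_again = function(a, b) shark_score_best(a, b, 5, S)), fams, sp)
  n_test <- length(dataset_sequences(subset_families(fams, sp$test)))
  for (r in res) {
    expect_equal(r$n_pairs, choose(n_test, 2))
    expect_true(r$auprc >= 0 && r$auprc <= 1)
    expect_true(r$f1 >= 0 && r$f1 <= 1)
    expect_equal(sum(r$sensitivity_by_pid$n_pairs), sum(attr(res, "labels")))
  }
  # identical method registered twice gives identical metrics
  expect_equal(res$best5[c("auprc", "f1", "best_f1")],
               res$best5_again[c("auprc", "f1", "best_f1")])
  # failing scorer excludes pairs with a warning
  poison <- dataset_sequences(subset_families(fams, sp$test))[[1]]
  flaky <- function(a, b) if (a == poison || b == poison) stop("boom") else 1
  expect_warning(res2 <- run_benchmark(list(flaky = flaky), fams, sp),
                 "excluded")
  expect_gt(res2$flaky$n_failed, 0)
  # written outputs
  out <- withr::local_tempdir()
  run_benchmark(list(dive = model), fams, sp, out = out)
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "pr_curve_dive.tsv")))
})

test_that("external hit tables parse with reject collection", {
  blast <- c(
    "q1\tt1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-30\t180",
    "q1\tt2\t50\t80\t10\t2\t1\t80\t5\t84\t0.002\t60",
    "q1\tbroken\tnot\tenough",
    "q2\tt3\t40\t60\t20\t3\t1\t60\t2\t61\tNOTANUMBER\t30")
  f <- withr::local_tempfile(lines = blast)
  out <- parse_external_hits(f, "blast_tab")
  expect_equal(nrow(out$hits), 2)
  expect_equal(out$hits$e_value, c(1e-30, 0.002))
  expect_equal(nrow(out$rejects), 2)
  hmmer <- c(
    "# comment line",
    "t1 - q1 - 1.2e-10 55.0 0.1 1e-9 54 0 - - - - desc",
    "t2 - q1 - 0.5 10 0 0.6 9 0 - - - - desc",
    "short line")
  f2 <- withr::local_tempfile(lines = hmmer)
  out2 <- parse_external_hits(f2, "hmmer_tab")
  expect_equal(out2$hits$query, c("q1", "q1"))
  expect_equal(out2$hits$target, c("t1", "t2"))
  expect_equal(out2$hits$e_value, c(1.2e-10, 0.5))
  expect_equal(nrow(out2$rejects), 1)
  # empty file parses to zero records
  f3 <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(parse_external_hits(f3, "blast_tab")$hits), 0)
  # E-value cutoff turns hits into detections for the metric suite
  det <- out$hits$e_value <= 1
  expect_equal(det, c(TRUE, TRUE))
})
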