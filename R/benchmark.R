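#' Precision-recall curve
#'
#' Computed at every distinct score value (ties grouped: all pairs with equal
#' scores enter or leave the predicted-positive set together), threshold
#' semantics "score >= threshold predicts positive". No interpolation is
#' applied between points.
#'
#' @param scores numeric scores (higher = more confident positive)
#' @param labels binary labels (0/1), same length; both classes must occur
#' @return data.frame of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall` (thresholds decreasing, recall non-decreasing);
#'   attribute `prevalence`
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels))
    shark_stop("shark_config_error", "scores and labels differ in length")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    shark_stop("shark_config_error", "labels must contain both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  P <- sum(y)
  curve <- data.frame(threshold = s[last],
                      precision = tp[last] / (tp[last] + fp[last]),
                      recall = tp[last] / P)
  attr(curve, "prevalence") <- P / length(y)
  class(curve) <- c("pr_curve", "data.frame")
  curve
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) integral: the precision of each
#' threshold step weighted by the recall gained at that step. Equals 1 for a
#' perfectly separating scorer and the positive prevalence for a constant
#' scorer.
#'
#' @param curve [pr_curve()] result (or `scores`/`labels` via `...`)
#' @return numeric in `[0, 1]`
#' @export
auprc <- function(curve) {
  if (!inherits(curve, "pr_curve"))
    shark_stop("shark_config_error", "auprc expects a pr_curve object")
  if (!nrow(curve)) shark_stop("shark_config_error", "empty curve")
  dr <- diff(c(0, curve$recall))
  sum(dr * curve$precision)
}

#' F1 score at a threshold, and the best-F1 threshold
#'
#' `f1_at_threshold()` computes the harmonic mean of precision and recall of
#' the classifier "score >= threshold" (0 when nothing is predicted
#' positive). `best_f1_threshold()` scans all distinct score values and
#' returns the one maximizing F1, preferring the lower threshold on ties.
#'
#' @param scores numeric scores
#' @param labels binary labels (must include positives)
#' @param threshold decision threshold
#' @return `f1_at_threshold()`: numeric in `[0, 1]`; `best_f1_threshold()`:
#'   list with `threshold` and `f1`
#' @export
f1_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!any(labels == 1L))
    shark_stop("shark_config_error", "labels contain no positives")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  if (tp == 0L) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(labels == 1L)
  2 * prec * rec / (prec + rec)
}

#' @rdname f1_at_threshold
#' @export
best_f1_threshold <- function(scores, labels) {
  th <- sort(unique(scores))
  f1 <- vapply(th, function(t) f1_at_threshold(scores, labels, t), 1)
  i <- which(f1 == max(f1))[1L]  # ties -> lowest threshold
  list(threshold = th[i], f1 = f1[i])
}

#' Sensitivity (recall) of a detector by pairwise-identity bin
#'
#' Among true homolog pairs only, the fraction detected within each identity
#' bin. Bins are half-open `[lo, hi)` except the last, which is closed; empty
#' bins report `NA` (undefined), not 0. The default edges give
#' 10-percentage-point bins over `[0, 0.5]` plus a `>= 0.5` bin, matching an
#' identity-capped benchmark regime.
#'
#' @param pid pairwise identities of the positive pairs, in `[0, 1]`
#' @param detected logical/0-1 vector: was each positive pair detected?
#' @param bin_edges increasing bin edges (default `c(0, .1, .2, .3, .4, .5, 1)`)
#' @return data.frame with `bin_lo`, `bin_hi`, `n_pairs`, `sensitivity`
#' @export
sensitivity_by_pid_bin <- function(pid, detected,
                                   bin_edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1)) {
  if (length(pid) != length(detected))
    shark_stop("shark_config_error", "pid and detected differ in length")
  if (any(pid < 0 | pid > 1))
    shark_stop("shark_config_error", "pid values must be in [0, 1]")
  nb <- length(bin_edges) - 1L
  idx <- findInterval(pid, bin_edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    n_pairs = vapply(seq_len(nb), function(b) sum(idx == b), 1L))
  out$sensitivity <- vapply(seq_len(nb), function(b)
    if (out$n_pairs[b] == 0L) NA_real_ else mean(detected[idx == b] == 1), 1)
  out
}

#' Alignment parameters for the Smith-Waterman baseline
#'
#' @param matrix substitution matrix name, file path, or matrix (see
#'   [load_substitution_matrix()])
#' @param gap_open,gap_extend non-negative gap penalties; a gap of length L
#'   costs `gap_open + (L - 1) * gap_extend`, so `gap_open >= gap_extend`
#' @return list of class `alignment_params`
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  M <- load_substitution_matrix(matrix)
  if (!all(AA_ALPHABET %in% rownames(M)) || !all(AA_ALPHABET %in% colnames(M)))
    shark_stop("shark_config_error",
               "substitution matrix must cover the 20 canonical residues")
  if (gap_open < 0 || gap_extend < 0 || gap_open < gap_extend)
    shark_stop("shark_config_error",
               "need gap_open >= gap_extend >= 0")
  structure(list(matrix = M[AA_ALPHABET, AA_ALPHABET],
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Smith-Waterman local alignment score
#'
#' Standard affine-gap local alignment (Gotoh dynamic programming) used as
#' the alignment baseline of the benchmark harness. The empty local
#' alignment scores 0, so the result is never negative. A gap of length L
#' costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param s1,s2 residue strings
#' @param params [alignment_params()]
#' @return non-negative alignment score
#' @examples
#' smith_waterman("AAA", "AAA") # 3 * BLOSUM62[A,A] = 12
#' @export
smith_waterman <- function(s1, s2, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (!nchar(s1) || !nchar(s2)) return(0)
  c1 <- encode_seq(s1); c2 <- encode_seq(s2)
  sw_score_cpp(c1, c2, params$matrix, params$gap_open, params$gap_extend)
}

#' Run the evaluation harness on a dataset split
#'
#' All-vs-all comparison of the sequences in the test families: every pair is
#' scored by every registered method, labels come from family membership, and
#' the full metric suite (PR curve, auPRC, F1 at the stated threshold, best-F1
#' threshold, sensitivity by identity bin) is computed per method. A method
#' failing on a pair excludes that pair from the method's metrics with a
#' warning.
#'
#' Methods are named entries that are either a fitted [shark_dive()] model
#' (scored by ensemble probability, detection threshold = the model's), or a
#' `function(s1, s2) -> score` (detection threshold = its best-F1 threshold,
#' mirroring how alignment baselines are conventionally thresholded).
#'
#' @param methods named list of methods
#' @param families list of `seq_family` objects
#' @param split [split_by_family()] result; its `test` families are evaluated
#' @param bin_edges identity-bin edges, see [sensitivity_by_pid_bin()]
#' @param out optional directory; when given, metrics (TSV + JSON) and
#'   per-method PR curves (TSV) are written there
#' @return list of class `benchmark_result`: per-method list with `auprc`,
#'   `f1`, `threshold`, `threshold_kind`, `best_f1`, `best_f1_threshold`,
#'   `sensitivity_by_pid`, `curve`, `n_pairs`, `n_failed`; plus attributes
#'   `labels`, `pid`
#' @export
run_benchmark <- function(methods, families, split, bin_edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1),
                          out = NULL) {
  stopifnot(is.list(methods), length(names(methods)) == length(methods))
  test_fams <- subset_families(families, split$test)
  if (!length(test_fams))
    shark_stop("shark_config_error", "test split is empty")
  seqs <- dataset_sequences(test_fams)
  fmap <- dataset_family_map(test_fams)
  fam <- setNames(fmap$family_id, fmap$sequence_id)
  ids <- names(seqs)
  pr <- combn(length(ids), 2L)
  pairs <- data.frame(id1 = ids[pr[1L, ]], id2 = ids[pr[2L, ]],
                      stringsAsFactors = FALSE)
  labels <- as.integer(fam[pairs$id1] == fam[pairs$id2])
  pid <- vapply(which(labels == 1L), function(i)
    pairwise_identity(seqs[[pairs$id1[i]]], seqs[[pairs$id2[i]]]), 1)
  results <- list()
  for (nm in names(methods)) {
    m <- methods[[nm]]
    if (inherits(m, "shark_dive")) {
      feats <- pair_features(pairs, seqs, m$feature_map, m$matrix)
      sc <- predict(m, feats)
      failed <- rep(FALSE, nrow(pairs))
      thr <- m$threshold; thr_kind <- "stated"
    } else if (is.function(m)) {
      sc <- rep(NA_real_, nrow(pairs))
      for (i in seq_len(nrow(pairs)))
        sc[i] <- tryCatch(m(seqs[[pairs$id1[i]]], seqs[[pairs$id2[i]]]),
                          error = function(e) NA_real_)
      failed <- is.na(sc)
      if (any(failed))
        warning(sprintf("%s: %d pair(s) failed and were excluded", nm,
                        sum(failed)), call. = FALSE)
      thr <- NULL; thr_kind <- "best_f1"
    } else {
      shark_stop("shark_config_error",
                 sprintf("method %s is neither a model nor a function", nm))
    }
    ok <- !failed
    curve <- pr_curve(sc[ok], labels[ok])
    best <- best_f1_threshold(sc[ok], labels[ok])
    if (is.null(thr)) thr <- best$threshold
    detected <- (sc >= thr)[labels == 1L]
    detected[is.na(detected)] <- FALSE
    results[[nm]] <- list(
      method = nm,
      auprc = auprc(curve),
      f1 = f1_at_threshold(sc[ok], labels[ok], thr),
      threshold = thr, threshold_kind = thr_kind,
      best_f1 = best$f1, best_f1_threshold = best$threshold,
      sensitivity_by_pid = sensitivity_by_pid_bin(pid, detected, bin_edges),
      curve = curve, n_pairs = sum(ok), n_failed = sum(failed))
  }
  res <- structure(results, class = "benchmark_result",
                   labels = labels, pid = pid)
  if (!is.null(out)) write_benchmark(res, out)
  res
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark (all-vs-all on test families):\n")
  df <- benchmark_table(x)
  print(transform(df, auprc = round(auprc, 4), f1 = round(f1, 4),
                  best_f1 = round(best_f1, 4),
                  threshold = signif(threshold, 4)), row.names = FALSE)
  invisible(x)
}

benchmark_table <- function(res) {
  do.call(rbind, lapply(res, function(r)
    data.frame(method = r$method, auprc = r$auprc, f1 = r$f1,
               threshold = r$threshold, threshold_kind = r$threshold_kind,
               best_f1 = r$best_f1, n_pairs = r$n_pairs,
               n_failed = r$n_failed, stringsAsFactors = FALSE)))
}

write_benchmark <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tab <- benchmark_table(res)
  write_tsv_hash(tab, file.path(out, "metrics.tsv"))
  jsonlite::write_json(
    lapply(res, function(r) r[c("method", "auprc", "f1", "threshold",
                                "threshold_kind", "best_f1",
                                "best_f1_threshold", "n_pairs", "n_failed")]),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(res)) {
    write_tsv_hash(res[[nm]]$curve,
                   file.path(out, sprintf("pr_curve_%s.tsv", gsub("\\W", "_", nm))))
    write_tsv_hash(res[[nm]]$sensitivity_by_pid,
                   file.path(out, sprintf("sensitivity_%s.tsv", gsub("\\W", "_", nm))))
  }
  invisible(out)
}

#' Parse tabular outputs of external homology-search tools
#'
#' Reads BLAST `outfmt 6`-style (12 tab-separated columns; E-value in column
#' 11) or HMMER `tblout`-style (whitespace-separated; target in column 1,
#' query in column 3, full-sequence E-value in column 5) files into
#' (query, target, e_value) records. The harness never executes the external
#' tools; it only consumes their files. Malformed lines are collected in a
#' rejects table and parsing continues.
#'
#' @param path file path
#' @param dialect `"blast_tab"` or `"hmmer_tab"`
#' @return list with `hits` (data.frame `query`, `target`, `e_value`) and
#'   `rejects` (data.frame `line`, `text`, `reason`)
#' @export
parse_external_hits <- function(path, dialect = c("blast_tab", "hmmer_tab")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  hits <- list(); rejects <- list()
  for (i in seq_along(lines)) {
    l <- lines[[i]]
    if (!nzchar(trimws(l)) || startsWith(l, "#")) next
    f <- if (dialect == "blast_tab") strsplit(l, "\t", fixed = TRUE)[[1]]
         else strsplit(trimws(l), "\\s+")[[1]]
    rec <- tryCatch({
      if (dialect == "blast_tab") {
        if (length(f) < 12L) stop("expected 12 columns")
        ev <- suppressWarnings(as.numeric(f[11]))
        if (is.na(ev)) stop("non-numeric E-value")
        data.frame(query = f[1], target = f[2], e_value = ev,
                   stringsAsFactors = FALSE)
      } else {
        if (length(f) < 5L) stop("expected >= 5 columns")
        ev <- suppressWarnings(as.numeric(f[5]))
        if (is.na(ev)) stop("non-numeric E-value")
        data.frame(query = f[3], target = f[1], e_value = ev,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e)
      data.frame(line = i, text = l, reason = conditionMessage(e),
                 stringsAsFactors = FALSE))
    if ("e_value" %in% names(rec)) hits[[length(hits) + 1L]] <- rec
    else rejects[[length(rejects) + 1L]] <- rec
  }
  list(hits = if (length(hits)) do.call(rbind, hits)
       else data.frame(query = character(0), target = character(0),
                       e_value = numeric(0)),
       rejects = if (length(rejects)) do.call(rbind, rejects)
       else data.frame(line = integer(0), text = character(0),
                       reason = character(0)))
}
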