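#' Homology search of a query against a sequence database
#'
#' Scores the query against every database entry with the fitted ensemble and
#' returns one hit per entry, ranked by probability (descending; ties broken
#' by target id, so the ordering is fully deterministic). Entries whose
#' sequences cannot be scored (invalid residues without `sanitize`) are
#' skipped with a warning and reported in the `rejects` attribute.
#'
#' @param model fitted [shark_dive()] model
#' @param query named character vector of length 1 (or a plain string)
#' @param database named character vector of sequences (non-empty)
#' @param threshold probability at or above which a hit is flagged as a
#'   predicted homolog; must lie in `[0, 1]`
#' @param sanitize drop k-mers containing non-canonical residues
#' @return data.frame of class `shark_hits` with columns `query_id`,
#'   `target_id`, `rank`, `probability`, `predicted_homolog` and the 10
#'   feature columns; attribute `rejects` lists skipped entries
#' @export
shark_search <- function(model, query, database, threshold = 0.5,
                         sanitize = FALSE) {
  check_dive(model)
  if (!length(database))
    shark_stop("shark_config_error", "database must be non-empty")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    shark_stop("shark_config_error", "threshold must be in [0, 1]")
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  q <- toupper(query[[1]])
  if (is.null(names(database)))
    names(database) <- paste0("target", seq_along(database))
  qc <- encode_seq(q, sanitize = sanitize)
  map <- validate_feature_map(model$feature_map)
  feats <- matrix(NA_real_, length(database), 10L,
                  dimnames = list(names(database), feature_names()))
  rejects <- character(0)
  for (i in seq_along(database)) {
    ti <- names(database)[i]
    f <- tryCatch({
      s <- toupper(database[[i]])
      feature_vector_codes(qc, encode_seq(s, sanitize = sanitize), q, s,
                           map, model$matrix, quiet = TRUE)
    }, shark_error = function(e) {
      warning(sprintf("skipping database entry %s: %s", ti,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(f)) rejects <- c(rejects, ti) else feats[i, ] <- f
  }
  keep <- !rownames(feats) %in% rejects
  feats <- feats[keep, , drop = FALSE]
  prob <- predict(model, feats)
  ord <- order(-prob, rownames(feats))
  hits <- data.frame(query_id = qid, target_id = rownames(feats)[ord],
                     rank = seq_along(ord), probability = prob[ord],
                     predicted_homolog = as.integer(prob[ord] >= threshold),
                     stringsAsFactors = FALSE)
  hits <- cbind(hits, as.data.frame(feats[ord, , drop = FALSE],
                                    row.names = seq_along(ord)))
  structure(hits, rejects = rejects, class = c("shark_hits", "data.frame"))
}

#' Background score distribution from unrelated sequence pairs
#'
#' Samples `n_pairs` pairs of records (cross-family pairs when a family map
#' is supplied, otherwise pairs of distinct records) and stores their per-k
#' feature samples. The resulting empirical distributions put an individual
#' pair's k-mer scores in context: a score in the upper tail of the unrelated
#' background supports homology at that k.
#'
#' @param sequences named character vector of sequence records (>= 2)
#' @param n_pairs number of background pairs (capped, with a warning, at the
#'   number of available pairs)
#' @param family_map optional data.frame (`sequence_id`, `family_id`); when
#'   given, only cross-family pairs are sampled
#' @param model optional fitted model whose feature map/matrix to use
#' @param seed integer seed
#' @param sanitize drop k-mers containing non-canonical residues
#' @return object of class `shark_background`: list with `samples`
#'   (n_pairs x 10 matrix), `n_pairs`, `seed`
#' @export
build_background <- function(sequences, n_pairs = 1000, family_map = NULL,
                             model = NULL, seed = 1, sanitize = FALSE) {
  if (length(sequences) < 2L)
    shark_stop("shark_config_error", "need at least 2 sequences")
  ids <- names(sequences)
  pr <- combn(length(ids), 2L)
  if (!is.null(family_map)) {
    fam <- setNames(family_map$family_id, family_map$sequence_id)[ids]
    pr <- pr[, fam[pr[1L, ]] != fam[pr[2L, ]], drop = FALSE]
  }
  if (!ncol(pr))
    shark_stop("shark_config_error", "no unrelated pairs available")
  if (n_pairs > ncol(pr)) {
    warning(sprintf("n_pairs capped at %d available unrelated pairs", ncol(pr)),
            call. = FALSE)
    n_pairs <- ncol(pr)
  }
  withr_seed(derive_seed(seed, "background"))
  sel <- pr[, sample.int(ncol(pr), n_pairs), drop = FALSE]
  pairs <- data.frame(id1 = ids[sel[1L, ]], id2 = ids[sel[2L, ]],
                      stringsAsFactors = FALSE)
  fm <- if (!is.null(model)) model$feature_map else default_feature_map()
  mx <- if (!is.null(model)) model$matrix else build_similarity_matrix()
  feats <- pair_features(pairs, sequences, fm, mx, sanitize = sanitize)
  structure(list(samples = as.matrix(feats[, feature_names()]),
                 n_pairs = n_pairs, seed = seed),
            class = "shark_background")
}

#' @export
print.shark_background <- function(x, ...) {
  cat(sprintf("background distribution: %d unrelated pairs (seed %d)\n",
              x$n_pairs, x$seed))
  print(round(apply(x$samples, 2L, quantile, c(0.05, 0.5, 0.95)), 3))
  invisible(x)
}

#' Percentile context of a feature vector against a background
#'
#' For each k, the fraction of background samples at or below the pair's
#' feature value — i.e. the empirical percentile of the pair among unrelated
#' pairs. Values near 1 mean the pair scores above almost all unrelated
#' pairs at that k.
#'
#' @param features named numeric vector from [compute_feature_vector()]
#' @param background [build_background()] object
#' @return named numeric vector of per-k percentiles in `[0, 1]`
#' @export
score_context <- function(features, background) {
  stopifnot(inherits(background, "shark_background"))
  fn <- feature_names()
  if (!all(fn %in% names(features)))
    shark_stop("shark_config_error", "features must be a named k1..k10 vector")
  vapply(fn, function(j)
    mean(background$samples[, j] <= features[[j]]), 1)
}

#' Extract similar k-mer spans between two sequences
#'
#' All k-mer pairs whose similarity meets the threshold `T`, mapped back onto
#' both sequences: the interpretability layer that turns a high pair score
#' into candidate shared motifs. One k-mer may match many (and vice versa),
#' so repeated or swapped motifs are reported as multiple spans. Offsets are
#' 0-based; spans are sorted by similarity (descending), then by query and
#' target offset.
#'
#' @param s1,s2 residue strings (query, target)
#' @param k k-mer length (default 8)
#' @param T similarity threshold in `[0, 1]` (default 0.85)
#' @param matrix residue similarity matrix
#' @param sanitize drop k-mers containing non-canonical residues
#' @return data.frame of class `match_spans` with columns `k`, `query_start`,
#'   `target_start`, `query_kmer`, `target_kmer`, `w`; empty (with a warning)
#'   when either sequence is shorter than `k`
#' @export
extract_matches <- function(s1, s2, k = 8, T = 0.85,
                            matrix = build_similarity_matrix(),
                            sanitize = FALSE) {
  if (!is.numeric(T) || T < 0 || T > 1)
    shark_stop("shark_config_error", "T must be in [0, 1]")
  empty <- data.frame(k = integer(0), query_start = integer(0),
                      target_start = integer(0), query_kmer = character(0),
                      target_kmer = character(0), w = numeric(0),
                      stringsAsFactors = FALSE)
  W <- tryCatch(kmer_similarity_matrix(s1, s2, k, matrix, sanitize = sanitize),
                shark_too_short = function(e) {
                  warning(conditionMessage(e), call. = FALSE)
                  NULL
                })
  if (is.null(W)) return(structure(empty, class = c("match_spans", "data.frame")))
  idx <- which(!is.na(W) & W >= T, arr.ind = TRUE)
  if (!nrow(idx))
    return(structure(empty, class = c("match_spans", "data.frame")))
  spans <- data.frame(
    k = as.integer(k),
    query_start = attr(W, "start1")[idx[, 1L]],
    target_start = attr(W, "start2")[idx[, 2L]],
    query_kmer = attr(W, "kmers1")[idx[, 1L]],
    target_kmer = attr(W, "kmers2")[idx[, 2L]],
    w = W[idx],
    stringsAsFactors = FALSE)
  spans <- spans[order(-spans$w, spans$query_start, spans$target_start), ,
                 drop = FALSE]
  rownames(spans) <- NULL
  structure(spans, class = c("match_spans", "data.frame"))
}

check_spans <- function(s1, s2, spans) {
  s1 <- toupper(s1); s2 <- toupper(s2)
  okq <- substring(s1, spans$query_start + 1L,
                   spans$query_start + spans$k) == spans$query_kmer
  okt <- substring(s2, spans$target_start + 1L,
                   spans$target_start + spans$k) == spans$target_kmer
  if (!all(okq & okt))
    shark_stop("shark_integrity_error",
               "match spans do not re-derive from the parent sequences")
  invisible(TRUE)
}

#' Write / read a match-span report
#'
#' TSV rendering of [extract_matches()] output (header line starting with
#' `#`; 0-based offsets; similarity to 6 decimals). `read_match_report()`
#' restores the spans loss-lessly up to that precision.
#'
#' @param spans `match_spans` data.frame
#' @param path file path
#' @param s1,s2 optional parent sequences; when given, span integrity is
#'   verified before writing
#' @export
write_match_report <- function(spans, path, s1 = NULL, s2 = NULL) {
  if (!is.null(s1) && !is.null(s2) && nrow(spans)) check_spans(s1, s2, spans)
  out <- spans
  out$w <- sprintf("%.6f", out$w)
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(spans), collapse = "\t")), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_match_report
#' @export
read_match_report <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "#"))
    shark_stop("shark_io_error", "not a match report (missing # header)")
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t")[[1]]
  if (length(lines) == 1L) {
    spans <- data.frame(k = integer(0), query_start = integer(0),
                        target_start = integer(0), query_kmer = character(0),
                        target_kmer = character(0), w = numeric(0))
  } else {
    spans <- utils::read.delim(textConnection(lines[-1]), header = FALSE,
                               col.names = cols, stringsAsFactors = FALSE)
    spans$k <- as.integer(spans$k)
    spans$query_start <- as.integer(spans$query_start)
    spans$target_start <- as.integer(spans$target_start)
  }
  structure(spans, class = c("match_spans", "data.frame"))
}

#' Plain-text panel of matched spans under both sequences
#'
#' Human-readable rendering: each sequence is printed with a marker line
#' flagging every position covered by at least one matched span. Positions in
#' the header are 1-based inclusive (internal offsets are 0-based half-open).
#'
#' @param s1,s2 parent sequences
#' @param spans `match_spans` data.frame
#' @param width wrap width (default 60)
#' @return character vector of report lines (invisibly printed with `cat`)
#' @export
render_match_panel <- function(s1, s2, spans, width = 60) {
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (nrow(spans)) check_spans(s1, s2, spans)
  mark <- function(s, starts, k) {
    m <- rep(" ", nchar(s))
    for (i in seq_along(starts)) {
      span <- (starts[i] + 1L):(starts[i] + k[i])
      m[span] <- "*"
    }
    paste(m, collapse = "")
  }
  m1 <- mark(s1, spans$query_start, spans$k)
  m2 <- mark(s2, spans$target_start, spans$k)
  lines <- c(sprintf("# matched k-mer spans (%d span(s)); positions 1-based inclusive",
                     nrow(spans)))
  chunk <- function(label, s, m) {
    out <- character(0)
    for (off in seq(1L, nchar(s), by = width)) {
      end <- min(off + width - 1L, nchar(s))
      out <- c(out,
               sprintf("%-7s %5d %s %d", label, off, substr(s, off, end), end),
               sprintf("%13s %s", "", substr(m, off, end)))
    }
    out
  }
  lines <- c(lines, chunk("query", s1, m1), chunk("target", s2, m2))
  lines
}
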