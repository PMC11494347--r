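#' Default per-k feature map of the homology classifier
#'
#' One score algorithm per k-mer length k = 1..10: the k = 1 feature is the
#' cosine Similarity Ratio over residue counts, i.e. a pure amino-acid
#' composition comparison that equals 1 exactly for identical sequences;
#' k = 2..4 use the Normalized Google Distance (stored in the feature vector
#' as the similarity `1 - NGD`); k = 5..10 use the SHARK-score (best). Every
#' feature therefore reads "higher = more similar" and attains its maximum 1
#' on a self-comparison. The map is a plain data.frame and can be overridden
#' wholesale wherever a `feature_map` argument is accepted; trained models
#' archive the map they were fitted with.
#'
#' @return data.frame with columns `k` (1..10), `algorithm`
#'   (`shark_best`, `shark_T`, `ngd`, `euclidean`, `similarity_ratio`) and
#'   `T` (threshold, `NA` unless `algorithm == "shark_T"`)
#' @export
default_feature_map <- function() {
  data.frame(
    k = 1:10,
    algorithm = c("similarity_ratio", "ngd", "ngd", "ngd",
                  rep("shark_best", 6)),
    T = rep(NA_real_, 10),
    stringsAsFactors = FALSE)
}

validate_feature_map <- function(map) {
  if (!is.data.frame(map) || !all(c("k", "algorithm") %in% names(map)))
    shark_stop("shark_config_error",
               "feature map must be a data.frame with columns k, algorithm")
  if (!identical(sort(as.integer(map$k)), 1:10))
    shark_stop("shark_config_error", "feature map must have keys k = 1..10")
  ok <- map$algorithm %in% c("shark_best", "shark_T", "ngd", "euclidean",
                             "similarity_ratio")
  if (!all(ok))
    shark_stop("shark_config_error",
               sprintf("unknown algorithm(s): %s",
                       paste(unique(map$algorithm[!ok]), collapse = ", ")))
  if (is.null(map$T)) map$T <- NA_real_
  bad <- map$algorithm == "shark_T" & (is.na(map$T) | map$T < 0 | map$T > 1)
  if (any(bad))
    shark_stop("shark_config_error", "shark_T entries need T in [0, 1]")
  map[order(map$k), , drop = FALSE]
}

feature_names <- function() paste0("k", 1:10)

# single-pair feature computation on pre-encoded sequences; kept separate so
# bulk feature computation pays validation cost once per sequence
feature_vector_codes <- function(c1, c2, s1, s2, map, matrix, quiet = FALSE) {
  out <- numeric(nrow(map))
  short <- integer(0)
  for (r in seq_len(nrow(map))) {
    k <- map$k[r]
    if (length(c1) < k || length(c2) < k ||
        !kmer_exists(c1, k) || !kmer_exists(c2, k)) {
      out[r] <- 0; short <- c(short, k); next
    }
    alg <- map$algorithm[r]
    if (alg == "shark_best") {
      v <- shark_best_cpp(c1, c2, matrix, as.integer(k))
      if (is.na(v)) { out[r] <- 0; short <- c(short, k) } else out[r] <- v
    } else if (alg == "shark_T") {
      v <- shark_T_cpp(c1, c2, matrix, as.integer(k), map$T[r])
      if (is.na(v)) { out[r] <- 0; short <- c(short, k) } else out[r] <- v
    } else {
      x1 <- kmer_ids(c1, k); x2 <- kmer_ids(c2, k)
      if (!length(x1) || !length(x2)) { out[r] <- 0; short <- c(short, k); next }
      out[r] <- switch(alg,
        ngd = 1 - ngd_sets(unique(x1), unique(x2), k),
        euclidean = euclid_counts(x1, x2),
        similarity_ratio = cosine_counts(x1, x2))
    }
  }
  if (length(short) && !quiet)
    warning(sprintf("pair too short for k = %s; feature(s) set to 0",
                    paste(short, collapse = ",")), call. = FALSE)
  names(out) <- feature_names()
  out
}

kmer_exists <- function(codes, k) {
  if (length(codes) < k) return(FALSE)
  if (!any(codes == 0L)) return(TRUE)
  # any run of k consecutive canonical codes?
  r <- rle(codes > 0L)
  any(r$values & r$lengths >= k)
}

# numeric base-20 ids of the valid k-mers of an encoded sequence (exact for
# k <= 11); windows touching a non-canonical code (0) are dropped
kmer_ids <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  ids <- numeric(n - k + 1L)
  for (p in seq_len(k)) ids <- ids * 20 + (codes[p:(n - k + p)] - 1)
  if (any(codes == 0L)) {
    cs <- cumsum(codes == 0L)
    bad <- (cs[k:n] - c(0, cs[seq_len(n - k)])) > 0
    ids <- ids[!bad]
  }
  ids
}

ngd_sets <- function(X, Y, k) {
  I <- sum(X %in% Y)
  if (I == 0L) return(1)
  lx <- log(length(X)); ly <- log(length(Y))
  min(max((max(lx, ly) - log(I)) / (k * log(20) - min(lx, ly)), 0), 1)
}

count_vectors <- function(x1, x2) {
  keys <- unique(c(x1, x2))
  list(vx = tabulate(match(x1, keys), length(keys)),
       vy = tabulate(match(x2, keys), length(keys)))
}

euclid_counts <- function(x1, x2) {
  cv <- count_vectors(x1, x2)
  sqrt(sum((cv$vx - cv$vy)^2))
}

cosine_counts <- function(x1, x2) {
  cv <- count_vectors(x1, x2)
  sum(cv$vx * cv$vy) / (sqrt(sum(cv$vx^2)) * sqrt(sum(cv$vy^2)))
}

#' Per-pair feature vector for the homology classifier
#'
#' Computes the 10 per-k scores defined by the feature map for one sequence
#' pair. Normalized-Google-Distance features are stored as `1 - NGD` so that
#' every feature reads "higher = more similar". For a k larger than either
#' sequence the feature is set to 0 with a warning instead of failing, so
#' database-scale scoring never aborts on short entries.
#'
#' @param s1,s2 residue strings
#' @param feature_map see [default_feature_map()]
#' @param matrix residue similarity matrix from [build_similarity_matrix()]
#' @param sanitize drop k-mers containing non-canonical residues rather than
#'   raising an error
#' @param quiet suppress the too-short warnings
#' @return named numeric vector of length 10 (`k1` .. `k10`)
#' @examples
#' compute_feature_vector("SGSYGQSSYGGQ", "GSYGQQSYGGSA")
#' @export
compute_feature_vector <- function(s1, s2, feature_map = default_feature_map(),
                                   matrix = build_similarity_matrix(),
                                   sanitize = FALSE, quiet = FALSE) {
  map <- validate_feature_map(feature_map)
  s1 <- toupper(s1); s2 <- toupper(s2)
  c1 <- encode_seq(s1, sanitize = sanitize)
  c2 <- encode_seq(s2, sanitize = sanitize)
  feature_vector_codes(c1, c2, s1, s2, map, matrix, quiet = quiet)
}

#' Feature matrix for a table of sequence pairs
#'
#' Bulk version of [compute_feature_vector()]: one row of features per row of
#' `pairs`.
#'
#' @param pairs data.frame with columns `id1`, `id2`
#' @param sequences named character vector mapping ids to residue strings
#' @inheritParams compute_feature_vector
#' @return `pairs` with the 10 feature columns `k1` .. `k10` appended
#' @export
pair_features <- function(pairs, sequences,
                          feature_map = default_feature_map(),
                          matrix = build_similarity_matrix(),
                          sanitize = FALSE, quiet = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("id1", "id2") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$id1, pairs$id2)), names(sequences))
  if (length(miss))
    shark_stop("shark_config_error",
               sprintf("sequences missing for ids: %s",
                       paste(utils::head(miss, 5), collapse = ", ")))
  map <- validate_feature_map(feature_map)
  seqs <- toupper(sequences)
  codes <- lapply(seqs, encode_seq, sanitize = sanitize)
  F <- matrix(0, nrow(pairs), 10L, dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id1[i]; b <- pairs$id2[i]
    F[i, ] <- feature_vector_codes(codes[[a]], codes[[b]], seqs[[a]], seqs[[b]],
                                   map, matrix, quiet = quiet)
  }
  cbind(pairs, as.data.frame(F))
}
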