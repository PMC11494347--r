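#' Decompose a sequence into overlapping k-mers
#'
#' Stride-1 decomposition into the `len - k + 1` overlapping substrings of
#' length `k`. With `sanitize = TRUE`, k-mers containing non-canonical
#' residue codes (X, B, Z, U, O, ...) are dropped; otherwise such codes
#' raise an invalid-residue error.
#'
#' @param sequence residue string
#' @param k k-mer length (positive integer)
#' @param parent_id optional identifier carried along
#' @param sanitize drop k-mers containing non-canonical residues
#' @return object of class `kmer_list`: list with `parent_id`, `k`,
#'   `kmers` (character) and `start` (0-based offsets into the parent)
#' @examples
#' extract_kmers("ACDE", 2)
#' @export
extract_kmers <- function(sequence, k, parent_id = NULL, sanitize = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) shark_stop("shark_config_error", "k must be >= 1")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < k)
    shark_stop("shark_too_short",
               sprintf("sequence length %d < k = %d", n, k))
  codes <- encode_seq(sequence, sanitize = sanitize)
  start <- 0:(n - k)
  kmers <- substring(sequence, start + 1L, start + k)
  if (sanitize) {
    bad <- which(codes == 0L)
    if (length(bad)) {
      drop <- unique(unlist(lapply(bad, function(b)
        max(1L, b - k + 1L):min(n - k + 1L, b))))
      keep <- setdiff(seq_along(start), drop)
      kmers <- kmers[keep]; start <- start[keep]
    }
  }
  structure(list(parent_id = parent_id, k = k, kmers = kmers,
                 start = as.integer(start)),
            class = "kmer_list")
}

#' @export
print.kmer_list <- function(x, ...) {
  cat(sprintf("k-mer list (k = %d, %d k-mers%s)\n", x$k, length(x$kmers),
              if (is.null(x$parent_id)) "" else paste0(", parent ", x$parent_id)))
  print(utils::head(data.frame(start = x$start, kmer = x$kmers), 10))
  if (length(x$kmers) > 10) cat(sprintf("... %d more\n", length(x$kmers) - 10))
  invisible(x)
}

#' Physicochemical similarity between two equal-length k-mers
#'
#' Position-wise, ungapped aggregation: the arithmetic mean of the residue
#' similarities at each of the k positions, so `w` stays in `[0, 1]`, is
#' symmetric, and equals 1 exactly for identical k-mers.
#'
#' @param x,y k-mer strings of equal length
#' @param matrix residue similarity matrix from [build_similarity_matrix()]
#' @return numeric in `[0, 1]`
#' @examples
#' S <- build_similarity_matrix()
#' kmer_similarity("LI", "IL", S)
#' @export
kmer_similarity <- function(x, y, matrix = build_similarity_matrix()) {
  if (nchar(x) != nchar(y))
    shark_stop("shark_config_error", "k-mers must have equal length")
  cx <- encode_seq(x); cy <- encode_seq(y)
  mean(matrix[cbind(cx, cy)])
}

#' k-mer similarity matrix between two sequences
#'
#' The `(n1 - k + 1) x (n2 - k + 1)` matrix `w` of pairwise k-mer
#' similarities between all overlapping k-mers of `s1` (rows) and `s2`
#' (columns); the raw material of every SHARK-score and of the match
#' extraction in [extract_matches()].
#'
#' @param s1,s2 residue strings, both of length at least `k`
#' @param k k-mer length
#' @param matrix residue similarity matrix
#' @param sanitize drop k-mers containing non-canonical residues (their
#'   entries become `NA` and are ignored by the score aggregators)
#' @return numeric matrix with attributes `k`, `kmers1`, `kmers2`,
#'   `start1`, `start2` (0-based offsets)
#' @export
kmer_similarity_matrix <- function(s1, s2, k, matrix = build_similarity_matrix(),
                                   sanitize = FALSE) {
  k1 <- extract_kmers(s1, k, sanitize = sanitize)  # validates length/alphabet
  k2 <- extract_kmers(s2, k, sanitize = sanitize)
  c1 <- encode_seq(toupper(s1), sanitize = sanitize)
  c2 <- encode_seq(toupper(s2), sanitize = sanitize)
  W <- kmer_sim_matrix_cpp(c1, c2, matrix, as.integer(k))
  structure(W, k = as.integer(k),
            kmers1 = k1$kmers, kmers2 = k2$kmers,
            start1 = k1$start, start2 = k2$start)
}

# shared front door for the pair scores: validates, upper-cases, and signals
# shark_too_short for sequences shorter than k
score_codes <- function(s1, s2, k, sanitize = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) shark_stop("shark_config_error", "k must be >= 1")
  c1 <- encode_seq(toupper(s1), sanitize = sanitize)
  c2 <- encode_seq(toupper(s2), sanitize = sanitize)
  if (length(c1) < k || length(c2) < k)
    shark_stop("shark_too_short",
               sprintf("sequence length %d < k = %d",
                       min(length(c1), length(c2)), k))
  list(c1 = c1, c2 = c2, k = k)
}

#' SHARK-score (best)
#'
#' For every k-mer of one sequence, the best-matching k-mer of the other is
#' found in the k-mer similarity matrix; these per-k-mer maxima are averaged.
#' Because that directional average is not symmetric in the arguments, the
#' score is the mean of the two directions. Identical sequences score exactly
#' 1; higher means more similar.
#'
#' @inheritParams kmer_similarity_matrix
#' @return numeric in `[0, 1]`
#' @examples
#' S <- build_similarity_matrix()
#' shark_score_best("PKVKTQVKKT", "PRVKTQVRRT", 5, S)
#' @export
shark_score_best <- function(s1, s2, k, matrix = build_similarity_matrix(),
                             sanitize = FALSE) {
  cc <- score_codes(s1, s2, k, sanitize)
  v <- shark_best_cpp(cc$c1, cc$c2, matrix, cc$k)
  if (is.na(v))
    shark_stop("shark_too_short", "no valid k-mers after sanitization")
  v
}

#' SHARK-score (T)
#'
#' All entries of the k-mer similarity matrix at or above the similarity
#' threshold `T` are summed and normalized by the total number of k-mer
#' pairs, bounding the score in `[0, 1]` and making it non-increasing in `T`.
#' At `T = 0` this is the mean k-mer similarity (for k = 1, a pure
#' composition comparison).
#'
#' @inheritParams kmer_similarity_matrix
#' @param T similarity threshold in `[0, 1]`
#' @return numeric in `[0, 1]`
#' @export
shark_score_T <- function(s1, s2, k, T, matrix = build_similarity_matrix(),
                          sanitize = FALSE) {
  if (!is.numeric(T) || T < 0 || T > 1)
    shark_stop("shark_config_error", "T must be in [0, 1]")
  cc <- score_codes(s1, s2, k, sanitize)
  v <- shark_T_cpp(cc$c1, cc$c2, matrix, cc$k, T)
  if (is.na(v))
    shark_stop("shark_too_short", "no valid k-mers after sanitization")
  v
}

# distinct k-mer sets for the set-based baselines
kmer_set <- function(s, k, sanitize = FALSE)
  unique(extract_kmers(s, k, sanitize = sanitize)$kmers)

kmer_counts <- function(s, k, sanitize = FALSE) {
  km <- extract_kmers(s, k, sanitize = sanitize)$kmers
  table(km)
}

#' Normalized Google Distance over k-mer sets
#'
#' Set-based distance between the distinct k-mer vocabularies `X` and `Y` of
#' the two sequences:
#' \deqn{NGD = \frac{\max(\log|X|, \log|Y|) - \log|X \cap Y|}
#'   {\log N - \min(\log|X|, \log|Y|)}}
#' with the "corpus size" `N = 20^k` (the full canonical k-mer space).
#' Identical vocabularies give 0; an empty intersection is defined as 1; the
#' value is clamped to `[0, 1]`. Note this is a distance — the classifier
#' features store `1 - NGD` so that higher always means more similar.
#'
#' @inheritParams kmer_similarity_matrix
#' @return numeric in `[0, 1]`
#' @export
ngd <- function(s1, s2, k, sanitize = FALSE) {
  X <- kmer_set(s1, k, sanitize); Y <- kmer_set(s2, k, sanitize)
  if (!length(X) || !length(Y))
    shark_stop("shark_too_short", "no valid k-mers after sanitization")
  I <- length(intersect(X, Y))
  if (I == 0L) return(1)
  lx <- log(length(X)); ly <- log(length(Y))
  v <- (max(lx, ly) - log(I)) / (k * log(20) - min(lx, ly))
  min(max(v, 0), 1)
}

#' Euclidean distance between k-mer count vectors
#'
#' The Euclidean norm of the difference of the two k-mer count vectors over
#' the `20^k` k-mer space (computed sparsely over the observed k-mers).
#'
#' @inheritParams kmer_similarity_matrix
#' @return non-negative numeric; 0 iff the count vectors are identical
#' @export
euclidean_kmer_distance <- function(s1, s2, k, sanitize = FALSE) {
  cx <- kmer_counts(s1, k, sanitize); cy <- kmer_counts(s2, k, sanitize)
  keys <- union(names(cx), names(cy))
  vx <- as.numeric(cx[keys]); vx[is.na(vx)] <- 0
  vy <- as.numeric(cy[keys]); vy[is.na(vy)] <- 0
  sqrt(sum((vx - vy)^2))
}

#' Cosine Similarity Ratio between k-mer count vectors
#'
#' Cosine similarity of the two k-mer count vectors: 1 when the vectors are
#' parallel (e.g. identical sequences), 0 when the k-mer sets are disjoint.
#'
#' @inheritParams kmer_similarity_matrix
#' @return numeric in `[0, 1]`
#' @export
similarity_ratio <- function(s1, s2, k, sanitize = FALSE) {
  cx <- kmer_counts(s1, k, sanitize); cy <- kmer_counts(s2, k, sanitize)
  if (!length(cx) || !length(cy))
    shark_stop("shark_too_short", "no valid k-mers after sanitization")
  keys <- union(names(cx), names(cy))
  vx <- as.numeric(cx[keys]); vx[is.na(vx)] <- 0
  vy <- as.numeric(cy[keys]); vy[is.na(vy)] <- 0
  sum(vx * vy) / (sqrt(sum(vx^2)) * sqrt(sum(vy^2)))
}
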