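# shared fixtures and independent oracles for the test suite

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# brute-force k-mer similarity matrix: nested loops over all k-mer pairs,
# independent of the package's sliding-window kernel
brute_kmer_matrix <- function(s1, s2, k, S) {
  n1 <- nchar(s1) - k + 1; n2 <- nchar(s2) - k + 1
  W <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    x <- substr(s1, i, i + k - 1); y <- substr(s2, j, j + k - 1)
    cx <- match(strsplit(x, "")[[1]], AA20)
    cy <- match(strsplit(y, "")[[1]], AA20)
    W[i, j] <- mean(S[cbind(cx, cy)])
  }
  W
}

brute_best <- function(W) (mean(apply(W, 1, max)) + mean(apply(W, 2, max))) / 2
brute_T <- function(W, T) sum(W[W >= T]) / length(W)

# dense count-vector recomputation over the full observed k-mer space
brute_counts <- function(s, k) {
  n <- nchar(s)
  table(substring(s, 1:(n - k + 1), k:n))
}
brute_euclid <- function(s1, s2, k) {
  c1 <- brute_counts(s1, k); c2 <- brute_counts(s2, k)
  keys <- union(names(c1), names(c2))
  v1 <- as.numeric(c1[keys]); v1[is.na(v1)] <- 0
  v2 <- as.numeric(c2[keys]); v2[is.na(v2)] <- 0
  sqrt(sum((v1 - v2)^2))
}
brute_cosine <- function(s1, s2, k) {
  c1 <- brute_counts(s1, k); c2 <- brute_counts(s2, k)
  keys <- union(names(c1), names(c2))
  v1 <- as.numeric(c1[keys]); v1[is.na(v1)] <- 0
  v2 <- as.numeric(c2[keys]); v2[is.na(v2)] <- 0
  sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
}

# independent affine-gap Smith-Waterman DP (full matrices, no rolling rows);
# same gap convention as the package: gap of length L costs go + (L-1)*ge
brute_sw <- function(s1, s2, M, go, ge) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  if (!n || !m) return(0)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
    H[i, j] <- max(0, H[i - 1, j - 1] + M[a[i - 1], b[j - 1]], E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# small, quickly generated dataset + fitted ensemble, memoized across tests
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$fams))
    .fixture_env$fams <- generate_dataset(n_families = 10,
                                          members_range = c(4, 5),
                                          length_range = c(50, 120), seed = 42)
  .fixture_env$fams
}

tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    fams <- tiny_dataset()
    pairs <- build_training_pairs(fams, seed = 42)
    feats <- pair_features(pairs, dataset_sequences(fams))
    .fixture_env$model <- shark_dive(feats, n_submodels = 5, seed = 42)
    .fixture_env$feats <- feats
  }
  .fixture_env$model
}

tiny_feats <- function() { tiny_model(); .fixture_env$feats }
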