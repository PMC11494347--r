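#' Grantham amino-acid property table
#'
#' The per-residue side-chain properties underlying all similarity
#' computations in the package: chemical composition (`c`, the atomic
#' weight ratio of non-carbon elements in side-chain substituents),
#' polarity (`p`) and molecular volume (`v`), on Grantham's original
#' dimensionless scales. The table ships with the package as a TSV and can
#' be swapped for an alternative property scheme of the same shape.
#'
#' @param path optional path to a TSV with columns `residue`, `c`, `p`, `v`
#'   (header line; `#` comment lines ignored). Defaults to the packaged table.
#' @return data.frame with 20 rows (one per canonical residue, alphabetical)
#'   and columns `residue`, `c`, `p`, `v`.
#' @examples
#' head(grantham_properties())
#' @export
grantham_properties <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "grantham_properties.tsv", package = "shark")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "c", "p", "v")
  if (!all(need %in% names(df)))
    shark_stop("shark_config_error",
               "property table must have columns residue, c, p, v")
  df <- df[order(df$residue), , drop = FALSE]
  if (!identical(df$residue, AA_ALPHABET))
    shark_stop("shark_config_error",
               "property table must cover exactly the 20 canonical residues")
  if (!all(is.finite(as.matrix(df[, c("c", "p", "v")]))) ||
      any(as.matrix(df[, c("c", "p", "v")]) < 0))
    shark_stop("shark_config_error", "properties must be finite and non-negative")
  rownames(df) <- df$residue
  df
}

# published formula constants; rho rescales the mean pairwise distance to 100
GRANTHAM_ALPHA <- 1.833
GRANTHAM_BETA  <- 0.1018
GRANTHAM_GAMMA <- 0.000399

grantham_rho <- function(props) {
  m <- as.matrix(props[, c("c", "p", "v")])
  pairs <- combn(nrow(m), 2)
  d <- sqrt(GRANTHAM_ALPHA * (m[pairs[1, ], "c"] - m[pairs[2, ], "c"])^2 +
            GRANTHAM_BETA  * (m[pairs[1, ], "p"] - m[pairs[2, ], "p"])^2 +
            GRANTHAM_GAMMA * (m[pairs[1, ], "v"] - m[pairs[2, ], "v"])^2)
  100 / mean(d)
}

#' Grantham distance between two residues
#'
#' Physicochemical distance
#' \deqn{D(a,b) = \rho\,[\alpha (c_a-c_b)^2 + \beta (p_a-p_b)^2 +
#'   \gamma (v_a-v_b)^2]^{1/2}}
#' with the published constants \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018},
#' \eqn{\gamma = 0.000399} and \eqn{\rho} chosen so that the mean over the
#' 190 residue pairs is 100. Rounding to integers reproduces the classical
#' distance table (maximum 215 for Cys-Trp).
#'
#' @param a,b canonical one-letter residue codes (vectorised, recycled)
#' @param properties property table as returned by [grantham_properties()]
#' @return numeric vector of non-negative distances
#' @examples
#' grantham_distance("L", "I") # ~5
#' grantham_distance("C", "W") # ~215, the table maximum
#' @export
grantham_distance <- function(a, b, properties = grantham_properties()) {
  a <- toupper(a); b <- toupper(b)
  if (!all(a %in% AA_ALPHABET) || !all(b %in% AA_ALPHABET))
    shark_stop("shark_invalid_residue",
               sprintf("invalid residue code(s): %s",
                       paste(setdiff(unique(c(a, b)), AA_ALPHABET), collapse = ", ")))
  rho <- grantham_rho(properties)
  pa <- properties[a, ]; pb <- properties[b, ]
  rho * sqrt(GRANTHAM_ALPHA * (pa$c - pb$c)^2 +
             GRANTHAM_BETA  * (pa$p - pb$p)^2 +
             GRANTHAM_GAMMA * (pa$v - pb$v)^2)
}

#' Full 20 x 20 Grantham distance matrix
#'
#' @inheritParams grantham_distance
#' @return symmetric numeric matrix with zero diagonal, dimnames = residues
#' @export
grantham_distance_matrix <- function(properties = grantham_properties()) {
  aa <- properties$residue
  D <- outer(seq_along(aa), seq_along(aa), function(i, j)
    grantham_distance(aa[i], aa[j], properties))
  dimnames(D) <- list(aa, aa)
  D
}

#' Residue similarity matrix from Grantham distances
#'
#' Linear conversion of distance into a bounded similarity,
#' `sim(a, b) = 1 - D(a, b) / normalization`, so that identical residues score
#' 1 and the most dissimilar pair (Cys-Trp, distance 215) scores 0 under the
#' default normalization. The result is the substitution kernel used by all
#' k-mer similarity computations.
#'
#' @inheritParams grantham_distance
#' @param normalization positive scaling constant; must be at least the
#'   maximum pairwise distance so similarities stay in `[0, 1]`. Default 215.
#' @return 20 x 20 symmetric numeric matrix in `[0, 1]` with unit diagonal;
#'   carries the normalization constant as attribute `"normalization"`.
#' @examples
#' S <- build_similarity_matrix()
#' S["L", "I"] # 1 - 5/215
#' @export
build_similarity_matrix <- function(properties = grantham_properties(),
                                    normalization = 215) {
  D <- grantham_distance_matrix(properties)
  if (normalization < max(D))
    shark_stop("shark_config_error",
               sprintf("normalization (%g) below maximum distance (%g)",
                       normalization, max(D)))
  S <- 1 - D / normalization
  attr(S, "normalization") <- normalization
  S
}

#' Residue similarity between two residues
#'
#' @inheritParams grantham_distance
#' @param normalization see [build_similarity_matrix()]
#' @return numeric in `[0, 1]`
#' @export
residue_similarity <- function(a, b, properties = grantham_properties(),
                               normalization = 215) {
  1 - grantham_distance(a, b, properties) / normalization
}

#' Read / write substitution matrices in NCBI/EMBOSS text layout
#'
#' The plain-text layout used by NCBI and EMBOSS matrix files: `#` comment
#' lines, a header row of residue codes, then one labelled row per residue.
#'
#' @param path file path
#' @return `read_substitution_matrix()`: numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    shark_stop("shark_io_error", sprintf("not a matrix file: %s", path))
  cols <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(vapply(rows, length, 1L) != length(cols) + 1L))
    shark_stop("shark_io_error", "matrix rows do not match header width")
  lab <- vapply(rows, `[[`, "", 1L)
  M <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(M) <- list(lab, cols)
  if (anyNA(M)) shark_stop("shark_io_error", "non-numeric matrix entries")
  M
}

#' @rdname read_substitution_matrix
#' @param M numeric matrix with residue dimnames
#' @param digits decimals written (default 4; integers written as-is)
#' @param comment optional character vector of comment lines (without `#`)
#' @export
write_substitution_matrix <- function(M, path, digits = 4, comment = NULL) {
  stopifnot(is.matrix(M), !is.null(dimnames(M)))
  fmt <- function(x) {
    if (all(x == round(x))) format(x, trim = TRUE)
    else format(round(x, digits), trim = TRUE, nsmall = digits)
  }
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rownames(M)[i], fmt(M[i, ])), collapse = " "), "")
  lines <- c(if (!is.null(comment)) paste("#", comment),
             paste(colnames(M), collapse = " "), body)
  writeLines(lines, path)
  invisible(path)
}

#' Load a named or file-based substitution matrix
#'
#' `"BLOSUM62"` and `"PAM30"` resolve to the matrices shipped with Biostrings;
#' any other value is treated as a path to an NCBI/EMBOSS-layout matrix file.
#'
#' @param matrix matrix name, file path, or an already-built numeric matrix
#' @return numeric matrix with residue dimnames
#' @export
load_substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  stopifnot(is.character(matrix), length(matrix) == 1L)
  if (toupper(matrix) %in% c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                             "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                             "PAM250")) {
    e <- new.env()
    utils::data(list = toupper(matrix), package = "Biostrings", envir = e)
    return(get(toupper(matrix), envir = e))
  }
  if (!file.exists(matrix))
    shark_stop("shark_io_error", sprintf("matrix file not found: %s", matrix))
  read_substitution_matrix(matrix)
}
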