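#' Mutation parameters for the homolog-family generator
#'
#' @param substitution_rate per-residue substitution probability in `[0, 1]`
#' @param insertion_rate per-position insertion probability in `[0, 1]`
#' @param deletion_rate per-position deletion probability in `[0, 1]`
#' @param max_indel_length maximum insertion/deletion length (lengths are
#'   drawn from a geometric distribution truncated at this value)
#' @param grantham_bias if `TRUE`, substitutions are biased toward
#'   physicochemically similar residues (replacement probability proportional
#'   to a power of the Grantham similarity); if `FALSE`, replacements are
#'   uniform over the other 19 residues
#' @return list of class `mutation_params`
#' @export
mutation_params <- function(substitution_rate = 0.38, insertion_rate = 0.08,
                            deletion_rate = 0.08, max_indel_length = 5,
                            grantham_bias = TRUE) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    shark_stop("shark_config_error", "mutation rates must be in [0, 1]")
  if (max_indel_length < 1)
    shark_stop("shark_config_error", "max_indel_length must be >= 1")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 max_indel_length = as.integer(max_indel_length),
                 grantham_bias = isTRUE(grantham_bias)),
            class = "mutation_params")
}

#' Disordered-region-like residue composition
#'
#' Default background composition of the generator: enriched in the
#' disorder-promoting residues S, G, P, Q, E, K and depleted in the
#' order-promoting W, C, F (and other aromatics/aliphatics), emulating the
#' compositional bias of intrinsically disordered regions. The exact
#' frequencies are a package choice, not an empirical census.
#'
#' @return named numeric probability vector over the 20 canonical residues
#' @export
disorder_composition <- function() {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  w[c("S", "G", "P", "Q", "E", "K")] <- 3
  w[c("A", "T", "D", "R", "N")] <- 1.6
  w[c("W", "C", "F", "Y", "I", "M", "H")] <- 0.4
  w / sum(w)
}

trunc_geom <- function(n, p = 0.5, max_len = 5) {
  l <- stats::rgeom(n, p) + 1L
  pmin(l, max_len)
}

# substitution targets: for each residue, a probability row over replacements
substitution_kernel <- function(matrix, bias = TRUE, power = 4) {
  K <- if (bias) matrix^power else matrix(1, 20, 20, dimnames = dimnames(matrix))
  diag(K) <- 0
  sweep(K, 1L, rowSums(K), "/")
}

mutate_codes <- function(codes, protected, params, kernel, profile) {
  n <- length(codes)
  # substitutions everywhere (motifs included: they diverge too, just
  # physicochemically conservatively when grantham_bias is on)
  hit <- which(runif(n) < params$substitution_rate)
  for (i in hit) codes[i] <- sample.int(20L, 1L, prob = kernel[codes[i], ])
  if (params$deletion_rate > 0 || params$insertion_rate > 0) {
    # deletions start only at unprotected positions and stop at motif borders,
    # so implanted motifs are never truncated (they drift via substitutions)
    keep <- rep(TRUE, n)
    del_start <- which(runif(n) < params$deletion_rate & !protected)
    for (i in del_start) {
      L <- trunc_geom(1L, max_len = params$max_indel_length)
      j <- i
      while (j <= n && j < i + L && !protected[j]) { keep[j] <- FALSE; j <- j + 1L }
    }
    ins_at <- which(runif(n + 1L) < params$insertion_rate)
    pieces <- vector("list", 2L * n + 1L)
    for (i in seq_len(n)) if (keep[i]) pieces[[2L * i]] <- codes[i]
    prot_out <- vector("list", 2L * n + 1L)
    for (i in seq_len(n)) if (keep[i]) prot_out[[2L * i]] <- protected[i]
    for (a in ins_at) {
      L <- trunc_geom(1L, max_len = params$max_indel_length)
      ins <- sample.int(20L, L, replace = TRUE, prob = profile)
      pieces[[2L * a - 1L]] <- ins
      prot_out[[2L * a - 1L]] <- rep(FALSE, L)
    }
    codes <- unlist(pieces)
    protected <- unlist(prot_out)
  }
  list(codes = codes, protected = protected)
}

codes_to_string <- function(codes) paste(AA_ALPHABET[codes], collapse = "")

#' Generate one synthetic homolog family
#'
#' Emulates the structure of a family of diverged, unalignable orthologous
#' segments: an ancestor sequence is drawn from `composition_profile`, the
#' motifs of `motif_set` are implanted at random non-overlapping positions,
#' and each member is an independently mutated copy of that ancestor
#' (substitutions optionally Grantham-biased toward similar residues;
#' geometric-length insertions/deletions that spare the motif spans, so motif
#' positions drift but their physicochemical character persists). Members
#' violating the pairwise-identity cap — mirroring the "max 50% identity"
#' filtering of curated homolog benchmarks — are re-mutated up to
#' `max_retries` times; if the cap cannot be met (e.g. all mutation rates 0)
#' an error reports the offending parameters.
#'
#' @param n_members number of member sequences (>= 2)
#' @param length_range ancestor length range (inclusive), default 50..300
#' @param motif_set character vector of motifs implanted in the ancestor
#'   (may be empty); each must be shorter than the minimum length
#' @param composition_profile named probability vector over the 20 residues
#' @param params [mutation_params()]
#' @param family_id identifier, used to prefix member ids
#' @param identity_cap maximum allowed pairwise identity (default 0.5)
#' @param max_retries re-mutation attempts per member before failing
#' @param seed integer seed; the family is a pure function of its arguments
#' @return list of class `seq_family` with `family_id`, `members` (named
#'   character vector), `ancestor` and `provenance` (all generator inputs)
#' @export
generate_family <- function(n_members = 8,
                            length_range = c(50, 300),
                            motif_set = character(0),
                            composition_profile = disorder_composition(),
                            params = mutation_params(),
                            family_id = "fam1",
                            identity_cap = 0.5,
                            max_retries = 100,
                            seed = 1) {
  if (n_members < 2L) shark_stop("shark_config_error", "n_members must be >= 2")
  if (length(motif_set) && max(nchar(motif_set)) >= min(length_range))
    shark_stop("shark_config_error", "motifs must be shorter than the minimum length")
  profile <- composition_profile[AA_ALPHABET]
  if (anyNA(profile)) shark_stop("shark_config_error",
                                 "composition profile must cover the 20 residues")
  profile <- profile / sum(profile)
  S <- build_similarity_matrix()
  kernel <- substitution_kernel(S, bias = params$grantham_bias)
  withr_seed(derive_seed(seed, paste0("family_", family_id)))
  L <- sample_range(length_range)
  anc <- sample.int(20L, L, replace = TRUE, prob = profile)
  protected <- rep(FALSE, L)
  if (length(motif_set)) {
    ordm <- sample.int(length(motif_set))
    slots <- integer(length(motif_set))
    slots[ordm] <- implant_positions(L, nchar(motif_set)[ordm])
    for (m in seq_along(motif_set)) {
      span <- slots[m]:(slots[m] + nchar(motif_set[m]) - 1L)
      anc[span] <- encode_seq(motif_set[m])
      protected[span] <- TRUE
    }
  }
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      mut <- mutate_codes(anc, protected, params, kernel, profile)
      s <- codes_to_string(mut$codes)
      prev <- vapply(members[seq_len(i - 1L)], identity, "")
      if (all(vapply(prev, function(p) pairwise_identity(s, p), 1) <= identity_cap)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      shark_stop("shark_generator_error",
                 sprintf(paste0("family %s: could not satisfy identity cap %.2f for ",
                                "member %d after %d retries (substitution_rate = %g, ",
                                "insertion_rate = %g, deletion_rate = %g)"),
                         family_id, identity_cap, i, max_retries,
                         params$substitution_rate, params$insertion_rate,
                         params$deletion_rate))
    members[[i]] <- s
  }
  members <- setNames(unlist(members),
                      paste0(family_id, "_m", seq_len(n_members)))
  structure(list(family_id = family_id, members = members,
                 ancestor = codes_to_string(anc),
                 provenance = list(motif_set = motif_set,
                                   composition_profile = profile,
                                   params = unclass(params),
                                   identity_cap = identity_cap,
                                   length_range = length_range,
                                   seed = seed)),
            class = "seq_family")
}

# non-overlapping implantation slots (1-based starts) for motifs of the given
# lengths in a sequence of length L: the free residues are distributed at
# random over the gaps around the motifs (stars-and-bars), so placement
# always succeeds when the motifs fit at all
implant_positions <- function(L, lens) {
  n <- length(lens)
  free <- L - sum(lens)
  if (free < 0L)
    shark_stop("shark_generator_error",
               sprintf("motifs (%d residues) do not fit in length %d",
                       sum(lens), L))
  gaps <- tabulate(sample.int(n + 1L, free, replace = TRUE), n + 1L)
  starts <- integer(n)
  pos <- 1L
  for (m in seq_len(n)) {
    pos <- pos + gaps[m]
    starts[m] <- pos
    pos <- pos + lens[m]
  }
  starts
}

# range sampling safe against length-1 ranges (sample() would misread them)
sample_range <- function(range, n = 1L) {
  vals <- range[1]:range[2]
  vals[sample.int(length(vals), n, replace = TRUE)]
}

#' @export
print.seq_family <- function(x, ...) {
  cat(sprintf("sequence family %s: %d members, lengths %d-%d, %d motif(s)\n",
              x$family_id, length(x$members), min(nchar(x$members)),
              max(nchar(x$members)), length(x$provenance$motif_set)))
  invisible(x)
}

#' Generate a synthetic dataset of homolog families
#'
#' Families draw distinct motif sets and per-family composition profiles: a
#' family profile is the disorder-like base composition perturbed by
#' `spread * N(0,1)` on the log scale (renormalized), so `spread` controls
#' the compositional distance between families (`spread = 0` gives identical
#' profiles and a warning that families may be hard to separate). Family
#' sizes are drawn from `members_range`. All output is a pure function of
#' `seed`.
#'
#' @param n_families number of families (>= 2), default 50
#' @param members_range family size range (inclusive), default 5..20
#' @param length_range ancestor length range, default 50..300
#' @param n_motifs motifs implanted per family, default 3
#' @param motif_length_range motif length range, default 6..10
#' @param spread inter-family compositional spread (log-scale SD), default 0.5
#' @param params [mutation_params()]
#' @param identity_cap see [generate_family()]
#' @param seed integer seed
#' @return list of `seq_family` objects with a `provenance` attribute
#' @export
generate_dataset <- function(n_families = 50, members_range = c(5, 20),
                             length_range = c(50, 300), n_motifs = 5,
                             motif_length_range = c(6, 10), spread = 1,
                             params = mutation_params(), identity_cap = 0.5,
                             seed = 1) {
  if (n_families < 2L) shark_stop("shark_config_error", "n_families must be >= 2")
  if (spread == 0)
    warning("spread = 0: family composition profiles coincide; inter-family separation is not guaranteed",
            call. = FALSE)
  base <- disorder_composition()
  withr_seed(derive_seed(seed, "dataset"))
  fam_seed <- sample.int(2^30, n_families)
  fam_size <- sample_range(members_range, n_families)
  profiles <- lapply(seq_len(n_families), function(i) {
    p <- base * exp(spread * rnorm(20L))
    p / sum(p)
  })
  motif_sets <- list()
  for (i in seq_len(n_families)) {
    for (try in 1:100) {
      lens <- sample_range(motif_length_range, n_motifs)
      ms <- vapply(lens, function(l)
        paste(sample(AA_ALPHABET, l, replace = TRUE, prob = profiles[[i]]),
              collapse = ""), "")
      if (!any(vapply(motif_sets, function(old) any(ms %in% old), TRUE))) break
      if (try == 100)
        shark_stop("shark_generator_error", "could not draw distinct motif sets")
    }
    motif_sets[[i]] <- ms
  }
  fams <- lapply(seq_len(n_families), function(i)
    generate_family(n_members = fam_size[i], length_range = length_range,
                    motif_set = motif_sets[[i]],
                    composition_profile = profiles[[i]], params = params,
                    family_id = sprintf("F%03d", i), identity_cap = identity_cap,
                    seed = fam_seed[i]))
  attr(fams, "provenance") <- list(n_families = n_families,
                                   members_range = members_range,
                                   length_range = length_range,
                                   n_motifs = n_motifs,
                                   motif_length_range = motif_length_range,
                                   spread = spread, params = unclass(params),
                                   identity_cap = identity_cap, seed = seed)
  fams
}

#' Flatten a family list into a named sequence vector / family map
#'
#' @param families list of `seq_family` objects
#' @return `dataset_sequences()`: named character vector of all member
#'   sequences; `dataset_family_map()`: data.frame with `sequence_id`,
#'   `family_id`.
#' @export
dataset_sequences <- function(families)
  unlist(lapply(families, `[[`, "members"))

#' @rdname dataset_sequences
#' @export
dataset_family_map <- function(families) {
  do.call(rbind, lapply(families, function(f)
    data.frame(sequence_id = names(f$members), family_id = f$family_id,
               stringsAsFactors = FALSE)))
}

#' Global pairwise sequence identity
#'
#' End-to-end (Needleman-Wunsch) alignment with BLOSUM62 and affine gap
#' penalties (open 10, extend 1); identity is the number of identical aligned
#' positions divided by the alignment length, gap columns included. This is
#' the identity convention used for the identity cap of the generator and the
#' PID bins of the benchmark harness.
#'
#' @param s1,s2 non-empty residue strings
#' @return identity in `[0, 1]`
#' @examples
#' pairwise_identity("AAAA", "AAAC") # 0.75
#' @export
pairwise_identity <- function(s1, s2) {
  if (!nchar(s1) || !nchar(s2))
    shark_stop("shark_config_error", "sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    s1, s2, substitutionMatrix = pid_matrix(), gapOpening = 10,
    gapExtension = 1, type = "global", scoreOnly = FALSE)
  Biostrings::pid(aln, type = "PID1") / 100
}

pid_matrix <- local({
  M <- NULL
  function() {
    if (is.null(M)) M <<- load_substitution_matrix("BLOSUM62")
    M
  }
})

#' Family-wise train/validation/test split
#'
#' Families (never individual sequences) are shuffled with the seed and
#' partitioned by cumulative ratio with largest-remainder rounding, so the
#' partitions are disjoint, exhaustive, and as close to the requested ratios
#' as integer counts allow.
#'
#' @param families list of `seq_family` objects (>= 3)
#' @param ratios positive train/validation/test ratios summing to 1
#' @param seed integer seed
#' @return list of class `dataset_split` with `train`, `validation`, `test`
#'   (family-id character vectors) and `seed`
#' @export
split_by_family <- function(families, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(families) < 3L)
    shark_stop("shark_config_error", "need at least 3 families to split")
  if (length(ratios) != 3L || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    shark_stop("shark_config_error", "ratios must be 3 positive values summing to 1")
  ids <- vapply(families, `[[`, "", "family_id")
  withr_seed(derive_seed(seed, "split"))
  ids <- sample(ids)
  n <- length(ids)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  bounds <- cumsum(sizes)
  structure(list(train = sort(ids[seq_len(bounds[1])]),
                 validation = sort(ids[(bounds[1] + 1):bounds[2]]),
                 test = sort(ids[(bounds[2] + 1):bounds[3]]),
                 seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("family split: %d train / %d validation / %d test (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Subset families by id
#' @param families list of `seq_family` objects
#' @param ids family ids to keep
#' @return filtered family list
#' @export
subset_families <- function(families, ids) {
  families[vapply(families, `[[`, "", "family_id") %in% ids]
}
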