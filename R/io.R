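#' Read a protein FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' wrapped sequence lines are joined and upper-cased. Duplicate ids, empty
#' files and (unless `sanitize`) non-canonical residues raise explicit
#' errors.
#'
#' @param path FASTA file path
#' @param sanitize allow non-canonical residue codes (they are dropped at the
#'   k-mer level downstream)
#' @return named character vector of sequences, in file order
#' @export
read_fasta <- function(path, sanitize = FALSE) {
  if (!file.exists(path))
    shark_stop("shark_io_error", sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    shark_stop("shark_io_error",
                               sprintf("cannot read FASTA %s: %s", path,
                                       conditionMessage(e))))
  if (!length(set))
    shark_stop("shark_io_error", sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    shark_stop("shark_io_error",
               sprintf("duplicate sequence id(s): %s",
                       paste(unique(dup), collapse = ", ")))
  seqs <- setNames(toupper(as.character(set)), ids)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), AA_ALPHABET)
    if (length(bad) && !sanitize)
      shark_stop("shark_invalid_residue",
                 sprintf("record %s contains non-canonical code(s): %s (use sanitize)",
                         ids[i], paste(bad, collapse = ", ")))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences (non-empty)
#' @param path output path
#' @param width line-wrap width (default 60)
#' @export
write_fasta <- function(records, path, width = 60) {
  if (!length(records))
    shark_stop("shark_io_error", "nothing to write: empty record list")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    shark_stop("shark_io_error", "records must be named")
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write a family map TSV
#'
#' Two tab-separated columns, `sequence_id` and `family_id`, with a `#`
#' header line.
#'
#' @param path file path
#' @return `read_family_map()`: data.frame with `sequence_id`, `family_id`
#' @export
read_family_map <- function(path) {
  df <- read_tsv_hash(path)
  if (!all(c("sequence_id", "family_id") %in% names(df)))
    shark_stop("shark_io_error",
               "family map needs columns sequence_id, family_id")
  df
}

#' @rdname read_family_map
#' @param map data.frame with columns `sequence_id`, `family_id`
#' @export
write_family_map <- function(map, path) {
  write_tsv_hash(map[, c("sequence_id", "family_id")], path)
}

# TSV with a single '#'-prefixed header line (the package's tabular dialect)
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  close(con)
  invisible(path)
}

read_tsv_hash <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "#"))
    shark_stop("shark_io_error", sprintf("missing # header line: %s", path))
  cols <- strsplit(sub("^#", "", lines[[1]]), "\t")[[1]]
  if (length(lines) == 1L)
    return(setNames(as.data.frame(replicate(length(cols), character(0),
                                            simplify = FALSE)), cols))
  utils::read.delim(textConnection(lines[-1]), header = FALSE,
                    col.names = cols, stringsAsFactors = FALSE)
}

config_defaults <- function() {
  list(
    seed = 1L,
    normalization = 215,
    sanitize = FALSE,
    feature_map = default_feature_map(),
    gbdt = list(nrounds = 200L, max_depth = 3L, eta = 0.1, monotone = TRUE),
    n_submodels = 10L,
    threshold = 0.5,
    negative_ratio = 1,
    generator = list(n_families = 50L, members_range = c(5L, 20L),
                     length_range = c(50L, 300L), n_motifs = 5L,
                     motif_length_range = c(6L, 10L), spread = 1,
                     substitution_rate = 0.38, insertion_rate = 0.08,
                     deletion_rate = 0.08, max_indel_length = 5L,
                     grantham_bias = TRUE, identity_cap = 0.5),
    evaluation = list(split_ratios = c(0.6, 0.2, 0.2),
                      pid_bin_edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1)),
    interpret = list(k = 8L, T = 0.85, background_pairs = 10000L),
    verbosity = 1L)
}

#' Load the package configuration
#'
#' Validated defaults, optionally overridden by a YAML file (only known keys
#' accepted, recursively for the nested sections) and then by an `overrides`
#' list (the CLI's flag layer).
#'
#' @param path optional YAML file
#' @param overrides optional named list applied after the file
#' @return config list of class `shark_config`
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- config_defaults()
  apply_layer <- function(cfg, layer, where) {
    for (key in names(layer)) {
      if (!key %in% names(cfg))
        shark_stop("shark_config_error",
                   sprintf("unknown configuration key '%s' (%s)", key, where))
      if (is.list(cfg[[key]]) && !is.data.frame(cfg[[key]]) &&
          is.list(layer[[key]]))
        cfg[[key]] <- apply_layer(cfg[[key]], layer[[key]],
                                  paste0(where, "$", key))
      else cfg[[key]] <- layer[[key]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      shark_stop("shark_io_error", sprintf("config file not found: %s", path))
    cfg <- apply_layer(cfg, yaml::read_yaml(path), "file")
  }
  if (!is.null(overrides)) cfg <- apply_layer(cfg, overrides, "override")
  validate_config(cfg)
  structure(cfg, class = c("shark_config", "list"))
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed)) shark_stop("shark_config_error", "seed must be numeric")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    shark_stop("shark_config_error", "threshold must be in (0, 1)")
  if (cfg$normalization <= 0)
    shark_stop("shark_config_error", "normalization must be positive")
  validate_feature_map(as.data.frame(cfg$feature_map))
  invisible(cfg)
}

#' Write a provenance record next to an output
#'
#' JSON sidecar with the package version, the effective configuration, the
#' seed, and md5 digests of the input files, so every output directory
#' documents how it was produced.
#'
#' @param path output JSON path
#' @param config effective configuration (list)
#' @param seed effective seed
#' @param inputs character vector of input file paths to digest
#' @export
write_provenance <- function(path, config = NULL, seed = NULL,
                             inputs = character(0)) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  obj <- list(package = "shark",
              version = as.character(utils::packageVersion("shark")),
              seed = seed, config = config, input_md5 = digests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
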