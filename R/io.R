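# File formats: FASTA via Biostrings, tab-separated tables with a
# "#key: value" provenance header, and a plain key:value config file.

DATASET_SCHEMA_VERSION <- "1.0"

#' Read a FASTA file of nucleotide sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a plain named
#' character vector; sequences are normalised to upper case.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  out <- toupper(as.character(ss))
  # keep only the identifier token of each header line
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out
}

#' Write named sequences to a FASTA file
#'
#' @param records Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("records must be named")
  }
  ss <- Biostrings::DNAStringSet(toupper(unlist(records)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write a tube-level dataset table as TSV
#'
#' Tab-separated, UTF-8, LF, with `"."` as the null token and a leading
#' provenance header of `#key: value` lines (schema version, seed, simulation
#' parameters).
#'
#' @param dataset Tube-level data.frame (`cell_id`, `gene`, `tube_index`,
#'   `positive`, `site_calls`; extra columns are dropped from the public
#'   schema).
#' @param path Output path.
#' @param seed,params Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, seed = NULL, params = NULL) {
  cols <- c("cell_id", "gene", "tube_index", "positive", "site_calls")
  if (!all(cols %in% names(dataset))) {
    stop("dataset needs columns: ", paste(cols, collapse = ", "))
  }
  hdr <- c(paste0("#schema_version: ", DATASET_SCHEMA_VERSION))
  if (!is.null(seed)) hdr <- c(hdr, paste0("#seed: ", seed))
  if (!is.null(params) && inherits(params, "sim_params")) {
    hdr <- c(hdr, vapply(names(unclass(params)), function(nm) {
      paste0("#param_", nm, ": ", params[[nm]])
    }, ""))
  }
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  d <- dataset[, cols, drop = FALSE]
  if (nrow(d)) {
    lines <- do.call(paste, c(lapply(d, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a tube-level dataset table written by [write_dataset()]
#'
#' @param path Path to the TSV file.
#' @return data.frame in the tube-level schema, with the provenance header
#'   attached as attribute `"provenance"` (named character vector).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  prov <- character(0)
  if (length(hdr)) {
    kv <- strsplit(sub("^#", "", hdr), ": ", fixed = TRUE)
    prov <- stats::setNames(vapply(kv, function(x) paste(x[-1L],
                                                         collapse = ": "), ""),
                            vapply(kv, `[`, "", 1L))
  }
  d <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                  stringsAsFactors = FALSE, colClasses = c(
                    cell_id = "character", gene = "character",
                    tube_index = "integer", positive = "integer",
                    site_calls = "character"))
  attr(d, "provenance") <- prov
  d
}

#' Write / read a generic TSV table
#'
#' @param x data.frame. / @param path File path.
#' @return `path` invisibly / the data.frame.
#' @rdname tsv_io
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = ".")
}

#' Read a key: value configuration file
#'
#' Plain `key: value` text (a YAML subset); values are parsed by YAML rules,
#' so numbers and booleans come back typed.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' Build simulation parameters from a configuration list
#'
#' Unknown keys raise an error naming the key; missing keys fall back to the
#' [sim_params()] defaults.
#'
#' @param config Named list (e.g. from [read_config()]).
#' @return A [sim_params()].
#' @export
params_from_config <- function(config) {
  known <- names(formals(sim_params))
  extra <- setdiff(names(config), c(known, "n_cells", "seed", "out"))
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  do.call(sim_params, config[intersect(names(config), known)])
}
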