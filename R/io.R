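#' Read sequence records (FASTA, FASTQ or plain/2-column TSV)
#'
#' Format is auto-detected from the first character unless given. FASTQ
#' qualities are parsed (and validated structurally) but discarded; malformed
#' FASTQ stops with the offending line number. TSV input is either one
#' sequence per line or two columns (id, sequence).
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"fasta"}, \code{"fastq"},
#'   \code{"tsv"}.
#' @return named character vector of uppercase sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("no such file: %s", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1, 1)
    format <- if (identical(first, ">")) "fasta"
              else if (identical(first, "@")) "fastq" else "tsv"
  }
  if (format == "fastq") {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop_usage("malformed FASTQ %s: truncated record at line %d",
                 path, (length(lines) %/% 4L) * 4L + 1L)
    bad <- which(substr(lines[seq(1, length(lines), by = 4L)], 1, 1) != "@")
    if (length(bad))
      stop_usage("malformed FASTQ %s: expected @ at line %d", path,
                 (bad[1] - 1L) * 4L + 1L)
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) >= 2L)
      return(setNames(toupper(dt[[2]]), as.character(dt[[1]])))
    return(setNames(toupper(dt[[1]]), paste0("seq_", seq_len(nrow(dt)))))
  }
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTQ output assigns a flat quality (\code{"I"}, Q40) to every base:
#' simulated reads carry no meaningful quality information.
#'
#' @param seqs named character vector (names become record ids; unnamed
#'   sequences get seq_1..seq_n).
#' @param path output file.
#' @param format \code{"fasta"} or \code{"fastq"}.
#' @return the path, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ids <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  ids[!nzchar(ids)] <- paste0("seq_", which(!nzchar(ids)))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", ids, "\n", seqs), con, sep = "\n")
  } else {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n)
                        strrep("I", n), character(1))), con, sep = "\n")
  }
  invisible(path)
}

#' Read a single-cell tape table
#'
#' Autodetects between the raw schema (cell_id, umi, target_bc, tape
#' sequence; routed through \code{\link{collapse_umis}} and parsing) and the
#' collapsed schema (cell_id, target_bc, site1..siteK). Common header
#' variants (CBC/cell/cell_id, TargetBC/target_bc, Site1/site1...) are
#' accepted; blank site fields mean unedited.
#'
#' @param path TSV/CSV file with a header row.
#' @return data.table with normalized column names; attribute \code{schema}
#'   is \code{"raw"} or \code{"collapsed"}.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: %s", path)
  dt <- data.table::fread(path, colClasses = "character")
  nm <- tolower(names(dt))
  nm[nm %in% c("cbc", "cell", "cellbc", "cell_barcode")] <- "cell_id"
  nm[nm %in% c("targetbc", "target", "tape_id")] <- "target_bc"
  nm[nm %in% c("umi_seq", "umis")] <- "umi"
  nm[nm %in% c("sequence", "seq", "tape_seq", "read")] <- "tape"
  nm <- sub("^insertbc", "site", nm)
  data.table::setnames(dt, nm)
  has_sites <- any(grepl("^site[0-9]+$", nm))
  schema <- if (all(c("cell_id", "umi", "target_bc", "tape") %in% nm)) "raw"
            else if (all(c("cell_id", "target_bc") %in% nm) && has_sites) "collapsed"
            else stop_usage(paste("unknown cell-table schema in %s: need either",
                                  "(cell_id, umi, target_bc, tape) or",
                                  "(cell_id, target_bc, site1..siteK)"), path)
  if (schema == "collapsed")
    for (sc in grep("^site[0-9]+$", names(dt), value = TRUE))
      dt[[sc]][is.na(dt[[sc]])] <- ""
  data.table::setattr(dt, "schema", schema)
  dt
}

#' Write a collapsed cell table as TSV
#' @param cells data.table as produced by \code{\link{simulate_clone}}.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  data.table::fwrite(cells, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read/write a labeled matrix as CSV (bigram matrices, distance matrices)
#' @param m matrix with dimnames.
#' @param path CSV file.
#' @return \code{write_matrix_csv}: the path; \code{read_matrix_csv}: the
#'   matrix.
#' @export
write_matrix_csv <- function(m, path) {
  dt <- data.table::as.data.table(as.data.frame(m), keep.rownames = "symbol")
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Load a run configuration (YAML)
#'
#' A flat list of stage parameters and paths. Stochastic stages must name an
#' explicit integer seed; silent nondeterminism is a configuration error.
#'
#' @param path YAML file.
#' @return named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_usage("config must be a YAML mapping")
  structure(cfg, class = "run_config")
}
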