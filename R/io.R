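#' Read an expression matrix from TSV
#'
#' Expects a rectangular tab-separated file whose first column holds feature
#' identifiers (probes or genes) and whose header row holds sample
#' identifiers. Values must be finite numbers.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression TSV needs a header and at least one row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row at line ", bad, " of ", path, " (", widths[bad],
         " fields, expected ", widths[1L], ")")
  }
  header <- fields[[1L]]
  samples <- header[-1L]
  body <- fields[-1L]
  ids <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(samples)))
  )
  if (length(samples) == 1L) vals <- matrix(vals, nrow = 1L)
  mat <- t(vals)
  if (anyNA(mat) || any(!is.finite(mat))) {
    bad <- which(apply(is.na(mat) | !is.finite(mat), 1L, any))[1L]
    stop("non-numeric or non-finite cell at line ", bad + 1L, " of ", path)
  }
  dimnames(mat) <- list(ids, samples)
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the identifier column in the header.
#' @export
write_expression_tsv <- function(mat, path, id_column = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV table with required columns
#' @param path Path to file.
#' @param required Character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, required = character()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample stage metadata
#'
#' Two columns: `sample` and `stage`. Stage values are kept in first-appearance
#' order unless they match the default stage names.
#'
#' @param path Path to metadata TSV.
#' @return data.frame with columns sample, stage (factor with ordered levels).
#' @export
read_stage_tsv <- function(path) {
  df <- read_tsv_table(path, required = c("sample", "stage"))
  lv <- unique(df$stage)
  df$stage <- factor(df$stage, levels = lv)
  df
}

#' Read a probe table
#'
#' Columns `probe_id`, `probeset_id`, `sequence`.
#' @param path Path to probe TSV.
#' @return data.frame.
#' @export
read_probe_tsv <- function(path) {
  df <- read_tsv_table(path, required = c("probe_id", "probeset_id", "sequence"))
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id(s) in ", path, ": ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  df
}

#' Read a transcript attribute table
#'
#' Columns `transcript_id`, `gene_id`, `gene_symbol`, `biotype`; the contract
#' stands in for a full GTF attribute parse.
#' @param path Path to attribute TSV.
#' @return data.frame.
#' @export
read_transcript_attrs_tsv <- function(path) {
  read_tsv_table(path,
                 required = c("transcript_id", "gene_id", "gene_symbol", "biotype"))
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return [Biostrings::DNAStringSet] named by record id (first token).
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
  x
}

#' Write transcript sequences to FASTA (60-character wrap)
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_transcript_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes. The
#' description field is used as the category tag (biological process, pathway,
#' disease) when present.
#'
#' @param path GMT path.
#' @return Object of class `gene_set_collection`: named list of character
#'   vectors with a `category` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  structure(sets,
            category = stats::setNames(vapply(fields, `[`, character(1L), 2L), nm),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets Named list of character vectors (optionally with a `category`
#'   attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  cat_tags <- attr(sets, "category")
  if (is.null(cat_tags)) cat_tags <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, cat_tags[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' Columns `sample`, `time`, `event` (0/1), and optionally `group` or an
#' expression column for median dichotomization.
#' @param path Survival TSV path.
#' @return data.frame.
#' @export
read_survival_tsv <- function(path) {
  df <- read_tsv_table(path, required = c("sample", "time", "event"))
  if (any(df$time < 0)) stop("negative survival time in ", path)
  if (!all(df$event %in% c(0, 1))) stop("event column must be 0/1 in ", path)
  df
}
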