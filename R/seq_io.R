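# Amino-acid alphabet used throughout: the 20 standard residues plus X for
# unknown. Degenerate codes (B, Z, U, J, O) are rejected unless mapped to X.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
AA_DEGENERATE <- c("B", "Z", "U", "J", "O")

#' Construct a validated collection of protein records
#'
#' The central sequence container of the package: a data frame with columns
#' `id`, `description` and `sequence`. Sequences are upper-cased, trailing
#' stop symbols (`*`) are stripped, and only the 20 standard residues plus
#' `X` are accepted.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Optional character vector of free-text descriptions.
#' @param permissive If `TRUE`, degenerate codes B, Z, U, J, O are mapped to
#'   `X` instead of raising an error.
#' @return A data frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, description = "", permissive = FALSE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  sequence <- sub("\\*+$", "", sequence)
  if (length(description) == 1L) description <- rep(description, length(id))
  if (length(id) != length(sequence) || length(id) != length(description))
    stop("id, sequence and description must have equal lengths")
  if (any(!nzchar(id)))
    stop("protein ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("sequences must have length >= 1 (offending id: ",
         paste(id[!nzchar(sequence)], collapse = ", "), ")")
  if (permissive) {
    sequence <- chartr(paste(AA_DEGENERATE, collapse = ""),
                       strrep("X", length(AA_DEGENERATE)), sequence)
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(
      sprintf("[%s]", paste(AA_ALPHABET, collapse = "")), "",
      sequence[bad]), "")))
    stop("sequence(s) contain characters outside the amino-acid alphabet (",
         paste(ch, collapse = ", "), "); offending id(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, description = as.character(description),
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Parses a multi-line FASTA file into a [protein_records] collection. The
#' identifier is the first whitespace-delimited token of each header; the
#' remainder of the header becomes the description. Sequences are upper-cased
#' and trailing stops stripped; duplicate identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @param permissive Map degenerate residue codes to X instead of erroring.
#' @return A `protein_records` data frame.
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(protein_records(character(), character(), character()))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    return(protein_records(character(), character(), character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_records(ids, as.character(set), desc, permissive = permissive)
}

#' Write protein records to FASTA
#'
#' Round-trip safe: `read_fasta(write_fasta(x, f))` reproduces `x`. Sequences
#' are wrapped at 60 columns.
#'
#' @param records A `protein_records` data frame.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(inherits(records, "protein_records"))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a delimited expression table into a masked matrix
#'
#' The first column holds gene identifiers, remaining columns hold numeric
#' values (log2-scale expression). Cells equal to `missing_token` are masked:
#' the value grid carries `NA` there and the congruent logical `mask` is
#' `TRUE`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param missing_token Token marking missing cells (default `"NA"`).
#' @param sep Field delimiter (default tab).
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes x conditions) and `mask` (logical matrix).
#' @export
read_expression_table <- function(path, missing_token = "NA", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop("expression table needs a gene column plus >= 1 condition column")
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(vals))) stop("duplicate condition labels in expression table")
  mask <- vals == missing_token
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!mask & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
                 vals[bad[1L, 1L], bad[1L, 2L]]))
  }
  num[mask] <- NA_real_
  dimnames(num) <- list(genes, colnames(vals))
  dimnames(mask) <- dimnames(num)
  expression_matrix(num, mask)
}

#' Build an expression matrix object
#'
#' @param values Numeric matrix, genes in rows, conditions in columns; `NA`
#'   marks missing cells.
#' @param mask Optional logical matrix congruent with `values`; defaults to
#'   `is.na(values)`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, mask = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(values), dim(mask)))
    stop("mask and value grid must be congruent in shape")
  if (anyDuplicated(rownames(values))) stop("duplicate row labels")
  if (anyDuplicated(colnames(values))) stop("duplicate column labels")
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "expression_matrix")
}

#' Write an expression matrix as TSV
#'
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @param missing_token Token written for masked cells.
#' @export
write_expression_table <- function(expr, path, missing_token = "NA") {
  stopifnot(inherits(expr, "expression_matrix"))
  vals <- expr$values
  out <- cbind(gene = rownames(vals),
               as.data.frame(ifelse(expr$mask, missing_token,
                                    format(vals, trim = TRUE, digits = 15))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' Expected columns: `sample`, `gene`, `ct`, and optionally `treatment` and
#' `timepoint` (hours). One row per replicate well. Ct values must be finite
#' and positive.
#'
#' @param path Path to a delimited file with header.
#' @param sep Field delimiter.
#' @return A validated data frame of class `ct_table`.
#' @export
read_ct_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ct_table(df)
}

#' Validate a Ct table
#'
#' @param df Data frame with columns `sample`, `gene`, `ct` (and optionally
#'   `treatment`, `timepoint`).
#' @return `df` with class `ct_table` prepended.
#' @export
ct_table <- function(df) {
  need <- c("sample", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and positive")
  if (nrow(df) == 0L) stop("Ct table is empty")
  class(df) <- unique(c("ct_table", class(df)))
  df
}

# Shared TSV writer used by the reporting layer.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
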