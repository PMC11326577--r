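#' Read protein sequences from FASTA
#'
#' One `protein_record` per entry, order preserved. The first
#' whitespace-delimited token of the header is the id; any remainder
#' becomes the free-text annotation. Sequences are upper-cased and
#' validated against the package alphabet (20 canonical residues +
#' X); duplicate ids, empty sequences and illegal letters are
#' rejected with an error naming the offending entry.
#'
#' @param path FASTA file path
#' @return list of [protein_record()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(list())
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    stop("malformed FASTA '", path, "': entry with empty header")
  ids <- sub("\\s.*$", "", trimws(headers))
  ann <- sub("^\\S+\\s*", "", trimws(headers))
  ann[!nzchar(ann)] <- NA_character_
  seqs <- unname(as.character(set))
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    records[[i]] <- tryCatch(
      protein_record(ids[i], seqs[i], ann[i]),
      error = function(e) stop("FASTA entry ", i, " ('", ids[i], "') in '",
                               path, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  check_records(records)
  records
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p))`
#' reproduces ids, sequences and annotations.
#'
#' @param records list of [protein_record()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_fasta <- function(records, path) {
  check_records(records)
  seqs <- vapply(records, `[[`, character(1), "sequence")
  ids <- vapply(records, `[[`, character(1), "id")
  ann <- vapply(records, `[[`, character(1), "annotation")
  headers <- ifelse(is.na(ann), ids, paste(ids, ann))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read per-residue label files
#'
#' Label TSV dialect: two columns `record_id<TAB>label_string`, no
#' header, the label string one character per residue from
#' \{N, B, P, T\}. Every record must be labelled; label strings whose
#' length does not match the sequence and unknown label codes are
#' errors.
#'
#' @param path label TSV path
#' @param records list of [protein_record()] the labels refer to
#' @return list of [labeled_sequence()], in `records` order
#' @export
read_labels <- function(path, records) {
  ids <- check_records(records)
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("record_id", "label_string"))
  if (anyDuplicated(df$record_id))
    stop("duplicate record id(s) in label file: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "))
  unknown <- setdiff(df$record_id, ids)
  if (length(unknown))
    stop("label file refers to unknown record(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(ids, df$record_id)
  if (length(missing))
    stop("no labels for record(s): ", paste(missing, collapse = ", "))
  strings <- df$label_string[match(ids, df$record_id)]
  lapply(seq_along(records), function(i)
    labeled_sequence(records[[i]], string_to_labels(strings[i])))
}

#' @rdname read_labels
#' @param labeled list of [labeled_sequence()]
#' @export
write_labels <- function(labeled, path) {
  lines <- vapply(labeled, function(x)
    paste(x$record$id, labels_to_string(x$labels), sep = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read prediction reports
#'
#' Prediction TSV dialect (with header):
#' `record_id<TAB>depo_probability<TAB>is_depolymerase<TAB>label_string`.
#' Probabilities are written to 6 decimals; a round trip reproduces
#' labels, probabilities to that precision, and binary calls. An
#' empty result list yields a header-only file.
#'
#' @param results list of [prediction_result()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_predictions <- function(results, path) {
  header <- "record_id\tdepo_probability\tis_depolymerase\tlabel_string"
  lines <- vapply(results, function(r)
    sprintf("%s\t%.6f\t%s\t%s", r$record_id, r$depo_probability,
            if (r$is_depolymerase) "1" else "0",
            labels_to_string(r$token_labels)), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' @rdname write_predictions
#' @return `read_predictions()`: data frame with columns `record_id`,
#'   `depo_probability`, `is_depolymerase` (logical) and
#'   `label_string`
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "numeric",
                                         "integer", "character"))
  df$is_depolymerase <- df$is_depolymerase == 1L
  for (s in df$label_string) string_to_labels(s)  # validate codes
  df
}

#' Read and write binary truth tables
#'
#' Truth TSV dialect: `record_id<TAB>is_depolymerase` with 0/1 calls,
#' no header.
#'
#' @param path TSV path
#' @return named logical vector keyed by record id
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  df <- utils::read.delim(path, header = FALSE,
                          colClasses = c("character", "integer"),
                          col.names = c("record_id", "is_depolymerase"))
  if (any(!df$is_depolymerase %in% c(0L, 1L)))
    stop("truth calls must be 0 or 1")
  stats::setNames(df$is_depolymerase == 1L, df$record_id)
}

#' @rdname read_truth
#' @param truth named logical vector
#' @export
write_truth <- function(truth, path) {
  writeLines(paste(names(truth), as.integer(truth), sep = "\t"), path)
  invisible(path)
}
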