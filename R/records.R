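#' Protein records and labelled sequences
#'
#' `protein_record()` is the atom of every pipeline stage: an
#' identifier, an amino-acid sequence over the canonical 20 letters
#' plus X, and an optional free-text functional annotation.
#' `labeled_sequence()` pairs a record with one trainable fold label
#' per residue; the length invariant is asserted at construction and
#' therefore holds everywhere downstream.
#'
#' @param id non-empty identifier, unique within a dataset
#' @param sequence amino-acid string; lower case accepted and
#'   normalised to upper
#' @param annotation optional free-text functional label
#' @return an object of class `protein_record`
#' @examples
#' r <- protein_record("p1", "MKLVNNAG")
#' nchar(r$sequence)
#' @export
protein_record <- function(id, sequence, annotation = NA_character_) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("record id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string (record '", id, "')")
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop("empty sequence for record '", id, "'")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), .AA_ALPHABET)
  if (length(bad))
    stop("illegal residue letter(s) ", paste(bad, collapse = ", "),
         " in record '", id, "'")
  structure(list(id = id, sequence = sequence,
                 annotation = as.character(annotation)[1]),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  ann <- if (is.na(x$annotation)) "" else paste0(" [", x$annotation, "]")
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id,
              nchar(x$sequence), ann))
  invisible(x)
}

record_length <- function(record) nchar(record$sequence)

# validates a list of protein_record and unique ids
check_records <- function(records) {
  if (!is.list(records)) stop("records must be a list of protein_record")
  ok <- vapply(records, inherits, logical(1), what = "protein_record")
  if (!all(ok)) stop("records must all be protein_record objects")
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  invisible(ids)
}

#' @rdname protein_record
#' @param record a `protein_record`
#' @param labels character vector of trainable fold labels, one per
#'   residue (see [fold_labels()])
#' @return `labeled_sequence()`: an object of class `labeled_sequence`
#' @export
labeled_sequence <- function(record, labels) {
  if (!inherits(record, "protein_record"))
    stop("record must be a protein_record")
  labels <- as.character(labels)
  if (length(labels) != record_length(record))
    stop("label vector length (", length(labels),
         ") does not match sequence length (", record_length(record),
         ") for record '", record$id, "'")
  bad <- setdiff(unique(labels), .TRAINABLE_LABELS)
  if (length(bad))
    stop("non-trainable label(s) ", paste(bad, collapse = ", "),
         " for record '", record$id, "'")
  structure(list(record = record, labels = labels),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = .TRAINABLE_LABELS))
  cat(sprintf("<labeled_sequence> %s (%d aa): %s\n", x$record$id,
              length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Per-protein prediction result
#'
#' One row of model output: per-residue fold labels, the per-residue
#' 4-class probability matrix, the sequence-level depolymerase
#' probability, and the binary call. The binary call is a pure
#' function of the probability and the fixed 0.5 threshold (ties
#' positive); `token_labels` is the per-residue argmax of
#' `token_scores`.
#'
#' @param record_id record identifier
#' @param token_scores numeric matrix, length x 4, rows summing to 1
#' @param depo_probability sequence-level probability in \[0, 1\]
#' @param threshold binary decision threshold (default 0.5)
#' @return an object of class `prediction_result`
#' @export
prediction_result <- function(record_id, token_scores, depo_probability,
                              threshold = 0.5) {
  if (!is.matrix(token_scores) || ncol(token_scores) != 4L)
    stop("token_scores must be a length x 4 matrix")
  rs <- rowSums(token_scores)
  if (any(abs(rs - 1) > 1e-6))
    stop("token score rows must sum to 1 (record '", record_id, "')")
  if (!is.numeric(depo_probability) || length(depo_probability) != 1L ||
      is.na(depo_probability) || depo_probability < 0 || depo_probability > 1)
    stop("depo_probability must be a single value in [0, 1]")
  labels <- .TRAINABLE_LABELS[max.col(token_scores, ties.method = "first")]
  structure(list(record_id = record_id,
                 token_labels = labels,
                 token_scores = token_scores,
                 depo_probability = depo_probability,
                 is_depolymerase = depo_probability >= threshold,
                 threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s: p(depolymerase)=%.4f -> %s\n",
              x$record_id, x$depo_probability,
              if (x$is_depolymerase) "depolymerase" else "negative"))
  invisible(x)
}
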