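#' Fold-class labels
#'
#' Per-residue labels used throughout the package. Four labels are
#' trainable: \code{NONE} (not part of a polysaccharide-degrading
#' domain), \code{BETA_HELIX} (right-handed beta-helix),
#' \code{BETA_PROPELLER} (n-bladed beta-propeller) and
#' \code{TRIPLE_HELIX}. Integer codes 0--3 and one-letter codes
#' N/B/P/T are stable. A curation-only extension adds the folds
#' screened for during structure-based curation (TIM barrel,
#' alpha/alpha toroid, alpha/beta hydrolase, flavodoxin-like); these
#' never appear in training labels.
#'
#' @format `fold_labels()` returns a character vector of the four
#'   trainable label names in code order; `curation_folds()` returns
#'   the extended set.
#' @name fold-labels
NULL

.TRAINABLE_LABELS <- c("NONE", "BETA_HELIX", "BETA_PROPELLER", "TRIPLE_HELIX")
.LABEL_CHARS <- c(NONE = "N", BETA_HELIX = "B", BETA_PROPELLER = "P",
                  TRIPLE_HELIX = "T")
.CURATION_ONLY <- c("TIM_BARREL", "TOROID", "ALPHA_BETA_HYDROLASE",
                    "FLAVODOXIN_LIKE")

#' @rdname fold-labels
#' @export
fold_labels <- function() .TRAINABLE_LABELS

#' @rdname fold-labels
#' @export
curation_folds <- function() c(.TRAINABLE_LABELS, .CURATION_ONLY)

#' @rdname fold-labels
#' @param label character vector of trainable label names
#' @return `fold_code()`: stable integer codes (NONE = 0L).
#' @export
fold_code <- function(label) {
  idx <- match(label, .TRAINABLE_LABELS)
  if (anyNA(idx)) {
    stop("unknown trainable fold label: ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' @rdname fold-labels
#' @param code integer codes in 0..3
#' @export
fold_from_code <- function(code) {
  if (any(code < 0L | code > 3L)) stop("fold code out of range 0..3")
  .TRAINABLE_LABELS[code + 1L]
}

# one-letter <-> label-name conversion for label strings (N/B/P/T)
labels_to_string <- function(labels) {
  ch <- .LABEL_CHARS[labels]
  if (anyNA(ch)) {
    stop("non-trainable label in label vector: ",
         paste(unique(labels[is.na(ch)]), collapse = ", "))
  }
  paste(ch, collapse = "")
}

string_to_labels <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, .LABEL_CHARS)
  if (anyNA(idx)) {
    stop("unknown label code '", paste(unique(ch[is.na(idx)]), collapse = "','"),
         "' in label string (allowed: N, B, P, T)")
  }
  names(.LABEL_CHARS)[idx]
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_ALPHABET <- c(.AA20, "X")

#' Amino-acid alphabet accepted by the package
#'
#' The 20 canonical residues plus X (unknown). Sequences are
#' case-normalised to upper case on input; any other letter is
#' rejected.
#' @return character vector of allowed one-letter residue codes
#' @export
aa_alphabet <- function() .AA_ALPHABET
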