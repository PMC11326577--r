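#' Fold repeat grammars
#'
#' A grammar describes the synthetic sequence signal of one fold
#' class: a repeat period, a per-position residue distribution over
#' the repeat unit, and domain-length bounds. The three default
#' positive grammars echo real fold periodicities while remaining
#' synthetic: period-22 coils with a polar/small residue bias for the
#' right-handed beta-helix, period-45 blade-like repeats with an
#' aromatic bias for the n-bladed beta-propeller, and Gly-X-Y
#' period-3 repeats for the triple helix. A fourth, never-labelled
#' heptad grammar supplies repeat-bearing hard negatives (structural
#' proteins without catalytic activity).
#'
#' @param fold a trainable fold label (or "NONE" for the decoy
#'   grammar)
#' @param repeat_unit_length repeat period in residues
#' @param residue_bias either a probability vector named by the 20
#'   canonical residues (shared by all repeat positions) or a matrix
#'   with `repeat_unit_length` rows giving a per-position
#'   distribution
#' @param min_domain_length,max_domain_length inclusive bounds on the
#'   injected domain length (min >= 30)
#' @return object of class `fold_grammar`
#' @export
fold_grammar <- function(fold, repeat_unit_length, residue_bias,
                         min_domain_length = 60L,
                         max_domain_length = 150L) {
  if (min_domain_length < 30L) stop("min_domain_length must be >= 30")
  if (max_domain_length < min_domain_length)
    stop("max_domain_length must be >= min_domain_length")
  if (is.matrix(residue_bias)) {
    if (nrow(residue_bias) != repeat_unit_length)
      stop("residue_bias matrix must have repeat_unit_length rows")
    bias <- residue_bias
  } else {
    bias <- matrix(residue_bias, nrow = repeat_unit_length,
                   ncol = length(residue_bias), byrow = TRUE,
                   dimnames = list(NULL, names(residue_bias)))
  }
  if (!setequal(colnames(bias), .AA20))
    stop("residue_bias must be named by the 20 canonical residues")
  bias <- bias[, .AA20, drop = FALSE]
  bias <- bias / rowSums(bias)
  structure(list(fold = fold,
                 repeat_unit_length = as.integer(repeat_unit_length),
                 residue_bias = bias,
                 min_domain_length = as.integer(min_domain_length),
                 max_domain_length = as.integer(max_domain_length)),
            class = "fold_grammar")
}

# distribution with `mass` spread over `letters`, remainder uniform
.biased_dist <- function(letters, mass = 0.9) {
  p <- stats::setNames(rep((1 - mass) / (20 - length(letters)), 20), .AA20)
  p[letters] <- mass / length(letters)
  p
}

#' @rdname fold_grammar
#' @export
default_grammars <- function() {
  gxy <- rbind(.biased_dist("G", 0.95),
               .biased_dist(c("P", "A", "Q", "K"), 0.9),
               .biased_dist(c("P", "A", "Q", "K"), 0.9))
  colnames(gxy) <- .AA20
  list(
    BETA_HELIX = fold_grammar("BETA_HELIX", 22L,
                              .biased_dist(c("S", "T", "N", "D", "G", "V"))),
    BETA_PROPELLER = fold_grammar("BETA_PROPELLER", 45L,
                                  .biased_dist(c("W", "Y", "F", "R", "L", "A"))),
    TRIPLE_HELIX = fold_grammar("TRIPLE_HELIX", 3L, gxy)
  )
}

#' @rdname fold_grammar
#' @export
decoy_grammar <- function() {
  fold_grammar("NONE", 7L, .biased_dist(c("L", "E", "K", "I", "M")))
}

#' Synthetic dataset configuration
#'
#' Study conditions for the desk-scale experiments: per-fold positive
#' counts, negative count (a fraction of which are hard negatives
#' carrying decoy repeats), the sequence-length range (whose minimum
#' mirrors the 200-aa curation filter), the three positive grammars,
#' the background residue composition, and the seed. Defaults
#' produce 800 proteins (3 x 100 positives + 500 negatives, positive
#' fraction 0.375, echoing the roughly 1:2 positive:negative balance
#' of curated training sets), lengths 200--500 aa.
#'
#' @param n_positive_per_fold positives per fold class
#' @param n_negative negatives (all-NONE labels)
#' @param length_range integer c(min, max), min >= 200
#' @param seed integer seed; generation is byte-identical for a
#'   fixed seed
#' @param grammars list of the 3 positive [fold_grammar()]s
#' @param negative_composition background residue distribution
#' @param hard_negative_fraction fraction of negatives carrying a
#'   decoy repeat region
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_positive_per_fold = 100L,
                             n_negative = 500L,
                             length_range = c(200L, 500L),
                             seed = 7L,
                             grammars = default_grammars(),
                             negative_composition =
                               stats::setNames(rep(0.05, 20), .AA20),
                             hard_negative_fraction = 0.3) {
  if (length_range[1] < 200L)
    stop("length_range minimum must be >= 200 (mirrors the curation filter)")
  if (length_range[2] < length_range[1]) stop("invalid length_range")
  if (length(grammars) != 3L)
    stop("exactly three positive grammars required")
  folds <- vapply(grammars, `[[`, character(1), "fold")
  if (!setequal(folds, setdiff(.TRAINABLE_LABELS, "NONE")))
    stop("grammars must cover the three positive fold classes")
  negative_composition <- negative_composition[.AA20]
  negative_composition <- negative_composition / sum(negative_composition)
  structure(list(n_positive_per_fold = as.integer(n_positive_per_fold),
                 n_negative = as.integer(n_negative),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed),
                 grammars = grammars,
                 negative_composition = negative_composition,
                 hard_negative_fraction = hard_negative_fraction),
            class = "synthetic_config")
}

# samples one tiled repeat region of `len` residues from a grammar
sample_repeat_region <- function(grammar, len) {
  pos <- (seq_len(len) - 1L) %% grammar$repeat_unit_length + 1L
  vapply(pos, function(p)
    sample(.AA20, 1L, prob = grammar$residue_bias[p, ]), character(1))
}

#' Inject a fold domain into a background sequence
#'
#' Replaces residues in `[start, start + domain_length)` (0-based,
#' half-open) of the record by grammar-sampled repeats and labels
#' them with the grammar's fold; all other residues are labelled
#' NONE. Uses the current RNG state; seed at the call site for
#' reproducibility.
#'
#' @param record background [protein_record()]
#' @param grammar a [fold_grammar()]
#' @param start 0-based domain start
#' @param domain_length domain length (> 0; the domain must fit)
#' @return a [labeled_sequence()]
#' @export
inject_domain <- function(record, grammar, start, domain_length) {
  n <- record_length(record)
  if (domain_length <= 0L) stop("domain length must be positive")
  if (start < 0L || start + domain_length > n)
    stop("domain [", start, ", ", start + domain_length,
         ") overruns sequence of length ", n,
         " (record '", record$id, "')")
  ch <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  idx <- seq.int(start + 1L, start + domain_length)
  ch[idx] <- sample_repeat_region(grammar, domain_length)
  labels <- rep("NONE", n)
  if (grammar$fold != "NONE") labels[idx] <- grammar$fold
  labeled_sequence(protein_record(record$id, paste(ch, collapse = ""),
                                  record$annotation),
                   labels)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `3 * n_positive_per_fold` positive proteins — each a
#' background sequence with exactly one contiguous fold-specific
#' domain — and `n_negative` negatives with all-NONE labels, a
#' `hard_negative_fraction` of which carry an unlabelled decoy
#' repeat region. Byte-identical for a fixed `cfg$seed`. The binary
#' truth of a protein is whether any residue carries a non-NONE
#' label.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `labeled` (list of [labeled_sequence()]) and
#'   `truth` (named logical vector)
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  labeled <- list()
  draw_background <- function(id, ann) {
    len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    protein_record(id, paste(sample(.AA20, len, replace = TRUE,
                                    prob = cfg$negative_composition),
                             collapse = ""), ann)
  }
  for (g in cfg$grammars) {
    short <- .LABEL_CHARS[g$fold]
    for (i in seq_len(cfg$n_positive_per_fold)) {
      rec <- draw_background(sprintf("pos_%s_%03d", short, i),
                             "synthetic depolymerase")
      dlen <- sample(g$min_domain_length:g$max_domain_length, 1L)
      start <- sample(0:(record_length(rec) - dlen), 1L)
      labeled[[length(labeled) + 1L]] <- inject_domain(rec, g, start, dlen)
    }
  }
  n_hard <- round(cfg$n_negative * cfg$hard_negative_fraction)
  decoy <- decoy_grammar()
  for (i in seq_len(cfg$n_negative)) {
    hard <- i <= n_hard
    rec <- draw_background(sprintf("neg_%03d", i),
                           if (hard) "synthetic structural protein"
                           else "synthetic hypothetical protein")
    if (hard) {
      dlen <- sample(decoy$min_domain_length:decoy$max_domain_length, 1L)
      start <- sample(0:(record_length(rec) - dlen), 1L)
      labeled[[length(labeled) + 1L]] <- inject_domain(rec, decoy, start, dlen)
    } else {
      labeled[[length(labeled) + 1L]] <-
        labeled_sequence(rec, rep("NONE", record_length(rec)))
    }
  }
  truth <- vapply(labeled, function(x) any(x$labels != "NONE"), logical(1))
  names(truth) <- vapply(labeled, function(x) x$record$id, character(1))
  list(labeled = labeled, truth = truth)
}
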