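#' Protein units and domain segments
#'
#' A protein unit is a stable structural segment between secondary
#' structure and domain, produced by an external structure-based
#' decomposition and consumed here from its interval table. A domain
#' segment is a contiguous residue interval carrying a non-NONE fold
#' class. All residue coordinates are 0-based half-open; the
#' human-readable report uses 1-based inclusive coordinates.
#'
#' @param start,end 0-based half-open interval, `end > start`
#' @param unit_id integer unit index
#' @return a `protein_unit` / `domain_segment`
#' @export
protein_unit <- function(start, end, unit_id = NA_integer_) {
  if (end <= start || start < 0) stop("invalid unit interval [", start,
                                      ", ", end, ")")
  structure(list(start = as.integer(start), end = as.integer(end),
                 unit_id = as.integer(unit_id)),
            class = "protein_unit")
}

#' @rdname protein_unit
#' @param fold trainable fold label, not NONE
#' @export
domain_segment <- function(start, end, fold) {
  if (end <= start || start < 0)
    stop("invalid segment interval [", start, ", ", end, ")")
  if (!fold %in% .TRAINABLE_LABELS || fold == "NONE")
    stop("segment fold must be a positive trainable label")
  structure(list(start = as.integer(start), end = as.integer(end),
                 fold = fold),
            class = "domain_segment")
}

# validates sortedness / non-overlap of unit or segment lists
check_intervals <- function(xs, what = "segments") {
  if (length(xs) < 2L) return(invisible(xs))
  for (i in 2:length(xs)) {
    if (xs[[i]]$start < xs[[i - 1L]]$end)
      stop(what, " overlap or are unsorted at interval ", i)
  }
  invisible(xs)
}

#' Project a structural match onto protein units
#'
#' Training-label construction: a unit is assigned the match's fold
#' iff at least 50% of its residues fall inside the match interval;
#' consecutive contiguous labelled units are merged into one segment.
#' Enlarging the match interval never removes a labelled unit.
#'
#' @param units sorted non-overlapping list of [protein_unit()]
#' @param match a [structure_hit()] with a trainable positive
#'   `target_fold` and a valid query interval
#' @return list of [domain_segment()] (possibly empty)
#' @export
project_match_to_units <- function(units, match) {
  stopifnot(inherits(match, "structure_hit"))
  if (length(units) == 0L) return(list())
  check_intervals(units, "units")
  if (is.na(match$query_start) || is.na(match$query_end) ||
      match$query_end <= match$query_start)
    stop("structural match has no usable query interval")
  labeled <- vapply(units, function(u) {
    ov <- max(0L, min(u$end, match$query_end) -
                  max(u$start, match$query_start))
    ov / (u$end - u$start) >= 0.5
  }, logical(1))
  segments <- list()
  cur <- NULL
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (labeled[i]) {
      if (!is.null(cur) && cur$end == u$start) {
        cur$end <- u$end
      } else {
        if (!is.null(cur))
          segments[[length(segments) + 1L]] <-
            domain_segment(cur$start, cur$end, match$target_fold)
        cur <- list(start = u$start, end = u$end)
      }
    }
  }
  if (!is.null(cur))
    segments[[length(segments) + 1L]] <-
      domain_segment(cur$start, cur$end, match$target_fold)
  segments
}

# majority vote over a centred window clipped at the ends; ties keep
# the original centre label
.smooth_labels <- function(labels, window) {
  if (window <= 1L) return(labels)
  n <- length(labels)
  h <- (window - 1L) %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    w <- labels[max(1L, i - h):min(n, i + h)]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1L) top
    else if (labels[i] %in% top) labels[i] else top[1L]
  }
  out
}

#' Extract domain segments from per-residue labels
#'
#' Inference-time delineation: majority-vote smoothing over an odd
#' window is applied first, then every maximal run of one non-NONE
#' label at least `min_segment_length` residues long becomes a
#' segment. Defaults: minimum segment 30 residues (mirroring the
#' 30-aligned-position homology floor), window 9.
#'
#' @param labels per-residue trainable fold labels
#' @param min_segment_length shortest reported segment
#' @param smoothing_window odd smoothing window (1 = no smoothing)
#' @return sorted non-overlapping list of [domain_segment()]
#' @export
labels_to_segments <- function(labels, min_segment_length = 30L,
                               smoothing_window = 9L) {
  if (smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd")
  bad <- setdiff(unique(labels), .TRAINABLE_LABELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  labels <- .smooth_labels(labels, smoothing_window)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != "NONE" & r$lengths >= min_segment_length
  mapply(function(s, e, f) domain_segment(s, e, f),
         starts[keep], ends[keep], r$values[keep],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Paint domain segments back onto a label vector
#'
#' Exact inverse of run extraction:
#' `labels_to_segments(segments_to_labels(S, n), 1, 1)` reproduces
#' `S`. Overlapping or out-of-range segments are errors.
#'
#' @param segments list of [domain_segment()]
#' @param protein_length total residue count
#' @return per-residue label vector of length `protein_length`
#' @export
segments_to_labels <- function(segments, protein_length) {
  labels <- rep("NONE", protein_length)
  if (length(segments) == 0L) return(labels)
  ord <- order(vapply(segments, `[[`, integer(1), "start"))
  segments <- segments[ord]
  check_intervals(segments, "segments")
  last <- segments[[length(segments)]]
  if (last$end > protein_length)
    stop("segment [", last$start, ", ", last$end,
         ") exceeds protein length ", protein_length)
  for (s in segments)
    labels[(s$start + 1L):s$end] <- s$fold
  labels
}

#' Residue-set Jaccard between two label vectors
#'
#' Overlap of the positive (non-NONE) residue sets — the delineation
#' recovery measure against injected truth.
#'
#' @param a,b equal-length label vectors
#' @return Jaccard index in \[0, 1\] (1 when both are all-NONE)
#' @export
label_jaccard <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  pa <- a != "NONE"; pb <- b != "NONE"
  u <- sum(pa | pb)
  if (u == 0L) return(1)
  sum(pa & pb) / u
}

#' Read and write interval tables
#'
#' Units TSV dialect: `record_id<TAB>unit_id<TAB>start<TAB>end`;
#' segments TSV dialect: `record_id<TAB>start<TAB>end<TAB>fold`
#' (0-based half-open, no header).
#'
#' @param path TSV path
#' @return `read_units()`: named list (by record id) of
#'   [protein_unit()] lists
#' @export
read_units <- function(path) {
  if (!file.exists(path)) stop("units file not found: ", path)
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("record_id", "unit_id",
                                        "start", "end"),
                          colClasses = c("character", "integer",
                                         "integer", "integer"))
  lapply(split(df, df$record_id), function(d) {
    d <- d[order(d$start), ]
    check_intervals(
      mapply(protein_unit, d$start, d$end, d$unit_id, SIMPLIFY = FALSE),
      "units")
  })
}

#' @rdname read_units
#' @param segments_by_record named list (by record id) of
#'   [domain_segment()] lists
#' @export
write_segments <- function(segments_by_record, path) {
  lines <- character(0)
  for (id in names(segments_by_record))
    for (s in segments_by_record[[id]])
      lines <- c(lines, paste(id, s$start, s$end, s$fold, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
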