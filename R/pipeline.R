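#' Pipeline commands
#'
#' The five workflow commands behind the command-line interface
#' (`inst/scripts/depolyscan`). Each command is a plain function over
#' the package's building blocks, never mutates its inputs, and
#' writes a `manifest.json` into its output directory recording the
#' command, package and R versions, seed, configuration, and MD5
#' hashes of all inputs and outputs, so that a deterministic run can
#' be reproduced bit-for-bit from the manifest alone.
#'
#' @name pipeline-commands
NULL

#' @describeIn pipeline-commands Generate a synthetic labelled
#'   dataset and write `sequences.fasta`, `labels.tsv` and
#'   `truth.tsv`.
#' @param outdir output directory (created)
#' @param cfg a [synthetic_config()]
#' @param seed optional seed overriding `cfg$seed`
#' @export
cmd_simulate <- function(outdir, cfg = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(cfg)
  fasta <- file.path(outdir, "sequences.fasta")
  labels <- file.path(outdir, "labels.tsv")
  truth <- file.path(outdir, "truth.tsv")
  write_fasta(lapply(ds$labeled, `[[`, "record"), fasta)
  write_labels(ds$labeled, labels)
  write_truth(ds$truth, truth)
  write_manifest(outdir, "simulate", character(0),
                 c(fasta, labels, truth),
                 list(n_positive_per_fold = cfg$n_positive_per_fold,
                      n_negative = cfg$n_negative,
                      length_range = cfg$length_range,
                      hard_negative_fraction = cfg$hard_negative_fraction),
                 cfg$seed)
  invisible(outdir)
}

#' @describeIn pipeline-commands Sequentially train the stacked model
#'   on a FASTA + label file, using a cluster-atomic 70/20/10
#'   group-shuffle split (identity clusters unless a cluster map is
#'   given); writes the model archive plus `splits.tsv`.
#' @param fasta,labels training data paths
#' @param fractions token / binary / eval fractions summing to 1
#' @param cluster_map optional named cluster id per record id
#' @param backbone,token_cfg,head_cfg model configuration
#' @export
cmd_train <- function(fasta, labels, outdir,
                      fractions = c(0.7, 0.2, 0.1),
                      cluster_map = NULL,
                      backbone = backbone_spec(),
                      token_cfg = token_classifier_config(),
                      head_cfg = binary_head_config(),
                      seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  records <- read_fasta(fasta)
  labeled <- read_labels(labels, records)
  ids <- vapply(records, `[[`, character(1), "id")
  if (is.null(cluster_map)) cluster_map <- stats::setNames(ids, ids)
  splits <- group_shuffle_split(ids, cluster_map, fractions, seed)
  model <- depo_train(labeled, backbone, token_cfg, head_cfg,
                      splits = splits)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  archive <- file.path(outdir, "model")
  save_depo_model(model, archive)
  split_path <- file.path(outdir, "splits.tsv")
  split_df <- do.call(rbind, lapply(names(splits), function(k)
    if (length(splits[[k]])) data.frame(record_id = splits[[k]], split = k)
    else NULL))
  utils::write.table(split_df, split_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(outdir, "train", c(fasta, labels),
                 c(list.files(archive, recursive = TRUE,
                              full.names = TRUE), split_path),
                 list(fractions = fractions,
                      backbone = backbone$kind,
                      token_seed = token_cfg$seed,
                      head_seed = head_cfg$seed),
                 seed)
  invisible(outdir)
}

#' @describeIn pipeline-commands Predict depolymerases for a FASTA
#'   file with a saved model archive; writes `predictions.tsv` and
#'   delineated `segments.tsv`. Records shorter than 200 aa are
#'   processed with a warning — the length filter belongs to
#'   curation and training-set assembly, not prediction.
#' @param model_dir model archive directory from [save_depo_model()]
#' @param min_segment_length,smoothing_window delineation parameters
#'   (see [labels_to_segments()])
#' @export
cmd_predict <- function(model_dir, fasta, outdir,
                        min_segment_length = 30L,
                        smoothing_window = 9L) {
  model <- load_depo_model(model_dir)
  records <- read_fasta(fasta)
  short <- vapply(records, record_length, integer(1)) < 200L
  if (any(short))
    warning(sum(short), " record(s) shorter than 200 aa; predictions ",
            "for them fall outside the length range the model targets")
  results <- predict(model, records)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pred_path <- file.path(outdir, "predictions.tsv")
  seg_path <- file.path(outdir, "segments.tsv")
  write_predictions(results, pred_path)
  segs <- lapply(results, function(r)
    labels_to_segments(r$token_labels, min_segment_length,
                       smoothing_window))
  names(segs) <- vapply(results, `[[`, character(1), "record_id")
  write_segments(segs, seg_path)
  write_manifest(outdir, "predict",
                 c(list.files(model_dir, recursive = TRUE,
                              full.names = TRUE), fasta),
                 c(pred_path, seg_path),
                 list(min_segment_length = min_segment_length,
                      smoothing_window = smoothing_window,
                      threshold = model$head$cfg$threshold),
                 NA_integer_)
  invisible(outdir)
}

#' @describeIn pipeline-commands Benchmark predictions (and any
#'   number of competitor score files, `record_id<TAB>score`) against
#'   a truth table; writes `report.tsv` and `report.json`.
#' @param predictions path to a predictions TSV from `cmd_predict`
#' @param truth path to a truth TSV
#' @param tool_files named character vector of competitor score
#'   files
#' @param threshold decision threshold
#' @export
cmd_evaluate <- function(predictions, truth, outdir,
                         tool_files = character(0), threshold = 0.5) {
  pred <- read_predictions(predictions)
  truth_map <- read_truth(truth)
  tool_scores <- list(
    depolyscan = stats::setNames(pred$depo_probability, pred$record_id))
  for (tool in names(tool_files)) {
    df <- utils::read.delim(tool_files[[tool]], header = FALSE,
                            colClasses = c("character", "numeric"),
                            col.names = c("record_id", "score"))
    tool_scores[[tool]] <- stats::setNames(df$score, df$record_id)
  }
  report <- benchmark_report(tool_scores, truth_map, threshold)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(outdir, "report.tsv")
  js <- file.path(outdir, "report.json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  full <- lapply(attr(report, "reports"), function(r)
    list(precision = r$precision, recall = r$recall,
         specificity = r$specificity, accuracy = r$accuracy,
         f1 = r$f1, mcc = r$mcc, pr_auc = r$pr_auc,
         counts = list(tp = r$counts$tp, fp = r$counts$fp,
                       tn = r$counts$tn, fn = r$counts$fn),
         threshold = r$threshold,
         zero_denominator_flags = r$zero_denominator_flags))
  jsonlite::write_json(full, js, auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "evaluate",
                 c(predictions, truth, unname(tool_files)),
                 c(tsv, js), list(threshold = threshold), NA_integer_)
  invisible(report)
}

#' @describeIn pipeline-commands Run the curation funnel on a FASTA
#'   plus the external search/clustering outputs; writes
#'   `curated.fasta`, per-record `provenance.tsv` (the stage that
#'   removed each record, or "curated"), per-stage `funnel.tsv`
#'   counts, and the fold assignment `folds.tsv`.
#' @param homology_hits,structure_hits,clstr paths to the hit tables
#'   and CD-HIT `.clstr` file
#' @param ap_clusters path to the embedding-cluster table
#'   (`record_id<TAB>cluster_id`, no header); defaults to every
#'   record in its own cluster when NULL
#' @param fold_map named character vector or fold-map YAML path
#' @param allowed_annotations character vector of annotations, or a
#'   path to a one-per-line text file
#' @export
cmd_curate <- function(fasta, homology_hits, structure_hits, clstr,
                       fold_map, allowed_annotations, outdir,
                       ap_clusters = NULL,
                       cfg = curation_config()) {
  records <- read_fasta(fasta)
  hh <- parse_homology_hits(homology_hits)
  sh <- parse_structure_hits(structure_hits, fold_map)
  clusters <- parse_cdhit_clstr(clstr)
  ids <- vapply(records, `[[`, character(1), "id")
  ap <- if (is.null(ap_clusters)) stats::setNames(ids, ids) else {
    df <- utils::read.delim(ap_clusters, header = FALSE,
                            colClasses = "character",
                            col.names = c("record_id", "cluster_id"))
    stats::setNames(df$cluster_id, df$record_id)
  }
  if (length(allowed_annotations) == 1L &&
      file.exists(allowed_annotations))
    allowed_annotations <- readLines(allowed_annotations)
  out <- curate_records(records, hh, sh, clusters, ap,
                        allowed_annotations, cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cur_path <- file.path(outdir, "curated.fasta")
  write_fasta(out$curated, cur_path)
  ids <- vapply(records, `[[`, character(1), "id")
  stage_names <- names(out$survivors)
  fate <- vapply(ids, function(id) {
    for (k in seq_along(stage_names)[-1]) {
      if (!id %in% out$survivors[[k]])
        return(paste0("removed_by:", stage_names[k]))
    }
    "curated"
  }, character(1))
  prov_path <- file.path(outdir, "provenance.tsv")
  writeLines(paste(ids, fate, sep = "\t"), prov_path)
  funnel_path <- file.path(outdir, "funnel.tsv")
  utils::write.table(out$funnel, funnel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  folds_path <- file.path(outdir, "folds.tsv")
  writeLines(paste(names(out$folds), out$folds, sep = "\t"), folds_path)
  inputs <- c(fasta, homology_hits, structure_hits, clstr)
  write_manifest(outdir, "curate", inputs,
                 c(cur_path, prov_path, funnel_path, folds_path),
                 unclass(cfg), NA_integer_)
  invisible(out)
}
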