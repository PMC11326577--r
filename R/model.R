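#' Fit the stacked depolymerase model
#'
#' The central fitting function. Training is sequential: the
#' per-residue token classifier is fitted first
#' ([train_token_classifier()]); its parameters are then frozen and
#' the convolutional binary head is fitted on its per-residue output
#' ([train_binary_head()]). By default both stages see all of
#' `labeled`; pass `splits` (record-id vectors, e.g. from
#' [group_shuffle_split()]) to train each stage on its own portion as
#' in a 70/20/10 protocol.
#'
#' @param labeled list of [labeled_sequence()] training data
#' @param backbone a [backbone_spec()]
#' @param token_cfg a [token_classifier_config()]
#' @param head_cfg a [binary_head_config()]
#' @param splits optional list with `token_train` and `binary_train`
#'   record-id vectors
#' @param truth optional named logical binary truth overriding
#'   label-derived truth for the head stage
#' @return object of class `depo_model`
#' @seealso [predict.depo_model()], [save_depo_model()]
#' @export
depo_train <- function(labeled, backbone = backbone_spec(),
                       token_cfg = token_classifier_config(),
                       head_cfg = binary_head_config(),
                       splits = NULL, truth = NULL) {
  ids <- vapply(labeled, function(x) x$record$id, character(1))
  pick <- function(which) {
    if (is.null(splits)) return(labeled)
    sel <- splits[[which]]
    missing <- setdiff(sel, ids)
    if (length(missing))
      stop("split '", which, "' names unknown record(s): ",
           paste(missing, collapse = ", "))
    labeled[match(sel, ids)]
  }
  token_train <- pick("token_train")
  binary_train <- pick("binary_train")
  token_model <- train_token_classifier(token_train, backbone, token_cfg)
  frozen <- object_fingerprint(token_model$W)
  head <- train_binary_head(binary_train, token_model, head_cfg, truth)
  stopifnot(identical(frozen, object_fingerprint(token_model$W)))
  structure(list(
    token_model = token_model,
    head = head,
    backbone = backbone,
    meta = list(
      n_token_train = length(token_train),
      n_binary_train = length(binary_train),
      token_seed = token_cfg$seed,
      head_seed = head_cfg$seed,
      split_fingerprint = object_fingerprint(
        list(sort(vapply(token_train, function(x) x$record$id, character(1))),
             sort(vapply(binary_train, function(x) x$record$id, character(1))))),
      token_weights_fingerprint = frozen)),
    class = "depo_model")
}

#' Predict depolymerases
#'
#' Runs the stacked model on protein records: per-residue 4-class
#' probabilities from the token stage, then one depolymerase
#' probability per sequence from the binary head. A record longer
#' than the backbone context produces a per-record failure entry
#' (collected in the `"failed"` attribute, with a warning); the
#' remaining records are still processed.
#'
#' @param object a fitted `depo_model`
#' @param records list of [protein_record()]
#' @param ... unused
#' @return list of [prediction_result()], one per successful record,
#'   with attribute `"failed"` (data frame id/reason) when any record
#'   could not be processed
#' @export
predict.depo_model <- function(object, records, ...) {
  check_records(records)
  results <- list()
  failed <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  for (rec in records) {
    res <- tryCatch({
      P <- token_probabilities(object$token_model, rec$sequence)
      p <- binary_probability(object$head, P)
      prediction_result(rec$id, P, p, object$head$cfg$threshold)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- rbind(failed, data.frame(id = rec$id,
                                         reason = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (nrow(failed)) {
    warning(nrow(failed), " record(s) could not be processed: ",
            paste(failed$id, collapse = ", "))
    attr(results, "failed") <- failed
  }
  results
}

#' @export
print.depo_model <- function(x, ...) {
  cat("Stacked depolymerase classifier\n")
  cat(sprintf("  backbone: %s (%s, dim %d)\n", x$backbone$kind,
              x$backbone$model_name, x$backbone$embedding_dim))
  cat(sprintf("  token stage: %d training sequences, final loss %.4f\n",
              x$meta$n_token_train,
              utils::tail(x$token_model$loss_history, 1)))
  cat(sprintf("  binary head: %d training sequences, final loss %.4f, threshold %.2f\n",
              x$meta$n_binary_train, utils::tail(x$head$loss_history, 1),
              x$head$cfg$threshold))
  invisible(x)
}

#' @export
summary.depo_model <- function(object, ...) {
  cat("Stacked depolymerase classifier\n\n")
  print(object$token_model)
  cat(sprintf("<binary_head> conv kernels %s, channels %s, dense %d -> 1, input %s\n",
              paste(object$head$cfg$conv_kernels, collapse = "/"),
              paste(object$head$cfg$conv_channels, collapse = "/"),
              object$head$cfg$dense_hidden, object$head$cfg$input_mode))
  cat(sprintf("\ntoken training loss: %s\n",
              paste(sprintf("%.4f", object$token_model$loss_history),
                    collapse = " ")))
  cat(sprintf("head training loss:  %s\n",
              paste(sprintf("%.4f", object$head$loss_history),
                    collapse = " ")))
  invisible(object)
}

#' Save and reload a fitted model
#'
#' The archive is a directory holding a config YAML, plain-text
#' weight matrices written at full precision, and a metadata JSON
#' (seeds, data fingerprints). `load_depo_model()` reproduces the
#' model bit-exactly: predictions before saving and after reloading
#' are identical. A corrupted archive fails with an error naming the
#' missing file.
#'
#' @param model a `depo_model`
#' @param dir archive directory (created if absent)
#' @return `save_depo_model()`: invisibly, `dir`;
#'   `load_depo_model()`: the restored `depo_model`
#' @export
save_depo_model <- function(model, dir) {
  stopifnot(inherits(model, "depo_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wdir <- file.path(dir, "weights")
  dir.create(wdir, showWarnings = FALSE)
  cfg <- list(backbone = unclass(model$backbone),
              token_cfg = unclass(model$token_model$cfg),
              head_cfg = unclass(model$head$cfg))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  write_matrix_txt(model$token_model$W, file.path(wdir, "token_W.txt"))
  for (nm in names(model$head$params))
    write_matrix_txt(model$head$params[[nm]],
                     file.path(wdir, paste0("head_", nm, ".txt")))
  jsonlite::write_json(
    c(model$meta,
      list(token_loss_history = model$token_model$loss_history,
           head_loss_history = model$head$loss_history)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_depo_model
#' @export
load_depo_model <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path))
    stop("model archive is missing config.yaml: ", dir)
  cfg <- yaml::read_yaml(cfg_path)
  backbone <- do.call(backbone_spec, cfg$backbone[
    setdiff(names(cfg$backbone), character(0))])
  token_cfg <- do.call(token_classifier_config,
                       cfg$token_cfg[setdiff(names(cfg$token_cfg), "n_labels")])
  head_cfg <- do.call(binary_head_config, cfg$head_cfg)
  if (backbone$kind == "pretrained_plm")
    stop("archive was fitted with a pretrained language-model backbone; ",
         "its weights are not available in this installation")
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    stop("model archive is missing metadata.json: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  wdir <- file.path(dir, "weights")
  token_model <- structure(
    list(W = read_matrix_txt(file.path(wdir, "token_W.txt")),
         backbone = backbone, cfg = token_cfg,
         loss_history = meta$token_loss_history),
    class = "token_model")
  pnames <- c("W1", "b1", "W2", "b2", "Wd1", "bd1", "Wd2", "bd2")
  params <- lapply(pnames, function(nm)
    read_matrix_txt(file.path(wdir, paste0("head_", nm, ".txt"))))
  names(params) <- pnames
  for (nm in c("b1", "b2", "bd1")) params[[nm]] <- drop(params[[nm]])
  params$bd2 <- as.numeric(params$bd2)
  head <- structure(list(params = params, cfg = head_cfg,
                         loss_history = meta$head_loss_history),
                    class = "binary_head")
  structure(list(token_model = token_model, head = head,
                 backbone = backbone,
                 meta = meta[setdiff(names(meta),
                                     c("token_loss_history",
                                       "head_loss_history"))]),
            class = "depo_model")
}
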