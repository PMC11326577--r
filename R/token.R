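#' Token-classifier configuration
#'
#' Hyperparameters of the per-residue 4-class classifier (a softmax
#' head over backbone features, trained with Adam). The number of
#' labels is fixed at 4.
#'
#' @param learning_rate Adam step size
#' @param batch_size sequences per minibatch
#' @param epochs passes over the training set
#' @param dropout input-feature dropout rate during training
#' @param seed training seed
#' @return object of class `token_classifier_config`
#' @export
token_classifier_config <- function(learning_rate = 0.05,
                                    batch_size = 16L,
                                    epochs = 40L,
                                    dropout = 0,
                                    seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1)
  structure(list(n_labels = 4L, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed)),
            class = "token_classifier_config")
}

# one Adam step; state carries first/second moments and step count
.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the per-residue token classifier
#'
#' Fits the 4-class per-residue classifier on labelled sequences:
#' every residue of every training protein is one training token,
#' featurised by the backbone, and a softmax layer is optimised by
#' minibatch Adam under cross-entropy. Deterministic for a fixed
#' `cfg$seed`. The returned model maps any sequence to an L x 4
#' matrix of per-residue class probabilities.
#'
#' @param token_train non-empty list of [labeled_sequence()]
#' @param backbone a [backbone_spec()]
#' @param cfg a [token_classifier_config()]
#' @return object of class `token_model` with elements `W`
#'   ((dim + 1) x 4 weights incl. intercept row), `backbone`, `cfg`,
#'   `loss_history` (mean cross-entropy per epoch)
#' @export
train_token_classifier <- function(token_train, backbone = backbone_spec(),
                                   cfg = token_classifier_config()) {
  if (length(token_train) == 0L)
    stop("token training set is empty")
  ok <- vapply(token_train, inherits, logical(1), what = "labeled_sequence")
  if (!all(ok)) stop("token_train must be a list of labeled_sequence")
  feats <- lapply(token_train, function(x)
    embed_sequence(backbone, x$record$sequence))
  ys <- lapply(token_train, function(x) fold_code(x$labels) + 1L)
  D <- backbone$embedding_dim
  W <- matrix(0, D + 1L, 4L)
  state <- .adam_init(list(W = W))
  set.seed(cfg$seed)
  n <- length(token_train)
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    total_loss <- 0; total_tok <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      X <- do.call(rbind, feats[b])
      if (cfg$dropout > 0) {
        mask <- matrix(stats::rbinom(length(X), 1L, 1 - cfg$dropout),
                       nrow(X)) / (1 - cfg$dropout)
        X <- X * mask
      }
      X1 <- cbind(X, 1)
      y <- unlist(ys[b], use.names = FALSE)
      P <- .softmax_rows(X1 %*% W)
      m <- nrow(X1)
      total_loss <- total_loss - sum(log(pmax(P[cbind(seq_len(m), y)], 1e-12)))
      total_tok <- total_tok + m
      Yh <- matrix(0, m, 4L); Yh[cbind(seq_len(m), y)] <- 1
      G <- crossprod(X1, P - Yh) / m
      upd <- .adam_step(list(W = W), list(W = G), state, cfg$learning_rate)
      W <- upd$params$W; state <- upd$state
    }
    loss_history[epoch] <- total_loss / total_tok
  }
  structure(list(W = W, backbone = backbone, cfg = cfg,
                 loss_history = loss_history),
            class = "token_model")
}

#' Per-residue class probabilities
#'
#' @param model a `token_model`
#' @param sequence amino-acid string
#' @return L x 4 matrix of class probabilities (columns in
#'   [fold_labels()] order), rows summing to 1
#' @export
token_probabilities <- function(model, sequence) {
  stopifnot(inherits(model, "token_model"))
  X1 <- cbind(embed_sequence(model$backbone, sequence), 1)
  P <- .softmax_rows(X1 %*% model$W)
  colnames(P) <- .TRAINABLE_LABELS
  P
}

#' @export
print.token_model <- function(x, ...) {
  cat(sprintf("<token_model> %s backbone (dim %d), %d epochs, final loss %.4f\n",
              x$backbone$kind, x$backbone$embedding_dim,
              length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}
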