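#' Binary-head configuration
#'
#' The sequence-level classifier stacked on the token output: two 1-D
#' convolutional layers scan the per-residue class signal for
#' fold-domain patterns, global max- and average-pooling collapse the
#' variable length, and two dense layers emit one depolymerase
#' probability. Input is either the per-residue class-probability
#' vectors (default; strictly generalises hard labels) or the one-hot
#' encoding of the per-residue argmax labels.
#'
#' @param conv_kernels odd kernel sizes of the two conv layers
#' @param conv_channels output channels of the two conv layers
#' @param dense_hidden width of the first dense layer (the second is
#'   the single-probability output)
#' @param input_mode "class_probabilities" or "one_hot_labels"
#' @param threshold binary decision threshold (ties positive)
#' @param learning_rate,batch_size,epochs,dropout,seed training
#'   hyperparameters (dropout applies to the hidden dense layer)
#' @return object of class `binary_head_config`
#' @export
binary_head_config <- function(conv_kernels = c(7L, 5L),
                               conv_channels = c(16L, 16L),
                               dense_hidden = 16L,
                               input_mode = c("class_probabilities",
                                              "one_hot_labels"),
                               threshold = 0.5,
                               learning_rate = 0.003,
                               batch_size = 16L,
                               epochs = 30L,
                               dropout = 0.1,
                               seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (length(conv_kernels) != 2L || length(conv_channels) != 2L)
    stop("exactly two convolutional layers are required")
  if (any(conv_kernels %% 2L == 0L))
    stop("conv kernel sizes must be odd")
  stopifnot(threshold >= 0, threshold <= 1, dense_hidden >= 1,
            learning_rate > 0, epochs >= 1, dropout >= 0, dropout < 1)
  structure(list(conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 dense_hidden = as.integer(dense_hidden),
                 input_mode = input_mode, threshold = threshold,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed)),
            class = "binary_head_config")
}

# ---- 1-D convolution with 'same' zero padding, im2col formulation ----

.im2col <- function(X, k) {
  n <- nrow(X); pad <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, ncol(X)), X, matrix(0, pad, ncol(X)))
  do.call(cbind, lapply(0:(k - 1L), function(o)
    Xp[(1L + o):(n + o), , drop = FALSE]))
}

.col2im <- function(dCols, k, n, cin) {
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, n + 2L * pad, cin)
  for (o in 0:(k - 1L)) {
    block <- dCols[, (o * cin + 1L):((o + 1L) * cin), drop = FALSE]
    rows <- (1L + o):(n + o)
    dXp[rows, ] <- dXp[rows, ] + block
  }
  dXp[(pad + 1L):(pad + n), , drop = FALSE]
}

.head_init <- function(cfg, cin = 4L) {
  k <- cfg$conv_kernels; c <- cfg$conv_channels; h <- cfg$dense_hidden
  rn <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(W1 = rn(k[1] * cin, c[1], k[1] * cin), b1 = numeric(c[1]),
       W2 = rn(k[2] * c[1], c[2], k[2] * c[1]), b2 = numeric(c[2]),
       Wd1 = rn(2L * c[2], h, 2L * c[2]), bd1 = numeric(h),
       Wd2 = rn(h, 1L, h), bd2 = 0)
}

# forward pass; keeps intermediates for backprop when training=TRUE
.head_forward <- function(params, X, cfg, training = FALSE,
                          drop_mask = NULL) {
  k <- cfg$conv_kernels
  C1 <- .im2col(X, k[1])
  Z1 <- sweep(C1 %*% params$W1, 2, params$b1, "+")
  A1 <- pmax(Z1, 0)
  C2 <- .im2col(A1, k[2])
  Z2 <- sweep(C2 %*% params$W2, 2, params$b2, "+")
  A2 <- pmax(Z2, 0)
  imax <- max.col(t(A2), ties.method = "first")
  mx <- A2[cbind(imax, seq_len(ncol(A2)))]
  av <- colMeans(A2)
  f <- c(mx, av)
  zd1 <- drop(f %*% params$Wd1) + params$bd1
  rd1 <- pmax(zd1, 0)
  if (training && !is.null(drop_mask)) rd1 <- rd1 * drop_mask
  z <- drop(rd1 %*% params$Wd2) + params$bd2
  p <- 1 / (1 + exp(-z))
  if (!training) return(p)
  list(p = p, X = X, C1 = C1, Z1 = Z1, A1 = A1, C2 = C2, Z2 = Z2,
       A2 = A2, imax = imax, f = f, zd1 = zd1, rd1 = rd1)
}

# backprop of BCE loss for one sequence; returns gradient list
.head_backward <- function(params, fw, y, cfg, drop_mask = NULL) {
  k <- cfg$conv_kernels
  n <- nrow(fw$X); c2 <- ncol(fw$A2)
  dz <- fw$p - y
  dWd2 <- matrix(fw$rd1 * dz, ncol = 1L)
  dbd2 <- dz
  drd1 <- drop(params$Wd2) * dz
  if (!is.null(drop_mask)) drd1 <- drd1 * drop_mask
  dzd1 <- drd1 * (fw$zd1 > 0)
  dWd1 <- outer(fw$f, dzd1)
  dbd1 <- dzd1
  df <- drop(params$Wd1 %*% dzd1)
  dmx <- df[seq_len(c2)]; dav <- df[c2 + seq_len(c2)]
  dA2 <- matrix(rep(dav / n, each = n), n, c2)
  dA2[cbind(fw$imax, seq_len(c2))] <-
    dA2[cbind(fw$imax, seq_len(c2))] + dmx
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$C2, dZ2)
  db2 <- colSums(dZ2)
  dA1 <- .col2im(dZ2 %*% t(params$W2), k[2], n, ncol(fw$A1))
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$C1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2)
}

# token output -> head input per the configured mode
.head_input <- function(P, cfg) {
  if (cfg$input_mode == "class_probabilities") return(unname(P))
  H <- matrix(0, nrow(P), ncol(P))
  H[cbind(seq_len(nrow(P)), max.col(P, ties.method = "first"))] <- 1
  H
}

#' Train the binary head on frozen token output
#'
#' Second stage of the sequential training: the token model is
#' frozen, its per-residue output on the binary-training sequences is
#' computed once, and the convolutional head is optimised with Adam
#' under binary cross-entropy. The token-model parameters are never
#' touched. Deterministic for a fixed `cfg$seed`.
#'
#' @param binary_train list of [labeled_sequence()] (labels are used
#'   only to derive the binary truth: any non-NONE residue)
#' @param token_model a frozen [train_token_classifier()] model
#' @param cfg a [binary_head_config()]
#' @param truth optional named logical overriding the label-derived
#'   truth
#' @return object of class `binary_head` with the trained parameters
#'   and the per-epoch mean loss
#' @export
train_binary_head <- function(binary_train, token_model,
                              cfg = binary_head_config(), truth = NULL) {
  stopifnot(inherits(token_model, "token_model"))
  if (length(binary_train) == 0L) stop("binary training set is empty")
  ids <- vapply(binary_train, function(x) x$record$id, character(1))
  y <- if (is.null(truth))
    vapply(binary_train, function(x) any(x$labels != "NONE"), logical(1))
  else as.logical(truth[ids])
  if (length(unique(y)) < 2L)
    stop("binary training set must contain both classes")
  inputs <- lapply(binary_train, function(x)
    .head_input(token_probabilities(token_model, x$record$sequence), cfg))
  set.seed(cfg$seed)
  params <- .head_init(cfg)
  state <- .adam_init(params)
  n <- length(inputs)
  loss_history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      grads <- NULL
      for (i in b) {
        mask <- if (cfg$dropout > 0)
          stats::rbinom(cfg$dense_hidden, 1L, 1 - cfg$dropout) /
            (1 - cfg$dropout) else NULL
        fw <- .head_forward(params, inputs[[i]], cfg, training = TRUE,
                            drop_mask = mask)
        ep_loss <- ep_loss - (if (y[i]) log(max(fw$p, 1e-12))
                              else log(max(1 - fw$p, 1e-12)))
        g <- .head_backward(params, fw, as.numeric(y[i]), cfg, mask)
        grads <- if (is.null(grads)) g
        else Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, length(b))
      upd <- .adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
    loss_history[epoch] <- ep_loss / n
  }
  structure(list(params = params, cfg = cfg, loss_history = loss_history),
            class = "binary_head")
}

#' Sequence-level depolymerase probability from token output
#'
#' @param head a trained `binary_head`
#' @param token_probs L x 4 per-residue class-probability matrix
#' @return probability in \[0, 1\]
#' @export
binary_probability <- function(head, token_probs) {
  stopifnot(inherits(head, "binary_head"))
  .head_forward(head$params, .head_input(token_probs, head$cfg), head$cfg)
}
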