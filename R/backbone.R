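#' Embedding backbones
#'
#' The token classifier runs over per-residue feature matrices
#' produced by a backbone. Two kinds exist:
#' \describe{
#'   \item{mock}{A deterministic hash-derived encoding of each
#'     residue and its k-mer context (default half-window 6, i.e.
#'     13-mers). Feature `(i, d)` is the sum over window offsets of a
#'     fixed pseudo-random projection value for (residue, offset,
#'     dimension), so the embedding is a linear function of the
#'     windowed one-hot encoding: reproducible everywhere, no model
#'     download, and local — a substitution at position i only
#'     changes rows within the half-window around i.}
#'   \item{pretrained_plm}{One of the three published protein
#'     language-model configurations. Weights are not bundled;
#'     selecting this kind without a usable weights directory fails
#'     loudly at load time — the mock is never silently
#'     substituted.}
#' }
#'
#' @param kind "mock" or "pretrained_plm"
#' @param model_name for pretrained_plm, one of
#'   `esm2_t6_8M_UR50D`, `esm2_t12_35M_UR50D`, `esm2_t30_150M_UR50D`
#'   (default the 12-layer configuration, the balance of memory and
#'   efficiency)
#' @param embedding_dim feature dimension (mock default 280, enough
#'   to carry the full windowed residue encoding without loss)
#' @param half_window mock k-mer context half-width
#' @param max_context longest accepted sequence; longer input is an
#'   error reporting the limit
#' @return object of class `backbone_spec`
#' @export
backbone_spec <- function(kind = c("mock", "pretrained_plm"),
                          model_name = "esm2_t12_35M_UR50D",
                          embedding_dim = 280L,
                          half_window = 6L,
                          max_context = if (kind[1] == "mock") 100000L else 1022L) {
  kind <- match.arg(kind)
  published <- c("esm2_t6_8M_UR50D", "esm2_t12_35M_UR50D",
                 "esm2_t30_150M_UR50D")
  if (kind == "pretrained_plm" && !model_name %in% published)
    stop("model_name must be one of the published configurations: ",
         paste(published, collapse = ", "))
  structure(list(kind = kind, model_name = model_name,
                 embedding_dim = as.integer(embedding_dim),
                 half_window = as.integer(half_window),
                 max_context = as.integer(max_context)),
            class = "backbone_spec")
}

# deterministic pseudo-random stream (Lehmer LCG), independent of
# R's RNG so embedding never perturbs user-visible random state
.lcg_stream <- function(n, seed) {
  m <- 2147483647
  x <- (as.numeric(seed) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% m
    out[i] <- x / m
  }
  out
}

.backbone_cache <- new.env(parent = emptyenv())

# fixed projection tensor V[residue (21), offset (2h+1), dim D]
.mock_projection <- function(embedding_dim, half_window) {
  key <- paste0("d", embedding_dim, "h", half_window)
  if (!is.null(.backbone_cache[[key]])) return(.backbone_cache[[key]])
  w <- 2L * half_window + 1L
  vals <- .lcg_stream(21L * w * embedding_dim, 987654321)
  V <- array(2 * vals - 1, dim = c(21L, w, embedding_dim))
  .backbone_cache[[key]] <- V
  V
}

#' Embed a sequence into per-residue features
#'
#' @param backbone a [backbone_spec()]
#' @param sequence amino-acid string over the package alphabet
#' @return numeric matrix, sequence length x `embedding_dim`
#' @export
embed_sequence <- function(backbone, sequence) {
  stopifnot(inherits(backbone, "backbone_spec"))
  n <- nchar(sequence)
  if (n > backbone$max_context)
    stop("sequence length ", n, " exceeds the backbone context limit of ",
         backbone$max_context)
  if (backbone$kind == "pretrained_plm")
    stop("pretrained protein language-model weights for '",
         backbone$model_name, "' are not available in this installation; ",
         "provide a weights directory or use the mock backbone explicitly")
  idx <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]],
               .AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains letters outside the alphabet")
  h <- backbone$half_window
  V <- .mock_projection(backbone$embedding_dim, h)
  E <- matrix(0, n, backbone$embedding_dim)
  for (o in -h:h) {
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    E[ok, ] <- E[ok, ] + V[idx[src[ok]], o + h + 1L, ]
  }
  E / sqrt(2 * h + 1)
}
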