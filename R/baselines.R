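# Baseline models --------------------------------------------------------
#
# (1) A plain feed-forward regressor on functional features (3 hidden
# ReLU layers), (2) its additive-metadata personalized variant, where a
# linear projection of the metadata vector is added elementwise to the
# output of the second hidden layer, and (3) full fine-tuning of the
# encoder (the adapter-free forward pass lives in hyperadapter.R).

#' FFNN configuration
#'
#' Exactly three equal hidden layers with ReLU activations; width 30 is
#' the functional-feature default, 256 suits wider embedding inputs.
#'
#' @param input_width Input feature dimension.
#' @param hidden Hidden width (applied to all three layers).
#' @param meta_dim Metadata dimension for the personalized variant
#'   (`NULL` for the plain model).
#' @return A list of class `ffnn_config`.
#' @export
ffnn_config <- function(input_width, hidden = 30L, meta_dim = NULL) {
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden),
                 meta_dim = if (is.null(meta_dim)) NULL else as.integer(meta_dim)),
            class = "ffnn_config")
}

#' Initialize FFNN parameters
#'
#' @param cfg An [ffnn_config()].
#' @param seed Integer seed.
#' @return Nested parameter list; includes a `proj` block when
#'   `cfg$meta_dim` is set (zero-initialized so the personalized model
#'   starts identical to the plain one).
#' @export
init_ffnn_params <- function(cfg, seed = 1L) {
  with_local_seed(substream_seed(seed, "ffnn-init"), {
    hw <- cfg$hidden
    p <- list(
      W1 = rand_mat(cfg$input_width, hw, sqrt(2 / cfg$input_width)),
      b1 = rep(0, hw),
      W2 = rand_mat(hw, hw, sqrt(2 / hw)), b2 = rep(0, hw),
      W3 = rand_mat(hw, hw, sqrt(2 / hw)), b3 = rep(0, hw),
      w = rep(0, hw), b = 0
    )
    if (!is.null(cfg$meta_dim)) {
      p$proj <- list(W = matrix(0, cfg$meta_dim, hw), b = rep(0, hw))
    }
    p
  })
}

ffnn_forward_cached <- function(X, params, M = NULL) {
  a1 <- affine_forward(X, params$W1, params$b1); h1 <- relu(a1)
  a2 <- affine_forward(h1, params$W2, params$b2); h2 <- relu(a2)
  if (!is.null(M)) {
    padd <- affine_forward(M, params$proj$W, params$proj$b)
    h2p <- h2 + padd
  } else h2p <- h2
  a3 <- affine_forward(h2p, params$W3, params$b3); h3 <- relu(a3)
  pred <- drop(h3 %*% params$w) + params$b
  list(pred = pred, X = X, M = M, a1 = a1, h1 = h1, a2 = a2, h2p = h2p,
       a3 = a3, h3 = h3)
}

ffnn_backward <- function(dpred, cache, params) {
  g <- list()
  g$w <- drop(crossprod(cache$h3, dpred)); g$b <- sum(dpred)
  dh3 <- tcrossprod(dpred, params$w)
  da3 <- dh3 * (cache$a3 > 0)
  b3 <- affine_backward(da3, cache$h2p, params$W3)
  g$W3 <- b3$dW; g$b3 <- b3$db
  dh2p <- b3$dX
  if (!is.null(cache$M)) {
    g$proj <- list(W = crossprod(cache$M, dh2p), b = colSums(dh2p))
  }
  da2 <- dh2p * (cache$a2 > 0)
  b2 <- affine_backward(da2, cache$h1, params$W2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- b2$dX * (cache$a1 > 0)
  b1 <- affine_backward(da1, cache$X, params$W1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

#' Feed-forward network forward pass
#'
#' `affine -> ReLU` three times, then an affine head to a scalar.
#'
#' @param x Feature vector or `n x input_width` matrix.
#' @param params Parameters from [init_ffnn_params()].
#' @return Scalar prediction (or length-n vector).
#' @export
ffnn_forward <- function(x, params) {
  X <- if (is.null(dim(x))) matrix(x, 1) else x
  stop_if_not(ncol(X) == nrow(params$W1), "input width mismatch")
  p <- ffnn_forward_cached(X, params)$pred
  if (is.null(dim(x))) drop(p) else p
}

#' Personalized FFNN forward pass
#'
#' The metadata vector is linearly projected and added elementwise to the
#' second hidden layer's output; with the projection zeroed this equals
#' [ffnn_forward()] exactly.
#'
#' @param x Feature vector or matrix.
#' @param m_S Metadata vector, or a matrix with one row per row of `x`.
#' @param params Parameters including the `proj` block.
#' @return Scalar prediction (or vector).
#' @export
personalized_ffnn_forward <- function(x, m_S, params) {
  X <- if (is.null(dim(x))) matrix(x, 1) else x
  M <- if (is.null(dim(m_S))) matrix(m_S, nrow(X), length(m_S), byrow = TRUE) else m_S
  stop_if_not(!is.null(params$proj), "params lack a metadata projection block")
  stop_if_not(ncol(M) == nrow(params$proj$W), "metadata width mismatch")
  p <- ffnn_forward_cached(X, params, M)$pred
  if (is.null(dim(x))) drop(p) else p
}
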