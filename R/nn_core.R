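# Neural-network primitives ---------------------------------------------
#
# Small, dependency-free matrix implementations of the layers used by the
# encoder and baselines, each with an explicit backward pass. Rows are
# positions (time frames), columns are hidden channels; a batch of B
# sequences of length T is a (B*T) x h matrix in sample-major row order.
# All forward functions return caches sufficient for their backward pass;
# backward functions return the input gradient plus parameter gradients.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

relu <- function(x) pmax(x, 0)

# Row-wise layer normalization across the h channels of each position.
ln_forward <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, xhat = xhat, inv = inv, g = g)
}

ln_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

affine_forward <- function(X, W, b) sweep(X %*% W, 2, b, "+")

affine_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# Multi-head self-attention over each sample's T rows.
attn_forward <- function(Hn, B, Tlen, p, n_heads) {
  h <- ncol(Hn)
  dk <- h / n_heads
  Q <- affine_forward(Hn, p$Wq, p$bq)
  K <- affine_forward(Hn, p$Wk, p$bk)
  V <- affine_forward(Hn, p$Wv, p$bv)
  O <- matrix(0, nrow(Hn), h)
  A <- array(0, dim = c(Tlen, Tlen, n_heads, B))
  scale <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    r <- ((b - 1) * Tlen + 1):(b * Tlen)
    for (a in seq_len(n_heads)) {
      ca <- ((a - 1) * dk + 1):(a * dk)
      S <- tcrossprod(Q[r, ca, drop = FALSE], K[r, ca, drop = FALSE]) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      Ab <- E / rowSums(E)
      A[, , a, b] <- Ab
      O[r, ca] <- Ab %*% V[r, ca, drop = FALSE]
    }
  }
  out <- affine_forward(O, p$Wo, p$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A, Hn = Hn)
}

attn_backward <- function(dOut, cache, B, Tlen, p, n_heads, param_grads = TRUE) {
  h <- ncol(cache$Hn)
  dk <- h / n_heads
  scale <- 1 / sqrt(dk)
  ob <- affine_backward(dOut, cache$O, p$Wo)
  dO <- ob$dX
  dQ <- matrix(0, nrow(dOut), h)
  dK <- matrix(0, nrow(dOut), h)
  dV <- matrix(0, nrow(dOut), h)
  for (b in seq_len(B)) {
    r <- ((b - 1) * Tlen + 1):(b * Tlen)
    for (a in seq_len(n_heads)) {
      ca <- ((a - 1) * dk + 1):(a * dk)
      Ab <- cache$A[, , a, b]
      if (Tlen == 1L) Ab <- matrix(Ab, 1, 1)
      dOb <- dO[r, ca, drop = FALSE]
      Vb <- cache$V[r, ca, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[r, ca] <- crossprod(Ab, dOb)
      dS <- Ab * (dA - rowSums(dA * Ab))
      dQ[r, ca] <- dS %*% cache$K[r, ca, drop = FALSE] * scale
      dK[r, ca] <- crossprod(dS, cache$Q[r, ca, drop = FALSE]) * scale
    }
  }
  dHn <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- NULL
  if (param_grads) {
    grads <- list(
      Wq = crossprod(cache$Hn, dQ), bq = colSums(dQ),
      Wk = crossprod(cache$Hn, dK), bk = colSums(dK),
      Wv = crossprod(cache$Hn, dV), bv = colSums(dV),
      Wo = ob$dW, bo = ob$db
    )
  }
  list(dHn = dHn, grads = grads)
}

# Sinusoidal positional encodings (T x h).
positional_encoding <- function(Tlen, h) {
  pos <- seq_len(Tlen) - 1
  i <- seq_len(h) - 1
  angle <- outer(pos, 10000^(-2 * (i %/% 2) / h))
  pe <- matrix(0, Tlen, h)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

rand_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}
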