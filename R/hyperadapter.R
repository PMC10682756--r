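# Hypernetwork-generated adapters in a transformer encoder --------------
#
# The core method: a (desk-scale) pre-LN transformer encoder over frame
# sequences, with bottleneck adapter modules inserted after the attention
# and feedforward blocks (before the additive skip connections). All
# adapter parameters -- down/up projections and the adapter layer-norm's
# beta/gamma -- are generated per subject by shared hypernetworks
# conditioned on the subject metadata vector m_S concatenated with learned
# layer and position embeddings.

#' Encoder / adapter / hypernetwork configuration
#'
#' Desk-scale defaults (4 layers, width 64 in full-size spirit but default
#' here to a small encoder suitable for CPU experiments). The adapter
#' bottleneck `d` must be smaller than the hidden width `h`; adapter
#' positions are fixed to `j = 0` (after attention) and `j = 1` (after
#' feedforward).
#'
#' @param input_dim Width of each input frame.
#' @param h Hidden width of the encoder.
#' @param L Number of encoder layers.
#' @param n_heads Attention heads (`h` must be divisible by `n_heads`).
#' @param ff_mult Feedforward expansion factor.
#' @param d Adapter bottleneck width (`d < h`).
#' @param s Subject-embedding dimension.
#' @param e Layer/position embedding dimension.
#' @param hI_hidden Hidden width of the conditioning projection `h_I`.
#' @param ln_eps Layer-norm epsilon (makes LN of constant vectors
#'   well-defined; required for the identity-at-initialization property).
#' @param n_frames Frames per recording in sequence mode.
#' @param use_positions Add sinusoidal positional encodings to the input
#'   projection (disable to make the encoder permutation-equivariant).
#' @param generator_bias Whether the weight generators `h_D`, `h_U`,
#'   `h_LN` carry their own additive bias terms.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(input_dim = 8L, h = 16L, L = 2L, n_heads = 2L,
                           ff_mult = 2L, d = 4L, s = 8L, e = 4L,
                           hI_hidden = 16L, ln_eps = 1e-5, n_frames = 4L,
                           use_positions = TRUE, generator_bias = TRUE) {
  stop_if_not(d < h, "adapter bottleneck d must be smaller than h")
  stop_if_not(s >= 1, "subject embedding dimension must be >= 1")
  stop_if_not(h %% n_heads == 0, "h must be divisible by n_heads")
  structure(list(input_dim = as.integer(input_dim), h = as.integer(h),
                 L = as.integer(L), n_heads = as.integer(n_heads),
                 ff_mult = as.integer(ff_mult), d = as.integer(d),
                 s = as.integer(s), e = as.integer(e),
                 hI_hidden = as.integer(hI_hidden), ln_eps = ln_eps,
                 n_frames = as.integer(n_frames),
                 use_positions = isTRUE(use_positions),
                 generator_bias = isTRUE(generator_bias)),
            class = "encoder_config")
}

#' Initialize encoder (backbone) parameters
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed.
#' @return Nested list of parameter arrays (input projection, per-layer
#'   attention/feedforward/layer-norm weights, final layer norm,
#'   regression head).
#' @export
init_encoder_params <- function(cfg, seed = 1L) {
  with_local_seed(substream_seed(seed, "encoder-init"), {
    h <- cfg$h
    hf <- cfg$h * cfg$ff_mult
    layer <- function() list(
      ln1 = list(g = rep(1, h), b = rep(0, h)),
      attn = list(Wq = rand_mat(h, h), bq = rep(0, h),
                  Wk = rand_mat(h, h), bk = rep(0, h),
                  Wv = rand_mat(h, h), bv = rep(0, h),
                  Wo = rand_mat(h, h), bo = rep(0, h)),
      ln2 = list(g = rep(1, h), b = rep(0, h)),
      ff = list(W1 = rand_mat(h, hf), b1 = rep(0, hf),
                W2 = rand_mat(hf, h), b2 = rep(0, h))
    )
    list(
      in_proj = list(W = rand_mat(cfg$input_dim, h), b = rep(0, h)),
      layers = lapply(seq_len(cfg$L), function(i) layer()),
      ln_f = list(g = rep(1, h), b = rep(0, h)),
      head = list(w = rep(0, h), b = 0)
    )
  })
}

#' Initialize hypernetwork parameters
#'
#' Embedding tables and the conditioning projection `h_I` are
#' small-Gaussian; the output layers of the up-projection generator and
#' the LN generator are zero (with the LN generator's gamma bias at 1), so
#' that at initialization every generated adapter is an exact identity and
#' the personalized model reproduces the frozen backbone.
#'
#' @param cfg An [encoder_config()].
#' @param meta_dim Length of the metadata vector `m_S`.
#' @param seed Integer seed.
#' @return Nested list: `layer_emb` (L x e), `pos_emb` (2 x e), `hI`
#'   (two affine stages), and the three generators `gen_D`, `gen_U`,
#'   `gen_ln`.
#' @export
init_hypernet_params <- function(cfg, meta_dim, seed = 1L) {
  with_local_seed(substream_seed(seed, "hypernet-init"), {
    e <- cfg$e; s <- cfg$s; h <- cfg$h; d <- cfg$d
    cond_dim <- meta_dim + 2L * e
    list(
      layer_emb = rand_mat(cfg$L, e, 0.1),
      pos_emb = rand_mat(2L, e, 0.1),
      hI = list(W1 = rand_mat(cfg$hI_hidden, cond_dim, 1 / sqrt(cond_dim)),
                b1 = rep(0, cfg$hI_hidden),
                W2 = rand_mat(s, cfg$hI_hidden, 1 / sqrt(cfg$hI_hidden)),
                b2 = rep(0, s)),
      gen_D = list(W = rand_mat(d * (h + 1L), s, 0.05),
                   b = rep(0, d * (h + 1L))),
      gen_U = list(W = matrix(0, h * (d + 1L), s), b = rep(0, h * (d + 1L))),
      gen_ln = list(W = matrix(0, 2L * h, s),
                    b = c(rep(0, h), rep(1, h)))
    )
  })
}

#' Apply an adapter module
#'
#' Computes `A(x) = LN(U(GeLU(D(x)))) + x`, where `D`/`U` are the down-
#' and up-projections and LN normalizes across the `h` channels of each
#' position with parameters `gamma`, `beta`.
#'
#' @param x An `h`-vector or a `T x h` matrix of positions.
#' @param p Adapter parameters: `W_D` (d x h), `b_D`, `W_U` (h x d),
#'   `b_U`, `beta`, `gamma`.
#' @param eps Layer-norm epsilon.
#' @return Same shape as `x`.
#' @export
adapter_apply <- function(x, p, eps = 1e-5) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, 1) else x
  stop_if_not(all(is.finite(X)), "non-finite adapter input")
  out <- adapter_forward(X, p, eps)$out
  if (vec_in) drop(out) else out
}

adapter_forward <- function(Z, p, eps) {
  D <- sweep(Z %*% t(p$W_D), 2, p$b_D, "+")
  G <- gelu(D)
  U <- sweep(G %*% t(p$W_U), 2, p$b_U, "+")
  ln <- ln_forward(U, p$gamma, p$beta, eps)
  list(out = ln$Y + Z, Z = Z, D = D, G = G, ln = ln)
}

adapter_backward <- function(dOut, cache, p) {
  lb <- ln_backward(dOut, cache$ln)
  dU <- lb$dX
  dG <- dU %*% p$W_U
  dWU <- crossprod(dU, cache$G)
  dbU <- colSums(dU)
  dD <- dG * gelu_grad(cache$D)
  dWD <- crossprod(dD, cache$Z)
  dbD <- colSums(dD)
  dZ <- dD %*% p$W_D + dOut
  list(dZ = dZ,
       grads = list(W_D = dWD, b_D = dbD, W_U = dWU, b_U = dbU,
                    beta = lb$db, gamma = lb$dg))
}

#' Conditioning input for one adapter site
#'
#' Concatenates the metadata vector with the learned embedding of layer
#' `i` (0-based) and position `j` (0 = after attention, 1 = after
#' feedforward).
#'
#' @param m_S Metadata vector.
#' @param i Layer index in `0..L-1`.
#' @param j Position index in `{0, 1}`.
#' @param hp Hypernetwork parameters.
#' @return Numeric vector of length `length(m_S) + 2e`.
#' @export
conditioning_input <- function(m_S, i, j, hp) {
  stop_if_not(i >= 0 && i < nrow(hp$layer_emb), "layer index out of range")
  stop_if_not(j %in% c(0, 1), "position index must be 0 or 1")
  c(as.numeric(m_S), hp$layer_emb[i + 1L, ], hp$pos_emb[j + 1L, ])
}

#' Subject embedding from a conditioning input
#'
#' `I_S = Affine2(ReLU(Affine1(cond)))`.
#'
#' @param cond Conditioning vector from [conditioning_input()].
#' @param hp Hypernetwork parameters.
#' @return The `s`-dimensional subject embedding.
#' @export
subject_embedding <- function(cond, hp) {
  a1 <- drop(hp$hI$W1 %*% cond) + hp$hI$b1
  r <- relu(a1)
  drop(hp$hI$W2 %*% r) + hp$hI$b2
}

subject_embedding_cached <- function(cond, hp) {
  a1 <- drop(hp$hI$W1 %*% cond) + hp$hI$b1
  r <- relu(a1)
  I <- drop(hp$hI$W2 %*% r) + hp$hI$b2
  list(I = I, cond = cond, a1 = a1, r = r)
}

#' Generate adapter parameters from a subject embedding
#'
#' The generators are affine maps of `I_S`: `h_D` emits the down
#' projection's weights and biases (`d * (h + 1)` numbers), `h_U` the up
#' projection's (`h * (d + 1)`), and `h_LN` beta and gamma (`2h`). With
#' zero generator biases the map is linear in `I_S`.
#'
#' @param I_S Subject embedding (length `s`).
#' @param hp Hypernetwork parameters.
#' @param cfg An [encoder_config()].
#' @return List `W_D`, `b_D`, `W_U`, `b_U`, `beta`, `gamma`.
#' @export
generate_adapter_params <- function(I_S, hp, cfg) {
  stop_if_not(all(is.finite(I_S)), "non-finite subject embedding")
  stop_if_not(length(I_S) == ncol(hp$gen_D$W), "embedding/generator size mismatch")
  h <- cfg$h; d <- cfg$d
  vD <- drop(hp$gen_D$W %*% I_S) + hp$gen_D$b
  vU <- drop(hp$gen_U$W %*% I_S) + hp$gen_U$b
  vL <- drop(hp$gen_ln$W %*% I_S) + hp$gen_ln$b
  list(W_D = matrix(vD[seq_len(d * h)], d, h), b_D = vD[d * h + seq_len(d)],
       W_U = matrix(vU[seq_len(h * d)], h, d), b_U = vU[h * d + seq_len(h)],
       beta = vL[seq_len(h)], gamma = vL[h + seq_len(h)])
}

# Generate all 2L adapter parameter sets for one subject, with caches for
# the backward pass.
generate_subject_adapters <- function(m_S, hp, cfg) {
  lapply(seq_len(cfg$L) - 1L, function(i) {
    lapply(c(0L, 1L), function(j) {
      emb <- subject_embedding_cached(conditioning_input(m_S, i, j, hp), hp)
      list(params = generate_adapter_params(emb$I, hp, cfg), emb = emb,
           i = i, j = j)
    })
  })
}

# Accumulate hypernetwork gradients from one adapter site's parameter
# gradients. `acc` is an environment holding grad arrays.
hypernet_site_backward <- function(dP, site, hp, cfg, meta_dim, acc) {
  h <- cfg$h; d <- cfg$d
  dvD <- c(as.vector(dP$W_D), dP$b_D)
  dvU <- c(as.vector(dP$W_U), dP$b_U)
  dvL <- c(dP$beta, dP$gamma)
  I <- site$emb$I
  acc$gen_D$W <- acc$gen_D$W + tcrossprod(dvD, I)
  acc$gen_U$W <- acc$gen_U$W + tcrossprod(dvU, I)
  acc$gen_ln$W <- acc$gen_ln$W + tcrossprod(dvL, I)
  if (cfg$generator_bias) {
    acc$gen_D$b <- acc$gen_D$b + dvD
    acc$gen_U$b <- acc$gen_U$b + dvU
    acc$gen_ln$b <- acc$gen_ln$b + dvL
  }
  dI <- drop(crossprod(hp$gen_D$W, dvD) + crossprod(hp$gen_U$W, dvU) +
               crossprod(hp$gen_ln$W, dvL))
  emb <- site$emb
  acc$hI$W2 <- acc$hI$W2 + tcrossprod(dI, emb$r)
  acc$hI$b2 <- acc$hI$b2 + dI
  dr <- drop(crossprod(hp$hI$W2, dI))
  da1 <- dr * (emb$a1 > 0)
  acc$hI$W1 <- acc$hI$W1 + tcrossprod(da1, emb$cond)
  acc$hI$b1 <- acc$hI$b1 + da1
  dcond <- drop(crossprod(hp$hI$W1, da1))
  e <- cfg$e
  acc$layer_emb[site$i + 1L, ] <- acc$layer_emb[site$i + 1L, ] +
    dcond[meta_dim + seq_len(e)]
  acc$pos_emb[site$j + 1L, ] <- acc$pos_emb[site$j + 1L, ] +
    dcond[meta_dim + e + seq_len(e)]
  invisible(NULL)
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

new_hypernet_grad_acc <- function(hp) {
  acc <- new.env(parent = emptyenv())
  acc$layer_emb <- hp$layer_emb * 0
  acc$pos_emb <- hp$pos_emb * 0
  acc$hI <- zero_like(hp$hI)
  acc$gen_D <- zero_like(hp$gen_D)
  acc$gen_U <- zero_like(hp$gen_U)
  acc$gen_ln <- zero_like(hp$gen_ln)
  acc
}

# Encoder forward over a batch ------------------------------------------
#
# X: (B*T) x input_dim matrix, sample-major. adapter_groups: NULL (plain
# encoder) or a list of groups, each list(rows = row indices into X,
# adapters = generate_subject_adapters() result). Groups must partition
# the rows.
encoder_forward <- function(X, B, Tlen, params, cfg, adapter_groups = NULL,
                            keep_cache = FALSE) {
  h <- cfg$h
  H <- affine_forward(X, params$in_proj$W, params$in_proj$b)
  if (cfg$use_positions) {
    pe <- positional_encoding(Tlen, h)
    H <- H + pe[rep(seq_len(Tlen), times = B), , drop = FALSE]
  }
  caches <- vector("list", cfg$L)
  x <- H
  for (li in seq_len(cfg$L)) {
    lp <- params$layers[[li]]
    c1 <- ln_forward(x, lp$ln1$g, lp$ln1$b, cfg$ln_eps)
    at <- attn_forward(c1$Y, B, Tlen, lp$attn, cfg$n_heads)
    ao <- at$out
    ad0 <- NULL
    if (!is.null(adapter_groups)) {
      ad0 <- vector("list", length(adapter_groups))
      out0 <- ao
      for (gi in seq_along(adapter_groups)) {
        g <- adapter_groups[[gi]]
        fw <- adapter_forward(ao[g$rows, , drop = FALSE],
                              g$adapters[[li]][[1]]$params, cfg$ln_eps)
        out0[g$rows, ] <- fw$out
        ad0[[gi]] <- fw
      }
      ao_out <- out0
    } else ao_out <- ao
    x1 <- x + ao_out
    c2 <- ln_forward(x1, lp$ln2$g, lp$ln2$b, cfg$ln_eps)
    f1 <- affine_forward(c2$Y, lp$ff$W1, lp$ff$b1)
    fg <- gelu(f1)
    f2 <- affine_forward(fg, lp$ff$W2, lp$ff$b2)
    ad1 <- NULL
    if (!is.null(adapter_groups)) {
      ad1 <- vector("list", length(adapter_groups))
      out1 <- f2
      for (gi in seq_along(adapter_groups)) {
        g <- adapter_groups[[gi]]
        fw <- adapter_forward(f2[g$rows, , drop = FALSE],
                              g$adapters[[li]][[2]]$params, cfg$ln_eps)
        out1[g$rows, ] <- fw$out
        ad1[[gi]] <- fw
      }
      f2_out <- out1
    } else f2_out <- f2
    x2 <- x1 + f2_out
    if (keep_cache) {
      caches[[li]] <- list(x_in = x, c1 = c1, at = at, ad0 = ad0, x1 = x1,
                           c2 = c2, f1 = f1, fg = fg, c2Y = c2$Y, ad1 = ad1)
    }
    x <- x2
  }
  cf <- ln_forward(x, params$ln_f$g, params$ln_f$b, cfg$ln_eps)
  grp <- rep(seq_len(B), each = Tlen)
  pooled <- rowsum(cf$Y, grp) / Tlen
  pred <- as.numeric(pooled %*% params$head$w) + params$head$b
  res <- list(pred = pred)
  if (keep_cache) {
    res$cache <- list(caches = caches, cf = cf, pooled = pooled, grp = grp,
                      B = B, Tlen = Tlen, adapter_groups = adapter_groups)
  }
  res
}

# Backward through the encoder. dpred: length-B gradient of the loss wrt
# predictions. Returns head/backbone gradients (if backbone_grads) and
# per-group adapter parameter gradients summed over the group's rows.
encoder_backward <- function(dpred, fw, params, cfg, backbone_grads = TRUE) {
  cache <- fw$cache
  B <- cache$B; Tlen <- cache$Tlen
  grads <- list(head = list(w = drop(crossprod(cache$pooled, dpred)),
                            b = sum(dpred)))
  dpooled <- tcrossprod(dpred, params$head$w)
  dY <- dpooled[cache$grp, , drop = FALSE] / Tlen
  lf <- ln_backward(dY, cache$cf)
  if (backbone_grads) grads$ln_f <- list(g = lf$dg, b = lf$db)
  dx <- lf$dX
  n_groups <- if (is.null(cache$adapter_groups)) 0L else length(cache$adapter_groups)
  adapter_grads <- if (n_groups > 0)
    lapply(seq_len(n_groups), function(i) vector("list", cfg$L)) else NULL
  layer_grads <- if (backbone_grads) vector("list", cfg$L) else NULL

  for (li in rev(seq_len(cfg$L))) {
    lc <- cache$caches[[li]]
    lp <- params$layers[[li]]
    # x2 = x1 + f2_out
    df2_out <- dx
    dx1 <- dx
    if (n_groups > 0) {
      df2 <- df2_out
      for (gi in seq_len(n_groups)) {
        g <- cache$adapter_groups[[gi]]
        ab <- adapter_backward(df2_out[g$rows, , drop = FALSE], lc$ad1[[gi]],
                               g$adapters[[li]][[2]]$params)
        df2[g$rows, ] <- ab$dZ
        adapter_grads[[gi]][[li]] <- list(NULL, ab$grads)
      }
    } else df2 <- df2_out
    a2 <- affine_backward(df2, lc$fg, lp$ff$W2)
    df1 <- a2$dX * gelu_grad(lc$f1)
    a1 <- affine_backward(df1, lc$c2Y, lp$ff$W1)
    l2 <- ln_backward(a1$dX, lc$c2)
    dx1 <- dx1 + l2$dX
    # x1 = x_in + ao_out
    dao_out <- dx1
    dx0 <- dx1
    if (n_groups > 0) {
      dao <- dao_out
      for (gi in seq_len(n_groups)) {
        g <- cache$adapter_groups[[gi]]
        ab <- adapter_backward(dao_out[g$rows, , drop = FALSE], lc$ad0[[gi]],
                               g$adapters[[li]][[1]]$params)
        dao[g$rows, ] <- ab$dZ
        adapter_grads[[gi]][[li]][[1]] <- ab$grads
      }
    } else dao <- dao_out
    atb <- attn_backward(dao, lc$at, B, Tlen, lp$attn, cfg$n_heads,
                         param_grads = backbone_grads)
    l1 <- ln_backward(atb$dHn, lc$c1)
    dx0 <- dx0 + l1$dX
    if (backbone_grads) {
      layer_grads[[li]] <- list(
        ln1 = list(g = l1$dg, b = l1$db),
        attn = atb$grads,
        ln2 = list(g = l2$dg, b = l2$db),
        ff = list(W1 = a1$dW, b1 = a1$db, W2 = a2$dW, b2 = a2$db)
      )
    }
    dx <- dx0
  }
  if (backbone_grads) grads$layers <- layer_grads
  list(grads = grads, adapter_grads = adapter_grads)
}

#' Forward pass of the personalized (hyperformer) model
#'
#' Runs the encoder over one or more frame sequences with all adapter
#' parameters generated on the fly from the subject's metadata vector.
#'
#' @param frames A `T x F` matrix (one recording) or a `B x T x F` array.
#' @param m_S The subject's metadata vector.
#' @param backbone Encoder parameters from [init_encoder_params()].
#' @param hp Hypernetwork parameters from [init_hypernet_params()].
#' @param cfg An [encoder_config()].
#' @return Scalar prediction (or length-B vector).
#' @export
hyperformer_forward <- function(frames, m_S, backbone, hp, cfg) {
  X <- frames_to_matrix(frames, cfg)
  B <- nrow(X) / dim_t(frames, cfg)
  Tlen <- dim_t(frames, cfg)
  adapters <- generate_subject_adapters(m_S, hp, cfg)
  groups <- list(list(rows = seq_len(nrow(X)), adapters = adapters))
  encoder_forward(X, B, Tlen, backbone, cfg, adapter_groups = groups)$pred
}

#' Forward pass of the plain (non-personalized) encoder
#'
#' Identical to [hyperformer_forward()] with all adapters removed; this is
#' the fine-tuned-encoder baseline's forward pass.
#'
#' @inheritParams hyperformer_forward
#' @return Scalar prediction (or length-B vector).
#' @export
finetune_encoder_forward <- function(frames, backbone, cfg) {
  X <- frames_to_matrix(frames, cfg)
  Tlen <- dim_t(frames, cfg)
  encoder_forward(X, nrow(X) / Tlen, Tlen, backbone, cfg)$pred
}

dim_t <- function(frames, cfg) {
  d <- dim(frames)
  if (length(d) == 3) d[2] else d[1]
}

frames_to_matrix <- function(frames, cfg) {
  d <- dim(frames)
  if (length(d) == 2) {
    stop_if_not(d[2] == cfg$input_dim, "frame width does not match config")
    return(frames)
  }
  stop_if_not(length(d) == 3 && d[3] == cfg$input_dim,
              "frames must be T x F or B x T x F with F = input_dim")
  # sample-major rows: rows 1..T are sample 1
  X <- matrix(0, d[1] * d[2], d[3])
  for (b in seq_len(d[1])) {
    X[((b - 1) * d[2] + 1):(b * d[2]), ] <- frames[b, , ]
  }
  X
}

# Parameter bookkeeping --------------------------------------------------

#' Flatten a nested parameter list
#'
#' @param params Nested list of numeric arrays.
#' @param prefix Internal.
#' @return Named list of arrays with dot-separated path names.
#' @export
flatten_params <- function(params, prefix = "") {
  out <- list()
  nms <- names(params)
  if (is.null(nms)) nms <- as.character(seq_along(params))
  for (k in seq_along(params)) {
    p <- params[[k]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k]
    if (is.list(p)) out <- c(out, flatten_params(p, key))
    else out[[key]] <- p
  }
  out
}

#' Total number of scalar parameters in a nested parameter list
#'
#' @param params Nested list of numeric arrays.
#' @return Integer count.
#' @export
count_params <- function(params) {
  sum(vapply(flatten_params(params), length, integer(1)))
}

set_flat_param <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  idx <- function(node, part) {
    if (!is.null(names(node)) && part %in% names(node)) part
    else as.integer(part)
  }
  assign_rec <- function(node, parts, value) {
    i <- idx(node, parts[1])
    if (length(parts) == 1) {
      node[[i]] <- value
      return(node)
    }
    node[[i]] <- assign_rec(node[[i]], parts[-1], value)
    node
  }
  assign_rec(params, parts, value)
}
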