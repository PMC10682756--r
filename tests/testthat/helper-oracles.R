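# Independent straight-line / brute-force reimplementations used as
# oracles. These deliberately share no code with the package internals:
# scalar loops, explicit double sums, no shared helpers.

naive_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

naive_spearman <- function(x, y) {
  rx <- naive_midranks(x)
  ry <- naive_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

naive_gini <- function(v) {
  n <- length(v)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(v[i] - v[j])
  s / (2 * n^2 * mean(v))
}

naive_mae <- function(truth, pred) {
  s <- 0
  for (i in seq_along(truth)) s <- s + abs(truth[i] - pred[i])
  s / length(truth)
}

naive_gelu <- function(x) x * pnorm(x)

naive_layer_norm <- function(x, gamma, beta, eps) {
  mu <- sum(x) / length(x)
  v <- sum((x - mu)^2) / length(x)
  ((x - mu) / sqrt(v + eps)) * gamma + beta
}

naive_adapter <- function(x, p, eps) {
  d <- length(p$b_D); h <- length(x)
  z <- numeric(d)
  for (k in seq_len(d)) z[k] <- sum(p$W_D[k, ] * x) + p$b_D[k]
  z <- naive_gelu(z)
  u <- numeric(h)
  for (k in seq_len(h)) u[k] <- sum(p$W_U[k, ] * z) + p$b_U[k]
  naive_layer_norm(u, p$gamma, p$beta, eps) + x
}

naive_subject_embedding <- function(cond, hp) {
  k1 <- length(hp$hI$b1)
  a <- numeric(k1)
  for (i in seq_len(k1)) a[i] <- sum(hp$hI$W1[i, ] * cond) + hp$hI$b1[i]
  a[a < 0] <- 0
  s <- length(hp$hI$b2)
  out <- numeric(s)
  for (i in seq_len(s)) out[i] <- sum(hp$hI$W2[i, ] * a) + hp$hI$b2[i]
  out
}

naive_generate_params <- function(I, hp, h, d) {
  gen <- function(W, b) {
    out <- numeric(nrow(W))
    for (i in seq_len(nrow(W))) out[i] <- sum(W[i, ] * I) + b[i]
    out
  }
  vD <- gen(hp$gen_D$W, hp$gen_D$b)
  vU <- gen(hp$gen_U$W, hp$gen_U$b)
  vL <- gen(hp$gen_ln$W, hp$gen_ln$b)
  list(W_D = matrix(vD[1:(d * h)], d, h), b_D = vD[d * h + 1:d],
       W_U = matrix(vU[1:(h * d)], h, d), b_U = vU[h * d + 1:h],
       beta = vL[1:h], gamma = vL[h + 1:h])
}

# A from-scratch, per-sample, loop-based reimplementation of the full
# encoder forward pass (optionally with one set of adapter params per
# site), used to cross-check the batched implementation.
naive_encoder_forward <- function(frames, params, cfg, adapters = NULL) {
  Tlen <- nrow(frames); h <- cfg$h
  X <- matrix(0, Tlen, h)
  for (t in seq_len(Tlen)) {
    X[t, ] <- as.numeric(frames[t, ] %*% params$in_proj$W) + params$in_proj$b
  }
  if (cfg$use_positions) {
    for (t in seq_len(Tlen)) {
      for (k in seq_len(h)) {
        i0 <- k - 1
        ang <- (t - 1) / 10000^(2 * (i0 %/% 2) / h)
        X[t, k] <- X[t, k] + if (i0 %% 2 == 0) sin(ang) else cos(ang)
      }
    }
  }
  ln_rows <- function(M, g, b) {
    t(apply(M, 1, function(r) naive_layer_norm(r, g, b, cfg$ln_eps)))
  }
  nh <- cfg$n_heads; dk <- h / nh
  for (li in seq_len(cfg$L)) {
    lp <- params$layers[[li]]
    Hn <- ln_rows(X, lp$ln1$g, lp$ln1$b)
    Q <- sweep(Hn %*% lp$attn$Wq, 2, lp$attn$bq, "+")
    K <- sweep(Hn %*% lp$attn$Wk, 2, lp$attn$bk, "+")
    V <- sweep(Hn %*% lp$attn$Wv, 2, lp$attn$bv, "+")
    O <- matrix(0, Tlen, h)
    for (a in seq_len(nh)) {
      ca <- ((a - 1) * dk + 1):(a * dk)
      for (t in seq_len(Tlen)) {
        sc <- numeric(Tlen)
        for (u in seq_len(Tlen)) sc[u] <- sum(Q[t, ca] * K[u, ca]) / sqrt(dk)
        w <- exp(sc - max(sc)); w <- w / sum(w)
        for (u in seq_len(Tlen)) O[t, ca] <- O[t, ca] + w[u] * V[u, ca]
      }
    }
    AO <- sweep(O %*% lp$attn$Wo, 2, lp$attn$bo, "+")
    if (!is.null(adapters)) {
      AO <- t(apply(AO, 1, function(r)
        naive_adapter(r, adapters[[li]][[1]], cfg$ln_eps)))
    }
    X <- X + AO
    H2 <- ln_rows(X, lp$ln2$g, lp$ln2$b)
    F1 <- naive_gelu(sweep(H2 %*% lp$ff$W1, 2, lp$ff$b1, "+"))
    F2 <- sweep(F1 %*% lp$ff$W2, 2, lp$ff$b2, "+")
    if (!is.null(adapters)) {
      F2 <- t(apply(F2, 1, function(r)
        naive_adapter(r, adapters[[li]][[2]], cfg$ln_eps)))
    }
    X <- X + F2
  }
  Xf <- ln_rows(X, params$ln_f$g, params$ln_f$b)
  pooled <- colMeans(Xf)
  sum(pooled * params$head$w) + params$head$b
}

naive_ffnn <- function(x, params, m = NULL) {
  lin <- function(v, W, b) as.numeric(v %*% W) + b
  h1 <- pmax(lin(x, params$W1, params$b1), 0)
  h2 <- pmax(lin(h1, params$W2, params$b2), 0)
  if (!is.null(m)) h2 <- h2 + lin(m, params$proj$W, params$proj$b)
  h3 <- pmax(lin(h2, params$W3, params$b3), 0)
  sum(h3 * params$w) + params$b
}

# Small shared fixtures ---------------------------------------------------

tiny_cohort <- function(n = 2L, seed = 11L) {
  generate_cohort(cohort_config(n_control = n, n_subclinical = n,
                                n_patients = n, seed = seed))
}

tiny_ema <- function(cohort, seed = 11L, ...) {
  generate_ema(cohort, schedule_config(seed = seed, ...),
               mood_config(seed = seed), feature_model(seed = seed))
}

random_adapter_params <- function(h, d, scale = 0.5) {
  list(W_D = matrix(rnorm(d * h, 0, scale), d, h), b_D = rnorm(d, 0, scale),
       W_U = matrix(rnorm(h * d, 0, scale), h, d), b_U = rnorm(h, 0, scale),
       beta = rnorm(h, 0, scale), gamma = rnorm(h, 0, scale))
}
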