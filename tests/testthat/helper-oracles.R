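# Naive scalar-loop oracles for every network stage, written directly
# from the stage definitions and kept independent of the vectorised
# implementation under test.

naive_conv <- function(D, params, cfg) {
  L <- nrow(D); d <- ncol(D); w <- cfg$w; m <- cfg$m
  left <- (w - 1) %/% 2
  C <- matrix(0, L, m)
  for (j in 1:L) for (f in 1:m) {
    acc <- params$bc[f]
    for (t in 1:w) {
      jj <- j + t - 1 - left
      if (jj >= 1 && jj <= L)
        for (c in 1:d)
          acc <- acc + D[jj, c] * params$Wc[(t - 1) * d + c, f]
    }
    C[j, f] <- max(0, acc)
  }
  C
}

naive_softmax_row <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

naive_attention <- function(C, params, cfg) {
  L <- nrow(C); m <- cfg$m; h <- cfg$h; r <- cfg$r
  scale <- if (cfg$attn_scale == "sqrt_r") 1 / sqrt(r) else 1 / r
  Zcat <- matrix(0, L, m)
  for (i in 1:h) {
    Q <- C %*% params$Aq[[i]]
    K <- C %*% params$Ak[[i]]
    V <- C %*% params$Av[[i]]
    Zi <- matrix(0, L, r)
    for (a in 1:L) {
      s <- numeric(L)
      for (b in 1:L) s[b] <- sum(Q[a, ] * K[b, ]) * scale
      wgt <- naive_softmax_row(s)
      for (c in 1:r) Zi[a, c] <- sum(wgt * V[, c])
    }
    Zcat[, ((i - 1) * r + 1):(i * r)] <- Zi
  }
  Zcat %*% params$Ao + C
}

naive_ffn <- function(Z, params) {
  Fm <- Z
  for (j in 1:nrow(Z)) {
    hid <- pmax(0, as.numeric(Z[j, ] %*% params$W1) + params$b1)
    Fm[j, ] <- as.numeric(hid %*% params$W2) + params$b2 + Z[j, ]
  }
  Fm
}

naive_pool <- function(F) {
  m <- ncol(F)
  pave <- pmaxv <- numeric(m)
  for (c in 1:m) {
    pave[c] <- sum(F[, c]) / nrow(F)
    pmaxv[c] <- max(F[, c])
  }
  c(pave, pmaxv)
}

naive_output <- function(P, params) {
  acc <- params$bO
  for (i in seq_along(P)) acc <- acc + P[i] * params$wO[i]
  acc
}

naive_forward <- function(D, params, cfg)
  naive_output(naive_pool(naive_ffn(naive_attention(
    naive_conv(D, params, cfg), params, cfg), params)), params)

# Random small instance (config + params + input) for oracle comparisons.
rand_instance <- function(seed, Lmax = 6, mmax = 8) {
  set.seed(seed)
  h <- sample(c(1L, 2L), 1L)
  m <- h * sample(1:(mmax %/% h), 1L)
  cfg <- ddg_config(NULL, m = m, w = sample(c(1L, 3L, 5L), 1L), h = h,
                    s = sample(2:10, 1L))
  d <- sample(2:5, 1L)
  L <- sample(1:Lmax, 1L)
  params <- ddg_params_init(cfg, d, seed = seed + 1L)
  params$bc <- stats::rnorm(cfg$m, sd = 0.2)  # exercise conv biases
  params$b1 <- stats::rnorm(cfg$s, sd = 0.2)
  params$b2 <- stats::rnorm(cfg$m, sd = 0.2)
  params$bO <- stats::rnorm(1)
  list(cfg = cfg, params = params, D = matrix(stats::rnorm(L * d), L, d),
       L = L, d = d)
}

# Random sequence helper shared across test files.
rand_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
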