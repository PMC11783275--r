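# Named hyperparameter presets explored in cross-validation; m = conv
# filters, h = attention heads, s = FFN hidden width. w = 15 throughout.
MODEL_PRESETS <- list(
  model0 = list(m = 32L,  h = 2L, s = 128L),
  model1 = list(m = 64L,  h = 2L, s = 256L),
  model2 = list(m = 64L,  h = 4L, s = 256L),
  model3 = list(m = 128L, h = 4L, s = 512L),
  model4 = list(m = 128L, h = 8L, s = 512L),
  model5 = list(m = 256L, h = 8L, s = 1024L)
)

#' Model hyperparameter configuration
#'
#' Defines the regression head: a 1D convolution with `m` filters of width
#' `w` (ReLU), one transformer encoder layer with `h` self-attention heads
#' of per-head dimension `r = m/h` and a position-wise feed-forward
#' network with `s` hidden units, global average + max pooling, and a
#' linear output. Named presets `"model0"` .. `"model5"` give the grid
#' explored during model selection; `"model4"` (m = 128, h = 8, s = 512)
#' is the selected full-scale configuration, with r = 16.
#'
#' @param preset Preset name, or `NULL` to give `m`, `h`, `s` explicitly.
#' @param m Number of convolution filters (model width); must be divisible
#'   by `h`.
#' @param w Convolution filter width (default 15).
#' @param h Number of attention heads.
#' @param s Hidden width of the position-wise FFN.
#' @param attn_scale `"sqrt_r"` (default) scales attention logits by
#'   `1/sqrt(r)` as in the original transformer; `"r"` scales by `1/r`,
#'   kept for sensitivity checks.
#' @return A `ddg_config` object with fields `m`, `w`, `h`, `r`, `s`,
#'   `attn_scale`, `preset`.
#' @examples
#' ddg_config("model4")$r  # 16
#' @export
ddg_config <- function(preset = "model4", m = NULL, w = 15L, h = NULL,
                       s = NULL, attn_scale = c("sqrt_r", "r")) {
  attn_scale <- match.arg(attn_scale)
  if (!is.null(preset)) {
    preset <- tolower(preset)
    if (!preset %in% names(MODEL_PRESETS))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(MODEL_PRESETS), collapse = ", "), call. = FALSE)
    p <- MODEL_PRESETS[[preset]]
    if (is.null(m)) m <- p$m
    if (is.null(h)) h <- p$h
    if (is.null(s)) s <- p$s
  }
  if (is.null(m) || is.null(h) || is.null(s))
    stop("either give a preset or all of m, h, s", call. = FALSE)
  m <- as.integer(m); w <- as.integer(w); h <- as.integer(h)
  s <- as.integer(s)
  if (m < 1L || w < 1L || h < 1L || s < 1L)
    stop("m, w, h, s must be positive", call. = FALSE)
  if (m %% h != 0L)
    stop("m (", m, ") must be divisible by the number of heads h (", h, ")",
         call. = FALSE)
  structure(list(m = m, w = w, h = h, r = m %/% h, s = s,
                 attn_scale = attn_scale,
                 preset = if (is.null(preset)) NA_character_ else preset),
            class = "ddg_config")
}

#' @export
print.ddg_config <- function(x, ...) {
  cat(sprintf(
    "ddG model config%s: m = %d filters (w = %d), h = %d heads (r = %d), s = %d, attn scale = %s\n",
    if (is.na(x$preset)) "" else paste0(" [", x$preset, "]"),
    x$m, x$w, x$h, x$r, x$s, x$attn_scale))
  invisible(x)
}

#' Initialise model parameters
#'
#' Seeded He/Glorot-style random initialisation of every learnable tensor
#' of the regression head for input channel dimension `d`:
#' convolution filters `Wc` ((w*d) x m, tap-major rows) and biases `bc`;
#' per-head attention projections `Aq`, `Ak`, `Av` (each m x r) and the
#' output projection `Ao` (m x m); FFN weights `W1` (m x s), `b1`, `W2`
#' (s x m), `b2`; output weights `wO` (length 2m) and bias `bO`.
#'
#' @param cfg A [ddg_config()].
#' @param d Input embedding dimension.
#' @param seed Integer seed; fixed (cfg, d, seed) give identical
#'   parameters.
#' @return A `ddg_params` list of numeric arrays.
#' @export
ddg_params_init <- function(cfg, d, seed = 1L) {
  stopifnot(inherits(cfg, "ddg_config"))
  d <- as.integer(d)
  m <- cfg$m; w <- cfg$w; h <- cfg$h; r <- cfg$r; s <- cfg$s
  with_seed(seed, {
    p <- list(
      Wc = matrix(stats::rnorm(w * d * m, sd = sqrt(2 / (w * d))), w * d, m),
      bc = numeric(m),
      Aq = lapply(seq_len(h), function(i)
        matrix(stats::rnorm(m * r, sd = sqrt(1 / m)), m, r)),
      Ak = lapply(seq_len(h), function(i)
        matrix(stats::rnorm(m * r, sd = sqrt(1 / m)), m, r)),
      Av = lapply(seq_len(h), function(i)
        matrix(stats::rnorm(m * r, sd = sqrt(1 / m)), m, r)),
      Ao = matrix(stats::rnorm(m * m, sd = sqrt(1 / m)), m, m),
      W1 = matrix(stats::rnorm(m * s, sd = sqrt(2 / m)), m, s),
      b1 = numeric(s),
      W2 = matrix(stats::rnorm(s * m, sd = sqrt(1 / s)), s, m),
      b2 = numeric(m),
      wO = stats::rnorm(2 * m, sd = sqrt(1 / (2 * m))),
      bO = 0
    )
    structure(c(p, list(d = d)), class = "ddg_params")
  })
}

check_params <- function(params, cfg, d = NULL) {
  stopifnot(inherits(params, "ddg_params"), inherits(cfg, "ddg_config"))
  if (!is.null(d) && params$d != d)
    stop("input has ", d, " channels but the model was built for ",
         params$d, call. = FALSE)
  if (nrow(params$Wc) != cfg$w * params$d || ncol(params$Wc) != cfg$m ||
      length(params$Aq) != cfg$h || ncol(params$Aq[[1L]]) != cfg$r)
    stop("parameter shapes do not match the configuration", call. = FALSE)
  invisible(TRUE)
}

# Unfold D (L x d) into the im2col matrix (L x (w*d)) under zero
# same-padding, so the convolution is a single matrix product. Column
# block t (width d) holds the input rows shifted by tap t.
conv_im2col <- function(D, w) {
  L <- nrow(D); d <- ncol(D)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  Xp <- rbind(matrix(0, left, d), D, matrix(0, right, d))
  Xc <- matrix(0, L, w * d)
  for (t in seq_len(w))
    Xc[, ((t - 1L) * d + 1L):(t * d)] <- Xp[t:(t + L - 1L), , drop = FALSE]
  Xc
}

#' 1D convolution stage
#'
#' Applies `m` filters of width `w` across the residue axis of the
#' difference matrix with zero same-padding (the output keeps all L rows,
#' as required by the residual connection and pooling downstream),
#' followed by ReLU.
#'
#' @param D `L x d` difference matrix.
#' @param params,cfg Model parameters and configuration.
#' @return `L x m` non-negative activation matrix `C`.
#' @export
conv1d_forward <- function(D, params, cfg) {
  check_params(params, cfg, d = ncol(D))
  Xc <- conv_im2col(D, cfg$w)
  pre <- Xc %*% params$Wc
  pre <- sweep(pre, 2L, params$bc, "+")
  pmax(pre, 0)
}

# Row-wise softmax with max-subtraction (no overflow for any finite
# input). `keep` flags the key positions a query may attend to.
softmax_rows <- function(S, keep = NULL) {
  if (!is.null(keep)) S[, !keep] <- -Inf
  mx <- apply(S, 1L, max)
  W <- exp(S - mx)
  W[!is.finite(W)] <- 0
  W / rowSums(W)
}

#' Multi-head self-attention stage
#'
#' For each head `i`, projects the conv output `C` to queries, keys and
#' values (`Qi = C Aq_i`, `Ki = C Ak_i`, `Vi = C Av_i`), computes
#' `Zi = softmax(Qi Ki' / sqrt(r)) Vi`, concatenates the heads, applies
#' the output projection `Ao` and adds the residual: `Z = [Z1..Zh] Ao + C`.
#' No positional encoding, layer normalisation or dropout is used. Masked
#' (padded) positions receive zero attention weight and contribute
#' nothing.
#'
#' @param C `L x m` input matrix.
#' @param params,cfg Model parameters and configuration.
#' @param mask Optional logical vector of length L, `TRUE` for real
#'   positions and `FALSE` for padding.
#' @param keep Return intermediate activations (for backpropagation and
#'   inspection) instead of just `Z`.
#' @return `Z` (`L x m`), or a list of intermediates when `keep = TRUE`
#'   (including per-head attention weight matrices `attn`, each
#'   row-stochastic over unmasked keys).
#' @export
multi_head_attention <- function(C, params, cfg, mask = NULL, keep = FALSE) {
  check_params(params, cfg)
  m <- cfg$m; h <- cfg$h; r <- cfg$r
  if (ncol(C) != m) stop("C must have m = ", m, " columns", call. = FALSE)
  scale <- if (cfg$attn_scale == "sqrt_r") 1 / sqrt(r) else 1 / r
  L <- nrow(C)
  Zcat <- matrix(0, L, m)
  Q <- K <- V <- W <- Zh <- vector("list", h)
  for (i in seq_len(h)) {
    Q[[i]] <- C %*% params$Aq[[i]]
    K[[i]] <- C %*% params$Ak[[i]]
    V[[i]] <- C %*% params$Av[[i]]
    S <- (Q[[i]] %*% t(K[[i]])) * scale
    W[[i]] <- softmax_rows(S, keep = mask)
    Zh[[i]] <- W[[i]] %*% V[[i]]
    Zcat[, ((i - 1L) * r + 1L):(i * r)] <- Zh[[i]]
  }
  Z <- Zcat %*% params$Ao + C
  if (!keep) return(Z)
  list(Z = Z, Zcat = Zcat, Q = Q, K = K, V = V, attn = W, scale = scale)
}

#' Position-wise feed-forward stage
#'
#' Applies the same two-layer ReLU network independently to every row of
#' `Z`, with a residual connection:
#' `f_j = ReLU(z_j W1 + b1) W2 + b2 + z_j`.
#'
#' @param Z `L x m` matrix.
#' @param params,cfg Model parameters and configuration.
#' @param keep Return intermediates for backpropagation.
#' @return `F` (`L x m`), or a list of intermediates.
#' @export
position_ffn <- function(Z, params, cfg, keep = FALSE) {
  check_params(params, cfg)
  pre <- sweep(Z %*% params$W1, 2L, params$b1, "+")
  H <- pmax(pre, 0)
  Fm <- sweep(H %*% params$W2, 2L, params$b2, "+") + Z
  if (!keep) return(Fm)
  list(F = Fm, H = H, pre = pre)
}

#' Pooling stage
#'
#' Collapses the encoder output over the residue axis: `pave` holds the
#' column means and `pmax` the column maxima, both over unmasked positions
#' only; the result is their concatenation `P = [pave, pmax]` of length
#' 2m. Pooling is invariant to row permutations.
#'
#' @param F `L x m` matrix.
#' @param mask Optional logical vector of length L (`TRUE` = real
#'   position); at least one position must be unmasked.
#' @param keep Return the max-row indices too (for backpropagation).
#' @return Numeric vector `P` of length 2m, or a list with `P`, `pave`,
#'   `pmax`, `amax`, `n`.
#' @export
pool_concat <- function(F, mask = NULL, keep = FALSE) {
  if (!is.matrix(F)) stop("F must be a matrix", call. = FALSE)
  if (!is.null(mask)) {
    if (length(mask) != nrow(F))
      stop("mask length must equal nrow(F)", call. = FALSE)
    if (!any(mask)) stop("all positions are masked", call. = FALSE)
    Fu <- F[mask, , drop = FALSE]
  } else Fu <- F
  pave <- colMeans(Fu)
  amax <- max.col(t(Fu), ties.method = "first")
  pmaxv <- Fu[cbind(amax, seq_len(ncol(Fu)))]
  P <- c(pave, pmaxv)
  if (!keep) return(P)
  rows <- if (is.null(mask)) seq_len(nrow(F)) else which(mask)
  list(P = P, pave = pave, pmax = pmaxv, amax = rows[amax], n = nrow(Fu))
}

#' Linear output stage
#'
#' `y_hat = P . wO + bO`, the predicted ddG in kcal/mol (negative =
#' destabilizing).
#'
#' @param P Pooled vector of length 2m.
#' @param params Model parameters.
#' @return Scalar prediction.
#' @export
output_head <- function(P, params) {
  if (length(P) != length(params$wO))
    stop("P has length ", length(P), "; expected ", length(params$wO),
         call. = FALSE)
  sum(P * params$wO) + params$bO
}

#' Full forward pass
#'
#' Composes the stages: convolution, multi-head self-attention,
#' position-wise FFN, dual pooling and linear output. Deterministic for
#' fixed parameters.
#'
#' @param D `L x d` difference matrix.
#' @param params,cfg Model parameters and configuration.
#' @param mask Optional logical vector of length L for padded positions.
#' @param keep Return every intermediate activation (used by the
#'   backward pass) instead of the scalar.
#' @return Scalar predicted ddG, or the full activation state.
#' @export
ddg_forward <- function(D, params, cfg, mask = NULL, keep = FALSE) {
  check_params(params, cfg, d = ncol(D))
  Xc <- conv_im2col(D, cfg$w)
  preC <- sweep(Xc %*% params$Wc, 2L, params$bc, "+")
  C <- pmax(preC, 0)
  att <- multi_head_attention(C, params, cfg, mask = mask, keep = TRUE)
  ffn <- position_ffn(att$Z, params, cfg, keep = TRUE)
  pool <- pool_concat(ffn$F, mask = mask, keep = TRUE)
  y <- output_head(pool$P, params)
  if (!keep) return(y)
  list(y = y, Xc = Xc, preC = preC, C = C, att = att, ffn = ffn,
       pool = pool, mask = mask)
}

#' Batched forward pass with padding and masking
#'
#' Pads variable-length difference matrices with zero rows to a common
#' length and masks the padding out of both the attention softmax and the
#' pooling, so each sequence's prediction equals its unbatched value.
#'
#' @param Dlist List of `L_i x d` difference matrices.
#' @param params,cfg Model parameters and configuration.
#' @return Numeric vector of predictions, one per input matrix.
#' @export
ddg_forward_batch <- function(Dlist, params, cfg) {
  stopifnot(is.list(Dlist), length(Dlist) >= 1L)
  Lmax <- max(vapply(Dlist, nrow, 1L))
  vapply(Dlist, function(D) {
    L <- nrow(D)
    if (L < Lmax) {
      D <- rbind(D, matrix(0, Lmax - L, ncol(D)))
      mask <- c(rep(TRUE, L), rep(FALSE, Lmax - L))
    } else mask <- NULL
    ddg_forward(D, params, cfg, mask = mask)
  }, numeric(1L))
}
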