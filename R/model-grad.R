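# Reverse-mode gradients of the regression head, derived stage by stage
# from the forward definitions in model.R. `state` is ddg_forward(...,
# keep = TRUE); `dy` the upstream derivative dLoss/dy_hat. Returns
# dLoss/d(theta) with the same layout as ddg_params. Training uses
# unpadded single-record passes, so no mask handling is needed here.
ddg_backward <- function(state, params, cfg, dy = 1) {
  m <- cfg$m; h <- cfg$h; r <- cfg$r
  L <- nrow(state$C)

  g <- list(Wc = NULL, bc = NULL, Aq = vector("list", h),
            Ak = vector("list", h), Av = vector("list", h),
            Ao = NULL, W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
            wO = NULL, bO = NULL)

  # output head: y = P . wO + bO
  g$wO <- state$pool$P * dy
  g$bO <- dy
  dP <- params$wO * dy

  # pooling: pave = colMeans(F); pmax picks one row per column
  dpave <- dP[seq_len(m)]
  dpmax <- dP[m + seq_len(m)]
  dF <- matrix(rep(dpave / L, each = L), L, m)
  idx <- cbind(state$pool$amax, seq_len(m))
  dF[idx] <- dF[idx] + dpmax

  # FFN: F = ReLU(Z W1 + b1) W2 + b2 + Z
  dH <- dF %*% t(params$W2)
  dpre <- dH * (state$ffn$pre > 0)
  g$W2 <- t(state$ffn$H) %*% dF
  g$b2 <- colSums(dF)
  g$W1 <- t(state$att$Z) %*% dpre
  g$b1 <- colSums(dpre)
  dZ <- dF + dpre %*% t(params$W1)

  # attention: Z = [Z1..Zh] Ao + C
  g$Ao <- t(state$att$Zcat) %*% dZ
  dZcat <- dZ %*% t(params$Ao)
  dC <- dZ  # residual branch
  C <- state$C
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * r + 1L):(i * r)
    dZi <- dZcat[, cols, drop = FALSE]
    Wi <- state$att$attn[[i]]
    dWi <- dZi %*% t(state$att$V[[i]])
    dVi <- t(Wi) %*% dZi
    # softmax rows: dS = W * (dW - rowSums(dW * W))
    dS <- Wi * (dWi - rowSums(dWi * Wi))
    dS <- dS * state$att$scale
    dQi <- dS %*% state$att$K[[i]]
    dKi <- t(dS) %*% state$att$Q[[i]]
    g$Aq[[i]] <- t(C) %*% dQi
    g$Ak[[i]] <- t(C) %*% dKi
    g$Av[[i]] <- t(C) %*% dVi
    dC <- dC + dQi %*% t(params$Aq[[i]]) + dKi %*% t(params$Ak[[i]]) +
      dVi %*% t(params$Av[[i]])
  }

  # convolution: C = ReLU(Xc Wc + bc)
  dpreC <- dC * (state$preC > 0)
  g$Wc <- t(state$Xc) %*% dpreC
  g$bc <- colSums(dpreC)
  g
}

# Flat iteration over the learnable tensors of a ddg_params / gradient
# list, as (name, index-or-NA) pairs; keeps Adam and the numeric gradient
# check generic over the parameter layout.
param_slots <- function(h) {
  slots <- list(list("Wc", NA), list("bc", NA))
  for (i in seq_len(h)) {
    slots <- c(slots, list(list("Aq", i), list("Ak", i), list("Av", i)))
  }
  c(slots, list(list("Ao", NA), list("W1", NA), list("b1", NA),
                list("W2", NA), list("b2", NA), list("wO", NA),
                list("bO", NA)))
}

slot_get <- function(params, s)
  if (is.na(s[[2L]])) params[[s[[1L]]]] else params[[s[[1L]]]][[s[[2L]]]]

slot_set <- function(params, s, value) {
  if (is.na(s[[2L]])) params[[s[[1L]]]] <- value
  else params[[s[[1L]]]][[s[[2L]]]] <- value
  params
}

# Zero-filled gradient accumulator matching `params`.
grad_zero <- function(params, h) {
  g <- params
  for (s in param_slots(h)) {
    v <- slot_get(params, s)
    g <- slot_set(g, s, v * 0)
  }
  g
}

grad_add <- function(acc, g, h) {
  for (s in param_slots(h))
    acc <- slot_set(acc, s, slot_get(acc, s) + slot_get(g, s))
  acc
}

adam_state_init <- function(params, h) {
  list(m = grad_zero(params, h), v = grad_zero(params, h), t = 0L)
}

# One Adam update; standard bias-corrected first/second moments.
adam_step <- function(params, grad, state, h, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (s in param_slots(h)) {
    gv <- slot_get(grad, s)
    mv <- beta1 * slot_get(state$m, s) + (1 - beta1) * gv
    vv <- beta2 * slot_get(state$v, s) + (1 - beta2) * gv * gv
    state$m <- slot_set(state$m, s, mv)
    state$v <- slot_set(state$v, s, vv)
    upd <- (mv / bc1) / (sqrt(vv / bc2) + eps)
    params <- slot_set(params, s, slot_get(params, s) - lr * upd)
  }
  list(params = params, state = state)
}
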