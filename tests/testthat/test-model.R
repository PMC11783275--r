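test_that("configuration presets and shape rules hold", {
  cfg4 <- ddg_config("model4")
  expect_equal(cfg4$m, 128L)
  expect_equal(cfg4$h, 8L)
  expect_equal(cfg4$s, 512L)
  expect_equal(cfg4$r, 16L)  # per-head dimension of the selected model
  expect_equal(cfg4$w, 15L)
  cfg0 <- ddg_config("model0")
  expect_equal(c(cfg0$m, cfg0$h, cfg0$s), c(32L, 2L, 128L))
  expect_error(ddg_config(NULL, m = 10, h = 4, s = 8), "divisible")
  expect_error(ddg_config("model9"), "unknown preset")
})

test_that("convolution matches the sliding-window oracle and edge cases", {
  cfg <- ddg_config(NULL, m = 4, w = 5, h = 2, s = 8)
  par <- ddg_params_init(cfg, 3, seed = 1)
  D0 <- matrix(0, 6, 3)
  par0 <- par; par0$bc <- rep(0, 4)
  expect_equal(conv1d_forward(D0, par0, cfg), matrix(0, 6, 4))
  par1 <- par; par1$bc <- rep(1, 4)
  expect_equal(conv1d_forward(D0, par1, cfg), matrix(1, 6, 4))

  for (seed in 1:40) {
    inst <- rand_instance(seed)
    C <- conv1d_forward(inst$D, inst$params, inst$cfg)
    expect_equal(C, naive_conv(inst$D, inst$params, inst$cfg),
                 tolerance = 1e-6)
    expect_true(all(C >= 0))
    expect_equal(nrow(C), inst$L)  # same-length padding
  }
})

test_that("attention matches the scalar oracle and its closed forms", {
  for (seed in 1:40) {
    inst <- rand_instance(seed)
    C <- conv1d_forward(inst$D, inst$params, inst$cfg)
    Z <- multi_head_attention(C, inst$params, inst$cfg)
    expect_equal(Z, naive_attention(C, inst$params, inst$cfg),
                 tolerance = 1e-6)
  }

  # L = 1: softmax over one position is 1, so Z = [V1..Vh] Ao + C
  inst <- rand_instance(101)
  C1 <- matrix(rnorm(inst$cfg$m), 1, inst$cfg$m)
  Vcat <- do.call(cbind, lapply(seq_len(inst$cfg$h), function(i)
    C1 %*% inst$params$Av[[i]]))
  expect_equal(multi_head_attention(C1, inst$params, inst$cfg),
               Vcat %*% inst$params$Ao + C1, tolerance = 1e-10)

  # identical rows in -> identical rows out
  Cr <- matrix(rnorm(inst$cfg$m), 4, inst$cfg$m, byrow = TRUE)
  Zr <- multi_head_attention(Cr, inst$params, inst$cfg)
  expect_equal(Zr[1, ], Zr[3, ], tolerance = 1e-10)

  # attention weights are row-stochastic for every head
  att <- multi_head_attention(conv1d_forward(inst$D, inst$params, inst$cfg),
                              inst$params, inst$cfg, keep = TRUE)
  for (W in att$attn) {
    expect_true(all(W >= 0))
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
  }
})

test_that("position-wise FFN matches hand computation and is equivariant", {
  inst <- rand_instance(7)
  cfg <- inst$cfg; par <- inst$params
  Z <- matrix(rnorm(5 * cfg$m), 5, cfg$m)

  expect_equal(position_ffn(Z, par, cfg), naive_ffn(Z, par),
               tolerance = 1e-6)

  # W2 = 0, b2 = 0 -> pure residual
  par0 <- par; par0$W2 <- par$W2 * 0; par0$b2 <- par$b2 * 0
  expect_equal(position_ffn(Z, par0, cfg), Z)

  # single row against scalar hand arithmetic
  cfgh <- ddg_config(NULL, m = 2, w = 1, h = 1, s = 2)
  ph <- ddg_params_init(cfgh, 2, seed = 1)
  ph$W1 <- matrix(c(1, 0, -1, 2), 2, 2)
  ph$b1 <- c(0.5, -0.5)
  ph$W2 <- matrix(c(1, 1, 0, 1), 2, 2)
  ph$b2 <- c(0, 0.25)
  z <- matrix(c(1, 2), 1, 2)
  hid <- pmax(0, c(1*1 + 2*0 + 0.5, 1*(-1) + 2*2 - 0.5))  # (1.5, 2.5)
  f <- c(hid[1]*1 + hid[2]*1 + 0 + 1, hid[1]*0 + hid[2]*1 + 0.25 + 2)
  expect_equal(as.numeric(position_ffn(z, ph, cfgh)), f)

  # permuting rows permutes outputs identically
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(position_ffn(Z[perm, ], par, cfg),
               position_ffn(Z, par, cfg)[perm, ])
})

test_that("pooling and output head match hand arithmetic", {
  F1 <- matrix(c(1, 3, -2, 0), 2, 2)  # rows (1,-2), (3,0)
  expect_equal(pool_concat(F1), c(2, -1, 3, 0))
  expect_equal(pool_concat(F1[c(2, 1), ]), c(2, -1, 3, 0))  # row perm

  f <- c(0.3, -1.2, 5)
  Fc <- matrix(f, 4, 3, byrow = TRUE)
  expect_equal(pool_concat(Fc), c(f, f))  # all rows equal

  for (seed in 1:30) {
    set.seed(seed)
    F <- matrix(rnorm(12), 4, 3)
    expect_equal(pool_concat(F), naive_pool(F), tolerance = 1e-12)
  }

  cfg <- ddg_config(NULL, m = 3, w = 1, h = 1, s = 2)
  par <- ddg_params_init(cfg, 2, seed = 2)
  expect_equal(output_head(rep(0, 6), replace(par, "bO", 2.5)), 2.5)
  parz <- par; parz$wO <- rep(0, 6); parz$bO <- -1
  expect_equal(output_head(rnorm(6), parz), -1)
  for (seed in 1:20) {
    set.seed(seed)
    P <- rnorm(6)
    expect_equal(output_head(P, par), naive_output(P, par))
  }
  expect_error(output_head(rep(0, 5), par), "length")
})

test_that("full forward matches the composed oracle and is deterministic", {
  for (seed in 1:30) {
    inst <- rand_instance(seed)
    y <- ddg_forward(inst$D, inst$params, inst$cfg)
    expect_equal(y, naive_forward(inst$D, inst$params, inst$cfg),
                 tolerance = 1e-6)
    expect_identical(y, ddg_forward(inst$D, inst$params, inst$cfg))
    expect_true(is.finite(y))
  }
})

test_that("the post-conv pipeline is permutation-invariant", {
  # no positional encoding + pooling invariance: permuting the rows of C
  # must leave the final prediction unchanged
  post_conv <- function(C, params, cfg) {
    F <- position_ffn(multi_head_attention(C, params, cfg), params, cfg)
    output_head(pool_concat(F), params)
  }
  for (seed in 1:15) {
    inst <- rand_instance(seed, Lmax = 6)
    if (inst$L < 2) next
    C <- conv1d_forward(inst$D, inst$params, inst$cfg)
    perm <- sample(nrow(C))
    expect_equal(post_conv(C[perm, , drop = FALSE], inst$params, inst$cfg),
                 post_conv(C, inst$params, inst$cfg), tolerance = 1e-10)
  }
})

test_that("batched padded+masked inference equals unbatched", {
  cfg <- ddg_config(NULL, m = 8, w = 5, h = 2, s = 16)
  par <- ddg_params_init(cfg, 4, seed = 9)
  set.seed(42)
  Dlist <- lapply(c(3, 7, 5, 1), function(L) matrix(rnorm(L * 4), L, 4))
  batched <- ddg_forward_batch(Dlist, par, cfg)
  single <- vapply(Dlist, function(D) ddg_forward(D, par, cfg), numeric(1))
  expect_equal(batched, single, tolerance = 1e-5)
})

test_that("softmax overflow protection keeps outputs finite", {
  cfg <- ddg_config(NULL, m = 4, w = 3, h = 1, s = 4)
  par <- ddg_params_init(cfg, 2, seed = 3)
  D <- matrix(1e4, 5, 2)  # huge activations -> huge attention logits
  y <- ddg_forward(D, par, cfg)
  expect_true(is.finite(y))
})

test_that("analytic gradients match central finite differences", {
  inst <- rand_instance(13, Lmax = 5, mmax = 6)
  cfg <- inst$cfg; par <- inst$params; D <- inst$D
  st <- ddg_forward(D, par, cfg, keep = TRUE)
  g <- stabemb:::ddg_backward(st, par, cfg, dy = 1)
  eps <- 1e-6
  for (s in stabemb:::param_slots(cfg$h)) {
    v <- stabemb:::slot_get(par, s)
    ga <- stabemb:::slot_get(g, s)
    set.seed(1)
    for (j in sample(length(v), min(5, length(v)))) {
      vp <- v; vp[j] <- vp[j] + eps
      yp <- ddg_forward(D, stabemb:::slot_set(par, s, vp), cfg)
      vm <- v; vm[j] <- vm[j] - eps
      ym <- ddg_forward(D, stabemb:::slot_set(par, s, vm), cfg)
      expect_equal(ga[j], (yp - ym) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("plain-r attention scaling is available behind the flag", {
  cfgs <- ddg_config(NULL, m = 4, w = 3, h = 2, s = 8)
  cfgr <- ddg_config(NULL, m = 4, w = 3, h = 2, s = 8, attn_scale = "r")
  par <- ddg_params_init(cfgs, 3, seed = 5)
  set.seed(6)
  D <- matrix(rnorm(12), 4, 3)
  ys <- ddg_forward(D, par, cfgs)
  yr <- ddg_forward(D, par, cfgr)
  expect_false(isTRUE(all.equal(ys, yr)))  # r = 2: the scalings differ
  expect_true(is.finite(yr))
})
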