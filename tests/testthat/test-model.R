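test_that("embedding lookup returns the right rows and shapes", {
  cfg <- tiny_config()
  vocab <- kmer_vocabulary(2)
  expect_length(vocab, 16L)
  set.seed(1)
  emb <- matrix(rnorm(16 * 8), 16, 8)
  tk <- tokenize_kmers("AUGAUG", 2)
  E <- embed_tokens(tk, emb, vocab)
  expect_equal(dim(E), c(5L, 8L))
  # identical tokens give identical rows ("AU" occurs at 1 and 4)
  expect_equal(tk$tokens[1], tk$tokens[4])
  expect_equal(E[1, ], E[4, ])
  # changing one embedding row changes only matching output rows
  emb2 <- emb
  emb2[match("AU", vocab), ] <- 0
  E2 <- embed_tokens(tk, emb2, vocab)
  expect_equal(E2[c(2, 3, 5), ], E[c(2, 3, 5), ])
  expect_false(isTRUE(all.equal(E2[1, ], E[1, ])))
  expect_error(embed_tokens(c("XX"), emb, vocab), "vocabulary")
})

test_that("BiLSTM output is L x d_b, zero for zero weights, and sums both passes", {
  cfg <- tiny_config()
  set.seed(2)
  theta <- init_parameters(cfg)
  lstm <- list(f = theta$lstm_f, b = theta$lstm_b)
  E <- matrix(rnorm(6 * 8), 6, 8)
  H <- bilstm_encode(E, lstm)
  expect_equal(dim(H), c(6L, 8L))
  # L = 1 degenerate case still works
  expect_equal(dim(bilstm_encode(E[1, , drop = FALSE], lstm)), c(1L, 8L))

  # all-zero parameters: every gate saturates to a constant, cell stays zero
  z <- lapply(theta$lstm_f, function(x) x * 0)
  H0 <- bilstm_encode(E, list(f = z, b = z))
  expect_true(all(H0 == 0))

  # single-step scalar oracle: L = 1, explicit gate arithmetic
  th1 <- theta$lstm_f
  x <- E[1, ]
  a <- drop(x %*% th1$Wx) + th1$b
  Hd <- 8L
  i <- 1 / (1 + exp(-a[1:Hd])); f <- 1 / (1 + exp(-a[Hd + 1:Hd]))
  g <- tanh(a[2 * Hd + 1:Hd]); o <- 1 / (1 + exp(-a[3 * Hd + 1:Hd]))
  h_fwd <- o * tanh(i * g)
  a2 <- drop(x %*% theta$lstm_b$Wx) + theta$lstm_b$b
  i2 <- 1 / (1 + exp(-a2[1:Hd])); g2 <- tanh(a2[2 * Hd + 1:Hd])
  o2 <- 1 / (1 + exp(-a2[3 * Hd + 1:Hd]))
  h_bwd <- o2 * tanh(i2 * g2)
  expect_equal(drop(bilstm_encode(E[1, , drop = FALSE], lstm)), h_fwd + h_bwd,
               tolerance = 1e-12)
})

test_that("scaled dot-product attention matches the naive loop oracle", {
  # degenerate cases
  set.seed(3)
  Q1 <- matrix(rnorm(4), 1); K1 <- matrix(rnorm(4), 1); V1 <- matrix(rnorm(3), 1)
  expect_equal(unclass(scaled_dot_attention(Q1, K1, V1))[1, ], V1[1, ])

  # identical keys -> uniform weights -> column mean of V
  K <- matrix(rep(1:4, each = 5), 5, 4)
  Q <- matrix(rnorm(20), 5, 4)
  V <- matrix(rnorm(15), 5, 3)
  out <- scaled_dot_attention(Q, K, V)
  expect_equal(unclass(out), matrix(colMeans(V), 5, 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(rowSums(attr(out, "weights")) - 1) < 1e-9))

  # random instances vs oracle, with and without masks
  for (rep in 1:100) {
    L <- sample(2:6, 1); dk <- sample(2:5, 1); dv <- sample(2:5, 1)
    Q <- matrix(rnorm(L * dk), L); K <- matrix(rnorm(L * dk), L)
    V <- matrix(rnorm(L * dv), L)
    mask <- if (rep %% 3 == 0) {
      m <- runif(L) > 0.3; if (!any(m)) m[1] <- TRUE; m
    } else NULL
    got <- scaled_dot_attention(Q, K, V, mask)
    expect_lt(max(abs(unclass(got) - oracle_attention(Q, K, V, mask))), 1e-10)
  }
  expect_error(scaled_dot_attention(Q, K, V, rep(FALSE, nrow(Q))), "mask")
})

test_that("multi-head attention matches an explicit transcription and maps to width 38", {
  cfg <- tiny_config()
  set.seed(4)
  for (rep in 1:100) {
    theta <- init_parameters(cfg)
    attn <- list(WQ = theta$WQ, WK = theta$WK, WV = theta$WV, Wo = theta$Wo_attn)
    L <- sample(2:7, 1)
    FB <- matrix(rnorm(L * cfg$d_b), L)
    got <- multi_head(FB, attn)
    expect_equal(dim(got), c(L, 38L))
    expect_lt(max(abs(got - oracle_multi_head(FB, attn))), 1e-10)
  }
  # h = 1 reduces to single attention + linear map
  cfg1 <- essmir_config(k = 2, d_b = 8, d_k = 4, d_v = 4, h = 1, mlp_hidden = 8L,
                        seed = 9)
  set.seed(9)
  th1 <- init_parameters(cfg1)
  FB <- matrix(rnorm(5 * 8), 5)
  a1 <- list(WQ = th1$WQ, WK = th1$WK, WV = th1$WV, Wo = th1$Wo_attn)
  direct <- unclass(scaled_dot_attention(FB %*% th1$WQ[[1]], FB %*% th1$WK[[1]],
                                         FB %*% th1$WV[[1]])) %*% th1$Wo_attn
  expect_equal(multi_head(FB, a1), direct, tolerance = 1e-12)
})

test_that("weight attention matches the scalar transcription and its identities", {
  cfg <- tiny_config()
  set.seed(5)
  for (rep in 1:100) {
    theta <- init_parameters(cfg)
    wa <- list(W_inter = theta$W_inter, b_inter = theta$b_inter,
               W_conv = theta$W_conv, b_conv = theta$b_conv)
    L <- sample(1:6, 1)
    fs <- rnorm(38); FM <- matrix(rnorm(L * 38), L)
    got <- weight_attention(fs, FM, wa)
    expect_length(got, 38L)
    expect_lt(max(abs(as.numeric(got) - oracle_weight_attention(fs, FM, wa))), 1e-10)
  }
  # h_m = 0 makes every alpha_i = 0.5 so F_W = 0.5 * sum h_i
  theta <- init_parameters(cfg)
  wa0 <- list(W_inter = theta$W_inter * 0, b_inter = theta$b_inter * 0,
              W_conv = theta$W_conv, b_conv = theta$b_conv)
  FM <- matrix(rnorm(4 * 38), 4)
  fs <- rnorm(38)
  got <- weight_attention(fs, FM, wa0)
  Hi <- pmax(FM %*% t(wa0$W_conv) + matrix(wa0$b_conv, 4, 38, byrow = TRUE), 0)
  expect_equal(as.numeric(got), 0.5 * colSums(Hi), tolerance = 1e-12)
  expect_true(all(attr(got, "alpha") == 0.5))
  # L = 1: F_W = alpha_1 h_1
  g1 <- weight_attention(fs, FM[1, , drop = FALSE],
                         list(W_inter = theta$W_inter, b_inter = theta$b_inter,
                              W_conv = theta$W_conv, b_conv = theta$b_conv))
  expect_equal(as.numeric(g1),
               oracle_weight_attention(fs, FM[1, , drop = FALSE],
                                       list(W_inter = theta$W_inter,
                                            b_inter = theta$b_inter,
                                            W_conv = theta$W_conv,
                                            b_conv = theta$b_conv)))
  expect_error(weight_attention(fs, FM[0, , drop = FALSE],
                                list(W_inter = theta$W_inter,
                                     b_inter = theta$b_inter,
                                     W_conv = theta$W_conv,
                                     b_conv = theta$b_conv)), "position")
})

test_that("the MLP head and softmax implement the stated algebra", {
  cfg <- tiny_config()
  set.seed(6)
  theta <- init_parameters(cfg)
  # zero weights -> zero logits
  z0 <- lapply(theta$mlp, function(x) if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
  expect_equal(mlp_forward(rnorm(76), z0), c(0, 0))
  # random instance vs explicit loops
  for (rep in 1:20) {
    th <- init_parameters(cfg)
    ff <- rnorm(76)
    h <- ff
    for (l in seq_along(th$mlp$W)) {
      pre <- numeric(nrow(th$mlp$W[[l]]))
      for (r in seq_along(pre)) pre[r] <- sum(th$mlp$W[[l]][r, ] * h) + th$mlp$b[[l]][r]
      h <- pmax(pre, 0)
    }
    z <- numeric(2)
    for (r in 1:2) z[r] <- sum(th$mlp$W_out[r, ] * h) + th$mlp$b_out[r]
    expect_equal(mlp_forward(ff, th$mlp), z, tolerance = 1e-12)
  }
  expect_error(mlp_forward(rnorm(10), theta$mlp), "width")

  # softmax identities
  expect_equal(softmax_proba(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_proba(c(log(3), 0)), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(softmax_proba(c(1000, 0)), c(1, 0))  # no overflow
  set.seed(8)
  for (i in 1:20) expect_equal(sum(softmax_proba(rnorm(2, sd = 10))), 1,
                               tolerance = 1e-9)
})

test_that("cross-entropy loss has its closed-form values and L2 monotonicity", {
  p <- matrix(c(0, 1), 1)  # probability 1 at class 1
  expect_equal(cross_entropy_loss(p, 1L), 0)
  p2 <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(p2, c(0L, 1L, 0L, 1L)), log(2), tolerance = 1e-12)
  cfg <- tiny_config()
  set.seed(10)
  theta <- init_parameters(cfg)
  base <- cross_entropy_loss(p2, c(0L, 1L, 0L, 1L))
  reg <- cross_entropy_loss(p2, c(0L, 1L, 0L, 1L), theta, lambda = 0.1)
  expect_gt(reg, base)
  expect_warning(cross_entropy_loss(matrix(c(0, 1), 1), 0L), "clamped")
})

test_that("the full forward pass is pure and dimensionally consistent", {
  cfg <- tiny_config()
  set.seed(11)
  theta <- init_parameters(cfg)
  vocab <- kmer_vocabulary(cfg$k)
  rec <- toy_record()
  fs <- rnorm(38)
  o1 <- essmir_forward(rec, fs, theta, vocab, cfg)
  o2 <- essmir_forward(rec, fs, theta, vocab, cfg)
  expect_identical(o1, o2)
  expect_equal(sum(o1$p), 1, tolerance = 1e-9)
  expect_length(o1$Ff, 76L)
  L <- nchar(rec$precursor$residues) - cfg$k + 1
  expect_equal(dim(o1$FB), c(L, cfg$d_b))
  expect_equal(dim(o1$FM), c(L, 38L))
  expect_equal(o1$Ff, c(fs, o1$FW))
})

test_that("analytic gradients match central finite differences end to end", {
  cfg <- tiny_config(lambda_l2 = 1e-3)
  set.seed(7)
  theta <- init_parameters(cfg)
  vocab <- kmer_vocabulary(cfg$k)
  set.seed(8)
  mkex <- function(s, y) list(idx = match(tokenize_kmers(s, cfg$k)$tokens, vocab),
                              fs = rnorm(38), y = y)
  ex <- list(mkex("GAUGCA", 1L), mkex("AUUGGCC", 0L), mkex("GGGAAAUU", 1L))
  lg <- essmir:::essmir_loss_grad(theta, ex, cfg)
  ga <- unlist(lg$grads, use.names = FALSE)
  gn <- numeric_gradient(theta, ex, cfg, eps = 1e-6)
  rel <- abs(ga - gn) / pmax(abs(ga), abs(gn), 1e-8)
  # 1e-4 relative for every parameter, with an absolute floor well below the
  # finite-difference noise for near-zero gradients
  expect_true(all(abs(ga - gn) < 1e-7 | rel < 1e-4))
})

test_that("padding via masks does not change attention or fusion outputs", {
  cfg <- tiny_config()
  set.seed(13)
  theta <- init_parameters(cfg)
  attn <- list(WQ = theta$WQ, WK = theta$WK, WV = theta$WV, Wo = theta$Wo_attn)
  wa <- list(W_inter = theta$W_inter, b_inter = theta$b_inter,
             W_conv = theta$W_conv, b_conv = theta$b_conv)
  L <- 5; pad <- 3
  FB <- matrix(rnorm(L * cfg$d_b), L)
  FBp <- rbind(FB, matrix(rnorm(pad * cfg$d_b), pad))
  mask <- c(rep(TRUE, L), rep(FALSE, pad))
  m_plain <- multi_head(FB, attn)
  m_pad <- multi_head(FBp, attn, mask)
  expect_lt(max(abs(m_plain - m_pad[1:L, ])), 1e-9)
  fs <- rnorm(38)
  w_plain <- weight_attention(fs, m_plain, wa)
  w_pad <- weight_attention(fs, m_pad, wa, mask)
  expect_lt(max(abs(as.numeric(w_plain) - as.numeric(w_pad))), 1e-9)
})
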