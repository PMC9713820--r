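#' Model and training configuration
#'
#' @param k k-mer word size (default 4).
#' @param d_b Embedding and LSTM hidden width (default 128).
#' @param d_k,d_v Per-head query/key and value widths (default 64).
#' @param h Number of attention heads (default 4).
#' @param d_output Per-position attention output width; must equal the
#'   static-feature dimension 38 (required by the weight-attention inner
#'   product).
#' @param mlp_hidden Integer vector of hidden-layer widths (default 76).
#' @param lambda_l2 L2 regularisation coefficient (default 1e-4).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 200).
#' @param batch_size Minibatch size (default 16).
#' @param seed Seed for initialisation and shuffling.
#' @return Object of class `"essmir_config"`.
#' @export
essmir_config <- function(k = 4L, d_b = 128L, d_k = 64L, d_v = 64L, h = 4L,
                          d_output = 38L, mlp_hidden = 76L, lambda_l2 = 1e-4,
                          learning_rate = 1e-3, epochs = 200L, batch_size = 16L,
                          seed = 1L) {
  if (d_output != 38L) {
    stop("d_output must equal the static-feature dimension (38)")
  }
  dims <- c(k = k, d_b = d_b, d_k = d_k, d_v = d_v, h = h, d_output = d_output,
            epochs = epochs, batch_size = batch_size)
  if (any(dims < 1L)) stop("all dimensions/counts must be positive")
  structure(list(k = as.integer(k), d_b = as.integer(d_b), d_k = as.integer(d_k),
                 d_v = as.integer(d_v), h = as.integer(h),
                 d_output = as.integer(d_output), d_f = 38L + as.integer(d_output),
                 mlp_hidden = as.integer(mlp_hidden), lambda_l2 = lambda_l2,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "essmir_config")
}

#' @export
print.essmir_config <- function(x, ...) {
  cat(sprintf(paste0("<essmir_config> k=%d d_b=%d d_k=%d d_v=%d h=%d d_output=%d ",
                     "d_f=%d mlp=[%s]\n  lambda=%g lr=%g epochs=%d batch=%d seed=%d\n"),
              x$k, x$d_b, x$d_k, x$d_v, x$h, x$d_output, x$d_f,
              paste(x$mlp_hidden, collapse = ","), x$lambda_l2, x$learning_rate,
              x$epochs, x$batch_size, x$seed))
  invisible(x)
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform weight matrices, zero biases (LSTM forget-gate bias 1),
#' drawn from the current RNG state.
#'
#' @param config An [essmir_config()].
#' @return Nested named list of numeric parameter tensors.
#' @export
init_parameters <- function(config) {
  d <- config$d_b
  lstm_dir <- function() {
    b <- numeric(4L * d)
    b[d + seq_len(d)] <- 1  # forget-gate bias
    list(Wx = glorot(d, 4L * d), Wh = glorot(d, 4L * d), b = b)
  }
  mk_heads <- function(nc) lapply(seq_len(config$h), function(j) glorot(d, nc))
  widths <- c(config$d_f, config$mlp_hidden)
  theta <- list(
    emb = glorot(4L^config$k, d),
    lstm_f = lstm_dir(),
    lstm_b = lstm_dir(),
    WQ = mk_heads(config$d_k), WK = mk_heads(config$d_k), WV = mk_heads(config$d_v),
    Wo_attn = glorot(config$h * config$d_v, config$d_output),
    W_inter = glorot(config$d_output, 38L), b_inter = numeric(config$d_output),
    W_conv = glorot(config$d_output, config$d_output), b_conv = numeric(config$d_output),
    mlp = list(
      W = lapply(seq_along(config$mlp_hidden),
                 function(l) glorot(widths[l + 1L], widths[l])),
      b = lapply(config$mlp_hidden, numeric),
      W_out = glorot(2L, widths[length(widths)]),
      b_out = numeric(2L)))
  theta
}

collect_weights <- function(theta) {
  c(list(theta$emb,
         theta$lstm_f$Wx, theta$lstm_f$Wh, theta$lstm_b$Wx, theta$lstm_b$Wh,
         theta$Wo_attn, theta$W_inter, theta$W_conv, theta$mlp$W_out),
    theta$WQ, theta$WK, theta$WV, theta$mlp$W)
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

## add the gradient of lambda/2 * ||W||^2 for every weight tensor
add_l2_grad <- function(grads, theta, lambda) {
  if (lambda == 0) return(grads)
  grads$emb <- grads$emb + lambda * theta$emb
  for (dir in c("lstm_f", "lstm_b")) {
    grads[[dir]]$Wx <- grads[[dir]]$Wx + lambda * theta[[dir]]$Wx
    grads[[dir]]$Wh <- grads[[dir]]$Wh + lambda * theta[[dir]]$Wh
  }
  for (nm in c("WQ", "WK", "WV")) {
    for (j in seq_along(theta[[nm]])) {
      grads[[nm]][[j]] <- grads[[nm]][[j]] + lambda * theta[[nm]][[j]]
    }
  }
  grads$Wo_attn <- grads$Wo_attn + lambda * theta$Wo_attn
  grads$W_inter <- grads$W_inter + lambda * theta$W_inter
  grads$W_conv <- grads$W_conv + lambda * theta$W_conv
  for (l in seq_along(theta$mlp$W)) {
    grads$mlp$W[[l]] <- grads$mlp$W[[l]] + lambda * theta$mlp$W[[l]]
  }
  grads$mlp$W_out <- grads$mlp$W_out + lambda * theta$mlp$W_out
  grads
}

#' Full network forward pass for one record
#'
#' tokenize -> embed -> BiLSTM -> multi-head self-attention ->
#' weight-attention fusion with the standardized static feature ->
#' concatenation -> MLP -> softmax.
#'
#' @param record A `"mirna_record"` (or a `"token_seq"`).
#' @param fs_std Standardized static feature vector (length 38).
#' @param theta Parameters from [init_parameters()].
#' @param vocab k-mer vocabulary matching `theta$emb`.
#' @param config The [essmir_config()].
#' @return List with `p` (class probabilities, `p[2]` = essential), `z`
#'   (logits), `Ff` (fused d_f vector), `FW`, `FM`, `FB`.
#' @export
essmir_forward <- function(record, fs_std, theta, vocab, config) {
  toks <- if (inherits(record, "token_seq")) record else
    tokenize_kmers(record$precursor, config$k)
  E <- embed_tokens(toks, theta$emb, vocab)
  FB <- bilstm_encode(E, list(f = theta$lstm_f, b = theta$lstm_b))
  mh <- mh_forward(FB, list(WQ = theta$WQ, WK = theta$WK, WV = theta$WV,
                            Wo = theta$Wo_attn))
  wa <- wa_forward(fs_std, mh$out,
                   list(W_inter = theta$W_inter, b_inter = theta$b_inter,
                        W_conv = theta$W_conv, b_conv = theta$b_conv))
  ff <- c(fs_std, wa$FW)
  z <- mlp_forward(ff, theta$mlp)
  list(p = softmax_proba(z), z = z, Ff = ff, FW = wa$FW, FM = mh$out, FB = FB)
}

## ---- batched loss + gradient ----------------------------------------------

## batch: list of list(idx = token indices into vocab, fs = standardized
## static vector, y = 0/1). Returns mean regularised loss, gradients shaped
## like theta, and the N x 2 probability matrix.
essmir_loss_grad <- function(theta, batch, config, lambda = config$lambda_l2) {
  B <- length(batch)
  d <- config$d_b
  lens <- vapply(batch, function(s) length(s$idx), integer(1))
  Lmax <- max(lens)
  X <- array(0, c(B, Lmax, d))
  Xr <- array(0, c(B, Lmax, d))
  for (b in seq_len(B)) {
    E <- theta$emb[batch[[b]]$idx, , drop = FALSE]
    X[b, seq_len(lens[b]), ] <- E
    Xr[b, seq_len(lens[b]), ] <- E[rev(seq_len(lens[b])), , drop = FALSE]
  }
  fwd <- lstm_forward(X, theta$lstm_f$Wx, theta$lstm_f$Wh, theta$lstm_f$b)
  bwd <- lstm_forward(Xr, theta$lstm_b$Wx, theta$lstm_b$Wh, theta$lstm_b$b)

  attn <- list(WQ = theta$WQ, WK = theta$WK, WV = theta$WV, Wo = theta$Wo_attn)
  wa_par <- list(W_inter = theta$W_inter, b_inter = theta$b_inter,
                 W_conv = theta$W_conv, b_conv = theta$b_conv)
  grads <- zero_like(theta)
  dHf <- array(0, dim(fwd$H))
  dHb <- array(0, dim(bwd$H))
  P <- matrix(0, B, 2L)
  ce <- 0
  for (b in seq_len(B)) {
    L <- lens[b]
    Hf <- matrix(fwd$H[b, seq_len(L), ], L)
    Hb <- matrix(bwd$H[b, seq_len(L), ], L)[rev(seq_len(L)), , drop = FALSE]
    FB <- Hf + Hb
    mh <- mh_forward(FB, attn)
    wa <- wa_forward(batch[[b]]$fs, mh$out, wa_par)
    ff <- c(batch[[b]]$fs, wa$FW)
    mf <- mlp_forward_cache(ff, theta$mlp)
    p <- softmax_proba(mf$z)
    P[b, ] <- p
    y <- batch[[b]]$y
    ce <- ce - log(max(p[y + 1L], 1e-12))
    ## backward
    dz <- p
    dz[y + 1L] <- dz[y + 1L] - 1
    dz <- dz / B
    mb <- mlp_backward(dz, mf$cache, theta$mlp)
    grads$mlp$W_out <- grads$mlp$W_out + mb$dW_out
    grads$mlp$b_out <- grads$mlp$b_out + mb$db_out
    for (l in seq_along(theta$mlp$W)) {
      grads$mlp$W[[l]] <- grads$mlp$W[[l]] + mb$dW[[l]]
      grads$mlp$b[[l]] <- grads$mlp$b[[l]] + mb$db[[l]]
    }
    dFW <- mb$dff[38L + seq_len(config$d_output)]
    wb <- wa_backward(dFW, wa$cache, wa_par)
    grads$W_inter <- grads$W_inter + wb$dW_inter
    grads$b_inter <- grads$b_inter + wb$db_inter
    grads$W_conv <- grads$W_conv + wb$dW_conv
    grads$b_conv <- grads$b_conv + wb$db_conv
    mhb <- mh_backward(wb$dFM, mh$cache, attn)
    grads$Wo_attn <- grads$Wo_attn + mhb$dWo
    for (j in seq_len(config$h)) {
      grads$WQ[[j]] <- grads$WQ[[j]] + mhb$dWQ[[j]]
      grads$WK[[j]] <- grads$WK[[j]] + mhb$dWK[[j]]
      grads$WV[[j]] <- grads$WV[[j]] + mhb$dWV[[j]]
    }
    dHf[b, seq_len(L), ] <- mhb$dFB
    dHb[b, seq_len(L), ] <- mhb$dFB[rev(seq_len(L)), , drop = FALSE]
  }
  fb <- lstm_backward(dHf, fwd$cache, theta$lstm_f$Wx, theta$lstm_f$Wh)
  bb <- lstm_backward(dHb, bwd$cache, theta$lstm_b$Wx, theta$lstm_b$Wh)
  grads$lstm_f$Wx <- grads$lstm_f$Wx + fb$dWx
  grads$lstm_f$Wh <- grads$lstm_f$Wh + fb$dWh
  grads$lstm_f$b <- grads$lstm_f$b + fb$db
  grads$lstm_b$Wx <- grads$lstm_b$Wx + bb$dWx
  grads$lstm_b$Wh <- grads$lstm_b$Wh + bb$dWh
  grads$lstm_b$b <- grads$lstm_b$b + bb$db
  for (b in seq_len(B)) {
    L <- lens[b]
    dE <- matrix(fb$dX[b, seq_len(L), ], L) +
      matrix(bb$dX[b, seq_len(L), ], L)[rev(seq_len(L)), , drop = FALSE]
    agg <- rowsum(dE, group = batch[[b]]$idx)
    rows <- as.integer(rownames(agg))
    grads$emb[rows, ] <- grads$emb[rows, , drop = FALSE] + agg
  }
  loss <- ce / B
  if (lambda > 0) {
    loss <- loss + lambda / 2 * sum(vapply(collect_weights(theta),
                                           function(w) sum(w^2), numeric(1)))
    grads <- add_l2_grad(grads, theta, lambda)
  }
  list(loss = loss, grads = grads, p = P)
}

## ---- Adam ------------------------------------------------------------------

adam_state <- function(theta_flat) {
  list(m = theta_flat * 0, v = theta_flat * 0, t = 0L)
}

adam_step <- function(theta_flat, grad_flat, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta_flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}

## run RNG-touching code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Train model parameters on prepared examples
#'
#' Minibatch Adam on the L2-regularised cross-entropy. Deterministic for a
#' fixed config seed.
#'
#' The learning rate decays linearly to 10 percent of its initial value over
#' the epochs, which damps minibatch noise in the final iterates.
#'
#' @param examples List of prepared examples, each
#'   `list(idx = token indices, fs = standardized static vector, y = 0/1)`.
#' @param config An [essmir_config()].
#' @param theta Optional warm-start parameters (default: fresh
#'   [init_parameters()] seeded from the config).
#' @param verbose Print the loss every 10 epochs.
#' @return List with `theta` (trained parameters) and `loss_trajectory`
#'   (one mean regularised loss per epoch).
#' @export
train_parameters <- function(examples, config, theta = NULL, verbose = FALSE) {
  ys <- vapply(examples, `[[`, numeric(1), "y")
  if (length(unique(ys)) < 2L) stop("training set must contain both classes")
  with_seed(config$seed, {
    if (is.null(theta)) theta <- init_parameters(config)
    flat <- unlist(theta, use.names = FALSE)
    st <- adam_state(flat)
    traj <- numeric(config$epochs)
    n <- length(examples)
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$learning_rate *
        (1 - 0.9 * (ep - 1) / max(1L, config$epochs - 1L))
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        sel <- ord[s:min(s + config$batch_size - 1L, n)]
        lg <- essmir_loss_grad(theta, examples[sel], config)
        if (!is.finite(lg$loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               "; reduce the learning rate")
        }
        up <- adam_step(flat, unlist(lg$grads, use.names = FALSE), st, lr_ep)
        flat <- up$theta
        st <- up$state
        theta <- utils::relist(flat, theta)
        ep_loss <- ep_loss + lg$loss * length(sel)
      }
      traj[ep] <- ep_loss / n
      if (verbose && (ep %% 10L == 0L || ep == 1L)) {
        message(sprintf("epoch %3d  loss %.5f", ep, traj[ep]))
      }
    }
    list(theta = theta, loss_trajectory = traj)
  })
}
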