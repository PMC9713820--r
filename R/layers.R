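## Network layers: k-mer embedding lookup, batched (Bi)LSTM, scaled
## dot-product multi-head self-attention, weight-attention fusion and the
## MLP head. Every layer has a forward-with-cache and a matching analytic
## backward; the exported single-sequence functions are thin wrappers over
## the same code paths the trainer uses.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

#' All k-mers over the RNA alphabet
#'
#' @param k Word size.
#' @return Character vector of the 4^k k-mers in lexicographic (A,U,C,G) order.
#' @export
kmer_vocabulary <- function(k) {
  alpha <- c("A", "U", "C", "G")
  v <- alpha
  if (k > 1L) for (i in 2:k) v <- as.vector(outer(v, alpha, paste0))
  v
}

#' Embed a token sequence
#'
#' @param tokens A `"token_seq"` (see [tokenize_kmers()]) or character vector.
#' @param emb_table Numeric matrix, vocabulary x d_b.
#' @param vocab Character vector naming the rows of `emb_table`.
#' @return L x d_b matrix; row i is the embedding of token i.
#' @export
embed_tokens <- function(tokens, emb_table, vocab) {
  tok <- if (inherits(tokens, "token_seq")) tokens$tokens else tokens
  idx <- match(tok, vocab)
  if (anyNA(idx)) stop("token not in vocabulary: ", tok[which(is.na(idx))[1L]])
  emb_table[idx, , drop = FALSE]
}

## ---- LSTM (batched over sequences; padding after the true length) --------

## X: array (B, L, D); returns H (B, L, Hd) and caches for BPTT.
## Gate block order in the 4H axis: input, forget, cell, output.
lstm_forward <- function(X, Wx, Wh, b) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  Hd <- ncol(Wh) / 4L
  H <- array(0, c(B, L, Hd))
  I <- Fg <- G <- O <- Cc <- Tc <- array(0, c(B, L, Hd))
  h <- matrix(0, B, Hd); cc <- matrix(0, B, Hd)
  bm <- matrix(b, B, length(b), byrow = TRUE)
  for (t in seq_len(L)) {
    xt <- matrix(X[, t, ], nrow = B)
    a <- xt %*% Wx + h %*% Wh + bm
    i <- sigmoid(a[, 1:Hd, drop = FALSE])
    f <- sigmoid(a[, Hd + 1:Hd, drop = FALSE])
    g <- tanh(a[, 2L * Hd + 1:Hd, drop = FALSE])
    o <- sigmoid(a[, 3L * Hd + 1:Hd, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[, t, ] <- i; Fg[, t, ] <- f; G[, t, ] <- g; O[, t, ] <- o
    Cc[, t, ] <- cc; Tc[, t, ] <- tc; H[, t, ] <- h
  }
  list(H = H, cache = list(X = X, I = I, Fg = Fg, G = G, O = O, C = Cc, Tc = Tc, H = H))
}

lstm_backward <- function(dH, cache, Wx, Wh) {
  X <- cache$X
  B <- dim(X)[1L]; L <- dim(X)[2L]; Hd <- dim(cache$H)[3L]
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * Hd)
  dX <- array(0, dim(X))
  dh_next <- matrix(0, B, Hd); dc_next <- matrix(0, B, Hd)
  for (t in rev(seq_len(L))) {
    i <- matrix(cache$I[, t, ], B); f <- matrix(cache$Fg[, t, ], B)
    g <- matrix(cache$G[, t, ], B); o <- matrix(cache$O[, t, ], B)
    tc <- matrix(cache$Tc[, t, ], B)
    c_prev <- if (t > 1L) matrix(cache$C[, t - 1L, ], B) else matrix(0, B, Hd)
    h_prev <- if (t > 1L) matrix(cache$H[, t - 1L, ], B) else matrix(0, B, Hd)
    dh <- matrix(dH[, t, ], B) + dh_next
    do <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g; dg <- dc * i; df <- dc * c_prev
    dc_next <- dc * f
    dA <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2), do * o * (1 - o))
    xt <- matrix(X[, t, ], B)
    dWx <- dWx + crossprod(xt, dA)
    dWh <- dWh + crossprod(h_prev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(Wx)
    dh_next <- dA %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

#' Encode an embedded sequence with a bidirectional LSTM
#'
#' Runs a forward LSTM over positions 1..L and a backward LSTM over L..1
#' (each with hidden size equal to the input width) and returns their
#' element-wise sum at each position.
#'
#' @param E L x d_b matrix of token embeddings.
#' @param lstm List with components `f` and `b`, each `list(Wx, Wh, b)`
#'   (input, recurrent and bias parameters of one direction).
#' @return L x d_b matrix.
#' @export
bilstm_encode <- function(E, lstm) {
  L <- nrow(E); D <- ncol(E)
  X <- array(E, c(1L, L, D)) * 0
  X[1L, , ] <- E
  fwd <- lstm_forward(X, lstm$f$Wx, lstm$f$Wh, lstm$f$b)
  Xr <- X; Xr[1L, , ] <- E[rev(seq_len(L)), , drop = FALSE]
  bwd <- lstm_forward(Xr, lstm$b$Wx, lstm$b$Wh, lstm$b$b)
  Hf <- matrix(fwd$H[1L, , ], L)
  Hb <- matrix(bwd$H[1L, , ], L)[rev(seq_len(L)), , drop = FALSE]
  Hf + Hb
}

## ---- attention ------------------------------------------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with masked key positions excluded from
#' the softmax (set to -Inf before normalisation).
#'
#' @param Q,K L x d_k query/key matrices.
#' @param V L x d_v value matrix.
#' @param mask Optional logical vector of length L; `FALSE` marks padding.
#' @return L x d_v output matrix (attribute `"weights"` holds the L x L
#'   attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  sd <- sdpa_forward(Q, K, V, mask)
  structure(sd$out, weights = sd$A)
}

sdpa_forward <- function(Q, K, V, mask = NULL) {
  dk <- ncol(K)
  S <- tcrossprod(Q, K) / sqrt(dk)
  if (!is.null(mask)) {
    if (!any(mask)) stop("attention mask excludes every position")
    S[, !mask] <- -Inf
  }
  S <- sweep(S, 1L, apply(S, 1L, max), "-")
  Ex <- exp(S)
  A <- Ex / rowSums(Ex)
  list(out = A %*% V, A = A)
}

sdpa_backward <- function(dOut, A, Q, K, V) {
  dk <- ncol(K)
  dA <- dOut %*% t(V)
  dV <- crossprod(A, dOut)
  dS <- A * (dA - rowSums(dA * A))
  list(dQ = dS %*% K / sqrt(dk), dK = crossprod(dS, Q) / sqrt(dk), dV = dV)
}

#' Multi-head self-attention mapped to the static-feature width
#'
#' Each head projects the BiLSTM features to queries, keys and values,
#' applies scaled dot-product attention, and the concatenated heads are
#' mapped by an output matrix to `d_output` (38) columns per position.
#'
#' @param FB L x d_input matrix (BiLSTM features; queries = keys = values).
#' @param attn List with `WQ`, `WK`, `WV` (lists of per-head projection
#'   matrices) and `Wo` ((h d_v) x d_output).
#' @param mask Optional logical vector of length L.
#' @return L x d_output matrix.
#' @export
multi_head <- function(FB, attn, mask = NULL) {
  mh_forward(FB, attn, mask)$out
}

mh_forward <- function(FB, attn, mask = NULL) {
  h <- length(attn$WQ)
  heads <- vector("list", h)
  for (j in seq_len(h)) {
    Q <- FB %*% attn$WQ[[j]]
    K <- FB %*% attn$WK[[j]]
    V <- FB %*% attn$WV[[j]]
    sd <- sdpa_forward(Q, K, V, mask)
    heads[[j]] <- list(Q = Q, K = K, V = V, A = sd$A, out = sd$out)
  }
  Cmat <- do.call(cbind, lapply(heads, `[[`, "out"))
  list(out = Cmat %*% attn$Wo, cache = list(heads = heads, Cmat = Cmat, FB = FB))
}

mh_backward <- function(dFM, cache, attn) {
  h <- length(attn$WQ)
  dv <- ncol(cache$heads[[1L]]$V)
  dC <- dFM %*% t(attn$Wo)
  dWo <- crossprod(cache$Cmat, dFM)
  FB <- cache$FB
  dFB <- matrix(0, nrow(FB), ncol(FB))
  dWQ <- dWK <- dWV <- vector("list", h)
  for (j in seq_len(h)) {
    hd <- cache$heads[[j]]
    dHead <- dC[, (j - 1L) * dv + seq_len(dv), drop = FALSE]
    bk <- sdpa_backward(dHead, hd$A, hd$Q, hd$K, hd$V)
    dWQ[[j]] <- crossprod(FB, bk$dQ)
    dWK[[j]] <- crossprod(FB, bk$dK)
    dWV[[j]] <- crossprod(FB, bk$dV)
    dFB <- dFB + bk$dQ %*% t(attn$WQ[[j]]) + bk$dK %*% t(attn$WK[[j]]) +
      bk$dV %*% t(attn$WV[[j]])
  }
  list(dFB = dFB, dWQ = dWQ, dWK = dWK, dWV = dWV, dWo = dWo)
}

## ---- weight attention ------------------------------------------------------

#' Weight-attention fusion of static and attention features
#'
#' Computes `h_m = ReLU(W_inter f_s + b_inter)`,
#' `h_i = ReLU(W_conv F_M[i,] + b_conv)`, per-position affinities
#' `alpha_i = sigmoid(h_m . h_i)` and the fused vector
#' `F_W = sum_i alpha_i h_i` over unmasked positions.
#'
#' @param fs_std Standardized static feature vector (length 38).
#' @param FM L x 38 matrix of attention features.
#' @param wa List with `W_inter`, `b_inter`, `W_conv`, `b_conv`.
#' @param mask Optional logical vector of length L.
#' @return Numeric vector of length 38 (attribute `"alpha"` holds the
#'   per-position weights).
#' @export
weight_attention <- function(fs_std, FM, wa, mask = NULL) {
  w <- wa_forward(fs_std, FM, wa, mask)
  structure(w$FW, alpha = w$alpha)
}

wa_forward <- function(fs_std, FM, wa, mask = NULL) {
  if (nrow(FM) == 0L) stop("weight attention needs at least one position")
  pre_m <- drop(wa$W_inter %*% fs_std) + wa$b_inter
  hm <- relu(pre_m)
  pre_i <- FM %*% t(wa$W_conv) + matrix(wa$b_conv, nrow(FM), length(wa$b_conv), byrow = TRUE)
  Hi <- relu(pre_i)
  s <- drop(Hi %*% hm)
  alpha <- sigmoid(s)
  if (!is.null(mask)) {
    if (!any(mask)) stop("weight attention mask excludes every position")
    alpha[!mask] <- 0
  }
  FW <- drop(crossprod(Hi, alpha))
  list(FW = FW, alpha = alpha,
       cache = list(fs = fs_std, pre_m = pre_m, hm = hm, pre_i = pre_i,
                    Hi = Hi, alpha = alpha, FM = FM, mask = mask))
}

wa_backward <- function(dFW, cache, wa) {
  Hi <- cache$Hi; alpha <- cache$alpha
  live <- if (is.null(cache$mask)) rep(TRUE, length(alpha)) else cache$mask
  dalpha <- drop(Hi %*% dFW) * live
  dHi <- alpha %o% dFW
  ds <- dalpha * alpha * (1 - alpha)
  dhm <- drop(crossprod(Hi, ds))
  dHi <- dHi + ds %o% cache$hm
  dpre_i <- dHi * (cache$pre_i > 0)
  dW_conv <- crossprod(dpre_i, cache$FM)
  db_conv <- colSums(dpre_i)
  dFM <- dpre_i %*% wa$W_conv
  dpre_m <- dhm * (cache$pre_m > 0)
  dW_inter <- dpre_m %o% cache$fs
  db_inter <- dpre_m
  list(dFM = dFM, dW_inter = dW_inter, db_inter = db_inter,
       dW_conv = dW_conv, db_conv = db_conv)
}

## ---- MLP head --------------------------------------------------------------

#' MLP head on the fused feature
#'
#' ReLU hidden layers followed by a linear map to the two class logits.
#'
#' @param ff Fused feature vector (length d_f).
#' @param mlp List with `W` (list of hidden weight matrices, out x in),
#'   `b` (list of hidden biases), `W_out` (2 x last hidden), `b_out` (2).
#' @return Numeric logit vector of length 2.
#' @export
mlp_forward <- function(ff, mlp) {
  mlp_forward_cache(ff, mlp)$z
}

mlp_forward_cache <- function(ff, mlp) {
  if (length(ff) != ncol(mlp$W[[1L]])) {
    stop("feature length ", length(ff), " does not match MLP input width ",
         ncol(mlp$W[[1L]]))
  }
  acts <- list(ff)
  pres <- list()
  hcur <- ff
  for (l in seq_along(mlp$W)) {
    pre <- drop(mlp$W[[l]] %*% hcur) + mlp$b[[l]]
    hcur <- relu(pre)
    pres[[l]] <- pre
    acts[[l + 1L]] <- hcur
  }
  z <- drop(mlp$W_out %*% hcur) + mlp$b_out
  list(z = z, cache = list(acts = acts, pres = pres))
}

mlp_backward <- function(dz, cache, mlp) {
  nl <- length(mlp$W)
  dW_out <- dz %o% cache$acts[[nl + 1L]]
  db_out <- dz
  dh <- drop(crossprod(mlp$W_out, dz))
  dW <- db <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    dpre <- dh * (cache$pres[[l]] > 0)
    dW[[l]] <- dpre %o% cache$acts[[l]]
    db[[l]] <- dpre
    dh <- drop(crossprod(mlp$W[[l]], dpre))
  }
  list(dff = dh, dW = dW, db = db, dW_out = dW_out, db_out = db_out)
}

#' Class probabilities from logits
#'
#' Numerically stabilized softmax (max subtraction).
#'
#' @param z Numeric logit vector.
#' @return Probability vector summing to 1.
#' @export
softmax_proba <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

#' L2-regularised cross-entropy loss
#'
#' Mean cross-entropy of predicted class probabilities against one-hot
#' labels, plus `lambda/2` times the squared norm of all weight matrices
#' (biases excluded). Probabilities below 1e-12 at the true label are
#' clamped with a warning.
#'
#' @param p N x 2 matrix of class probabilities (rows sum to 1).
#' @param y Integer vector of labels (0/1), length N.
#' @param theta Optional parameter set (see [init_parameters()]) for the
#'   regularisation term.
#' @param lambda L2 coefficient.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(p, y, theta = NULL, lambda = 0) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  pt <- p[cbind(seq_len(nrow(p)), y + 1L)]
  if (any(pt < 1e-12)) {
    warning("predicted probability at true label clamped to 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  ce <- -mean(log(pt))
  if (lambda > 0 && !is.null(theta)) {
    ce <- ce + lambda / 2 * sum(vapply(collect_weights(theta),
                                       function(w) sum(w^2), numeric(1)))
  }
  ce
}
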