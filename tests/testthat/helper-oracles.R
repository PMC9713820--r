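# Independent brute-force oracles used to validate the package's dynamic
# programming and network algebra. These deliberately share no code with the
# implementation: plain loops and exhaustive enumeration only.

# all legal secondary structures (lists of pair index pairs) on positions
# i..j: non-crossing, complementary, min_loop unpaired inside every pair
enumerate_structures <- function(ch, i, j, min_loop = 3L,
                                 pairs_ok = c("AU", "UA", "CG", "GC", "GU", "UG")) {
  if (i >= j) return(list(list()))
  out <- lapply(enumerate_structures(ch, i + 1L, j, min_loop, pairs_ok),
                identity)  # i unpaired
  if (i + min_loop + 1L > j) return(out)
  for (k in seq.int(i + min_loop + 1L, j)) {
    if (!paste0(ch[i], ch[k]) %in% pairs_ok) next
    inner <- enumerate_structures(ch, i + 1L, k - 1L, min_loop, pairs_ok)
    outer_ <- enumerate_structures(ch, k + 1L, j, min_loop, pairs_ok)
    for (a in inner) for (b in outer_) {
      out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
  }
  out
}

# max pairs and enumeration-based pair probabilities for short sequences
oracle_fold <- function(seq_str, min_loop = 3L, w = exp(1)) {
  ch <- strsplit(seq_str, "")[[1L]]
  L <- length(ch)
  structs <- enumerate_structures(ch, 1L, L, min_loop)
  npairs <- vapply(structs, length, integer(1))
  weights <- w^npairs
  Z <- sum(weights)
  P <- matrix(0, L, L)
  for (s in seq_along(structs)) {
    for (pr in structs[[s]]) {
      P[pr[1L], pr[2L]] <- P[pr[1L], pr[2L]] + weights[s]
    }
  }
  P <- P / Z
  P <- P + t(P)
  list(max_pairs = max(npairs), Z = Z, P = P, n_structures = length(structs))
}

random_rna <- function(L) paste(sample(c("A", "U", "C", "G"), L, replace = TRUE),
                                collapse = "")

# naive softmax-attention with explicit scalar loops
oracle_attention <- function(Q, K, V, mask = NULL) {
  L <- nrow(Q); dk <- ncol(K)
  out <- matrix(0, L, ncol(V))
  for (i in seq_len(L)) {
    s <- numeric(L)
    for (j in seq_len(L)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    if (!is.null(mask)) s[!mask] <- -Inf
    e <- exp(s - max(s))
    a <- e / sum(e)
    for (j in seq_len(L)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# index-by-index transcription of the multi-head equations
oracle_multi_head <- function(FB, attn, mask = NULL) {
  h <- length(attn$WQ)
  concat <- NULL
  for (j in seq_len(h)) {
    head <- oracle_attention(FB %*% attn$WQ[[j]], FB %*% attn$WK[[j]],
                             FB %*% attn$WV[[j]], mask)
    concat <- cbind(concat, head)
  }
  concat %*% attn$Wo
}

# scalar-loop transcription of the weight-attention equations
oracle_weight_attention <- function(fs, FM, wa, mask = NULL) {
  relu_ <- function(v) ifelse(v > 0, v, 0)
  hm <- relu_(as.numeric(wa$W_inter %*% fs) + wa$b_inter)
  L <- nrow(FM)
  FW <- numeric(length(hm))
  for (i in seq_len(L)) {
    if (!is.null(mask) && !mask[i]) next
    hi <- relu_(as.numeric(wa$W_conv %*% FM[i, ]) + wa$b_conv)
    alpha <- 1 / (1 + exp(-sum(hm * hi)))
    FW <- FW + alpha * hi
  }
  FW
}

# pairwise-comparison AUC (normalized Mann-Whitney U, ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# central finite differences of the training loss over the flat parameters
numeric_gradient <- function(theta, examples, config, eps = 1e-6) {
  flat <- unlist(theta, use.names = FALSE)
  lossf <- function(v) {
    essmir:::essmir_loss_grad(utils::relist(v, theta), examples, config)$loss
  }
  g <- numeric(length(flat))
  for (i in seq_along(flat)) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    g[i] <- (lossf(vp) - lossf(vm)) / (2 * eps)
  }
  g
}

# small labeled toy record used across test files: mature = positions [3, 18)
toy_record <- function() {
  pre <- normalize_sequence("GGGAAAUUUCCCAAAGGGAAAUUUCCC", "toy-pre")
  mat <- normalize_sequence("AAAUUUCCCAAAGGG", "toy-mat")
  pair_precursor_matures(list(pre), list(mat),
                         mapping = list("toy-pre" = "toy-mat"),
                         labels = c("toy-pre" = 1L))[[1L]]
}

# a small config that keeps network tests fast
tiny_config <- function(...) {
  essmir_config(k = 2, d_b = 8, d_k = 4, d_v = 4, h = 2, mlp_hidden = 16L,
                epochs = 5L, batch_size = 4L, seed = 7L, ...)
}

mature_sequences_for_test <- function(r) essmir:::mature_sequences(r)[1]

record_ids_for_test <- function(recs) {
  vapply(recs, function(r) r$precursor$id, character(1))
}
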