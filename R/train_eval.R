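## Model fitting, prediction and stratified cross-validated evaluation.

prepare_examples <- function(records, fs_std_matrix, config, vocab) {
  lapply(seq_along(records), function(i) {
    toks <- tokenize_kmers(records[[i]]$precursor, config$k)
    idx <- match(toks$tokens, vocab)
    list(idx = idx, fs = as.numeric(fs_std_matrix[i, ]),
         y = records[[i]]$label)
  })
}

#' Fit an essential-miRNA classifier
#'
#' Computes the 38-dimensional static feature for every record, fits a
#' z-score standardizer on these (training) records, and trains the fused
#' sequence/static network by minibatch Adam on L2-regularised
#' cross-entropy.
#'
#' @param records List of labeled `"mirna_record"` objects (both classes
#'   required).
#' @param config An [essmir_config()].
#' @param engine A [structure_engine()] used for the folding block of the
#'   static feature.
#' @param static_matrix Optional precomputed (unstandardized) static feature
#'   matrix for `records` (rows in the same order), e.g. from
#'   [static_feature_matrix()]; saves refolding.
#' @param verbose Print training progress.
#' @return Object of class `"essmir"` with elements `theta`, `config`,
#'   `vocab`, `standardizer`, `loss_trajectory`, `engine` and `call`.
#' @export
essmir <- function(records, config = essmir_config(),
                   engine = structure_engine("reference"),
                   static_matrix = NULL, verbose = FALSE) {
  labs <- record_labels(records)
  if (anyNA(labs)) stop("all training records must be labeled")
  if (length(unique(labs)) < 2L) stop("training set must contain both classes")
  if (is.null(static_matrix)) static_matrix <- static_feature_matrix(records, engine)
  std <- fit_standardizer(static_matrix)
  fs_std <- apply_standardizer(static_matrix, std)
  vocab <- kmer_vocabulary(config$k)
  ex <- prepare_examples(records, fs_std, config, vocab)
  tr <- train_parameters(ex, config, verbose = verbose)
  structure(list(theta = tr$theta, config = config, vocab = vocab,
                 standardizer = std, loss_trajectory = tr$loss_trajectory,
                 engine = engine, n_train = length(records),
                 call = match.call()),
            class = "essmir")
}

#' @export
print.essmir <- function(x, ...) {
  cat("Essential-miRNA classifier (BiLSTM + multi-head attention + static fusion)\n")
  cat(sprintf("  trained on %d records; k=%d, d_b=%d, h=%d heads, %d epochs\n",
              x$n_train, x$config$k, x$config$d_b, x$config$h, x$config$epochs))
  cat(sprintf("  final training loss: %.4f\n",
              x$loss_trajectory[length(x$loss_trajectory)]))
  invisible(x)
}

#' @export
summary.essmir <- function(object, ...) {
  npar <- length(unlist(object$theta, use.names = FALSE))
  cat("Essential-miRNA classifier\n")
  print(object$config)
  cat(sprintf("  parameters: %d; vocabulary: %d %d-mers; folding engine: %s\n",
              npar, length(object$vocab), object$config$k, object$engine$name))
  cat(sprintf("  training loss: initial %.4f -> final %.4f over %d epochs\n",
              object$loss_trajectory[1L],
              object$loss_trajectory[length(object$loss_trajectory)],
              length(object$loss_trajectory)))
  invisible(object)
}

#' @export
coef.essmir <- function(object, ...) object$theta

#' @export
plot.essmir <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trajectory), x$loss_trajectory, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "Training loss trajectory", ...)
  invisible(x)
}

#' Predict essentiality for new records
#'
#' @param object A fitted `"essmir"` model.
#' @param newdata List of `"mirna_record"` objects.
#' @param type `"prob"` (probability of the essential class), `"class"`
#'   (0/1 at `threshold`), or `"feature"` (the fused d_f feature matrix,
#'   e.g. for external dimensionality-reduction plots).
#' @param threshold Classification threshold on the essential-class
#'   probability.
#' @param static_matrix Optional precomputed static feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities or classes (named by record id),
#'   or a feature matrix for `type = "feature"`.
#' @export
predict.essmir <- function(object, newdata, type = c("prob", "class", "feature"),
                           threshold = 0.5, static_matrix = NULL, ...) {
  type <- match.arg(type)
  if (is.null(static_matrix)) {
    static_matrix <- static_feature_matrix(newdata, object$engine)
  }
  fs_std <- apply_standardizer(static_matrix, object$standardizer)
  outs <- lapply(seq_along(newdata), function(i) {
    essmir_forward(newdata[[i]], as.numeric(fs_std[i, ]), object$theta,
                   object$vocab, object$config)
  })
  ids <- record_ids(newdata)
  if (type == "feature") {
    m <- do.call(rbind, lapply(outs, `[[`, "Ff"))
    rownames(m) <- ids
    colnames(m) <- c(colnames(static_matrix), paste0("FW.", seq_len(object$config$d_output)))
    return(m)
  }
  p1 <- vapply(outs, function(o) o$p[2L], numeric(1))
  names(p1) <- ids
  if (type == "class") return(as.integer(p1 >= threshold))
  p1
}

## ---- metrics ---------------------------------------------------------------

#' AUC, accuracy and F1 of scores against binary labels
#'
#' AUC is computed by the rank (Mann-Whitney) method with ties contributing
#' 0.5; accuracy and F1 are evaluated at `threshold`.
#'
#' @param scores Numeric scores (higher = more likely essential).
#' @param labels 0/1 labels.
#' @param threshold Classification threshold (default 0.5).
#' @return Named list `auc`, `acc`, `f1`. With a single class present, `auc`
#'   is `NA`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  auc <- if (npos == 0L || nneg == 0L) NA_real_ else {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- mean(pred == labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(auc = auc, acc = acc, f1 = f1)
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals members across folds so that per-class
#' counts and total fold sizes each differ by at most one.
#'
#' @param labels 0/1 label vector.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold indices in 1..n_folds, same length as
#'   `labels`.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  tab <- table(factor(labels, levels = c(1, 0)))
  if (any(tab < n_folds)) {
    stop("every class needs at least ", n_folds, " members for ", n_folds, " folds")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cls in c(1, 0)) {  # deal positives first, then negatives
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  folds
}

#' Sample negative records from an unlabeled pool
#'
#' Uniform sample without replacement; sampled records get label 0.
#'
#' @param pool List of `"mirna_record"` objects.
#' @param n Number to draw.
#' @param seed RNG seed.
#' @return List of `n` records with label 0.
#' @export
sample_negatives <- function(pool, n, seed = 1L) {
  if (length(pool) < n) {
    stop("negative pool (", length(pool), ") smaller than requested n = ", n)
  }
  sel <- with_seed(seed, sample.int(length(pool), n))
  lapply(pool[sel], function(r) { r$label <- 0L; r })
}

#' Stratified k-fold cross-validation
#'
#' For each fold, fits the full pipeline on the remaining folds (static
#' features standardized with training-fold statistics only) and scores the
#' held-out records. Reports per-fold AUC/ACC/F1, the AUC of the pooled
#' out-of-fold scores (a single ROC over all records), and fold-mean
#' metrics.
#'
#' @param records Labeled `"mirna_record"` list.
#' @param config An [essmir_config()]; its seed also drives fold assignment
#'   unless `seed` is given.
#' @param n_folds Number of folds (default 5).
#' @param seed Fold/assignment seed (default `config$seed`).
#' @param engine A [structure_engine()].
#' @param verbose Print per-fold progress.
#' @return Object of class `"essmir_cv"`: per-fold metrics, pooled
#'   out-of-fold scores and labels, aggregate metrics, fold assignments and
#'   the config snapshot.
#' @export
essmir_cv <- function(records, config = essmir_config(), n_folds = 5L,
                      seed = config$seed, engine = structure_engine("reference"),
                      verbose = FALSE) {
  labs <- record_labels(records)
  if (anyNA(labs)) stop("all records must be labeled for cross-validation")
  folds <- make_folds(labs, n_folds, seed)
  static_all <- static_feature_matrix(records, engine)  # unstandardized; pure per-record
  scores <- numeric(length(records))
  fold_rows <- vector("list", n_folds)
  for (fd in seq_len(n_folds)) {
    tr_idx <- which(folds != fd)
    te_idx <- which(folds == fd)
    fold_cfg <- config
    fold_cfg$seed <- config$seed + fd  # independent init/shuffling per fold
    fit <- essmir(records[tr_idx], fold_cfg, engine,
                  static_matrix = static_all[tr_idx, , drop = FALSE])
    p1 <- predict(fit, records[te_idx],
                  static_matrix = static_all[te_idx, , drop = FALSE])
    scores[te_idx] <- p1
    m <- compute_metrics(p1, labs[te_idx])
    fold_rows[[fd]] <- data.frame(fold = fd, n = length(te_idx),
                                  n_pos = sum(labs[te_idx] == 1),
                                  auc = m$auc, acc = m$acc, f1 = m$f1)
    if (verbose) {
      message(sprintf("fold %d/%d: AUC %.4f ACC %.4f F1 %.4f",
                      fd, n_folds, m$auc, m$acc, m$f1))
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  pooled <- compute_metrics(scores, labs)
  structure(list(per_fold = per_fold,
                 auc_pooled = pooled$auc,
                 auc_mean = mean(per_fold$auc),
                 acc_mean = mean(per_fold$acc),
                 f1_mean = mean(per_fold$f1),
                 acc_pooled = pooled$acc, f1_pooled = pooled$f1,
                 scores = scores, labels = labs, folds = folds,
                 threshold = 0.5, seed = seed, n_folds = n_folds,
                 config = config, engine = engine$name),
            class = "essmir_cv")
}

#' @export
print.essmir_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d records, seed %d, engine %s)\n",
              x$n_folds, length(x$labels), x$seed, x$engine))
  print(x$per_fold, row.names = FALSE, digits = 4)
  cat(sprintf("pooled AUC %.4f | mean AUC %.4f | mean ACC %.4f | mean F1 %.4f\n",
              x$auc_pooled, x$auc_mean, x$acc_mean, x$f1_mean))
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' @param report An `"essmir_cv"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  out <- list(n_folds = report$n_folds, seed = report$seed,
              engine = report$engine, threshold = report$threshold,
              per_fold = report$per_fold,
              auc_pooled = report$auc_pooled, auc_mean = report$auc_mean,
              acc_mean = report$acc_mean, f1_mean = report$f1_mean,
              config = unclass(report$config),
              folds = report$folds, scores = report$scores,
              labels = report$labels)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
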