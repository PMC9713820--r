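## RNA secondary-structure quantities behind a pluggable engine contract.
## The built-in reference engine (maximum base pairing + a McCaskill-style
## partition function over the same structure space) keeps the whole test
## path free of external binaries; the "vienna" engine shells out to RNAfold
## for thermodynamic values.

WATSON_CRICK_WOBBLE <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Create a folding-engine handle
#'
#' @param name `"reference"` (built-in maximum base pairing + partition
#'   function) or `"vienna"` (RNAfold adapter; requires the RNAfold binary on
#'   the PATH).
#' @param min_loop Minimum hairpin loop size (unpaired bases enclosed by a
#'   pair); default 3, the standard steric constraint.
#' @param pair_weight Boltzmann weight per base pair for the reference
#'   partition function; default `exp(1)`.
#' @param allowed_pairs Character vector of allowed pair types.
#' @return An object of class `"fold_engine"`.
#' @export
structure_engine <- function(name = c("reference", "vienna"), min_loop = 3L,
                             pair_weight = exp(1),
                             allowed_pairs = WATSON_CRICK_WOBBLE) {
  name <- match.arg(name)
  if (pair_weight <= 0) stop("pair_weight must be > 0")
  if (name == "vienna" && Sys.which("RNAfold") == "") {
    stop("RNAfold binary not found on PATH; use structure_engine(\"reference\") instead")
  }
  structure(list(name = name, min_loop = as.integer(min_loop),
                 pair_weight = pair_weight, allowed_pairs = allowed_pairs),
            class = "fold_engine")
}

residue_vector <- function(seq) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  strsplit(s, "", fixed = TRUE)[[1L]]
}

## L x L logical matrix: TRUE where (i, j) may pair (complementarity + loop).
pairable_matrix <- function(ch, min_loop, allowed_pairs) {
  L <- length(ch)
  M <- matrix(FALSE, L, L)
  if (L >= min_loop + 2L) {
    for (i in seq_len(L - min_loop - 1L)) {
      js <- (i + min_loop + 1L):L
      M[i, js] <- paste0(ch[i], ch[js]) %in% allowed_pairs
    }
  }
  M | t(M)
}

#' Maximum base-pairing structure (reference engine)
#'
#' Nussinov-style dynamic programming maximising the number of base pairs,
#' with deterministic traceback: at each interval, pairing the leftmost
#' position with its smallest optimal partner is preferred.
#'
#' @param seq An `"rna_seq"` or residue string.
#' @param min_loop Minimum hairpin loop size.
#' @param allowed_pairs Allowed pair types.
#' @return List of class `"mfe_result"`: `structure` (dot-bracket), `energy`
#'   (pseudo-energy, minus the pair count; not kcal/mol), `pair_count`, and
#'   `pairs` (2-column matrix of 1-based paired positions).
#' @export
reference_nussinov <- function(seq, min_loop = 3L, allowed_pairs = WATSON_CRICK_WOBBLE) {
  ch <- residue_vector(seq)
  L <- length(ch)
  ok <- pairable_matrix(ch, min_loop, allowed_pairs)
  N <- matrix(0L, L + 1L, L + 1L)  # N[i, j]: max pairs on i..j (extra row/col guard)
  if (L >= 2L) {
    for (s in seq_len(L - 1L)) {
      for (i in seq_len(L - s)) {
        j <- i + s
        best <- N[i + 1L, j]
        ks <- which(ok[i, i:j]) + i - 1L
        if (length(ks)) {
          # guard row/col of N are zero, so degenerate subintervals contribute 0
          inner <- 1L + N[cbind(i + 1L, ks - 1L)] + N[cbind(ks + 1L, j)]
          best <- max(best, inner)
        }
        N[i, j] <- best
      }
    }
  }
  ## traceback
  pairs <- matrix(0L, 0L, 2L)
  stack <- list(c(1L, L))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || N[i, j] == 0L) next
    placed <- FALSE
    ks <- which(ok[i, i:j]) + i - 1L
    for (k in ks) {
      left <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
      right <- if (k + 1L <= j) N[k + 1L, j] else 0L
      if (1L + left + right == N[i, j]) {
        pairs <- rbind(pairs, c(i, k))
        if (k - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        placed <- TRUE
        break
      }
    }
    if (!placed) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  db <- rep(".", L)
  if (nrow(pairs)) { db[pairs[, 1L]] <- "("; db[pairs[, 2L]] <- ")" }
  structure(list(structure = paste(db, collapse = ""),
                 energy = -as.numeric(N[1L, L]),
                 pair_count = as.integer(N[1L, L]),
                 pairs = pairs),
            class = "mfe_result")
}

#' Base-pair probability matrix (reference partition function)
#'
#' McCaskill-style inside/outside dynamic programming over the same
#' structure space as [reference_nussinov()] (non-crossing pairs, minimum
#' loop size, allowed pair set), with a uniform Boltzmann weight per pair:
#' each structure has weight `pair_weight^pairs`, and
#' `p[i, j]` is the probability that positions i and j are paired.
#'
#' @inheritParams reference_nussinov
#' @param pair_weight Boltzmann weight per pair (> 0).
#' @return L x L symmetric numeric matrix of pair probabilities.
#' @export
reference_partition <- function(seq, min_loop = 3L, pair_weight = exp(1),
                                allowed_pairs = WATSON_CRICK_WOBBLE) {
  if (pair_weight <= 0) stop("pair_weight must be > 0")
  ch <- residue_vector(seq)
  L <- length(ch)
  if (L > 250L) {
    stop("reference_partition supports sequences up to 250 nt (got ", L, ")")
  }
  ok <- pairable_matrix(ch, min_loop, allowed_pairs)
  w <- pair_weight
  ## Zp[i+1, j+1] = inside partition function over interval i..j; empty = 1.
  Zp <- matrix(1, L + 2L, L + 2L)
  Zin <- function(i, j) Zp[i + 1L, j + 1L]  # scalar accessor, i > j -> 1
  if (L >= 2L) {
    for (s in seq_len(L - 1L)) {
      for (i in seq_len(L - s)) {
        j <- i + s
        z <- Zp[i + 2L, j + 1L]  # i unpaired
        ks <- which(ok[i, i:j]) + i - 1L
        if (length(ks)) {
          z <- z + sum(w * Zp[cbind(i + 2L, ks)] * Zp[cbind(ks + 2L, j + 1L)])
        }
        Zp[i + 1L, j + 1L] <- z
      }
    }
  }
  Ztot <- Zin(1L, L)
  if (!is.finite(Ztot)) {
    stop("partition function overflowed; reduce pair_weight or sequence length")
  }
  ## Outside pass. Zout[i, j]: weight of all exterior configurations given
  ## (i, j) paired, excluding the pair's own weight and interior.
  ##   Zout[i, j] = Z(1, i-1) Z(j+1, L) +
  ##                sum_{q > j} OutR[i, q] Z(j+1, q-1)
  ##   OutR[i, q] = sum_{p < i, (p,q) pairable} w Zout[p, q] Z(p+1, i-1)
  ## processed in increasing i so every Zout[p, q] with p < i is ready.
  P <- matrix(0, L, L)
  if (any(ok)) {
    Zout <- matrix(0, L, L)
    OutR <- matrix(0, L, L)
    for (i in seq_len(L)) {
      if (i >= 2L) {
        for (q in seq_len(L)) {
          ps <- which(ok[seq_len(i - 1L), q])
          if (length(ps)) {
            OutR[i, q] <- sum(w * Zout[cbind(ps, q)] * Zp[cbind(ps + 2L, i)])
          }
        }
      }
      js <- which(ok[i, ])
      js <- js[js > i]
      for (j in js) {
        z <- Zin(1L, i - 1L) * Zin(j + 1L, L)
        if (j < L) {
          qs <- (j + 1L):L
          z <- z + sum(OutR[i, qs] * Zp[cbind(j + 2L, qs)])
        }
        Zout[i, j] <- z
        P[i, j] <- w * Zin(i + 1L, j - 1L) * z / Ztot
      }
    }
  }
  P <- P + t(P)
  dimnames(P) <- NULL
  P
}

#' Fold a sequence with the selected engine
#'
#' @param seq An `"rna_seq"` or residue string.
#' @param engine A [structure_engine()] handle.
#' @return An `"mfe_result"`; for the reference engine `energy` is the
#'   pseudo-energy minus-pair-count, for vienna it is the MFE in kcal/mol.
#' @export
fold_mfe <- function(seq, engine = structure_engine("reference")) {
  stopifnot(inherits(engine, "fold_engine"))
  if (engine$name == "reference") {
    reference_nussinov(seq, engine$min_loop, engine$allowed_pairs)
  } else {
    vienna_fold(seq)$mfe
  }
}

#' Base-pair probabilities with the selected engine
#'
#' @inheritParams fold_mfe
#' @return L x L symmetric probability matrix.
#' @export
pair_probabilities <- function(seq, engine = structure_engine("reference")) {
  stopifnot(inherits(engine, "fold_engine"))
  if (engine$name == "reference") {
    reference_partition(seq, engine$min_loop, engine$pair_weight, engine$allowed_pairs)
  } else {
    vienna_fold(seq, partition = TRUE)$probs
  }
}

## RNAfold adapter: one sequence per call, run in a scratch dir so the
## PostScript dot plot never lands in the user's cwd.
vienna_fold <- function(seq, partition = FALSE) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  L <- nchar(s)
  dir <- tempfile("vienna")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  infile <- file.path(dir, "in.fa")
  writeLines(c(">q", s), infile)
  owd <- setwd(dir); on.exit(setwd(owd), add = TRUE)
  args <- c("--noPS", if (partition) "-p", "in.fa")
  out <- suppressWarnings(system2("RNAfold", args, stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("RNAfold failed: ", paste(out, collapse = "\n"))
  }
  mfe_line <- out[3L]
  db <- sub("\\s.*$", "", mfe_line)
  energy <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", mfe_line))
  mfe <- structure(list(structure = db, energy = energy,
                        pair_count = sum(strsplit(db, "")[[1L]] == "("),
                        pairs = NULL),
                   class = "mfe_result")
  probs <- NULL
  if (partition) {
    dp <- readLines("q_dp.ps")
    ub <- grep("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", dp, value = TRUE)
    probs <- matrix(0, L, L)
    if (length(ub)) {
      f <- do.call(rbind, lapply(strsplit(ub, " "), function(x) as.numeric(x[1:3])))
      probs[f[, 1:2, drop = FALSE]] <- f[, 3L]^2
      probs <- probs + t(probs)
    }
  }
  list(mfe = mfe, probs = probs)
}

#' Ensemble and energy metrics of a folded sequence
#'
#' Computes, for a sequence of length L with MFE result and base-pair
#' probability matrix `p`:
#' \itemize{
#'   \item `mfe`, `nmfe = mfe / L`
#'   \item base-pairing propensity `dP = pair_count / L`
#'   \item Shannon entropy `dQ = -(1/L) sum_{i<j} p_ij log2 p_ij`
#'   \item base-pair distance (ensemble diversity)
#'     `dD = (1/L) sum_{i<j} p_ij (1 - p_ij)`
#'   \item each of dP/dQ/dD additionally divided by L once more
#'     (`dP_L`, `dQ_L`, `dD_L`).
#' }
#'
#' @param seq An `"rna_seq"` or residue string.
#' @param mfe An `"mfe_result"` for the same sequence.
#' @param probs L x L base-pair probability matrix for the same sequence.
#' @return List of class `"fold_metrics"` with fields `mfe`, `nmfe`, `dP`,
#'   `dP_L`, `dQ`, `dQ_L`, `dD`, `dD_L`.
#' @export
structure_metrics <- function(seq, mfe, probs) {
  ch <- residue_vector(seq)
  L <- length(ch)
  if (!all(dim(probs) == c(L, L))) {
    stop("probability matrix dimension ", nrow(probs), " does not match |S| = ", L)
  }
  up <- probs[upper.tri(probs)]
  pos <- up[up > 0]
  dQ <- if (length(pos)) -sum(pos * log2(pos)) / L else 0
  dD <- sum(up * (1 - up)) / L
  dP <- mfe$pair_count / L
  structure(list(mfe = mfe$energy, nmfe = mfe$energy / L,
                 dP = dP, dP_L = dP / L, dQ = dQ, dQ_L = dQ / L,
                 dD = dD, dD_L = dD / L),
            class = "fold_metrics")
}

#' Fold metrics for a record or sequence in one call
#'
#' @param seq An `"rna_seq"`, `"mirna_record"` or residue string.
#' @param engine A [structure_engine()] handle.
#' @return A `"fold_metrics"` list (see [structure_metrics()]).
#' @export
fold_metrics <- function(seq, engine = structure_engine("reference")) {
  if (inherits(seq, "mirna_record")) seq <- seq$precursor
  if (engine$name == "vienna") {
    vf <- vienna_fold(seq, partition = TRUE)
    structure_metrics(seq, vf$mfe, vf$probs)
  } else {
    structure_metrics(seq, fold_mfe(seq, engine), pair_probabilities(seq, engine))
  }
}
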