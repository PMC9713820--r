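## The 38-dimensional statistic-and-structure feature of a precursor/mature
## pair: base contents (U, C, G) of precursor, mature and non-mature parts,
## mature and non-mature lengths, the ternary cleavage-site class,
## dinucleotide counts over {U, C, G} for precursor and mature, and the
## folding block (MFE, nMFE, dP, dP/L, dQ, dQ/L, dD, dD/L).

DINUC_ORDER <- c("UU", "UC", "UG", "CU", "CC", "CG", "GU", "GC", "GG")

STATIC_FEATURE_NAMES <- c(
  paste0("pre_content.", c("U", "C", "G")),
  paste0("mat_content.", c("U", "C", "G")),
  paste0("nonmat_content.", c("U", "C", "G")),
  "mat_length", "nonmat_length", "cleavage_class",
  paste0("pre_dinuc.", DINUC_ORDER),
  paste0("mat_dinuc.", DINUC_ORDER),
  "mfe", "nmfe",
  c("dP", "dP_L", "dQ", "dQ_L", "dD", "dD_L"))

#' U/C/G content of a sequence
#'
#' Fraction of U, C and G among all residues (A counts only toward the
#' denominator). An empty string yields zeros.
#'
#' @param seq An `"rna_seq"` or residue string.
#' @return Named numeric vector `c(U=, C=, G=)`.
#' @export
base_content <- function(seq) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  n <- nchar(s)
  if (n == 0L) return(c(U = 0, C = 0, G = 0))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  c(U = sum(ch == "U"), C = sum(ch == "C"), G = sum(ch == "G")) / n
}

#' Dinucleotide counts over \{U, C, G\}
#'
#' Counts overlapping adjacent pairs; any pair containing A is ignored.
#' Fixed output order UU, UC, UG, CU, CC, CG, GU, GC, GG.
#'
#' @param seq An `"rna_seq"` or residue string (length >= 2).
#' @return Named integer vector of length 9.
#' @export
dinucleotide_counts <- function(seq) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  n <- nchar(s)
  if (n < 2L) stop("dinucleotide counts need a sequence of length >= 2 (got ", n, ")")
  pairs <- substring(s, seq_len(n - 1L), 2:n)
  out <- vapply(DINUC_ORDER, function(d) sum(pairs == d), integer(1))
  names(out) <- DINUC_ORDER
  out
}

## as dinucleotide_counts but over several segments (no junction pairs) and
## tolerant of short/empty segments
dinucleotide_counts_segments <- function(segments) {
  out <- stats::setNames(integer(9L), DINUC_ORDER)
  for (s in segments) if (nchar(s) >= 2L) out <- out + dinucleotide_counts(s)
  out
}

#' Non-mature part of a precursor
#'
#' The precursor residues with every mature interval excised; the remaining
#' segments are concatenated in 5'-to-3' order.
#'
#' @param record A `"mirna_record"`.
#' @return Character scalar (possibly empty).
#' @export
non_mature_sequence <- function(record) {
  paste(non_mature_segments(record), collapse = "")
}

non_mature_segments <- function(record) {
  s <- record$precursor$residues
  L <- nchar(s)
  ivs <- record$matures[order(vapply(record$matures, `[[`, integer(1), "start"))]
  segs <- character(0)
  cur <- 0L
  for (m in ivs) {
    if (m$start < cur) stop("mature intervals overlap in '", record$precursor$id, "'")
    if (m$start > cur) segs <- c(segs, substr(s, cur + 1L, m$start))
    cur <- m$end
  }
  if (cur < L) segs <- c(segs, substr(s, cur + 1L, L))
  segs
}

#' Cleavage-site base class
#'
#' The cleavage site of a mature arm is its 5'-most nucleotide. Returns 1 if
#' every site is U, -1 if no site is U, 0 otherwise (mixed).
#'
#' @param record A `"mirna_record"`.
#' @return Integer in \{-1, 0, 1\}.
#' @export
cleavage_site_class <- function(record) {
  first <- vapply(record$matures, function(m) {
    substr(record$precursor$residues, m$start + 1L, m$start + 1L)
  }, character(1))
  is_u <- first == "U"
  if (all(is_u)) 1L else if (!any(is_u)) -1L else 0L
}

#' The 38-dimensional statistic-and-structure feature vector
#'
#' Concatenates, in fixed order: precursor/mature/non-mature U-C-G contents
#' (3 x 3), mature and non-mature lengths, the cleavage-site class,
#' precursor and mature dinucleotide counts (2 x 9), MFE and nMFE, and the
#' base-pair ensemble block dP, dP/L, dQ, dQ/L, dD, dD/L. For two-arm
#' precursors the mature blocks are computed over both arms (contents and
#' dinucleotides pooled without counting the artificial junction pair;
#' `mat_length` is the total).
#'
#' @param record A `"mirna_record"`.
#' @param metrics A `"fold_metrics"` for the precursor (see [fold_metrics()]).
#' @return Named numeric vector of length 38.
#' @export
static_feature_vector <- function(record, metrics) {
  stopifnot(inherits(record, "mirna_record"), inherits(metrics, "fold_metrics"))
  mats <- mature_sequences(record)
  mat_all <- paste(mats, collapse = "")
  nonmat_segs <- non_mature_segments(record)
  nonmat_all <- paste(nonmat_segs, collapse = "")
  v <- c(
    base_content(record$precursor),
    base_content(mat_all),
    base_content(nonmat_all),
    nchar(mat_all),
    nchar(nonmat_all),
    cleavage_site_class(record),
    dinucleotide_counts(record$precursor),
    dinucleotide_counts_segments(mats),
    metrics$mfe, metrics$nmfe,
    metrics$dP, metrics$dP_L, metrics$dQ, metrics$dQ_L, metrics$dD, metrics$dD_L)
  names(v) <- STATIC_FEATURE_NAMES
  stopifnot(length(v) == 38L)
  v
}

#' Static feature matrix for a set of records
#'
#' @param records List of `"mirna_record"` objects.
#' @param engine A [structure_engine()] handle used for the folding block.
#' @return Numeric matrix, one row per record (rownames = precursor ids),
#'   38 named columns.
#' @export
static_feature_matrix <- function(records, engine = structure_engine("reference")) {
  rows <- lapply(records, function(r) static_feature_vector(r, fold_metrics(r, engine)))
  m <- do.call(rbind, rows)
  rownames(m) <- record_ids(records)
  m
}

#' Fit a per-dimension z-score standardizer
#'
#' Means and standard deviations are estimated on training rows only; apply
#' the same stats to held-out rows to avoid information leakage.
#' Zero-variance dimensions pass through unchanged.
#'
#' @param x Numeric matrix of training feature rows (>= 2 rows).
#' @return Object of class `"feature_standardizer"` with `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 2L) stop("standardizer needs at least 2 training vectors")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  structure(list(mean = mu, sd = sdv), class = "feature_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param x Numeric vector or matrix of feature rows.
#' @param stats A `"feature_standardizer"` from [fit_standardizer()].
#' @return Standardized object of the same shape.
#' @export
apply_standardizer <- function(x, stats) {
  stopifnot(inherits(stats, "feature_standardizer"))
  p <- if (is.null(dim(x))) length(x) else ncol(x)
  if (p != length(stats$mean)) {
    stop("feature dimension ", p, " does not match standardizer (",
         length(stats$mean), ")")
  }
  sdv <- stats$sd
  keep <- !is.finite(sdv) | sdv == 0  # constant dims pass through
  if (is.null(dim(x))) {
    out <- (x - stats$mean) / ifelse(keep, 1, sdv)
    out[keep] <- x[keep]
    return(out)
  }
  out <- sweep(sweep(x, 2L, stats$mean, "-"), 2L, ifelse(keep, 1, sdv), "/")
  out[, keep] <- x[, keep]
  out
}

#' Export a feature matrix as TSV
#'
#' @param x Feature matrix with rownames (record ids) and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_features_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
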