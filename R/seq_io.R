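#' Normalize a raw RNA sequence
#'
#' Uppercases, strips whitespace, converts DNA-style T to U and validates the
#' result against the RNA alphabet \{A, U, C, G\}.
#'
#' @param raw Character scalar; the raw sequence (DNA or RNA case-insensitive).
#' @param id Character scalar; non-empty sequence identifier.
#' @return An object of class `"rna_seq"`: a list with elements `id` and
#'   `residues` (a single uppercase string over A/U/C/G).
#' @examples
#' normalize_sequence("atgc", "x")$residues  # "AUGC"
#' @export
normalize_sequence <- function(raw, id) {
  stopifnot(is.character(raw), length(raw) == 1L, is.character(id), length(id) == 1L)
  if (!nzchar(id)) stop("sequence id must be non-empty")
  s <- gsub("[[:space:]]", "", raw)
  if (!nzchar(s)) stop("sequence '", id, "' is empty after whitespace removal")
  s <- toupper(s)
  s <- chartr("T", "U", s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c("A", "U", "C", "G"))
  if (length(bad)) {
    stop("sequence '", id, "': invalid character '", ch[bad[1L]],
         "' at position ", bad[1L], " (alphabet is A/U/C/G)")
  }
  structure(list(id = id, residues = s), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

seq_len_nt <- function(seq) nchar(seq$residues)

#' Read an RNA FASTA file
#'
#' Reads a (possibly line-wrapped, CRLF-tolerant) FASTA file and returns
#' normalized RNA sequences in file order. The identifier is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return List of `"rna_seq"` objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  out <- mapply(function(s, id) normalize_sequence(s, id),
                as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write RNA sequences to FASTA
#'
#' @param seqs List of `"rna_seq"` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(x) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Pair precursor sequences with their mature miRNAs
#'
#' Locates each mature miRNA inside its precursor by exact substring search
#' (leftmost occurrence) and assembles labeled precursor records. Coordinates
#' are 0-based, half-open.
#'
#' @param precursors List of `"rna_seq"` precursors.
#' @param matures List of `"rna_seq"` mature miRNAs.
#' @param mapping Named list: precursor id -> character vector of mature ids
#'   (1 or 2 per precursor).
#' @param labels Optional named vector: precursor id -> 0/1 label (NA allowed
#'   for unlabeled pools).
#' @return List of `"mirna_record"` objects, each with fields `precursor`
#'   (`"rna_seq"`), `matures` (list of intervals with `start`, `end`,
#'   `mature_id`) and `label`.
#' @export
pair_precursor_matures <- function(precursors, matures, mapping, labels = NULL) {
  pre_ids <- vapply(precursors, `[[`, character(1), "id")
  mat_ids <- vapply(matures, `[[`, character(1), "id")
  names(precursors) <- pre_ids
  names(matures) <- mat_ids
  out <- vector("list", length(mapping))
  for (i in seq_along(mapping)) {
    pid <- names(mapping)[i]
    if (!pid %in% pre_ids) stop("precursor '", pid, "' not found among FASTA records")
    mids <- mapping[[i]]
    if (length(mids) > 2L) {
      stop("precursor '", pid, "' maps to ", length(mids),
           " matures; at most 2 (5p/3p) are allowed")
    }
    pre <- precursors[[pid]]
    ivs <- lapply(mids, function(mid) {
      if (!mid %in% mat_ids) stop("mature '", mid, "' not found among FASTA records")
      m <- matures[[mid]]
      pos <- regexpr(m$residues, pre$residues, fixed = TRUE)
      if (pos < 0L) stop("mature '", mid, "' is not a substring of precursor '", pid, "'")
      mature_interval(start = pos - 1L, end = pos - 1L + nchar(m$residues),
                      mature_id = mid, precursor_len = seq_len_nt(pre))
    })
    lab <- if (is.null(labels) || is.na(labels[pid])) NA_integer_ else as.integer(labels[pid])
    out[[i]] <- mirna_record(pre, ivs, lab)
  }
  names(out) <- names(mapping)
  out
}

mature_interval <- function(start, end, mature_id, precursor_len) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end && end <= precursor_len)) {
    stop("invalid mature interval [", start, ",", end, ") for precursor of length ",
         precursor_len)
  }
  if (end - start < 15L) {
    stop("mature interval [", start, ",", end, ") is shorter than 15 nt")
  }
  list(start = start, end = end, mature_id = mature_id)
}

mirna_record <- function(precursor, matures, label = NA_integer_) {
  if (length(matures) < 1L || length(matures) > 2L) {
    stop("a record needs 1 or 2 mature intervals, got ", length(matures))
  }
  if (length(matures) == 2L) {
    a <- matures[[1L]]; b <- matures[[2L]]
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
    if (a$end > b$start) {
      stop("mature intervals overlap in precursor '", precursor$id, "'")
    }
    matures <- list(a, b)
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("label must be 0, 1 or NA")
  structure(list(precursor = precursor, matures = matures, label = label),
            class = "mirna_record")
}

#' @export
print.mirna_record <- function(x, ...) {
  iv <- vapply(x$matures, function(m) sprintf("[%d,%d)", m$start, m$end), character(1))
  cat(sprintf("<mirna_record> %s (%d nt), matures %s, label %s\n",
              x$precursor$id, seq_len_nt(x$precursor),
              paste(iv, collapse = " "), ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

mature_sequences <- function(record) {
  vapply(record$matures, function(m) {
    substr(record$precursor$residues, m$start + 1L, m$end)
  }, character(1))
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Sliding window of width `k`, stride 1, yielding `|S| - k + 1` tokens.
#'
#' @param seq An `"rna_seq"` object or a plain residue string.
#' @param k Integer word size (k >= 1).
#' @return Object of class `"token_seq"`: list with `tokens` (character
#'   vector) and `k`.
#' @examples
#' tokenize_kmers("AUUGUCC", 3)$tokens  # AUU UUG UGU GUC UCC
#' @export
tokenize_kmers <- function(seq, k) {
  s <- if (inherits(seq, "rna_seq")) seq$residues else seq
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nchar(s)
  if (n < k) stop("sequence length ", n, " is shorter than k = ", k)
  starts <- seq_len(n - k + 1L)
  structure(list(tokens = substring(s, starts, starts + k - 1L), k = k),
            class = "token_seq")
}

#' Load a labeled benchmark dataset
#'
#' Reads precursor and mature FASTA files and a 3-column tab-separated
#' mapping (`precursor_id`, `mature_ids` semicolon-joined, `label`), and
#' returns labeled records.
#'
#' @param precursor_fasta,mature_fasta FASTA paths.
#' @param mapping_tsv Path to the mapping/label TSV (header required).
#' @param quiet Suppress the class-count message.
#' @return List of `"mirna_record"` objects.
#' @export
load_benchmark <- function(precursor_fasta, mature_fasta, mapping_tsv, quiet = FALSE) {
  pre <- read_fasta(precursor_fasta)
  mat <- read_fasta(mature_fasta)
  tab <- utils::read.delim(mapping_tsv, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("precursor_id", "mature_ids", "label")
  if (!all(need %in% names(tab))) {
    stop("mapping TSV must have columns: ", paste(need, collapse = ", "))
  }
  lab_raw <- trimws(tab$label)
  ok <- lab_raw %in% c("0", "1", "NA", "")
  if (any(!ok)) stop("label outside {0,1}: '", lab_raw[which(!ok)[1L]], "'")
  labels <- suppressWarnings(as.integer(lab_raw))
  names(labels) <- tab$precursor_id
  mapping <- lapply(strsplit(tab$mature_ids, ";", fixed = TRUE), trimws)
  names(mapping) <- tab$precursor_id
  recs <- pair_precursor_matures(pre, mat, mapping, labels)
  if (!quiet) {
    labs <- vapply(recs, `[[`, integer(1), "label")
    message(sprintf("loaded %d records: %d positive, %d negative, %d unlabeled",
                    length(recs), sum(labs == 1L, na.rm = TRUE),
                    sum(labs == 0L, na.rm = TRUE), sum(is.na(labs))))
  }
  recs
}

#' Write records as a benchmark dataset
#'
#' Emits `precursors.fa`, `matures.fa` and `mapping.tsv` in the dialect read
#' by [load_benchmark()].
#'
#' @param records List of `"mirna_record"` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- lapply(records, `[[`, "precursor")
  mats <- list(); rows <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    seqs <- mature_sequences(r)
    ids <- vapply(r$matures, `[[`, character(1), "mature_id")
    for (j in seq_along(ids)) mats[[ids[j]]] <- structure(
      list(id = ids[j], residues = seqs[j]), class = "rna_seq")
    rows[i] <- paste(r$precursor$id, paste(ids, collapse = ";"),
                     ifelse(is.na(r$label), "NA", r$label), sep = "\t")
  }
  write_fasta(pre, file.path(dir, "precursors.fa"))
  write_fasta(mats, file.path(dir, "matures.fa"))
  writeLines(c("precursor_id\tmature_ids\tlabel", rows), file.path(dir, "mapping.tsv"))
  invisible(dir)
}

record_labels <- function(records) vapply(records, `[[`, integer(1), "label")
record_ids <- function(records) vapply(records, function(r) r$precursor$id, character(1))
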