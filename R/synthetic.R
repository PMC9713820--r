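## Seeded generator of labeled synthetic pre-miRNA hairpins. The two
## classes differ in stem GC content and in the probability that the mature
## arm starts with U, so the separation is visible to the statistic-and-
## structure feature extractor (contents, dinucleotides, folding block,
## cleavage class) as well as to the sequence encoder.

#' Configuration for the synthetic hairpin generator
#'
#' Defaults emulate the benchmark's data model: 60-120 nt hairpin
#' precursors with a ~22 nt mature arm on the 5' side, a GC-rich stem for
#' the essential class and a U-biased mature 5' end.
#'
#' @param n_pos,n_neg Records per class.
#' @param stem_len Integer range of stem lengths (default 18-30).
#' @param loop_len Integer range of loop lengths (default 4-10).
#' @param mature_len Integer range of mature lengths (default 20-24).
#' @param gc_pos,gc_neg Stem GC probability per class (defaults 0.70 / 0.45).
#' @param u_start_pos,u_start_neg Probability that the mature arm starts
#'   with U (defaults 0.9 / 0.3).
#' @param min_len,max_len Precursor length window (default 60-120); short
#'   cores are extended with unpaired flanks.
#' @param seed RNG seed.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_pos = 77L, n_neg = 77L, stem_len = c(18L, 30L),
                         loop_len = c(4L, 10L), mature_len = c(20L, 24L),
                         gc_pos = 0.70, gc_neg = 0.45,
                         u_start_pos = 0.9, u_start_neg = 0.3,
                         min_len = 60L, max_len = 120L, seed = 1L) {
  stopifnot(all(c(gc_pos, gc_neg, u_start_pos, u_start_neg) >= 0),
            all(c(gc_pos, gc_neg, u_start_pos, u_start_neg) <= 1),
            n_pos >= 1L, n_neg >= 1L,
            stem_len[1L] <= stem_len[2L], loop_len[1L] <= loop_len[2L],
            mature_len[1L] <= mature_len[2L])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
                 mature_len = as.integer(mature_len), gc_pos = gc_pos,
                 gc_neg = gc_neg, u_start_pos = u_start_pos,
                 u_start_neg = u_start_neg, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "synth_config")
}

#' Class-parameter presets by effect size
#'
#' `"strong"` uses the default class separation, `"weak"` halves it, and
#' `"none"` gives both classes the pooled parameters (a null dataset).
#'
#' @param effect One of `"strong"`, `"weak"`, `"none"`.
#' @param ... Passed to [synth_config()].
#' @return A `"synth_config"`.
#' @export
synth_effect <- function(effect = c("strong", "weak", "none"), ...) {
  effect <- match.arg(effect)
  pars <- switch(effect,
    strong = list(gc_pos = 0.70, gc_neg = 0.45, u_start_pos = 0.9, u_start_neg = 0.3),
    weak = list(gc_pos = 0.64, gc_neg = 0.51, u_start_pos = 0.75, u_start_neg = 0.45),
    none = list(gc_pos = 0.575, gc_neg = 0.575, u_start_pos = 0.6, u_start_neg = 0.6))
  do.call(synth_config, c(pars, list(...)))
}

rand_base <- function(n, gc) {
  pick_gc <- stats::runif(n) < gc
  out <- character(n)
  out[pick_gc] <- sample(c("G", "C"), sum(pick_gc), replace = TRUE)
  out[!pick_gc] <- sample(c("A", "U"), sum(!pick_gc), replace = TRUE)
  out
}

rc_base <- function(ch) chartr("AUCG", "UAGC", ch)

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

#' Generate one synthetic hairpin record
#'
#' Left stem drawn with class GC bias, right stem its reverse complement
#' (guaranteeing a foldable hairpin), random loop, unpaired flanks added to
#' reach the configured length window, and one mature interval on the 5'
#' arm whose first nucleotide is U with class probability. Uses the current
#' RNG state.
#'
#' @param cfg A [synth_config()].
#' @param positive Logical; draw from the positive (essential) class?
#' @param id Record identifier.
#' @return A labeled `"mirna_record"`.
#' @export
generate_hairpin <- function(cfg, positive, id) {
  gc <- if (positive) cfg$gc_pos else cfg$gc_neg
  u_start <- if (positive) cfg$u_start_pos else cfg$u_start_neg
  stem <- sample_range(cfg$stem_len)
  loop <- sample_range(cfg$loop_len)
  mat_len <- sample_range(cfg$mature_len)
  core <- 2L * stem + loop
  flank_total <- max(0L, cfg$min_len - core) + sample(0L:10L, 1L)
  flank_total <- min(flank_total, cfg$max_len - core)
  f5 <- flank_total %/% 2L
  f3 <- flank_total - f5
  left <- rand_base(stem, gc)
  loop_seq <- sample(c("A", "U", "C", "G"), loop, replace = TRUE)
  right <- rev(rc_base(left))
  seq_ch <- c(rand_base(f5, 0.4), left, loop_seq, right, rand_base(f3, 0.4))
  ## mature arm: starts inside the 5' stem, may run into the loop
  max_start <- f5 + max(0L, stem + loop - mat_len)
  m_start <- sample_range(c(f5, max_start))  # 0-based
  first_u <- stats::runif(1L) < u_start
  cur <- seq_ch[m_start + 1L]
  if (first_u && cur != "U") {
    seq_ch[m_start + 1L] <- "U"
  } else if (!first_u && cur == "U") {
    seq_ch[m_start + 1L] <- sample(c("A", "C", "G"), 1L)
  }
  pre <- structure(list(id = id, residues = paste(seq_ch, collapse = "")),
                   class = "rna_seq")
  iv <- mature_interval(m_start, m_start + mat_len, paste0(id, "-mat"),
                        precursor_len = length(seq_ch))
  mirna_record(pre, list(iv), label = as.integer(positive))
}

#' Generate a labeled synthetic dataset
#'
#' Exactly `n_pos` positive and `n_neg` negative hairpin records, fully
#' reproducible for a fixed seed. Optionally writes the FASTA/TSV benchmark
#' dialect consumed by [load_benchmark()].
#'
#' @param cfg A [synth_config()] (or [synth_effect()] preset).
#' @param dir Optional output directory for `precursors.fa`, `matures.fa`
#'   and `mapping.tsv`.
#' @return List of `"mirna_record"` objects (positives first).
#' @export
generate_dataset <- function(cfg = synth_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- with_seed(cfg$seed, {
    c(lapply(seq_len(cfg$n_pos), function(i) {
        generate_hairpin(cfg, TRUE, sprintf("syn-pos-%03d", i))
      }),
      lapply(seq_len(cfg$n_neg), function(i) {
        generate_hairpin(cfg, FALSE, sprintf("syn-neg-%03d", i))
      }))
  })
  if (!is.null(dir)) write_benchmark(recs, dir)
  recs
}
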