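test_that("base content counts U, C, G fractions with A in the denominator only", {
  expect_equal(unname(base_content("UUCG")), c(0.50, 0.25, 0.25))
  expect_equal(unname(base_content("AAAA")), c(0, 0, 0))
  expect_equal(unname(base_content("UCG")), rep(1 / 3, 3))
  # fractions plus the A fraction sum to 1
  set.seed(4)
  for (i in 1:10) {
    s <- random_rna(sample(5:60, 1))
    bc <- base_content(s)
    a_frac <- sum(strsplit(s, "")[[1]] == "A") / nchar(s)
    expect_equal(sum(bc) + a_frac, 1, tolerance = 1e-12)
  }
})

test_that("dinucleotide counts use overlapping windows and skip A-containing pairs", {
  d <- dinucleotide_counts("UUCG")
  expect_equal(unname(d[c("UU", "UC", "CG")]), c(1L, 1L, 1L))
  expect_equal(sum(d), 3L)
  expect_equal(sum(dinucleotide_counts("AUAU")), 0L)
  expect_equal(unname(dinucleotide_counts("GGG")["GG"]), 2L)
  expect_error(dinucleotide_counts("G"), "length >= 2")
  # total <= |S| - 1 with equality iff no A
  set.seed(5)
  for (i in 1:10) {
    s <- random_rna(sample(5:40, 1))
    tot <- sum(dinucleotide_counts(s))
    expect_lte(tot, nchar(s) - 1L)
    if (!grepl("A", s)) expect_equal(tot, nchar(s) - 1L)
  }
})

test_that("non-mature sequence excises mature intervals in 5'-3' order", {
  p <- normalize_sequence(paste0("AA", strrep("UGGC", 4), "CC"), "p")
  m <- normalize_sequence(strrep("UGGC", 4), "m")
  rec <- pair_precursor_matures(list(p), list(m), list(p = "m"))[[1]]
  expect_equal(non_mature_sequence(rec), "AACC")

  # mature spanning the entire precursor leaves an empty string
  p2 <- normalize_sequence(strrep("UGGC", 4), "p2")
  rec2 <- pair_precursor_matures(list(p2), list(m), list(p2 = "m"))[[1]]
  expect_equal(non_mature_sequence(rec2), "")
  expect_equal(unname(base_content(non_mature_sequence(rec2))), c(0, 0, 0))

  # two arms: the middle segment and flanks survive (independent slicing)
  s <- paste0("GCGC", strrep("UGUG", 4), "AAAA", strrep("CACC", 4), "GG")
  p3 <- normalize_sequence(s, "p3")
  m5 <- normalize_sequence(strrep("UGUG", 4), "m5")
  m3 <- normalize_sequence(strrep("CACC", 4), "m3")
  rec3 <- pair_precursor_matures(list(p3), list(m5, m3),
                                 list(p3 = c("m5", "m3")))[[1]]
  expect_equal(non_mature_sequence(rec3), "GCGCAAAAGG")
})

test_that("cleavage-site class is the ternary all-U / none-U / mixed code", {
  mk2 <- function(first5, first3) {
    s <- paste0("GG", first5, strrep("GGC", 5), "AAAA", first3, strrep("CCG", 5), "UU")
    p <- normalize_sequence(s, "p")
    a5 <- normalize_sequence(paste0(first5, strrep("GGC", 5)), "a5")
    a3 <- normalize_sequence(paste0(first3, strrep("CCG", 5)), "a3")
    pair_precursor_matures(list(p), list(a5, a3), list(p = c("a5", "a3")))[[1]]
  }
  expect_equal(cleavage_site_class(mk2("U", "U")), 1L)
  expect_equal(cleavage_site_class(mk2("U", "G")), 0L)
  expect_equal(cleavage_site_class(mk2("G", "C")), -1L)
  # single arm starting G -> all non-U
  p <- normalize_sequence(paste0("AA", strrep("GGC", 6)), "p")
  m <- normalize_sequence(strrep("GGC", 6), "m")
  expect_equal(cleavage_site_class(
    pair_precursor_matures(list(p), list(m), list(p = "m"))[[1]]), -1L)
})

test_that("the static feature vector is 38-dimensional and matches a naive recount", {
  rec <- toy_record()
  met <- fold_metrics(rec)
  v <- static_feature_vector(rec, met)
  expect_length(v, 38L)
  expect_named(v)

  # independent recount, block by block
  s <- rec$precursor$residues
  mat <- substr(s, rec$matures[[1]]$start + 1, rec$matures[[1]]$end)
  nonmat <- paste0(substr(s, 1, rec$matures[[1]]$start),
                   substr(s, rec$matures[[1]]$end + 1, nchar(s)))
  cnt <- function(x, ch) lengths(regmatches(x, gregexpr(ch, x)))
  expect_equal(unname(v[1:3]), c(cnt(s, "U"), cnt(s, "C"), cnt(s, "G")) / nchar(s))
  expect_equal(unname(v[4:6]), c(cnt(mat, "U"), cnt(mat, "C"), cnt(mat, "G")) / nchar(mat))
  expect_equal(unname(v[7:9]),
               c(cnt(nonmat, "U"), cnt(nonmat, "C"), cnt(nonmat, "G")) / nchar(nonmat))
  expect_equal(unname(v["mat_length"]), nchar(mat))
  expect_equal(unname(v["nonmat_length"]), nchar(s) - nchar(mat))
  expect_equal(unname(v["cleavage_class"]),
               if (substr(mat, 1, 1) == "U") 1 else -1)
  naive_dinuc <- function(x) {
    prs <- substring(x, 1:(nchar(x) - 1), 2:nchar(x))
    vapply(c("UU", "UC", "UG", "CU", "CC", "CG", "GU", "GC", "GG"),
           function(d) sum(prs == d), numeric(1))
  }
  expect_equal(unname(v[13:21]), unname(naive_dinuc(s)))
  expect_equal(unname(v[22:30]), unname(naive_dinuc(mat)))
  expect_equal(unname(v[31:32]), c(met$mfe, met$nmfe))
  expect_equal(unname(v[33:38]),
               c(met$dP, met$dP_L, met$dQ, met$dQ_L, met$dD, met$dD_L))

  # purity: same inputs, same vector
  expect_identical(v, static_feature_vector(rec, met))
})

test_that("dimensionality is 38 regardless of arm count and lengths", {
  recs <- generate_dataset(synth_config(n_pos = 4, n_neg = 4, seed = 2))
  m <- static_feature_matrix(recs)
  expect_equal(dim(m), c(8L, 38L))
  s <- paste0("GCGC", strrep("UGUG", 4), "AAAA", strrep("CACC", 4), "GG")
  p3 <- normalize_sequence(s, "p3")
  m5 <- normalize_sequence(strrep("UGUG", 4), "m5")
  m3 <- normalize_sequence(strrep("CACC", 4), "m3")
  rec2 <- pair_precursor_matures(list(p3), list(m5, m3),
                                 list(p3 = c("m5", "m3")))[[1]]
  v2 <- static_feature_vector(rec2, fold_metrics(rec2))
  expect_length(v2, 38L)
  # two-arm mature blocks pool both arms; junction pair not counted
  expect_equal(unname(v2["mat_length"]), 32)
  both <- paste0(strrep("UGUG", 4), strrep("CACC", 4))
  expect_equal(unname(v2[4:6]), unname(base_content(both)))
  junction_counts <- dinucleotide_counts(both)
  arm_counts <- dinucleotide_counts(strrep("UGUG", 4)) +
    dinucleotide_counts(strrep("CACC", 4))
  expect_equal(unname(v2[22:30]), unname(arm_counts))
  expect_false(isTRUE(all.equal(unname(junction_counts), unname(arm_counts))))
})

test_that("standardization is a train-only z-score with constant dims passing through", {
  set.seed(12)
  x <- cbind(matrix(rnorm(50, 5, 2), 10), const = rep(3, 10))
  st <- fit_standardizer(x)
  z <- apply_standardizer(x, st)
  expect_true(all(abs(colMeans(z[, 1:5])) < 1e-9))
  expect_true(all(abs(apply(z[, 1:5], 2, sd) - 1) < 1e-9))
  expect_equal(z[, 6], x[, 6])  # constant dimension unchanged

  # leakage guard: test rows standardized with train stats differ from a refit
  y <- matrix(rnorm(50, 8, 3), 10)
  zt <- apply_standardizer(cbind(y, rep(3, 10)), st)
  zr <- apply_standardizer(cbind(y, rep(3, 10)), fit_standardizer(cbind(y, rep(3, 10))))
  expect_false(isTRUE(all.equal(zt, zr)))

  expect_error(fit_standardizer(matrix(1, 1, 3)), "at least 2")
  # vector path agrees with matrix path
  expect_equal(apply_standardizer(x[3, ], st), z[3, ])
})
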