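test_that("one-hot encoding honours padding, truncation and column order", {
  p14 <- random_peptides(1, len_range = c(14, 14))[[1]]
  set.seed(1)
  m <- one_hot_encode(p14, 60)
  expect_equal(dim(m), c(60L, 22L))
  expect_equal(unname(rowSums(m)), rep(1, 60))        # exact one-hot rows
  expect_true(all(m[15:60, "-"] == 1))                # right padding
  x <- one_hot_encode(polypeptide("X"), 5)
  expect_equal(unname(x[1, "X"]), 1)
  expect_equal(colnames(m)[21:22], c("X", "-"))

  long <- polypeptide(strrep("A", 70))
  trunc <- one_hot_encode(long, 60)
  expect_equal(sum(trunc[, "A"]), 60)                  # truncated from right

  # injectivity up to truncation: distinct peptides <= 60 aa differ
  set.seed(2)
  peps <- random_peptides(25, len_range = c(5, 20))
  keys <- vapply(peps, function(p) {
    paste(which(t(one_hot_encode(p, 60)) == 1), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(keys[!duplicated(vapply(peps, `[[`,
    character(1), "residues"))]), 0)
})

test_that("bundled property scales are complete and AAindex files parse", {
  tabs <- property_scales()
  expect_gte(length(tabs), 12)
  for (v in tabs) {
    expect_length(v, 20)
    expect_setequal(names(v), seqpka:::AA20)
  }
  # AAindex1 flat-file record format (H / I lines, two value rows)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "H FAKE000001",
    "D A planted test scale",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.1     0.2     0.3     0.4     0.5     0.6     0.7     0.8     0.9     1.0",
    "    1.1     1.2     1.3     1.4     1.5     1.6     1.7     1.8     1.9     2.0",
    "//"), tmp)
  sc <- read_aaindex(tmp)
  expect_named(sc, "FAKE000001")
  expect_equal(unname(sc$FAKE000001[c("A", "R", "V")]), c(0.1, 0.2, 2.0))
})

test_that("scale selection finds a planted feature and caps at 10", {
  set.seed(33)
  peps <- random_peptides(80, len_range = c(8, 20))
  planted <- stats::setNames(runif(20, -2, 2), seqpka:::AA20)
  y <- vapply(peps, function(p) {
    mean(planted[strsplit(p$residues, "")[[1]]])
  }, numeric(1)) * 2 + 5 + rnorm(80, 0, 0.05)
  ds <- labelled_dataset(data.frame(
    sequence = vapply(peps, `[[`, character(1), "residues"), value = y),
    kind = "pI")
  tabs <- c(property_scales(),
            list(planted = planted, constant = stats::setNames(rep(1, 20),
                                                               seqpka:::AA20)))
  sel <- select_informative_scales(tabs, ds, k = 5)
  expect_equal(names(sel$f_regression)[1], "planted")
  expect_false("constant" %in% sel$selected)
  # the k cap is honoured even when more are requested
  sel50 <- select_informative_scales(tabs, ds, k = 50)
  expect_lte(length(sel50$f_regression), 10)
  expect_lte(length(sel50$mutual_info), 10)
  # ranking is invariant to affine rescaling of a scale
  tabs$planted <- planted * 3.7 + 11
  sel_aff <- select_informative_scales(tabs, ds, k = 5)
  expect_equal(names(sel_aff$f_regression), names(sel$f_regression))
  expect_equal(names(sel_aff$mutual_info), names(sel$mutual_info))
  expect_error(select_informative_scales(list(c = stats::setNames(
    rep(0, 20), seqpka:::AA20)), ds), "constant")
})

test_that("kmer windows centre on ionizable residues with boundary padding", {
  s <- polypeptide("ALRWI")
  w <- kmer_window(s, 3, 5)
  expect_equal(w$window, "ALRWI")
  expect_equal(w$residue, "R")

  left <- kmer_window(polypeptide("RAAAA"), 1, 5)
  expect_equal(left$window, "--RAA")

  expect_error(kmer_window(s, 3, 4), "odd")
  expect_error(kmer_window(s, 1, 5), "not ionizable")
  expect_error(kmer_window(s, 9, 5), "out of range")

  # terminus windows centre on a virtual position outside the chain
  nt <- kmer_window(s, NA, 3, terminus = "n_term")
  expect_equal(nt$window, "--A")
  expect_equal(nt$group, "n_term")
  expect_equal(nt$residue, "-")
  ct <- kmer_window(s, NA, 3, terminus = "c_term")
  expect_equal(ct$window, "I--")

  # windows of all sizes agree on their common centre symbol
  long <- polypeptide("GGGGKGGGG")
  for (k in c(3, 5, 7, 9)) {
    w <- kmer_window(long, 5, k)
    expect_equal(substr(w$window, (k + 1) / 2, (k + 1) / 2), "K")
  }
})

test_that("base-method vectors have the fixed 19-method contract", {
  expect_length(default_base_methods(), 19)
  set.seed(3)
  p <- random_peptides(1)[[1]]
  v <- base_method_vector(p)
  expect_length(v, 19)
  expect_true(all(v >= 0 & v <= 14))
  expect_named(v, default_base_methods())
  # configured order is respected
  rev_order <- rev(default_base_methods())
  expect_equal(unname(base_method_vector(p, rev_order)), rev(unname(v)))
  expect_error(base_method_vector(p, c("EMBOSS", "NoSuchMethod")),
               "unknown pKa set")
})

test_that("peptide tensors satisfy the four-channel contract", {
  p <- polypeptide("ACDKLMRYW", id = "t")
  scales <- property_scales()[c("hydropathy_kd", "charge_at_ph7")]
  tens <- build_peptide_tensor(p, scales, base_pi = 6.5)
  expect_equal(dim(tens), c(60L, 22L, 4L))
  expect_equal(unname(rowSums(tens[, , 1])), rep(1, 60))
  # channel 3: group counts broadcast uniformly down their columns
  comp <- seqpka:::composition_vector(ionizable_composition(p))
  expect_equal(tens[1, 1:9, 3], unname(comp) / p$length)
  expect_equal(tens[60, 1:9, 3], unname(comp) / p$length)
  # channel 4: base prediction broadcast in column 1
  expect_equal(unique(tens[, 1, 4]), 6.5 / 14)
  expect_error(build_peptide_tensor(polypeptide(strrep("A", 61)), scales),
               "longer")
  expect_error(build_peptide_tensor(p, property_scales()[rep(1, 23)]),
               "22 scales")
})
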