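test_that("clustering merges duplicates, averages labels, and is idempotent", {
  ds <- labelled_dataset(data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c("ACDK", "GGKD", "ACDK", "WYR"),
    value = c(5.0, 7.1, 6.0, 9.2)), kind = "pI")
  cl <- cluster_and_average(ds)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$value[cl$sequence == "ACDK"], 5.5)
  expect_equal(sum(cl$merged), nrow(ds))       # conservation
  expect_equal(as.data.frame(cluster_and_average(cl)), as.data.frame(cl))

  distinct <- labelled_dataset(data.frame(
    sequence = c("AAA", "CCC"), value = c(5, 6)), kind = "pI")
  expect_equal(cluster_and_average(distinct)$value, c(5, 6))
})

test_that("75/25 splits are disjoint, exhaustive and seed-reproducible", {
  ds <- labelled_dataset(data.frame(
    sequence = replicate(100, paste(sample(seqpka:::AA20, 8, TRUE),
                                    collapse = "")),
    value = runif(100, 3, 11)), kind = "pI")
  sp <- split_dataset(ds, 0.25, seed = 5)
  expect_equal(nrow(sp$train75), 75)
  expect_equal(nrow(sp$test25), 25)
  expect_length(intersect(sp$train75$id, sp$test25$id), 0)
  expect_setequal(c(sp$train75$id, sp$test25$id), ds$id)
  sp2 <- split_dataset(ds, 0.25, seed = 5)
  expect_identical(sp$test25$id, sp2$test25$id)
  # the protein-scale split: 2324 records -> 1743 + 581
  expect_equal(round(2324 * 0.25), 581)
  expect_error(split_dataset(seqpka:::subset_dataset(ds, 1:3), seed = 1),
               "too small")
})

test_that("metric suite matches an independent spreadsheet-style oracle", {
  pred <- c(5.1, 6.4, 7.0, 4.8, 9.3)
  expv <- c(5.0, 6.0, 7.5, 4.2, 9.0)
  rep <- metrics(pred, expv, threshold = 0.5)
  # independent arithmetic: errors 0.1, 0.4, -0.5, 0.6, 0.3
  expect_equal(rep$rmse, sqrt((0.01 + 0.16 + 0.25 + 0.36 + 0.09) / 5))
  expect_equal(rep$mae, (0.1 + 0.4 + 0.5 + 0.6 + 0.3) / 5)
  n <- 5
  r_hand <- (n * sum(pred * expv) - sum(pred) * sum(expv)) /
    sqrt((n * sum(pred^2) - sum(pred)^2) * (n * sum(expv^2) - sum(expv)^2))
  expect_equal(rep$r2_pearson, r_hand^2)
  expect_equal(rep$r2_determination,
               1 - sum((pred - expv)^2) / sum((expv - mean(expv))^2))
  expect_equal(rep$outliers, 1L)  # strict '>': the -0.5 error is not one

  perfect <- metrics(expv, expv)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2_pearson, 1)
  expect_equal(perfect$outliers, 0L)

  two <- metrics(c(5.4, 6.6), c(5.0, 6.0), threshold = 0.5)
  expect_equal(two$outliers, 1L)   # errors 0.4 and 0.6

  expect_warning(metrics(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("metric identities hold on random vectors", {
  set.seed(99)
  for (i in 1:20) {
    y <- runif(50, 2, 12)
    p <- y + rnorm(50, 0, 0.7)
    rep <- metrics(p, y)
    expect_gte(rep$rmse, rep$mae)
    expect_equal(rep$rmse^2, sum((p - y)^2) / 50)  # direct summation oracle
    expect_gte(rep$outliers, 0)
    expect_lte(rep$outliers, rep$n)
  }
})

test_that("cross-validation partitions exactly and pools correctly", {
  ds <- labelled_dataset(data.frame(
    sequence = replicate(55, paste(sample(seqpka:::AA20, 6, TRUE),
                                   collapse = "")),
    value = runif(55, 3, 11)), kind = "pI")
  const <- mean(ds$value)
  factory <- function(train) function(test) rep(const, nrow(test))
  cv <- cross_validate(factory, ds, folds = 10, seed = 3)
  expect_equal(sort(unique(cv$assignments)), 1:10)
  expect_equal(length(cv$assignments), 55)
  expect_equal(cv$pooled$n, 55)
  # constant predictor: pooled RMSE has the closed form sd around the constant
  expect_equal(cv$pooled$rmse, sqrt(mean((ds$value - const)^2)))
  cv2 <- cross_validate(factory, ds, folds = 10, seed = 3)
  expect_identical(cv$assignments, cv2$assignments)
  expect_error(cross_validate(factory, ds, folds = 60, seed = 1),
               "more folds")
})

test_that("benchmark tabulates methods in Table-2 layout, ranked by RMSE", {
  set.seed(17)
  cfg <- generator_config(n = 60, hidden_set = "EMBOSS", noise_sd = 0.2,
                          seed = 17)
  ds <- generate_pi_dataset(cfg)
  tab <- benchmark(c("EMBOSS", "Dawson", "Patrickios"), ds,
                   threshold = 0.25)
  expect_s3_class(tab, "benchmark_table")
  expect_true(all(c("method", "rmse", "mae", "r2_pearson",
                    "r2_determination", "outliers") %in% names(tab)))
  expect_equal(nrow(tab), 3)
  expect_true(!is.unsorted(tab$rmse))
  expect_equal(tab$method[1], "EMBOSS")  # the generating set wins

  # two methods with identical predictions give identical reports
  dup <- benchmark(list(a = get_pka_set("Dawson"),
                        b = get_pka_set("Dawson")), ds)
  expect_equal(dup$rmse[1], dup$rmse[2])
  expect_equal(dup$method, c("a", "b"))  # deterministic name tie-break

  # a failing method is marked invalid without affecting the others
  bad <- benchmark(list(ok = get_pka_set("EMBOSS"),
                        broken = function(seqs) stop("boom")), ds)
  expect_true(bad$invalid[bad$method == "broken"])
  expect_true(is.na(bad$rmse[bad$method == "broken"]))
  expect_false(bad$invalid[bad$method == "ok"])
})

test_that("pKa type summaries report per-type accuracy", {
  cfg <- generator_config(n = 4, length_range = c(60L, 90L),
                          noise_sd = 0.1, seed = 21)
  ds <- generate_pka_dataset(cfg)
  pred <- ds$value + rnorm(nrow(ds), 0, 0.2)
  tab <- pka_type_summary(pred, ds, threshold = 0.5)
  expect_true("All" %in% tab$type)
  expect_equal(tab$n[tab$type == "All"], nrow(ds))
  expect_true(all(tab$rmse >= tab$mae - 1e-12))
})

test_that("dataset TSV round-trips through the documented dialect", {
  cfg <- generator_config(n = 20, seed = 9)
  ds <- generate_pi_dataset(cfg)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_labelled_dataset(ds, tmp)
  back <- read_labelled_dataset(tmp)
  expect_equal(attr(back, "kind"), "pI")
  expect_equal(back$sequence, ds$sequence)
  expect_equal(back$value, ds$value, tolerance = 1e-12)

  pk <- generate_pka_dataset(generator_config(n = 2,
                                              length_range = c(60L, 80L),
                                              seed = 9))
  write_labelled_dataset(pk, tmp)
  back2 <- read_labelled_dataset(tmp)
  expect_equal(attr(back2, "kind"), "pKa")
  expect_equal(back2$position, pk$position)
})
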