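test_that("a perfect feature drives the stacker held-out RMSE to ~0", {
  set.seed(21)
  y <- runif(60, 3, 11)
  X <- matrix(rep(y, 19), ncol = 19)
  m <- train_svr_stack(X, y, seed = 1)
  expect_lte(m$cv_rmse, 0.05)
  expect_true(!is.null(m$cost) && !is.null(m$gamma))  # recorded choice
})

test_that("the stacker enforces its input contract", {
  set.seed(22)
  y <- runif(60, 3, 11)
  X19 <- matrix(rep(y, 19), ncol = 19) + rnorm(60 * 19, 0, 0.2)
  # enriched inputs (e.g. appended length/Mw columns) are rejected
  X21 <- cbind(X19, runif(60, 5, 30), runif(60, 500, 3000))
  expect_error(train_svr_stack(X21, y, seed = 1), "rejected")
  expect_error(train_svr_stack(X19[1:20, ], y[1:20], seed = 1),
               "at least 30")
  expect_error(train_svr_stack(X19, rep(7, 60), seed = 1), "zero variance")
  Xbad <- X19; Xbad[1, 1] <- NA
  expect_error(train_svr_stack(Xbad, y, seed = 1), "non-finite")

  m <- train_svr_stack(X19, y, seed = 1)
  expect_error(predict_pi_stack(m, rep(7, 5)), "expects")
  # clipping contract on arbitrary inputs
  set.seed(23)
  preds <- predict_pi_stack(m, matrix(runif(100 * 19, 0, 14), ncol = 19))
  expect_true(all(preds >= 0 & preds <= 14))
})

test_that("fitted models survive a save/load round trip unchanged", {
  set.seed(24)
  y <- runif(50, 3, 11)
  X <- matrix(rep(y, 19), ncol = 19) + rnorm(50 * 19, 0, 0.3)
  m <- train_svr_stack(X, y, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  probe <- matrix(runif(10 * 19, 2, 12), ncol = 19)
  expect_identical(predict_pi_stack(m, probe), predict_pi_stack(m2, probe))
})

test_that("the peptide convnet has the specified architecture", {
  net <- build_peptide_convnet(convnet_config(), seed = 4)
  expect_equal(net$layer_sequence,
               c("sepconv", "avgpool", "sepconv", "avgpool", "flatten",
                 "dense", "dense", "dense"))
  # first depthwise kernel spans all 22 symbol columns with a window of 5
  expect_equal(dim(net$weights$kd1), c(22L * 5L, 4L))
  expect_equal(dim(net$weights$d3W), c(16L, 1L))       # scalar output
  # deterministic parameter count and seeded init
  net2 <- build_peptide_convnet(convnet_config(), seed = 4)
  expect_identical(net$weights, net2$weights)
  expect_equal(net$n_parameters, net2$n_parameters)
  net3 <- build_peptide_convnet(convnet_config(), seed = 5)
  expect_false(identical(net$weights, net3$weights))
  # scalar output per example
  set.seed(6)
  tens <- array(rnorm(3 * 60 * 22 * 4), c(3, 60, 22, 4))
  expect_length(predict(net, tens), 3)
})

test_that("convnet training honours the validation split and converges on
          constant labels", {
  set.seed(31)
  tens <- array(rnorm(120 * 60 * 22 * 4, 0, 0.3), c(120, 60, 22, 4))
  ylab <- rep(7, 120)
  # convergence check: no dropout noise, no early stop, brisk learning rate
  net <- build_peptide_convnet(convnet_config(epochs = 100L,
                                              patience = 100L, dropout = 0,
                                              learning_rate = 3e-3),
                               seed = 1)
  expect_warning(
    train_regressor(net, tens[1:80, , , , drop = FALSE], ylab[1:80],
                    seed = 1),
    "fewer than 100")
  trained <- train_regressor(net, tens, ylab, seed = 1)
  expect_equal(trained$n_val, floor(120 * 0.2))        # 80/20 split
  expect_equal(trained$n_train, 120 - floor(120 * 0.2))
  expect_lte(mean((predict(trained, tens) - 7)^2), 1e-3)
  h <- trained$history
  expect_lte(h$val_loss[nrow(h)], h$val_loss[1] + 1e-12)
})

test_that("the convnet learns synthetic peptide pI well beyond the mean
          predictor", {
  ds <- generate_pi_dataset(generator_config(n = 200, noise_sd = 0.05,
                                             seed = 11))
  seqs <- seqpka:::dataset_sequences(ds)
  scales <- property_scales()[c("hydropathy_kd", "charge_at_ph7",
                                "sidechain_pka")]
  tens <- seqpka:::peptide_tensor_batch(seqs, scales)
  val_rmse <- vapply(1:3, function(sd_i) {
    net <- build_peptide_convnet(convnet_config(), seed = sd_i)
    net <- train_regressor(net, tens, ds$value, seed = sd_i)
    sqrt(min(net$history$val_loss)) * sd(ds$value)
  }, numeric(1))
  expect_lte(mean(val_rmse), 0.25)
  expect_lte(max(val_rmse), 0.30)
  # >= 50% RMSE reduction against the naive mean-label predictor
  expect_lte(mean(val_rmse), 0.5 * sd(ds$value))
})

test_that("the pKa ensemble trains nine members and reports by type", {
  model <- tiny_pka_model()
  expect_length(model$members, 9)
  expect_s3_class(model$type_report, "data.frame")
  expect_true("All" %in% model$type_report$type)
  expect_true(is.finite(model$oof_rmse))
})

test_that("pKa predictions enumerate sites and respect the pH range", {
  model <- tiny_pka_model()
  res <- predict_pka(model, polypeptide("ALRWI"))
  expect_equal(nrow(res), 3)                   # R3 plus both termini
  expect_equal(res$group, c("n_term", "side_chain", "c_term"))
  expect_true(all(res$pka > 0 & res$pka < 14))
  res2 <- predict_pka(model, polypeptide("ALRWI"))
  expect_identical(res, res2)                  # deterministic once fitted
  expect_error(predict_pka(model, polypeptide("ALRWI"), positions = 9),
               "out of range")
  only_r <- predict_pka(model, polypeptide("ALRWI"), positions = 3)
  expect_equal(nrow(only_r), 1)

  # per-type prediction means recover the generative base values (zero
  # context / low noise generator behind the shared model); pooled over
  # several proteins so the per-type samples are not tiny
  ds <- shared_models$pka_data
  base <- attr(ds, "base_pka")
  ids <- unique(ds$id)[1:4]
  pred <- do.call(rbind, lapply(ids, function(id) {
    predict_pka(model, polypeptide(ds$sequence[ds$id == id][1], id = id))
  }))
  side <- pred[pred$group == "side_chain", ]
  for (tp in unique(side$residue)) {
    expect_lt(abs(mean(side$pka[side$residue == tp]) - base[[tp]]), 0.5)
  }
})

test_that("ensemble preconditions and leakage guards hold", {
  w <- stats::setNames(rep(1, 20), seqpka:::AA20)
  small <- generate_pka_dataset(generator_config(
    n = 2L, length_range = c(60L, 70L), composition_weights = w,
    noise_sd = 0.1, seed = 3))
  expect_error(train_pka_ensemble(small, tiny_ensemble_config(), seed = 1),
               "at least 200")

  # shuffling the labels destroys stacker skill (no-leakage property)
  ds <- shared_models$pka_data
  shuffled <- as.data.frame(ds)
  set.seed(41)
  shuffled$value <- sample(shuffled$value)
  sh_ds <- labelled_dataset(shuffled, kind = "pKa")
  sh_model <- suppressWarnings(
    train_pka_ensemble(sh_ds, tiny_ensemble_config(), seed = 2))
  true_model <- tiny_pka_model()
  expect_gt(sh_model$oof_rmse, 2 * true_model$oof_rmse)
  # shuffled labels leave no learnable signal: RMSE at the label sd
  expect_gt(sh_model$oof_rmse, 0.8 * sd(sh_ds$value))
})
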