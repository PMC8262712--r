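# Trainable predictors: SVR stacking over base-method pI predictions, and
# the kmer MLP ensemble with an SVR stacker for per-residue pKa.

#' Support-vector-regression configuration
#'
#' @param cost_grid Grid of RBF-SVR cost values C.
#' @param gamma_grid Grid of RBF kernel widths.
#' @param epsilon_grid Grid of epsilon-insensitive band widths (on the
#'   standardized response); values below the label noise let the
#'   regressor track well-designed inputs tightly.
#' @param folds Internal cross-validation folds for the grid search.
#' @param n_inputs Expected input width; the default 19 (the base-method
#'   prediction vector) makes the stacker reject enriched heterogeneous
#'   inputs such as appended length or molecular-weight columns.  Set NULL
#'   to accept any width.
#' @return An `svr_config` list.
#' @export
svr_config <- function(cost_grid = c(0.1, 1, 10, 100),
                       gamma_grid = c(1e-3, 1e-2, 1e-1, 1),
                       epsilon_grid = c(0.01, 0.1),
                       folds = 5L, n_inputs = 19L) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1,
            length(epsilon_grid) >= 1, folds >= 2)
  structure(list(cost_grid = cost_grid, gamma_grid = gamma_grid,
                 epsilon_grid = epsilon_grid,
                 folds = as.integer(folds),
                 n_inputs = if (is.null(n_inputs)) NULL else
                   as.integer(n_inputs)),
            class = "svr_config")
}

# Grid-searched RBF SVR: returns the fitted e1071 model plus the chosen
# hyperparameters and the cross-validated RMSE that selected them.
svr_grid_fit <- function(X, y, cfg, seed) {
  set.seed(seed)
  n <- nrow(X)
  fold <- sample(rep_len(seq_len(cfg$folds), n))
  eps_grid <- if (is.null(cfg$epsilon_grid)) 0.1 else cfg$epsilon_grid
  best <- list(rmse = Inf)
  for (C in cfg$cost_grid) {
    for (g in cfg$gamma_grid) {
      for (eps in eps_grid) {
        pred <- numeric(n)
        for (f in seq_len(cfg$folds)) {
          hold <- fold == f
          fit <- e1071::svm(X[!hold, , drop = FALSE], y[!hold],
                            type = "eps-regression", kernel = "radial",
                            cost = C, gamma = g, epsilon = eps,
                            scale = TRUE)
          pred[hold] <- stats::predict(fit, X[hold, , drop = FALSE])
        }
        rmse <- sqrt(mean((pred - y)^2))
        if (rmse < best$rmse) {
          best <- list(rmse = rmse, cost = C, gamma = g, epsilon = eps)
        }
      }
    }
  }
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = best$cost, gamma = best$gamma,
                    epsilon = best$epsilon, scale = TRUE)
  list(fit = fit, cost = best$cost, gamma = best$gamma,
       epsilon = best$epsilon, cv_rmse = best$rmse)
}

#' Train the SVR stacking model for pI
#'
#' Fits an RBF-kernel support-vector regressor on base-method prediction
#' vectors with a cross-validated grid search over (C, gamma); the chosen
#' hyperparameters and the held-out (CV) RMSE are recorded in the model.
#'
#' @param X n x 19 matrix of base-method pI predictions (see
#'   [base_method_matrix]); width checked against `cfg$n_inputs`.
#' @param y Experimental pI values, length n (n >= 30).
#' @param cfg An [svr_config].
#' @param seed Integer seed (grid-search fold assignment).
#' @param methods Optional method-name vector recorded for provenance.
#' @return An `svr_stack` model.
#' @export
train_svr_stack <- function(X, y, cfg = svr_config(), seed = 1L,
                            methods = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 30) stop("need at least 30 training rows")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in the training inputs")
  }
  if (stats::sd(y) == 0) stop("degenerate response: zero variance")
  if (!is.null(cfg$n_inputs) && ncol(X) != cfg$n_inputs) {
    stop("input has ", ncol(X), " columns but the configuration expects ",
         cfg$n_inputs, "; enriched heterogeneous inputs are rejected")
  }
  g <- svr_grid_fit(X, y, cfg, seed)
  structure(list(fit = g$fit, cost = g$cost, gamma = g$gamma,
                 cv_rmse = g$cv_rmse, n_inputs = ncol(X),
                 methods = methods, seed = seed, cfg = cfg),
            class = "svr_stack")
}

#' Predict pI with a fitted stacker
#'
#' @param model An [train_svr_stack] result.
#' @param base Base-method prediction vector (length = model input width) or
#'   matrix with one row per sequence.
#' @return pI predictions clipped into \[0, 14\] (clip events messaged).
#' @export
predict_pi_stack <- function(model, base) {
  stopifnot(inherits(model, "svr_stack"))
  if (is.null(dim(base))) base <- matrix(base, nrow = 1L)
  if (ncol(base) != model$n_inputs) {
    stop("base vector has length ", ncol(base), "; the model expects ",
         model$n_inputs)
  }
  clip_ph(as.numeric(stats::predict(model$fit, base)))
}

#' @export
print.svr_stack <- function(x, ...) {
  cat(sprintf("<svr_stack> %d inputs, C=%g gamma=%g, CV RMSE %.4f\n",
              x$n_inputs, x$cost, x$gamma, x$cv_rmse))
  invisible(x)
}

# ---- kmer MLP ensemble for per-residue pKa --------------------------------

#' Configuration of the pKa kmer ensemble
#'
#' Nine member MLPs over kmer encodings of increasing window size, stacked
#' by an RBF SVR fitted on out-of-fold member predictions.  The member ->
#' kmer-size mapping is one member per odd size 3..15 plus two extra members
#' on size 9 with different seeds.
#'
#' @param kmer_sizes Window size per member (default c(3,5,7,9,11,13,15,9,9)).
#' @param scale_ids Bundled property scales appended per window position
#'   (default hydropathy, charge at pH 7, Hopp-Woods hydrophilicity).
#' @param mlp An [mlp_config] for the members (default: three dense layers
#'   256/64/16 with dropout 0.2, 60-epoch cap).
#' @param stacker An [svr_config] for the stacker (input width 9).
#' @param stack_folds Folds used to generate out-of-fold member predictions
#'   for stacker training (default 3).
#' @return A `pka_ensemble_config` list.
#' @export
pka_ensemble_config <- function(kmer_sizes = c(3L, 5L, 7L, 9L, 11L, 13L,
                                               15L, 9L, 9L),
                                scale_ids = c("hydropathy_kd",
                                              "charge_at_ph7",
                                              "hydrophilicity_hw"),
                                mlp = mlp_config(epochs = 60L,
                                                 patience = 8L),
                                stacker = svr_config(n_inputs = NULL,
                                                     folds = 3L),
                                stack_folds = 3L) {
  stopifnot(length(kmer_sizes) == 9L, all(kmer_sizes %% 2 == 1),
            all(kmer_sizes >= 3), all(kmer_sizes <= 15),
            stack_folds >= 2)
  structure(list(kmer_sizes = as.integer(kmer_sizes),
                 scale_ids = scale_ids, mlp = mlp, stacker = stacker,
                 stack_folds = as.integer(stack_folds)),
            class = "pka_ensemble_config")
}

# Encode every site of a pKa dataset for one kmer size: one row per site.
encode_pka_sites <- function(ds, k, scales) {
  seq_cache <- new.env(parent = emptyenv())
  get_seq <- function(id, residues) {
    if (is.null(seq_cache[[id]])) {
      seq_cache[[id]] <- polypeptide(residues, id = id)
    }
    seq_cache[[id]]
  }
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    s <- get_seq(ds$id[i], ds$sequence[i])
    win <- if (ds$group[i] == "side_chain") {
      kmer_window(s, ds$position[i], k)
    } else {
      kmer_window(s, 1L, k, terminus = ds$group[i])
    }
    kmer_encode(win, scales)
  })
  do.call(rbind, rows)
}

#' Train the pKa kmer ensemble
#'
#' Trains the nine member MLPs on kmer encodings of the labelled sites, then
#' fits the SVR stacker on out-of-fold member predictions (members are
#' refitted per fold, so the stacker never sees a member's training
#' predictions).  A per-residue-type accuracy report over the out-of-fold
#' ensemble predictions is attached; residue types with fewer than 5
#' examples are excluded from the report with a warning.
#'
#' @param ds A [labelled_dataset] of kind `"pKa"` with >= 200 sites spanning
#'   >= 4 residue types.
#' @param cfg A [pka_ensemble_config].
#' @param seed Integer seed.
#' @return A `pka_ensemble` model with fields `members`, `stacker`,
#'   `type_report`, `oof_rmse`.
#' @export
train_pka_ensemble <- function(ds, cfg = pka_ensemble_config(), seed = 1L) {
  stopifnot(inherits(ds, "labelled_dataset"), attr(ds, "kind") == "pKa")
  n <- nrow(ds)
  if (n < 200) stop("need at least 200 labelled sites")
  type <- ifelse(ds$group == "side_chain", ds$residue, ds$group)
  if (length(unique(type)) < 4) {
    stop("need sites spanning at least 4 residue types")
  }
  rare <- names(which(table(type) < 5))
  if (length(rare) > 0) {
    warning("residue type(s) with < 5 examples excluded from the per-type ",
            "report: ", paste(rare, collapse = ", "))
  }
  scales <- lapply(cfg$scale_ids, property_scale_values)
  names(scales) <- cfg$scale_ids
  y <- ds$value
  enc <- lapply(cfg$kmer_sizes, encode_pka_sites, ds = ds, scales = scales)

  set.seed(seed)
  fold <- sample(rep_len(seq_len(cfg$stack_folds), n))
  oof <- matrix(NA_real_, n, 9L)
  for (f in seq_len(cfg$stack_folds)) {
    hold <- fold == f
    for (m in seq_len(9L)) {
      fit <- mlp_fit(enc[[m]][!hold, , drop = FALSE], y[!hold],
                     config = cfg$mlp, seed = seed + 100L * m + f)
      oof[hold, m] <- predict(fit, enc[[m]][hold, , drop = FALSE])
    }
  }
  members <- lapply(seq_len(9L), function(m) {
    mlp_fit(enc[[m]], y, config = cfg$mlp, seed = seed + 100L * m)
  })
  st <- svr_grid_fit(oof, y, cfg$stacker, seed = seed + 7L)
  oof_pred <- clip_ph(as.numeric(stats::predict(st$fit, oof)))
  keep <- !type %in% rare
  report <- pka_type_summary(oof_pred[keep],
                             subset_dataset(ds, which(keep)),
                             threshold = 0.5)
  structure(list(members = members, stacker = st, cfg = cfg, seed = seed,
                 scale_ids = cfg$scale_ids,
                 type_report = report,
                 oof_rmse = sqrt(mean((oof_pred - y)^2))),
            class = "pka_ensemble")
}

#' @export
print.pka_ensemble <- function(x, ...) {
  cat(sprintf("<pka_ensemble> 9 members (k = %s), stacker C=%g gamma=%g\n",
              paste(x$cfg$kmer_sizes, collapse = ","),
              x$stacker$cost, x$stacker$gamma))
  cat(sprintf("  out-of-fold RMSE %.4f over %d sites\n", x$oof_rmse,
              sum(x$type_report$n[x$type_report$type == "All"])))
  invisible(x)
}

#' Predict per-site pKa values
#'
#' When `positions` is omitted, every ionizable side chain (C, D, E, H, K,
#' R, Y) plus both terminal groups is predicted.
#'
#' @param model A fitted [train_pka_ensemble] result.
#' @param seq A [polypeptide].
#' @param positions Optional integer vector of side-chain positions (must be
#'   ionizable); termini are included only when `positions` is omitted.
#' @return Data.frame with `position` (NA for termini), `residue`, `group`,
#'   `pka` (clipped into \[0, 14\]).
#' @export
predict_pka <- function(model, seq, positions = NULL) {
  stopifnot(inherits(model, "pka_ensemble"), inherits(seq, "polypeptide"))
  sites <- if (is.null(positions)) {
    ionizable_sites(seq)
  } else {
    chars <- seq_chars(seq)
    if (any(positions < 1 | positions > seq$length)) {
      stop("position out of range")
    }
    data.frame(position = as.integer(positions),
               residue = chars[positions],
               group = "side_chain", stringsAsFactors = FALSE)
  }
  scales <- lapply(model$scale_ids, property_scale_values)
  names(scales) <- model$scale_ids
  ds_like <- data.frame(id = seq$id, sequence = seq$residues,
                        position = sites$position, residue = sites$residue,
                        group = sites$group, stringsAsFactors = FALSE)
  member_pred <- vapply(seq_len(9L), function(m) {
    X <- encode_pka_sites(ds_like, model$cfg$kmer_sizes[m], scales)
    predict(model$members[[m]], X)
  }, numeric(nrow(sites)))
  if (is.null(dim(member_pred))) {
    member_pred <- matrix(member_pred, nrow = nrow(sites))
  }
  sites$pka <- clip_ph(as.numeric(stats::predict(model$stacker$fit,
                                                 member_pred)))
  sites
}

#' Save / load a fitted model
#'
#' Single-file archive holding the model object (configuration, weights,
#' and any pKa-set provenance it records).
#'
#' @param model Any fitted model from this package.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
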