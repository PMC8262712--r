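# Dataset handling and the metric suite: clustering, 75/25 splits, 10-fold
# cross-validation, RMSE/MAE/r2/outliers, and the benchmark harness.

#' Labelled dataset container
#'
#' Wraps a data.frame of experimentally labelled records.  For pI data the
#' columns are `id`, `sequence`, `value`; for pKa data additionally
#' `position` (1-based, NA for termini), `residue` and `group`.
#'
#' @param df Records data.frame.
#' @param kind `"pI"` or `"pKa"`.
#' @param provenance Free-text provenance tag.
#' @param split Split tag: `"none"`, `"train75"` or `"test25"`.
#' @return A `labelled_dataset` (data.frame subclass).
#' @export
labelled_dataset <- function(df, kind = c("pI", "pKa"),
                             provenance = "", split = "none") {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(df), all(c("sequence", "value") %in% names(df)))
  if (!"id" %in% names(df)) df$id <- sprintf("rec%05d", seq_len(nrow(df)))
  if (any(df$value <= 0 | df$value >= 14)) {
    stop("labels must lie in the open interval (0, 14)")
  }
  if (kind == "pKa" && !all(c("position", "residue", "group") %in% names(df))) {
    stop("pKa datasets need position, residue and group columns")
  }
  structure(df, class = c("labelled_dataset", "data.frame"),
            kind = kind, provenance = provenance, split = split)
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> kind=%s n=%d split=%s %s\n",
              attr(x, "kind"), nrow(x), attr(x, "split"),
              attr(x, "provenance")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

dataset_sequences <- function(ds) {
  lapply(seq_len(nrow(ds)),
         function(i) polypeptide(ds$sequence[i], id = ds$id[i]))
}

#' Merge duplicate records and average their labels
#'
#' Identical sequences (for pKa data: identical (sequence, site) pairs) are
#' merged into one record whose label is the arithmetic mean of the merged
#' labels.  The number of records merged into each row is recorded in a
#' `merged` column.
#'
#' @param ds A [labelled_dataset].
#' @return A clustered [labelled_dataset]; idempotent.
#' @export
cluster_and_average <- function(ds) {
  stopifnot(inherits(ds, "labelled_dataset"))
  kind <- attr(ds, "kind")
  key <- if (kind == "pI") ds$sequence else {
    paste(ds$sequence, ds$position, ds$group, sep = "\r")
  }
  first <- !duplicated(key)
  idx <- match(key, key[first])
  value <- as.numeric(tapply(ds$value, idx, mean))
  merged_prev <- if ("merged" %in% names(ds)) ds$merged else rep(1L, nrow(ds))
  merged <- as.integer(tapply(merged_prev, idx, sum))
  out <- as.data.frame(ds)[first, , drop = FALSE]
  out$value <- value
  out$merged <- merged
  rownames(out) <- NULL
  labelled_dataset(out, kind = kind,
                   provenance = attr(ds, "provenance"),
                   split = attr(ds, "split"))
}

#' Random 75/25 train/test split
#'
#' @param ds A clustered [labelled_dataset].
#' @param fraction Test fraction (default 0.25).
#' @param seed Integer seed; the split is seed-reproducible.
#' @return List with elements `train75` and `test25`, disjoint and
#'   exhaustive, test size = round(n * fraction).
#' @export
split_dataset <- function(ds, fraction = 0.25, seed) {
  stopifnot(inherits(ds, "labelled_dataset"), fraction > 0, fraction < 1)
  if (missing(seed)) stop("split_dataset() requires an explicit seed")
  n <- nrow(ds)
  if (n < 4) stop("dataset too small to split (n < 4)")
  set.seed(seed)
  n_test <- round(n * fraction)
  test_idx <- sort(sample.int(n, n_test))
  mk <- function(rows, tag) {
    out <- as.data.frame(ds)[rows, , drop = FALSE]
    rownames(out) <- NULL
    labelled_dataset(out, kind = attr(ds, "kind"),
                     provenance = attr(ds, "provenance"), split = tag)
  }
  list(train75 = mk(setdiff(seq_len(n), test_idx), "train75"),
       test25 = mk(test_idx, "test25"))
}

#' Regression metric suite
#'
#' RMSE, MAE, squared Pearson correlation, coefficient of determination, and
#' the outlier count at a pH-unit threshold (strict `>` at the boundary).
#' With a zero-variance experimental vector the correlation is undefined and
#' reported as NA with a warning.
#'
#' @param predicted,experimental Equal-length numeric vectors, n >= 2.
#' @param threshold Outlier threshold in pH units: the convention is 0.5 for
#'   proteins and pKa values, 0.25 for peptides.
#' @param method Optional method name carried into the report.
#' @return An `evaluation_report` (one-row data.frame): method, n, rmse,
#'   mae, r2_pearson, r2_determination, outliers, threshold.
#' @export
metrics <- function(predicted, experimental, threshold = 0.5,
                    method = "method") {
  stopifnot(length(predicted) == length(experimental),
            length(predicted) >= 2)
  if (any(!is.finite(predicted)) || any(!is.finite(experimental))) {
    stop("metrics() requires finite inputs")
  }
  err <- predicted - experimental
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (stats::sd(experimental) == 0) {
    warning("experimental values have zero variance; correlation undefined")
    r2p <- NA_real_
  } else if (stats::sd(predicted) == 0) {
    r2p <- NA_real_
  } else {
    r2p <- stats::cor(predicted, experimental)^2
  }
  ss_res <- sum(err^2)
  ss_tot <- sum((experimental - mean(experimental))^2)
  r2d <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(data.frame(method = method, n = length(err), rmse = rmse,
                       mae = mae, r2_pearson = r2p, r2_determination = r2d,
                       outliers = sum(abs(err) > threshold),
                       threshold = threshold, stringsAsFactors = FALSE),
            class = c("evaluation_report", "data.frame"))
}

#' K-fold cross-validation
#'
#' Folds partition the records exactly; pooled metrics are computed over the
#' concatenated out-of-fold predictions, so the pooled n equals the dataset
#' n.
#'
#' @param model_factory `function(train_ds)` returning an object with a
#'   `function(test_ds)` semantic: either a function to call on the held-out
#'   split, or an object for which `predict_fn(model, test_ds)` works.
#' @param ds A [labelled_dataset].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param threshold Outlier threshold for the reports.
#' @param predict_fn Called as `predict_fn(model, test_ds)`; default treats
#'   the factory result as a function.
#' @return List with `fold_reports` (one [metrics] row per fold), `pooled`
#'   (metrics over concatenated out-of-fold predictions), `assignments`
#'   (fold id per record) and `predictions`.
#' @export
cross_validate <- function(model_factory, ds, folds = 10, seed,
                           threshold = 0.5,
                           predict_fn = function(model, test) model(test)) {
  stopifnot(inherits(ds, "labelled_dataset"))
  if (missing(seed)) stop("cross_validate() requires an explicit seed")
  n <- nrow(ds)
  if (folds > n) stop("more folds than records")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    hold <- which(assign == f)
    train <- subset_dataset(ds, setdiff(seq_len(n), hold))
    test <- subset_dataset(ds, hold)
    model <- model_factory(train)
    p <- predict_fn(model, test)
    pred[hold] <- p
    reports[[f]] <- metrics(p, ds$value[hold], threshold = threshold,
                            method = sprintf("fold%02d", f))
  }
  list(fold_reports = do.call(rbind, reports),
       pooled = metrics(pred, ds$value, threshold = threshold,
                        method = "pooled"),
       assignments = assign, predictions = pred)
}

subset_dataset <- function(ds, rows) {
  out <- as.data.frame(ds)[rows, , drop = FALSE]
  rownames(out) <- NULL
  labelled_dataset(out, kind = attr(ds, "kind"),
                   provenance = attr(ds, "provenance"),
                   split = attr(ds, "split"))
}

#' Benchmark pKa-set methods on a labelled pI dataset
#'
#' Runs every named method over the dataset and tabulates the metric suite,
#' sorted by RMSE ascending (ties broken by method name), in the layout of a
#' published method-comparison table: RMSE, MAE, r2, outliers.  A method
#' that fails on any sequence is reported as invalid (NA metrics) without
#' affecting the others.
#'
#' @param methods Character vector of registry set names, or a named list
#'   mixing [pka_set] objects and prediction functions
#'   `function(seqs) numeric`.
#' @param ds A [labelled_dataset] of kind `"pI"`.
#' @param threshold Outlier threshold (0.5 proteins / 0.25 peptides).
#' @return A `benchmark_table` data.frame of [metrics] rows plus an
#'   `invalid` flag column.
#' @export
benchmark <- function(methods, ds, threshold = 0.5) {
  stopifnot(inherits(ds, "labelled_dataset"), attr(ds, "kind") == "pI")
  if (is.character(methods)) {
    methods <- stats::setNames(as.list(methods), methods)
  }
  stopifnot(length(names(methods)) == length(methods),
            all(nzchar(names(methods))))
  seqs <- dataset_sequences(ds)
  rows <- lapply(names(methods), function(nm) {
    m <- methods[[nm]]
    pred <- tryCatch({
      if (is.function(m)) m(seqs) else predict_pi(seqs, m)
    }, error = function(e) e)
    if (inherits(pred, "error")) {
      r <- data.frame(method = nm, n = nrow(ds), rmse = NA_real_,
                      mae = NA_real_, r2_pearson = NA_real_,
                      r2_determination = NA_real_, outliers = NA_integer_,
                      threshold = threshold, stringsAsFactors = FALSE)
      r$invalid <- TRUE
      return(r)
    }
    r <- metrics(pred, ds$value, threshold = threshold, method = nm)
    r$invalid <- FALSE
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$invalid, out$rmse, out$method), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' Per-residue-type pKa accuracy summary
#'
#' Summarizes per-site pKa predictions against experimental values by
#' residue type (the layout of a per-type accuracy table): n, mean and sd of
#' the experimental values, RMSE, MAE and outliers at the given threshold.
#'
#' @param predicted Numeric vector of per-site predictions.
#' @param ds A [labelled_dataset] of kind `"pKa"` (same row order).
#' @param threshold Outlier threshold (default 0.5).
#' @return Data.frame with one row per residue type plus an `All` row.
#' @export
pka_type_summary <- function(predicted, ds, threshold = 0.5) {
  stopifnot(inherits(ds, "labelled_dataset"), attr(ds, "kind") == "pKa",
            length(predicted) == nrow(ds))
  type <- ifelse(ds$group == "side_chain", ds$residue, ds$group)
  types <- sort(unique(type))
  one <- function(sel, label) {
    err <- predicted[sel] - ds$value[sel]
    data.frame(type = label, n = sum(sel),
               mean_exp = mean(ds$value[sel]),
               sd_exp = stats::sd(ds$value[sel]),
               rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
               outliers = sum(abs(err) > threshold),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(types, function(tp) one(type == tp, tp))
  out <- rbind(do.call(rbind, rows), one(rep(TRUE, nrow(ds)), "All"))
  rownames(out) <- NULL
  out
}

# ---- dataset file I/O ------------------------------------------------------

#' Read a labelled dataset from TSV
#'
#' Tab-separated with a header; columns `id`, `sequence`, `value` for pI
#' data, plus `position`, `residue`, `group` for pKa data.  This is the
#' dialect [write_labelled_dataset()] emits and the benchmark harness reads.
#'
#' @param path File path.
#' @param kind `"pI"` or `"pKa"`; default inferred from the columns.
#' @return A [labelled_dataset].
#' @export
read_labelled_dataset <- function(path, kind = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(kind)) {
    kind <- if ("position" %in% names(df)) "pKa" else "pI"
  }
  if (kind == "pKa" && !"group" %in% names(df)) {
    df$group <- ifelse(is.na(df$position), NA_character_, "side_chain")
  }
  labelled_dataset(df, kind = kind, provenance = path)
}

#' Write a labelled dataset as TSV
#'
#' @param ds A [labelled_dataset].
#' @param path File path.
#' @export
write_labelled_dataset <- function(ds, path) {
  utils::write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
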