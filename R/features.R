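# Model inputs: one-hot encodings, property-scale channels with univariate
# selection, kmer windows centred on ionizable residues, base-method
# prediction vectors, and the four-channel peptide tensor.

the_scales <- new.env(parent = emptyenv())

#' Bundled amino-acid property scales
#'
#' Returns the bundled canonical subset of property scales (hydropathy,
#' bulkiness, polarity, secondary-structure propensities, ...), each a named
#' numeric vector over the 20 standard residues.  The full AAindex
#' collection can be loaded with [read_aaindex()] and used anywhere a scale
#' table is accepted.
#'
#' @return Named list of named numeric vectors (class `property_scales`).
#' @export
property_scales <- function() {
  if (is.null(the_scales$tables)) {
    path <- system.file("extdata", "property_scales.json", package = "seqpka")
    js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    tabs <- lapply(js$scales, function(rec) {
      v <- unlist(rec$values)[AA20]
      attr(v, "description") <- rec$description
      v
    })
    the_scales$tables <- structure(tabs, class = "property_scales")
  }
  the_scales$tables
}

property_scale_values <- function(id) {
  tabs <- property_scales()
  if (!id %in% names(tabs)) {
    stop("unknown property scale '", id, "'")
  }
  tabs[[id]]
}

#' Read AAindex1 flat-file records
#'
#' Parses the standard AAindex1 record format: `H` lines carry the accession,
#' `I` starts the value block of two rows of ten values in the fixed
#' `A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V` layout, records end with `//`.
#' Records with missing (`NA`) values are dropped.
#'
#' @param path Path to an AAindex1-format file.
#' @return Named list of named numeric vectors over the 20 standard residues.
#' @export
read_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  acc <- NULL
  i <- 1L
  row_order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row_order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      acc <- trimws(substring(ln, 3))
    } else if (startsWith(ln, "I ") && !is.null(acc)) {
      v1 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1L]),
                                                 "\\s+")[[1L]]))
      v2 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L]),
                                                 "\\s+")[[1L]]))
      i <- i + 2L
      if (length(v1) == 10L && length(v2) == 10L &&
          !anyNA(c(v1, v2))) {
        v <- stats::setNames(c(v1, v2), c(row_order1, row_order2))[AA20]
        out[[acc]] <- v
      }
    }
    i <- i + 1L
  }
  structure(out, class = "property_scales")
}

#' One-hot encode a sequence
#'
#' Fixed column order: the 20 standard residues alphabetically, then X, then
#' the padding symbol.  Shorter sequences are right-padded (one-hot on the
#' padding column); longer sequences are truncated from the right.
#'
#' @param seq A [polypeptide].
#' @param max_len Row count: 60 for peptide mode, 1000 for protein mode.
#' @return A `max_len` x 22 0/1 matrix; every row sums to exactly 1.
#' @export
one_hot_encode <- function(seq, max_len = 60L) {
  stopifnot(inherits(seq, "polypeptide"), max_len >= 1)
  chars <- seq_chars(seq)
  if (length(chars) > max_len) chars <- chars[seq_len(max_len)]
  chars <- c(chars, rep(AA_PAD, max_len - length(chars)))
  m <- matrix(0, nrow = max_len, ncol = 22L,
              dimnames = list(NULL, AA22))
  m[cbind(seq_len(max_len), match(chars, AA22))] <- 1
  m
}

# F-statistic of a simple linear regression of y on x (the univariate
# regression score used for scale selection).
f_regression_score <- function(x, y) {
  if (stats::sd(x) == 0) return(0)
  r <- stats::cor(x, y)
  n <- length(x)
  r^2 * (n - 2) / max(1 - r^2, .Machine$double.eps)
}

# Binned mutual information between two continuous variables, in nats.
# Equal-frequency bins; a simple plug-in estimate, invariant to monotone
# (hence affine) rescaling of either variable.
binned_mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (is.null(bins)) bins <- max(2L, min(8L, floor(n / 5)))
  cut_ef <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bx <- cut_ef(x); by <- cut_ef(y)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Univariate selection of informative property scales
#'
#' Scores every scale against the dataset labels by (i) the univariate
#' regression F-statistic and (ii) binned mutual information, using the mean
#' scale value over each sequence's residues as the per-sequence feature.
#' Returns the union of the top-k scales under each criterion (k capped at
#' 10 per criterion); constant scales are excluded.
#'
#' @param tables Named list of scales (e.g. [property_scales()] or
#'   [read_aaindex()] output).
#' @param ds A [labelled_dataset] with at least 20 records.
#' @param k Scales to keep per criterion (<= 10).
#' @return List with `f_regression` and `mutual_info` (ranked scale ids with
#'   scores) and `selected` (union of ids, F-ranking first).
#' @export
select_informative_scales <- function(tables, ds, k = 10) {
  stopifnot(inherits(ds, "labelled_dataset"), nrow(ds) >= 20)
  k <- min(as.integer(k), 10L)
  usable <- Filter(function(v) stats::sd(v) > 0, tables)
  if (length(usable) == 0) stop("all scales are constant")
  seqs <- dataset_sequences(ds)
  feat <- vapply(usable, function(scale) {
    vapply(seqs, function(s) {
      ch <- seq_chars(s)
      mean(scale[ch[ch != AA_X]])
    }, numeric(1))
  }, numeric(length(seqs)))
  y <- ds$value
  fs <- apply(feat, 2, f_regression_score, y = y)
  mi <- apply(feat, 2, binned_mutual_information, y = y)
  top <- function(scores) {
    o <- order(scores, decreasing = TRUE)[seq_len(min(k, length(scores)))]
    stats::setNames(scores[o], colnames(feat)[o])
  }
  f_top <- top(fs); mi_top <- top(mi)
  list(f_regression = f_top, mutual_info = mi_top,
       selected = union(names(f_top), names(mi_top)))
}

#' Extract a kmer window centred on an ionizable residue
#'
#' @param seq A [polypeptide].
#' @param centre 1-based centre position; must hold an ionizable residue
#'   (C, D, E, H, K, R, Y) unless `terminus` names a terminal-group proxy.
#' @param k Odd window size between 3 and 15.
#' @param terminus `"n_term"` / `"c_term"` to centre on a terminal group:
#'   the window is then built around a virtual centre just outside the chain
#'   (position 0 or length + 1), so the centre symbol is the padding token —
#'   a terminus proxy that no side-chain window can produce.  NA (default)
#'   for a side-chain site.
#' @return A `kmer_window` list: `centre`, `residue` (`-` for a terminus
#'   proxy), `k`, `window` (length-k string, `-` beyond the sequence ends),
#'   `group`.
#' @export
kmer_window <- function(seq, centre, k, terminus = NA_character_) {
  stopifnot(inherits(seq, "polypeptide"))
  if (k %% 2 == 0 || k < 3 || k > 15) {
    stop("k must be odd and between 3 and 15")
  }
  chars <- seq_chars(seq)
  L <- length(chars)
  if (!is.na(terminus)) {
    terminus <- match.arg(terminus, c("n_term", "c_term"))
    centre <- if (terminus == "n_term") 0L else L + 1L
  } else {
    if (centre < 1 || centre > L) stop("centre position out of range")
    if (!chars[centre] %in% IONIZABLE_AA) {
      stop("centre residue '", chars[centre], "' at position ", centre,
           " is not ionizable")
    }
  }
  half <- (k - 1L) %/% 2L
  at <- (centre - half):(centre + half)
  win <- rep(AA_PAD, k)
  inside <- at >= 1L & at <= L
  win[inside] <- chars[at[inside]]
  structure(list(centre = as.integer(centre),
                 residue = if (is.na(terminus)) chars[centre] else AA_PAD,
                 k = as.integer(k), window = paste(win, collapse = ""),
                 group = if (is.na(terminus)) "side_chain" else terminus),
            class = "kmer_window")
}

# Numeric encoding of a kmer window: flattened k x 22 one-hot plus the
# per-position values of each scale (0 at padding), plus a 3-level group
# indicator (side chain / N-term / C-term).
kmer_encode <- function(window, scales) {
  chars <- strsplit(window$window, "", fixed = TRUE)[[1L]]
  oh <- matrix(0, nrow = window$k, ncol = 22L)
  oh[cbind(seq_len(window$k), match(chars, AA22))] <- 1
  scale_feats <- unlist(lapply(scales, function(sc) {
    v <- sc[chars]
    v[is.na(v)] <- 0  # padding and X contribute nothing
    rng <- max(sc) - min(sc)
    (v - min(sc)) / ifelse(rng == 0, 1, rng)
  }), use.names = FALSE)
  grp <- c(side_chain = 0, n_term = 1, c_term = 2)[window$group]
  c(as.numeric(oh), scale_feats,
    grp == 0, grp == 1, grp == 2)
}

#' Default base methods for the stacking ensemble
#'
#' The 19 Henderson-Hasselbalch methods whose predictions form the input
#' vector of the stacked pI regressor: the 17 plain registry sets plus the
#' position-aware Bjellqvist and ProMoST methods.  The order is fixed.
#'
#' @return Character vector of 19 method names.
#' @export
default_base_methods <- function() {
  reg <- pka_registry()
  plain <- names(reg)[vapply(reg, function(s) is.null(s$positional),
                             logical(1))]
  c(sort(plain), "Bjellqvist", "ProMoST")
}

#' Base-method pI prediction vector
#'
#' @param seq A [polypeptide].
#' @param methods Ordered character vector of registry method names
#'   (default: [default_base_methods()], 19 entries).  Unknown names are an
#'   error, never a silent NA.
#' @return Named numeric vector of pI predictions in method order.
#' @export
base_method_vector <- function(seq, methods = default_base_methods()) {
  vapply(methods, function(nm) isoelectric_point(seq, get_pka_set(nm)),
         numeric(1))
}

# Base-method prediction matrix for a list of sequences (n x length(methods)),
# vectorized per method.
base_method_matrix <- function(seqs, methods = default_base_methods()) {
  m <- vapply(methods, function(nm) predict_pi(seqs, get_pka_set(nm)),
              numeric(length(seqs)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(seqs))
  colnames(m) <- methods
  m
}

#' Build the four-channel peptide tensor
#'
#' Encodes one peptide (<= 60 residues) as the 60 x 22 x 4 model input:
#' channel 1 is the one-hot sequence; channel 2 holds per-residue values of
#' the selected property scales, one scale per column (min-max scaled over
#' the 20 residues, zero at padding); channel 3 broadcasts the nine
#' ionizable-group counts (divided by length) down their own columns;
#' channel 4 broadcasts the base-method pI prediction (divided by 14) down
#' column 1.
#'
#' @param seq A [polypeptide] of length <= 60 (longer is an error in
#'   peptide mode).
#' @param scales Named list of selected scales (at most 22).
#' @param base_pi Base-method pI prediction for the sequence, e.g. the
#'   IPC_peptide value; computed if NULL.
#' @param max_len Tensor length (default 60).
#' @return A 60 x 22 x 4 numeric array.
#' @export
build_peptide_tensor <- function(seq, scales, base_pi = NULL,
                                 max_len = 60L) {
  stopifnot(inherits(seq, "polypeptide"))
  if (seq$length > max_len) {
    stop("peptide longer than ", max_len,
         " residues; peptide mode does not truncate")
  }
  if (length(scales) > 22L) stop("at most 22 scales fit the channel")
  if (is.null(base_pi)) {
    base_pi <- isoelectric_point(seq, get_pka_set("IPC_peptide"))
  }
  chars <- seq_chars(seq)
  tensor <- array(0, dim = c(max_len, 22L, 4L))
  tensor[, , 1L] <- one_hot_encode(seq, max_len)
  for (j in seq_along(scales)) {
    sc <- scales[[j]]
    rng <- max(sc) - min(sc)
    v <- (sc[chars] - min(sc)) / ifelse(rng == 0, 1, rng)
    v[is.na(v)] <- 0
    tensor[seq_along(chars), j, 2L] <- v
  }
  comp <- composition_vector(ionizable_composition(seq))
  tensor[, seq_len(9L), 3L] <- matrix(comp / seq$length,
                                      nrow = max_len, ncol = 9L,
                                      byrow = TRUE)
  tensor[, 1L, 4L] <- base_pi / 14
  tensor
}

# Batch of peptide tensors: n x 60 x 22 x 4 array.
peptide_tensor_batch <- function(seqs, scales, base_method = "IPC_peptide",
                                 max_len = 60L) {
  base <- predict_pi(seqs, get_pka_set(base_method))
  out <- array(0, dim = c(length(seqs), max_len, 22L, 4L))
  for (i in seq_along(seqs)) {
    out[i, , , ] <- build_peptide_tensor(seqs[[i]], scales,
                                         base_pi = base[i],
                                         max_len = max_len)
  }
  out
}
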