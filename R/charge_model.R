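# Henderson-Hasselbalch net charge and isoelectric point.
#
# The net charge of a polypeptide at a given pH is the sum over ionizable
# groups g of the expected charge of that group:
#   basic groups  (N-terminus, H, K, R):  +n_g / (1 + 10^(pH - pKa_g))
#   acidic groups (C-terminus, C, D, E, Y): -n_g / (1 + 10^(pKa_g - pH))
# Q(pH) is strictly decreasing, so the isoelectric point (Q = 0) is a unique
# root, found here by bisection.

# Resolve a sequence (or composition) under a pKa set into charge terms:
# a data.frame with one row per distinct (pKa, sign) group and its count.
# Position-aware sets need the full sequence.
charge_terms <- function(x, set) {
  stopifnot(inherits(set, "pka_set"))
  if (inherits(x, "ionizable_composition")) {
    if (!is.null(set$positional)) {
      stop("pKa set '", set$name,
           "' is position-aware and needs the full sequence, ",
           "not just its composition")
    }
    comp <- x
    chars <- NULL
  } else {
    stopifnot(inherits(x, "polypeptide"))
    comp <- ionizable_composition(x)
    chars <- seq_chars(x)
  }

  if (is.null(set$positional)) {
    sc <- set$side_chain
    pka <- c(set$n_term, set$c_term, unname(sc))
    grp <- c("n_term", "c_term", names(sc))
    n <- c(1, 1, unname(comp$counts[names(sc)]))
  } else if (set$positional$style == "bjellqvist") {
    pos <- set$positional
    first <- chars[1L]
    last <- chars[length(chars)]
    nt <- pos$n_term_by_first[first]
    if (is.na(nt)) nt <- pos$n_term_default
    sc <- set$side_chain
    n <- unname(comp$counts[names(sc)])
    grp <- names(sc)
    pka_sc <- unname(sc)
    # the C-terminal residue's own side chain may use an adjusted pKa
    extra_pka <- numeric(0); extra_grp <- character(0); extra_n <- numeric(0)
    if (last %in% names(pos$c_terminal_side_chain)) {
      i <- match(last, grp)
      n[i] <- n[i] - 1
      extra_pka <- unname(pos$c_terminal_side_chain[last])
      extra_grp <- last
      extra_n <- 1
    }
    pka <- c(nt, set$c_term, pka_sc, extra_pka)
    grp <- c("n_term", "c_term", grp, extra_grp)
    n <- c(1, 1, n, extra_n)
  } else {  # promost
    pos <- set$positional
    L <- length(chars)
    term <- pos$terminal_by_residue
    t_n <- term[[chars[1L]]]; if (is.null(t_n)) t_n <- term[["X"]]
    t_c <- term[[chars[L]]];  if (is.null(t_c)) t_c <- term[["X"]]
    pka <- c(t_n[1L], t_c[2L])
    grp <- c("n_term", "c_term")
    n <- c(1, 1)
    for (aa in names(pos$side_chain3)) {
      at <- which(chars == aa)
      if (length(at) == 0L) next
      v3 <- pos$side_chain3[[aa]]
      cls <- ifelse(at == 1L, 1L, ifelse(at == L, 3L, 2L))
      for (k in 1:3) {
        m <- sum(cls == k)
        if (m > 0L) {
          pka <- c(pka, v3[k]); grp <- c(grp, aa); n <- c(n, m)
        }
      }
    }
  }
  keep <- n > 0
  data.frame(group = grp[keep], pka = pka[keep],
             sign = unname(GROUP_SIGN[grp[keep]]), n = n[keep],
             stringsAsFactors = FALSE)
}

# Q(pH) from a charge-terms table; vectorized over pH.
charge_from_terms <- function(terms, pH) {
  q <- numeric(length(pH))
  for (i in seq_len(nrow(terms))) {
    if (terms$sign[i] > 0) {
      q <- q + terms$n[i] / (1 + 10^(pH - terms$pka[i]))
    } else {
      q <- q - terms$n[i] / (1 + 10^(terms$pka[i] - pH))
    }
  }
  q
}

#' Net charge at a given pH
#'
#' Evaluates the Henderson-Hasselbalch net charge of a sequence (or of an
#' [ionizable_composition], for sets without positional overrides) under a
#' pKa set.  Vectorized over `pH`.
#'
#' @param x A [polypeptide] or [ionizable_composition].
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @param set A [pka_set] or registry set name.
#' @return Net charge in elementary-charge units, one value per `pH`.
#' @examples
#' net_charge(polypeptide("ACDK"), 7, "EMBOSS")
#' @export
net_charge <- function(x, pH, set) {
  if (is.character(set)) set <- get_pka_set(set)
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  charge_from_terms(charge_terms(x, set), pH)
}

#' Isoelectric point by bisection
#'
#' Finds the unique root of the net-charge curve on \[0, 14\] by bisection.
#' Because every unmodified chain has both termini, the curve always crosses
#' zero and the root is unique (Q is strictly decreasing).
#'
#' @param seq A [polypeptide] (or [ionizable_composition] for plain sets).
#' @param set A [pka_set] or registry set name.
#' @param tol Bisection tolerance in pH units (default 1e-3).
#' @param max_iter Maximum bisection iterations.
#' @return The pI in pH units.
#' @examples
#' isoelectric_point(polypeptide("ACDK"), "EMBOSS")
#' @export
isoelectric_point <- function(seq, set, tol = 1e-3, max_iter = 100L) {
  if (is.character(set)) set <- get_pka_set(set)
  stopifnot(tol > 0)
  terms <- charge_terms(seq, set)
  lo <- 0; hi <- 14
  q_lo <- charge_from_terms(terms, lo)
  q_hi <- charge_from_terms(terms, hi)
  if (q_lo < 0 || q_hi > 0) {
    stop("net charge does not change sign on [0, 14]; ",
         "cannot bracket an isoelectric point")
  }
  iter <- 0L
  while ((hi - lo) > tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    if (charge_from_terms(terms, mid) > 0) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  (lo + hi) / 2
}

#' Net-charge profile over a pH grid
#'
#' @param seq A [polypeptide].
#' @param set A [pka_set] or registry set name.
#' @param step Grid step in pH units (default 0.1).
#' @return An object of class `charge_profile`: list with `pH`, `charge`,
#'   and the set name.  Supports `plot()`.
#' @export
charge_profile <- function(seq, set, step = 0.1) {
  if (is.character(set)) set <- get_pka_set(set)
  stopifnot(step > 0)
  grid <- seq(0, 14, by = step)
  structure(list(pH = grid,
                 charge = charge_from_terms(charge_terms(seq, set), grid),
                 set = set$name, id = if (inherits(seq, "polypeptide")) seq$id else ""),
            class = "charge_profile")
}

#' @export
plot.charge_profile <- function(x, ...) {
  plot(x$pH, x$charge, type = "l", xlab = "pH",
       ylab = "net charge (e)", main = sprintf("%s (%s)", x$id, x$set), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# ---- vectorized multi-sequence path (used by the optimizer and benchmarks) -

# n x 9 matrix of group counts over GROUP_ORDER for a list of polypeptides.
composition_matrix <- function(seqs) {
  m <- t(vapply(seqs,
                function(s) composition_vector(ionizable_composition(s)),
                numeric(9)))
  colnames(m) <- GROUP_ORDER
  m
}

# Vectorized net charge for a counts matrix at per-row pH values.
charge_for_counts <- function(counts, pH, pka9) {
  q <- numeric(nrow(counts))
  for (g in seq_len(9L)) {
    if (is.na(pka9[g])) next
    if (GROUP_SIGN[GROUP_ORDER[g]] > 0) {
      q <- q + counts[, g] / (1 + 10^(pH - pka9[g]))
    } else {
      q <- q - counts[, g] / (1 + 10^(pka9[g] - pH))
    }
  }
  q
}

# Vectorized bisection pI for all rows of a counts matrix under one
# 9-vector of pKa values (NA = group absent).  Workhorse of the DE objective.
pi_for_counts <- function(counts, pka9, tol = 1e-3) {
  n <- nrow(counts)
  lo <- rep(0, n); hi <- rep(14, n)
  iters <- ceiling(log2(14 / tol))
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- charge_for_counts(counts, mid, pka9) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Predict isoelectric points for many sequences
#'
#' @param seqs List of [polypeptide] objects (or a single one).
#' @param set A [pka_set] or registry set name.
#' @param tol Solver tolerance in pH units.
#' @return Numeric vector of pI values, one per sequence.
#' @export
predict_pi <- function(seqs, set, tol = 1e-3) {
  if (inherits(seqs, "polypeptide")) seqs <- list(seqs)
  if (is.character(set)) set <- get_pka_set(set)
  if (is.null(set$positional)) {
    counts <- composition_matrix(seqs)
    pka9 <- pka_vector(set)
    pi_for_counts(counts, pka9, tol = tol)
  } else {
    vapply(seqs, isoelectric_point, numeric(1), set = set, tol = tol)
  }
}
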