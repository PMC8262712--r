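# Independent oracles used across the suite.  These deliberately do not
# share code with the package's charge model: net charge is summed term by
# term over an explicit residue loop, and the pI oracle is an exhaustive
# grid argmin of |Q|.

# Plain (non-positional) sets only: explicit per-group summation.
oracle_charge_fun <- function(seq_string, set) {
  chars <- strsplit(toupper(seq_string), "")[[1]]
  sc <- set$side_chain
  basic <- c("H", "K", "R")
  function(pH) {
    q <- 1 / (1 + 10^(pH - set$n_term)) - 1 / (1 + 10^(set$c_term - pH))
    for (aa in names(sc)) {
      n <- sum(chars == aa)
      if (n == 0) next
      q <- q + if (aa %in% basic) {
        n / (1 + 10^(pH - sc[[aa]]))
      } else {
        -n / (1 + 10^(sc[[aa]] - pH))
      }
    }
    q
  }
}

# Exhaustive grid argmin of |Q| with the stated 1e-4 step.
oracle_grid_pi <- function(qfun, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(qfun(grid)))]
}

# Seed-controlled random peptides (caller sets the seed).
random_peptides <- function(n, len_range = c(3, 30), ionizable_boost = 2) {
  w <- stats::setNames(rep(1, 20), seqpka:::AA20)
  w[seqpka:::IONIZABLE_AA] <- ionizable_boost
  w <- w / sum(w)
  lapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    polypeptide(paste(sample(seqpka:::AA20, len, replace = TRUE, prob = w),
                      collapse = ""), id = sprintf("rnd%04d", i))
  })
}

# A small fitted pKa ensemble shared between test files (helpers are loaded
# once per test run); trained lazily on first use.
shared_models <- new.env(parent = emptyenv())

tiny_pka_model <- function() {
  if (is.null(shared_models$pka)) {
    w <- stats::setNames(rep(1, 20), seqpka:::AA20)
    cfg <- generator_config(n = 8L, length_range = c(70L, 110L),
                            composition_weights = w, noise_sd = 0.1,
                            context_coef = rep(0, 6), seed = 77)
    ds <- generate_pka_dataset(cfg)
    shared_models$pka_data <- ds
    shared_models$pka <- suppressWarnings(
      train_pka_ensemble(ds, tiny_ensemble_config(), seed = 2))
  }
  shared_models$pka
}

# Small pKa-ensemble configuration for fast unit tests (the full-size
# defaults are exercised by the acceptance suite).
tiny_ensemble_config <- function() {
  pka_ensemble_config(
    mlp = mlp_config(widths = c(64L, 32L, 16L), dropout = 0.1,
                     epochs = 80L, patience = 15L),
    stack_folds = 2L,
    stacker = svr_config(cost_grid = c(1, 10, 100),
                         gamma_grid = c(0.01, 0.1),
                         folds = 2L, n_inputs = NULL))
}
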