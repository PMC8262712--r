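#' Construct a pKa set
#'
#' A pKa set holds the dissociation constants used by the
#' Henderson-Hasselbalch charge model: one value for each free terminus and
#' one per ionizable side chain.  Side chains a method treats as
#' non-titratable may be omitted.  Position-aware methods (Bjellqvist,
#' ProMoST) additionally carry positional override tables and require the
#' full sequence rather than just its composition.
#'
#' @param name Set name.
#' @param n_term,c_term Terminal group pKa values (pH units).
#' @param side_chain Named numeric vector over a subset of C, D, E, H, K, R, Y.
#' @param positional Optional positional override list (see the bundled JSON
#'   resource for the two supported layouts).
#' @param source Free-text provenance note.
#' @return An object of class `pka_set`.
#' @examples
#' pka_set("toy", n_term = 9, c_term = 2,
#'         side_chain = c(D = 4, E = 4.4, K = 10.5))
#' @export
pka_set <- function(name, n_term, c_term, side_chain,
                    positional = NULL, source = "") {
  side_chain <- unlist(side_chain)
  stopifnot(is.numeric(n_term), is.numeric(c_term), is.numeric(side_chain))
  extra <- setdiff(names(side_chain), IONIZABLE_AA)
  if (length(extra) > 0L) {
    stop("unknown side-chain group(s): ", paste(extra, collapse = ", "))
  }
  vals <- c(n_term, c_term, side_chain)
  if (any(vals <= 0 | vals >= 14)) {
    stop("pKa values must lie in the open interval (0, 14)")
  }
  structure(list(name = as.character(name),
                 n_term = unname(n_term), c_term = unname(c_term),
                 side_chain = side_chain, positional = positional,
                 source = source),
            class = "pka_set")
}

#' @export
print.pka_set <- function(x, ...) {
  cat(sprintf("<pka_set> %s%s\n", x$name,
              if (is.null(x$positional)) "" else " (position-aware)"))
  cat(sprintf("  N-term %.3f  C-term %.3f\n", x$n_term, x$c_term))
  sc <- x$side_chain
  cat("  ", paste(sprintf("%s=%.3f", names(sc), sc), collapse = "  "), "\n")
  invisible(x)
}

# pKa set as the canonical 9-vector over GROUP_ORDER (NA for absent groups).
pka_vector <- function(set) {
  v <- c(set$n_term, set$c_term,
         set$side_chain[IONIZABLE_AA])
  names(v) <- GROUP_ORDER
  v
}

# Inverse of pka_vector(): build a plain set from a full 9-vector.
pka_set_from_vector <- function(v, name = "custom", source = "") {
  stopifnot(length(v) == 9L)
  v <- stats::setNames(as.numeric(v), GROUP_ORDER)
  pka_set(name, n_term = v[["n_term"]], c_term = v[["c_term"]],
          side_chain = v[IONIZABLE_AA], source = source)
}

the_registry <- new.env(parent = emptyenv())

parse_set_json <- function(name, rec) {
  pka_set(name, n_term = rec$n_term, c_term = rec$c_term,
          side_chain = unlist(rec$side_chain),
          source = if (is.null(rec$source)) "" else rec$source)
}

parse_positional_json <- function(name, rec) {
  if (name == "Bjellqvist" || !is.null(rec$n_term_default)) {
    pos <- list(style = "bjellqvist",
                n_term_default = rec$n_term_default,
                n_term_by_first = unlist(rec$n_term_by_first),
                c_terminal_side_chain = unlist(rec$c_terminal_side_chain))
    pka_set(name, n_term = rec$n_term_default, c_term = rec$c_term,
            side_chain = unlist(rec$side_chain), positional = pos,
            source = rec$source)
  } else {
    sc3 <- lapply(rec$side_chain, as.numeric)   # [n_terminal, internal, c_terminal]
    term <- lapply(rec$terminal_by_residue, as.numeric)  # [n_term, c_term]
    pos <- list(style = "promost", side_chain3 = sc3, terminal_by_residue = term)
    mid <- vapply(sc3, `[`, numeric(1), 2L)
    dflt <- term[["X"]]
    pka_set(name, n_term = dflt[1L], c_term = dflt[2L],
            side_chain = mid, positional = pos, source = rec$source)
  }
}

#' Load pKa sets from a JSON resource
#'
#' Reads a JSON file in the same schema as the bundled resource
#' (`system.file("extdata", "pka_sets.json", package = "seqpka")`), so users
#' can ship custom sets.
#'
#' @param path Path to a JSON file.
#' @return Named list of [pka_set] objects.
#' @export
load_pka_sets <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (nm in names(js$sets)) out[[nm]] <- parse_set_json(nm, js$sets[[nm]])
  for (nm in names(js$positional_sets)) {
    out[[nm]] <- parse_positional_json(nm, js$positional_sets[[nm]])
  }
  out
}

#' Registry of published pKa sets
#'
#' Returns the bundled registry of named pKa sets used for benchmarking:
#' EMBOSS, Dawson, Rodwell, Grimsley, Solomon, Lehninger, Sillero, Thurlkill,
#' Toseland, Nozaki, Patrickios, DTASelect, Wikipedia, IPC_protein,
#' IPC_peptide, IPC2_protein, IPC2_peptide, plus the position-aware
#' Bjellqvist and ProMoST sets.
#'
#' @return Named list of [pka_set] objects.
#' @examples
#' names(pka_registry())
#' @export
pka_registry <- function() {
  if (is.null(the_registry$sets)) {
    path <- system.file("extdata", "pka_sets.json", package = "seqpka")
    the_registry$sets <- load_pka_sets(path)
  }
  the_registry$sets
}

#' Look up one pKa set by name
#'
#' @param name Set name.
#' @return A [pka_set].  Unknown names raise an error listing the available
#'   sets.
#' @export
get_pka_set <- function(name) {
  reg <- pka_registry()
  if (!name %in% names(reg)) {
    stop("unknown pKa set '", name, "'; available: ",
         paste(sort(names(reg)), collapse = ", "))
  }
  reg[[name]]
}
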