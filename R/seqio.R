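#' Polypeptide sequences
#'
#' A `polypeptide` is a validated amino-acid sequence in one-letter code with
#' an identifier.  The accepted alphabet is the 20 standard residues plus `X`
#' for an unknown residue; `B`, `Z`, `U`, `O`, digits and other symbols are
#' rejected.  Terminal `*` stop symbols are stripped with a warning.
#'
#' @param residues Character scalar, the sequence (case-insensitive).
#' @param id Character scalar identifier.
#' @return An object of class `polypeptide` with fields `id`, `residues`
#'   (upper-case string) and `length`.
#' @examples
#' p <- polypeptide("acdk", id = "pep1")
#' p$length
#' @export
polypeptide <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  s <- toupper(gsub("[ \t\r\n]", "", residues))
  if (grepl("\\*$", s)) {
    warning("stripping terminal '*' stop symbol from sequence '", id, "'")
    s <- sub("\\*+$", "", s)
  }
  if (!nzchar(s)) {
    stop("empty sequence for id '", id, "'")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c(AA20, AA_X))
  if (length(bad) > 0L) {
    stop("illegal character(s) ", paste0("'", bad, "'", collapse = ", "),
         " in sequence '", id, "'")
  }
  structure(list(id = as.character(id), residues = s, length = nchar(s)),
            class = "polypeptide")
}

#' @export
print.polypeptide <- function(x, ...) {
  cat(sprintf("<polypeptide> %s (%d aa)\n", x$id, x$length))
  cat(" ", x$residues, "\n")
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Read sequences from FASTA or plain text
#'
#' FASTA input may contain multiple records with free line width; record ids
#' are taken from the header up to the first whitespace.  Plain format holds
#' one sequence per line; ids are generated (`seq1`, `seq2`, ...).
#'
#' @param source A file path, connection, or character vector of lines.
#' @param format `"fasta"` or `"plain"`.
#' @return A list of [polypeptide] objects in input order.
#' @examples
#' read_sequences(c(">p1", "ACDK"), format = "fasta")
#' @export
read_sequences <- function(source, format = c("fasta", "plain")) {
  format <- match.arg(format)
  lines <- if (is.character(source) && (length(source) > 1L ||
                                        !file.exists(source[1L]))) {
    source
  } else {
    readLines(source, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  if (format == "plain") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty input: no sequences found")
    return(lapply(seq_along(lines), function(i) {
      polypeptide(lines[i], id = paste0("seq", i))
    }))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input: no sequences found")
  if (!startsWith(trimws(lines[1L]), ">")) {
    stop("FASTA input must start with a '>' header line")
  }
  is_hdr <- startsWith(lines, ">")
  rec <- cumsum(is_hdr)
  out <- vector("list", max(rec))
  for (r in seq_len(max(rec))) {
    block <- lines[rec == r]
    hdr <- sub("^>", "", block[1L])
    id <- strsplit(trimws(hdr), "[ \t]")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) {
      stop("FASTA record ", r, " has an empty identifier")
    }
    body <- paste(block[-1L], collapse = "")
    if (!nzchar(gsub("[ \t]", "", body))) {
      stop("FASTA record '", id, "' has an empty sequence body")
    }
    out[[r]] <- polypeptide(body, id = id)
  }
  out
}

#' Count ionizable groups of a sequence
#'
#' Counts the seven ionizable side chains (C, D, E, H, K, R, Y) and flags the
#' free N- and C-terminal groups (always present for an unmodified chain).
#' `X` residues contribute no ionizable group.
#'
#' @param seq A [polypeptide].
#' @return An object of class `ionizable_composition`: a list with `counts`
#'   (named integer vector over C, D, E, H, K, R, Y), `n_term` and `c_term`
#'   logical flags, and the source sequence `length`.
#' @examples
#' ionizable_composition(polypeptide("ACDK"))$counts
#' @export
ionizable_composition <- function(seq) {
  stopifnot(inherits(seq, "polypeptide"))
  chars <- seq_chars(seq)
  counts <- vapply(IONIZABLE_AA, function(a) sum(chars == a), integer(1))
  structure(list(counts = counts, n_term = TRUE, c_term = TRUE,
                 length = seq$length),
            class = "ionizable_composition")
}

# Composition as the 9-vector over GROUP_ORDER (termini first).
composition_vector <- function(comp) {
  c(n_term = as.integer(comp$n_term), c_term = as.integer(comp$c_term),
    comp$counts[IONIZABLE_AA])
}

#' Average molecular weight of a polypeptide
#'
#' Sum of standard average residue masses plus one water (18.01524 Da).
#' `X` contributes the mean of the 20 standard residue masses.
#'
#' @param seq A [polypeptide].
#' @return Mass in Da.
#' @examples
#' molecular_weight(polypeptide("G"))  # 75.07
#' @export
molecular_weight <- function(seq) {
  stopifnot(inherits(seq, "polypeptide"))
  chars <- seq_chars(seq)
  mx <- c(RESIDUE_MASS, X = mean(RESIDUE_MASS))
  sum(mx[chars]) + WATER_MASS
}

#' Write prediction rows as CSV
#'
#' RFC-4180-style CSV with a header row, '.' decimal separator, UTF-8.  Used
#' for both output modes: one row per sequence (pI) or one row per ionizable
#' site (pKa).
#'
#' @param records A data.frame; all rows share the column schema.
#' @param destination File path or connection.
#' @param digits Decimal places for numeric columns (default 3, below
#'   experimental resolution but above solver tolerance).
#' @return Invisibly, the formatted data.frame that was written.
#' @export
write_predictions_csv <- function(records, destination, digits = 3) {
  stopifnot(is.data.frame(records))
  fmt <- records
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- round(fmt[[j]], digits)
  }
  utils::write.csv(fmt, destination, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(fmt)
}

#' Enumerate ionizable sites of a sequence
#'
#' Lists every C, D, E, H, K, R, Y position (1-based) plus the two terminal
#' groups, the site inventory used for per-residue pKa prediction.
#'
#' @param seq A [polypeptide].
#' @return A data.frame with columns `position` (NA for termini), `residue`,
#'   and `group` (`"side_chain"`, `"n_term"` or `"c_term"`).
#' @export
ionizable_sites <- function(seq) {
  stopifnot(inherits(seq, "polypeptide"))
  chars <- seq_chars(seq)
  pos <- which(chars %in% IONIZABLE_AA)
  data.frame(
    position = c(NA_integer_, pos, NA_integer_),
    residue = c(chars[1L], chars[pos], chars[seq$length]),
    group = c("n_term", rep("side_chain", length(pos)), "c_term"),
    stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs List of [polypeptide] objects.
#' @param destination File path or connection.
#' @param width Line width for the sequence body.
#' @export
write_fasta <- function(seqs, destination, width = 60) {
  lines <- unlist(lapply(seqs, function(s) {
    body <- substring(s$residues,
                      seq(1, s$length, by = width),
                      pmin(seq(1, s$length, by = width) + width - 1, s$length))
    c(paste0(">", s$id), body)
  }))
  writeLines(lines, destination)
  invisible(destination)
}
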