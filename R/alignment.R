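## Alignment containers. Internally a character matrix (taxa x columns,
## one symbol per cell) with the taxon labels as rownames; this keeps
## column surgery (degeneracy coding, site deletion, co-Ser splitting)
## cheap and explicit. Coordinates are 0-based internally only where
## arithmetic demands it; everything user-facing is 1-based.

#' Build an in-frame codon (nucleotide) alignment
#'
#' @param seqs named character vector of aligned sequences (one string
#'   per taxon) over IUPAC nucleotide symbols plus \code{"-"} and
#'   \code{"?"}, or a character matrix with one symbol per cell and
#'   taxon rownames.
#' @param code the \code{\link{genetic_code}} the alignment is read
#'   under.
#' @return An object of class \code{codon_alignment}.
#' @details Sequences must share one length divisible by 3; the reading
#'   frame is fixed at offset 0. The IUPAC amino-acid-style ambiguity
#'   letters are all valid nucleotide symbols here, but \code{"Z"} under
#'   the 21-state amino-acid alphabet is a serine class label, not the
#'   Glu/Gln ambiguity code (see \code{\link{amino_alignment}}).
#' @export
codon_alignment <- function(seqs, code = genetic_code()) {
  m <- as_symbol_matrix(seqs)
  validate_taxa(rownames(m))
  if (ncol(m) %% 3L != 0L) {
    stop("frame error: alignment length ", ncol(m),
         " is not divisible by 3")
  }
  check_symbols(m, NT_SYMBOLS, "nucleotide")
  stopifnot(is_genetic_code(code))
  structure(m, class = c("codon_alignment", "alignment"), code = code)
}

#' Build an amino-acid alignment (20- or 21-state alphabet)
#'
#' Under the 21-state alphabet (\code{"aa21"}), \code{"S"} denotes only
#' residues derived from the \emph{Ser1} codon cluster (TCN) and
#' \code{"Z"} denotes the "novel amino acid" derived from \emph{Ser2}
#' (AGY). Under \code{"aa20"}, \code{"Z"} never appears. The IUPAC
#' amino-acid ambiguity codes B/J (and Z under \code{"aa20"}) are
#' rejected on input: in this toolkit the Ser2 convention takes
#' precedence.
#'
#' @param seqs named character vector of aligned amino-acid strings, or
#'   a character matrix with taxon rownames.
#' @param alphabet \code{"aa20"} or \code{"aa21"}.
#' @return An object of class \code{amino_alignment}.
#' @export
amino_alignment <- function(seqs, alphabet = c("aa21", "aa20")) {
  alphabet <- match.arg(alphabet)
  m <- as_symbol_matrix(seqs)
  validate_taxa(rownames(m))
  allowed <- c(if (alphabet == "aa21") AA21_LETTERS else AA20_LETTERS,
               "X", "-", "?")
  check_symbols(m, allowed, alphabet)
  structure(m, class = c("amino_alignment", "alignment"),
            alphabet = alphabet)
}

as_symbol_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    storage.mode(seqs) <- "character"
    return(seqs)
  }
  if (!is.character(seqs) || is.null(names(seqs))) {
    stop("seqs must be a named character vector or a character matrix")
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("format error: sequences differ in length (",
         paste(unique(lens), collapse = ", "), ")")
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

validate_taxa <- function(taxa) {
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("format error: every taxon needs a non-empty label")
  }
  if (anyDuplicated(taxa)) {
    stop("format error: duplicate taxon label '",
         taxa[duplicated(taxa)][[1]], "'")
  }
  invisible(taxa)
}

check_symbols <- function(m, allowed, what) {
  bad <- matrix(!(m %in% allowed), nrow = nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("symbol error: invalid ", what, " symbol '",
         m[idx[1], idx[2]], "' (taxon '", rownames(m)[idx[1]],
         "', column ", idx[2], ")")
  }
  invisible(m)
}

#' @export
print.alignment <- function(x, ...) {
  kind <- if (inherits(x, "codon_alignment")) {
    sprintf("codon alignment (%d codons, code: %s)",
            n_codons(x), attr(x, "code")$name)
  } else {
    sprintf("amino-acid alignment (alphabet: %s)", attr(x, "alphabet"))
  }
  cat(sprintf("%s: %d taxa x %d columns\n", kind, nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 5)
  for (t in show) {
    s <- paste(x[t, seq_len(min(60L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (ncol(x) > 60) "..." else ""))
  }
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Alignment dimensions and accessors
#'
#' @param aln an alignment.
#' @return \code{n_taxa}/\code{n_sites}/\code{n_codons} return integers;
#'   \code{taxa} the taxon labels; \code{as_strings} a named character
#'   vector of full-length sequences; \code{codon_strings} a taxa x
#'   codon-site matrix of 3-letter codon strings.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname alignment-accessors
#' @export
n_sites <- function(aln) ncol(aln)

#' @rdname alignment-accessors
#' @export
n_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ncol(aln) %/% 3L
}

#' @rdname alignment-accessors
#' @export
taxa <- function(aln) rownames(aln)

#' @rdname alignment-accessors
#' @export
as_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""),
                  rownames(aln))
}

#' @rdname alignment-accessors
#' @export
codon_strings <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  nc <- n_codons(aln)
  s <- as_strings(aln)
  m <- vapply(seq_len(nc), function(i) {
    substr(s, 3L * i - 2L, 3L * i)
  }, character(length(s)))
  if (length(s) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- rownames(aln)
  m
}

## rebuild a codon alignment from a taxa x codon-site matrix of
## 3-letter codon strings
from_codon_strings <- function(cm, code) {
  seqs <- apply(cm, 1, paste, collapse = "")
  codon_alignment(stats::setNames(seqs, rownames(cm)), code = code)
}

#' @export
`[.alignment` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  attrs <- attributes(x)
  attrs$dim <- dim(out)
  attrs$dimnames <- dimnames(out)
  attributes(out) <- attrs
  out
}
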