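#' Translate a codon into the 20- or 21-state amino-acid alphabet
#'
#' Under the 21-state alphabet, \emph{Ser1} codons (TCN in the standard
#' code) translate to \code{"S"} and \emph{Ser2} codons (AGY) to the
#' novel amino acid \code{"Z"}; under the 20-state alphabet both give
#' \code{"S"}. Ambiguous codons are expanded over their IUPAC sets and
#' translated only if all expansions agree (so degeneracy-coded input
#' translates naturally: TCN -> S, AGY -> Z, while the merged classes
#' YTN and MGN give \code{"X"}). \code{"---"} translates to \code{"-"};
#' partially gapped or unresolvable codons give \code{"X"}.
#'
#' @param codon 3-symbol IUPAC codon.
#' @param code a \code{\link{genetic_code}}.
#' @param alphabet \code{"aa21"} or \code{"aa20"}.
#' @param strict_stops error on stop codons instead of translating them
#'   to \code{"X"} with a warning.
#' @return A single amino-acid symbol.
#' @examples
#' translate_codon("TCT")                    # "S"
#' translate_codon("AGC")                    # "Z"
#' translate_codon("AGC", alphabet = "aa20") # "S"
#' translate_codon("AGN")                    # "X"
#' @export
translate_codon <- function(codon, code = genetic_code(),
                            alphabet = c("aa21", "aa20"),
                            strict_stops = FALSE) {
  alphabet <- match.arg(alphabet)
  out <- translate_lookup(codon, code, alphabet,
                          strict_stops = strict_stops)
  if (attr(out, "n_stops") > 0L && !strict_stops) {
    warning(attr(out, "n_stops"), " stop codon(s) translated to X")
  }
  as.character(out)
}

translate_lookup <- function(codons, code, alphabet,
                             strict_stops = FALSE) {
  split_ser <- alphabet == "aa21"
  uq <- unique(codons)
  n_stops <- 0L
  map <- vapply(uq, function(cd) {
    if (cd == "---") return("-")
    s <- strsplit(cd, "")[[1]]
    if (length(s) != 3L) stop("codon must have exactly 3 symbols: ", cd)
    if (any(s %in% c("-", "?"))) return("X")
    aas <- possible_aas(cd, code, split_ser = split_ser)
    if (identical(aas, "*")) {
      if (strict_stops) stop("stop codon ", cd, " in input")
      n_stops <<- n_stops + 1L
      return("X")
    }
    aas <- setdiff(aas, "*")
    if (length(aas) == 1L) aas else "X"
  }, "")
  structure(unname(map[match(codons, uq)]), n_stops = n_stops)
}

#' Translate a codon alignment
#'
#' One amino-acid column per codon column; taxa and their order are
#' preserved.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @inheritParams translate_codon
#' @return An \code{\link{amino_alignment}} in the requested alphabet.
#' @export
translate_alignment <- function(aln, alphabet = c("aa21", "aa20"),
                                strict_stops = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  alphabet <- match.arg(alphabet)
  code <- attr(aln, "code")
  cm <- codon_strings(aln)
  tr <- translate_lookup(as.vector(cm), code, alphabet,
                         strict_stops = strict_stops)
  if (attr(tr, "n_stops") > 0L) {
    warning(attr(tr, "n_stops"), " stop codon(s) translated to X")
  }
  out <- matrix(as.character(tr), nrow = nrow(cm),
                dimnames = dimnames(cm))
  amino_alignment(out, alphabet = alphabet)
}
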