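#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide ambiguity sets (DNA). '-' and '?' are handled by the
## callers, never expanded.
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## reverse lookup: sorted concrete set -> IUPAC symbol
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_NT, function(x) paste(sort(x), collapse = ""), "")
  stats::setNames(names(IUPAC_NT), keys)
})

NT_SYMBOLS <- c(names(IUPAC_NT), "-", "?")
AA20_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
AA21_LETTERS <- c(AA20_LETTERS, "Z")

#' Construct a genetic code with annotated serine codon clusters
#'
#' A genetic code maps each of the 64 DNA codons to a one-letter amino
#' acid (or \code{"*"} for stop) and records which codons belong to the
#' two disjoint serine clusters: \emph{Ser1} (TCN in the standard code)
#' and \emph{Ser2} (AGY in the standard code). The two clusters are not
#' interconvertible by a single synonymous nucleotide substitution,
#' which is why this toolkit keeps them apart.
#'
#' @param name \code{"standard"} for the standard nuclear code or
#'   \code{"mito-invert"} for the invertebrate mitochondrial code
#'   (AGA/AGG encode serine and therefore join \emph{Ser2}; ATA encodes
#'   Met; TGA encodes Trp).
#' @return An object of class \code{genetic_code} with elements
#'   \code{name}, \code{codon_to_aa} (named character vector of length
#'   64), \code{ser1} and \code{ser2} (codon sets).
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa[["ATG"]]
#' gc$ser2
#' @export
genetic_code <- function(name = c("standard", "mito-invert")) {
  name <- match.arg(name)
  nts <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(nts, nts, paste0))), nts, paste0)))
  ## standard code in TCAG nesting order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  map <- stats::setNames(aa, codons)
  if (name == "mito-invert") {
    map[c("AGA", "AGG")] <- "S"
    map[["ATA"]] <- "M"
    map[["TGA"]] <- "W"
  }
  ser <- names(map)[map == "S"]
  ser1 <- ser[substr(ser, 1, 2) == "TC"]
  ser2 <- setdiff(ser, ser1)
  structure(
    list(name = name, codon_to_aa = map, ser1 = ser1, ser2 = ser2),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "\n")
  cat("  Ser1 codons:", paste(x$ser1, collapse = " "), "\n")
  cat("  Ser2 codons:", paste(x$ser2, collapse = " "), "\n")
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

#' Amino-acid classes of a genetic code, with serine split
#'
#' Partitions the sense codons of a code into amino-acid classes. With
#' \code{split_ser = TRUE} the serine codons form two classes labelled
#' \code{"S"} (\emph{Ser1}) and \code{"Z"} (\emph{Ser2}); otherwise all
#' serine codons form one class \code{"S"}.
#'
#' @param code a \code{\link{genetic_code}}.
#' @param split_ser split serine into Ser1/Ser2?
#' @return Named character vector over the sense codons giving each
#'   codon's class label.
#' @export
codon_classes <- function(code = genetic_code(), split_ser = TRUE) {
  map <- code$codon_to_aa
  map <- map[map != "*"]
  if (split_ser) map[names(map) %in% code$ser2] <- "Z"
  map
}

#' Expand an IUPAC codon to its concrete codons
#'
#' @param codon a 3-character codon over IUPAC nucleotide symbols.
#'   Codons containing \code{"-"} or \code{"?"} expand to nothing.
#' @return Character vector of concrete \{A,C,G,T\} codons (possibly
#'   empty).
#' @export
expand_codon <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  if (length(s) != 3L) stop("codon must have exactly 3 symbols: ", codon)
  if (any(s %in% c("-", "?"))) return(character())
  bad <- setdiff(s, names(IUPAC_NT))
  if (length(bad)) {
    stop("invalid nucleotide symbol '", bad[[1]], "' in codon ", codon)
  }
  sets <- lapply(s, function(ch) IUPAC_NT[[ch]])
  as.vector(outer(sets[[1]], outer(sets[[2]], sets[[3]], paste0), paste0))
}

## position-wise IUPAC cover of a set of concrete codons, e.g.
## c("TTA","TTG","CTT",...) -> "YTN"
iupac_cover <- function(codons) {
  paste(vapply(1:3, function(i) {
    key <- paste(sort(unique(substr(codons, i, i))), collapse = "")
    IUPAC_FROM_SET[[key]]
  }, ""), collapse = "")
}

## amino acids (with optional Ser1/Ser2 split) reachable from a codon's
## IUPAC expansions; stops reported as "*"
possible_aas <- function(codon, code, split_ser = FALSE) {
  conc <- expand_codon(codon)
  if (!length(conc)) return(character())
  aa <- code$codon_to_aa[conc]
  if (split_ser) aa[conc %in% code$ser2] <- "Z"
  unique(unname(aa))
}
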