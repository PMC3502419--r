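## Degeneracy ("nonsynonymous-only") coding. Every codon is replaced by
## the fully degenerate IUPAC pattern of its amino-acid class, so that
## synonymous differences between sequences vanish while nonsynonymous
## ones survive. Three schemes:
##
##   degen1  - every class degenerated; the twofold-degenerate first
##             positions of Leu and Arg force the merged patterns
##             Leu+Phe = YTN and Arg+Ser2 = MGN.
##   degen8  - as degen1, but the problematic subsets TTR (Leu) and AGR
##             (Arg) are deleted (NNN); the remaining Leu/Arg codons
##             become CTN/CGN.
##   degenFS2- as degen1, but all Phe (TTY) and Ser2 (AGY) codons are
##             deleted (NNN); Leu/Arg keep the merged YTN/MGN patterns.
##
## Patterns are computed from the genetic code itself (position-wise
## IUPAC cover of each amino-acid class, serine split into Ser1/Ser2),
## which reproduces the published standard-code table and extends to
## alternate codes such as the invertebrate mitochondrial one.

#' Degeneracy-coding scheme
#'
#' Builds the per-codon lookup of a degeneracy scheme under a given
#' genetic code: each sense codon maps to its scheme target pattern,
#' stop codons map to \code{NNN}.
#'
#' @param name \code{"degen1"}, \code{"degen8"} or \code{"degenFS2"}.
#'   (The character-deletion coding \code{noLRall1nt2} is a column
#'   filter, not a per-codon recoding; see \code{\link{nolrall1nt2}}.)
#' @param code a \code{\link{genetic_code}}.
#' @return An object of class \code{degen_scheme} with the codon lookup
#'   (\code{table}), the set of scheme target patterns
#'   (\code{patterns}) and the deleted codons (\code{deleted}).
#' @examples
#' sc <- degen_scheme("degen1")
#' sc$table[["CAT"]]   # "CAY"
#' sc$table[["TTA"]]   # "YTN"
#' @export
degen_scheme <- function(name = c("degen1", "degen8", "degenFS2"),
                         code = genetic_code()) {
  name <- match.arg(name)
  cls <- codon_classes(code, split_ser = TRUE)
  codons <- names(cls)
  deleted <- character()
  if (name == "degen8") {
    ## Leu codons of form TTR and Arg codons of form AGR (under `code`)
    deleted <- c(codons[cls == "L" & substr(codons, 1, 2) == "TT"],
                 codons[cls == "R" & substr(codons, 1, 2) == "AG"])
  } else if (name == "degenFS2") {
    deleted <- c(codons[cls == "F"], codons[cls == "Z"])
  }
  ## merged classes driving the pattern: degen1/degenFS2 merge Leu with
  ## Phe (YTN) and Arg with Ser2 (MGN) through the first-position
  ## twofold degeneracy; degen8 degenerates the surviving members only
  tab <- stats::setNames(rep(NA_character_, length(codons)), codons)
  for (a in unique(cls)) {
    members <- codons[cls == a]
    live <- setdiff(members, deleted)
    if (name == "degen8") {
      if (length(live)) tab[live] <- iupac_cover(live)
    } else {
      tab[members] <- iupac_cover(members)
    }
  }
  tab[deleted] <- "NNN"
  stops <- setdiff(names(code$codon_to_aa), codons)
  tab[stops] <- "NNN"
  structure(
    list(name = name, code = code, table = tab,
         patterns = setdiff(unique(tab), "NNN"), deleted = deleted),
    class = "degen_scheme")
}

#' @export
print.degen_scheme <- function(x, ...) {
  cat("Degeneracy scheme:", x$name, "(code:", x$code$name, ")\n")
  cat("  target patterns:",
      paste(sort(unique(x$patterns)), collapse = " "), "\n")
  if (length(x$deleted)) {
    cat("  deleted codons:", paste(x$deleted, collapse = " "), "\n")
  }
  invisible(x)
}

#' Degeneracy-code a single codon
#'
#' Maps a (possibly IUPAC-ambiguous) codon to its scheme target
#' pattern. \code{"---"} passes through unchanged; codons containing a
#' partial gap (\code{-}/\code{?}) become \code{NNN}. A codon whose
#' IUPAC set equals one of the scheme's own target patterns is a fixed
#' point (so the coding is idempotent); any other ambiguous codon is
#' expanded to its concrete codons and recoded only if every expansion
#' agrees on the same target, otherwise it becomes \code{NNN}.
#'
#' @param codon 3-symbol IUPAC codon.
#' @param scheme a \code{\link{degen_scheme}} (or scheme name).
#' @param code genetic code (used when \code{scheme} is a name).
#' @param strict_stops error on stop codons instead of mapping them to
#'   \code{NNN}.
#' @return The recoded 3-symbol codon.
#' @examples
#' degen_codon("CAT")          # "CAY"
#' degen_codon("TTA")          # "YTN"
#' degen_codon("AGA")          # "MGN"
#' degen_codon("TTA", "degen8")  # "NNN"
#' @export
degen_codon <- function(codon, scheme = "degen1", code = genetic_code(),
                        strict_stops = FALSE) {
  if (!inherits(scheme, "degen_scheme")) {
    scheme <- degen_scheme(scheme, code = code)
  }
  recoded <- degen_lookup(codon, scheme, strict_stops = strict_stops)
  if (attr(recoded, "n_stops") > 0L && !strict_stops) {
    warning(attr(recoded, "n_stops"), " stop codon(s) recoded to NNN")
  }
  as.character(recoded)
}

## vectorized core: codons -> recoded codons, with a stop counter.
## Total on valid symbols; invalid symbols raise via expand_codon().
degen_lookup <- function(codons, scheme, strict_stops = FALSE) {
  uq <- unique(codons)
  stops <- setdiff(names(scheme$code$codon_to_aa),
                   names(codon_classes(scheme$code)))
  n_stops <- 0L
  map <- vapply(uq, function(cd) {
    if (cd == "---") return("---")
    s <- strsplit(cd, "")[[1]]
    if (length(s) != 3L) stop("codon must have exactly 3 symbols: ", cd)
    if (any(s %in% c("-", "?"))) return("NNN")
    conc <- expand_codon(cd)
    if (length(conc) == 1L && conc %in% stops) {
      if (strict_stops) stop("stop codon ", cd, " in input")
      n_stops <<- n_stops + 1L
      return("NNN")
    }
    if (cd %in% scheme$patterns) return(cd)  # idempotence fixed point
    out <- unique(unname(scheme$table[conc]))
    if (length(out) == 1L) out else "NNN"
  }, "")
  structure(unname(map[match(codons, uq)]), n_stops = n_stops)
}

#' Degeneracy-code a codon alignment
#'
#' Applies \code{\link{degen_codon}} to every codon of every taxon.
#' Dimensions and taxon order are preserved. Stop codons are recoded to
#' \code{NNN} with a warning reporting their count (or raise an error
#' with \code{strict_stops = TRUE}).
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param scheme scheme name or \code{\link{degen_scheme}}.
#' @param strict_stops error on stop codons?
#' @return The recoded \code{\link{codon_alignment}}.
#' @export
degen_alignment <- function(aln, scheme = "degen1",
                            strict_stops = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- attr(aln, "code")
  if (!inherits(scheme, "degen_scheme")) {
    scheme <- degen_scheme(scheme, code = code)
  }
  cm <- codon_strings(aln)
  rec <- degen_lookup(as.vector(cm), scheme,
                      strict_stops = strict_stops)
  if (attr(rec, "n_stops") > 0L) {
    warning(attr(rec, "n_stops"), " stop codon(s) recoded to NNN")
  }
  out <- matrix(as.character(rec), nrow = nrow(cm),
                dimnames = dimnames(cm))
  from_codon_strings(out, code)
}

#' noLRall1nt2 character-deletion coding
#'
#' Deletes all third-codon-position columns, and those first-position
#' columns whose codon column could encode leucine or arginine in any
#' taxon (their first positions are the only other places synonymous
#' change can hide). Second positions are always kept.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @return A list with \code{matrix} (taxa x kept columns, plain
#'   character matrix of nucleotide symbols) and \code{kept_columns}
#'   (original 1-based nucleotide column numbers).
#' @details A codon consisting only of \code{-}, \code{?} or \code{N}
#'   carries no amino-acid information and does not trigger deletion;
#'   any other codon triggers it if at least one of its IUPAC
#'   expansions translates to Leu or Arg.
#' @export
nolrall1nt2 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- attr(aln, "code")
  cm <- codon_strings(aln)
  uq <- unique(as.vector(cm))
  has_lr <- vapply(uq, function(cd) {
    if (grepl("^[-?N]{3}$", cd)) return(FALSE)
    if (grepl("[-?]", cd)) return(FALSE)   # partial gap: uninformative
    any(possible_aas(cd, code) %in% c("L", "R"))
  }, NA)
  lr_codon <- matrix(has_lr[match(as.vector(cm), uq)], nrow = nrow(cm))
  lr_column <- apply(lr_codon, 2, any)
  nc <- n_codons(aln)
  keep_nt1 <- (which(!lr_column) - 1L) * 3L + 1L
  keep_nt2 <- (seq_len(nc) - 1L) * 3L + 2L
  kept <- sort(c(keep_nt1, keep_nt2))
  list(matrix = unclass(aln)[, kept, drop = FALSE],
       kept_columns = kept)
}
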