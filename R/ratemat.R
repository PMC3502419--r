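## Codon and amino-acid exchangeability matrices. An exchangeability
## matrix is the symmetric factor S of a reversible rate matrix
## Q = S diag(pi); entries are relative, the diagonal is zero.
## Amino-acid state order is PAML's canonical
## A R N D C Q E G H I L K M F P S T W Y V, with the Ser2-derived state
## "Z" appended as state 21 under the 21-letter alphabet.

#' Sense codons of a genetic code, in codon-table order
#'
#' @param code a \code{\link{genetic_code}}.
#' @return Character vector of sense codons (61 for the standard code)
#'   in T/C/A/G-nested codon-table order.
#' @export
sense_codons <- function(code = genetic_code()) {
  names(code$codon_to_aa)[code$codon_to_aa != "*"]
}

#' Codon exchangeability matrix
#'
#' @param exch symmetric nonnegative matrix over the sense codons of
#'   \code{code} (dimnames must be the codons).
#' @param freqs codon equilibrium frequencies summing to 1, in the same
#'   order.
#' @param code genetic code.
#' @param source_tag free-text provenance tag.
#' @return An object of class \code{codon_rate_matrix}.
#' @export
codon_rate_matrix <- function(exch, freqs, code = genetic_code(),
                              source_tag = "") {
  states <- sense_codons(code)
  if (!identical(dim(exch), c(length(states), length(states))) ||
      !identical(rownames(exch), states) ||
      !identical(colnames(exch), states)) {
    stop("exch must be a ", length(states), "x", length(states),
         " matrix with the sense codons of the code as dimnames")
  }
  if (max(abs(exch - t(exch))) > 1e-9) stop("exch must be symmetric")
  if (any(exch < 0)) stop("exchangeabilities must be nonnegative")
  diag(exch) <- 0
  if (length(freqs) != length(states) || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be ", length(states),
         " nonnegative values summing to 1")
  }
  freqs <- stats::setNames(as.numeric(freqs) / sum(freqs), states)
  structure(list(states = states, exch = exch, freqs = freqs,
                 code = code, source_tag = source_tag),
            class = "codon_rate_matrix")
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat(sprintf("Codon exchangeability matrix: %d states (%s)%s\n",
              length(x$states), x$code$name,
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]")
              else ""))
  invisible(x)
}

#' Amino-acid exchangeability matrix
#'
#' @param exch symmetric nonnegative matrix over the 20 (or 21) states
#'   in PAML order; dimnames optional (set if missing).
#' @param freqs optional equilibrium frequencies.
#' @param alphabet \code{"aa20"} or \code{"aa21"}.
#' @param source_tag free-text provenance tag.
#' @return An object of class \code{aa_rate_matrix}.
#' @export
aa_rate_matrix <- function(exch, freqs = NULL,
                           alphabet = c("aa20", "aa21"),
                           source_tag = "") {
  alphabet <- match.arg(alphabet)
  states <- if (alphabet == "aa21") AA21_LETTERS else AA20_LETTERS
  if (!identical(dim(exch), c(length(states), length(states)))) {
    stop("exch must be ", length(states), "x", length(states))
  }
  dimnames(exch) <- list(states, states)
  if (max(abs(exch - t(exch))) > 1e-9) stop("exch must be symmetric")
  if (any(exch < 0)) stop("exchangeabilities must be nonnegative")
  diag(exch) <- 0
  if (!is.null(freqs)) {
    if (length(freqs) != length(states) || any(freqs < 0)) {
      stop("freqs must be ", length(states), " nonnegative values")
    }
    freqs <- stats::setNames(as.numeric(freqs) / sum(freqs), states)
  }
  structure(list(alphabet = alphabet, states = states, exch = exch,
                 freqs = freqs, source_tag = source_tag),
            class = "aa_rate_matrix")
}

#' @export
print.aa_rate_matrix <- function(x, ...) {
  cat(sprintf("Amino-acid exchangeability matrix: %s%s\n", x$alphabet,
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]")
              else ""))
  invisible(x)
}

#' Collapse a codon exchangeability matrix to amino-acid states
#'
#' Sums, for every pair of distinct amino-acid classes, all codon-pair
#' exchangeabilities between codons of the two classes. Under the
#' 21-letter alphabet serine is split into \emph{Ser1} (state S) and
#' \emph{Ser2} (state Z), so the S row concerns Ser1 only and the S/Z
#' entry collects the eight Ser1 x Ser2 codon pairs. Class frequencies
#' are the sums of member-codon frequencies.
#'
#' @param cm a \code{\link{codon_rate_matrix}}.
#' @param alphabet \code{"aa20"} or \code{"aa21"}.
#' @param normalize rescale so the mean off-diagonal exchangeability
#'   is 1?
#' @return An \code{\link{aa_rate_matrix}}.
#' @export
collapse_codon_matrix <- function(cm, alphabet = c("aa21", "aa20"),
                                  normalize = FALSE) {
  stopifnot(inherits(cm, "codon_rate_matrix"))
  alphabet <- match.arg(alphabet)
  cls <- codon_classes(cm$code, split_ser = alphabet == "aa21")
  if (!all(names(cls) %in% cm$states)) {
    stop("consistency error: code has codons absent from the matrix")
  }
  states <- if (alphabet == "aa21") AA21_LETTERS else AA20_LETTERS
  ## indicator matrix codons x classes, then S' E S sums class pairs
  ind <- outer(cm$states, states,
               function(cd, a) as.numeric(cls[cd] == a))
  ex <- t(ind) %*% cm$exch %*% ind
  diag(ex) <- 0
  freqs <- as.vector(t(ind) %*% cm$freqs)
  if (normalize) {
    off <- ex[upper.tri(ex)]
    ex <- ex / mean(off)
  }
  aa_rate_matrix(ex, freqs = freqs, alphabet = alphabet,
                 source_tag = paste0("collapsed:", cm$source_tag))
}

#' JTT amino-acid exchangeability matrix
#'
#' The Jones-Taylor-Thornton empirical 20-state matrix with its
#' equilibrium frequencies, taken from the constants shipped with the
#' phangorn package (PAML state order).
#'
#' @return An \code{\link{aa_rate_matrix}} (20 states).
#' @export
jtt_matrix <- function() {
  j <- get(".JTT", envir = asNamespace("phangorn"))
  n <- 20L
  ex <- matrix(0, n, n)
  ex[lower.tri(ex)] <- j$Q
  ex <- ex + t(ex)
  aa_rate_matrix(ex, freqs = as.numeric(j$bf), alphabet = "aa20",
                 source_tag = "JTT")
}

#' Expand a 20-state matrix to 21 states by splitting serine
#'
#' Splits each serine exchangeability of a 20-state matrix between
#' \emph{Ser1} (S) and \emph{Ser2} (Z) in proportion to the
#' corresponding rates of a 21-state reference matrix (typically a
#' codon-model collapse): for every non-serine state X,
#' \code{exch(S,X) + exch(Z,X) = jtt(S,X)} exactly. The intra-serine
#' entry, absent from any 20-state matrix, is set from the reference's
#' S/Z rate relative to the average of its other rates, rescaled by the
#' average of the expanded matrix's other rates (ratio of averages; an
#' explicit override is available).
#'
#' @param m20 an \code{\link{aa_rate_matrix}} with 20 states (e.g.
#'   \code{\link{jtt_matrix}()}).
#' @param ref21 an \code{\link{aa_rate_matrix}} with 21 states whose
#'   S/Z structure supplies the split proportions.
#' @param sz_rate optional explicit intra-serine exchangeability
#'   overriding the ratio-of-averages rule.
#' @return An \code{\link{aa_rate_matrix}} with 21 states. Serine
#'   frequency (if present) is split in proportion to the reference's
#'   S/Z frequencies (or 50/50 when the reference has none).
#' @export
expand_aa21 <- function(m20, ref21, sz_rate = NULL) {
  stopifnot(inherits(m20, "aa_rate_matrix"),
            inherits(ref21, "aa_rate_matrix"))
  if (m20$alphabet != "aa20" || ref21$alphabet != "aa21") {
    stop("usage error: need a 20-state matrix and a 21-state reference")
  }
  states <- AA21_LETTERS
  ex <- matrix(0, 21, 21, dimnames = list(states, states))
  others <- setdiff(states, c("S", "Z"))
  ex[others, others] <- m20$exch[others, others]
  for (x in others) {
    e1 <- ref21$exch["S", x]
    e2 <- ref21$exch["Z", x]
    tot <- e1 + e2
    if (tot == 0) {
      warning("reference S/Z rates to ", x,
              " are both zero; splitting 50/50")
      w1 <- 0.5
    } else {
      w1 <- e1 / tot
    }
    ex["S", x] <- ex[x, "S"] <- m20$exch["S", x] * w1
    ex["Z", x] <- ex[x, "Z"] <- m20$exch["S", x] * (1 - w1)
  }
  if (is.null(sz_rate)) {
    not_sz <- function(mat) {
      ut <- which(upper.tri(mat), arr.ind = TRUE)
      keep <- !(states[ut[, 1]] == "S" & states[ut[, 2]] == "Z")
      mat[upper.tri(mat)][keep]
    }
    sz_rate <- ref21$exch["S", "Z"] / mean(not_sz(ref21$exch)) *
      mean(not_sz(ex))
  }
  ex["S", "Z"] <- ex["Z", "S"] <- sz_rate
  freqs <- NULL
  if (!is.null(m20$freqs)) {
    w <- if (!is.null(ref21$freqs) &&
             sum(ref21$freqs[c("S", "Z")]) > 0) {
      ref21$freqs[["S"]] / sum(ref21$freqs[c("S", "Z")])
    } else 0.5
    freqs <- stats::setNames(numeric(21), states)
    freqs[others] <- m20$freqs[others]
    freqs["S"] <- m20$freqs[["S"]] * w
    freqs["Z"] <- m20$freqs[["S"]] * (1 - w)
  }
  aa_rate_matrix(ex, freqs = freqs, alphabet = "aa21",
                 source_tag = paste0(m20$source_tag, "+21"))
}

#' Summarize codon exchangeabilities by amino-acid-pair category
#'
#' Partitions all distinct codon pairs of a codon matrix into
#' synonymous categories (one per multi-codon amino acid, with
#' \emph{Ser1} and \emph{Ser2} kept separate), the intra-serine S/Z
#' category (the eight Ser1 x Ser2 pairs in the standard code), and
#' one nonsynonymous category per unordered amino-acid pair; each
#' category is reported with its arithmetic mean, minimum, maximum and
#' pair count.
#'
#' @param cm a \code{\link{codon_rate_matrix}}.
#' @return A data.frame with columns \code{category} (synonymous /
#'   intra-serine / nonsynonymous), \code{pair} (e.g. \code{"I/I"},
#'   \code{"S/Z"}, \code{"I/V"}), \code{n_pairs}, \code{mean},
#'   \code{min}, \code{max}.
#' @export
ecm_category_summary <- function(cm) {
  stopifnot(inherits(cm, "codon_rate_matrix"))
  cls <- codon_classes(cm$code, split_ser = TRUE)
  ut <- which(upper.tri(cm$exch), arr.ind = TRUE)
  a <- unname(cls[cm$states[ut[, 1]]])
  b <- unname(cls[cm$states[ut[, 2]]])
  lab <- paste(pmin(a, b), pmax(a, b), sep = "/")
  category <- ifelse(a == b, "synonymous",
                     ifelse(lab == "S/Z", "intra-serine",
                            "nonsynonymous"))
  vals <- cm$exch[upper.tri(cm$exch)]
  out <- do.call(rbind, lapply(split(seq_along(vals), lab), function(i) {
    data.frame(category = category[i[[1]]], pair = lab[i[[1]]],
               n_pairs = length(i), mean = mean(vals[i]),
               min = min(vals[i]), max = max(vals[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$category,
                  c("synonymous", "intra-serine", "nonsynonymous")),
            out$pair), ]
}

#' Export an amino-acid exchangeability matrix as PAML-style text
#'
#' Lower-triangular exchangeabilities row by row in state order,
#' followed by a frequency line when frequencies are present. 21-state
#' files carry leading comment lines (prefixed \code{#}) naming the
#' convention that state 21 (\code{Z}) holds the Ser2-derived residues;
#' \code{\link{import_rate_matrix}} skips such lines. Values round-trip
#' at 10 significant digits.
#'
#' @param m an \code{\link{aa_rate_matrix}}.
#' @param path optional output path.
#' @param normalize rescale so the mean off-diagonal exchangeability
#'   is 1 before writing?
#' @return Invisibly, the character vector of output lines.
#' @export
export_rate_matrix <- function(m, path = NULL, normalize = FALSE) {
  stopifnot(inherits(m, "aa_rate_matrix"))
  ex <- m$exch
  if (normalize) ex <- ex / mean(ex[upper.tri(ex)])
  n <- length(m$states)
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  hdr <- if (m$alphabet == "aa21") {
    c("# 21-state amino-acid exchangeabilities",
      paste("# state order:", paste(m$states, collapse = " ")),
      "# state 21 (Z) = Ser2-derived serine (AGY); S = Ser1 (TCN)")
  } else {
    character()
  }
  rows <- vapply(seq(2, n), function(i) {
    paste(fmt(ex[i, seq_len(i - 1)]), collapse = " ")
  }, "")
  lines <- c(hdr, rows,
             if (!is.null(m$freqs)) c("", paste(fmt(m$freqs),
                                                collapse = " ")))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Import a PAML-style amino-acid exchangeability matrix
#'
#' @param source path or character vector of lines as produced by
#'   \code{\link{export_rate_matrix}}.
#' @param alphabet \code{"aa20"} or \code{"aa21"}.
#' @return An \code{\link{aa_rate_matrix}}.
#' @export
import_rate_matrix <- function(source, alphabet = c("aa20", "aa21")) {
  alphabet <- match.arg(alphabet)
  n <- if (alphabet == "aa21") 21L else 20L
  lines <- source_lines(source)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  nums <- as.numeric(unlist(strsplit(trimws(lines), "\\s+")))
  n_tri <- n * (n - 1L) / 2L
  if (!(length(nums) %in% c(n_tri, n_tri + n))) {
    stop("format error: expected ", n_tri, " (or ", n_tri + n,
         ") numbers, found ", length(nums))
  }
  ex <- matrix(0, n, n)
  k <- 0L
  for (i in seq(2L, n)) for (j in seq_len(i - 1L)) {
    k <- k + 1L
    ex[i, j] <- ex[j, i] <- nums[[k]]
  }
  freqs <- if (length(nums) > n_tri) nums[(n_tri + 1):(n_tri + n)]
  aa_rate_matrix(ex, freqs = freqs, alphabet = alphabet,
                 source_tag = "imported")
}
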