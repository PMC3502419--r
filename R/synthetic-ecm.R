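#' Synthetic empirical-style codon exchangeability matrix
#'
#' A fully synthetic codon exchangeability matrix built in code as a
#' stand-in reference codon model for tests, simulations and worked
#' examples. It is parametric, not estimated from any database, and is
#' documented as synthetic wherever it appears: its values do not
#' reproduce any published empirical codon model.
#'
#' The construction reproduces the qualitative rate structure the
#' serine analyses rely on: for a codon pair differing at \code{d}
#' positions the exchangeability is
#' \deqn{\kappa^{t} \cdot \delta^{d-1} \cdot \omega^{[nonsyn]}}
#' where \code{t} counts transitions among the differing positions,
#' \eqn{\delta < 1} down-weights multi-nucleotide (doublet/triplet)
#' exchanges, and \eqn{\omega < 1} down-weights amino-acid-changing
#' exchanges. Direct Ser1/Ser2 interchange is therefore nonzero
#' (double substitutions happen) but slower than ordinary synonymous
#' change and, on average, intermediate between synonymous and
#' nonsynonymous rates.
#'
#' @param kappa transition/transversion exchangeability factor (> 0).
#' @param omega nonsynonymous down-weighting factor (> 0, < 1 for
#'   purifying selection).
#' @param delta per-extra-position down-weighting of multi-nucleotide
#'   exchanges (> 0, < 1).
#' @param nt_freqs equilibrium nucleotide frequencies (A, C, G, T) used
#'   to build codon frequencies as a normalized product over positions.
#' @param code genetic code.
#' @return A \code{\link{codon_rate_matrix}} tagged
#'   \code{"synthetic-ecm"}.
#' @examples
#' cm <- synthetic_ecm()
#' ecm_category_summary(cm)[1:3, ]
#' @export
synthetic_ecm <- function(kappa = 4, omega = 0.06, delta = 0.4,
                          nt_freqs = c(A = 0.3, C = 0.2, G = 0.2,
                                       T = 0.3),
                          code = genetic_code()) {
  stopifnot(kappa > 0, omega > 0, delta > 0, length(nt_freqs) == 4)
  states <- sense_codons(code)
  aa <- code$codon_to_aa[states]
  n <- length(states)
  pos <- lapply(1:3, function(i) substr(states, i, i))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") & y %in% c("A", "G")) |
      (x %in% c("C", "T") & y %in% c("C", "T"))
  }
  ex <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    diffs <- vapply(1:3, function(p) pos[[p]][i] != pos[[p]][j], NA)
    d <- sum(diffs)
    ti <- sum(vapply(which(diffs), function(p) {
      is_transition(pos[[p]][i], pos[[p]][j])
    }, NA))
    r <- kappa^ti * delta^(d - 1)
    if (aa[[i]] != aa[[j]]) r <- r * omega
    ex[i, j] <- ex[j, i] <- r
  }
  nt_freqs <- nt_freqs / sum(nt_freqs)
  fr <- nt_freqs[pos[[1]]] * nt_freqs[pos[[2]]] * nt_freqs[pos[[3]]]
  fr <- fr / sum(fr)
  codon_rate_matrix(ex, freqs = fr, code = code,
                    source_tag = "synthetic-ecm")
}
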