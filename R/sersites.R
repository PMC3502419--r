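## Serine-site machinery. At a given codon column of an alignment the
## two serine clusters can commingle ("co-Ser": at least one taxon with
## a Ser1 codon and at least one with a Ser2 codon) or not; these
## categories drive the targeted data-set manipulations.

## per-cell serine status: "ser1", "ser2", "other" or "missing".
## Ambiguous codons count as Ser1/Ser2 only when every IUPAC expansion
## agrees (conservative); mixed expansions count as "other".
ser_status <- function(codons, code) {
  uq <- unique(codons)
  st <- vapply(uq, function(cd) {
    if (grepl("[-?]", cd) || cd == "NNN") return("missing")
    conc <- expand_codon(cd)
    in1 <- conc %in% code$ser1
    in2 <- conc %in% code$ser2
    if (all(in1)) "ser1" else if (all(in2)) "ser2" else "other"
  }, "")
  unname(st[match(codons, uq)])
}

#' Classify codon columns by serine co-occurrence
#'
#' Counts, for every codon column, the taxa carrying \emph{Ser1}
#' codons (TCN; the degen1 pattern TCN included), \emph{Ser2} codons
#' (AGY), other resolved codons, and missing codons
#' (gap/\code{?}/NNN), and assigns the column to one of four
#' categories: \code{co-Ser} (both clusters present),
#' \code{non-co-Ser1}, \code{non-co-Ser2} (only one present) or
#' \code{non-Ser}. Degeneracy coding preserves Ser1/Ser2 identity, so
#' raw and degen1-coded alignments classify identically.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @return A data.frame with one row per codon site: \code{site}
#'   (1-based), \code{n_ser1}, \code{n_ser2}, \code{n_other},
#'   \code{n_missing}, \code{category}.
#' @export
classify_ser_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- attr(aln, "code")
  cm <- codon_strings(aln)
  st <- matrix(ser_status(as.vector(cm), code), nrow = nrow(cm))
  n1 <- colSums(st == "ser1")
  n2 <- colSums(st == "ser2")
  category <- ifelse(n1 >= 1 & n2 >= 1, "co-Ser",
              ifelse(n1 >= 1, "non-co-Ser1",
              ifelse(n2 >= 1, "non-co-Ser2", "non-Ser")))
  data.frame(site = seq_len(ncol(st)), n_ser1 = n1, n_ser2 = n2,
             n_other = colSums(st == "other"),
             n_missing = colSums(st == "missing"),
             category = category, stringsAsFactors = FALSE)
}

#' Serine site spectrum
#'
#' For every taxon depth \code{k}, the number of sites whose serine
#' occupancy (\code{n_ser1 + n_ser2}) is at least \code{k}, split by
#' site category. Counts are non-increasing in \code{k}.
#'
#' @param cls a classification from \code{\link{classify_ser_sites}}.
#' @param max_k largest depth reported (defaults to the maximum
#'   occupancy observed).
#' @return A data.frame with columns \code{k}, \code{co_ser},
#'   \code{non_co_ser1}, \code{non_co_ser2}, \code{non_co_ser} (the sum
#'   of the previous two) and \code{total}.
#' @export
ser_site_spectrum <- function(cls, max_k = NULL) {
  occ <- cls$n_ser1 + cls$n_ser2
  if (is.null(max_k)) max_k <- max(occ, 1L)
  out <- do.call(rbind, lapply(seq_len(max_k), function(k) {
    at <- occ >= k
    data.frame(
      k = k,
      co_ser = sum(at & cls$category == "co-Ser"),
      non_co_ser1 = sum(at & cls$category == "non-co-Ser1"),
      non_co_ser2 = sum(at & cls$category == "non-co-Ser2"))
  }))
  out$non_co_ser <- out$non_co_ser1 + out$non_co_ser2
  out$total <- out$co_ser + out$non_co_ser
  out
}

#' Per-taxon serine codon usage
#'
#' Proportions of the serine codons (TCT, TCC, TCA, TCG, AGT, AGC in
#' the standard code) per taxon, counting unambiguous serine codons
#' only, plus each taxon's and the aggregate Ser1:Ser2 balance.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @return A data.frame with one row per taxon: \code{taxon},
#'   \code{n_ser}, one proportion column per serine codon (NA when the
#'   taxon has no serine; such taxa are flagged \code{empty} and
#'   excluded from the aggregate), and \code{ser1_fraction}. The
#'   aggregate Ser1:(Ser1+Ser2) fraction across non-empty taxa is
#'   attached as attribute \code{"ser1_fraction_total"}.
#' @export
ser_codon_usage <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- attr(aln, "code")
  ser <- c(code$ser1, code$ser2)
  cm <- codon_strings(aln)
  counts <- t(apply(cm, 1, function(row) {
    tab <- table(factor(row, levels = ser))
    as.integer(tab)
  }))
  colnames(counts) <- ser
  n_ser <- rowSums(counts)
  props <- counts / ifelse(n_ser > 0, n_ser, NA_real_)
  out <- data.frame(taxon = rownames(cm), n_ser = n_ser,
                    empty = n_ser == 0, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- cbind(out, as.data.frame(props, row.names = NULL))
  s1 <- rowSums(counts[, code$ser1, drop = FALSE])
  out$ser1_fraction <- ifelse(n_ser > 0, s1 / n_ser, NA_real_)
  attr(out, "ser1_fraction_total") <- sum(s1) / sum(n_ser)
  out
}

MANIP_KINDS <- c("delete_ser_all", "delete_co_ser1", "delete_co_ser2",
                 "delete_co_ser_both", "delete_non_co_ser1",
                 "delete_non_co_ser2", "delete_non_co_ser_both",
                 "ser1_to_ser2", "ser2_to_ser1",
                 "delete_non_ser_at_co_ser", "split_co_ser",
                 "proxy_recode", "aa_swap", "delete_aa")

#' Targeted alignment manipulations around serine
#'
#' Applies one of the targeted data-set manipulations. Codon-level
#' kinds operate on a \code{\link{codon_alignment}} (deletion recodes a
#' codon to \code{NNN}):
#' \describe{
#'   \item{delete_ser_all}{every Ser1/Ser2 codon deleted}
#'   \item{delete_co_ser1 / delete_co_ser2 / delete_co_ser_both}{Ser1
#'     and/or Ser2 codons deleted at co-Ser sites}
#'   \item{delete_non_co_ser1 / delete_non_co_ser2 /
#'     delete_non_co_ser_both}{Ser1/Ser2 codons deleted at their
#'     non-co-Ser sites}
#'   \item{ser1_to_ser2 / ser2_to_ser1}{one serine cluster over-written
#'     with the other's degenerate pattern (TCN -> AGY or AGY -> TCN),
#'     mimicking the 20-amino-acid conflation at the nucleotide level}
#'   \item{delete_non_ser_at_co_ser}{non-serine codons deleted at
#'     co-Ser sites}
#'   \item{split_co_ser}{each co-Ser column duplicated into a
#'     serine-only and a non-serine-only column (the complementary
#'     cells masked), so change between Ser and non-Ser is ignored}
#'   \item{delete_aa}{all codons of one amino acid deleted
#'     (\code{source} = one-letter code)}
#' }
#' Amino-acid-level kinds operate on an \code{\link{amino_alignment}}
#' and need the paired codon alignment to locate serine cells:
#' \describe{
#'   \item{proxy_recode}{co-Ser1 (or co-Ser2) residues recoded as a
#'     proxy amino acid, \code{target} in \{F, W, Y\}; \code{source} is
#'     \code{"co_ser1"} or \code{"co_ser2"}}
#'   \item{aa_swap}{all residues of \code{source} recoded as
#'     \code{target} (e.g. D -> E)}
#'   \item{delete_aa}{residues of \code{source} masked with \code{"-"}}
#' }
#'
#' @param aln codon or amino-acid alignment (per kind, above).
#' @param kind manipulation name.
#' @param source,target amino-acid symbols or co-Ser group, where the
#'   kind takes parameters.
#' @param codon_aln the paired \code{\link{codon_alignment}}, required
#'   by the amino-acid-level kinds that select serine cells.
#' @return A list of class \code{manipulation}: \code{alignment} (same
#'   type as the input), \code{changes} (data.frame of changed cells:
#'   \code{taxon}, \code{site}, \code{from}, \code{to}) and
#'   \code{kind}. Only selected cells change; dimensions are preserved
#'   except by \code{split_co_ser}, which adds one column per co-Ser
#'   site.
#' @export
manipulate <- function(aln, kind, source = NULL, target = NULL,
                       codon_aln = NULL) {
  kind <- match.arg(kind, MANIP_KINDS)
  codon_kinds <- setdiff(MANIP_KINDS, c("proxy_recode", "aa_swap"))
  if (inherits(aln, "codon_alignment")) {
    if (!(kind %in% codon_kinds)) {
      stop("usage error: ", kind, " applies to amino-acid alignments")
    }
    manipulate_codon(aln, kind, source)
  } else if (inherits(aln, "amino_alignment")) {
    if (!(kind %in% c("proxy_recode", "aa_swap", "delete_aa"))) {
      stop("usage error: ", kind, " applies to codon alignments")
    }
    manipulate_aa(aln, kind, source, target, codon_aln)
  } else {
    stop("usage error: aln must be an alignment")
  }
}

manipulate_codon <- function(aln, kind, source) {
  code <- attr(aln, "code")
  cm <- codon_strings(aln)
  st <- matrix(ser_status(as.vector(cm), code), nrow = nrow(cm))
  cls <- classify_ser_sites(aln)
  cat_of <- cls$category[col(cm)]
  out <- cm
  sel <- switch(kind,
    delete_ser_all = st %in% c("ser1", "ser2"),
    delete_co_ser1 = st == "ser1" & cat_of == "co-Ser",
    delete_co_ser2 = st == "ser2" & cat_of == "co-Ser",
    delete_co_ser_both = st %in% c("ser1", "ser2") & cat_of == "co-Ser",
    delete_non_co_ser1 = st == "ser1" & cat_of == "non-co-Ser1",
    delete_non_co_ser2 = st == "ser2" & cat_of == "non-co-Ser2",
    delete_non_co_ser_both =
      (st == "ser1" & cat_of == "non-co-Ser1") |
      (st == "ser2" & cat_of == "non-co-Ser2"),
    ser1_to_ser2 = st == "ser1",
    ser2_to_ser1 = st == "ser2",
    delete_non_ser_at_co_ser = st == "other" & cat_of == "co-Ser",
    delete_aa = {
      if (is.null(source)) stop("usage error: delete_aa needs source")
      tr <- matrix(translate_lookup(as.vector(cm), code, "aa20"),
                   nrow = nrow(cm))
      tr == toupper(source)
    },
    split_co_ser = NULL)
  if (kind == "split_co_ser") {
    return(split_co_ser(aln, cm, st, cls))
  }
  sel <- matrix(as.logical(sel), nrow = nrow(cm))
  replacement <- switch(kind,
    ser1_to_ser2 = "AGY", ser2_to_ser1 = "TCN", "NNN")
  out[sel] <- replacement
  changes <- change_log(cm, out)
  structure(list(alignment = from_codon_strings(out, code),
                 changes = changes, kind = kind),
            class = "manipulation")
}

split_co_ser <- function(aln, cm, st, cls) {
  code <- attr(aln, "code")
  pieces <- lapply(seq_len(ncol(cm)), function(j) {
    if (cls$category[[j]] != "co-Ser") return(cm[, j, drop = FALSE])
    ser_only <- non_only <- cm[, j]
    is_ser <- st[, j] %in% c("ser1", "ser2")
    is_other <- st[, j] == "other"
    ser_only[is_other] <- "NNN"
    non_only[is_ser] <- "NNN"
    cbind(ser_only, non_only)
  })
  out <- do.call(cbind, pieces)
  rownames(out) <- rownames(cm)
  changes <- data.frame(taxon = character(), site = integer(),
                        from = character(), to = character(),
                        stringsAsFactors = FALSE)
  structure(list(alignment = from_codon_strings(out, code),
                 changes = changes, kind = "split_co_ser",
                 n_co_ser = sum(cls$category == "co-Ser")),
            class = "manipulation")
}

manipulate_aa <- function(aln, kind, source, target, codon_aln) {
  m <- unclass(aln)
  if (kind == "aa_swap" || kind == "delete_aa") {
    if (is.null(source)) stop("usage error: ", kind, " needs source")
    source <- toupper(source)
    sel <- m == source
    replacement <- if (kind == "delete_aa") "-" else toupper(target)
    if (kind == "aa_swap" && is.null(target)) {
      stop("usage error: aa_swap needs target")
    }
  } else {  # proxy_recode
    if (is.null(codon_aln)) {
      stop("usage error: proxy_recode needs the paired codon alignment")
    }
    stopifnot(inherits(codon_aln, "codon_alignment"))
    if (!identical(dim(m), c(n_taxa(codon_aln), n_codons(codon_aln)))) {
      stop("usage error: amino-acid and codon alignments do not match")
    }
    target <- toupper(target)
    if (!(target %in% c("F", "W", "Y"))) {
      stop("usage error: proxy target must be one of F, W, Y")
    }
    group <- match.arg(source, c("co_ser1", "co_ser2"))
    code <- attr(codon_aln, "code")
    cm <- codon_strings(codon_aln)
    st <- matrix(ser_status(as.vector(cm), code), nrow = nrow(cm))
    cls <- classify_ser_sites(codon_aln)
    want <- if (group == "co_ser1") "ser1" else "ser2"
    sel <- st == want & cls$category[col(st)] == "co-Ser"
    replacement <- target
  }
  out <- m
  out[sel] <- replacement
  changes <- change_log(m, out)
  structure(list(alignment = amino_alignment(out,
                                             attr(aln, "alphabet")),
                 changes = changes, kind = kind),
            class = "manipulation")
}

change_log <- function(before, after) {
  d <- which(before != after, arr.ind = TRUE)
  data.frame(taxon = rownames(before)[d[, 1]], site = unname(d[, 2]),
             from = before[d], to = after[d], stringsAsFactors = FALSE)
}

#' @export
print.manipulation <- function(x, ...) {
  cat(sprintf("Manipulation '%s': %d cell(s) changed\n", x$kind,
              nrow(x$changes)))
  print(x$alignment)
  invisible(x)
}
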