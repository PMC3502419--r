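## Compositional heterogeneity. Composition (not primary sequence) is
## the character: per-taxon proportions of nucleotides, codons or amino
## acids, pairwise Euclidean distances between those proportion
## vectors, distance trees, and bootstrap support for the purely
## compositional groupings. Long trees = much heterogeneity.

#' Composition vector of one sequence
#'
#' @param seq a character string (nucleotide or amino-acid sequence).
#' @param unit \code{"nt"}, \code{"codon"}, \code{"aa20"} or
#'   \code{"aa21"}. For \code{"codon"} the string must be in frame;
#'   for the amino-acid units a nucleotide string is translated first,
#'   while an amino-acid string is counted as is.
#' @param code genetic code (nucleotide input).
#' @param site_mask optional 1-based unit positions (codon sites for
#'   codon/amino-acid units, nucleotide columns for \code{"nt"}) to
#'   restrict counting to.
#' @param all_symbols count every non-missing symbol as its own
#'   category instead of fully resolved units only; this is the switch
#'   that makes the composition of degeneracy-coded matrices (with
#'   their R/Y/N patterns) visible.
#' @return An object of class \code{composition}: named proportion
#'   vector (attribute \code{n_counted} holds the number of units
#'   counted; a sequence with nothing countable yields an empty vector
#'   with \code{n_counted = 0}).
#' @export
composition_vector <- function(seq, unit = c("nt", "codon", "aa20",
                                             "aa21"),
                               code = genetic_code(), site_mask = NULL,
                               all_symbols = FALSE) {
  unit <- match.arg(unit)
  units <- sequence_units(seq, unit, code)
  if (!is.null(site_mask)) units <- units[site_mask]
  counted <- countable_units(units, unit, all_symbols)
  n <- length(counted)
  p <- if (n > 0) table(counted) / n else table(character())
  structure(stats::setNames(as.numeric(p), names(p)),
            n_counted = n, unit = unit, class = "composition")
}

sequence_units <- function(seq, unit, code) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (unit == "nt") return(strsplit(seq, "")[[1]])
  if (nchar(seq) %% 3L != 0L &&
      !all(strsplit(seq, "")[[1]] %in% c(AA21_LETTERS, "X", "-", "?"))) {
    stop("frame error: sequence length not divisible by 3")
  }
  is_nt <- all(strsplit(seq, "")[[1]] %in% NT_SYMBOLS) &&
    nchar(seq) %% 3L == 0L
  if (unit == "codon") {
    if (!is_nt) stop("usage error: codon unit needs nucleotide input")
    i <- seq_len(nchar(seq) %/% 3L)
    return(substring(seq, 3L * i - 2L, 3L * i))
  }
  ## amino-acid units
  if (is_nt) {
    i <- seq_len(nchar(seq) %/% 3L)
    codons <- substring(seq, 3L * i - 2L, 3L * i)
    as.character(translate_lookup(codons, code, unit))
  } else {
    strsplit(seq, "")[[1]]
  }
}

countable_units <- function(units, unit, all_symbols) {
  if (all_symbols) {
    drop <- if (unit %in% c("nt", "codon")) {
      c("-", "?", "N", "NNN", "---", "???")
    } else {
      c("-", "?", "X")
    }
    return(units[!(units %in% drop) & !grepl("[-?]", units)])
  }
  keep <- switch(unit,
    nt = units %in% c("A", "C", "G", "T"),
    codon = vapply(units, function(u) {
      !grepl("[-?]", u) && length(expand_codon(u)) == 1L
    }, NA),
    units %in% AA21_LETTERS)
  units[keep]
}

#' Euclidean compositional distance matrix
#'
#' Pairwise distances
#' \eqn{d(i,j) = \sqrt{\sum_u (p_{iu} - p_{ju})^2}} between the unit
#' composition vectors of all taxa, over the union of observed
#' categories.
#'
#' @param aln a codon or amino-acid alignment.
#' @inheritParams composition_vector
#' @param drop_empty drop taxa with nothing countable instead of
#'   raising an error naming them.
#' @return Symmetric numeric matrix with zero diagonal and the taxa as
#'   dimnames.
#' @export
euclidean_distance_matrix <- function(aln,
                                      unit = c("nt", "codon", "aa20",
                                               "aa21"),
                                      site_mask = NULL,
                                      all_symbols = FALSE,
                                      drop_empty = FALSE) {
  unit <- match.arg(unit)
  if (n_taxa(aln) < 2L) stop("usage error: need at least 2 taxa")
  code <- if (inherits(aln, "codon_alignment")) attr(aln, "code")
          else genetic_code()
  seqs <- as_strings(aln)
  comps <- lapply(seqs, composition_vector, unit = unit, code = code,
                  site_mask = site_mask, all_symbols = all_symbols)
  empty <- vapply(comps, function(x) attr(x, "n_counted") == 0L, NA)
  if (any(empty)) {
    if (!drop_empty) {
      stop("taxon '", names(comps)[empty][[1]],
           "' has no countable ", unit, " units")
    }
    comps <- comps[!empty]
  }
  cats <- sort(unique(unlist(lapply(comps, names))))
  pm <- t(vapply(comps, function(x) {
    out <- stats::setNames(numeric(length(cats)), cats)
    out[names(x)] <- as.numeric(x)
    out
  }, numeric(length(cats))))
  dm <- as.matrix(stats::dist(pm, method = "euclidean"))
  dimnames(dm) <- list(names(comps), names(comps))
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \code{\link[ape]{nj}}); negative
#' branch lengths are clamped to zero, with the pre-clamp values kept
#' in the attribute \code{"raw_edge_lengths"}.
#'
#' @param dm symmetric distance matrix with taxa as dimnames.
#' @return An \code{ape} \code{phylo} tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("usage error: need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  raw <- tr$edge.length
  tr$edge.length <- pmax(raw, 0)
  attr(tr, "raw_edge_lengths") <- raw
  tr
}

#' Total tree length
#'
#' Sum of (clamped, nonnegative) branch lengths; for a compositional
#' distance tree this is the overall compositional-heterogeneity
#' index of the data set.
#'
#' @param tree a \code{phylo} tree.
#' @return Nonnegative number.
#' @export
total_tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(pmax(tree$edge.length, 0))
}

#' Compositional bootstrap with majority-rule consensus
#'
#' Resamples columns of the chosen unit with replacement to the
#' original length, recomputes the composition distance matrix and a
#' neighbor-joining tree per replicate, and summarizes bipartition
#' frequencies across replicates together with the majority-rule
#' consensus (supports > 50\%) and the replicate tree lengths.
#'
#' @param aln a codon or amino-acid alignment.
#' @inheritParams euclidean_distance_matrix
#' @param reps number of pseudo-replicates (>= 1).
#' @param seed explicit RNG seed; when \code{NULL} one is drawn and
#'   recorded in the result.
#' @return An object of class \code{composition_bootstrap}:
#'   \code{supports} (data.frame: \code{bipartition} as the sorted
#'   \code{|}-joined label of the split side away from the
#'   alphabetically first taxon, \code{size},
#'   \code{support} in percent, nontrivial splits only),
#'   \code{tree_lengths} (length \code{reps}), \code{consensus}
#'   (majority-rule \code{phylo}), \code{observed_tree},
#'   \code{observed_length}, \code{reps}, \code{seed}, \code{unit}.
#' @export
composition_bootstrap <- function(aln,
                                  unit = c("nt", "codon", "aa20",
                                           "aa21"),
                                  reps = 300L, seed = NULL,
                                  site_mask = NULL,
                                  all_symbols = FALSE) {
  unit <- match.arg(unit)
  stopifnot(reps >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ## resampling unit = composition unit: nt columns for nt, codon
  ## columns otherwise
  ncols <- ncol(aln)
  per_codon <- unit != "nt" && inherits(aln, "codon_alignment")
  n_units <- if (per_codon) ncols %/% 3L else ncols
  if (!is.null(site_mask)) {
    pool <- site_mask
  } else {
    pool <- seq_len(n_units)
  }
  obs_dm <- euclidean_distance_matrix(aln, unit = unit,
                                      site_mask = site_mask,
                                      all_symbols = all_symbols)
  obs_tree <- nj_tree(obs_dm)
  m <- unclass(aln)
  trees <- vector("list", reps)
  lens <- numeric(reps)
  set.seed(seed)
  for (r in seq_len(reps)) {
    take <- sample(pool, length(pool), replace = TRUE)
    cols <- if (per_codon) {
      as.vector(rbind(3L * take - 2L, 3L * take - 1L, 3L * take))
    } else {
      take
    }
    sub <- m[, cols, drop = FALSE]
    attributes(sub) <- c(attributes(sub),
                         attributes(aln)[setdiff(names(attributes(aln)),
                                                 c("dim", "dimnames"))])
    dm <- tryCatch(
      euclidean_distance_matrix(sub, unit = unit,
                                all_symbols = all_symbols),
      error = function(e) {
        stop("replicate ", r, ": ", conditionMessage(e))
      })
    tr <- nj_tree(dm)
    trees[[r]] <- tr
    lens[[r]] <- total_tree_length(tr)
  }
  class(trees) <- "multiPhylo"
  supports <- bipartition_frequencies(trees, taxa(aln), reps)
  cons <- ape::consensus(trees, p = 0.5)
  structure(list(supports = supports, tree_lengths = lens,
                 consensus = cons, observed_tree = obs_tree,
                 observed_length = total_tree_length(obs_tree),
                 reps = reps, seed = seed, unit = unit),
            class = "composition_bootstrap")
}

bipartition_frequencies <- function(trees, labels, reps) {
  sp <- phangorn::as.splits(trees)
  labs <- attr(sp, "labels")
  w <- attr(sp, "weights")
  n <- length(labs)
  anchor <- sort(labs)[[1]]
  rows <- lapply(seq_along(sp), function(i) {
    side <- labs[sp[[i]]]
    ## orient each split away from the alphabetically first taxon so
    ## the labelling is independent of taxon input order
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= n - 1L) return(NULL)
    data.frame(bipartition = paste(sort(side), collapse = "|"),
               size = length(side), support = 100 * w[[i]] / reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bipartition = character(), size = integer(),
                      support = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- stats::aggregate(support ~ bipartition + size, out, sum)
    out <- out[order(-out$support, out$bipartition), ]
    rownames(out) <- NULL
  }
  out
}

#' Bootstrap support of one bipartition
#'
#' @param bs a \code{\link{composition_bootstrap}} result.
#' @param side character vector of taxon labels on one side of the
#'   split.
#' @return Support percentage (0 when the bipartition never occurred).
#' @export
bipartition_support <- function(bs, side) {
  stopifnot(inherits(bs, "composition_bootstrap"))
  all_taxa <- if (!is.null(bs$observed_tree$tip.label)) {
    bs$observed_tree$tip.label
  } else {
    unique(unlist(strsplit(bs$supports$bipartition, "|", fixed = TRUE)))
  }
  key1 <- paste(sort(side), collapse = "|")
  key2 <- paste(sort(setdiff(all_taxa, side)), collapse = "|")
  hit <- bs$supports$bipartition %in% c(key1, key2)
  if (any(hit)) max(bs$supports$support[hit]) else 0
}

#' @export
print.composition_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Compositional bootstrap (%s units): %d replicates, seed %d\n",
    x$unit, x$reps, x$seed))
  cat(sprintf("  observed tree length: %.4f\n", x$observed_length))
  top <- utils::head(x$supports[x$supports$support > 50, ], 10)
  if (nrow(top)) {
    cat("  bipartitions > 50%:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %5.1f%%  %s\n", top$support[[i]],
                  top$bipartition[[i]]))
    }
  } else {
    cat("  no bipartition above 50%\n")
  }
  invisible(x)
}
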