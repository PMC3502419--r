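## Codon alignment simulator. Sites evolve i.i.d. along a tree under a
## reversible continuous-time Markov chain over the sense codons,
## Q = S diag(pi) (exchangeabilities x target frequencies), scaled to
## one expected substitution per codon per unit branch length. Clade
## frequency overrides switch the process to a different target
## frequency vector on the stem branch of the clade and everywhere
## below it, which plants non-stationary compositional bias.

#' Specify a codon alignment simulation
#'
#' @param tree Newick string or \code{phylo} tree with branch lengths
#'   in expected substitutions per codon.
#' @param length number of codons (>= 1).
#' @param exch a \code{\link{codon_rate_matrix}} supplying
#'   exchangeabilities (default \code{\link{synthetic_ecm}()}) and the
#'   default frequencies.
#' @param root_freqs codon frequencies at the root / along unmarked
#'   branches (default: the frequencies of \code{exch}).
#' @param branch_overrides named list: each element is a codon
#'   frequency vector, its name a tip label or comma-separated tip
#'   labels whose most recent common ancestor roots the override
#'   clade.
#' @param ser_usage optional target Ser1:Ser2 usage odds (e.g. 3 for
#'   3:1), imposed on \code{root_freqs} (and on override vectors) by
#'   \code{\link{adjust_ser_usage}}.
#' @param seed integer RNG seed.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(tree, length, exch = synthetic_ecm(),
                            root_freqs = NULL,
                            branch_overrides = list(),
                            ser_usage = NULL, seed = 1L) {
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) NULL)
    if (is.null(tree)) stop("spec error: invalid Newick tree")
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("spec error: tree needs branch lengths")
  }
  if (length(tree$tip.label) < 2L) {
    stop("spec error: tree needs at least 2 leaves")
  }
  stopifnot(inherits(exch, "codon_rate_matrix"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("spec error: length must be >= 1")
  code <- exch$code
  if (is.null(root_freqs)) root_freqs <- exch$freqs
  check_freqs <- function(f, what) {
    if (length(f) != length(exch$states) || any(f < 0) ||
        abs(sum(f) - 1) > 1e-6) {
      stop("spec error: ", what, " must be ", length(exch$states),
           " nonnegative frequencies summing to 1")
    }
    stats::setNames(as.numeric(f) / sum(f), exch$states)
  }
  root_freqs <- check_freqs(root_freqs, "root_freqs")
  branch_overrides <- lapply(branch_overrides, check_freqs,
                             what = "branch override")
  for (nm in names(branch_overrides)) {
    tips <- trimws(strsplit(nm, ",", fixed = TRUE)[[1]])
    if (!all(tips %in% tree$tip.label)) {
      stop("spec error: override names unknown tip(s): ",
           paste(setdiff(tips, tree$tip.label), collapse = ", "))
    }
  }
  if (!is.null(ser_usage)) {
    stopifnot(is.numeric(ser_usage), ser_usage > 0)
    root_freqs <- adjust_ser_usage(root_freqs, ser_usage, code)
    branch_overrides <- lapply(branch_overrides, adjust_ser_usage,
                               ratio = ser_usage, code = code)
  }
  structure(list(tree = tree, length = length, exch = exch,
                 root_freqs = root_freqs,
                 branch_overrides = branch_overrides,
                 ser_usage = ser_usage, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Impose a Ser1:Ser2 usage ratio on codon frequencies
#'
#' Rescales the \emph{Ser1} and \emph{Ser2} codon frequencies so their
#' totals are in the requested odds while preserving the total serine
#' mass and the relative usage within each cluster.
#'
#' @param freqs named codon frequency vector over the sense codons.
#' @param ratio Ser1:Ser2 odds (Ser1 fraction = ratio / (1 + ratio)).
#' @param code genetic code.
#' @return Adjusted frequency vector (still summing to 1).
#' @export
adjust_ser_usage <- function(freqs, ratio, code = genetic_code()) {
  s1 <- intersect(names(freqs), code$ser1)
  s2 <- intersect(names(freqs), code$ser2)
  tot <- sum(freqs[s1]) + sum(freqs[s2])
  if (tot == 0) return(freqs)
  f1 <- ratio / (1 + ratio)
  freqs[s1] <- freqs[s1] / sum(freqs[s1]) * tot * f1
  freqs[s2] <- freqs[s2] / sum(freqs[s2]) * tot * (1 - f1)
  freqs / sum(freqs)
}

#' Tilt synonymous third-position GC content of codon frequencies
#'
#' Reweights codon frequencies within every amino-acid class
#' (\emph{Ser1} and \emph{Ser2} kept separate) by
#' \code{weight^(G or C at third position)}, preserving each class's
#' total mass. Because reweighting never crosses class boundaries, the
#' implied amino-acid composition, Ser1:Ser2 usage and
#' degeneracy-coded composition are untouched: the bias is purely
#' synonymous, visible to raw nucleotides only.
#'
#' @param freqs named codon frequency vector over sense codons.
#' @param weight multiplicative weight per G/C third position
#'   (> 1 enriches GC3).
#' @param code genetic code.
#' @return Adjusted frequency vector.
#' @export
bias_synonymous_gc <- function(freqs, weight = 8, code = genetic_code()) {
  cls <- codon_classes(code, split_ser = TRUE)[names(freqs)]
  w <- ifelse(substr(names(freqs), 3, 3) %in% c("G", "C"), weight, 1)
  out <- freqs
  for (a in unique(cls)) {
    i <- which(cls == a)
    mass <- sum(freqs[i])
    if (mass == 0) next
    out[i] <- freqs[i] * w[i] / sum(freqs[i] * w[i]) * mass
  }
  out / sum(out)
}

## transition probability factory: eigendecomposition of the
## pi-symmetrized generator, numerically stable for reversible Q
pmat_factory <- function(exch, freqs) {
  S <- exch$exch
  pi_ <- freqs
  Q <- S * rep(pi_, each = length(pi_))  # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(diag(Q) * pi_)
  if (mu <= 0) stop("spec error: degenerate rate matrix")
  Q <- Q / mu
  sp <- sqrt(pmax(pi_, .Machine$double.eps))
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- eig$vectors
  left <- (1 / sp) * V        # diag(1/sp) %*% V
  right <- t(V * sp)          # t(V) %*% diag(sp)
  function(t) {
    P <- left %*% (exp(eig$values * t) * right)
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Simulate a codon alignment on a known tree
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return A \code{\link{codon_alignment}} over the tree's tips (tip
#'   order preserved) with the true tree attached as attribute
#'   \code{"tree"} and the spec as attribute \code{"spec"}. Output is
#'   reproducible: the same spec (including seed) gives byte-identical
#'   alignments.
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- spec$exch$states
  L <- spec$length

  ## per-node frequency regime: root regime everywhere, then override
  ## regimes on each marked clade (stem branch included)
  regime <- rep(1L, ntip + tree$Nnode)
  freq_sets <- list(spec$root_freqs)
  for (nm in names(spec$branch_overrides)) {
    tips <- trimws(strsplit(nm, ",", fixed = TRUE)[[1]])
    if (!all(tips %in% tree$tip.label)) {
      stop("spec error: override names unknown tip(s): ",
           paste(setdiff(tips, tree$tip.label), collapse = ", "))
    }
    node <- if (length(tips) == 1L) {
      match(tips, tree$tip.label)
    } else {
      ape::getMRCA(tree, tips)
    }
    freq_sets <- c(freq_sets, list(spec$branch_overrides[[nm]]))
    below <- c(node,
               unlist(phangorn::Descendants(tree, node, type = "all")))
    regime[below] <- length(freq_sets)
  }

  pfuns <- lapply(freq_sets, function(f) pmat_factory(spec$exch, f))

  node_states <- matrix(NA_integer_, ntip + tree$Nnode, L)
  node_states[root, ] <- sample.int(length(states), L, replace = TRUE,
                                    prob = spec$root_freqs)
  ## cladewise order guarantees parents precede children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    ## the regime of the child governs its stem branch
    P <- pfuns[[regime[child]]](tree$edge.length[e])
    ps <- node_states[parent, ]
    cs <- integer(L)
    for (s in unique(ps)) {
      i <- which(ps == s)
      cs[i] <- sample.int(length(states), length(i), replace = TRUE,
                          prob = P[s, ])
    }
    node_states[child, ] <- cs
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(states[node_states[i, ]], collapse = "")
  }, "")
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs, code = spec$exch$code)
  attr(aln, "tree") <- spec$tree
  attr(aln, "spec") <- spec
  aln
}

#' Demo conditions: a clade with purely synonymous GC3 bias
#'
#' Builds the simulation used throughout the examples and tests of the
#' compositional-heterogeneity machinery: a balanced 16-taxon tree
#' (all branches 0.3 expected substitutions per codon), 500 codons
#' under the synthetic codon model, and a 4-taxon clade (tips t01-t04)
#' whose target codon frequencies are GC3-enriched via
#' \code{\link{bias_synonymous_gc}} while amino-acid composition and
#' Ser1:Ser2 usage stay untouched. Raw nucleotide composition then
#' groups the biased clade strongly, degeneracy-coded composition does
#' not.
#'
#' @param seed RNG seed for the simulation.
#' @param length number of codons.
#' @param weight GC3 enrichment weight (> 1).
#' @return A \code{\link{simulation_spec}}; the biased tips are in the
#'   attribute \code{"biased_clade"}.
#' @export
nonstationary_demo_spec <- function(seed = 1L, length = 500L,
                                    weight = 8) {
  tips <- sprintf("t%02d", 1:16)
  pair <- function(a, b) paste0("(", a, ":0.3,", b, ":0.3):0.3")
  quartet <- vapply(split(tips, rep(1:4, each = 4)), function(g) {
    paste0("(", pair(g[1], g[2]), ",", pair(g[3], g[4]), "):0.3")
  }, "")
  nwk <- paste0("((", quartet[1], ",", quartet[2], "):0.3,(",
                quartet[3], ",", quartet[4], "):0.3);")
  ex <- synthetic_ecm()
  ov <- list()
  ov[[paste(tips[1:4], collapse = ",")]] <-
    bias_synonymous_gc(ex$freqs, weight = weight, code = ex$code)
  spec <- simulation_spec(nwk, length = length, exch = ex,
                          branch_overrides = ov, seed = seed)
  attr(spec, "biased_clade") <- tips[1:4]
  spec
}
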