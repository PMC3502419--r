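test_that("composition vectors count resolved units only", {
  v <- composition_vector("AAAA", unit = "nt")
  expect_equal(as.numeric(v), 1)
  expect_equal(names(v), "A")
  v2 <- composition_vector("ACGT", unit = "nt")
  expect_equal(unname(as.numeric(v2)), rep(0.25, 4))
  v3 <- composition_vector("ATG---", unit = "codon")
  expect_equal(attr(v3, "n_counted"), 1L)
  expect_equal(names(v3), "ATG")
  ## ambiguity and missing are skipped under the default counting
  v4 <- composition_vector("ANG-?T", unit = "nt")
  expect_equal(attr(v4, "n_counted"), 3L)
  ## ...but count as categories with all_symbols (degen matrices)
  v5 <- composition_vector("AYGRYT", unit = "nt", all_symbols = TRUE)
  expect_equal(attr(v5, "n_counted"), 6L)
  expect_true(all(c("Y", "R") %in% names(v5)))
  v6 <- composition_vector("---", unit = "codon")
  expect_equal(attr(v6, "n_counted"), 0L)
})

test_that("Euclidean composition distances match a brute-force oracle", {
  aln <- codon_alignment(c(a = "AAAAAA", b = "CCCCCC"))
  dm <- euclidean_distance_matrix(aln, unit = "nt")
  expect_equal(dm["a", "b"], sqrt(2))
  expect_equal(diag(dm), c(a = 0, b = 0))

  same <- codon_alignment(c(a = "ACGACG", b = "ACGACG"))
  expect_equal(euclidean_distance_matrix(same, "nt")["a", "b"], 0)

  set.seed(41)
  for (unit in c("nt", "codon", "aa20", "aa21")) {
    aln <- random_codon_alignment(5, 30)
    dm <- euclidean_distance_matrix(aln, unit = unit)
    seqs <- as_strings(aln)
    for (i in 1:4) for (j in (i + 1):5) {
      pi_ <- composition_vector(seqs[[i]], unit)
      pj <- composition_vector(seqs[[j]], unit)
      cats <- union(names(pi_), names(pj))
      gi <- stats::setNames(numeric(length(cats)), cats)
      gj <- gi
      gi[names(pi_)] <- pi_; gj[names(pj)] <- pj
      expect_equal(dm[i, j], sqrt(sum((gi - gj)^2)),
                   info = paste(unit, i, j))
    }
  }
})

test_that("composition distances are a metric on random alignments", {
  set.seed(43)
  for (r in 1:5) {
    aln <- random_codon_alignment(6, 25)
    dm <- euclidean_distance_matrix(aln, "nt")
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0))
    n <- nrow(dm)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
    }
  }
})

test_that("taxa with nothing countable are reported or dropped", {
  aln <- codon_alignment(c(a = "ATGATG", b = "NNNNNN", c = "ATGCCC"))
  expect_error(euclidean_distance_matrix(aln, "codon"), "'b'")
  dm <- euclidean_distance_matrix(aln, "codon", drop_empty = TRUE)
  expect_equal(rownames(dm), c("a", "c"))
})

test_that("neighbor joining recovers additive metrics exactly", {
  for (nwk in c("((a:1,b:2):1,(c:3,d:1):2);",
                "(((a:1,b:1):1,(c:2,d:1):1):1,((e:1,f:2):2,(g:1,h:1):1):1);")) {
    true <- ape::read.tree(text = nwk)
    dm <- ape::cophenetic.phylo(true)
    est <- nj_tree(dm)
    expect_equal(unname(phangorn::RF.dist(true, est)), 0)
    expect_equal(total_tree_length(est), sum(true$edge.length))
    ## branch lengths agree through the path metric
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-10)
  }
})

test_that("neighbor joining is invariant to taxon input order", {
  set.seed(47)
  aln <- random_codon_alignment(8, 40)
  dm <- euclidean_distance_matrix(aln, "nt")
  t1 <- nj_tree(dm)
  perm <- sample(nrow(dm))
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(unname(phangorn::RF.dist(t1, t2)), 0)
})

test_that("negative branch lengths clamp to zero but stay on record", {
  dm <- matrix(c(0, 10, 3, 10, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_true(any(attr(tr, "raw_edge_lengths") < 0))
  expect_error(nj_tree(dm[1:2, 1:2]), "usage error")
})

test_that("tree length sums clamped branch lengths", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):0);")
  expect_equal(total_tree_length(tr), 6)
  tr$edge.length[] <- 0
  expect_equal(total_tree_length(tr), 0)
})

test_that("purely synonymous divergence is invisible to degen1 composition", {
  set.seed(53)
  for (i in 1:5) {
    pair <- synonymous_pair(60)
    deg <- degen_alignment(pair)
    expect_equal(
      euclidean_distance_matrix(deg, "nt",
                                all_symbols = TRUE)["t1", "t2"], 0)
    ## the raw nucleotide distance is positive unless the draw was
    ## (vanishingly unlikely) identical
    if (!identical(as_strings(pair)[[1]], as_strings(pair)[[2]])) {
      expect_gt(euclidean_distance_matrix(pair, "nt")["t1", "t2"], 0)
    }
  }
})

test_that("identical composition gives a zero-length tree", {
  aln <- codon_alignment(c(a = "ATGCCC", b = "ATGCCC", c = "CCCATG",
                           d = "ATGCCC"))
  dm <- euclidean_distance_matrix(aln, "nt")
  expect_equal(total_tree_length(nj_tree(dm)), 0)
})

test_that("the bootstrap contract holds: replicates, seeds, supports", {
  set.seed(59)
  aln <- random_codon_alignment(6, 20)
  bs <- composition_bootstrap(aln, "nt", reps = 25, seed = 101)
  expect_length(bs$tree_lengths, 25)
  expect_equal(bs$reps, 25)
  expect_equal(bs$seed, 101)
  expect_true(all(bs$supports$support >= 0 &
                    bs$supports$support <= 100))
  ## reproducible under the same seed
  bs2 <- composition_bootstrap(aln, "nt", reps = 25, seed = 101)
  expect_identical(bs$supports, bs2$supports)
  expect_identical(bs$tree_lengths, bs2$tree_lengths)
  ## taxon input order does not matter (same seed)
  perm <- c(3, 1, 6, 2, 4, 5)
  m <- unclass(aln)[perm, ]
  bsp <- composition_bootstrap(codon_alignment(m), "nt", reps = 25,
                               seed = 101)
  expect_identical(bs$supports, bsp$supports)
})

test_that("strong compositional contrast earns strong bootstrap support", {
  ## two 4-taxon groups with very different nucleotide pools
  set.seed(61)
  rich_at <- function() paste(sample(c("AAT", "ATA", "TTA", "ATT"), 40,
                                     TRUE), collapse = "")
  rich_gc <- function() paste(sample(c("GGC", "GCG", "CCG", "GCC"), 40,
                                     TRUE), collapse = "")
  seqs <- c(a1 = rich_at(), a2 = rich_at(), a3 = rich_at(),
            a4 = rich_at(), b1 = rich_gc(), b2 = rich_gc(),
            b3 = rich_gc(), b4 = rich_gc())
  bs <- composition_bootstrap(codon_alignment(seqs), "nt", reps = 100,
                              seed = 7)
  expect_gt(bipartition_support(bs, c("a1", "a2", "a3", "a4")), 90)
})
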