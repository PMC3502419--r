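## builds a small alignment with a known mix of site categories:
## site 1 co-Ser, site 2 non-co-Ser1, site 3 non-Ser, site 4 co-Ser
## (via degen patterns), site 5 non-co-Ser2 with missing data
mixed_ser_alignment <- function() {
  codon_alignment(c(
    t1 = paste0("TCA", "TCA", "AAA", "TCN", "AGT"),
    t2 = paste0("AGC", "TCC", "GGG", "AGY", "---"),
    t3 = paste0("GGG", "ATG", "GGG", "GGG", "NNN")))
}

test_that("sites classify by serine co-occurrence", {
  cls <- classify_ser_sites(mixed_ser_alignment())
  expect_equal(cls$category,
               c("co-Ser", "non-co-Ser1", "non-Ser", "co-Ser",
                 "non-co-Ser2"))
  expect_equal(cls$n_ser1, c(1, 2, 0, 1, 0))
  expect_equal(cls$n_ser2, c(1, 0, 0, 1, 1))
  expect_equal(cls$n_missing, c(0, 0, 0, 0, 2))
  ## counts always total the taxon count
  expect_true(all(rowSums(cls[, c("n_ser1", "n_ser2", "n_other",
                                  "n_missing")]) == 3))
})

test_that("ambiguous serine codons only count when all expansions agree", {
  aln <- codon_alignment(c(a = "TCMAGN", b = "GGGGGG"))
  cls <- classify_ser_sites(aln)
  expect_equal(cls$n_ser1, c(1, 0))   # TCM is certainly Ser1
  expect_equal(cls$n_ser2, c(0, 0))   # AGN may be Arg
  expect_equal(cls$category, c("non-co-Ser1", "non-Ser"))
})

test_that("classification is invariant under degen1 coding", {
  set.seed(13)
  for (i in 1:10) {
    aln <- random_codon_alignment(6, 30)
    expect_identical(classify_ser_sites(aln),
                     classify_ser_sites(degen_alignment(aln)))
  }
})

test_that("the serine site spectrum counts occupancy cumulatively", {
  aln <- codon_alignment(c(
    t1 = "TCAAGTAAA", t2 = "AGCGGGAAA", t3 = "GGGGGGAAA"))
  ## serine occupancy per site: 2 (co-Ser), 1 (non-co-Ser2), 0
  sp <- ser_site_spectrum(classify_ser_sites(aln), max_k = 3)
  expect_equal(sp$total, c(2, 1, 0))
  expect_equal(sp$co_ser, c(1, 1, 0))
  expect_equal(sp$non_co_ser2, c(1, 0, 0))
  expect_true(all(diff(sp$total) <= 0))

  none <- codon_alignment(c(a = "AAAGGG", b = "AAAGGG"))
  sp0 <- ser_site_spectrum(classify_ser_sites(none), max_k = 2)
  expect_true(all(sp0$total == 0))
})

test_that("serine codon usage reports per-taxon proportions and a ratio", {
  aln <- codon_alignment(c(a = "TCATCAAGT", b = "AAAGGGCCC"))
  u <- ser_codon_usage(aln)
  expect_equal(u$TCA[u$taxon == "a"], 2 / 3)
  expect_equal(u$AGT[u$taxon == "a"], 1 / 3)
  expect_equal(u$ser1_fraction[u$taxon == "a"], 2 / 3)
  expect_true(u$empty[u$taxon == "b"])
  expect_true(is.na(u$ser1_fraction[u$taxon == "b"]))
  expect_equal(attr(u, "ser1_fraction_total"), 2 / 3)

  ## invariant under codon-column shuffling
  set.seed(3)
  cm <- codon_strings(aln)
  shuffled <- from_codon_strings(cm[, sample(ncol(cm))], std_code)
  expect_equal(ser_codon_usage(shuffled)[, -1], u[, -1],
               ignore_attr = TRUE)
})

test_that("cluster-swapping directives rewrite exactly one cluster", {
  aln <- degen_alignment(mixed_ser_alignment())
  res <- manipulate(aln, "ser1_to_ser2")
  expect_true(all(res$changes$from == "TCN"))
  expect_true(all(res$changes$to == "AGY"))
  cls <- classify_ser_sites(res$alignment)
  expect_equal(sum(cls$category %in% c("co-Ser", "non-co-Ser1")), 0)
  ## everything else untouched
  before <- codon_strings(aln); after <- codon_strings(res$alignment)
  expect_identical(before[before != "TCN"], after[before != "TCN"])

  back <- manipulate(res$alignment, "ser2_to_ser1")
  expect_true(all(back$changes$to == "TCN"))
})

test_that("deletion directives mask the selected serine cells with NNN", {
  aln <- mixed_ser_alignment()
  cm <- codon_strings(aln)
  st <- matrix(ser_status(as.vector(cm), std_code), nrow = nrow(cm))

  res <- manipulate(aln, "delete_ser_all")
  out <- codon_strings(res$alignment)
  expect_true(all(out[st %in% c("ser1", "ser2")] == "NNN"))
  expect_identical(out[!(st %in% c("ser1", "ser2"))],
                   cm[!(st %in% c("ser1", "ser2"))])

  res1 <- manipulate(aln, "delete_co_ser1")
  out1 <- codon_strings(res1$alignment)
  expect_equal(nrow(res1$changes), 2)  # TCA at site 1, TCN at site 4
  expect_true(all(out1[, 2] == cm[, 2]))  # non-co-Ser1 site untouched

  resn <- manipulate(aln, "delete_non_co_ser1")
  expect_equal(sort(resn$changes$site), c(2, 2))
})

test_that("co-Ser complements are disjoint and jointly exhaustive", {
  set.seed(17)
  aln <- random_codon_alignment(8, 40)
  cm <- codon_strings(aln)
  st <- matrix(ser_status(as.vector(cm), std_code), nrow = nrow(cm))
  cls <- classify_ser_sites(aln)
  co <- which(cls$category == "co-Ser")
  a <- manipulate(aln, "delete_co_ser_both")$changes
  b <- manipulate(aln, "delete_non_ser_at_co_ser")$changes
  key <- function(ch) paste(ch$taxon, ch$site)
  expect_length(intersect(key(a), key(b)), 0)
  ## together they cover every non-missing cell of every co-Ser column
  non_missing <- sum(st[, co, drop = FALSE] != "missing")
  expect_equal(nrow(a[a$site %in% co, ]) + nrow(b), non_missing)
})

test_that("split_co_ser splits each co-Ser column into Ser and non-Ser parts", {
  aln <- codon_alignment(c(t1 = "TCA", t2 = "AGT", t3 = "GGG"))
  res <- manipulate(aln, "split_co_ser")
  out <- codon_strings(res$alignment)
  expect_equal(ncol(out), 2)
  expect_equal(unname(out[, 1]), c("TCA", "AGT", "NNN"))
  expect_equal(unname(out[, 2]), c("NNN", "NNN", "GGG"))

  set.seed(19)
  aln2 <- random_codon_alignment(6, 30)
  n_co <- sum(classify_ser_sites(aln2)$category == "co-Ser")
  res2 <- manipulate(aln2, "split_co_ser")
  expect_equal(n_codons(res2$alignment), n_codons(aln2) + n_co)
})

test_that("amino-acid proxies recode exactly the commingling serine cells", {
  caln <- mixed_ser_alignment()
  aa <- translate_alignment(caln, "aa20")
  res <- manipulate(aa, "proxy_recode", source = "co_ser1",
                    target = "W", codon_aln = caln)
  out <- unclass(res$alignment)
  ## only t1's Ser1 residues at the two co-Ser sites change
  expect_equal(res$changes$taxon, c("t1", "t1"))
  expect_equal(sort(res$changes$site), c(1, 4))
  expect_true(all(res$changes$to == "W"))
  expect_equal(unname(out["t1", 2]), "S")  # non-co-Ser1 site keeps S
  expect_error(manipulate(aa, "proxy_recode", source = "co_ser1",
                          target = "A", codon_aln = caln),
               "usage error")
})

test_that("generic amino-acid swaps and deletions behave and log changes", {
  aa <- amino_alignment(c(a = "DQD", b = "EDN"), alphabet = "aa20")
  sw <- manipulate(aa, "aa_swap", source = "D", target = "E")
  expect_identical(unname(as_strings(sw$alignment)), c("EQE", "EEN"))
  expect_equal(nrow(sw$changes), 3)
  del <- manipulate(aa, "delete_aa", source = "D")
  expect_identical(unname(as_strings(del$alignment)), c("-Q-", "E-N"))

  caln <- codon_alignment(c(a = "TTTAAA", b = "TTCGGG"))
  delF <- manipulate(caln, "delete_aa", source = "F")
  expect_identical(unname(as_strings(delF$alignment)),
                   c("NNNAAA", "NNNGGG"))
})

test_that("change logs reconcile with an independent diff", {
  set.seed(29)
  for (kind in c("delete_ser_all", "ser1_to_ser2",
                 "delete_co_ser_both")) {
    aln <- random_codon_alignment(6, 25)
    res <- manipulate(aln, kind)
    diff_n <- sum(codon_strings(aln) != codon_strings(res$alignment))
    expect_equal(nrow(res$changes), diff_n, info = kind)
    expect_equal(dim(res$alignment), dim(aln), info = kind)
  }
})

test_that("directive/type mismatches raise usage errors", {
  caln <- codon_alignment(c(a = "TCAAGT", b = "AGTTCA"))
  aa <- translate_alignment(caln, "aa20")
  expect_error(manipulate(caln, "proxy_recode", source = "co_ser1",
                          target = "W"), "usage error")
  expect_error(manipulate(aa, "delete_ser_all"), "usage error")
})
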