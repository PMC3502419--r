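## fixture builders shared across the suite; everything is generated
## in code, nothing is read from disk

std_code <- genetic_code()
SENSE <- sense_codons(std_code)

## random in-frame alignment of unambiguous sense codons
random_codon_alignment <- function(n_taxa = 6, n_codons = 20,
                                   codons = SENSE) {
  seqs <- vapply(seq_len(n_taxa), function(i) {
    paste(sample(codons, n_codons, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("tax", seq_len(n_taxa))
  codon_alignment(seqs)
}

## pair of sequences that differ only by synonymous substitutions that
## never cross the Ser1/Ser2 divide: per codon site, both rows draw
## from the same amino-acid class (Ser1 and Ser2 as separate classes)
synonymous_pair <- function(n_codons = 40) {
  cls <- codon_classes(std_code, split_ser = TRUE)
  groups <- split(names(cls), cls)
  groups <- groups[vapply(groups, length, 0L) > 1]
  picks <- sample(length(groups), n_codons, replace = TRUE)
  a <- vapply(picks, function(g) sample(groups[[g]], 1), "")
  b <- vapply(picks, function(g) sample(groups[[g]], 1), "")
  codon_alignment(c(t1 = paste(a, collapse = ""),
                    t2 = paste(b, collapse = "")))
}

## the published degen1 codon -> pattern table for the standard code,
## written out by hand from the coding definitions; the oracle against
## which the generic pattern construction is checked
DEGEN1_PATTERNS <- c(
  A = "GCN", R = "MGN", N = "AAY", D = "GAY", C = "TGY", Q = "CAR",
  E = "GAR", G = "GGN", H = "CAY", I = "ATH", L = "YTN", K = "AAR",
  M = "ATG", F = "TTY", P = "CCN", S1 = "TCN", S2 = "AGY", T = "ACN",
  W = "TGG", Y = "TAY", V = "GTN")

## independent codon -> amino-acid map (Biostrings' genetic code, not
## the package's own table)
oracle_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_degen1 <- function(codon) {
  aa <- oracle_aa(codon)
  if (aa == "*") return("NNN")
  if (aa == "S") {
    return(if (substr(codon, 1, 2) == "TC") "TCN" else "AGY")
  }
  unname(DEGEN1_PATTERNS[[aa]])
}
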