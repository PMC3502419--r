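#' Read a multiple sequence alignment
#'
#' Reads FASTA, relaxed PHYLIP (labels up to 64 characters, separated
#' from the sequence by whitespace) or NEXUS (DATA block) into a
#' validated alignment object. Taxon order is preserved from the file.
#'
#' @param source path to the file, or a character vector of file lines.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}.
#' @param datatype \code{"nucleotide"} for an in-frame codon alignment,
#'   \code{"aa20"} or \code{"aa21"} for amino acids.
#' @param code genetic code for nucleotide data.
#' @return A \code{\link{codon_alignment}} or
#'   \code{\link{amino_alignment}}.
#' @export
read_alignment <- function(source,
                           format = c("fasta", "phylip", "nexus"),
                           datatype = c("nucleotide", "aa20", "aa21"),
                           code = genetic_code()) {
  format <- match.arg(format)
  datatype <- match.arg(datatype)
  seqs <- switch(format,
    fasta = read_fasta(source),
    phylip = read_phylip(source),
    nexus = read_nexus(source))
  if (datatype == "nucleotide") {
    codon_alignment(seqs, code = code)
  } else {
    amino_alignment(seqs, alphabet = datatype)
  }
}

#' Serialize an alignment
#'
#' @param aln a codon or amino-acid alignment.
#' @param path optional output path; when \code{NULL} the serialized
#'   lines are returned only.
#' @param format \code{"fasta"} (wrapped at 80 columns),
#'   \code{"phylip"} (relaxed, sequential) or \code{"nexus"}. NEXUS
#'   output declares the datatype and, for the 21-state alphabet, the
#'   extended symbol list including \code{Z}.
#' @return Invisibly, the character vector of output lines.
#' @export
write_alignment <- function(aln, path = NULL,
                            format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (nrow(aln) == 0L) stop("usage error: empty alignment")
  seqs <- as_strings(aln)
  lines <- switch(format,
    fasta = format_fasta(seqs),
    phylip = format_phylip(seqs),
    nexus = format_nexus(seqs, aln))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
}

read_fasta <- function(source) {
  if (length(source) == 1L && file.exists(source)) {
    x <- Biostrings::readBStringSet(source)
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  lines <- source_lines(source)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("format error: no FASTA headers found")
  idx <- cumsum(hdr)
  labels <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  body <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  stats::setNames(toupper(gsub("\\s", "", unname(body))), labels)
}

format_fasta <- function(seqs, wrap = 80L) {
  unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = wrap)
    c(paste0(">", nm), substring(s, starts, pmin(starts + wrap - 1L,
                                                 nchar(s))))
  }))
}

read_phylip <- function(source) {
  lines <- source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("format error: PHYLIP header must hold ntax and nchar")
  }
  ntax <- as.integer(hdr[[1]]); nchar_exp <- as.integer(hdr[[2]])
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  seqs <- character(ntax); labels <- character(ntax)
  i <- 1L
  for (t in seq_len(ntax)) {
    if (i > length(toks)) stop("format error: truncated PHYLIP file")
    labels[[t]] <- toks[[i]]
    if (nchar(labels[[t]]) > 64L) {
      stop("format error: PHYLIP label longer than 64 characters")
    }
    i <- i + 1L
    s <- ""
    while (nchar(s) < nchar_exp) {
      if (i > length(toks)) {
        stop("format error: sequence for '", labels[[t]],
             "' shorter than declared (", nchar(s), " < ", nchar_exp, ")")
      }
      s <- paste0(s, toks[[i]])
      i <- i + 1L
    }
    if (nchar(s) != nchar_exp) {
      stop("format error: sequence for '", labels[[t]],
           "' longer than declared")
    }
    seqs[[t]] <- toupper(s)
  }
  stats::setNames(seqs, labels)
}

format_phylip <- function(seqs) {
  c(sprintf(" %d %d", length(seqs), nchar(seqs[[1]])),
    sprintf("%s %s", names(seqs), unname(seqs)))
}

read_nexus <- function(source) {
  path <- source
  if (!(length(source) == 1L && !grepl("\n", source) &&
        file.exists(source))) {
    path <- tempfile(fileext = ".nex")
    writeLines(source_lines(source), path)
    on.exit(unlink(path))
  }
  x <- ape::read.nexus.data(path)
  stats::setNames(toupper(vapply(x, paste, "", collapse = "")), names(x))
}

format_nexus <- function(seqs, aln) {
  if (inherits(aln, "codon_alignment")) {
    datatype <- "dna"
    symbols <- NULL  # standard DNA symbol set suffices
  } else {
    datatype <- "protein"
    letters <- if (identical(attr(aln, "alphabet"), "aa21")) {
      AA21_LETTERS
    } else {
      AA20_LETTERS
    }
    symbols <- paste(c(letters, "X"), collapse = "")
  }
  c("#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
            nchar(seqs[[1]])),
    sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-%s;", datatype,
            if (is.null(symbols)) "" else
              sprintf(" SYMBOLS=\"%s\"", symbols)),
    "  MATRIX",
    sprintf("    %s  %s", names(seqs), unname(seqs)),
    "  ;",
    "END;")
}
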