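## Sequence utilities: reverse complement, translation, IUPAC matching.

#' Reverse complement of a nucleotide string
#' @param x Nucleotide string (IUPAC codes allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string
#'
#' Standard genetic code, stop rendered as `"*"`. An incomplete trailing
#' codon is dropped.
#'
#' @param nt Nucleotide string over A/C/G/T.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @param to_stop If TRUE, translation halts at (and excludes) the first
#'   stop codon; otherwise stops are emitted as `"*"` and translation
#'   continues.
#' @return Peptide string (one-letter amino-acid codes).
#' @export
translate_nt <- function(nt, frame_offset = 0L, to_stop = FALSE) {
  nt <- toupper(as.character(nt))
  bad <- regexpr("[^ACGT]", nt)
  if (bad > 0L) stop("non-ACGT character at position ", bad)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  nt <- substring(nt, frame_offset + 1L)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (to_stop && any(aa == "*")) aa <- aa[seq_len(which(aa == "*")[1L] - 1L)]
  paste(aa, collapse = "")
}

## TRUE where pattern base (IUPAC) is compatible with subject base, vectorized
## over equal-length character vectors of single bases.
iupac_compatible <- function(pattern, subject) {
  map <- Biostrings::IUPAC_CODE_MAP
  p <- map[pattern]
  s <- map[subject]
  p[is.na(p)] <- ""
  s[is.na(s)] <- ""
  mapply(function(pc, sc) {
    any(strsplit(pc, "")[[1L]] %in% strsplit(sc, "")[[1L]])
  }, p, s, USE.NAMES = FALSE)
}

## split a string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## 1-letter -> 3-letter amino-acid codes (HGVS style), "*" -> "Ter"
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")
aa3 <- function(aa) {
  out <- AA3[chars(aa)]
  out[is.na(out)] <- "Xaa"
  paste(out, collapse = "")
}
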