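## Built-in reference fixtures.
##
## The full X. laevis adprhl1 locus sequence is not machine-readable, so two
## reconstructions are provided:
##   * exon6_local_model(): the 24-nt exon 6 local CDS assembled from the
##     published e6-1 spacer + PAM and the 15-bp variant window, with the
##     reading frame anchored so the window translates to GGRRG
##     (residues 269-273);
##   * synthetic_locus_pair(): a SYNTHETIC two-homeolog amplicon pair (S/L)
##     embedding that exon 6 site in invented flanking sequence, used by the
##     simulator and round-trip tests. Flanks, homeolog differences and the
##     9-bp intron length difference are synthetic stand-ins, not the real
##     locus.

E6_SPACER <- "GAGGGAAGAGGGGGAAGAAG"
E6_PAM <- "AGG"
E6_WINDOW_SEQ <- "GGGGGAAGAAGAGGA"   # 15-bp variant window including the PAM
E6_WT_PEPTIDE <- "GGRRG"             # residues 269-273

## synthetic flank constants (generated once, fixed): S-homeolog
SYN_S_INTRON5 <- "ACAGCTTCGTGTCGCTAGTACGGGCTGAGTTGGTTCCTGGGACACGGCTGCGGCGGCACTTTCCAATATTGACTACGTTGCTGACGGGCGCAATTAGACTGTACCTAGTTTAACGAATATGTTGATTGACGCCATATGTAAGCTACGTCATGAAACGCAG"
SYN_S_INTRON3 <- "GTCGCCGTATGAGGAAGGGTGCTATTTTAACCAACCCCCGTATTAGGCTCGATGGTGAGACGACTCGGACGAGGCTGTTCTGAAATCTATCAATCCTGTTAACGTGTGACCGGTGGCAGTCCACATCGGAAGCGGTCGATGACTCCCCACTCCGCTTCTTCCTTTCCGTTAGATTAATAC"
## L-homeolog: six 5'-flank substitutions, a 9-bp intron-3' deletion and one
## further substitution relative to S (the exon itself is identical)
SYN_L_INTRON5 <- "ACAACTTCGTGTTGCTAGTACGGGCTTAGTTGGTTCCTGGGACACGGCTGCGGCGGCACTTTCCAATATTGACTACGTTGCTGACGGGCGAAATTAGACTGTACCTAGTTTAACGAATATGTTGATTGACTCCATATGTAAGCTACGTCAAGAAACGCAG"
SYN_L_INTRON3 <- "GTCGCCGTATGAGGAAGGGTGCTATTTTAACCAACCCCCGTATTAGGCTCGATGGTGAGACGAGGCTGTTCTGAAATCTATCAATCCTGTTAACGTGTGCCCGGTGGCAGTCCACATCGGAAGCGGTCGATGACTCCCCACTCCGCTTCTTCCTTTCCGTTAGATTAATAC"
SYN_EXON_PRE <- "TCGTTCTTAGCTAACACGTCCTCATTGGAC"   # 10 synthetic codons
SYN_EXON_POST <- "TGGGATAAACGACTGCCT"              # 6 synthetic codons

#' The exon 6 local-CDS reference
#'
#' A 24-nt in-frame local CDS reconstructed from the published exon 6 spacer
#' (GAGGGAAGAGGGGGAAGAAG), its AGG PAM and the 15-bp variant window
#' (GGGGGAAGAAGAGGA), anchored so the window translates to GGRRG at residues
#' 269-273 (so the first codon of the fragment is Glu266). All exon 6 worked
#' examples are self-contained on this model.
#'
#' @return A [gene_model()] of the 24-nt fragment (allele `"e6"`, one exon,
#'   `residue_offset` 265).
#' @export
exon6_local_model <- function() {
  seqn <- paste0(E6_SPACER, E6_PAM, "A")
  gene_model(seqn, data.frame(exon_id = "e6", start = 0L, end = 24L),
             allele_id = "e6", residue_offset = 265L)
}

#' Variant window of the exon 6 local model
#'
#' The PAM-anchored 15-bp window on [exon6_local_model()] coordinates
#' (0-based half-open), covering codons 269-273.
#'
#' @return Integer `c(9, 24)`.
#' @export
exon6_window <- function() c(9L, 24L)

#' The exon 6 guide
#'
#' @return [guide_rna()] for the principal exon 6 guide (20-nt spacer,
#'   AGG PAM, forward).
#' @export
exon6_guide <- function() {
  guide_rna("gAdprhl1-e6-1", E6_SPACER, E6_PAM, "forward")
}

#' Synthetic two-homeolog amplicon pair
#'
#' A synthetic reconstruction of the S/L homeologous exon 6 amplicons: each
#' amplicon is intron / 72-nt exon / intron with the published 24-nt exon 6
#' site embedded codon-aligned at exon offset 30, so the window peptide and
#' residue numbering (266-273 across the site) match the local model. The
#' homeologs differ by seven flank substitutions (three within the first 40
#' nt, supporting the 5'-identity assignment rule) and a 9-bp intron length
#' difference (412 vs 403 bp amplicons). The flanking sequence is invented;
#' only the embedded site reproduces published sequence.
#'
#' @return Named list of two [gene_model()] objects (`S`, `L`) with
#'   attributes `window` (0-based half-open, `c(199, 214)`) and `cut` (207).
#' @export
synthetic_locus_pair <- function() {
  exon <- paste0(SYN_EXON_PRE, E6_SPACER, E6_PAM, "A", SYN_EXON_POST)
  exon_start <- nchar(SYN_S_INTRON5)   # 160 for both homeologs
  exons <- data.frame(exon_id = "e6", start = exon_start,
                      end = exon_start + nchar(exon))
  models <- list(
    S = gene_model(paste0(SYN_S_INTRON5, exon, SYN_S_INTRON3), exons,
                   allele_id = "S", residue_offset = 255L),
    L = gene_model(paste0(SYN_L_INTRON5, exon, SYN_L_INTRON3), exons,
                   allele_id = "L", residue_offset = 255L))
  attr(models, "window") <- c(exon_start + 39L, exon_start + 54L)
  attr(models, "cut") <- exon_start + 47L
  models
}
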