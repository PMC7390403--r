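#' Construct a gene model for one reference allele
#'
#' A gene model bundles the reference nucleotide sequence of one allele
#' (e.g. the S- or L-homeolog amplicon of an allotetraploid locus) with its
#' exon structure and codon frame. All coordinates are 0-based, half-open
#' internally; user-facing reports and HGVS strings are 1-based.
#'
#' Minus-strand genes are reverse-complemented into CDS orientation at
#' construction time, so every downstream computation runs on a single
#' (plus-strand, CDS-oriented) code path.
#'
#' @param sequence Nucleotide string over A/C/G/T (IUPAC N tolerated outside
#'   the CDS).
#' @param exons data.frame with columns `exon_id`, `start`, `end`
#'   (0-based half-open genomic coordinates), sorted or sortable,
#'   non-overlapping, each within the sequence.
#' @param allele_id Label for the allele, e.g. `"S"` or `"L"`.
#' @param cds_start_offset Genomic index (0-based) of the first coding base.
#'   Defaults to the start of the first exon.
#' @param cds_end_offset Genomic index one past the last coding base.
#'   Defaults to the end of the last exon.
#' @param strand `"+"` or `"-"`. For `"-"` the sequence and exon coordinates
#'   are flipped into CDS orientation and the original strand recorded.
#' @param residue_offset Integer added to the 1-based residue index of the
#'   first codon, so that a local CDS fragment can carry the residue
#'   numbering of its full-length protein (e.g. a fragment whose first codon
#'   is residue 266 uses `residue_offset = 265`). Default 0.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(sequence, exons, allele_id = "A",
                       cds_start_offset = NULL, cds_end_offset = NULL,
                       strand = c("+", "-"), residue_offset = 0L) {
  strand <- match.arg(strand)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty reference sequence")
  if (grepl("[^ACGTN]", sequence)) {
    bad <- regexpr("[^ACGTN]", sequence)
    stop("non-ACGTN character in reference sequence at position ", bad)
  }
  exons <- as.data.frame(exons)
  req <- c("exon_id", "start", "end")
  if (!all(req %in% names(exons))) {
    stop("exon table must have columns exon_id, start, end")
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  L <- nchar(sequence)

  if (strand == "-") {
    sequence <- revcomp(sequence)
    new_start <- L - exons$end
    exons$end <- L - exons$start
    exons$start <- new_start
    if (!is.null(cds_start_offset) || !is.null(cds_end_offset)) {
      cs <- cds_start_offset
      ce <- cds_end_offset
      cds_start_offset <- if (is.null(ce)) NULL else L - ce
      cds_end_offset <- if (is.null(cs)) NULL else L - cs
    }
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  for (i in seq_len(nrow(exons))) {
    if (exons$start[i] < 0L || exons$end[i] > L || exons$start[i] >= exons$end[i]) {
      stop("exon '", exons$exon_id[i], "' has out-of-range coordinates [",
           exons$start[i], ", ", exons$end[i], ") for sequence of length ", L)
    }
    if (i > 1L && exons$start[i] < exons$end[i - 1L]) {
      stop("exon '", exons$exon_id[i], "' overlaps exon '", exons$exon_id[i - 1L], "'")
    }
  }
  if (is.null(cds_start_offset)) cds_start_offset <- exons$start[1L]
  if (is.null(cds_end_offset)) cds_end_offset <- exons$end[nrow(exons)]
  cds_start_offset <- as.integer(cds_start_offset)
  cds_end_offset <- as.integer(cds_end_offset)

  model <- structure(
    list(allele_id = allele_id, sequence = sequence, exons = exons,
         cds_start_offset = cds_start_offset, cds_end_offset = cds_end_offset,
         strand = strand, residue_offset = as.integer(residue_offset)),
    class = "gene_model")
  if (length(cds_positions(model)) < 3L) {
    stop("concatenated CDS length must be >= 3 (got ",
         length(cds_positions(model)), ")")
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> allele", x$allele_id, "| ", nchar(x$sequence), "nt,",
      nrow(x$exons), "exon(s),", length(cds_positions(x)), "nt CDS",
      if (x$strand == "-") "(loaded from minus strand)" else "", "\n")
  invisible(x)
}

## 0-based genomic positions of coding bases, in transcript order
cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq.int(model$exons$start[i], model$exons$end[i] - 1L)
  }), use.names = FALSE)
  pos[pos >= model$cds_start_offset & pos < model$cds_end_offset]
}

#' Coding sequence of a gene model
#'
#' @param model A [gene_model()].
#' @return The concatenated exonic coding sequence (CDS orientation).
#' @export
cds_seq <- function(model) {
  pos <- cds_positions(model)
  paste(strsplit(model$sequence, "", fixed = TRUE)[[1L]][pos + 1L], collapse = "")
}

#' Number of whole codons in the CDS
#' @param model A [gene_model()].
#' @return Integer count of complete codons.
#' @export
cds_codon_count <- function(model) length(cds_positions(model)) %/% 3L

#' Map genomic coding positions to residue and codon offset
#'
#' Builds the codon map of a gene model: for every coding genomic position,
#' the 1-based residue index (shifted by the model's `residue_offset`) and
#' the within-codon offset 0/1/2. The map is bijective over coding positions;
#' trailing bases of an incomplete final codon are excluded.
#'
#' @param model A [gene_model()].
#' @return data.frame with columns `genomic_pos` (0-based), `residue_index`
#'   (1-based + offset) and `codon_offset` (0, 1, 2).
#' @export
codon_map <- function(model) {
  pos <- cds_positions(model)
  n <- (length(pos) %/% 3L) * 3L
  pos <- pos[seq_len(n)]
  idx <- seq_len(n) - 1L
  data.frame(genomic_pos = pos,
             residue_index = idx %/% 3L + 1L + model$residue_offset,
             codon_offset = idx %% 3L)
}

#' Residues touched by a genomic span
#'
#' @param model A [gene_model()].
#' @param start,end 0-based half-open genomic span; must be non-empty and lie
#'   entirely within the coding sequence.
#' @return list with `first_residue`, `last_residue` (1-based, offset-shifted)
#'   and `codon_offsets` of the first and last base.
#' @export
residues_of_span <- function(model, start, end) {
  if (end <= start) stop("zero-length or inverted span [", start, ", ", end, ")")
  cm <- codon_map(model)
  sel <- cm$genomic_pos >= start & cm$genomic_pos < end
  if (!all(seq.int(start, end - 1L) %in% cm$genomic_pos)) {
    stop("span [", start, ", ", end, ") is not fully within the coding sequence")
  }
  list(first_residue = min(cm$residue_index[sel]),
       last_residue = max(cm$residue_index[sel]),
       codon_offsets = c(cm$codon_offset[sel][1L],
                         cm$codon_offset[sel][sum(sel)]))
}

#' Load gene models from FASTA and an exon table
#'
#' The exon table is a TSV with columns `allele_id`, `exon_id`, `start`,
#' `end` (0-based half-open), and optionally `cds_start_offset`,
#' `cds_end_offset`, `strand`, `residue_offset` (constant per allele).
#' FASTA record ids must match the table's allele ids.
#'
#' @param fasta_path Path to a FASTA file of allele sequences.
#' @param exon_table_path Path to the exon TSV.
#' @return Named list of [gene_model()] objects, one per allele.
#' @export
load_gene_model <- function(fasta_path, exon_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(exon_table_path, stringsAsFactors = FALSE)
  if (!all(c("allele_id", "exon_id", "start", "end") %in% names(tab))) {
    stop("exon table must have columns allele_id, exon_id, start, end")
  }
  ids <- unique(tab$allele_id)
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) {
    stop("exon table allele id(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(ids, function(id) {
    sub <- tab[tab$allele_id == id, , drop = FALSE]
    first <- function(col, default) if (col %in% names(sub)) sub[[col]][1L] else default
    gene_model(as.character(seqs[[id]]), sub[, c("exon_id", "start", "end")],
               allele_id = id,
               cds_start_offset = if ("cds_start_offset" %in% names(sub))
                 sub$cds_start_offset[1L] else NULL,
               cds_end_offset = if ("cds_end_offset" %in% names(sub))
                 sub$cds_end_offset[1L] else NULL,
               strand = as.character(first("strand", "+")),
               residue_offset = as.integer(first("residue_offset", 0L)))
  })
  names(out) <- ids
  out
}

#' Load an exon table from a GFF3 file
#'
#' Convenience reader mapping `exon` (or `CDS`) features of a GFF3 file to
#' the exon-table layout used by [load_gene_model()]. Requires the
#' rtracklayer package.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param feature Feature type to extract, `"exon"` or `"CDS"`.
#' @return data.frame with columns `allele_id`, `exon_id`, `start`, `end`
#'   (converted to 0-based half-open).
#' @export
read_exon_gff3 <- function(gff3_path, feature = c("exon", "CDS")) {
  feature <- match.arg(feature)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_exon_gff3 requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(gff3_path, format = "gff3"))
  gr <- gr[gr$type == feature, , drop = FALSE]
  ids <- if (!is.null(gr$ID) && !anyNA(gr$ID)) as.character(gr$ID) else
    paste0(feature, seq_len(nrow(gr)))
  data.frame(allele_id = as.character(gr$seqnames),
             exon_id = ids,
             start = gr$start - 1L,
             end = gr$end,
             stringsAsFactors = FALSE)
}
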