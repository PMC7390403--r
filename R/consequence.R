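#' Annotate the protein consequence of a DNA lesion
#'
#' Converts a normalized DNA lesion into a protein-level consequence with an
#' HGVS-style `p.()` name and an amino-acid change count. Splice flags take
#' precedence over codon arithmetic:
#' \itemize{
#'   \item a disrupted splice acceptor is assumed to skip the exon — an
#'     in-frame skip deletes the exon's residues, an out-of-frame skip is a
#'     frameshift-equivalent truncating change;
#'   \item a disrupted splice donor is assumed to retain the following
#'     intron — translation proceeds into the intron until the first stop
#'     (truncating), or, for a stop-free intron of whole-codon length,
#'     yields an in-frame insertion of intron-encoded residues.
#' }
#' Otherwise the mutant CDS is rebuilt from the lesion's events, both CDS
#' are translated, and the peptides are compared after maximal common
#' prefix/suffix trimming (prefix first, giving the 3'-most, HGVS-normalized
#' description). A net indel not divisible by 3 is a frameshift; a premature
#' stop is nonsense. Amino-acid changes count substituted + inserted +
#' deleted residues (a delins counts `max(deleted, inserted)`).
#'
#' @param lesion A [call_lesion()] result (or compatible list with `events`,
#'   splice flags). All of the read's events are used, not only the
#'   in-window subset.
#' @param model The [gene_model()] of the allele the lesion was called on.
#' @return Object of class `protein_consequence` with fields `kind`,
#'   `aa_changes`, `hgvs_p`, `affected_residues`, `truncating`.
#' @export
annotate_consequence <- function(lesion, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!is.null(lesion$allele_id) && !is.na(lesion$allele_id) &&
      !identical(lesion$allele_id, model$allele_id)) {
    stop("lesion was called on allele '", lesion$allele_id,
         "', not on model allele '", model$allele_id, "'")
  }
  ev <- if (!is.null(lesion$events_all)) lesion$events_all else lesion$events
  if (is.null(ev)) ev <- empty_events()

  if (isTRUE(lesion$disrupts_acceptor)) {
    return(consequence_exon_skip(lesion$acceptor_exons, model))
  }
  if (isTRUE(lesion$disrupts_donor)) {
    return(consequence_intron_retention(lesion$donor_exons, model))
  }
  consequence_from_events(ev, model)
}

## residues encoded by the coding part of an exon
exon_coding_span <- function(model, exon_id) {
  row <- model$exons[model$exons$exon_id == exon_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("exon '", exon_id, "' not in model")
  c(max(row$start, model$cds_start_offset),
    min(row$end, model$cds_end_offset))
}

consequence_exon_skip <- function(exon_ids, model) {
  spans <- lapply(exon_ids, exon_coding_span, model = model)
  len <- sum(vapply(spans, function(s) s[2L] - s[1L], numeric(1)))
  if (len %% 3L == 0L) {
    res <- residues_of_span(model, spans[[1L]][1L], spans[[length(spans)]][2L])
    pep <- cds_seq(model)
    first <- res$first_residue - model$residue_offset
    last <- res$last_residue - model$residue_offset
    aa <- translate_nt(cds_seq(model))
    hg <- if (first == last) {
      sprintf("p.(%s%ddel)", aa3(substr(aa, first, first)), res$first_residue)
    } else {
      sprintf("p.(%s%d_%s%ddel)", aa3(substr(aa, first, first)),
              res$first_residue, aa3(substr(aa, last, last)), res$last_residue)
    }
    new_consequence("exon_skip", len %/% 3L, hg,
                    c(res$first_residue, res$last_residue), truncating = FALSE)
  } else {
    new_consequence("exon_skip", len %/% 3L + 1L, "p.(?fs)", NULL,
                    truncating = TRUE)
  }
}

consequence_intron_retention <- function(exon_ids, model) {
  ## intron following the first flagged donor exon
  exon_id <- exon_ids[1L]
  i <- which(model$exons$exon_id == exon_id)
  en <- model$exons$end[i]
  intron_end <- if (i < nrow(model$exons)) model$exons$start[i + 1L] else
    nchar(model$sequence)
  intron <- substr(model$sequence, en + 1L, intron_end)
  ilen <- nchar(intron)
  ## translate from the CDS start through the exon into the retained intron
  pos <- cds_positions(model)
  upstream <- pos[pos < en]
  lead <- paste(chars(model$sequence)[upstream + 1L], collapse = "")
  phase <- nchar(lead) %% 3L
  ext <- translate_nt(paste0(substring(lead, nchar(lead) - phase + 1L), intron))
  hit_stop <- grepl("*", ext, fixed = TRUE)
  if (!hit_stop && ilen %% 3L == 0L && phase == 0L) {
    res_before <- nchar(lead) %/% 3L + model$residue_offset
    aa <- translate_nt(cds_seq(model))
    hg <- sprintf("p.(%s%d_%s%dins%s)",
                  aa3(substr(aa, res_before - model$residue_offset,
                             res_before - model$residue_offset)), res_before,
                  aa3(substr(aa, res_before - model$residue_offset + 1L,
                             res_before - model$residue_offset + 1L)),
                  res_before + 1L, aa3(ext))
    new_consequence("intron_retention", ilen %/% 3L, hg, NULL,
                    truncating = FALSE)
  } else {
    new_consequence("intron_retention", ilen %/% 3L + 1L, "p.(?fs)", NULL,
                    truncating = TRUE)
  }
}

## rebuild the mutant CDS from events that fall inside coding sequence
mutant_cds <- function(events, model) {
  pos <- cds_positions(model)
  ref_cds <- chars(cds_seq(model))
  out <- ref_cds
  ins_after <- rep("", length(ref_cds) + 1L)   # insertions before CDS index i
  keep <- rep(TRUE, length(ref_cds))
  for (i in seq_len(nrow(events))) {
    p <- events$ref_start[i]
    d <- events$deleted[i]
    ins <- events$inserted[i]
    nd <- nchar(d)
    if (nd > 0L) {
      idx <- match(seq.int(p, p + nd - 1L), pos)
      keep[idx[!is.na(idx)]] <- FALSE
    }
    if (nchar(ins) > 0L) {
      at <- sum(pos < p) + 1L   # insert before this CDS index (1-based)
      if (nd > 0L) {
        idx <- match(seq.int(p, p + nd - 1L), pos)
        idx <- idx[!is.na(idx)]
        if (length(idx)) at <- min(idx)
      }
      ins_after[at] <- paste0(ins_after[at], ins)
    }
  }
  pieces <- character(0)
  for (i in seq_along(ref_cds)) {
    if (nzchar(ins_after[i])) pieces <- c(pieces, ins_after[i])
    if (keep[i]) pieces <- c(pieces, ref_cds[i])
  }
  if (nzchar(ins_after[length(ref_cds) + 1L])) {
    pieces <- c(pieces, ins_after[length(ref_cds) + 1L])
  }
  paste(pieces, collapse = "")
}

consequence_from_events <- function(events, model) {
  pos <- cds_positions(model)
  ## restrict to events touching the CDS (intronic non-splice events are
  ## silent at the protein level)
  touches <- vapply(seq_len(nrow(events)), function(i) {
    p <- events$ref_start[i]
    nd <- nchar(events$deleted[i])
    if (nd > 0L) any(seq.int(p, p + nd - 1L) %in% pos) else
      p > min(pos) && p <= max(pos)
  }, logical(1))
  events <- events[touches, , drop = FALSE]

  ref_cds <- cds_seq(model)
  if (nrow(events) == 0L) {
    return(new_consequence("wildtype", 0L, "p.(=)", NULL, truncating = FALSE))
  }
  alt_cds <- mutant_cds(events, model)
  net <- nchar(alt_cds) - nchar(ref_cds)
  ref_pep <- translate_nt(ref_cds)
  alt_pep <- translate_nt(alt_cds)
  off <- model$residue_offset

  if (net %% 3L != 0L) {
    return(frameshift_consequence(ref_pep, alt_pep, off))
  }

  ## maximal common prefix, then maximal common suffix (3'-most description)
  rp <- chars(ref_pep); ap <- chars(alt_pep)
  npre <- common_prefix(rp, ap)
  nsuf <- common_suffix(rp[seq_len(length(rp)) > npre],
                        ap[seq_len(length(ap)) > npre])
  ref_mid <- rp[seq.int(npre + 1L, length(rp) - nsuf, length.out = max(0L, length(rp) - nsuf - npre))]
  alt_mid <- ap[seq.int(npre + 1L, length(ap) - nsuf, length.out = max(0L, length(ap) - nsuf - npre))]

  if (length(ref_mid) == 0L && length(alt_mid) == 0L) {
    return(new_consequence("synonymous", 0L, "p.(=)", NULL, truncating = FALSE))
  }
  if (any(alt_mid == "*")) {
    k <- which(alt_mid == "*")[1L]
    res <- npre + k + off
    ref_at <- if (npre + k <= length(rp)) rp[npre + k] else "X"
    return(new_consequence("nonsense", length(rp) - npre - k + 1L,
                           sprintf("p.(%s%dTer)", aa3(ref_at), res),
                           res, truncating = TRUE))
  }
  first <- npre + 1L + off
  last <- length(rp) - nsuf + off
  if (length(alt_mid) == 0L) {
    hg <- if (length(ref_mid) == 1L) {
      sprintf("p.(%s%ddel)", aa3(ref_mid), first)
    } else {
      sprintf("p.(%s%d_%s%ddel)", aa3(ref_mid[1L]), first,
              aa3(ref_mid[length(ref_mid)]), last)
    }
    return(new_consequence("inframe_deletion", length(ref_mid), hg,
                           c(first, last), truncating = FALSE))
  }
  if (length(ref_mid) == 0L) {
    ## insertion between the flanking residues npre and npre+1
    a <- npre + off; b <- a + 1L
    hg <- sprintf("p.(%s%d_%s%dins%s)",
                  aa3(rp[npre]), a, aa3(rp[npre + 1L]), b,
                  aa3(paste(alt_mid, collapse = "")))
    return(new_consequence("inframe_insertion", length(alt_mid), hg,
                           c(a, b), truncating = FALSE))
  }
  if (length(ref_mid) == length(alt_mid)) {
    ndiff <- sum(ref_mid != alt_mid)
    if (length(ref_mid) == 1L) {
      hg <- sprintf("p.(%s%d%s)", aa3(ref_mid), first, aa3(alt_mid))
      return(new_consequence("missense", 1L, hg, first, truncating = FALSE))
    }
    hg <- sprintf("p.(%s%d_%s%ddelins%s)", aa3(ref_mid[1L]), first,
                  aa3(ref_mid[length(ref_mid)]), last,
                  aa3(paste(alt_mid, collapse = "")))
    return(new_consequence("missense", ndiff, hg, c(first, last),
                           truncating = FALSE))
  }
  hg <- sprintf("p.(%s%d_%s%ddelins%s)", aa3(ref_mid[1L]), first,
                aa3(ref_mid[length(ref_mid)]), last,
                aa3(paste(alt_mid, collapse = "")))
  new_consequence("inframe_delins", max(length(ref_mid), length(alt_mid)),
                  hg, c(first, last), truncating = FALSE)
}

frameshift_consequence <- function(ref_pep, alt_pep, off) {
  rp <- chars(ref_pep); ap <- chars(alt_pep)
  npre <- common_prefix(rp, ap)
  pos <- npre + 1L
  ref_at <- if (pos <= length(rp)) rp[pos] else "X"
  alt_at <- if (pos <= length(ap)) ap[pos] else "X"
  if (alt_at == "*") {
    return(new_consequence("nonsense", length(rp) - npre,
                           sprintf("p.(%s%dTer)", aa3(ref_at), pos + off),
                           pos + off, truncating = TRUE))
  }
  stop_at <- which(ap[seq_along(ap) >= pos] == "*")
  term <- if (length(stop_at)) sprintf("*%d", stop_at[1L]) else "*?"
  new_consequence("frameshift", length(rp) - npre,
                  sprintf("p.(%s%d%sfs%s)", aa3(ref_at), pos + off,
                          aa3(alt_at), term),
                  pos + off, truncating = TRUE)
}

common_prefix <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

common_suffix <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(rev(a)[seq_len(n)] != rev(b)[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

new_consequence <- function(kind, aa_changes, hgvs_p, affected_residues,
                            truncating) {
  structure(list(kind = kind, aa_changes = as.integer(aa_changes),
                 hgvs_p = hgvs_p, affected_residues = affected_residues,
                 truncating = truncating),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence>", x$kind, x$hgvs_p, "|", x$aa_changes,
      "aa change(s)", if (x$truncating) "| truncating" else "", "\n")
  invisible(x)
}

#' HGVS-style protein name of a consequence
#'
#' Returns the 3'-normalized `p.()` notation of an annotated consequence, or
#' annotates a lesion first when given one together with its model.
#'
#' @param x A `protein_consequence` or a `dna_lesion`.
#' @param model Required when `x` is a lesion.
#' @return HGVS protein notation string, e.g. `"p.(Arg272del)"`.
#' @export
hgvs_name <- function(x, model = NULL) {
  if (inherits(x, "dna_lesion")) {
    if (is.null(model)) stop("model required to annotate a lesion")
    x <- annotate_consequence(x, model)
  }
  stopifnot(inherits(x, "protein_consequence"))
  x$hgvs_p
}

#' Assign the genotype score code of a protein consequence
#'
#' Six-level code grading each allele by the size of the encoded amino-acid
#' lesion: 01 inactive (frameshift-stop or nonsense, including truncating
#' splice outcomes), 02 in-frame with more than 20 amino-acid changes, 03
#' with 11-20, 04 with 6-10, 05 with 1-5, 06 normal amino-acid sequence.
#' A lesion combining a frameshifting event with others scores 01.
#'
#' @param consequence A `protein_consequence`.
#' @return Object of class `genotype_score` (integer code 1-6, published as
#'   `"01"`..`"06"`).
#' @export
assign_score <- function(consequence) {
  stopifnot(inherits(consequence, "protein_consequence"))
  code <- if (consequence$kind %in% c("frameshift", "nonsense") ||
              isTRUE(consequence$truncating)) {
    1L
  } else {
    aa <- consequence$aa_changes
    if (aa == 0L) 6L
    else if (aa <= 5L) 5L
    else if (aa <= 10L) 4L
    else if (aa <= 20L) 3L
    else 2L
  }
  structure(code, class = "genotype_score")
}

#' @export
print.genotype_score <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.genotype_score <- function(x, ...) sprintf("%02d", unclass(x))
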