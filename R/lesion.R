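#' Construct an amplicon read
#'
#' @param read_id Read identifier.
#' @param sequence Read sequence over A/C/G/T/N.
#' @param qualities Optional quality string (FASTQ).
#' @param source `"sanger_clone"` (full-length plasmid clone insert) or
#'   `"ngs"` (short read).
#' @param orientation `"forward"`, `"reverse"` or `"unknown"` (resolved by
#'   alignment).
#' @return Object of class `amplicon_read`.
#' @export
amplicon_read <- function(read_id, sequence, qualities = NULL,
                          source = c("sanger_clone", "ngs"),
                          orientation = c("unknown", "forward", "reverse")) {
  source <- match.arg(source)
  orientation <- match.arg(orientation)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence) || grepl("[^ACGTN]", sequence)) {
    stop("read sequence must be non-empty over A/C/G/T/N")
  }
  structure(list(read_id = read_id, sequence = sequence, qualities = qualities,
                 source = source, orientation = orientation),
            class = "amplicon_read")
}

#' Read amplicon reads from FASTA or FASTQ
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` (Sanger clone inserts) or `"fastq"` (NGS reads).
#' @return List of [amplicon_read()] objects.
#' @export
read_amplicon_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  src <- if (format == "fasta") "sanger_clone" else "ngs"
  ss <- Biostrings::readDNAStringSet(path, format = format,
                                     with.qualities = (format == "fastq"))
  ids <- sub("\\s.*$", "", names(ss))
  quals <- if (format == "fastq") as.character(S4Vectors::mcols(ss)$qualities) else NULL
  lapply(seq_along(ss), function(i) {
    amplicon_read(ids[i], as.character(ss[[i]]),
                  qualities = if (!is.null(quals)) quals[i] else NULL,
                  source = src)
  })
}

## ---- lesion events -------------------------------------------------------

## empty event table
empty_events <- function() {
  data.frame(ref_start = integer(), deleted = character(),
             inserted = character(), stringsAsFactors = FALSE)
}

## extract raw (unnormalized) events from an alignment: mismatch runs become
## substitutions, gap runs become indels; adjacent deletion+insertion runs
## merge into one delins event
extract_events <- function(aln) {
  ops <- aln$ops
  rd <- chars(aln$oriented_read)
  rows <- list()
  for (k in seq_len(nrow(ops))) {
    o <- ops[k, ]
    if (o$op == "match") next
    del <- ""
    ins <- ""
    if (o$op %in% c("mismatch", "deletion")) {
      del <- substr_ref(aln, o$ref_pos, o$ref_pos + o$length)
    }
    if (o$op %in% c("mismatch", "insertion")) {
      ins <- paste(rd[(o$read_pos + 1L):(o$read_pos + o$length)], collapse = "")
    }
    rows[[length(rows) + 1L]] <- data.frame(ref_start = o$ref_pos, deleted = del,
                                            inserted = ins, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_events())
  ev <- do.call(rbind, rows)
  ## merge adjacent del+ins (either order) into a single delins event
  merged <- list()
  i <- 1L
  while (i <= nrow(ev)) {
    cur <- ev[i, ]
    if (i < nrow(ev)) {
      nxt <- ev[i + 1L, ]
      cur_end <- cur$ref_start + nchar(cur$deleted)
      if (nxt$ref_start == cur_end &&
          ((nchar(cur$deleted) > 0L && nchar(nxt$inserted) > 0L && nchar(nxt$deleted) == 0L) ||
           (nchar(cur$inserted) > 0L && nchar(cur$deleted) == 0L && nchar(nxt$deleted) > 0L))) {
        cur <- data.frame(ref_start = cur$ref_start,
                          deleted = paste0(cur$deleted, nxt$deleted),
                          inserted = paste0(cur$inserted, nxt$inserted),
                          stringsAsFactors = FALSE)
        i <- i + 1L
      }
    }
    merged[[length(merged) + 1L]] <- cur
    i <- i + 1L
  }
  do.call(rbind, merged)
}

## reference substring helper on an allele_alignment (0-based half-open)
substr_ref <- function(aln, from, to) {
  substr(attr(aln, "ref_seq"), from + 1L, to)
}

#' Right-align (3'-shift) lesion events within repeats
#'
#' Pure deletions and pure insertions are shifted as far 3' as the flanking
#' repeat structure allows, matching HGVS convention, so that a deletion
#' inside a repeat run is named identically regardless of which repeat copy
#' was physically removed. Substitutions and delins events are not shifted.
#' The operation is idempotent.
#'
#' @param events data.frame with columns `ref_start` (0-based), `deleted`,
#'   `inserted`.
#' @param ref Reference sequence string the positions refer to.
#' @return The normalized, sorted event table.
#' @export
normalize_events <- function(events, ref) {
  if (nrow(events) == 0L) return(events)
  rf <- chars(toupper(ref))
  L <- length(rf)
  for (i in seq_len(nrow(events))) {
    p <- events$ref_start[i]
    d <- events$deleted[i]
    ins <- events$inserted[i]
    nd <- nchar(d)
    if (nd > 0L && nchar(ins) == 0L) {
      while (p + nd < L && rf[p + 1L] == rf[p + nd + 1L]) p <- p + 1L
      events$ref_start[i] <- p
      events$deleted[i] <- paste(rf[(p + 1L):(p + nd)], collapse = "")
    } else if (nd == 0L && nchar(ins) > 0L) {
      s <- chars(ins)
      while (p < L && rf[p + 1L] == s[1L]) {
        s <- c(s[-1L], s[1L])
        p <- p + 1L
      }
      events$ref_start[i] <- p
      events$inserted[i] <- paste(s, collapse = "")
    }
  }
  events <- events[order(events$ref_start), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Realized sequence of a window under a set of events
#'
#' Applies normalized, non-overlapping events to the reference and returns
#' the sequence occupying the window: deleted reference bases are dropped,
#' insertions strictly inside the window (and the inserted part of delins
#' events starting in-window) are emitted in place.
#'
#' @param events Normalized event table (`ref_start`, `deleted`, `inserted`).
#' @param ref Reference sequence string.
#' @param window 0-based half-open interval.
#' @return The realized window sequence.
#' @export
realize_window <- function(events, ref, window) {
  rf <- chars(toupper(ref))
  deleted <- rep(FALSE, length(rf))
  ins_at <- list()
  for (i in seq_len(nrow(events))) {
    p <- events$ref_start[i]
    nd <- nchar(events$deleted[i])
    ins <- events$inserted[i]
    if (nd > 0L) deleted[(p + 1L):(p + nd)] <- TRUE
    if (nzchar(ins)) {
      key <- as.character(p)
      ins_at[[key]] <- paste0(if (is.null(ins_at[[key]])) "" else ins_at[[key]], ins)
    }
  }
  out <- character(0)
  for (p in seq.int(window[1L], window[2L] - 1L)) {
    key <- as.character(p)
    if (!is.null(ins_at[[key]])) {
      nd_here <- any(events$ref_start == p & nchar(events$deleted) > 0L)
      ## pure insertions at the window start boundary are outside the window
      if (p > window[1L] || nd_here) out <- c(out, chars(ins_at[[key]]))
    }
    if (!deleted[p + 1L]) out <- c(out, rf[p + 1L])
  }
  paste(out, collapse = "")
}

## which events intersect a window (0-based half-open)? Deletions and
## substitutions by interval overlap; insertions count when their inter-base
## position lies strictly inside the window.
events_in_window <- function(events, window) {
  if (nrow(events) == 0L) return(logical(0))
  nd <- nchar(events$deleted)
  ifelse(nd > 0L,
         events$ref_start < window[2L] & (events$ref_start + nd) > window[1L],
         events$ref_start > window[1L] & events$ref_start < window[2L])
}

#' Call the DNA lesion of an aligned read within a variant window
#'
#' Extracts the read's differences from the reference, right-normalizes
#' indels, intersects them with the PAM-anchored variant window, and flags
#' disrupted splice dinucleotides (the two intron bases adjacent to each
#' annotated exon). Reads that do not span the full window, or that carry N
#' bases inside it, are marked uninformative.
#'
#' @param aln An [align_read()] result. The reference sequence is taken from
#'   `model`.
#' @param window Integer vector `c(start, end)`, 0-based half-open reference
#'   interval of the variant window.
#' @param model The [gene_model()] the read was aligned to.
#' @return Object of class `dna_lesion`: normalized `events` inside the
#'   window, `events_all` (every event on the read), `net_indel`,
#'   `window_covered`, `window_seq` (realized read sequence across the
#'   window), `informative`, and splice-disruption flags with affected exon
#'   ids.
#' @export
call_lesion <- function(aln, window, model) {
  stopifnot(inherits(aln, "allele_alignment"), inherits(model, "gene_model"))
  window <- as.integer(window)
  L <- nchar(model$sequence)
  if (window[1L] < 0L || window[2L] > L || window[1L] >= window[2L]) {
    stop("window [", window[1L], ", ", window[2L],
         ") outside reference of length ", L)
  }
  attr(aln, "ref_seq") <- model$sequence
  ev <- normalize_events(extract_events(aln), model$sequence)
  inw <- events_in_window(ev, window)
  window_covered <- aln$ref_start <= window[1L] && aln$ref_end >= window[2L]

  ## realized window sequence from the normalized events (placement-stable);
  ## N detection separately from the raw aligned columns, since N bases are
  ## alignment-neutral and never enter the event list
  wseq <- NA_character_
  has_n <- FALSE
  if (window_covered) {
    wseq <- realize_window(ev[inw, , drop = FALSE], model$sequence, window)
    rd <- chars(aln$oriented_read)
    for (k in seq_len(nrow(aln$ops))) {
      o <- aln$ops[k, ]
      if (o$op %in% c("match", "mismatch")) {
        refs <- o$ref_pos + seq_len(o$length) - 1L
        keep <- refs >= window[1L] & refs < window[2L]
        if (any(keep) && any(rd[o$read_pos + which(keep)] == "N")) has_n <- TRUE
      }
    }
  }

  ## splice dinucleotides flanking each annotated exon
  acceptor_exons <- character(0)
  donor_exons <- character(0)
  if (nrow(ev) > 0L) {
    del_iv <- cbind(ev$ref_start, ev$ref_start + nchar(ev$deleted))
    hit <- function(a, b) any(del_iv[, 1L] < b & del_iv[, 2L] > a &
                                nchar(ev$deleted) > 0L)
    for (i in seq_len(nrow(model$exons))) {
      st <- model$exons$start[i]; en <- model$exons$end[i]
      id <- as.character(model$exons$exon_id[i])
      if (st >= 2L && hit(st - 2L, st)) acceptor_exons <- c(acceptor_exons, id)
      if (en + 2L <= L && hit(en, en + 2L)) donor_exons <- c(donor_exons, id)
    }
  }

  informative <- window_covered && !is.na(wseq) && !has_n &&
    !grepl("N", wseq, fixed = TRUE)
  structure(
    list(allele_id = model$allele_id, read_id = aln$read_id,
         orientation = aln$orientation,
         events = ev[inw, , drop = FALSE],
         events_all = ev,
         net_indel = sum(nchar(ev$inserted[inw])) - sum(nchar(ev$deleted[inw])),
         window = window, window_covered = window_covered,
         window_seq = wseq, informative = informative,
         disrupts_acceptor = length(acceptor_exons) > 0L,
         disrupts_donor = length(donor_exons) > 0L,
         acceptor_exons = acceptor_exons, donor_exons = donor_exons),
    class = "dna_lesion")
}

#' @export
print.dna_lesion <- function(x, ...) {
  cat("<dna_lesion>", if (!is.null(x$read_id)) x$read_id else "", "on",
      x$allele_id, "|", nrow(x$events), "in-window event(s), net",
      x$net_indel, "bp |",
      if (x$informative) "informative" else "uninformative", "\n")
  invisible(x)
}

#' Wild-type read test on the window peptide
#'
#' A read is wild type iff its realized variant-window sequence, translated
#' in the model's frame, equals the reference window peptide. Synonymous
#' substitutions inside the window therefore count as wild type — a
#' documented consequence of the peptide-level definition. The window must
#' be codon-aligned under the model's frame.
#'
#' @param lesion A [call_lesion()] result.
#' @param model The [gene_model()].
#' @param window Optional window override (defaults to the lesion's window).
#' @return TRUE/FALSE, or NA for uninformative reads (window not spanned, or
#'   N bases inside it).
#' @export
is_wildtype_read <- function(lesion, model, window = lesion$window) {
  stopifnot(inherits(lesion, "dna_lesion"))
  ref_pep <- window_peptide(model, window)
  if (!lesion$informative) return(NA)
  ws <- lesion$window_seq
  if (nchar(ws) %% 3L != 0L) return(FALSE)
  translate_nt(ws) == ref_pep
}

#' Reference peptide of a codon-aligned window
#'
#' @param model A [gene_model()].
#' @param window 0-based half-open genomic interval; must cover whole codons
#'   of the model's CDS.
#' @return Peptide string.
#' @export
window_peptide <- function(model, window) {
  cm <- codon_map(model)
  idx <- match(seq.int(window[1L], window[2L] - 1L), cm$genomic_pos)
  if (anyNA(idx)) stop("window is not fully within the coding sequence")
  if (cm$codon_offset[idx[1L]] != 0L ||
      cm$codon_offset[idx[length(idx)]] != 2L) {
    stop("window [", window[1L], ", ", window[2L],
         ") is not codon-aligned under the model's frame")
  }
  translate_nt(substr(model$sequence, window[1L] + 1L, window[2L]))
}

#' Snap a genomic window to codon boundaries
#'
#' Expands a window outwards to the nearest codon boundaries of the model's
#' frame and records the snap applied.
#'
#' @param model A [gene_model()].
#' @param window 0-based half-open interval.
#' @return Integer window with attribute `snapped` (bases added left/right).
#' @export
snap_window_to_codons <- function(model, window) {
  cm <- codon_map(model)
  i1 <- match(window[1L], cm$genomic_pos)
  i2 <- match(window[2L] - 1L, cm$genomic_pos)
  if (is.na(i1) || is.na(i2)) stop("window is not within the coding sequence")
  left <- cm$codon_offset[i1]
  right <- 2L - cm$codon_offset[i2]
  out <- c(cm$genomic_pos[i1 - left], cm$genomic_pos[i2 + right] + 1L)
  attr(out, "snapped") <- c(left = left, right = right)
  out
}

## ---- allele assignment and orientation -----------------------------------

#' Assign a read to the best-matching homeologous allele
#'
#' The read is aligned to every model (both orientations) and assigned to
#' the allele with the higher score. On near-ties (score difference at or
#' below `tie_threshold`, one mismatch by default) the assignment falls back
#' to sequence identity over the 5'-terminal `k5` bases of the oriented read
#' — the rule used to split PCR-chimeric clones by their 5' homeolog
#' identity. Unresolvable reads return `"ambiguous"`.
#'
#' @param read An [amplicon_read()] or sequence string.
#' @param models List of [gene_model()] objects.
#' @param type Alignment type passed to [align_read()].
#' @param tie_threshold Score difference at or below which the 5' rule is
#'   used (default 4 = one mismatch under the default scores).
#' @param k5 Number of 5'-terminal bases compared by the fallback rule.
#' @return Allele id (character), possibly `"ambiguous"`, with the per-model
#'   alignment scores as attribute `scores`.
#' @export
assign_allele <- function(read, models, type = c("global", "fitting"),
                          tie_threshold = 4, k5 = 40L) {
  type <- match.arg(type)
  if (length(models) < 1L) stop("need at least one gene model")
  alns <- lapply(models, function(m) align_read(read, m, type = type))
  assign_from_alignments(alns, models, tie_threshold = tie_threshold, k5 = k5)
}

## shared assignment rule given precomputed alignments (one per model)
assign_from_alignments <- function(alns, models, tie_threshold = 4, k5 = 40L) {
  scores <- vapply(alns, `[[`, numeric(1), "score")
  ids <- vapply(models, `[[`, character(1), "allele_id")
  names(scores) <- ids
  ord <- order(scores, decreasing = TRUE)
  out <- ids[ord[1L]]
  if (length(scores) > 1L && scores[ord[1L]] - scores[ord[2L]] <= tie_threshold) {
    oriented <- alns[[ord[1L]]]$oriented_read
    prefix <- chars(substr(oriented, 1L, k5))
    d5 <- vapply(models, function(m) {
      refp <- chars(substr(m$sequence, 1L, k5))
      n <- min(length(prefix), length(refp))
      sum(prefix[seq_len(n)] != refp[seq_len(n)]) +
        abs(length(prefix) - length(refp))
    }, numeric(1))
    best <- which(d5 == min(d5))
    out <- if (length(best) == 1L) ids[best] else "ambiguous"
  }
  structure(out, scores = scores)
}

#' Filter reads by mapped orientation
#'
#' Retains reads whose alignment orientation matches `keep`; the number
#' discarded is reported via `message()` and attached as an attribute.
#'
#' @param reads List of [amplicon_read()] objects (with orientation
#'   resolved), or a data.frame with an `orientation` column.
#' @param keep `"forward"`, `"reverse"` or `"both"`.
#' @return The retained subset, with attribute `n_discarded`.
#' @export
orientation_filter <- function(reads, keep = c("both", "forward", "reverse")) {
  keep <- match.arg(keep)
  ori <- if (is.data.frame(reads)) reads$orientation else
    vapply(reads, `[[`, character(1), "orientation")
  sel <- if (keep == "both") rep(TRUE, length(ori)) else ori == keep
  n_disc <- sum(!sel)
  if (n_disc > 0L) message(n_disc, " read(s) discarded by orientation filter")
  out <- if (is.data.frame(reads)) reads[sel, , drop = FALSE] else reads[sel]
  attr(out, "n_discarded") <- n_disc
  out
}

## events -> compact 1-based VCF-like string "POS:REF>ALT" joined by ";"
events_to_string <- function(events) {
  if (nrow(events) == 0L) return("")
  paste(sprintf("%d:%s>%s", events$ref_start + 1L,
                ifelse(nchar(events$deleted) > 0L, events$deleted, "-"),
                ifelse(nchar(events$inserted) > 0L, events$inserted, "-")),
        collapse = ";")
}
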