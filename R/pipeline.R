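#' Genotype a set of amplicon reads against homeologous references
#'
#' The full per-read pipeline: align each read to every reference allele
#' (both orientations), assign the read to its homeolog (near-ties resolved
#' by 5'-terminal identity), call and normalize the DNA lesion within the
#' variant window, test the wild-type window-peptide definition, annotate
#' the protein consequence and assign the genotype score.
#'
#' @param reads List of [amplicon_read()] objects (or plain sequences).
#' @param models Named list of [gene_model()] objects.
#' @param window 0-based half-open variant window (on every model's shared
#'   coordinates), e.g. `attr(synthetic_locus_pair(), "window")`.
#' @param type `"global"` for full-length Sanger clone inserts, `"fitting"`
#'   for shorter NGS reads; `"auto"` picks by the read's declared source.
#' @param keep_orientation Orientation filter applied after alignment
#'   (`"both"`, `"forward"`, `"reverse"`).
#' @param tie_threshold,k5 Passed to the allele-assignment rule.
#' @return data.frame with one row per retained read: `read_id`, `allele`,
#'   `orientation`, `score` (alignment), `window_covered`, `informative`,
#'   `window_seq`, `events` (1-based POS:REF>ALT, in-window), `events_all`,
#'   `net_indel`, `wildtype`, `kind`, `hgvs_p`, `aa_changes`, `score_code`.
#' @export
genotype_reads <- function(reads, models, window,
                           type = c("auto", "global", "fitting"),
                           keep_orientation = "both",
                           tie_threshold = 4, k5 = 40L) {
  type <- match.arg(type)
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "allele_id")
  }
  cache <- new.env(parent = emptyenv())   # identical clone sequences recur
  rows <- vector("list", length(reads))
  for (r in seq_along(reads)) {
    rd <- reads[[r]]
    if (!inherits(rd, "amplicon_read")) {
      rd <- amplicon_read(paste0("read", r), as.character(rd))
    }
    use_type <- if (type == "auto") {
      if (identical(rd$source, "ngs")) "fitting" else "global"
    } else type
    alns <- lapply(models, function(m) {
      key <- paste0(m$allele_id, "\r", use_type, "\r", rd$sequence)
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- align_read(list(read_id = NULL, sequence = rd$sequence), m,
                          type = use_type)
        cache[[key]] <- hit
      }
      hit$read_id <- rd$read_id
      hit
    })
    assignment <- assign_from_alignments(alns, models,
                                         tie_threshold = tie_threshold, k5 = k5)
    allele <- as.character(assignment)
    if (allele == "ambiguous") {
      rows[[r]] <- data.frame(
        read_id = rd$read_id, allele = "ambiguous",
        orientation = alns[[1L]]$orientation, score = max(attr(assignment, "scores")),
        window_covered = NA, informative = FALSE, window_seq = NA_character_,
        events = NA_character_, events_all = NA_character_,
        net_indel = NA_integer_, wildtype = NA,
        kind = NA_character_, hgvs_p = NA_character_,
        aa_changes = NA_integer_, score_code = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    aln <- alns[[allele]]
    model <- models[[allele]]
    lesion <- call_lesion(aln, window, model)
    wt <- is_wildtype_read(lesion, model)
    if (lesion$informative) {
      cons <- annotate_consequence(lesion, model)
      code <- as.integer(assign_score(cons))
      kind <- cons$kind; hg <- cons$hgvs_p; aa <- cons$aa_changes
    } else {
      kind <- NA_character_; hg <- NA_character_
      aa <- NA_integer_; code <- NA_integer_
    }
    rows[[r]] <- data.frame(
      read_id = rd$read_id, allele = allele, orientation = aln$orientation,
      score = aln$score, window_covered = lesion$window_covered,
      informative = lesion$informative, window_seq = lesion$window_seq,
      events = events_to_string(lesion$events),
      events_all = events_to_string(lesion$events_all),
      net_indel = lesion$net_indel, wildtype = wt,
      kind = kind, hgvs_p = hg, aa_changes = aa, score_code = code,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  orientation_filter(out, keep_orientation)
}

#' Write per-read genotype calls as TSV
#'
#' @param calls [genotype_reads()] output.
#' @param path Output path.
#' @return `calls`, invisibly.
#' @export
write_read_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Genotype a simulated cohort end to end
#'
#' Convenience wrapper running [genotype_reads()] per embryo of a
#' [simulate_cohort()] result and summarizing each embryo.
#'
#' @param sim A [simulate_cohort()] result.
#' @param keep_orientation Orientation filter for the per-read stage.
#' @return List with `calls` (per-embryo list of call tables) and `cohort`
#'   (list of [summarize_embryo()] records).
#' @export
genotype_cohort <- function(sim, keep_orientation = "both") {
  models <- sim$models
  window <- sim$window
  calls <- lapply(sim$embryos, function(e) {
    genotype_reads(e$reads, models, window, keep_orientation = keep_orientation)
  })
  cohort <- lapply(seq_along(sim$embryos), function(i) {
    summarize_embryo(calls[[i]], sim$embryos[[i]]$embryo_id,
                     sim$embryos[[i]]$phenotype)
  })
  list(calls = calls, cohort = cohort)
}
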