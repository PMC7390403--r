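#' Summarize one embryo's mosaic allele spectrum
#'
#' Groups an embryo's informative per-read calls into distinct alleles by
#' exact in-window sequence identity (so different repair junctions with
#' identical products merge), tallies genotype scores, and records whether
#' any read is wild type.
#'
#' @param calls data.frame of per-read annotations (as returned by
#'   [genotype_reads()]) for a single embryo: must contain columns `allele`,
#'   `window_seq`, `informative`, `wildtype`, `score_code`.
#' @param embryo_id Embryo identifier.
#' @param phenotype One of `"inert_ventricle"`, `"thin_wall_ventricle"`,
#'   `"other_malformation"`, `"normal"`.
#' @return Object of class `embryo_record`: allele table (locus, window
#'   sequence, count, score), `distinct_sequences`, `wildtype_present`,
#'   `score_tally` (named count vector over codes 1-6).
#' @export
summarize_embryo <- function(calls, embryo_id, phenotype) {
  phenotype <- match.arg(phenotype, phenotype_levels())
  calls <- calls[!is.na(calls$informative) & calls$informative, , drop = FALSE]
  if (nrow(calls) == 0L) {
    stop("embryo '", embryo_id, "' has no informative calls")
  }
  key <- paste(calls$allele, calls$window_seq, sep = "|")
  grp <- split(seq_len(nrow(calls)), key)
  alleles <- do.call(rbind, lapply(grp, function(idx) {
    sc <- calls$score_code[idx]
    modal <- as.integer(names(sort(table(sc), decreasing = TRUE))[1L])
    data.frame(locus = calls$allele[idx[1L]],
               window_seq = calls$window_seq[idx[1L]],
               count = length(idx),
               score = modal,
               mixed_scores = length(unique(sc)) > 1L,
               wildtype = isTRUE(calls$wildtype[idx[1L]]),
               stringsAsFactors = FALSE)
  }))
  alleles <- alleles[order(alleles$locus, -alleles$count), , drop = FALSE]
  rownames(alleles) <- NULL
  ## scores are tallied per read: window-identity groups can pool reads
  ## whose lesions extend differently beyond the window (large deletions
  ## that erase it entirely), so a single group score would misattribute
  tally <- vapply(1:6, function(code) sum(calls$score_code == code, na.rm = TRUE),
                  integer(1))
  names(tally) <- sprintf("%02d", 1:6)
  structure(list(embryo_id = embryo_id, phenotype = phenotype,
                 alleles = alleles,
                 n_informative = nrow(calls),
                 distinct_sequences = nrow(alleles),
                 wildtype_present = any(alleles$wildtype),
                 score_tally = tally),
            class = "embryo_record")
}

phenotype_levels <- function() {
  c("inert_ventricle", "thin_wall_ventricle", "other_malformation", "normal")
}

#' @export
print.embryo_record <- function(x, ...) {
  cat("<embryo_record>", x$embryo_id, "|", x$phenotype, "|",
      x$n_informative, "reads,", x$distinct_sequences, "distinct allele(s) |",
      if (x$wildtype_present) "WT present" else "no WT", "\n")
  invisible(x)
}

#' Genotype-score frequencies for a cohort
#'
#' Per-code counts and proportions of sequenced alleles (weighted by read
#' count), overall and split into the two phenotype groups used throughout:
#' heart defects (inert ventricle, thin-walled ventricle, other
#' malformations) versus normal morphology. Proportions in every table sum
#' to 1.
#'
#' @param cohort List of [summarize_embryo()] records.
#' @return Object of class `cohort_summary`: `overall`, `defect`, `normal`
#'   frequency tables and the per-embryo phenotype dichotomy.
#' @export
score_frequencies <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  phen <- vapply(cohort, `[[`, character(1), "phenotype")
  bad <- setdiff(phen, phenotype_levels())
  if (length(bad)) stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  groups <- list(overall = seq_along(cohort),
                 defect = which(phen != "normal"),
                 normal = which(phen == "normal"))
  tabs <- lapply(groups, function(idx) {
    if (length(idx) == 0L) return(NULL)
    counts <- Reduce(`+`, lapply(cohort[idx], `[[`, "score_tally"))
    data.frame(score = sprintf("%02d", 1:6), count = as.integer(counts),
               proportion = as.numeric(counts) / sum(counts),
               stringsAsFactors = FALSE)
  })
  structure(list(overall = tabs$overall, defect = tabs$defect,
                 normal = tabs$normal,
                 phenotypes = data.frame(
                   embryo_id = vapply(cohort, `[[`, character(1), "embryo_id"),
                   phenotype = phen,
                   group = ifelse(phen == "normal", "normal", "defect"),
                   stringsAsFactors = FALSE)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", nrow(x$phenotypes), "embryo(s);",
      sum(x$phenotypes$group == "defect"), "defect /",
      sum(x$phenotypes$group == "normal"), "normal\n")
  print(x$overall)
  invisible(x)
}

#' Exact one-sided test of wild-type presence vs phenotype
#'
#' Builds the 2x2 contingency table of wild-type-allele presence against the
#' phenotype dichotomy (defect vs normal) and computes the one-sided exact
#' p-value by direct hypergeometric enumeration of tables at least as
#' favourable to wild-type enrichment in the normal group (no asymptotic
#' approximation). Odds ratios with a zero cell are flagged degenerate
#' rather than reported as infinite.
#'
#' @param cohort List of [summarize_embryo()] records containing both
#'   phenotype groups.
#' @return Object of class `wt_association`: `table` (2x2), `odds_ratio`,
#'   `degenerate`, `p_value`, `alternative`.
#' @export
wildtype_phenotype_association <- function(cohort) {
  phen <- vapply(cohort, `[[`, character(1), "phenotype")
  wt <- vapply(cohort, `[[`, logical(1), "wildtype_present")
  normal <- phen == "normal"
  if (all(normal) || !any(normal)) {
    stop("association test needs both phenotype groups in the cohort")
  }
  tab <- matrix(c(sum(wt & normal), sum(!wt & normal),
                  sum(wt & !normal), sum(!wt & !normal)),
                nrow = 2L,
                dimnames = list(wildtype = c("present", "absent"),
                                phenotype = c("normal", "defect")))
  a <- tab[1L, 1L]
  m <- sum(tab[1L, ])   # wild-type-present embryos
  n <- sum(tab[2L, ])   # wild-type-absent embryos
  k <- sum(tab[, 1L])   # normal embryos
  ## one-sided: wild-type presence enriched among normal hearts
  p <- sum(stats::dhyper(seq.int(a, min(m, k)), m, n, k))
  degenerate <- any(tab == 0L)
  or <- if (degenerate) NA_real_ else
    (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  structure(list(table = tab, odds_ratio = or, degenerate = degenerate,
                 p_value = min(1, p),
                 alternative = "wild-type presence enriched in normal group"),
            class = "wt_association")
}

#' @export
print.wt_association <- function(x, ...) {
  print(x$table)
  cat(sprintf("one-sided exact p = %.4g; odds ratio %s\n", x$p_value,
              if (x$degenerate) "degenerate (zero cell)" else
                format(x$odds_ratio, digits = 4)))
  invisible(x)
}

#' Exact one-sided hypergeometric p for a 2x2 table
#'
#' Lower-level helper used by [wildtype_phenotype_association()]: the
#' probability, under fixed margins, of a count in cell (1,1) at least as
#' large as observed.
#'
#' @param tab 2x2 integer matrix.
#' @return One-sided exact p-value.
#' @export
exact_one_sided_p <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  a <- tab[1L, 1L]
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  min(1, sum(stats::dhyper(seq.int(a, min(m, k)), m, n, k)))
}

#' Write a cohort report
#'
#' JSON report with per-embryo records, score-frequency tables and the
#' wild-type association test.
#'
#' @param cohort List of embryo records.
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_cohort_report <- function(cohort, path) {
  summ <- score_frequencies(cohort)
  assoc <- tryCatch(wildtype_phenotype_association(cohort),
                    error = function(e) NULL)
  rep <- list(
    n_embryos = length(cohort),
    embryos = lapply(cohort, function(e) {
      list(embryo_id = e$embryo_id, phenotype = e$phenotype,
           n_informative = e$n_informative,
           distinct_sequences = e$distinct_sequences,
           wildtype_present = e$wildtype_present,
           score_tally = as.list(e$score_tally))
    }),
    score_frequencies = list(overall = summ$overall, defect = summ$defect,
                             normal = summ$normal),
    wildtype_association = if (!is.null(assoc)) list(
      table = as.data.frame(as.table(assoc$table)),
      odds_ratio = assoc$odds_ratio, degenerate = assoc$degenerate,
      p_value = assoc$p_value) else NULL)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rep)
}
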