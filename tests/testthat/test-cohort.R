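## minimal call tables for cohort tests, bypassing the aligner
mock_calls <- function(window_seqs, scores, wildtype, locus = "S") {
  data.frame(read_id = sprintf("r%02d", seq_along(window_seqs)),
             allele = locus, window_seq = window_seqs, informative = TRUE,
             wildtype = wildtype, score_code = scores,
             stringsAsFactors = FALSE)
}
mock_embryo <- function(id, phenotype, window_seqs, scores, wildtype) {
  summarize_embryo(mock_calls(window_seqs, scores, wildtype), id, phenotype)
}

test_that("embryo summaries group alleles by in-window sequence identity", {
  calls <- mock_calls(c(rep("AAA", 12), rep("AC", 5), rep("G", 3)),
                      c(rep(6L, 12), rep(5L, 5), rep(1L, 3)),
                      c(rep(TRUE, 12), rep(FALSE, 8)))
  rec <- summarize_embryo(calls, "t1", "normal")
  expect_equal(rec$distinct_sequences, 3L)
  expect_equal(rec$n_informative, 20L)
  expect_true(rec$wildtype_present)
  expect_equal(unname(rec$score_tally), c(3L, 0L, 0L, 0L, 5L, 12L))

  ## a single wild-type read among mutants still flags wild-type presence
  rec2 <- mock_embryo("t2", "normal", c(rep("X", 19), "WT"),
                      c(rep(1L, 19), 6L), c(rep(FALSE, 19), TRUE))
  expect_true(rec2$wildtype_present)
  expect_equal(rec2$distinct_sequences, 2L)

  bad <- mock_calls("AAA", 6L, TRUE)
  bad$informative <- FALSE
  expect_error(summarize_embryo(bad, "empty1", "normal"), "empty1")
  expect_error(summarize_embryo(mock_calls("A", 6L, TRUE), "x", "odd"), "arg")
})

test_that("score frequencies are parts-of-whole by phenotype group", {
  cohort <- list(
    mock_embryo("n1", "normal", c("WT", "WT"), c(6L, 6L), c(TRUE, TRUE)),
    mock_embryo("d1", "thin_wall_ventricle", c("A", "B"), c(1L, 5L),
                c(FALSE, FALSE)),
    mock_embryo("d2", "inert_ventricle", c("A",  "C"), c(1L, 1L),
                c(FALSE, FALSE)))
  fr <- score_frequencies(cohort)
  expect_equal(sum(fr$overall$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(fr$defect$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(fr$normal$proportion), 1, tolerance = 1e-12)
  expect_equal(fr$normal$proportion[6], 1)   # all-wildtype normal group
  expect_equal(fr$defect$count, c(3L, 0L, 0L, 0L, 1L, 0L))

  ## single-embryo cohort: proportions are that embryo's tally normalized
  fr1 <- score_frequencies(cohort[2])
  expect_equal(fr1$overall$proportion,
               unname(cohort[[2]]$score_tally) / 2)
  expect_null(fr1$normal)
})

test_that("the exact association test reproduces the cohort contingency", {
  ## wild-type alleles in all 5 normal embryos, 3 of 11 with defects
  cohort <- c(
    lapply(1:5, function(i) mock_embryo(paste0("n", i), "normal",
                                        "WT", 6L, TRUE)),
    lapply(1:3, function(i) mock_embryo(paste0("dw", i), "inert_ventricle",
                                        c("WT", "M"), c(6L, 1L), c(TRUE, FALSE))),
    lapply(1:8, function(i) mock_embryo(paste0("d", i), "thin_wall_ventricle",
                                        "M", 1L, FALSE)))
  assoc <- wildtype_phenotype_association(cohort)
  expect_equal(unname(assoc$table["present", ]), c(5L, 3L))
  expect_equal(unname(assoc$table["absent", ]), c(0L, 8L))
  ## hypergeometric tail: only the observed table is as extreme
  expect_equal(assoc$p_value, choose(8, 5) / choose(16, 5), tolerance = 1e-12)
  expect_true(assoc$degenerate)
  ## matches the brute-force oracle and the stats cross-check
  expect_equal(assoc$p_value, oracle_fisher_one_sided(assoc$table),
               tolerance = 1e-12)
  expect_equal(assoc$p_value,
               stats::fisher.test(assoc$table, alternative = "greater")$p.value,
               tolerance = 1e-9)

  ## identical proportions in both groups give p = 1
  bal <- c(lapply(1:2, function(i) mock_embryo(paste0("a", i), "normal",
                                               "WT", 6L, TRUE)),
           lapply(1:2, function(i) mock_embryo(paste0("b", i), "normal",
                                               "M", 1L, FALSE)),
           lapply(1:2, function(i) mock_embryo(paste0("c", i), "inert_ventricle",
                                               "WT", 6L, TRUE)),
           lapply(1:2, function(i) mock_embryo(paste0("e", i), "inert_ventricle",
                                               "M", 1L, FALSE)))
  bal_assoc <- wildtype_phenotype_association(bal)
  expect_equal(bal_assoc$p_value,
               stats::fisher.test(bal_assoc$table,
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_gt(bal_assoc$p_value, 0.5)   # no one-sided evidence
  expect_false(bal_assoc$degenerate)

  ## with wild type absent everywhere the observed count is the floor: p = 1
  nowt <- c(lapply(1:2, function(i) mock_embryo(paste0("f", i), "normal",
                                                "M", 1L, FALSE)),
            lapply(1:2, function(i) mock_embryo(paste0("g", i), "inert_ventricle",
                                                "M", 1L, FALSE)))
  expect_equal(wildtype_phenotype_association(nowt)$p_value, 1)

  expect_error(wildtype_phenotype_association(cohort[1:5]), "both phenotype")
})

test_that("exact p equals margin-fixed enumeration on random small tables", {
  set.seed(17)
  for (i in 1:200) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(exact_one_sided_p(tab), min(1, oracle_fisher_one_sided(tab)),
                 tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
})

test_that("association detects the lineage-thresholded phenotype rule with power >= 0.8", {
  ## self-consistency at the simulator's default effect size: 16 embryos,
  ## 200 seeded replicates, spectrum-level simulation
  set.seed(160916)
  pvals <- vapply(1:200, function(r) {
    sim <- simulate_cohort(n_embryos = 16, emit_reads = FALSE)
    phen <- vapply(sim$manifest, `[[`, character(1), "phenotype")
    wt <- vapply(sim$manifest, function(m)
      any(m$alleles$wildtype & m$alleles$count > 0), logical(1))
    normal <- phen == "normal"
    if (all(normal) || !any(normal)) return(1)
    exact_one_sided_p(matrix(c(sum(wt & normal), sum(!wt & normal),
                               sum(wt & !normal), sum(!wt & !normal)), 2,
                             byrow = TRUE))
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.8)
})

test_that("cohort reports serialize to JSON", {
  cohort <- list(
    mock_embryo("n1", "normal", "WT", 6L, TRUE),
    mock_embryo("d1", "inert_ventricle", "M", 1L, FALSE))
  path <- tempfile(fileext = ".json")
  rep <- write_cohort_report(cohort, path)
  expect_true(file.exists(path))
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_embryos, 2L)
  expect_equal(length(parsed$embryos), 2L)
})
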