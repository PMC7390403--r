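models <- synthetic_locus_pair()
WIN <- attr(models, "window")
CUT <- attr(models, "cut")

test_that("alignment recovers identity and clean deletions", {
  aln <- align_read(models$S$sequence, models$S)
  expect_equal(aln$score, 2 * nchar(models$S$sequence))
  expect_equal(unique(aln$ops$op), "match")

  ## 9-bp MMEJ product aligns as one 9-bp deletion
  pr <- enumerate_mmej(models$S$sequence, CUT, 3, 12)
  mut <- pr$product_sequence[pr$deletion_size == 9][1]
  aln9 <- align_read(mut, models$S)
  dels <- aln9$ops[aln9$ops$op == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$length, 9L)

  expect_warning(align_read("ACGTACGTACGTACG", models$S), "shorter than 20")
  expect_error(align_read("", models$S), "non-empty")
})

test_that("alignment scores equal the brute-force affine DP oracle", {
  set.seed(5)
  for (i in 1:120) {
    a <- random_dna(sample(3:12, 1))
    b <- random_dna(sample(3:12, 1))
    aln <- suppressWarnings(align_read(a, b, orientation = "forward"))
    expect_equal(aln$score, oracle_align_score(a, b), info = paste(a, b))
    alnf <- suppressWarnings(align_read(a, b, orientation = "forward",
                                        type = "fitting"))
    expect_equal(alnf$score, oracle_align_score(a, b, type = "fitting"),
                 info = paste("fitting", a, b))
  }
})

test_that("reverse-complement reads align on the reverse strand, same score", {
  pr <- enumerate_mmej(models$S$sequence, CUT, 3, 12)
  mut <- pr$product_sequence[pr$deletion_size == 12][1]
  fwd <- align_read(mut, models$S)
  rev <- align_read(revcomp(mut), models$S)
  expect_equal(fwd$orientation, "forward")
  expect_equal(rev$orientation, "reverse")
  expect_equal(fwd$score, rev$score)
  expect_equal(fwd$ops, rev$ops)
})

test_that("allele assignment follows score then the 5'-identity chimera rule", {
  expect_equal(as.character(assign_allele(models$S$sequence, models)), "S")
  expect_equal(as.character(assign_allele(models$L$sequence, models)), "L")

  ## chimera: S 5' half joined to L 3' half assigns to S (better score:
  ## only the L-specific tail differences are penalized)
  half <- 210
  chim <- paste0(substr(models$S$sequence, 1, half),
                 substr(models$L$sequence, half + 1, nchar(models$L$sequence)))
  expect_equal(as.character(assign_allele(chim, models)), "S")

  ## score-tied chimera between equal-length variants falls back to the
  ## 5'-identity rule
  s <- models$S$sequence
  v <- strsplit(s, "")[[1]]
  v[20] <- setdiff(c("A", "C", "G", "T"), v[20])[1]
  v[300] <- setdiff(c("A", "C", "G", "T"), v[300])[1]
  pair <- list(A = models$S,
               B = gene_model(paste(v, collapse = ""), models$S$exons, "B"))
  tie_read <- paste0(substr(s, 1, 150),
                     substr(pair$B$sequence, 151, nchar(s)))
  res <- assign_allele(tie_read, pair)
  expect_equal(diff(range(attr(res, "scores"))), 0)   # exact score tie
  expect_equal(as.character(res), "S")   # the 5' half matches allele S

  ## identical references are unresolvable
  twins <- list(A = gene_model(models$S$sequence, models$S$exons, "A"),
                B = gene_model(models$S$sequence, models$S$exons, "B"))
  expect_equal(as.character(assign_allele(models$S$sequence, twins)),
               "ambiguous")
})

test_that("lesion calling extracts, normalizes and windows events", {
  ## unmutated read
  aln <- align_read(models$S$sequence, models$S)
  les <- call_lesion(aln, WIN, models$S)
  expect_equal(nrow(les$events), 0L)
  expect_equal(les$net_indel, 0L)
  expect_true(les$window_covered)
  expect_true(les$informative)
  expect_true(is_wildtype_read(les, models$S))

  ## the 12-bp deletion product: one in-window deletion, net -12
  pr <- enumerate_mmej(models$S$sequence, CUT, 3, 12)
  mut <- pr$product_sequence[pr$deletion_size == 12][1]
  les12 <- call_lesion(align_read(mut, models$S), WIN, models$S)
  expect_equal(nrow(les12$events), 1L)
  expect_equal(les12$net_indel, -12L)
  expect_false(is_wildtype_read(les12, models$S))

  ## a read truncated before the window is uninformative
  stub <- substr(models$S$sequence, 1, WIN[1] - 5)
  les_tr <- call_lesion(align_read(stub, models$S, type = "fitting"),
                        WIN, models$S)
  expect_false(les_tr$window_covered)
  expect_false(les_tr$informative)
  expect_true(is.na(is_wildtype_read(les_tr, models$S)))

  expect_error(call_lesion(aln, c(-5, 10), models$S), "window")
})

test_that("N bases in the window make a read uninformative, not mutant", {
  s <- models$S$sequence
  nread <- paste0(substr(s, 1, WIN[1] + 3), "N",
                  substr(s, WIN[1] + 5, nchar(s)))
  les <- call_lesion(align_read(nread, models$S), WIN, models$S)
  expect_equal(nrow(les$events), 0L)   # N is not a substitution
  expect_false(les$informative)
  expect_true(is.na(is_wildtype_read(les, models$S)))
})

test_that("wild-type test is peptide-level: synonymous reads count as wild type", {
  ## GGG -> GGA at the first window codon keeps the peptide GGRRG
  s <- models$S$sequence
  syn <- paste0(substr(s, 1, WIN[1] + 2), "A", substr(s, WIN[1] + 4, nchar(s)))
  les <- call_lesion(align_read(syn, models$S), WIN, models$S)
  expect_equal(nrow(les$events), 1L)
  expect_equal(translate_nt(les$window_seq), "GGRRG")
  expect_true(is_wildtype_read(les, models$S))

  ## the 3-bp AGA deletion drops Arg272: peptide GGRG, not wild type
  pr <- enumerate_mmej(s, CUT, 3, 12)
  mut3 <- pr$product_sequence[pr$deletion_size == 3][1]
  les3 <- call_lesion(align_read(mut3, models$S), WIN, models$S)
  expect_equal(translate_nt(les3$window_seq), "GGRG")
  expect_false(is_wildtype_read(les3, models$S))
})

test_that("windows must be codon-aligned and snapping records the shift", {
  expect_error(window_peptide(models$S, WIN + 1L), "codon-aligned")
  snapped <- snap_window_to_codons(models$S, WIN + 1L)
  expect_equal(as.integer(snapped), c(WIN[1], WIN[2] + 3L))
  expect_equal(attr(snapped, "snapped"), c(left = 1L, right = 2L))
})

test_that("right-normalization is idempotent and placement-invariant", {
  s <- models$S$sequence
  set.seed(21)
  for (i in 1:25) {
    ev <- data.frame(ref_start = sample(150:250, 1),
                     deleted = "", inserted = "")
    size <- sample(1:9, 1)
    ev$deleted <- substr(s, ev$ref_start + 1, ev$ref_start + size)
    n1 <- normalize_events(ev, s)
    expect_identical(normalize_events(n1, s), n1)
  }
  ## a deletion inside the G-run of the window names identically whichever
  ## physical copy is removed
  run_start <- WIN[1]   # GGGGG run
  calls <- lapply(0:3, function(shift) {
    mut <- paste0(substr(s, 1, run_start + shift),
                  substr(s, run_start + shift + 2, nchar(s)))
    call_lesion(align_read(mut, models$S), WIN, models$S)
  })
  evs <- lapply(calls, `[[`, "events")
  for (k in 2:4) expect_equal(evs[[k]], evs[[1]])
})

test_that("orientation filter keeps the requested strand and reports drops", {
  reads <- list(amplicon_read("r1", models$S$sequence, orientation = "forward"),
                amplicon_read("r2", models$S$sequence, orientation = "reverse"),
                amplicon_read("r3", models$S$sequence, orientation = "reverse"))
  expect_message(kept <- orientation_filter(reads, "reverse"), "1 read")
  expect_length(kept, 2L)
  expect_equal(attr(kept, "n_discarded"), 1L)
  all_kept <- orientation_filter(reads, "both")
  expect_length(all_kept, 3L)
})

test_that("reads load from FASTA and FASTQ", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 clone", "ACGTACGTACGTACGTACGTACGT"), fa)
  rd <- read_amplicon_seqs(fa)
  expect_length(rd, 1L)
  expect_equal(rd[[1]]$read_id, "c1")
  expect_equal(rd[[1]]$source, "sanger_clone")

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@n1", "ACGTACGTAAC", "+", "IIIIIIIIIII"), fq)
  rq <- read_amplicon_seqs(fq, format = "fastq")
  expect_equal(rq[[1]]$source, "ngs")
  expect_equal(rq[[1]]$qualities, "IIIIIIIIIII")
})
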