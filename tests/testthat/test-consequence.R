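models <- synthetic_locus_pair()
WIN <- attr(models, "window")
CUT <- attr(models, "cut")

## lesion for a pure deletion on the S model
s_del_lesion <- function(start, size) {
  truth_lesion(deletion_events(models$S, start, size), models$S, WIN)
}

test_that("the stereotyped exon 6 deletions annotate and name correctly", {
  pr <- enumerate_mmej(models$S$sequence, CUT, 3, 12)
  by_size <- function(d) {
    row <- pr[pr$deletion_size == d, ][1, ]
    annotate_consequence(s_del_lesion(row$del_start, d), models$S)
  }
  c3 <- by_size(3)
  expect_equal(c3$kind, "inframe_deletion")
  expect_equal(c3$hgvs_p, "p.(Arg272del)")
  expect_equal(c3$aa_changes, 1L)

  c12 <- by_size(12)
  expect_equal(c12$hgvs_p, "p.(Gly270_Gly273del)")
  expect_equal(c12$aa_changes, 4L)
  expect_equal(as.integer(assign_score(c12)), 5L)

  nine <- pr[pr$deletion_size == 9, ]
  hg9 <- vapply(seq_len(nrow(nine)), function(k) {
    annotate_consequence(s_del_lesion(nine$del_start[k], 9), models$S)$hgvs_p
  }, character(1))
  expect_setequal(hg9, c("p.(Gly269_Arg271del)", "p.(Arg271_Gly273del)"))
})

test_that("missense, frameshift and identity lesions classify by the codon diff", {
  ## single-base missense
  cm <- codon_map(models$S)
  ## mutate the middle codon base of Arg268 (never synonymous)
  pos268 <- min(cm$genomic_pos[cm$residue_index == 268]) + 1L
  ref_base <- substr(models$S$sequence, pos268 + 1, pos268 + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  ev <- data.frame(ref_start = pos268, deleted = ref_base, inserted = alt)
  cons <- annotate_consequence(truth_lesion(ev, models$S, WIN), models$S)
  expect_equal(cons$kind, "missense")
  expect_equal(cons$aa_changes, 1L)
  expect_match(cons$hgvs_p, "^p\\.\\(Arg268")
  expect_equal(as.integer(assign_score(cons)), 5L)

  ## 1-bp deletion mid-exon is a frameshift, score 01
  fs <- annotate_consequence(s_del_lesion(CUT, 1), models$S)
  expect_equal(fs$kind, "frameshift")
  expect_equal(as.integer(assign_score(fs)), 1L)

  ## identity
  idm <- annotate_consequence(truth_lesion(empty_ev(), models$S, WIN), models$S)
  expect_equal(idm$kind, "wildtype")
  expect_equal(idm$hgvs_p, "p.(=)")
  expect_equal(as.integer(assign_score(idm)), 6L)
})

test_that("a 21-bp deletion spanning Met141..Gly147 names and counts 7 aa", {
  ## model whose first codon is residue 141 (Met) and codon 7 is Gly
  cds <- paste0("ATG", "GCT", "GAA", "CCT", "TGG", "AAA", "GGT",
                "TCA", "TTT", "CTG")   # MAEPWKGSFL
  m <- gene_model(cds, data.frame(exon_id = "e3", start = 0, end = 30),
                  allele_id = "x", residue_offset = 140L)
  ev <- data.frame(ref_start = 0L, deleted = substr(cds, 1, 21), inserted = "")
  les <- truth_lesion(ev, m, c(21L, 30L))
  cons <- annotate_consequence(les, m)
  expect_equal(cons$kind, "inframe_deletion")
  expect_equal(cons$hgvs_p, "p.(Met141_Gly147del)")
  expect_equal(cons$aa_changes, 7L)
  expect_equal(as.integer(assign_score(cons)), 4L)
})

test_that("acceptor loss skips the exon: a 41-aa exon scores 02", {
  ## three-exon model; the middle exon is 123 bp (41 whole codons)
  set.seed(8)
  ex1 <- "ATGGCTGCTACT"                       # 12 nt
  ex2 <- paste(rep("GGTGCAACT", 14), collapse = "")   # 126 -> trim to 123
  ex2 <- substr(ex2, 1, 123)
  ex3 <- "TCATTCAAGTAA"                       # 12 nt
  i1 <- "GTAAGCTTTTTCCCCAG"; i2 <- "GTACGTATTTTTTACAG"
  seqn <- paste0(ex1, i1, ex2, i2, ex3)
  m <- gene_model(seqn, data.frame(
    exon_id = c("e1", "e2", "e3"),
    start = c(0, 12 + nchar(i1), 12 + nchar(i1) + 123 + nchar(i2)),
    end = c(12, 12 + nchar(i1) + 123, nchar(seqn))))
  ## deletion removing the acceptor AG of exon 2
  acc <- 12 + nchar(i1) - 2
  ev <- data.frame(ref_start = acc, deleted = substr(seqn, acc + 1, acc + 2),
                   inserted = "")
  les <- truth_lesion(ev, m, c(0L, 3L))
  expect_true(les$disrupts_acceptor)
  cons <- annotate_consequence(les, m)
  expect_equal(cons$kind, "exon_skip")
  expect_equal(cons$aa_changes, 41L)
  expect_equal(as.integer(assign_score(cons)), 2L)
  expect_equal(cons$affected_residues, c(5L, 45L))

  ## skipping an exon whose length is not a codon multiple is truncating
  m2 <- gene_model(paste0(ex1, i1, substr(ex2, 1, 122), i2, ex3),
                   data.frame(exon_id = c("e1", "e2", "e3"),
                              start = c(0, 12 + nchar(i1),
                                        12 + nchar(i1) + 122 + nchar(i2)),
                              end = c(12, 12 + nchar(i1) + 122,
                                      12 + nchar(i1) + 122 + nchar(i2) + 12)))
  les2 <- truth_lesion(ev, m2, c(0L, 3L))
  cons2 <- annotate_consequence(les2, m2)
  expect_true(cons2$truncating)
  expect_equal(as.integer(assign_score(cons2)), 1L)
})

test_that("donor loss retains the intron and usually truncates", {
  ex1 <- "ATGGCTGCTACT"
  i1 <- "GTAAGCTTTTTCCCTAG"    # contains an in-frame stop on read-through
  ex2 <- "GGTGCAACTTCATAA"
  seqn <- paste0(ex1, i1, ex2)
  m <- gene_model(seqn, data.frame(exon_id = c("e1", "e2"),
                                   start = c(0, 12 + nchar(i1)),
                                   end = c(12, nchar(seqn))))
  ev <- data.frame(ref_start = 12L, deleted = substr(seqn, 13, 14),
                   inserted = "")
  les <- truth_lesion(ev, m, c(0L, 3L))
  expect_true(les$disrupts_donor)
  cons <- annotate_consequence(les, m)
  expect_equal(cons$kind, "intron_retention")
  expect_true(cons$truncating)
  expect_equal(as.integer(assign_score(cons)), 1L)

  ## a stop-free whole-codon intron reads through as an in-frame insertion
  i_clean <- "GTAAGCTTT"   # 9 nt, GTA AGC TTT = V S F
  m2 <- gene_model(paste0(ex1, i_clean, ex2),
                   data.frame(exon_id = c("e1", "e2"),
                              start = c(0, 12 + 9),
                              end = c(12, 12 + 9 + nchar(ex2))))
  les2 <- truth_lesion(ev, m2, c(0L, 3L))
  cons2 <- annotate_consequence(les2, m2)
  expect_equal(cons2$kind, "intron_retention")
  expect_false(cons2$truncating)
  expect_equal(cons2$aa_changes, 3L)
  expect_equal(as.integer(assign_score(cons2)), 5L)
})

test_that("the score table maps amino-acid changes to codes monotonically", {
  mk <- function(kind, aa, trunc = FALSE) {
    structure(list(kind = kind, aa_changes = as.integer(aa), hgvs_p = "p.(?)",
                   affected_residues = NULL, truncating = trunc),
              class = "protein_consequence")
  }
  expect_equal(as.integer(assign_score(mk("frameshift", 10, TRUE))), 1L)
  expect_equal(as.integer(assign_score(mk("nonsense", 2, TRUE))), 1L)
  expect_equal(as.integer(assign_score(mk("exon_skip", 41))), 2L)
  expect_equal(as.integer(assign_score(mk("inframe_deletion", 20))), 3L)
  expect_equal(as.integer(assign_score(mk("inframe_deletion", 11))), 3L)
  expect_equal(as.integer(assign_score(mk("inframe_deletion", 10))), 4L)
  expect_equal(as.integer(assign_score(mk("inframe_deletion", 6))), 4L)
  expect_equal(as.integer(assign_score(mk("missense", 5))), 5L)
  expect_equal(as.integer(assign_score(mk("missense", 1))), 5L)
  expect_equal(as.integer(assign_score(mk("wildtype", 0))), 6L)
  ## monotone non-increasing in aa_changes among in-frame consequences
  codes <- vapply(0:45, function(aa)
    as.integer(assign_score(mk("inframe_deletion", aa))), integer(1))
  expect_true(all(diff(codes) <= 0))
  expect_equal(format(assign_score(mk("wildtype", 0))), "06")
})

test_that("pure in-frame deletions count k/3 residues", {
  for (d in c(3L, 9L, 12L, 21L)) {
    start <- CUT - d %/% 2
    start <- start - ((start - models$S$exons$start[1]) %% 3L)  # codon-aligned
    cons <- annotate_consequence(s_del_lesion(start, d), models$S)
    expect_equal(cons$aa_changes, d %/% 3L)
  }
})

test_that("hgvs_name annotates lesions on demand", {
  pr <- enumerate_mmej(models$S$sequence, CUT, 3, 12)
  row <- pr[pr$deletion_size == 3, ][1, ]
  les <- s_del_lesion(row$del_start, 3)
  expect_equal(hgvs_name(les, models$S), "p.(Arg272del)")
  expect_error(hgvs_name(les), "model required")
})
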