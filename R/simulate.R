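#' Repair-outcome model for simulated Cas9 lesions
#'
#' Stochastic model of how a double-strand break is repaired at a target
#' site. A repair is a 1-bp missense substitution with probability
#' `p_substitution`; otherwise an MMEJ deletion drawn from the enumerated
#' products (by weight) with probability `p_mmej`, or an NHEJ indel. NHEJ
#' sizes follow truncated geometric distributions — the conventional
#' minimal choice where only size ranges, not a distribution, are reported
#' (deletions of 1 up to ~24 bp, insertions of a few bases).
#'
#' @param p_mmej Probability a non-substitution repair uses an MMEJ product.
#' @param p_substitution Per-repair probability of a 1-bp missense outcome.
#' @param p_insertion_vs_deletion NHEJ branch: probability of an insertion.
#' @param p_del_geom,max_del Truncated geometric parameter and cap for NHEJ
#'   deletion sizes.
#' @param p_ins_geom,max_ins Same for NHEJ insertion sizes.
#' @param min_microhomology,max_deletion,weight_scale MMEJ enumeration
#'   parameters (see [enumerate_mmej()]).
#' @return Object of class `repair_model`.
#' @export
repair_model <- function(p_mmej = 0.7, p_substitution = 0.02,
                         p_insertion_vs_deletion = 0.2,
                         p_del_geom = 0.2, max_del = 30L,
                         p_ins_geom = 0.4, max_ins = 6L,
                         min_microhomology = 3L, max_deletion = 30L,
                         weight_scale = 20) {
  stopifnot(p_mmej >= 0, p_mmej <= 1, p_substitution >= 0, p_substitution <= 1,
            p_insertion_vs_deletion >= 0, p_insertion_vs_deletion <= 1)
  structure(list(p_mmej = p_mmej, p_substitution = p_substitution,
                 p_insertion_vs_deletion = p_insertion_vs_deletion,
                 p_del_geom = p_del_geom, max_del = as.integer(max_del),
                 p_ins_geom = p_ins_geom, max_ins = as.integer(max_ins),
                 min_microhomology = as.integer(min_microhomology),
                 max_deletion = as.integer(max_deletion),
                 weight_scale = weight_scale),
            class = "repair_model")
}

#' Mosaicism model for simulated G0 embryos
#'
#' Phenomenological model of G0 mosaicism: each locus of an embryo carries
#' 1-6 distinct repaired alleles (mass concentrated at four or fewer),
#' allele frequencies follow a symmetric Dirichlet, each allele escapes
#' cutting (remains wild type) with probability `p_wildtype_escape`, and a
#' per-allele Beta-distributed lineage weight governs how much of each
#' allele reaches the cardiac lineage. An embryo develops a normal heart
#' iff the lineage-weighted fraction of functional alleles (genotype scores
#' in `functional_scores`; default wild-type only, since the stereotyped
#' small in-frame deletions at the exon 6 di-arginine site eliminate
#' function) is at least `theta`; otherwise a defect class is drawn.
#'
#' @param n_alleles_probs Probability over 1-6 distinct alleles per locus.
#' @param dirichlet_alpha Symmetric Dirichlet concentration of allele
#'   frequencies.
#' @param p_wildtype_escape Per-allele probability of remaining unrepaired
#'   wild type.
#' @param lineage_beta Shape1/shape2 of the per-allele cardiac lineage
#'   weight.
#' @param theta Functional-allele fraction needed for a normal heart.
#' @param functional_scores Genotype score codes counted as functional.
#' @param defect_class_probs Probabilities of the three defect classes,
#'   given a defect.
#' @return Object of class `mosaic_model`.
#' @export
mosaic_model <- function(n_alleles_probs = c(0.20, 0.30, 0.25, 0.15, 0.07, 0.03),
                         dirichlet_alpha = 1,
                         p_wildtype_escape = 0.15,
                         lineage_beta = c(1, 1),
                         theta = 0.15,
                         functional_scores = 6L,
                         defect_class_probs = c(inert_ventricle = 0.3,
                                                thin_wall_ventricle = 0.5,
                                                other_malformation = 0.2)) {
  stopifnot(length(n_alleles_probs) == 6L, all(n_alleles_probs >= 0),
            p_wildtype_escape >= 0, p_wildtype_escape <= 1,
            theta >= 0, theta <= 1)
  structure(list(n_alleles_probs = n_alleles_probs / sum(n_alleles_probs),
                 dirichlet_alpha = dirichlet_alpha,
                 p_wildtype_escape = p_wildtype_escape,
                 lineage_beta = lineage_beta, theta = theta,
                 functional_scores = as.integer(functional_scores),
                 defect_class_probs = defect_class_probs / sum(defect_class_probs)),
            class = "mosaic_model")
}

## truncated geometric pmf over sizes 1..max
trunc_geom_pmf <- function(p, max_size) {
  w <- stats::dgeom(seq_len(max_size) - 1L, p)
  w / sum(w)
}

## draw one repair outcome at a cut; returns normalized event table
draw_repair <- function(repair, model, products, cut) {
  ref <- model$sequence
  u <- stats::runif(1)
  if (u < repair$p_substitution) {
    ev <- draw_missense(model, cut)
  } else if (stats::runif(1) < repair$p_mmej && nrow(products) > 0L) {
    row <- products[sample.int(nrow(products), 1L, prob = products$weight), ]
    ev <- data.frame(ref_start = row$del_start,
                     deleted = substr(ref, row$del_start + 1L, row$del_end),
                     inserted = "", stringsAsFactors = FALSE)
  } else if (stats::runif(1) < repair$p_insertion_vs_deletion) {
    s <- sample.int(repair$max_ins, 1L,
                    prob = trunc_geom_pmf(repair$p_ins_geom, repair$max_ins))
    ev <- data.frame(ref_start = cut,
                     deleted = "",
                     inserted = paste(sample(c("A", "C", "G", "T"), s,
                                             replace = TRUE), collapse = ""),
                     stringsAsFactors = FALSE)
  } else {
    s <- sample.int(repair$max_del, 1L,
                    prob = trunc_geom_pmf(repair$p_del_geom, repair$max_del))
    start <- cut - sample.int(s + 1L, 1L) + 1L
    start <- max(0L, min(start, nchar(ref) - s))
    ev <- data.frame(ref_start = start,
                     deleted = substr(ref, start + 1L, start + s),
                     inserted = "", stringsAsFactors = FALSE)
  }
  normalize_events(ev, ref)
}

## 1-bp substitution near the cut guaranteed to change the encoded residue
draw_missense <- function(model, cut, tries = 50L) {
  cm <- codon_map(model)
  cand <- intersect(seq.int(cut - 3L, cut + 2L), cm$genomic_pos)
  rf <- chars(model$sequence)
  for (t in seq_len(tries)) {
    p <- cand[sample.int(length(cand), 1L)]
    alt <- sample(setdiff(c("A", "C", "G", "T"), rf[p + 1L]), 1L)
    row <- cm[cm$genomic_pos == p, ]
    codon_pos <- cm$genomic_pos[cm$residue_index == row$residue_index]
    codon <- rf[codon_pos + 1L]
    new_codon <- codon
    new_codon[row$codon_offset + 1L] <- alt
    aa_ref <- translate_nt(paste(codon, collapse = ""))
    aa_alt <- translate_nt(paste(new_codon, collapse = ""))
    if (aa_alt != aa_ref && aa_alt != "*") {
      return(data.frame(ref_start = p, deleted = rf[p + 1L], inserted = alt,
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not draw a missense substitution near the cut")
}

## apply a normalized event table to a reference sequence
apply_events <- function(events, ref) {
  rf <- chars(toupper(ref))
  realize_window(events, ref, c(0L, length(rf)))
}

#' Inject uniform substitution sequencing errors into a read
#'
#' @param sequence Read sequence.
#' @param rate Per-base substitution error rate in \[0, 0.1\].
#' @return List with `sequence` (mutated) and `positions` (1-based error
#'   positions, possibly empty).
#' @export
inject_sequencing_error <- function(sequence, rate) {
  if (rate < 0 || rate > 0.1) stop("error rate must be in [0, 0.1]")
  s <- chars(sequence)
  hit <- which(stats::runif(length(s)) < rate)
  for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  list(sequence = paste(s, collapse = ""), positions = hit)
}

#' Simulate one mosaic G0 embryo
#'
#' Draws, for each homeologous locus, a number of distinct alleles, a repair
#' outcome per allele (wild-type escape, MMEJ product, NHEJ indel or
#' missense), Dirichlet allele frequencies and multinomial clone counts;
#' assigns the phenotype from the lineage-weighted functional-allele
#' fraction; and emits reads with optional sequencing error. Every read is
#' recorded in a ground-truth manifest entry.
#'
#' @param models Named list of [gene_model()] homeologs.
#' @param window Variant window shared by the models.
#' @param cuts Named integer vector of cut positions per model.
#' @param products Named list of [enumerate_mmej()] tables per model.
#' @param repair A [repair_model()].
#' @param mosaic A [mosaic_model()].
#' @param embryo_id Identifier used in read names and the manifest.
#' @param reads_per_locus Clone reads drawn per locus.
#' @param error_rate Per-base substitution error rate.
#' @param p_reverse Probability a read is emitted reverse-complemented.
#' @param source Read source label (`"sanger_clone"` or `"ngs"`).
#' @param emit_reads If FALSE, only the allele spectrum and phenotype are
#'   drawn (clone counts are still recorded); used for spectrum-level
#'   simulation studies where read sequences are not needed.
#' @return List with `reads` (list of [amplicon_read()]), `phenotype`, and
#'   `truth` (per-allele and per-read manifest entry).
#' @export
simulate_embryo <- function(models, window, cuts, products, repair, mosaic,
                            embryo_id = "embryo1", reads_per_locus = 16L,
                            error_rate = 0, p_reverse = 0,
                            source = "sanger_clone", emit_reads = TRUE) {
  loci <- names(models)
  allele_tabs <- list()
  func_frac_parts <- numeric(0)
  for (locus in loci) {
    model <- models[[locus]]
    k <- sample.int(6L, 1L, prob = mosaic$n_alleles_probs)
    rows <- vector("list", k)
    for (a in seq_len(k)) {
      if (stats::runif(1) < mosaic$p_wildtype_escape) {
        ev <- empty_events()
      } else {
        ev <- draw_repair(repair, model, products[[locus]], cuts[[locus]])
      }
      truth_lesion <- lesion_from_events(ev, model, window)
      cons <- annotate_consequence(truth_lesion, model)
      rows[[a]] <- data.frame(
        locus = locus,
        sequence = apply_events(ev, model$sequence),
        window_seq = truth_lesion$window_seq,
        events = events_to_string(truth_lesion$events),
        events_all = events_to_string(ev),
        kind = cons$kind, hgvs_p = cons$hgvs_p,
        aa_changes = cons$aa_changes,
        score = as.integer(assign_score(cons)),
        wildtype = isTRUE(is_wildtype_read(truth_lesion, model)),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    f <- stats::rgamma(k, shape = mosaic$dirichlet_alpha)
    tab$freq <- f / sum(f)
    tab$count <- as.integer(stats::rmultinom(1L, reads_per_locus, tab$freq))
    tab$lineage <- stats::rbeta(k, mosaic$lineage_beta[1L], mosaic$lineage_beta[2L])
    g <- tab$freq * tab$lineage
    g <- if (sum(g) > 0) g / sum(g) else tab$freq
    func_frac_parts <- c(func_frac_parts,
                         sum(g[tab$score %in% mosaic$functional_scores]))
    allele_tabs[[locus]] <- tab
  }
  func_frac <- mean(func_frac_parts)
  phenotype <- if (func_frac >= mosaic$theta) "normal" else
    sample(names(mosaic$defect_class_probs), 1L,
           prob = mosaic$defect_class_probs)

  reads <- list()
  read_rows <- list()
  if (emit_reads) for (locus in loci) {
    tab <- allele_tabs[[locus]]
    n_read <- 0L
    for (a in seq_len(nrow(tab))) {
      for (cnt in seq_len(tab$count[a])) {
        n_read <- n_read + 1L
        rid <- sprintf("%s_%s_r%03d", embryo_id, locus, n_read)
        seq_out <- tab$sequence[a]
        err <- if (error_rate > 0) inject_sequencing_error(seq_out, error_rate)
          else list(sequence = seq_out, positions = integer(0))
        rev <- stats::runif(1) < p_reverse
        reads[[length(reads) + 1L]] <- amplicon_read(
          rid, if (rev) revcomp(err$sequence) else err$sequence,
          source = source)
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          read_id = rid, locus = locus, allele_index = a,
          orientation = if (rev) "reverse" else "forward",
          n_errors = length(err$positions),
          error_positions = paste(err$positions, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  alleles <- do.call(rbind, allele_tabs)
  rownames(alleles) <- NULL
  list(reads = reads, phenotype = phenotype, embryo_id = embryo_id,
       truth = list(embryo_id = embryo_id, phenotype = phenotype,
                    functional_fraction = func_frac,
                    alleles = alleles,
                    reads = if (length(read_rows)) do.call(rbind, read_rows)
                      else NULL))
}

## build a dna_lesion directly from a known event table (simulator truth
## path; independent of the aligner)
lesion_from_events <- function(events, model, window) {
  inw <- events_in_window(events, window)
  L <- nchar(model$sequence)
  acceptor_exons <- character(0)
  donor_exons <- character(0)
  if (nrow(events) > 0L) {
    del_iv <- cbind(events$ref_start, events$ref_start + nchar(events$deleted))
    hit <- function(a, b) any(del_iv[, 1L] < b & del_iv[, 2L] > a &
                                nchar(events$deleted) > 0L)
    for (i in seq_len(nrow(model$exons))) {
      st <- model$exons$start[i]; en <- model$exons$end[i]
      id <- as.character(model$exons$exon_id[i])
      if (st >= 2L && hit(st - 2L, st)) acceptor_exons <- c(acceptor_exons, id)
      if (en + 2L <= L && hit(en, en + 2L)) donor_exons <- c(donor_exons, id)
    }
  }
  structure(
    list(allele_id = model$allele_id, read_id = NA_character_,
         orientation = "forward",
         events = events[inw, , drop = FALSE],
         events_all = events,
         net_indel = sum(nchar(events$inserted[inw])) -
           sum(nchar(events$deleted[inw])),
         window = window, window_covered = TRUE,
         window_seq = realize_window(events[inw, , drop = FALSE],
                                     model$sequence, window),
         informative = TRUE,
         disrupts_acceptor = length(acceptor_exons) > 0L,
         disrupts_donor = length(donor_exons) > 0L,
         acceptor_exons = acceptor_exons, donor_exons = donor_exons),
    class = "dna_lesion")
}

#' Simulate a cohort of mosaic G0 embryos
#'
#' Independent [simulate_embryo()] draws with a single controlling seed and
#' a combined truth manifest.
#'
#' @param n_embryos Number of embryos (default 16).
#' @param models Homeolog models (default [synthetic_locus_pair()]).
#' @param guide Guide RNA (default [exon6_guide()]); its unique target site
#'   on each model defines the cut.
#' @param repair,mosaic Repair and mosaicism models.
#' @param window Variant window; defaults to the locus pair's window.
#' @param reads_per_locus,error_rate,p_reverse,source Passed to
#'   [simulate_embryo()].
#' @param seed Integer seed controlling all randomness (optional).
#' @return Object of class `cohort_simulation`: `embryos` (list of
#'   simulate_embryo results), `manifest`, `models`, `window`, `cuts` and
#'   the generating parameters.
#' @export
simulate_cohort <- function(n_embryos = 16L, models = synthetic_locus_pair(),
                            guide = exon6_guide(), repair = repair_model(),
                            mosaic = mosaic_model(), window = NULL,
                            reads_per_locus = 16L, error_rate = 0,
                            p_reverse = 0, source = "sanger_clone",
                            emit_reads = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(window)) window <- attr(models, "window")
  if (is.null(window)) stop("no variant window given or attached to models")
  cuts <- vapply(models, function(m) {
    sites <- locate_target(guide, m, max_mismatches = 0L)
    if (length(sites) == 0L) {
      stop("guide ", guide$name, " not found on allele ", m$allele_id)
    }
    cut_position(sites[[1L]])
  }, integer(1))
  products <- lapply(models, function(m) {
    enumerate_mmej(m$sequence, cuts[[m$allele_id]],
                   min_microhomology = repair$min_microhomology,
                   max_deletion = repair$max_deletion,
                   weight_scale = repair$weight_scale)
  })
  embryos <- lapply(seq_len(n_embryos), function(i) {
    simulate_embryo(models, window, cuts, products, repair, mosaic,
                    embryo_id = sprintf("embryo%03d", i),
                    reads_per_locus = reads_per_locus,
                    error_rate = error_rate, p_reverse = p_reverse,
                    source = source, emit_reads = emit_reads)
  })
  structure(list(embryos = embryos,
                 manifest = lapply(embryos, `[[`, "truth"),
                 models = models, window = window, cuts = cuts,
                 products = products,
                 params = list(n_embryos = n_embryos, repair = repair,
                               mosaic = mosaic,
                               reads_per_locus = reads_per_locus,
                               error_rate = error_rate,
                               p_reverse = p_reverse, seed = seed)),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat("<cohort_simulation>", length(x$embryos), "embryo(s),",
      sum(vapply(x$embryos, function(e) length(e$reads), integer(1))),
      "reads total\n")
  invisible(x)
}

#' Expected in-frame fraction among mutant alleles
#'
#' Closed-form generative probability that a (non-escaped) repaired allele
#' is in-frame under a repair model and its MMEJ product table: missense
#' substitutions are in-frame; MMEJ products contribute their weight mass on
#' multiples of 3; NHEJ contributes the truncated-geometric mass on
#' multiples of 3 for each branch.
#'
#' @param repair A [repair_model()].
#' @param products [enumerate_mmej()] table at the simulated site.
#' @return Probability in \[0, 1\].
#' @export
expected_inframe_fraction <- function(repair, products) {
  w_if <- sum(products$weight[products$in_frame])
  del_pmf <- trunc_geom_pmf(repair$p_del_geom, repair$max_del)
  ins_pmf <- trunc_geom_pmf(repair$p_ins_geom, repair$max_ins)
  p3_del <- sum(del_pmf[seq_len(repair$max_del) %% 3L == 0L])
  p3_ins <- sum(ins_pmf[seq_len(repair$max_ins) %% 3L == 0L])
  p_nhej_if <- repair$p_insertion_vs_deletion * p3_ins +
    (1 - repair$p_insertion_vs_deletion) * p3_del
  repair$p_substitution +
    (1 - repair$p_substitution) *
    (repair$p_mmej * w_if + (1 - repair$p_mmej) * p_nhej_if)
}

#' Calibrate the MMEJ share to a target in-frame fraction
#'
#' Solves for `p_mmej` so that [expected_inframe_fraction()] equals a target
#' (e.g. an empirically reported in-frame mutation frequency), holding the
#' other repair parameters fixed.
#'
#' @param repair A [repair_model()].
#' @param products [enumerate_mmej()] table at the simulated site.
#' @param target Desired in-frame probability among mutant alleles.
#' @return A `repair_model` with adjusted `p_mmej`.
#' @export
calibrate_inframe <- function(repair, products, target) {
  f <- function(p) {
    r <- repair; r$p_mmej <- p
    expected_inframe_fraction(r, products) - target
  }
  lo <- f(0); hi <- f(1)
  if (sign(lo) == sign(hi)) {
    stop("target in-frame fraction ", target,
         " is outside the achievable range [",
         round(min(lo, hi) + target, 3), ", ",
         round(max(lo, hi) + target, 3), "]")
  }
  repair$p_mmej <- stats::uniroot(f, c(0, 1))$root
  repair
}

#' Write a simulated cohort to disk
#'
#' Reads as FASTA (Sanger clones) or FASTQ (NGS), a phenotype TSV
#' (embryo_id, phenotype) and the truth manifest as JSON.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- if (identical(sim$params$source, "ngs")) "fastq" else "fasta"
  seqs <- unlist(lapply(sim$embryos, function(e)
    vapply(e$reads, `[[`, character(1), "sequence")))
  ids <- unlist(lapply(sim$embryos, function(e)
    vapply(e$reads, `[[`, character(1), "read_id")))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  reads_path <- file.path(dir, paste0("reads.", fmt))
  if (fmt == "fastq") {
    Biostrings::writeXStringSet(ss, reads_path, format = "fastq")
  } else {
    Biostrings::writeXStringSet(ss, reads_path)
  }
  phen_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(
    data.frame(embryo_id = vapply(sim$embryos, `[[`, character(1), "embryo_id"),
               phenotype = vapply(sim$embryos, `[[`, character(1), "phenotype")),
    phen_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(sim$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(c(reads = reads_path, phenotypes = phen_path,
              manifest = manifest_path))
}

#' Run a simulation from a YAML configuration
#'
#' The YAML file may set any of: `n_embryos`, `reads_per_locus`,
#' `error_rate`, `p_reverse`, `source`, `seed`, and nested `repair:` /
#' `mosaic:` blocks whose keys mirror [repair_model()] / [mosaic_model()]
#' arguments.
#'
#' @param config_path YAML configuration path.
#' @param out_dir Output directory for [write_cohort()].
#' @return The [simulate_cohort()] result, invisibly.
#' @export
simulate_from_config <- function(config_path, out_dir) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("simulate_from_config requires the yaml package")
  }
  cfg <- yaml::read_yaml(config_path)
  repair <- do.call(repair_model, as.list(cfg$repair))
  mosaic <- do.call(mosaic_model, as.list(cfg$mosaic))
  args <- cfg[setdiff(names(cfg), c("repair", "mosaic"))]
  sim <- do.call(simulate_cohort,
                 c(args, list(repair = repair, mosaic = mosaic)))
  write_cohort(sim, out_dir)
  invisible(sim)
}
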