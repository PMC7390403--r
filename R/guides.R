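#' Construct a guide RNA definition
#'
#' @param name Guide label.
#' @param spacer Gene-specific spacer sequence, 5'->3', 18-25 nt, IUPAC codes
#'   allowed.
#' @param pam PAM pattern immediately 3' of the protospacer (IUPAC), default
#'   `"NGG"` (SpCas9).
#' @param orientation Intended orientation of the protospacer on the
#'   reference, `"forward"` or `"reverse"`.
#' @return Object of class `guide_rna`.
#' @export
guide_rna <- function(name, spacer, pam = "NGG",
                      orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  spacer <- toupper(as.character(spacer))
  pam <- toupper(as.character(pam))
  if (nchar(spacer) < 18L || nchar(spacer) > 25L) {
    stop("spacer length must be in [18, 25], got ", nchar(spacer))
  }
  iupac <- paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  if (grepl(sprintf("[^%s]", iupac), spacer) ||
      grepl(sprintf("[^%s]", iupac), pam)) {
    stop("spacer and PAM must be IUPAC nucleotide codes")
  }
  structure(list(name = name, spacer = spacer, pam_pattern = pam,
                 intended_orientation = orientation),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat("<guide_rna>", x$name, " 5'-", x$spacer, " PAM:", x$pam_pattern,
      switch(x$intended_orientation, forward = "(->)", reverse = "(<-)"), "\n")
  invisible(x)
}

#' Read a guide table (name, spacer, pam, direction)
#'
#' TSV with columns `name`, `spacer`, `pam`, `direction` where direction is
#' `forward`/`reverse` (or `->`/`<-`).
#'
#' @param path Path to the TSV file.
#' @return List of [guide_rna()] objects, named by guide.
#' @export
read_guide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "spacer", "pam", "direction")
  if (!all(need %in% names(tab))) {
    stop("guide table must have columns ", paste(need, collapse = ", "))
  }
  dir <- ifelse(tab$direction %in% c("reverse", "<-", "-"), "reverse", "forward")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$name[i], tab$spacer[i], tab$pam[i], dir[i])
  })
  names(out) <- tab$name
  out
}

#' Principal adprhl1 and tyrosinase guide definitions
#'
#' The published guide set bundled with the package: spacer, PAM and
#' orientation for the tyrosinase controls, the principal adprhl1 guides for
#' exons 3, 4 and 6 (including the two exon 6 seed-mismatch controls) and the
#' additional longer-spacer guides.
#'
#' @return Named list of [guide_rna()] objects.
#' @export
adprhl1_guides <- function() {
  path <- system.file("extdata", "guides_adprhl1.tsv", package = "amplimosaic",
                      mustWork = TRUE)
  read_guide_table(path)
}

#' Locate gRNA target sites on a gene model
#'
#' Scans both strands for positions where the spacer aligns with at most
#' `max_mismatches` substitutions and the PAM pattern matches immediately 3'
#' of the protospacer on the site strand. IUPAC ambiguity codes in spacer and
#' PAM are treated as character classes. Mismatch positions are recorded as
#' 1-based spacer indices counted from the 5' end.
#'
#' @param guide A [guide_rna()].
#' @param model A [gene_model()].
#' @param max_mismatches Maximum spacer substitutions tolerated (PAM must
#'   always match).
#' @param cut_distance Blunt-cut distance from the PAM, in bp (default 3, the
#'   canonical SpCas9 cut between spacer positions 17 and 18 of a 20-mer).
#' @return List of `target_site` objects (empty list if no site is found).
#'   Each site records allele_id, strand, protospacer/PAM intervals (0-based
#'   half-open, reference forward coordinates), the inter-base cut position
#'   and the mismatch positions.
#' @export
locate_target <- function(guide, model, max_mismatches = 0L, cut_distance = 3L) {
  stopifnot(inherits(guide, "guide_rna"), inherits(model, "gene_model"))
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  seq_f <- model$sequence
  L <- nchar(seq_f)
  sp <- nchar(guide$spacer)
  pl <- nchar(guide$pam_pattern)
  sites <- list()

  scan_strand <- function(subject, strand) {
    hits <- tryCatch(
      Biostrings::matchPattern(Biostrings::DNAString(guide$spacer),
                               Biostrings::DNAString(subject),
                               max.mismatch = max_mismatches, fixed = FALSE),
      error = function(e) NULL)
    if (is.null(hits) || length(hits) == 0L) return(invisible(NULL))
    sub_chars <- chars(subject)
    sp_chars <- chars(guide$spacer)
    pam_chars <- chars(guide$pam_pattern)
    for (h in seq_along(hits)) {
      s0 <- Biostrings::start(hits)[h] - 1L   # 0-based protospacer start
      if (s0 + sp + pl > nchar(subject)) next
      pam_site <- sub_chars[(s0 + sp + 1L):(s0 + sp + pl)]
      if (!all(iupac_compatible(pam_chars, pam_site))) next
      mism <- which(!iupac_compatible(sp_chars, sub_chars[(s0 + 1L):(s0 + sp)]))
      if (length(mism) > max_mismatches) next
      if (strand == "+") {
        proto <- c(s0, s0 + sp)
        pam <- c(s0 + sp, s0 + sp + pl)
        cut <- pam[1L] - cut_distance
      } else {
        ## coordinates on the reverse strand map back to forward coordinates
        proto <- c(L - (s0 + sp), L - s0)
        pam <- c(proto[1L] - pl, proto[1L])
        cut <- proto[1L] + cut_distance
      }
      sites[[length(sites) + 1L]] <<- structure(
        list(allele_id = model$allele_id, guide_name = guide$name,
             strand = strand,
             protospacer_interval = proto, pam_interval = pam,
             spacer_length = sp, cut_position = as.integer(cut),
             cut_distance = as.integer(cut_distance),
             mismatch_positions = as.integer(mism)),
        class = "target_site")
    }
    invisible(NULL)
  }

  scan_strand(seq_f, "+")
  scan_strand(revcomp(seq_f), "-")
  sites
}

#' @export
print.target_site <- function(x, ...) {
  cat("<target_site>", x$guide_name, "on", x$allele_id,
      sprintf("strand %s, protospacer [%d,%d), PAM [%d,%d), cut @%d",
              x$strand, x$protospacer_interval[1L], x$protospacer_interval[2L],
              x$pam_interval[1L], x$pam_interval[2L], x$cut_position),
      if (length(x$mismatch_positions))
        paste0("mismatches: ", paste(x$mismatch_positions, collapse = ",")) else
        "perfect match", "\n")
  invisible(x)
}

#' Cut position of a target site
#'
#' The blunt double-strand break sits `cut_distance` bp 5' of the PAM on the
#' protospacer strand (between spacer positions 17/18 of a 20-mer at the
#' default distance of 3). Returned as a 0-based inter-base index on the
#' forward reference: a cut value of k falls between bases k-1 and k.
#'
#' @param site A `target_site` from [locate_target()].
#' @return Integer inter-base index.
#' @export
cut_position <- function(site) {
  stopifnot(inherits(site, "target_site"))
  site$cut_position
}

#' Seed-sequence activity rule
#'
#' A perfect match of the PAM-proximal seed portion of the spacer is required
#' for cleavage: the site is `inactive` iff any recorded mismatch falls within
#' the `seed_length` spacer positions adjacent to the PAM, otherwise `active`.
#'
#' @param site A `target_site` with recorded mismatch positions.
#' @param seed_length Number of PAM-proximal spacer positions forming the
#'   seed (default 10).
#' @return `"active"` or `"inactive"`.
#' @export
predict_activity <- function(site, seed_length = 10L) {
  stopifnot(inherits(site, "target_site"))
  if (seed_length > site$spacer_length) {
    stop("seed_length (", seed_length, ") exceeds spacer length (",
         site$spacer_length, ")")
  }
  seed_from <- site$spacer_length - seed_length + 1L
  if (any(site$mismatch_positions >= seed_from)) "inactive" else "active"
}
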