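## Affine-gap pairwise alignment (Gotoh) with deterministic tie-breaking.
##
## A gap of length g costs gap_open + g * gap_extend (both negative), so a
## 1-bp gap costs gap_open + gap_extend. Tie-breaking at traceback prefers
## diagonal, then deletions (gap in the read) over insertions, opening gaps
## as far left as possible; lesion right-normalization downstream makes the
## residual choices unobservable.
##
## "global" aligns both sequences end to end; "fitting" aligns the whole
## read against any substring of the reference (free end gaps on the
## reference), the mode for short reads within a longer amplicon.

## substitution score vector of read base r against all ref chars;
## N (either side) scores 0 and is treated as a neutral match
sub_scores <- function(r, ref_chars, match, mismatch) {
  out <- ifelse(ref_chars == r, match, mismatch)
  out[ref_chars == "N"] <- 0
  if (r == "N") out[] <- 0
  out
}

nw_affine <- function(read, ref, type = c("global", "fitting"),
                      match = 2, mismatch = -4, gap_open = -10,
                      gap_extend = -1) {
  type <- match.arg(type)
  rd <- chars(toupper(read))
  rf <- chars(toupper(ref))
  m <- length(rd)
  n <- length(rf)
  if (m == 0L || n == 0L) stop("cannot align empty sequences")
  op <- gap_open; ex <- gap_extend
  NEG <- -1e18

  H <- matrix(NEG, m + 1L, n + 1L)
  V <- matrix(NEG, m + 1L, n + 1L)   # gap in ref (consumes read): insertion
  H[1L, 1L] <- 0
  H[1L, -1L] <- if (type == "global") op + ex * seq_len(n) else 0
  H[-1L, 1L] <- op + ex * seq_len(m)
  V[-1L, 1L] <- op + ex * seq_len(m)

  drow_of <- function(Mfull) {
    ## Mfull indexed 0..n (R index 1..n+1); D[j] = ex*j + max_{k<j}(M[k]+op-ex*k)
    t <- Mfull + op - ex * (0:n)
    c(NEG, cummax(t)[seq_len(n)]) + ex * (0:n)
  }
  m_row <- function(i) {
    sub <- sub_scores(rd[i], rf, match, mismatch)
    c(H[i + 1L, 1L], pmax(H[i, seq_len(n)] + sub, V[i + 1L, -1L]))
  }

  for (i in seq_len(m)) {
    V[i + 1L, -1L] <- pmax(H[i, -1L] + op + ex, V[i, -1L] + ex)
    Mfull <- m_row(i)
    Dfull <- drow_of(Mfull)
    H[i + 1L, ] <- pmax(Mfull, Dfull)
    H[i + 1L, 1L] <- op + ex * i
  }

  if (type == "global") {
    jend <- n
    score <- H[m + 1L, n + 1L]
  } else {
    jend <- which.max(H[m + 1L, ]) - 1L
    score <- H[m + 1L, jend + 1L]
  }

  ## traceback (single steps, collected in reverse). `state` tracks whether
  ## the current cell value is the full optimum H or the no-horizontal-gap
  ## optimum M (required after stepping left across a horizontal gap).
  steps <- character(0)
  i <- m; j <- jend
  state <- "H"
  eps <- 1e-9
  repeat {
    if (i == 0L && (type == "fitting" || j == 0L)) break
    if (i == 0L) { steps <- c(steps, rep("D", j)); j <- 0L; break }
    if (j == 0L) { steps <- c(steps, rep("I", i)); i <- 0L; break }
    sub <- sub_scores(rd[i], rf, match, mismatch)[j]
    Mfull <- m_row(i)
    cur <- if (state == "H") H[i + 1L, j + 1L] else Mfull[j + 1L]
    if (abs(cur - (H[i, j] + sub)) < eps) {
      steps <- c(steps, if (rf[j] == "N" || rd[i] == "N" || rd[i] == rf[j]) "M" else "X")
      i <- i - 1L; j <- j - 1L
      state <- "H"
      next
    }
    if (state == "H") {
      Dfull <- drow_of(Mfull)
      if (abs(cur - Dfull[j + 1L]) < eps) {
        ## horizontal gap (deletion): longest (leftmost-opening) run preferred
        g_cand <- which(abs(Mfull[seq_len(j)] + op + ex * (j - (seq_len(j) - 1L)) - cur) < eps)
        g <- j - (min(g_cand) - 1L)
        steps <- c(steps, rep("D", g))
        j <- j - g
        state <- "M"
        next
      }
    }
    ## vertical gap (insertion): follow the V chain upwards, preferring
    ## extension on ties (longest gap, leftmost opening)
    repeat {
      v <- V[i + 1L, j + 1L]
      ext_ok <- i > 1L && abs(v - (V[i, j + 1L] + ex)) < eps
      steps <- c(steps, "I")
      i <- i - 1L
      if (!ext_ok) break
    }
    state <- "H"
  }
  steps <- rev(steps)
  list(score = score, steps = steps, ref_start = j, ref_end = jend)
}

## compress traceback steps into an operations table
steps_to_ops <- function(steps, ref_start) {
  if (length(steps) == 0L) {
    return(data.frame(op = character(), length = integer(),
                      ref_pos = integer(), read_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(steps)
  opname <- c(M = "match", X = "mismatch", I = "insertion", D = "deletion")
  ref_pos <- integer(length(r$values))
  read_pos <- integer(length(r$values))
  rp <- ref_start; qp <- 0L
  for (k in seq_along(r$values)) {
    ref_pos[k] <- rp; read_pos[k] <- qp
    if (r$values[k] %in% c("M", "X", "D")) rp <- rp + r$lengths[k]
    if (r$values[k] %in% c("M", "X", "I")) qp <- qp + r$lengths[k]
  }
  data.frame(op = unname(opname[r$values]), length = r$lengths,
             ref_pos = ref_pos, read_pos = read_pos, stringsAsFactors = FALSE)
}

#' Align an amplicon read to a reference allele
#'
#' Global (end-to-end) alignment for full-length Sanger clone inserts;
#' fitting alignment (free end gaps on the reference) for NGS reads shorter
#' than the amplicon. Default scores: match +2, mismatch -4, gap open -10,
#' gap extend -1 (a gap of length g costs `-10 - g`). With
#' `orientation = "auto"` the read and its reverse complement are both
#' aligned and the better strand kept.
#'
#' @param read Read sequence (character) or a list with `read_id` and
#'   `sequence` fields.
#' @param model A [gene_model()] (or a plain reference string).
#' @param type `"global"` or `"fitting"`.
#' @param orientation `"auto"`, `"forward"` or `"reverse"`.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return Object of class `allele_alignment`: allele_id, score, orientation,
#'   `ref_start`/`ref_end` (0-based half-open reference span covered) and an
#'   `ops` table of (op, length, ref_pos, read_pos) runs tiling the read.
#' @export
align_read <- function(read, model, type = c("global", "fitting"),
                       orientation = c("auto", "forward", "reverse"),
                       match = 2, mismatch = -4, gap_open = -10,
                       gap_extend = -1) {
  type <- match.arg(type)
  orientation <- match.arg(orientation)
  read_id <- NULL
  if (is.list(read)) { read_id <- read$read_id; read <- read$sequence }
  read <- toupper(as.character(read))
  ref <- if (inherits(model, "gene_model")) model$sequence else toupper(model)
  allele_id <- if (inherits(model, "gene_model")) model$allele_id else NA_character_
  if (!nzchar(read) || !nzchar(ref)) stop("read and reference must be non-empty")
  if (nchar(read) < 20L) {
    warning("read ", if (!is.null(read_id)) read_id else "", " shorter than 20 nt")
  }
  cand <- switch(orientation,
                 auto = c("forward", "reverse"),
                 forward = "forward", reverse = "reverse")
  ## a strand whose score reaches this fraction of the perfect score is
  ## decisive: the opposite strand cannot align comparably unless the read
  ## is near-palindromic, so it is not computed
  decisive <- 0.8 * match * nchar(read)
  best <- NULL
  for (ori in cand) {
    seq_use <- if (ori == "reverse") revcomp(read) else read
    aln <- nw_affine(seq_use, ref, type = type, match = match,
                     mismatch = mismatch, gap_open = gap_open,
                     gap_extend = gap_extend)
    if (is.null(best) || aln$score > best$score) {
      best <- aln; best$orientation <- ori; best$oriented_read <- seq_use
    }
    if (length(cand) > 1L && best$score >= decisive) break
  }
  structure(list(read_id = read_id, allele_id = allele_id,
                 score = best$score, orientation = best$orientation,
                 ref_start = best$ref_start, ref_end = best$ref_end,
                 ops = steps_to_ops(best$steps, best$ref_start),
                 oriented_read = best$oriented_read,
                 ref_length = nchar(ref), type = type),
            class = "allele_alignment")
}

#' @export
print.allele_alignment <- function(x, ...) {
  nind <- sum(x$ops$op %in% c("insertion", "deletion"))
  cat("<allele_alignment>", if (!is.null(x$read_id)) x$read_id else "",
      "vs", x$allele_id, "| score", x$score, "|", x$orientation,
      sprintf("| ref [%d,%d) | %d indel op(s)\n", x$ref_start, x$ref_end, nind))
  invisible(x)
}
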