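#' Enumerate microhomology-mediated deletion products around a cut
#'
#' Microhomology-mediated end-joining (MMEJ, Alt-NHEJ) anneals short direct
#' repeats flanking a double-strand break, deleting the intervening sequence
#' plus one repeat copy. This enumerator finds every deletion product
#' consistent with that mechanism: a deletion interval of size
#' `<= max_deletion` that can be placed to contain or abut the cut and whose
#' junction flanks share a direct-repeat identity of at least
#' `min_microhomology` bases (the longer of the left-flank suffix match and
#' the right-flank prefix match at that junction).
#'
#' Distinct repeat placements of one deletion yield the same joined molecule,
#' so products are deduplicated by product sequence; all contributing maximal
#' repeat pairs are retained in the `repeat_pairs` attribute. The reported
#' `deleted_interval` is the right-most (3'-shifted) valid placement,
#' matching HGVS-style normalization downstream.
#'
#' Each product carries a nonnegative weight used only by the cohort
#' simulator: `weight = mh_length * exp(-deletion_size / weight_scale)`,
#' normalized over products — longer homology up-weights, longer deletion
#' down-weights. The weighting is a stated modelling convention, not an
#' empirical repair model.
#'
#' @param sequence Reference nucleotide string (local context around the cut).
#' @param cut 0-based inter-base cut index within the sequence.
#' @param min_microhomology Minimum junction repeat length (>= 1), default 2.
#' @param max_deletion Maximum deletion size in bp, default 30.
#' @param weight_scale Length scale (bp) of the exponential deletion-size
#'   down-weighting, default 20.
#' @return data.frame of class `mmej_products` with columns `repeat_seq`,
#'   `mh_length`, `left_repeat_start`, `right_repeat_start`, `del_start`,
#'   `del_end`, `deletion_size`, `in_frame`, `product_sequence`, `weight`;
#'   attribute `repeat_pairs` lists every contributing maximal pair per
#'   product. Zero-row data.frame when no repeat qualifies.
#' @export
enumerate_mmej <- function(sequence, cut, min_microhomology = 2L,
                           max_deletion = 30L, weight_scale = 20) {
  sequence <- toupper(as.character(sequence))
  s <- chars(sequence)
  L <- length(s)
  if (cut < 0L || cut > L) stop("cut index ", cut, " outside sequence [0, ", L, "]")
  if (min_microhomology < 1L) stop("min_microhomology must be >= 1")

  rows <- list()
  pairs <- list()
  for (d in seq_len(min(max_deletion, L - 1L))) {
    eq <- s[seq_len(L - d)] == s[seq.int(d + 1L, L)]
    if (!any(eq)) next
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_i <- which(r$values & r$lengths >= min_microhomology)
    for (ri in run_i) {
      a <- starts[ri] - 1L           # 0-based left repeat start
      k <- r$lengths[ri]             # maximal repeat length
      ## placements: delete [a+i, a+i+d) for i in 0..k; valid iff the
      ## interval touches the cut and its junction flanks carry >=
      ## min_microhomology identity (left suffix i, right prefix k-i)
      i_all <- 0:k
      touches <- (a + i_all) <= cut & cut <= (a + i_all + d)
      flank_ok <- pmax(i_all, k - i_all) >= min_microhomology
      valid <- i_all[touches & flank_ok]
      if (length(valid) == 0L) next
      i_use <- max(valid)            # right-most valid placement
      del_start <- a + i_use
      del_end <- del_start + d
      product <- paste0(substr(sequence, 1L, del_start),
                        substr(sequence, del_end + 1L, L))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_seq = substr(sequence, a + 1L, a + k),
        mh_length = k,
        left_repeat_start = a,
        right_repeat_start = a + d,
        del_start = del_start,
        del_end = del_end,
        deletion_size = d,
        in_frame = (d %% 3L) == 0L,
        product_sequence = product,
        stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <- list(product_sequence = product,
                                          left_start = a, right_start = a + d,
                                          mh_length = k)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(repeat_seq = character(), mh_length = integer(),
                      left_repeat_start = integer(), right_repeat_start = integer(),
                      del_start = integer(), del_end = integer(),
                      deletion_size = integer(), in_frame = logical(),
                      product_sequence = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "repeat_pairs") <- list()
    class(out) <- c("mmej_products", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ## deduplicate by product sequence, keeping the longest-homology
  ## representative; record all contributing repeat pairs
  ord <- order(out$product_sequence, -out$mh_length, -out$del_start)
  out <- out[ord, , drop = FALSE]
  keep <- !duplicated(out$product_sequence)
  dedup <- out[keep, , drop = FALSE]
  dedup <- dedup[order(dedup$deletion_size, dedup$del_start), , drop = FALSE]
  rownames(dedup) <- NULL
  w <- dedup$mh_length * exp(-dedup$deletion_size / weight_scale)
  dedup$weight <- w / sum(w)
  attr(dedup, "repeat_pairs") <- split(
    do.call(rbind, lapply(pairs, as.data.frame))[, c("product_sequence",
                                                     "left_start", "right_start",
                                                     "mh_length")],
    factor(vapply(pairs, `[[`, "", "product_sequence"),
           levels = dedup$product_sequence))
  class(dedup) <- c("mmej_products", "data.frame")
  dedup
}

#' Apply an MMEJ product's deletion to a reference sequence
#'
#' @param sequence The reference the products were enumerated on.
#' @param product One row of an [enumerate_mmej()] result.
#' @return The joined product sequence (equals `product_sequence`).
#' @export
apply_mmej_product <- function(sequence, product) {
  paste0(substr(sequence, 1L, product$del_start),
         substr(sequence, product$del_end + 1L, nchar(sequence)))
}
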