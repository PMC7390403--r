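## Independent oracles used across the suite. Each is written from the
## definition it checks, not from the implementation's code path.

## ---- affine-gap alignment score oracle -----------------------------------
## Memoized three-state recursion over alignment endings (match/deletion/
## insertion), scoring a gap of length g as open + g * ext. Independent of
## the package's row-vectorized formulation.
oracle_align_score <- function(a, b, match = 2, mismatch = -4,
                               open = -10, ext = -1,
                               type = c("global", "fitting")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e15
  memo <- new.env(parent = emptyenv())
  sub <- function(i, j) if (av[i] == bv[j]) match else mismatch
  ## start(i, j): score of the empty alignment prefix at (i, j); for fitting
  ## mode any amount of leading reference is free
  start_ok <- function(i, j) {
    if (i == 0 && (j == 0 || type == "fitting")) 0 else NEG
  }
  mm <- function(i, j) state("M", i, j)   # column consuming a[i] and b[j]
  dd <- function(i, j) state("D", i, j)   # gap column consuming b[j]
  ii <- function(i, j) state("I", i, j)   # gap column consuming a[i]
  state <- function(s, i, j) {
    if (s == "M" && (i < 1 || j < 1)) return(NEG)
    if (s == "D" && j < 1) return(NEG)
    if (s == "I" && i < 1) return(NEG)
    key <- paste(s, i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- switch(s,
      M = sub(i, j) + max(start_ok(i - 1, j - 1), mm(i - 1, j - 1),
                          dd(i - 1, j - 1), ii(i - 1, j - 1)),
      D = max(max(start_ok(i, j - 1), mm(i, j - 1), ii(i, j - 1)) + open + ext,
              dd(i, j - 1) + ext),
      I = max(max(start_ok(i - 1, j), mm(i - 1, j), dd(i - 1, j)) + open + ext,
              ii(i - 1, j) + ext))
    memo[[key]] <- out
    out
  }
  ends <- function(i, j) max(start_ok(i, j), mm(i, j), dd(i, j), ii(i, j))
  if (type == "global") return(ends(m, n))
  max(vapply(0:n, function(j) max(start_ok(m, j), mm(m, j), ii(m, j)),
             numeric(1)))
}

## ---- MMEJ product oracle -------------------------------------------------
## Tries every deletion interval of size <= max_del that contains or abuts
## the cut and keeps it iff its junction flanks share >= min_mh identity
## (left-flank suffix vs deleted end, or deleted start vs right flank).
## Returns the deduplicated set of product sequences.
oracle_mmej_products <- function(seq, cut, min_mh, max_del) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  prods <- character(0)
  for (d in 1:min(max_del, L - 1)) {
    for (i in 0:(L - d)) {
      j <- i + d
      if (!(i <= cut && cut <= j)) next
      ## prefix identity: s[i..) vs s[j..)
      kp <- 0
      while (j + kp < L && s[i + kp + 1] == s[j + kp + 1]) kp <- kp + 1
      ## suffix identity: s[..i) vs s[..j)
      ks <- 0
      while (i - ks > 0 && s[i - ks] == s[j - ks]) ks <- ks + 1
      if (max(kp, ks) >= min_mh) {
        prods <- c(prods, paste0(substr(seq, 1, i), substr(seq, j + 1, L)))
      }
    }
  }
  sort(unique(prods))
}

## ---- exact-test oracle ---------------------------------------------------
## Enumerates every 2x2 table with the observed margins; sums the exact
## probability (product of binomial coefficients over the margin total) of
## tables whose (1,1) cell is at least the observed one.
oracle_fisher_one_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  xs <- max(0, k - n):min(m, k)
  probs <- vapply(xs, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(N, k))
  }, numeric(1))
  sum(probs[xs >= a])
}

## ---- misc helpers --------------------------------------------------------
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## events for a pure deletion of [start, start+size) on a model
deletion_events <- function(model, start, size) {
  data.frame(ref_start = start,
             deleted = substr(model$sequence, start + 1, start + size),
             inserted = "", stringsAsFactors = FALSE)
}

## truth lesion builder (exported-internal path used by the simulator)
truth_lesion <- function(events, model, window) {
  amplimosaic:::lesion_from_events(
    amplimosaic::normalize_events(events, model$sequence), model, window)
}

empty_ev <- function() {
  data.frame(ref_start = integer(), deleted = character(),
             inserted = character(), stringsAsFactors = FALSE)
}
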