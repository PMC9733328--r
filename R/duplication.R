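# Internal duplicated segments of a CDS, found by ungapped self-alignment:
# exact k-mer seeds off the main diagonal, extended with an X-drop rule and
# trimmed back to the best-scoring endpoints. Expanding coding sequences of
# repeat-born genes grow partly by repeat expansion and mostly by tandem-like
# segmental duplications; this module recovers those blocks.

#' Find duplicated segments by ungapped self-alignment
#'
#' Exact 12-mer seeds pairing two positions of the same sequence (off the
#' main diagonal) are extended without gaps in both directions, scoring +1
#' per match and -3 per mismatch, stopping when the running score drops 12
#' below its maximum and trimming back to the maximum. Blocks shorter than
#' `min_len` or below `min_identity` are discarded. When `mask_unit` is
#' given, positions inside pure repeat tracts of that unit are masked from
#' seeding — a pure (CAG)n tract is trivially self-similar — although
#' extensions may run into them.
#'
#' @param seq DNA string.
#' @param min_len minimum block length in nt (>= 12).
#' @param min_identity minimum matching fraction in (0.5, 1].
#' @param mask_unit optional 3-letter repeat unit to mask from seeding.
#' @param k seed length.
#' @return data.frame with columns `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open, `a_start < b_start`, intervals disjoint), `length`,
#'   `identity`, ordered by length (desc) then `a_start`.
#' @export
self_alignment_blocks <- function(seq, min_len = 24L, min_identity = 0.9,
                                  mask_unit = NULL, k = 12L) {
  seq <- .validate_dna(seq, allow_n = TRUE, what = "seq")
  stopifnot(min_len >= 12L, min_identity > 0.5, min_identity <= 1, k >= 8L)
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), identity = numeric(0))
  n <- nchar(seq)
  if (n < min_len || n < 2L * k) return(empty)

  masked <- logical(n)
  if (!is.null(mask_unit)) {
    tr <- find_repeat_tracts(seq, mask_unit, min_units = 2L, max_divergence = 0)
    for (i in seq_len(nrow(tr))) masked[(tr$start[i] + 1L):tr$end[i]] <- TRUE
  }
  ch <- .chars(seq)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  # a window is unseedable only when it lies entirely inside a pure tract;
  # windows touching an erosion are informative and may seed
  seedable <- !vapply(1:(n - k + 1L), function(p) all(masked[p:(p + k - 1L)]),
                      logical(1))
  seedable <- seedable & !grepl("N", kmers, fixed = TRUE)
  groups <- split(which(seedable), kmers[seedable])
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(empty)

  # X-drop extension of a seed pair (i, j), i < j, 1-based. b must not run
  # past the sequence and a must not run into b.
  .extend <- function(i, j) {
    d <- j - i
    # rightwards from seed end
    score <- k; best <- k; best_r <- k - 1L  # offsets relative to i
    r <- k
    while (i + r <= n - d && r < d) {
      score <- score + if (ch[i + r] == ch[j + r]) 1L else -3L
      if (score > best) { best <- score; best_r <- r }
      if (best - score >= 12L) break
      r <- r + 1L
    }
    right <- best_r
    # leftwards from seed start
    score <- 0L; best <- 0L; best_l <- 0L
    l <- 1L
    while (i - l >= 1L && right + l <= d - 1L) {
      score <- score + if (ch[i - l] == ch[j - l]) 1L else -3L
      if (score > best) { best <- score; best_l <- l }
      if (best - score >= 12L) break
      l <- l + 1L
    }
    a_s <- i - best_l; a_e <- i + right  # 1-based inclusive
    len <- a_e - a_s + 1L
    matches <- sum(ch[a_s:a_e] == ch[(a_s + d):(a_e + d)])
    list(a_s = a_s, a_e = a_e, d = d, len = len, identity = matches / len)
  }

  blocks <- list()
  claimed <- list()  # per-diagonal claimed a-intervals, to dedupe seeds
  for (g in groups) {
    pairs <- utils::combn(g, 2L, simplify = FALSE)
    for (pr in pairs) {
      i <- pr[1L]; j <- pr[2L]
      d <- j - i
      if (d < k) next  # overlapping copies of the seed itself
      key <- as.character(d)
      cl <- claimed[[key]]
      if (!is.null(cl) && any(i >= cl[, 1L] & i <= cl[, 2L])) next
      ext <- .extend(i, j)
      if (ext$len >= min_len && ext$identity >= min_identity &&
          ext$a_e <= ext$a_s + d - 1L) {
        blocks[[length(blocks) + 1L]] <- ext
      }
      claimed[[key]] <- rbind(cl, c(ext$a_s, ext$a_e))
    }
  }
  if (length(blocks) == 0L) return(empty)

  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(a_start = b$a_s - 1L, a_end = b$a_e,
               b_start = b$a_s - 1L + b$d, b_end = b$a_e + b$d,
               length = b$len, identity = b$identity)
  }))
  out <- unique(out)
  # one block per diagonal extent: among overlapping blocks on the same
  # diagonal keep the longest, then highest identity, then leftmost
  out <- out[order(-out$length, -out$identity, out$a_start), , drop = FALSE]
  diag_id <- out$b_start - out$a_start
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & diag_id == diag_id[i] & seq_len(nrow(out)) > i)
    for (j in later) {
      if (out$a_start[j] < out$a_end[i] && out$a_end[j] > out$a_start[i])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$length, out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile duplication blocks into a decomposition of the sequence
#'
#' Greedy tiling, longest block first (ties broken leftmost); later blocks
#' are trimmed to the positions not already claimed, so tiles never overlap.
#' Positions claimed by no block are reported as `unexplained`; tiles and
#' unexplained intervals together cover the whole sequence.
#'
#' @param seq the DNA string the blocks were computed on.
#' @param blocks data.frame from [self_alignment_blocks()].
#' @return object of class `decomposition`: list with `blocks`, `tiles`
#'   (data.frame start, end, label — both copies of a duplication share a
#'   label) and `unexplained` (data.frame start, end).
#' @export
tile_decomposition <- function(seq, blocks) {
  seq <- .validate_dna(seq, allow_n = TRUE, what = "seq")
  n <- nchar(seq)
  occupied <- logical(n)
  tiles <- list()
  if (nrow(blocks) > 0L) {
    blocks <- blocks[order(-blocks$length, blocks$a_start), , drop = FALSE]
    for (i in seq_len(nrow(blocks))) {
      label <- paste0("D", i)
      placed <- FALSE
      for (iv in list(c(blocks$a_start[i], blocks$a_end[i]),
                      c(blocks$b_start[i], blocks$b_end[i]))) {
        pos <- (iv[1L] + 1L):iv[2L]
        free <- pos[!occupied[pos]]
        if (length(free) == 0L) next
        runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
        for (rn in runs) {
          tiles[[length(tiles) + 1L]] <- data.frame(
            start = rn[1L] - 1L, end = rn[length(rn)], label = label)
          placed <- TRUE
        }
        occupied[free] <- TRUE
      }
      if (!placed) next
    }
  }
  tiles <- if (length(tiles)) do.call(rbind, tiles) else
    data.frame(start = integer(0), end = integer(0), label = character(0))
  free <- which(!occupied)
  unexplained <- if (length(free)) {
    runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
    do.call(rbind, lapply(runs, function(rn) {
      data.frame(start = rn[1L] - 1L, end = rn[length(rn)])
    }))
  } else data.frame(start = integer(0), end = integer(0))
  rownames(tiles) <- NULL
  rownames(unexplained) <- NULL
  structure(list(blocks = blocks, tiles = tiles[order(tiles$start), ],
                 unexplained = unexplained),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Decomposition: %d block(s), %d tile(s), %d unexplained interval(s)\n",
              nrow(x$blocks), nrow(x$tiles), nrow(x$unexplained)))
  invisible(x)
}
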