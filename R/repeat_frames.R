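# Detection of eroded trinucleotide repeat tracts and classification of CDS
# codons into the three repeat reading frames. For a (CAG)n repeat the frames
# encode polyglutamine (CAG), polyserine (AGC) and polyalanine (GCA); coding
# sequences born from such repeats drift between these frames as the repeat
# erodes.

#' Find eroded trinucleotide repeat tracts
#'
#' Greedy seed-and-extend detector. Exact two-unit seeds (any rotation of the
#' unit) are extended one 3-nt window at a time in both directions while the
#' running mismatch fraction (cumulative mismatched bases over bases covered)
#' stays at or below `max_divergence`; a window mismatching at two or more of
#' its three positions terminates extension regardless. Overlapping candidates
#' are resolved longest-first, then leftmost. The reported unit is the
#' lexicographically minimal rotation, with `phase` recording the offset
#' (0-2) of the first full canonical unit within the tract.
#'
#' @param seq DNA string (N allowed; N never matches).
#' @param unit 3-letter repeat unit.
#' @param min_units minimum number of whole units for a reported tract.
#' @param max_divergence maximum running mismatch fraction in `[0, 0.5)`.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `unit` (canonical), `phase`, `n_units`, `purity` (fraction of unit
#'   windows matching the phased unit exactly). Zero rows when nothing found.
#' @export
#' @examples
#' find_repeat_tracts("CAGCAGTAGCAGCAG", "CAG", min_units = 3,
#'                    max_divergence = 0.2)
find_repeat_tracts <- function(seq, unit = "CAG", min_units = 3L,
                               max_divergence = 0) {
  seq <- .validate_dna(seq, allow_n = TRUE, what = "seq")
  unit <- .check_codon(unit)
  stopifnot(min_units >= 2L, max_divergence >= 0, max_divergence < 0.5)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit = character(0), phase = integer(0),
                      n_units = integer(0), purity = numeric(0))
  n <- nchar(seq)
  if (n < 3L * min_units) return(empty)

  canon <- canonical_unit(unit)
  rots <- rotations(canon)
  ch <- .chars(seq)

  # exact 2-unit seeds of any rotation (overlapping occurrences included)
  hex <- substring(seq, 1:(n - 5L), 6:n)
  seeds <- list()
  for (k in 0:2) {
    pos <- which(hex == strrep(rots[k + 1L], 2L))
    if (length(pos)) seeds[[length(seeds) + 1L]] <- cbind(pos = pos, k = k)
  }
  if (length(seeds) == 0L) return(empty)
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[order(seeds[, "pos"]), , drop = FALSE]

  .win_mm <- function(at, r) sum(ch[at:(at + 2L)] != .chars(r))

  # extend every seed, in its own register, under the running mismatch budget
  exts <- list()
  for (i in seq_len(nrow(seeds))) {
    p <- seeds[i, "pos"]; k <- seeds[i, "k"]
    r <- rots[k + 1L]
    cum_mm <- 0L; cum_len <- 6L
    left <- p; right <- p + 6L  # [left, right) 1-based, right exclusive
    repeat {  # rightward
      at <- right
      if (at + 2L > n) break
      wm <- .win_mm(at, r)
      if (wm >= 2L || (cum_mm + wm) / (cum_len + 3L) > max_divergence) break
      cum_mm <- cum_mm + wm; cum_len <- cum_len + 3L; right <- at + 3L
    }
    repeat {  # leftward
      at <- left - 3L
      if (at < 1L) break
      wm <- .win_mm(at, r)
      if (wm >= 2L || (cum_mm + wm) / (cum_len + 3L) > max_divergence) break
      cum_mm <- cum_mm + wm; cum_len <- cum_len + 3L; left <- at
    }
    exts[[i]] <- c(left, right)
  }
  exts <- unique(do.call(rbind, exts))
  exts <- exts[order(exts[, 1L]), , drop = FALSE]

  # merge overlapping extents: register variants of the same tract
  merged <- list()
  cur <- exts[1L, ]
  for (i in seq_len(nrow(exts))[-1L]) {
    if (exts[i, 1L] < cur[2L]) cur[2L] <- max(cur[2L], exts[i, 2L])
    else { merged[[length(merged) + 1L]] <- cur; cur <- exts[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur

  rows <- list()
  for (mv in merged) {
    L <- mv[1L]; R <- mv[2L]
    # register vote: the true register of a point-eroded tract never shows a
    # window with 2+ mismatches (one hit per unit), while shifted registers
    # do wherever adjacent units are both eroded — so minimise heavy-mismatch
    # windows first, then maximise exact windows
    best <- NULL
    for (o in 0:2) {
      w0 <- L + (o - L) %% 3L
      if (R - w0 < 3L) next
      starts <- seq.int(w0, R - 3L, by = 3L)
      wins <- substring(seq, starts, starts + 2L)
      for (kk in 0:2) {
        rc <- .chars(rots[kk + 1L])
        mm <- vapply(wins, function(w) sum(.chars(w) != rc), integer(1),
                     USE.NAMES = FALSE)
        n_exact <- sum(mm == 0L)
        n_heavy <- sum(mm >= 2L)
        if (is.null(best) || n_heavy < best$n_heavy ||
            (n_heavy == best$n_heavy && n_exact > best$n_exact))
          best <- list(n_exact = n_exact, n_heavy = n_heavy, w0 = w0, k = kk)
      }
    }
    if (best$n_exact == 0L) next
    r <- rots[best$k + 1L]
    # re-delimit by walking outward from an exact anchor window in the chosen
    # register, under the same running mismatch budget
    starts <- seq.int(best$w0, best$w0 + 3L * ((R - best$w0) %/% 3L) - 3L,
                      by = 3L)
    exact <- substring(seq, starts, starts + 2L) == r
    runs <- rle(exact)
    run_ends <- cumsum(runs$lengths)
    li <- which.max(ifelse(runs$values, runs$lengths, -1L))
    left <- starts[run_ends[li] - runs$lengths[li] + 1L]
    right <- starts[run_ends[li]] + 3L
    cum_mm <- 0L; cum_len <- right - left
    repeat {
      at <- right
      if (at + 2L > n) break
      wm <- .win_mm(at, r)
      if (wm >= 2L || (cum_mm + wm) / (cum_len + 3L) > max_divergence) break
      cum_mm <- cum_mm + wm; cum_len <- cum_len + 3L; right <- at + 3L
    }
    repeat {
      at <- left - 3L
      if (at < 1L) break
      wm <- .win_mm(at, r)
      if (wm >= 2L || (cum_mm + wm) / (cum_len + 3L) > max_divergence) break
      cum_mm <- cum_mm + wm; cum_len <- cum_len + 3L; left <- at
    }
    # a lone mismatching terminal window is more often flank than repeat;
    # allow one single-mismatch trim per side
    if (right - left > 3L && .win_mm(left, r) == 1L) left <- left + 3L
    if (right - left > 3L && .win_mm(right - 3L, r) == 1L) right <- right - 3L
    len <- right - left
    if (len < 3L * min_units) next
    starts <- seq.int(left, right - 3L, by = 3L)
    wins <- substring(seq, starts, starts + 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      start = left - 1L, end = right - 1L,
      unit = canon, phase = (3L - best$k) %% 3L,
      n_units = len %/% 3L, purity = mean(wins == r))
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify CDS codons into repeat reading frames
#'
#' Each codon is labelled by its minimal Hamming distance to the three
#' rotations of the repeat unit (for CAG: polyQ/polyS/polyA). A codon is
#' assigned to a frame only when that minimum is at most 1 and unique; ties
#' are conservatively `"other"`, and codons containing N are
#' `"undetermined"`. Runs of equal labels partition the codon sequence;
#' `n_switches` counts adjacent run pairs whose labels are both repeat frames
#' and differ (the frameshift events visible in predicted repeat-derived
#' proteins).
#'
#' @param cds DNA string; a trailing partial codon is dropped with a warning.
#' @param unit 3-letter repeat unit.
#' @return object of class `frame_segmentation`: list with `codon_labels`,
#'   `runs` (data.frame start_codon, end_codon half-open, label) and
#'   `n_switches`.
#' @export
classify_codon_frames <- function(cds, unit = "CAG") {
  cds <- .validate_dna(cds, allow_n = TRUE, what = "cds")
  unit <- .check_codon(unit)
  if (nchar(cds) %% 3L != 0L)
    warning("cds length not a multiple of 3; trailing partial codon dropped")
  fn <- frame_names(unit)
  cods <- codons(cds)
  labels <- vapply(cods, function(cod) {
    if (grepl("N", cod, fixed = TRUE)) return("undetermined")
    d <- vapply(fn, hamming, integer(1), a = cod)
    m <- min(d)
    if (m <= 1L && sum(d == m) == 1L) names(fn)[which.min(d)] else "other"
  }, character(1), USE.NAMES = FALSE)
  if (length(labels) == 0L) {
    runs <- data.frame(start_codon = integer(0), end_codon = integer(0),
                       label = character(0))
    return(structure(list(codon_labels = labels, runs = runs, n_switches = 0L),
                     class = "frame_segmentation"))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  runs <- data.frame(start_codon = c(0L, ends[-length(ends)]),
                     end_codon = ends, label = r$values,
                     stringsAsFactors = FALSE)
  rep_frames <- names(fn)
  lab <- runs$label
  n_switches <- if (nrow(runs) < 2L) 0L else
    sum(lab[-1L] %in% rep_frames & lab[-nrow(runs)] %in% rep_frames &
          lab[-1L] != lab[-nrow(runs)])
  structure(list(codon_labels = labels, runs = runs,
                 n_switches = as.integer(n_switches)),
            class = "frame_segmentation")
}

#' @export
print.frame_segmentation <- function(x, ...) {
  cat(sprintf("Frame segmentation: %d codons, %d runs, %d frame switches\n",
              length(x$codon_labels), nrow(x$runs), x$n_switches))
  invisible(x)
}

#' Amino-acid composition of a protein
#'
#' Fractions over counted residues (stop characters `*` are ignored), with
#' the serine fraction — the signature of polyS-frame repeat expansion —
#' reported alongside.
#'
#' @param protein amino-acid string (single letters; `*` ignored).
#' @return list with `fractions` (named numeric, sums to 1) and `serine`.
#' @export
aa_composition <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L)
    stop("protein must be a single string", call. = FALSE)
  res <- .chars(toupper(protein))
  res <- res[res != "*"]
  if (length(res) == 0L) stop("empty protein", call. = FALSE)
  if (any(!res %in% c(LETTERS)))
    stop("protein contains non-letter residues", call. = FALSE)
  fr <- table(res) / length(res)
  fractions <- stats::setNames(as.numeric(fr), names(fr))
  list(fractions = fractions,
       serine = if ("S" %in% names(fractions)) fractions[["S"]] else 0)
}

#' Joint repeat-frame report for a coding sequence
#'
#' Combines tract detection, frame segmentation and amino-acid composition,
#' and counts in-frame stop codons when the same nucleotides are read in each
#' of the three repeat frame registers (offsets 0-2). When a tract is present
#' the offsets are mapped to frame names using the register of the longest
#' tract; a pure polyQ-register repeat carrying one TAG shows 1 stop in the
#' polyQ reading and 0 in the polyS/polyA readings of the same sequence.
#'
#' @param cds DNA string (the CDS region to analyse).
#' @param unit 3-letter repeat unit.
#' @param min_units,max_divergence tract-detection settings, see
#'   [find_repeat_tracts()].
#' @return object of class `repeat_frame_report`: list with `tracts`,
#'   `segmentation`, `composition` (NULL when the CDS is too short to
#'   translate) and `frame_stops` (data.frame offset, codon, frame, n_stops).
#' @export
repeat_frame_report <- function(cds, unit = "CAG", min_units = 2L,
                                max_divergence = 0.2) {
  cds <- .validate_dna(cds, allow_n = TRUE, what = "cds")
  unit <- .check_codon(unit)
  tracts <- find_repeat_tracts(cds, unit, min_units, max_divergence)
  seg <- classify_codon_frames(cds, unit)
  prot <- suppressWarnings(translate_cds(cds))
  comp <- if (nchar(gsub("*", "", prot, fixed = TRUE)) > 0L)
    aa_composition(prot) else NULL

  canon <- canonical_unit(unit)
  rots <- rotations(canon)
  fn <- frame_names(unit)
  frame_of <- rep(NA_character_, 3L)
  codon_of <- rep(NA_character_, 3L)
  if (nrow(tracts) > 0L) {
    main <- tracts[which.max(tracts$n_units), ]
    p <- main$start + main$phase  # 0-based position of a canonical unit
    for (j in 0:2) {
      cod <- rots[((j - p) %% 3L) + 1L]
      codon_of[j + 1L] <- cod
      frame_of[j + 1L] <- names(fn)[match(cod, fn)]
    }
  }
  n_stops <- vapply(0:2, function(j) {
    sum(codons(cds, j) %in% STOP_CODONS)
  }, numeric(1))
  frame_stops <- data.frame(offset = 0:2, codon = codon_of, frame = frame_of,
                            n_stops = as.integer(n_stops),
                            stringsAsFactors = FALSE)
  structure(list(tracts = tracts, segmentation = seg, composition = comp,
                 frame_stops = frame_stops),
            class = "repeat_frame_report")
}

#' @export
print.repeat_frame_report <- function(x, ...) {
  cat(sprintf("Repeat-frame report: %d tract(s), %d frame switch(es)\n",
              nrow(x$tracts), x$segmentation$n_switches))
  print(x$frame_stops)
  invisible(x)
}
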