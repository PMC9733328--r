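# Internal helpers shared across modules. All coordinates in this package are
# 0-based half-open unless a function says otherwise.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.validate_dna <- function(x, allow_n = TRUE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regmatches(x, regexpr(sprintf("[^%s]", alphabet), x))
  if (length(bad) > 0L)
    stop(what, " contains a character outside {", paste(strsplit(alphabet, "")[[1]], collapse = ","),
         "}: '", bad, "'", call. = FALSE)
  x
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  x <- .validate_dna(x, allow_n = TRUE, what = "sequence")
  paste(rev(.chars(chartr("ACGTN", "TGCAN", x))), collapse = "")
}

# All three left-rotations of a trinucleotide unit; rotations(u)[k+1] is u
# rotated left by k.
rotations <- function(unit) {
  stopifnot(nchar(unit) == 3L)
  vapply(0:2, function(k) {
    paste0(substr(unit, k + 1L, 3L), substr(unit, 1L, k))
  }, character(1))
}

canonical_unit <- function(unit) min(rotations(unit))

#' Reading-frame names of a trinucleotide repeat unit
#'
#' The three reading frames of a repeat unit are its three rotations. For
#' units whose rotation set is {CAG, AGC, GCA} the homopolymer names
#' polyQ/polyS/polyA are used; otherwise frames are named frame0..frame2 in
#' rotation order.
#'
#' @param unit 3-letter DNA repeat unit.
#' @return named character vector mapping frame name to frame codon.
#' @export
#' @examples
#' frame_names("CAG")
frame_names <- function(unit) {
  rots <- rotations(toupper(unit))
  std <- c(CAG = "polyQ", AGC = "polyS", GCA = "polyA")
  if (all(rots %in% names(std))) {
    stats::setNames(rots, unname(std[rots]))
  } else {
    stats::setNames(rots, paste0("frame", 0:2))
  }
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(.chars(a) != .chars(b))
}

# Complete codons of a sequence read from `offset` (0-based); trailing partial
# codon dropped.
codons <- function(seq, offset = 0L) {
  n <- nchar(seq)
  if (n - offset < 3L) return(character(0))
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Convert between 0-based half-open and 1-based closed intervals
#'
#' Internally all intervals are 0-based half-open (BED convention); reports
#' for human reading may use 1-based closed coordinates. The two conversions
#' are exact inverses.
#'
#' @param start,end interval bounds in the source convention.
#' @return a list with elements `start` and `end` in the target convention.
#' @export
to_onebased <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  list(start = start + 1L, end = end)
}

#' @rdname to_onebased
#' @export
to_zerobased <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  list(start = start - 1L, end = end)
}
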