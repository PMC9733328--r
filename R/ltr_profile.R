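# Column-wise divergence of an element-family alignment against its
# consensus, and motif presence/co-occurrence statistics. This is the
# machinery behind per-position nucleotide exchange-rate profiles of an LTR
# subfamily and censuses such as "what fraction of copies still carry the
# start codon the original insertion brought in".

#' Construct a family alignment
#'
#' A gapped alignment of element copies to a family consensus. All rows must
#' have equal width. Consensus coordinates (0-based) index the non-gap
#' columns of the consensus row.
#'
#' @param rows named character vector of gapped rows (alphabet ACGTN-).
#' @param consensus_id id of the consensus row; default: the first row.
#' @return object of class `family_alignment`: list with `consensus`,
#'   `consensus_id`, `copies` (named vector), `width`, `col_of_pos`
#'   (consensus position p, 0-based, sits in column `col_of_pos[p + 1]`).
#' @export
family_alignment <- function(rows, consensus_id = NULL) {
  if (length(rows) == 0L) stop("alignment has zero rows", call. = FALSE)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named", call. = FALSE)
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  if (any(grepl("[^ACGTN-]", rows)))
    stop("alignment contains characters outside {A,C,G,T,N,-}", call. = FALSE)
  ci <- if (is.null(consensus_id)) 1L else match(consensus_id, names(rows))
  if (is.na(ci))
    stop("consensus id '", consensus_id, "' not present in alignment",
         call. = FALSE)
  consensus <- rows[[ci]]
  copies <- rows[-ci]
  if (length(copies) == 0L) stop("alignment has no copy rows", call. = FALSE)
  col_of_pos <- which(.chars(consensus) != "-")
  structure(list(consensus = consensus, consensus_id = names(rows)[ci],
                 copies = copies, width = unname(widths[1L]),
                 col_of_pos = col_of_pos),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("Family alignment: consensus '%s' (%d positions), %d copies, width %d\n",
              x$consensus_id, length(x$col_of_pos), length(x$copies), x$width))
  invisible(x)
}

.copy_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$copies), "", fixed = TRUE))
  rownames(m) <- names(aln$copies)
  m
}

#' Per-position nucleotide exchange rates against the consensus
#'
#' For every consensus position, the fraction of informative copies (non-gap,
#' non-N at that column) whose base differs from the consensus base. Copies
#' gapped at a column drop out of that column's denominator; positions with
#' no informative copy are flagged undefined (rate `NA`), never reported as
#' zero.
#'
#' @param aln a [family_alignment].
#' @return object of class `exchange_profile`: data.frame with `pos`
#'   (0-based consensus coordinate), `consensus_base`, `n_informative`,
#'   `n_mismatch`, `rate`, `undefined`.
#' @export
column_exchange_rates <- function(aln) {
  stopifnot(inherits(aln, "family_alignment"))
  m <- .copy_matrix(aln)[, aln$col_of_pos, drop = FALSE]
  cons <- .chars(aln$consensus)[aln$col_of_pos]
  informative <- m != "-" & m != "N"
  n_inf <- colSums(informative)
  n_mm <- colSums(informative & (m != matrix(cons, nrow(m), ncol(m), byrow = TRUE)))
  rate <- ifelse(n_inf > 0L, n_mm / n_inf, NA_real_)
  out <- data.frame(pos = seq_along(cons) - 1L, consensus_base = cons,
                    n_informative = as.integer(n_inf),
                    n_mismatch = as.integer(n_mm),
                    rate = rate, undefined = n_inf == 0L)
  class(out) <- c("exchange_profile", "data.frame")
  out
}

.window_strings <- function(aln, motif, consensus_start) {
  motif <- .validate_dna(motif, allow_n = FALSE, what = "motif")
  len <- nchar(motif)
  npos <- length(aln$col_of_pos)
  if (consensus_start < 0L || consensus_start + len > npos)
    stop("motif window [", consensus_start, ", ", consensus_start + len,
         ") outside consensus coordinates [0, ", npos, ")", call. = FALSE)
  cols <- aln$col_of_pos[(consensus_start + 1L):(consensus_start + len)]
  m <- .copy_matrix(aln)[, cols, drop = FALSE]
  list(windows = apply(m, 1L, paste, collapse = ""),
       gapped = apply(m == "-", 1L, any),
       motif = motif)
}

#' Fraction of copies carrying a motif at a consensus window
#'
#' Copies with any gap in the window are excluded from both numerator and
#' denominator. An all-gapped window yields an undefined fraction (`NA`)
#' with an explicit flag.
#'
#' @param aln a [family_alignment].
#' @param motif DNA motif (e.g. `"ATG"`).
#' @param consensus_start 0-based consensus coordinate of the window start.
#' @return list with `fraction`, `n_informative`, `n_carriers`, `undefined`.
#' @export
motif_presence <- function(aln, motif, consensus_start) {
  stopifnot(inherits(aln, "family_alignment"))
  w <- .window_strings(aln, motif, consensus_start)
  inf <- !w$gapped
  n_inf <- sum(inf)
  n_car <- sum(w$windows[inf] == w$motif)
  list(fraction = if (n_inf > 0L) n_car / n_inf else NA_real_,
       n_informative = n_inf, n_carriers = n_car, undefined = n_inf == 0L)
}

#' Co-occurrence census of two motif windows across copies
#'
#' Computed on the copies informative (gap-free) at both windows, so the
#' additivity identity `at_least_one = a_only + b_only + both` holds exactly.
#' This is the structure of a start-codon census over an LTR family: some
#' copies retain only the first AUG, some only the second, some both.
#'
#' @param aln a [family_alignment].
#' @param motif_a,motif_b DNA motifs.
#' @param start_a,start_b 0-based consensus coordinates of each window.
#' @return list with `a_only`, `b_only`, `both`, `at_least_one` (fractions),
#'   marginal fractions `a_marginal`, `b_marginal`, and `n_informative`.
#' @export
motif_cooccurrence <- function(aln, motif_a, start_a, motif_b, start_b) {
  stopifnot(inherits(aln, "family_alignment"))
  wa <- .window_strings(aln, motif_a, start_a)
  wb <- .window_strings(aln, motif_b, start_b)
  inf <- !wa$gapped & !wb$gapped
  n_inf <- sum(inf)
  if (n_inf == 0L)
    return(list(a_only = NA_real_, b_only = NA_real_, both = NA_real_,
                at_least_one = NA_real_, a_marginal = NA_real_,
                b_marginal = NA_real_, n_informative = 0L))
  a <- wa$windows[inf] == wa$motif
  b <- wb$windows[inf] == wb$motif
  list(a_only = mean(a & !b), b_only = mean(!a & b), both = mean(a & b),
       at_least_one = mean(a | b),
       a_marginal = mean(a), b_marginal = mean(b),
       n_informative = n_inf)
}
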