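# Exhaustive combinatorics of point-mutation neighbourhoods of codons.
# These functions quantify why an expanding (CAG)n repeat tolerates point
# mutations so well in its serine (AGC) and alanine (GCA) reading frames:
# the mutational neighbourhood of those codons contains no stop codon at
# Hamming distance 1, while the glutamine (CAG) frame gains TAG from a single
# C-to-T change.

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L)
    stop("codon must be a single string", call. = FALSE)
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 letters over {A,C,G,T}: got '", codon, "'",
         call. = FALSE)
  codon
}

.check_distance <- function(distance) {
  if (!distance %in% 1:3) stop("distance must be 1, 2 or 3", call. = FALSE)
  as.integer(distance)
}

#' Enumerate all codons at an exact point-mutation distance
#'
#' Generates every codon reachable from `codon` by changing exactly
#' `distance` of its three positions (each to one of the three alternative
#' bases), classifies each outcome against the genetic code, and tallies the
#' classes. The outcome count is `choose(3, distance) * 3^distance`:
#' 9 at distance 1, 27 at distance 2, 27 at distance 3.
#'
#' Classification: an outcome translating to `"*"` is *nonsense*; one
#' translating to the same amino acid as the source (and not a stop) is
#' *silent*; anything else is *missense*. Note that for a stop-codon source,
#' mutants that remain stops are still counted as nonsense.
#'
#' @param codon source codon (3 letters over ACGT).
#' @param distance number of simultaneous point mutations (1, 2 or 3).
#' @param code codon table, defaults to the standard code.
#' @return an object of class `mutant_profile`: list with `source`,
#'   `distance`, `outcomes` (data.frame of codon, aa, class in lexicographic
#'   codon order) and `counts` (named totals silent/missense/nonsense).
#' @export
#' @examples
#' p <- enumerate_point_mutants("CAG", 1)
#' p$counts  # one nonsense outcome: TAG
enumerate_point_mutants <- function(codon, distance = 1L, code = genetic_code()) {
  codon <- .check_codon(codon)
  distance <- .check_distance(distance)
  src <- .chars(codon)
  pos_sets <- utils::combn(3L, distance, simplify = FALSE)
  muts <- character(0)
  for (ps in pos_sets) {
    alts <- lapply(ps, function(p) setdiff(DNA_BASES, src[p]))
    grid <- expand.grid(alts, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      m <- src
      m[ps] <- as.character(grid[r, ])
      muts <- c(muts, paste(m, collapse = ""))
    }
  }
  muts <- sort(muts)  # deterministic lexicographic order; exact-distance sets are disjoint
  aa <- unname(code[muts])
  src_aa <- unname(code[codon])
  class <- ifelse(aa == "*", "nonsense",
                  ifelse(aa == src_aa, "silent", "missense"))
  counts <- c(silent = sum(class == "silent"),
              missense = sum(class == "missense"),
              nonsense = sum(class == "nonsense"))
  structure(list(source = codon, distance = distance,
                 outcomes = data.frame(codon = muts, aa = aa, class = class,
                                       stringsAsFactors = FALSE),
                 counts = counts),
            class = "mutant_profile")
}

#' @export
print.mutant_profile <- function(x, ...) {
  cat(sprintf("Point-mutant profile of %s at distance %d: %d outcomes\n",
              x$source, x$distance, nrow(x$outcomes)))
  cat(sprintf("  silent %d, missense %d, nonsense %d\n",
              x$counts["silent"], x$counts["missense"], x$counts["nonsense"]))
  invisible(x)
}

#' Amino acids reachable from a codon by point mutation
#'
#' The distinct non-silent amino acids reachable at the given distance, plus
#' counts of nonsense and silent outcomes. For the serine codon AGC at
#' distance 1 this yields the six amino acids Gly, Arg, Cys, Asn, Thr, Ile
#' and zero stops, with one silent change (AGT).
#'
#' @inheritParams enumerate_point_mutants
#' @return list with `amino_acids` (sorted distinct single letters, source
#'   amino acid excluded), `n_stop`, `n_silent`, `n_outcomes`.
#' @export
amino_reachability <- function(codon, distance = 1L, code = genetic_code()) {
  prof <- enumerate_point_mutants(codon, distance, code)
  out <- prof$outcomes
  list(amino_acids = sort(unique(out$aa[out$class == "missense"])),
       n_stop = unname(prof$counts["nonsense"]),
       n_silent = unname(prof$counts["silent"]),
       n_outcomes = nrow(out))
}

#' Probability that a random point-mutation combination creates a stop
#'
#' With all outcomes equiprobable (the default) this is simply the nonsense
#' count over the outcome count — e.g. 1/27 (about 3.7%) for two simultaneous
#' hits on CAG. Supplying `kappa` weights each mutated site's target base by
#' transition/transversion bias: a transition (A<->G, C<->T) has weight
#' `kappa`, each transversion weight 1, normalised per site.
#'
#' @inheritParams enumerate_point_mutants
#' @param kappa optional transition/transversion ratio; `NULL` (default)
#'   means unweighted (equivalent to `kappa = 1`).
#' @return numeric fraction in `[0, 1]`.
#' @export
#' @examples
#' stop_fraction("CAG", 2)  # 1/27
stop_fraction <- function(codon, distance = 1L, kappa = NULL,
                          code = genetic_code()) {
  prof <- enumerate_point_mutants(codon, distance, code)
  out <- prof$outcomes
  if (is.null(kappa)) return(unname(prof$counts["nonsense"]) / nrow(out))
  stopifnot(is.numeric(kappa), kappa > 0)
  src <- .chars(prof$source)
  w <- vapply(out$codon, function(m) {
    mc <- .chars(m)
    diff <- which(mc != src)
    prod(vapply(diff, function(p) {
      .base_weight(src[p], mc[p], kappa) / (kappa + 2)
    }, numeric(1)))
  }, numeric(1))
  sum(w[out$class == "nonsense"]) / sum(w)
}

.base_weight <- function(from, to, kappa) {
  purines <- c("A", "G")
  transition <- (from %in% purines) == (to %in% purines)
  if (transition) kappa else 1
}

#' Minimum point mutations to a stop codon, per repeat reading frame
#'
#' For each of the three reading frames of a trinucleotide repeat unit
#' (the three rotations of the unit), returns the exact Hamming distance from
#' that frame's codon to the nearest stop codon. For CAG this is
#' polyQ = 1 (the single C-to-T change giving TAG), polyS = 2, polyA = 2:
#' a single point mutation in a (CAG)n repeat can create a stop only in the
#' polyQ frame.
#'
#' @param unit a 3-letter DNA repeat unit.
#' @return named integer vector (names from [frame_names()]), with the frame
#'   codon attached as the `"codons"` attribute.
#' @export
min_mutations_to_stop_per_frame <- function(unit) {
  unit <- .check_codon(unit)
  fn <- frame_names(unit)
  mins <- vapply(fn, function(cod) {
    min(vapply(STOP_CODONS, hamming, integer(1), a = cod))
  }, integer(1))
  attr(mins, "codons") <- fn
  mins
}
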