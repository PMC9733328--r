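# Assembly of spliced transcripts from a genome and an exon model, splice-site
# checking, and ORF inference from a designated start codon.

#' Splice a transcript from a genome sequence and exon model
#'
#' Extracts and concatenates the exons; minus-strand models are
#' reverse-complemented at extraction so all downstream analyses see the
#' sense strand. Each intron is checked for the canonical GT..AG dinucleotides
#' on the transcribed strand; non-canonical introns are flagged (with a
#' warning), never rejected.
#'
#' @param genome single DNA string (the parent sequence of the model).
#' @param model an [exon_model].
#' @param id transcript id.
#' @return object of class `transcript`: list with `id`, `residues`,
#'   `exon_map` (data.frame t_start, t_end, g_start, g_end, 0-based half-open,
#'   in transcript order) and `splice_flags` (per-intron logical, transcript
#'   order).
#' @export
splice_transcript <- function(genome, model, id = model$seq_id) {
  genome <- .validate_dna(genome, allow_n = TRUE, what = "genome")
  stopifnot(inherits(model, "exon_model"))
  ex <- model$exons
  if (any(ex[, "start"] < 0L) || any(ex[, "end"] > nchar(genome)))
    stop("exon interval out of genome bounds", call. = FALSE)

  pieces <- substring(genome, ex[, "start"] + 1L, ex[, "end"])
  introns <- if (nrow(ex) > 1L)
    substring(genome, ex[-nrow(ex), "end"] + 1L, ex[-1L, "start"]) else character(0)

  if (model$strand == "-") {
    pieces <- rev(vapply(pieces, revcomp, character(1), USE.NAMES = FALSE))
    introns <- rev(vapply(introns, revcomp, character(1), USE.NAMES = FALSE))
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  residues <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  t_end <- cumsum(lens)
  exon_map <- data.frame(t_start = c(0L, t_end[-length(t_end)]),
                         t_end = t_end,
                         g_start = ex[, "start"], g_end = ex[, "end"])
  splice_flags <- vapply(introns, function(intr) {
    nchar(intr) >= 4L && startsWith(intr, "GT") && endsWith(intr, "AG")
  }, logical(1), USE.NAMES = FALSE)
  if (any(!splice_flags))
    warning(sprintf("%d non-canonical intron(s) in transcript '%s'",
                    sum(!splice_flags), id))
  structure(list(id = id, residues = residues, exon_map = exon_map,
                 splice_flags = splice_flags, strand = model$strand),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("Transcript '%s': %d nt, %d exon(s), %d/%d canonical intron(s)\n",
              x$id, nchar(x$residues), nrow(x$exon_map),
              sum(x$splice_flags), length(x$splice_flags)))
  invisible(x)
}

.transcript_seq <- function(transcript) {
  if (inherits(transcript, "transcript")) transcript$residues
  else .validate_dna(transcript, allow_n = TRUE, what = "transcript")
}

#' Find an open reading frame in a transcript
#'
#' Scans 5' to 3'. Under the default `"first_aug"` policy the leftmost ATG is
#' the start; an integer `start_policy` designates a fixed transcript offset
#' (0-based) which must hold an ATG — needed to probe alternative starts such
#' as the second codon of an AUGAUG arrangement. Translation proceeds to the
#' first in-frame stop, or to the transcript end (`terminated = FALSE`) when
#' none occurs before it. Absence of any ATG under `"first_aug"` is an
#' explicit no-ORF result, not an error.
#'
#' @param transcript a `transcript` object or DNA string.
#' @param start_policy `"first_aug"` or a 0-based integer offset.
#' @return object of class `orf_record`: list with `found`, `start`, `stop`
#'   (offset just past the stop codon, or transcript length if unterminated),
#'   `n_codons` (excluding the stop), `protein`, `terminated`,
#'   `partial_trailing` (nt dropped at the 3' end).
#' @export
find_orf <- function(transcript, start_policy = "first_aug") {
  seq <- .transcript_seq(transcript)
  n <- nchar(seq)
  if (identical(start_policy, "first_aug")) {
    start <- as.integer(regexpr("ATG", seq, fixed = TRUE)) - 1L
    if (start < 0L)
      return(structure(list(found = FALSE, start = NA_integer_,
                            stop = NA_integer_, n_codons = 0L, protein = "",
                            terminated = FALSE, partial_trailing = NA_integer_),
                       class = "orf_record"))
  } else {
    start <- as.integer(start_policy)
    if (is.na(start) || start < 0L || start + 3L > n)
      stop("start offset out of transcript bounds", call. = FALSE)
    if (substring(seq, start + 1L, start + 3L) != "ATG")
      stop("no ATG at designated start offset ", start, call. = FALSE)
  }
  cods <- codons(seq, start)
  partial <- (n - start) %% 3L
  stop_idx <- which(cods %in% STOP_CODONS)
  if (length(stop_idx) > 0L) {
    k <- stop_idx[1L]
    coding <- cods[seq_len(k - 1L)]
    stop_off <- start + 3L * k
    terminated <- TRUE
  } else {
    coding <- cods
    stop_off <- n
    terminated <- FALSE
  }
  code <- genetic_code()
  aa <- unname(code[coding])
  aa[is.na(aa)] <- "X"
  structure(list(found = TRUE, start = start, stop = stop_off,
                 n_codons = length(coding),
                 protein = paste(aa, collapse = ""),
                 terminated = terminated,
                 partial_trailing = if (terminated) 0L else partial),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  if (!x$found) {
    cat("No ORF found\n")
  } else {
    cat(sprintf("ORF at [%d, %d): %d codons, %s\n", x$start, x$stop,
                x$n_codons,
                if (x$terminated) "terminated" else "runs to transcript end"))
  }
  invisible(x)
}

#' CDS report: ORF joined with repeat-frame analysis
#'
#' Infers the ORF, analyses the CDS (start codon through the last codon
#' before the stop) with [repeat_frame_report()], and quantifies repeat
#' content left downstream of the stop — in weakly coding orthologues most of
#' the repeat sits 3' of a short CDS.
#'
#' @inheritParams find_orf
#' @param unit repeat unit for the frame analysis.
#' @param min_units,max_divergence tract-detection settings for downstream
#'   repeat counting (pure tracts, divergence 0, are counted downstream).
#' @return list of class `cds_report` with `orf`, `cds_n_codons`,
#'   `frame_report` (NULL when no ORF), `downstream_repeat_units` (total
#'   whole units in pure tracts 3' of the stop) and `partial_trailing`.
#' @export
cds_report <- function(transcript, start_policy = "first_aug", unit = "CAG",
                       min_units = 2L, max_divergence = 0.2) {
  seq <- .transcript_seq(transcript)
  orf <- find_orf(transcript, start_policy)
  if (!orf$found) {
    return(structure(list(orf = orf, cds_n_codons = 0L, frame_report = NULL,
                          downstream_repeat_units = 0L,
                          partial_trailing = NA_integer_),
                     class = "cds_report"))
  }
  cds_end <- if (orf$terminated) orf$stop - 3L else orf$stop - orf$partial_trailing
  cds <- substring(seq, orf$start + 1L, cds_end)
  fr <- if (nchar(cds) >= 3L)
    repeat_frame_report(cds, unit, min_units = min_units,
                        max_divergence = max_divergence) else NULL
  downstream <- substring(seq, orf$stop + 1L, nchar(seq))
  dn_units <- 0L
  if (nchar(downstream) >= 6L) {
    tr <- find_repeat_tracts(downstream, unit, min_units = 2L,
                             max_divergence = 0)
    dn_units <- sum(tr$n_units)
  }
  structure(list(orf = orf, cds_n_codons = orf$n_codons, frame_report = fr,
                 downstream_repeat_units = as.integer(dn_units),
                 partial_trailing = orf$partial_trailing),
            class = "cds_report")
}

#' @export
print.cds_report <- function(x, ...) {
  print(x$orf)
  cat(sprintf("CDS: %d codons; %d repeat unit(s) downstream of stop\n",
              x$cds_n_codons, x$downstream_repeat_units))
  invisible(x)
}
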