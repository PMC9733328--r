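# Seeded generators producing every input class the pipeline consumes, with
# planted ground truth, so all stages are testable without genome downloads.
# Each generator is a pure function of its parameters and seed: the same call
# regenerates byte-identical output.

.rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                               collapse = "")

# replace every occurrence of a motif in a string by mutating its last base
.scrub_motif <- function(seq, motif) {
  repeat {
    at <- regexpr(motif, seq, fixed = TRUE)
    if (at < 0L) return(seq)
    p <- as.integer(at) + nchar(motif) - 1L
    cur <- substring(seq, p, p)
    substr(seq, p, p) <- setdiff(DNA_BASES, cur)[1L]
  }
}

#' Generate an LTR family alignment with planted divergence and motifs
#'
#' Draws a random consensus and `n_copies` copies, substituting each copy
#' position independently with the per-position probability in
#' `rate_profile`, then (optionally) planting two motif windows according to
#' `motif_plan` — the structure of a start-codon census where copies carry
#' the first AUG only, the second only, both, or neither. With
#' `exact_fractions = TRUE` carriers are assigned deterministically (the
#' first `floor(f * n)` copies per category) so census statistics are exact;
#' the sampled mode draws categories per copy. `indel_rate` deletes copy
#' positions (gap characters) outside the motif windows.
#'
#' @param consensus_len consensus length in nt.
#' @param n_copies number of copies.
#' @param rate_profile per-position substitution probability, recycled to
#'   `consensus_len`.
#' @param indel_rate per-position deletion (gap) probability in copies.
#' @param motif_plan `NULL`, or list with `motif` (e.g. "ATG"), `start_a`,
#'   `start_b` (0-based consensus coordinates) and `fractions`
#'   (c(a_only, b_only, both), summing to <= 1).
#' @param seed integer seed.
#' @param exact_fractions deterministic carrier assignment (default) versus
#'   sampled categories.
#' @return list with `alignment` (a [family_alignment]), `truth` (list with
#'   per-copy `categories`, the `rate_profile` used, and the motif plan) —
#'   regeneration from the same seed is byte-identical.
#' @export
gen_ltr_family <- function(consensus_len = 300L, n_copies = 100L,
                           rate_profile = 0.05, indel_rate = 0,
                           motif_plan = NULL, seed = 1L,
                           exact_fractions = TRUE) {
  stopifnot(consensus_len >= 10L, n_copies >= 1L)
  rate_profile <- rep_len(rate_profile, consensus_len)
  stopifnot(all(rate_profile >= 0), all(rate_profile <= 1))
  motif_cols <- integer(0)
  if (!is.null(motif_plan)) {
    stopifnot(all(c("motif", "start_a", "start_b", "fractions") %in%
                    names(motif_plan)))
    if (sum(motif_plan$fractions) > 1 + 1e-12)
      stop("motif_plan fractions must sum to <= 1", call. = FALSE)
    ml <- nchar(motif_plan$motif)
    wa <- motif_plan$start_a + seq_len(ml)
    wb <- motif_plan$start_b + seq_len(ml)
    if (max(wa, wb) > consensus_len)
      stop("motif windows outside consensus", call. = FALSE)
    motif_cols <- c(wa, wb)
  }
  set.seed(seed)
  cons <- .chars(.rand_dna(consensus_len))
  if (!is.null(motif_plan)) {
    cons[wa] <- .chars(motif_plan$motif)
    cons[wb] <- .chars(motif_plan$motif)
  }

  categories <- rep("neither", n_copies)
  if (!is.null(motif_plan)) {
    f <- motif_plan$fractions
    if (exact_fractions) {
      # epsilon guards against floor(0.29 * 100) == 28 style FP surprises
      na <- floor(f[1L] * n_copies + 1e-9)
      nb <- floor(f[2L] * n_copies + 1e-9)
      nab <- floor(f[3L] * n_copies + 1e-9)
      categories <- rep(c("a_only", "b_only", "both", "neither"),
                        c(na, nb, nab, n_copies - na - nb - nab))
    } else {
      categories <- sample(c("a_only", "b_only", "both", "neither"),
                           n_copies, replace = TRUE,
                           prob = c(f, 1 - sum(f)))
    }
  }

  copies <- character(n_copies)
  for (i in seq_len(n_copies)) {
    cp <- cons
    hit <- stats::runif(consensus_len) < rate_profile
    for (p in which(hit)) cp[p] <- sample(setdiff(DNA_BASES, cons[p]), 1L)
    if (!is.null(motif_plan)) {
      mot <- .chars(motif_plan$motif)
      cat_i <- categories[i]
      for (side in c("a", "b")) {
        win <- if (side == "a") wa else wb
        carries <- cat_i == "both" || cat_i == paste0(side, "_only")
        if (carries) {
          cp[win] <- mot
        } else if (all(cp[win] == mot)) {
          p <- win[length(win)]
          cp[p] <- sample(setdiff(DNA_BASES, mot[length(mot)]), 1L)
        }
      }
    }
    if (indel_rate > 0) {
      del <- stats::runif(consensus_len) < indel_rate
      del[motif_cols] <- FALSE
      cp[del] <- "-"
    }
    copies[i] <- paste(cp, collapse = "")
  }
  rows <- stats::setNames(c(paste(cons, collapse = ""), copies),
                          c("consensus", sprintf("copy_%03d", seq_len(n_copies))))
  list(alignment = family_alignment(rows, consensus_id = "consensus"),
       truth = list(categories = categories, rate_profile = rate_profile,
                    motif_plan = motif_plan, seed = seed))
}

#' Generate a repeat-expansion CDS with erosion and planted duplications
#'
#' Builds ATG + a framed repeat body of `n_units` codons of the chosen
#' reading frame (polyS = AGC, polyQ = CAG, polyA = GCA for the CAG unit) +
#' a terminal TAA. Each body codon is eroded with probability `erosion_rate`
#' by one random point mutation, resampled (up to 25 attempts) so that no
#' stop codon enters the chosen frame; infeasible constraints raise an error.
#' Planted duplications then copy codon-aligned segments of the requested
#' lengths to the position immediately after their source, preserving the
#' frame. Duplication breakpoints are reported in final-CDS coordinates.
#'
#' @param n_units number of repeat codons in the body.
#' @param erosion_rate per-codon erosion probability.
#' @param frame frame name for the `unit` (see [frame_names()]).
#' @param planted_dups integer vector of duplication lengths in nt (rounded
#'   up to multiples of 3).
#' @param seed integer seed.
#' @param unit repeat unit.
#' @return list with `cds`, `protein`, and `truth` (list with `eroded_codons`
#'   — 0-based body codon indices pre-duplication — and `dups`, a data.frame
#'   of a/b intervals in 0-based final-CDS coordinates).
#' @export
gen_repeat_cds <- function(n_units = 100L, erosion_rate = 0.1,
                           frame = "polyS", planted_dups = integer(0),
                           seed = 1L, unit = "CAG") {
  stopifnot(n_units >= 2L, erosion_rate >= 0, erosion_rate < 1)
  fn <- frame_names(unit)
  if (!frame %in% names(fn))
    stop("unknown frame '", frame, "'", call. = FALSE)
  codon <- fn[[frame]]
  set.seed(seed)
  body <- rep(codon, n_units)
  eroded <- which(stats::runif(n_units) < erosion_rate)
  for (i in eroded) {
    ok <- FALSE
    for (attempt in 1:25) {
      mut <- .chars(codon)
      p <- sample.int(3L, 1L)
      mut[p] <- sample(setdiff(DNA_BASES, mut[p]), 1L)
      cand <- paste(mut, collapse = "")
      if (!cand %in% STOP_CODONS) { body[i] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not erode codon without creating a stop",
                  call. = FALSE)
  }

  dups <- data.frame(a_start = integer(0), a_end = integer(0),
                     b_start = integer(0), b_end = integer(0))
  for (len in planted_dups) {
    len <- 3L * ((as.integer(len) + 2L) %/% 3L)
    nb <- length(body)
    seg_codons <- len %/% 3L
    if (seg_codons >= nb) stop("planted duplication longer than body",
                               call. = FALSE)
    src <- sample.int(nb - seg_codons + 1L, 1L)  # codon index
    piece <- body[src:(src + seg_codons - 1L)]
    body <- append(body, piece, after = src + seg_codons - 1L)
    a_start <- 3L * (src - 1L)  # 0-based nt within body
    new <- data.frame(a_start = a_start, a_end = a_start + len,
                      b_start = a_start + len, b_end = a_start + 2L * len)
    # earlier recorded intervals after the insertion point shift right
    ins_at <- a_start + len
    for (cn in c("a_start", "b_start"))
      dups[[cn]] <- ifelse(dups[[cn]] >= ins_at, dups[[cn]] + len, dups[[cn]])
    for (cn in c("a_end", "b_end"))
      dups[[cn]] <- ifelse(dups[[cn]] > ins_at, dups[[cn]] + len, dups[[cn]])
    dups <- rbind(dups, new)
  }
  # shift from body coordinates to CDS coordinates (ATG prefix)
  for (cn in c("a_start", "a_end", "b_start", "b_end"))
    dups[[cn]] <- dups[[cn]] + 3L
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  list(cds = cds,
       protein = suppressWarnings(translate_cds(cds)),
       truth = list(eroded_codons = eroded - 1L, dups = dups, frame = frame,
                    seed = seed))
}

#' Generate a small genome with a spliced transcript model
#'
#' Emits a genome sequence, a BED-style exon model and the planted truth:
#' the spliced transcript and the transcript offset of the designated start
#' codon. The 5' exon carries a planted `start_motif` (default the tandem
#' `ATGATG` arrangement of an LTR-derived first exon) at `start_offset`, and
#' the exon sequence upstream of it is scrubbed of spurious ATGs so the
#' first-AUG policy finds the planted start. Introns begin GT and end AG
#' when `canonical_splice` is TRUE, and GC..AG otherwise.
#'
#' @param n_exons number of exons (>= 1).
#' @param exon_lens exon lengths, recycled to `n_exons`.
#' @param intron_lens intron lengths, recycled to `n_exons - 1`.
#' @param canonical_splice plant canonical GT..AG introns.
#' @param start_motif motif planted at the 5' exon start region.
#' @param start_offset 0-based offset of the motif within the first exon.
#' @param seed integer seed.
#' @return list with `genome`, `exon_model`, and `truth` (list with
#'   `transcript`, `orf_start` — transcript offset of the planted motif —
#'   and the seed).
#' @export
gen_transcript_locus <- function(n_exons = 2L, exon_lens = c(120L, 240L),
                                 intron_lens = 150L, canonical_splice = TRUE,
                                 start_motif = "ATGATG", start_offset = 10L,
                                 seed = 1L) {
  stopifnot(n_exons >= 1L)
  exon_lens <- rep_len(as.integer(exon_lens), n_exons)
  intron_lens <- if (n_exons > 1L)
    rep_len(as.integer(intron_lens), n_exons - 1L) else integer(0)
  stopifnot(all(exon_lens >= start_offset + nchar(start_motif)),
            all(intron_lens >= 4L))
  set.seed(seed)
  exons <- vapply(exon_lens, .rand_dna, character(1))
  # plant the start and remove competing upstream ATGs
  e1 <- exons[1L]
  substr(e1, start_offset + 1L, start_offset + nchar(start_motif)) <- start_motif
  # scrub ATGs upstream of the planted start (none can span the junction,
  # since the motif starts with A)
  prefix <- .scrub_motif(substring(e1, 1L, start_offset), "ATG")
  exons[1L] <- paste0(prefix,
                      substring(e1, start_offset + 1L, nchar(e1)))
  introns <- vapply(intron_lens, function(il) {
    intr <- .rand_dna(il)
    donor <- if (canonical_splice) "GT" else "GC"
    paste0(donor, substring(intr, 3L, il - 2L), "AG")
  }, character(1))

  parts <- character(0)
  coords <- matrix(integer(0), ncol = 2L)
  at <- 0L
  for (i in seq_len(n_exons)) {
    parts <- c(parts, exons[i])
    coords <- rbind(coords, c(at, at + exon_lens[i]))
    at <- at + exon_lens[i]
    if (i < n_exons) {
      parts <- c(parts, introns[i])
      at <- at + intron_lens[i]
    }
  }
  genome <- paste(parts, collapse = "")
  model <- exon_model("synthetic_locus", coords, strand = "+")
  list(genome = genome, exon_model = model,
       truth = list(transcript = paste(exons, collapse = ""),
                    orf_start = start_offset, seed = seed))
}
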