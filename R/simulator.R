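# Stochastic generational simulator of a repeat locus evolving under point
# substitution, unit slippage and segmental duplication, tracking when each
# repeat reading frame first gains a stop codon. The model formalises the
# event triad by which repeat-born coding sequences change: repeat expansion,
# duplications, and point mutations. All rates are illustrative parameters,
# not estimates from any genome.

#' Simulation parameters
#'
#' @param mu per-site per-generation substitution probability.
#' @param kappa transition/transversion ratio (1 = unbiased target choice).
#' @param sigma per-generation probability of one +/-1-unit slippage event
#'   inside a currently detected repeat tract.
#' @param delta per-generation probability of one segmental duplication.
#' @param dup_len length-2 vector, uniform duplication length range in nt.
#' @param generations number of generations (>= 1).
#' @param n_replicates number of independent replicates.
#' @param seed base seed; replicate r runs from `seed + r`.
#' @param unit repeat unit defining tracts and reading frames.
#' @param ins_prob probability a slippage event is an insertion (0.5 =
#'   equiprobable insertion/deletion; 1 forces insertions).
#' @param snapshot_every record the full sequence every this many
#'   generations (`NULL` = final sequence only).
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(mu = 0.001, kappa = 1, sigma = 0, delta = 0,
                       dup_len = c(24L, 96L), generations = 100L,
                       n_replicates = 1L, seed = 1L, unit = "CAG",
                       ins_prob = 0.5, snapshot_every = NULL) {
  for (p in c(mu = mu, sigma = sigma, delta = delta, ins_prob = ins_prob)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(dup_len) != 2L || dup_len[1L] < 3L || dup_len[2L] < dup_len[1L])
    stop("dup_len must be c(L_min, L_max) with L_min >= 3", call. = FALSE)
  if (seed + n_replicates >= 2^31) stop("seed too large", call. = FALSE)
  unit <- .check_codon(unit)
  structure(list(mu = mu, kappa = kappa, sigma = sigma, delta = delta,
                 dup_len = as.integer(dup_len),
                 generations = as.integer(generations),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), unit = unit, ins_prob = ins_prob,
                 snapshot_every = snapshot_every),
            class = "sim_params")
}

.draw_base <- function(from, kappa) {
  targets <- setdiff(DNA_BASES, from)
  w <- vapply(targets, .base_weight, numeric(1), from = from, kappa = kappa)
  sample(targets, 1L, prob = w)
}

#' Evolve a repeat locus over generations
#'
#' Per generation: every site is independently substituted with probability
#' `mu` (target base drawn with `kappa` weighting); with probability `sigma`
#' one slippage event inserts or deletes one whole unit at a uniformly chosen
#' unit boundary inside a currently detected repeat tract (tracts re-detected
#' at event time with divergence tolerance 0.1); with probability `delta` one
#' duplication copies a uniformly chosen segment of uniformly drawn length to
#' the position immediately after its source. Every event is logged so the
#' final sequence can be reproduced by [replay_events()].
#'
#' Stop-codon gain is tracked in the register of the longest pure repeat
#' tract of the initial sequence: for each of the three reading frames the
#' first generation at which a stop codon appears inside the tracked region
#' is recorded. Insertions of non-multiple-of-3 length inside the region mark
#' the replicate frameshifted from that generation on (unit slippage, being
#' 3 nt, never frameshifts).
#'
#' @param initial_seq DNA string (ACGT), e.g. a pure `(CAG)n` locus.
#' @param params a [sim_params] object.
#' @return object of class `sim_trajectory`: list with `params`,
#'   `initial_seq`, `region` (tracked 0-based interval or NULL), `frames`
#'   (offset-to-frame-name map) and `replicates`, each replicate holding
#'   `final_seq`, `events` (data.frame generation, type, pos, length,
#'   detail), `first_stop_gen` (named, NA = never), `frameshift_gen`
#'   and `snapshots`.
#' @export
evolve <- function(initial_seq, params) {
  initial_seq <- .validate_dna(initial_seq, allow_n = FALSE,
                               what = "initial_seq")
  if (!inherits(params, "sim_params")) stop("params must be sim_params",
                                            call. = FALSE)
  tr0 <- find_repeat_tracts(initial_seq, params$unit, min_units = 2L,
                            max_divergence = 0)
  region <- NULL
  frames <- NULL
  deltas <- NULL
  if (nrow(tr0) > 0L) {
    main <- tr0[which.max(tr0$n_units), ]
    region <- c(start = main$start, end = main$end)
    canon <- canonical_unit(params$unit)
    rots <- rotations(canon)
    fn <- frame_names(params$unit)
    p0 <- main$start + main$phase
    # in-region offset delta reading rotation k starts at region_start + delta
    deltas <- vapply(names(fn), function(nm) {
      cod <- fn[[nm]]
      kk <- match(cod, rots) - 1L
      as.integer((p0 - main$start + kk) %% 3L)
    }, integer(1))
    frames <- deltas
  }
  reps <- vector("list", params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    reps[[r]] <- .evolve_one(initial_seq, params, params$seed + r,
                             region, deltas)
  }
  structure(list(params = params, initial_seq = initial_seq,
                 region = region, frames = frames, replicates = reps),
            class = "sim_trajectory")
}

.stop_in_register <- function(ch, from, to, delta) {
  # any stop codon reading [from, to) 1-based at in-region offset delta
  first <- from + delta
  if (to - first + 1L < 3L) return(FALSE)
  idx <- seq.int(first, to - 2L, by = 3L)
  c1 <- ch[idx]; c2 <- ch[idx + 1L]; c3 <- ch[idx + 2L]
  any((c1 == "T" & c2 == "A" & (c3 == "A" | c3 == "G")) |
        (c1 == "T" & c2 == "G" & c3 == "A"))
}

.evolve_one <- function(initial_seq, params, seed, region, deltas) {
  set.seed(seed)
  ch <- .chars(initial_seq)
  # tracked region as 1-based [rs, re] inclusive; NULL region disables tracking
  tracking <- !is.null(region)
  rs <- if (tracking) region[["start"]] + 1L else NA_integer_
  re <- if (tracking) region[["end"]] else NA_integer_
  first_stop <- if (tracking)
    stats::setNames(rep(NA_integer_, length(deltas)), names(deltas)) else NULL
  frameshift_gen <- NA_integer_
  ev_gen <- integer(0); ev_type <- character(0); ev_pos <- integer(0)
  ev_len <- integer(0); ev_detail <- character(0)
  snapshots <- list()

  shift_region <- function(at, len) {
    # insertion of `len` chars before 1-based position `at` (deletion: len<0)
    if (!tracking || !is.na(frameshift_gen)) return()
    if (at <= rs) {
      rs <<- rs + len; re <<- re + len
    } else if (at <= re + 1L) {
      re <<- re + len
      if (len %% 3L != 0L) frameshift_gen <<- g
    }
  }

  for (g in seq_len(params$generations)) {
    changed <- FALSE
    L <- length(ch)
    # substitutions
    m <- stats::rbinom(1L, L, params$mu)
    if (m > 0L) {
      pos <- sort(sample.int(L, m))
      for (p in pos) {
        to <- .draw_base(ch[p], params$kappa)
        ev_gen <- c(ev_gen, g); ev_type <- c(ev_type, "sub")
        ev_pos <- c(ev_pos, p - 1L); ev_len <- c(ev_len, 1L)
        ev_detail <- c(ev_detail, to)
        ch[p] <- to
      }
      changed <- TRUE
    }
    # slippage
    if (params$sigma > 0 && stats::runif(1L) < params$sigma) {
      cur <- paste(ch, collapse = "")
      tr <- find_repeat_tracts(cur, params$unit, min_units = 2L,
                               max_divergence = 0.1)
      if (nrow(tr) > 0L) {
        starts <- unlist(lapply(seq_len(nrow(tr)), function(i) {
          seq.int(tr$start[i] + tr$phase[i] %% 3L + 1L, by = 3L,
                  length.out = max(0L, (tr$end[i] - tr$start[i]) %/% 3L - 1L))
        }))
        starts <- starts[starts + 2L <= length(ch)]
        if (length(starts) > 0L) {
          at <- if (length(starts) == 1L) starts else sample(starts, 1L)
          if (stats::runif(1L) < params$ins_prob) {
            piece <- ch[at:(at + 2L)]
            ch <- append(ch, piece, after = at - 1L)
            ev_gen <- c(ev_gen, g); ev_type <- c(ev_type, "ins")
            ev_pos <- c(ev_pos, at - 1L); ev_len <- c(ev_len, 3L)
            ev_detail <- c(ev_detail, paste(piece, collapse = ""))
            shift_region(at, 3L)
          } else {
            ev_gen <- c(ev_gen, g); ev_type <- c(ev_type, "del")
            ev_pos <- c(ev_pos, at - 1L); ev_len <- c(ev_len, 3L)
            ev_detail <- c(ev_detail, paste(ch[at:(at + 2L)], collapse = ""))
            ch <- ch[-(at:(at + 2L))]
            shift_region(at, -3L)
          }
          changed <- TRUE
        }
      }
    }
    # segmental duplication
    if (params$delta > 0 && stats::runif(1L) < params$delta) {
      L <- length(ch)
      len <- sample(params$dup_len[1L]:params$dup_len[2L], 1L)
      len <- min(len, L)
      src <- if (L - len + 1L == 1L) 1L else sample.int(L - len + 1L, 1L)
      piece <- ch[src:(src + len - 1L)]
      ch <- append(ch, piece, after = src + len - 1L)
      ev_gen <- c(ev_gen, g); ev_type <- c(ev_type, "dup")
      ev_pos <- c(ev_pos, src - 1L); ev_len <- c(ev_len, len)
      ev_detail <- c(ev_detail, "")
      shift_region(src + len, len)
      changed <- TRUE
    }
    # stop-gain tracking (status can only change after events)
    if (tracking && changed && is.na(frameshift_gen)) {
      for (nm in names(deltas)) {
        if (is.na(first_stop[[nm]]) &&
            .stop_in_register(ch, rs, re, deltas[[nm]]))
          first_stop[[nm]] <- g
      }
    }
    if (!is.null(params$snapshot_every) && g %% params$snapshot_every == 0L)
      snapshots[[as.character(g)]] <- paste(ch, collapse = "")
  }
  list(final_seq = paste(ch, collapse = ""),
       events = data.frame(generation = ev_gen, type = ev_type, pos = ev_pos,
                           length = ev_len, detail = ev_detail,
                           stringsAsFactors = FALSE),
       first_stop_gen = first_stop,
       frameshift_gen = frameshift_gen,
       snapshots = snapshots)
}

#' Replay a logged event sequence
#'
#' Applies a replicate's event log to the initial sequence; by construction
#' this reproduces the simulated final sequence exactly, which is the
#' integrity check on the logging.
#'
#' @param initial_seq the sequence the simulation started from.
#' @param events the `events` data.frame of one replicate.
#' @return the reconstructed final sequence.
#' @export
replay_events <- function(initial_seq, events) {
  ch <- .chars(.validate_dna(initial_seq, allow_n = FALSE))
  for (i in seq_len(nrow(events))) {
    type <- events$type[i]; pos <- events$pos[i]; len <- events$length[i]
    if (type == "sub") {
      ch[pos + 1L] <- events$detail[i]
    } else if (type == "ins") {
      ch <- append(ch, .chars(events$detail[i]), after = pos)
    } else if (type == "del") {
      ch <- ch[-((pos + 1L):(pos + len))]
    } else if (type == "dup") {
      piece <- ch[(pos + 1L):(pos + len)]
      ch <- append(ch, piece, after = pos + len)
    } else stop("unknown event type: ", type, call. = FALSE)
  }
  paste(ch, collapse = "")
}

#' Per-frame ORF survival curve
#'
#' Fraction of replicates in which the tracked repeat region has not yet
#' gained a stop codon in the given frame, per generation (first-passage, so
#' the curve is monotone non-increasing), with binomial standard errors.
#' Replicates frameshifted by generation t are excluded at t.
#'
#' @param traj a `sim_trajectory` from [evolve()].
#' @param frame frame name (e.g. `"polyQ"`, `"polyS"`, `"polyA"`).
#' @return data.frame with `generation` (0..G), `surviving_fraction`, `se`,
#'   `n` (replicates at risk).
#' @export
frame_survival <- function(traj, frame) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (is.null(traj$frames))
    stop("trajectory has no tracked repeat region", call. = FALSE)
  if (!frame %in% names(traj$frames))
    stop("unknown frame '", frame, "'; expected one of ",
         paste(names(traj$frames), collapse = ", "), call. = FALSE)
  G <- traj$params$generations
  stop_gen <- vapply(traj$replicates, function(r) {
    v <- r$first_stop_gen[[frame]]
    if (is.na(v)) Inf else as.numeric(v)
  }, numeric(1))
  fs_gen <- vapply(traj$replicates, function(r) {
    if (is.na(r$frameshift_gen)) Inf else as.numeric(r$frameshift_gen)
  }, numeric(1))
  gens <- 0:G
  out <- lapply(gens, function(t) {
    at_risk <- fs_gen > t
    n <- sum(at_risk)
    p <- if (n > 0L) mean(stop_gen[at_risk] > t) else NA_real_
    se <- if (n > 0L) sqrt(p * (1 - p) / n) else NA_real_
    data.frame(generation = t, surviving_fraction = p, se = se, n = n)
  })
  do.call(rbind, out)
}

#' Closed-form single-hit stop-gain hazard per codon per generation
#'
#' The probability that a single generation's point mutation turns one codon
#' of the given repeat reading frame into a stop codon, from the codon-space
#' minima and the mutation weights: the sum over single-base changes reaching
#' a stop of `mu * w(base)`, where targets are weighted by the
#' transition/transversion ratio `kappa`. For the CAG repeat this is
#' `mu * kappa / (kappa + 2)` in the polyQ frame (the single C-to-T
#' transition giving TAG; `mu/3` when unbiased) and exactly 0 in the polyS
#' and polyA frames.
#'
#' @param unit repeat unit.
#' @param frame frame name (see [frame_names()]).
#' @param mu per-site per-generation substitution probability.
#' @param kappa transition/transversion ratio.
#' @return numeric hazard.
#' @export
stop_gain_hazard <- function(unit, frame, mu, kappa = 1) {
  unit <- .check_codon(unit)
  fn <- frame_names(unit)
  if (!frame %in% names(fn))
    stop("unknown frame '", frame, "'; expected one of ",
         paste(names(fn), collapse = ", "), call. = FALSE)
  cod <- .chars(fn[[frame]])
  h <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, cod[p])) {
      mut <- cod; mut[p] <- b
      if (paste(mut, collapse = "") %in% STOP_CODONS)
        h <- h + mu * .base_weight(cod[p], b, kappa) / (kappa + 2)
    }
  }
  h
}
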