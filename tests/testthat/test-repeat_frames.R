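test_that("pure and eroded tracts are detected with correct span and purity", {
  t1 <- find_repeat_tracts("CAGCAGCAGCAG", "CAG", min_units = 3,
                           max_divergence = 0)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$n_units, 4)
  expect_equal(t1$purity, 1.0)
  expect_equal(c(t1$start, t1$end), c(0, 12))

  t2 <- find_repeat_tracts("CAGCAGTAGCAGCAG", "CAG", min_units = 3,
                           max_divergence = 0.2)
  expect_equal(nrow(t2), 1)
  expect_equal(c(t2$start, t2$end), c(0, 15))
  expect_equal(t2$purity, 4 / 5)  # one of five unit windows mismatches

  expect_equal(nrow(find_repeat_tracts("ACGTACGTACGT", "CAG", 3, 0)), 0)
})

test_that("tracts are reported under the canonical unit with correct phase", {
  # same repeat entered in a different register
  t <- find_repeat_tracts("GCAGCAGCAGCA", "GCA", min_units = 3,
                          max_divergence = 0)
  expect_equal(t$unit, "AGC")  # lexicographic minimum of the rotations
  # canonical AGC first occurs at offset `phase` of the tract
  expect_identical(substring("GCAGCAGCAGCA", t$start + t$phase + 1,
                             t$start + t$phase + 3), "AGC")
})

test_that("eroded planted tracts are recovered within one unit", {
  # flanks are pyrimidine-only so no flank window is within one mismatch of
  # any CAG rotation: the planted boundary is then unambiguous ground truth
  rand_flank <- function(n) paste(sample(c("T", "C"), n, TRUE), collapse = "")
  for (e in c(0.1, 0.2)) {
    set.seed(202)
    hits <- 0L
    n_rep <- 200L
    for (i in seq_len(n_rep)) {
      n_units <- 30L
      units <- rep("CAG", n_units)
      eroded <- runif(n_units) < e
      for (j in which(eroded)) {
        u <- strsplit(units[j], "")[[1]]
        p <- sample.int(3, 1)
        u[p] <- sample(setdiff(c("A", "C", "G", "T"), u[p]), 1)
        units[j] <- paste(u, collapse = "")
      }
      s <- paste0(rand_flank(50), paste(units, collapse = ""), rand_flank(50))
      tr <- find_repeat_tracts(s, "CAG", min_units = 3, max_divergence = 0.2)
      if (nrow(tr) == 0) next
      main <- tr[which.max(tr$n_units), ]
      if (abs(main$start - 50) <= 3 && abs(main$end - (50 + 3 * n_units)) <= 3)
        hits <- hits + 1L
    }
    expect_gte(hits, n_rep * 0.95)
  }
})

test_that("codons are classified into repeat frames with conservative ties", {
  s <- classify_codon_frames("AGCAGCAGC", "CAG")
  expect_identical(s$codon_labels, rep("polyS", 3))
  expect_equal(s$n_switches, 0)

  s2 <- classify_codon_frames("AGCAGCGCAGCA", "CAG")
  expect_identical(s2$runs$label, c("polyS", "polyA"))
  expect_equal(s2$runs$end_codon - s2$runs$start_codon, c(2, 2))
  expect_equal(s2$n_switches, 1)

  s3 <- classify_codon_frames("ATGGATTTT", "CAG")
  expect_identical(unique(s3$codon_labels), "other")
  expect_equal(s3$n_switches, 0)

  expect_identical(classify_codon_frames("CANAGC")$codon_labels,
                   c("undetermined", "polyS"))
  expect_warning(classify_codon_frames("AGCAG"), "partial codon")
})

test_that("classification is invariant to non-repeat flanks outside the codons", {
  set.seed(7)
  core <- paste0(strrep("AGC", 5), strrep("GCA", 4))
  base <- classify_codon_frames(core)
  for (i in 1:10) {
    flank_l <- rand_dna(3 * sample.int(5, 1))
    flank_r <- rand_dna(3 * sample.int(5, 1))
    ext <- classify_codon_frames(paste0(flank_l, core, flank_r))
    n_l <- nchar(flank_l) / 3
    inner <- ext$codon_labels[(n_l + 1):(n_l + length(base$codon_labels))]
    expect_identical(inner, base$codon_labels)
  }
})

test_that("aa_composition returns fractions over counted residues", {
  expect_equal(aa_composition("SSSS")$fractions, c(S = 1.0))
  expect_equal(aa_composition("SSSS")$serine, 1.0)
  expect_equal(aa_composition(translate_cds(strrep("AGC", 10)))$serine, 1.0)
  c4 <- aa_composition("SQAD")
  expect_true(all(c4$fractions == 0.25))
  expect_equal(sum(aa_composition("MSSQ*")$fractions), 1)
  expect_error(aa_composition(""), "empty")
  expect_error(aa_composition("***"), "empty")
})

test_that("frame stop counts match per-register re-translation", {
  pure <- strrep("CAG", 20)
  r <- repeat_frame_report(pure, "CAG")
  expect_true(all(r$frame_stops$n_stops == 0))

  s <- paste0(strrep("CAG", 5), "TAG", strrep("CAG", 5))
  r2 <- repeat_frame_report(s, "CAG")
  fs <- r2$frame_stops
  expect_equal(fs$n_stops[fs$frame == "polyQ"], 1)
  expect_equal(fs$n_stops[fs$frame %in% c("polyS", "polyA")], c(0, 0))

  # oracle: per-register stop counting by translation
  set.seed(31)
  for (i in 1:5) {
    x <- rand_dna(300)
    r3 <- repeat_frame_report(x, "CAG")
    for (j in 0:2) {
      prot <- oracle_translate(substring(x, j + 1, nchar(x)))
      n_stop <- lengths(regmatches(prot, gregexpr("*", prot, fixed = TRUE)))
      expect_equal(r3$frame_stops$n_stops[r3$frame_stops$offset == j],
                   unname(n_stop))
    }
  }
})

test_that("a single point mutation in (CAG)n can gain a stop only in polyQ", {
  # exhaustive: every single mutant of (CAG)10, every frame register
  s <- strrep("CAG", 10)
  base <- vapply(0:2, function(j) {
    prot <- oracle_translate(substring(s, j + 1, nchar(s)))
    lengths(regmatches(prot, gregexpr("*", prot, fixed = TRUE)))
  }, integer(1))
  expect_true(all(base == 0))
  for (p in seq_len(nchar(s))) {
    for (b in setdiff(c("A", "C", "G", "T"), substring(s, p, p))) {
      mut <- s
      substr(mut, p, p) <- b
      r <- repeat_frame_report(mut, "CAG", min_units = 2,
                               max_divergence = 0.2)
      fs <- r$frame_stops
      q_stops <- fs$n_stops[fs$offset == 0]  # polyQ register of this locus
      other <- fs$n_stops[fs$offset != 0]
      expect_true(all(other == 0))
      is_c1_to_t <- (p %% 3 == 1) && b == "T"
      expect_equal(q_stops, as.integer(is_c1_to_t))
    }
  }
})
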