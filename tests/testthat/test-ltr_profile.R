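test_that("exchange rates are zero for identical copies and exact for planted counts", {
  cons <- strrep("ACGT", 10)
  rows <- setNames(c(cons, rep(cons, 10)), c("cons", paste0("c", 1:10)))
  aln <- family_alignment(rows)
  prof <- column_exchange_rates(aln)
  expect_true(all(prof$rate == 0))
  expect_true(all(prof$n_informative == 10))

  # plant a mutation at position j in exactly 37 of 100 copies
  fam <- gen_ltr_family(consensus_len = 50, n_copies = 100,
                        rate_profile = 0, seed = 2)
  aln2 <- fam$alignment
  j <- 20  # 0-based
  cons_ch <- strsplit(aln2$consensus, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), cons_ch[j + 1])[1]
  copies <- aln2$copies
  for (i in 1:37) substr(copies[i], j + 1, j + 1) <- alt
  aln2 <- family_alignment(c(setNames(aln2$consensus, "consensus"), copies),
                           consensus_id = "consensus")
  prof2 <- column_exchange_rates(aln2)
  expect_equal(prof2$rate[prof2$pos == j], 0.37)
})

test_that("gaps drop copies from a column's denominator; all-gap is undefined", {
  rows <- c(cons = "ACGTAC",
            c1 = "AC-TAC",
            c2 = "ACTTAC",
            c3 = "AC-TAC")
  prof <- column_exchange_rates(family_alignment(rows))
  expect_equal(prof$n_informative[prof$pos == 2], 1)
  expect_equal(prof$rate[prof$pos == 2], 1)  # the one informative copy mismatches

  rows_all_gap <- c(cons = "ACG", c1 = "A-G", c2 = "A-G")
  p2 <- column_exchange_rates(family_alignment(rows_all_gap))
  expect_true(p2$undefined[p2$pos == 1])
  expect_true(is.na(p2$rate[p2$pos == 1]))

  # consensus gap columns carry no consensus coordinate
  rows_cgap <- c(cons = "AC-G", c1 = "ACTG")
  p3 <- column_exchange_rates(family_alignment(rows_cgap))
  expect_equal(nrow(p3), 3)
})

test_that("rate estimates recover planted per-position rates within 3 SE", {
  set.seed(140)
  n <- 100
  L <- 250
  n_pos <- 0; n_ok <- 0
  for (rep in 1:20) {
    r_true <- runif(L, 0, 0.4)
    fam <- gen_ltr_family(consensus_len = L, n_copies = n,
                          rate_profile = r_true, seed = 1000 + rep)
    # the generator substitutes to a random *different* base, so every
    # substitution is a mismatch and rate(j) estimates r_true(j) directly
    prof <- column_exchange_rates(fam$alignment)
    se <- sqrt(r_true * (1 - r_true) / n)
    ok <- abs(prof$rate - r_true) <= 3 * se
    n_pos <- n_pos + L
    n_ok <- n_ok + sum(ok)
  }
  expect_gte(n_ok / n_pos, 0.99)
})

test_that("motif presence handles carriers, gaps, and undefined windows", {
  rows <- c(cons = "AAATGCC",
            c1 = "AAATGCC",
            c2 = "AACTGCC",
            c3 = "AA-TGCC")
  aln <- family_alignment(rows)
  p <- motif_presence(aln, "ATG", 2)
  expect_equal(p$n_informative, 2)  # c3 gapped in window
  expect_equal(p$fraction, 0.5)

  all_carry <- motif_presence(family_alignment(
    c(cons = "ATG", c1 = "ATG", c2 = "ATG")), "ATG", 0)
  expect_equal(all_carry$fraction, 1.0)

  all_gap <- motif_presence(family_alignment(
    c(cons = "ATGC", c1 = "---C", c2 = "---C")), "ATG", 0)
  expect_true(all_gap$undefined)

  expect_error(motif_presence(aln, "ATG", 5), "outside")
})

test_that("co-occurrence census is additive and matches planted fractions", {
  fam <- gen_ltr_family(
    consensus_len = 200, n_copies = 100, rate_profile = 0.03,
    motif_plan = list(motif = "ATG", start_a = 10, start_b = 13,
                      fractions = c(0.14, 0.29, 0.15)),
    seed = 8, exact_fractions = TRUE)
  cc <- motif_cooccurrence(fam$alignment, "ATG", 10, "ATG", 13)
  expect_equal(cc$a_only, 0.14)
  expect_equal(cc$b_only, 0.29)
  expect_equal(cc$both, 0.15)
  expect_equal(cc$at_least_one, 0.58)
  expect_equal(cc$at_least_one, cc$a_only + cc$b_only + cc$both)

  none <- motif_cooccurrence(family_alignment(
    c(cons = "ATGATG", c1 = "CTGCTG", c2 = "GTGGTG")), "ATG", 0, "ATG", 3)
  expect_equal(unlist(none[c("a_only", "b_only", "both", "at_least_one")]),
               c(a_only = 0, b_only = 0, both = 0, at_least_one = 0))

  all_both <- motif_cooccurrence(family_alignment(
    c(cons = "ATGATG", c1 = "ATGATG", c2 = "ATGATG")), "ATG", 0, "ATG", 3)
  expect_equal(unlist(all_both[c("a_only", "b_only", "both", "at_least_one")]),
               c(a_only = 0, b_only = 0, both = 1, at_least_one = 1))
})

test_that("statistics are invariant to copy order", {
  fam <- gen_ltr_family(
    consensus_len = 120, n_copies = 50, rate_profile = 0.08,
    motif_plan = list(motif = "ATG", start_a = 5, start_b = 8,
                      fractions = c(0.2, 0.2, 0.2)),
    seed = 33)
  aln <- fam$alignment
  set.seed(9)
  perm <- sample(length(aln$copies))
  aln_p <- family_alignment(c(setNames(aln$consensus, "consensus"),
                              aln$copies[perm]), consensus_id = "consensus")
  p1 <- column_exchange_rates(aln)
  p2 <- column_exchange_rates(aln_p)
  expect_equal(p1$rate, p2$rate)
  c1 <- motif_cooccurrence(aln, "ATG", 5, "ATG", 8)
  c2 <- motif_cooccurrence(aln_p, "ATG", 5, "ATG", 8)
  expect_equal(c1[1:4], c2[1:4])
})
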