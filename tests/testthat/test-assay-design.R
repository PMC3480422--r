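# Assay design: Tm thermodynamics, signature discovery, pair
# enumeration, specificity, Ta optimum, selection.

# golden Tm values frozen from an independent nearest-neighbor
# implementation under identical conventions (unified 1998 parameters,
# entropic salt correction at 50 mM Na+, 200 nM primer, CT/4)
GOLDEN_TM <- c(
  AGCGTAGCTAGCCTAAGGCA = 56.7997,
  ATATATATATAT = 8.4911,      # self-complementary
  GCGCGCGCGCGC = 62.8164      # self-complementary
)

test_that("compute_tm matches the independent golden values", {
  for (s in names(GOLDEN_TM)) {
    expect_lt(abs(compute_tm(s) - GOLDEN_TM[[s]]), 0.01)
  }
  # equal-length AT-only vs GC-only: GC strictly hotter
  expect_lt(compute_tm("ATATATATATAT"), compute_tm("GCGCGCGCGCGC"))
})

test_that("compute_tm is deterministic and symmetric under reverse complement", {
  p <- "AGCGTAGCTAGCCTAAGGCA"
  rc <- "TGCCTTAGGCTAGCTACGCT"
  expect_identical(compute_tm(p), compute_tm(p))
  expect_equal(compute_tm(rc), compute_tm(p), tolerance = 1e-12)
})

test_that("compute_tm validates input and handles degeneracy as worst case", {
  expect_error(compute_tm("ACGTACG"), "shorter")
  expect_error(compute_tm("ACGTACGX"), "non-nucleotide")
  # R = A or G: reported Tm is the minimum over the two expansions
  degen <- "AGCGTAGCTAGCCTARGGCA"
  expected <- min(compute_tm("AGCGTAGCTAGCCTAAGGCA"),
                  compute_tm("AGCGTAGCTAGCCTAGGGCA"))
  expect_equal(compute_tm(degen), expected, tolerance = 1e-12)
  # expansion cap
  expect_error(compute_tm("NNNNNNNNNN"), "cap")
})

test_that("planted signature motifs are recovered as the top-ranked window", {
  spec <- synthetic_spec(seed = 7, n_taxa = 4, members_per_taxon = 2,
                         seq_length = 600)
  rs <- generate_reference_set(spec)
  for (tx in spec$taxa[1:2]) {
    members <- rs$taxonomy$id[rs$taxonomy$family == tx]
    w <- find_signature_windows(rs$alignment, members)
    expect_gt(nrow(w), 0)
    slot <- rs$slots[[tx]]$fwd
    # the best window covers the planted forward motif and mismatches
    # every non-target across the whole motif
    expect_lte(w$start[1], slot[1])
    expect_gte(w$end[1], slot[2])
    expect_equal(w$min_total_mm[1], spec$motif_length)
    expect_equal(w$min_3p_mm[1], 5)
  }
})

test_that("no signature window exists without a distinguishing motif", {
  # target identical to a non-target
  aln <- c(t1 = "ACGTACGTACGTACGTACGTACGTACGT",
           t2 = "ACGTACGTACGTACGTACGTACGTACGT",
           n1 = "ACGTACGTACGTACGTACGTACGTACGT")
  expect_equal(nrow(find_signature_windows(
    aln, c("t1", "t2"),
    constraints = design_constraints(primer_min = 18, primer_max = 20))), 0)
  # target members disagreeing at every column
  aln2 <- c(t1 = paste(rep("A", 30), collapse = ""),
            t2 = paste(rep("C", 30), collapse = ""),
            n1 = paste(rep("G", 30), collapse = ""))
  expect_equal(nrow(find_signature_windows(aln2, c("t1", "t2"))), 0)
  # a taxon whose motif was never planted yields no window either
  spec <- synthetic_spec(seed = 7, n_taxa = 4, members_per_taxon = 2,
                         seq_length = 600,
                         motif_taxa = c("Alaimidae", "Aphelenchidae",
                                        "Aphelenchoididae"))
  rs <- generate_reference_set(spec)
  unplanted <- setdiff(spec$taxa, spec$motif_taxa)
  members <- rs$taxonomy$id[rs$taxonomy$family == unplanted]
  expect_equal(nrow(find_signature_windows(rs$alignment, members)), 0)
})

test_that("planted motifs are recovered across many seeded worlds", {
  for (seed in 1:25) {
    spec <- synthetic_spec(seed = seed, n_taxa = 3, members_per_taxon = 2,
                           seq_length = 450)
    rs <- generate_reference_set(spec)
    tx <- spec$taxa[1 + seed %% 3]
    members <- rs$taxonomy$id[rs$taxonomy$family == tx]
    w <- find_signature_windows(rs$alignment, members)
    slot <- rs$slots[[tx]]
    expect_gt(nrow(w), 0)
    covers_fwd <- w$start[1] <= slot$fwd[1] && w$end[1] >= slot$fwd[2]
    covers_rev <- w$start[1] <= slot$rev[1] && w$end[1] >= slot$rev[2]
    expect_true(covers_fwd || covers_rev, info = paste("seed", seed))
  }
})

# two planted 20-nt primer sites with Tm ~63 C, 60 nt apart on a 240-nt
# reference shared by two target members; one distant non-target
make_pair_alignment <- function() {
  site_f <- "CTCGGCTAGCAAACGCGCGG"     # Tm 63.2
  site_r <- "TGCCACATGGGACCGGCCAA"     # Tm 63.0 (plus strand site)
  set.seed(101)
  bg <- paste(sample(c("A", "C", "G", "T"), 240, TRUE), collapse = "")
  insert_at <- function(s, sub, at) {
    paste0(substr(s, 1, at - 1), sub, substr(s, at + nchar(sub), nchar(s)))
  }
  target <- insert_at(insert_at(bg, site_f, 41), site_r, 121)
  nt <- bg                               # non-target: background only
  c(t1 = target, t2 = target, n1 = nt)
}

test_that("enumerate_primer_pairs obeys Tm, amplicon and pairing constraints", {
  aln <- make_pair_alignment()
  w <- find_signature_windows(aln, c("t1", "t2"),
                              constraints = design_constraints(min_mismatch = 10))
  expect_gte(nrow(w), 2)
  cons <- design_constraints(ta_tolerance = 1)
  pairs <- enumerate_primer_pairs(w, constraints = cons)
  expect_gt(length(pairs), 0)
  best <- pairs[[1]]
  # forward site precedes reverse site; amplicon bookkeeping spans both
  expect_lt(best$forward$ref_window[2], best$reverse$ref_window[1])
  expect_equal(best$amplicon_length,
               best$reverse$ref_window[2] - best$forward$ref_window[1] + 1)
  # 20-nt sites 60 nt apart: full-width amplicon = 100 nt
  expect_true(any(vapply(pairs, function(p) p$amplicon_length == 100, TRUE)))
  for (p in pairs) {
    expect_lte(abs(p$forward$tm - 63), cons$ta_tolerance + 1e-9)
    expect_lte(abs(p$forward$tm - p$reverse$tm), cons$max_tm_diff + 1e-9)
    expect_gte(p$amplicon_length, cons$amplicon_min)
    expect_lte(p$amplicon_length, cons$amplicon_max)
  }
  # an amplicon bound below the site geometry excludes everything
  # (forward windows need >= 10 site positions, so they start by 51;
  # reverse windows end no earlier than 130: minimum amplicon is 80)
  expect_length(enumerate_primer_pairs(
    w, constraints = design_constraints(amplicon_max = 70, ta_tolerance = 1)), 0)
  # zero Ta tolerance excludes windows at 62-63.5 C
  expect_length(enumerate_primer_pairs(
    w, constraints = design_constraints(ta_tolerance = 0)), 0)
})

test_that("score_specificity computes empirical gaps and in-silico proxies", {
  aln <- make_pair_alignment()
  w <- find_signature_windows(aln, c("t1", "t2"),
                              constraints = design_constraints(min_mismatch = 10))
  pair <- enumerate_primer_pairs(w)[[1]]

  # empirical: gap = earliest non-target minus latest target
  emp <- score_specificity(pair, empirical = c(16, 42))
  expect_equal(emp$delta_ct, 26)
  expect_equal(emp$source, "empirical")
  # antisymmetry under swapping the two Cts
  expect_equal(score_specificity(pair, empirical = c(42, 16))$delta_ct, -26)

  # in silico against the designed alignment: planted sites mismatch the
  # non-target everywhere, so no amplification is predicted
  sc <- score_specificity(pair, target_seqs = aln[c("t1", "t2")],
                          nontarget_seqs = aln["n1"])
  expect_false(any(sc$per_nontarget$predicted_amplifiable))
  expect_true(sc$not_available)
  expect_true(is.na(sc$delta_ct))

  # non-target identical to a target: proxy gap collapses to zero
  sc0 <- score_specificity(pair, target_seqs = aln[c("t1", "t2")],
                           nontarget_seqs = c(n2 = unname(aln["t1"])))
  expect_true(sc0$per_nontarget$predicted_amplifiable)
  expect_equal(sc0$delta_ct, 0)

  # a pair that fails to bind a target member errors with its name
  expect_error(
    score_specificity(pair, target_seqs = c(t9 = unname(aln["n1"])),
                      nontarget_seqs = aln["n1"]),
    "t9"
  )
})

test_that("assess_ta_optimum demands a sharp optimum at the design Ta", {
  # shape with flat plateau below 63 and a steep rise above
  prof <- data.frame(ta = c(58, 60, 61.5, 63, 64, 65, 66),
                     ct = c(18.2, 18.1, 18.0, 18.0, 21.0, 24.1, 27.2))
  res <- assess_ta_optimum(prof)
  expect_true(res$pass)
  expect_gte(res$sharpness, 1)

  flat <- data.frame(ta = c(58, 60, 63, 65, 66), ct = rep(18, 5))
  expect_false(assess_ta_optimum(flat)$pass)

  shifted <- data.frame(ta = c(58, 60, 63, 65, 66),
                        ct = c(15, 16.5, 18.5, 21, 23.5))
  expect_false(assess_ta_optimum(shifted)$pass)  # minimum sits at 58

  expect_error(assess_ta_optimum(data.frame(ta = c(62, 63), ct = c(1, 2))),
               ">= 3")
})

test_that("select_assay discards weak gaps and ranks survivors correctly", {
  aln <- make_pair_alignment()
  w <- find_signature_windows(aln, c("t1", "t2"),
                              constraints = design_constraints(min_mismatch = 10))
  pairs <- enumerate_primer_pairs(w)
  cand <- function(pair, delta, unit, na = FALSE) {
    sc <- if (na) {
      score_specificity(pair, target_seqs = aln[c("t1", "t2")],
                        nontarget_seqs = aln["n1"])
    } else {
      score_specificity(pair, empirical = c(16, 16 + delta))
    }
    list(pair = pair, score = sc, unit_template_ct = unit)
  }

  # gap below 12 discarded, 13 wins
  sel <- select_assay(list(cand(pairs[[1]], 11, 20), cand(pairs[[2]], 13, 20)),
                      taxon = "T")
  expect_equal(sel$delta_ct, 13)
  expect_equal(attr(sel, "n_discarded"), 1)

  # equal gaps: lowest Ct per unit template wins
  sel2 <- select_assay(list(cand(pairs[[1]], 20, 24), cand(pairs[[2]], 20, 21)))
  expect_equal(sel2$unit_template_ct, 21)

  # a single large-gap candidate is simply selected
  sel3 <- select_assay(list(cand(pairs[[1]], 42, 20)))
  expect_equal(sel3$delta_ct, 42)

  # not-available (no non-target signal) outranks any numeric gap
  sel4 <- select_assay(list(cand(pairs[[1]], 42, 20),
                            cand(pairs[[2]], 0, 30, na = TRUE)))
  expect_true(sel4$not_available)

  # permutation invariance
  px <- pairs[rep(seq_along(pairs), length.out = 4)]
  cands <- list(cand(px[[1]], 14, 25), cand(px[[2]], 20, 22),
                cand(px[[3]], 20, 21), cand(px[[4]], 11, 10))
  picks <- lapply(1:6, function(i) {
    set.seed(i)
    select_assay(cands[sample(length(cands))])
  })
  for (p in picks[-1]) {
    expect_equal(p$pair$forward$sequence, picks[[1]]$pair$forward$sequence)
    expect_equal(p$delta_ct, picks[[1]]$delta_ct)
  }

  # negative empirical gaps are always discarded
  expect_error(select_assay(list(cand(pairs[[1]], -26, 20))), "no assay passes")
})
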