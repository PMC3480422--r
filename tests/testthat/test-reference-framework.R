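# Reference framework: loading, monophyly, assay-target resolution,
# occurrence tables.

test_that("load_framework builds genus and family groups from files", {
  dir <- write_tiny_framework()
  fw <- load_framework(file.path(dir, "aln.fasta"), file.path(dir, "tax.tsv"),
                       file.path(dir, "tree.nwk"))
  expect_s3_class(fw, "nq_framework")
  expect_setequal(names(fw$groups), c("Alphidae", "Betidae", "Alpha", "Beta"))
  expect_setequal(fw$groups[["Alpha"]]$member_ids, c("A1", "A2"))
  expect_setequal(fw$groups[["Betidae"]]$member_ids, c("B1", "B2"))
  # gap accounting: B sequences carry one gap
  expect_equal(fw$sequences$ungapped_length[fw$sequences$id == "B1"], 59)
  expect_equal(fw$sequences$ungapped_length[fw$sequences$id == "A1"], 60)
})

test_that("load_framework rejects ragged alignments and unknown taxonomy ids", {
  dir <- write_tiny_framework()
  # unknown id
  tax <- read.delim(file.path(dir, "tax.tsv"))
  tax$id[1] <- "X9"
  write.table(tax, file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(
    load_framework(file.path(dir, "aln.fasta"), file.path(dir, "bad.tsv")),
    "X9"
  )
  # ragged alignment
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACG"),
             file.path(dir, "ragged.fasta"))
  expect_error(
    load_framework(file.path(dir, "ragged.fasta"), file.path(dir, "tax.tsv")),
    "ragged"
  )
})

test_that("tree leaves missing from the alignment are dropped with a warning", {
  dir <- write_tiny_framework()
  writeLines("(((A1,A2),(B1,B2)),GHOST);", file.path(dir, "tree2.nwk"))
  expect_warning(
    fw <- load_framework(file.path(dir, "aln.fasta"), file.path(dir, "tax.tsv"),
                         file.path(dir, "tree2.nwk")),
    "GHOST"
  )
  expect_false("GHOST" %in% fw$tree$tip.label)
})

test_that("synthetic reference sets round-trip through disk unchanged", {
  spec <- synthetic_spec(seed = 1, n_taxa = 8, members_per_taxon = 3,
                         seq_length = 1200)
  rs <- generate_reference_set(spec)
  dir <- tempfile()
  paths <- write_reference_set(rs, dir)
  fw <- load_framework(paths[["fasta"]], paths[["taxonomy"]], paths[["tree"]])
  expect_identical(fw$alignment, rs$alignment)
  fams <- Filter(function(g) g$rank == "family", fw$groups)
  expect_setequal(names(fams), spec$taxa)
  for (tx in spec$taxa) {
    expect_setequal(fw$groups[[tx]]$member_ids,
                    rs$taxonomy$id[rs$taxonomy$family == tx])
  }
  expect_setequal(fw$tree$tip.label, rs$taxonomy$id)
})

test_that("check_monophyly handles clean, mixed and single-leaf taxa", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  clean <- check_monophyly(tr, c("A", "B"))
  expect_equal(clean$status, "monophyletic")
  expect_length(clean$intruder_ids, 0)

  mixed <- check_monophyly(tr, c("A", "C"))
  expect_equal(mixed$status, "not_monophyletic")
  expect_setequal(mixed$intruder_ids, oracle_intruders(tr, c("A", "C")))

  single <- check_monophyly(tr, "A")
  expect_equal(single$status, "single-leaf")
  expect_true(single$monophyletic)

  expect_equal(check_monophyly(tr, c("Z1", "Z2"))$status, "unresolvable")
})

test_that("check_monophyly agrees with exhaustive clade enumeration", {
  set.seed(41)
  for (i in 1:40) {
    ntip <- sample(4:8, 1)
    tr <- ape::rtree(ntip)
    members <- sample(tr$tip.label, sample(2:(ntip - 1), 1))
    rep <- check_monophyly(tr, members)
    expect_equal(rep$monophyletic, oracle_monophyletic(tr, members),
                 info = paste("tree", i))
    if (!rep$monophyletic) {
      expect_setequal(rep$intruder_ids, oracle_intruders(tr, members))
    }
  }
})

test_that("assay targets drop to genus rank only for non-monophyletic families", {
  # F1 monophyletic; F2 interleaved with F1... use a hand-built topology:
  # F2 genera G1 (a,b) and G2 (c,d) separated by F1's clade
  tr <- ape::read.tree(text = "(((a,b),((e,f),(g,h))),(c,d));")
  groups <- list(
    F1 = taxon_group("F1", "family", c("e", "f", "g", "h")),
    F2 = taxon_group("F2", "family", c("a", "b", "c", "d")),
    G1 = taxon_group("G1", "genus", c("a", "b")),
    G2 = taxon_group("G2", "genus", c("c", "d"))
  )
  reports <- list(F1 = check_monophyly(tr, groups$F1),
                  F2 = check_monophyly(tr, groups$F2))
  res <- resolve_assay_targets(groups, reports, tree = tr)
  expect_setequal(names(res$targets), c("F1", "G1", "G2"))
  expect_equal(res$targets$F1$rank, "family")
  expect_equal(res$targets$G1$rank, "genus")
  expect_length(res$unassayable, 0)
  # returned member sets never overlap
  ids <- unlist(lapply(res$targets, `[[`, "member_ids"))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("families with no monophyletic representation are flagged un-assayable", {
  # genera themselves interleaved: a,c vs b,d
  tr <- ape::read.tree(text = "(((a,x1),(b,x2)),((c,x3),(d,x4)));")
  groups <- list(
    FX = taxon_group("FX", "family", c("a", "b", "c", "d")),
    GA = taxon_group("GA", "genus", c("a", "b")),
    GB = taxon_group("GB", "genus", c("c", "d"))
  )
  reports <- list(FX = check_monophyly(tr, groups$FX))
  res <- resolve_assay_targets(groups, reports, tree = tr)
  expect_length(res$targets, 0)
  expect_equal(res$unassayable, "FX")
})

test_that("occurrence table loading validates and summarises", {
  tab <- occurrence_fixture()
  s <- occurrence_summary(tab)
  expect_equal(s$n_genera, 45)
  expect_equal(s$n_field, 38)
  expect_equal(s$n_forest, 25)
  expect_equal(s$n_qpcr, 20)
  expect_equal(s$n_range, 16)

  # duplicate genus rejected
  dup <- rbind(tab, tab[1, ])
  f <- tempfile(fileext = ".csv")
  write.csv(dup, f, row.names = FALSE)
  expect_error(load_occurrence_table(f), "duplicate")

  # empty table -> all counts zero
  f2 <- tempfile(fileext = ".csv")
  write.csv(tab[0, ], f2, row.names = FALSE)
  s0 <- occurrence_summary(load_occurrence_table(f2))
  expect_true(all(unlist(s0) == 0))
})

test_that("coverage_fraction applies the exclusion rule per habitat", {
  tab <- occurrence_fixture()
  forest <- coverage_fraction(tab, "forest")
  expect_equal(as.integer(forest), 72)
  expect_equal(attr(forest, "numerator"), 13)
  expect_equal(attr(forest, "denominator"), 18)

  field <- coverage_fraction(tab, "field")
  expect_equal(as.integer(field), 65)      # 20/31 under the stated rule
  expect_equal(attr(field, "denominator"), 31)

  # row permutation cannot change counts
  set.seed(7)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(as.integer(coverage_fraction(shuf, "forest")), 72)
  expect_equal(unlist(occurrence_summary(shuf)), unlist(occurrence_summary(tab)))

  # degenerate cases
  all_q <- tab
  all_q$qpcr <- TRUE; all_q$plant_parasite <- FALSE
  expect_equal(as.integer(coverage_fraction(all_q, "field")), 100)
  none <- tab
  none$field <- FALSE
  expect_error(coverage_fraction(none, "field"), "no free-living")
})
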