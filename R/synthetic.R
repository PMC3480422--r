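# Seeded synthetic data with the statistical structure of the seasonal
# survey: reference sets with planted signature motifs, calibration
# dilution series, and two-site 18-time-point Ct panels.

DEFAULT_FAMILIES <- c(
  "Alaimidae", "Aphelenchidae", "Aphelenchoididae", "Cephalobidae",
  "Diphtherophoridae", "Dorylaimidae", "Metateratocephalidae",
  "Monhysteridae", "Mononchidae", "Mylonchulidae", "Plectidae",
  "Prismatolaimidae", "Teratocephalidae", "Rhabditidae", "Panagrolaimidae"
)

DEFAULT_GUILDS <- c(
  Alaimidae = "B", Aphelenchidae = "F", Aphelenchoididae = "F",
  Cephalobidae = "B", Diphtherophoridae = "F", Dorylaimidae = "O",
  Metateratocephalidae = "B", Monhysteridae = "B", Mononchidae = "P",
  Mylonchulidae = "P", Plectidae = "B", Prismatolaimidae = "B",
  Teratocephalidae = "B", Rhabditidae = "B", Panagrolaimidae = "B"
)

DEFAULT_CP <- c(
  Alaimidae = 4, Aphelenchidae = 2, Aphelenchoididae = 2, Cephalobidae = 2,
  Diphtherophoridae = 3, Dorylaimidae = 4, Metateratocephalidae = 3,
  Monhysteridae = 2, Mononchidae = 4, Mylonchulidae = 4, Plectidae = 2,
  Prismatolaimidae = 3, Teratocephalidae = 3, Rhabditidae = 1,
  Panagrolaimidae = 1
)

# 18 sampling occasions between week 1 (mid March) and week 40 (mid
# December), every 2-4 weeks, as in the emulated survey design
DEFAULT_WEEKS <- c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 26, 29, 32, 35, 38, 40)

#' Specification for the synthetic-data generators
#'
#' Bundles every knob of the synthetic world: the reference-set geometry
#' (taxa, members, sequence and planted-motif lengths), the true
#' calibration curves, the Ct and observation noise, and the seasonal
#' density model.  With `n_taxa = 15` (the monitored panel size of the
#' emulated survey) the taxa carry the names of real soil nematode
#' families and, where available, the packaged calibration parameters as
#' true curves.  The seasonal model gives each taxon and site a
#' log-normal density trajectory around a smooth annual cycle
#' `base * exp(amp * sin(2 pi (week - phase) / 40))`, drawn once,
#' deterministically, from the seed.
#'
#' @param seed integer master seed; everything downstream derives from
#'   it, so a fixed seed yields byte-identical outputs.
#' @param n_taxa number of monitored taxa (default 15).
#' @param members_per_taxon reference sequences per taxon.
#' @param seq_length ungapped reference sequence length, nt (default
#'   1700, full-length SSU rDNA scale).
#' @param motif_length planted signature motif length, nt.
#' @param motif_taxa taxa that receive planted signature motifs
#'   (default: all).
#' @param polyphyletic_taxa taxa whose two genera are interleaved in the
#'   reference tree, making the family non-monophyletic.
#' @param ct_noise_sd Gaussian Ct noise, cycles (default 0.3).
#' @param dispersion log-normal sdlog of sampled densities around the
#'   seasonal mean (default 0.3).
#' @param sample_effect_sd log10 sd of a community-wide per-sample
#'   multiplier (correlated across taxa), giving synthetic total
#'   densities a realistic coefficient of variation (default 0.15).
#' @param obs_noise_sd log10 observation error of the synthetic
#'   microscopy totals (default 0.2).
#' @param weeks sampling weeks (default: 18 occasions over weeks 1-40).
#' @param reps_field,reps_forest composite samples per occasion
#'   (defaults 4 and 2).
#' @param true_curves data frame `taxon, a, b` of true calibration
#'   parameters; defaults to the packaged assay table where taxon names
#'   match, else to mid-range values.
#' @return an `nq_synthetic_spec` list.
#' @export
synthetic_spec <- function(seed, n_taxa = 15L, members_per_taxon = 3L,
                           seq_length = 1700L, motif_length = 20L,
                           motif_taxa = NULL, polyphyletic_taxa = character(0),
                           ct_noise_sd = 0.3, dispersion = 0.3,
                           sample_effect_sd = 0.15,
                           obs_noise_sd = 0.2, weeks = DEFAULT_WEEKS,
                           reps_field = 4L, reps_forest = 2L,
                           true_curves = NULL) {
  taxa <- if (n_taxa <= length(DEFAULT_FAMILIES)) {
    DEFAULT_FAMILIES[seq_len(n_taxa)]
  } else {
    c(DEFAULT_FAMILIES, sprintf("Synthfamilia%02d", seq_len(n_taxa - length(DEFAULT_FAMILIES))))
  }
  if (is.null(motif_taxa)) motif_taxa <- taxa
  if (motif_length >= seq_length) {
    stop("motif_length must be smaller than seq_length", call. = FALSE)
  }
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  if (is.null(true_curves)) {
    fix <- tryCatch(calibration_fixture(), error = function(e) NULL)
    true_curves <- with_seed(child_seed(seed, 11), {
      a <- round(runif(length(taxa), -5.5, -3.0), 2)
      b <- round(runif(length(taxa), 15, 26), 2)
      data.frame(taxon = taxa, a = a, b = b, stringsAsFactors = FALSE)
    })
    if (!is.null(fix)) {
      for (i in seq_along(taxa)) {
        hit <- which(fix$family == taxa[i] | fix$assay == taxa[i])
        if (length(hit) > 0L) {
          true_curves$a[i] <- fix$a[hit[1]]
          true_curves$b[i] <- fix$b[hit[1]]
        }
      }
    }
  }
  guilds <- ifelse(taxa %in% names(DEFAULT_GUILDS),
                   DEFAULT_GUILDS[taxa],
                   rep_len(c("B", "F", "O", "P"), length(taxa)))
  cp <- ifelse(taxa %in% names(DEFAULT_CP), DEFAULT_CP[taxa],
               rep_len(c(2, 3), length(taxa)))
  seasonal <- with_seed(child_seed(seed, 13), {
    do.call(rbind, lapply(c("field", "forest"), function(site) {
      data.frame(
        taxon = taxa, site = site,
        base = round(10^runif(length(taxa), 0.8, 2.3), 2),
        amp = round(runif(length(taxa), 0.3, 1.0), 3),
        phase = round(runif(length(taxa), 0, 40), 1),
        stringsAsFactors = FALSE
      )
    }))
  })
  structure(list(
    seed = seed, n_taxa = as.integer(n_taxa), taxa = taxa,
    members_per_taxon = as.integer(members_per_taxon),
    seq_length = as.integer(seq_length),
    motif_length = as.integer(motif_length),
    motif_taxa = motif_taxa, polyphyletic_taxa = polyphyletic_taxa,
    ct_noise_sd = ct_noise_sd, dispersion = dispersion,
    sample_effect_sd = sample_effect_sd,
    obs_noise_sd = obs_noise_sd, weeks = weeks,
    reps_field = as.integer(reps_field),
    reps_forest = as.integer(reps_forest),
    guilds = setNames(unname(guilds), taxa),
    cp = setNames(as.numeric(cp), taxa),
    true_curves = true_curves, seasonal = seasonal
  ), class = "nq_synthetic_spec")
}

#' Generate a synthetic aligned reference set with planted signatures
#'
#' Builds a gapped SSU-rDNA-like alignment, taxonomy and reference tree
#' in which every taxon listed in `spec$motif_taxa` carries two planted
#' taxon-specific motifs (a forward and a reverse primer site an
#' amplicon-length apart); all non-targets keep the shared template at
#' those positions, so the planted windows are unique by construction.
#' Members of a taxon are identical inside their motif slots and carry
#' random private substitutions elsewhere.  A short insertion present in
#' alternating taxa makes the alignment genuinely gapped.  Taxa named in
#' `spec$polyphyletic_taxa` have their two genera interleaved with the
#' other families in the tree, so the family is not monophyletic while
#' both genera are.
#'
#' @param spec an [synthetic_spec()].
#' @return an `nq_reference_set`: list with `alignment` (named character
#'   vector), `taxonomy` (data frame `id, genus, family, guild, cp`),
#'   `newick`, `tree` ([ape::phylo]), `slots` (planted window
#'   coordinates per taxon, ungapped 1-based), `spec`.
#' @export
generate_reference_set <- function(spec) {
  taxa <- spec$taxa
  motif <- spec$motif_length
  gap_inner <- 60L                      # amplicon = gap_inner + 2 * motif
  stride <- (spec$seq_length - 50L) %/% spec$n_taxa
  if (stride < 2L * motif + gap_inner + 5L) {
    stop("reference geometry infeasible: sequence too short for ",
         spec$n_taxa, " taxa with ", motif, "-nt motifs", call. = FALSE)
  }
  if (4^motif < 4 * spec$n_taxa) {
    stop("motif space too small for unique signatures", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  with_seed(child_seed(spec$seed, 1), {
    template <- sample(bases, spec$seq_length, replace = TRUE)
    slots <- lapply(seq_along(taxa), function(t) {
      a <- 25L + (t - 1L) * stride
      b <- a + motif + gap_inner
      list(fwd = c(a, a + motif - 1L), rev = c(b, b + motif - 1L))
    })
    names(slots) <- taxa
    all_slot_pos <- unlist(lapply(slots, function(s) {
      c(s$fwd[1]:s$fwd[2], s$rev[1]:s$rev[2])
    }))

    seqs <- list(); tax_rows <- list()
    for (t in seq_along(taxa)) {
      tx <- taxa[t]
      base_seq <- template
      if (tx %in% spec$motif_taxa) {
        for (w in slots[[tx]]) {
          idx <- w[1]:w[2]
          # substitute every motif position so non-targets mismatch
          # throughout the window
          base_seq[idx] <- vapply(template[idx], function(x) {
            sample(setdiff(bases, x), 1L)
          }, "")
        }
      }
      n_gen <- if (spec$members_per_taxon >= 2L) 2L else 1L
      for (m in seq_len(spec$members_per_taxon)) {
        id <- sprintf("%s_%02d", tx, m)
        s <- base_seq
        mut <- sample(setdiff(seq_len(spec$seq_length), all_slot_pos),
                      max(1L, spec$seq_length %/% 100L))
        s[mut] <- vapply(s[mut], function(x) sample(setdiff(bases, x), 1L), "")
        seqs[[id]] <- s
        genus <- sprintf("%s_g%d", tx, ((m - 1L) %% n_gen) + 1L)
        tax_rows[[id]] <- data.frame(
          id = id, genus = genus, family = tx,
          guild = unname(spec$guilds[tx]), cp = unname(spec$cp[tx]),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  taxonomy <- do.call(rbind, tax_rows)
  rownames(taxonomy) <- NULL

  # gapped alignment: a 6-nt insert carried by odd-indexed taxa only
  ins_at <- 12L
  ins <- c("T", "C", "A", "G", "C", "T")
  aln <- vapply(names(seqs), function(id) {
    tx_i <- match(taxonomy$family[taxonomy$id == id], taxa)
    s <- seqs[[id]]
    piece <- if (tx_i %% 2L == 1L) ins else rep("-", 6L)
    paste(c(s[1:ins_at], piece, s[(ins_at + 1L):length(s)]), collapse = "")
  }, "")

  # slots are reported in ungapped coordinates of the taxon's own members;
  # taxa carrying the insertion are shifted by its length
  slots <- lapply(seq_along(taxa), function(t) {
    s <- slots[[t]]
    if (t %% 2L == 1L) s <- lapply(s, `+`, 6L)
    s
  })
  names(slots) <- taxa

  newick <- build_newick(taxonomy, taxa, spec$polyphyletic_taxa)
  structure(list(
    alignment = aln, taxonomy = taxonomy, newick = newick,
    tree = ape::read.tree(text = newick),
    slots = slots, spec = spec
  ), class = "nq_reference_set")
}

# caterpillar tree over family clades; polyphyletic families contribute
# their genus clades at opposite ends so other families intervene
build_newick <- function(taxonomy, taxa, polyphyletic) {
  genus_clade <- function(ids) {
    if (length(ids) == 1L) ids else paste0("(", paste(ids, collapse = ","), ")")
  }
  units <- list(); tail_units <- list()
  for (tx in taxa) {
    rows <- taxonomy[taxonomy$family == tx, ]
    by_genus <- split(rows$id, rows$genus)
    clades <- vapply(by_genus, genus_clade, "")
    if (tx %in% polyphyletic && length(clades) >= 2L) {
      units[[length(units) + 1L]] <- clades[[1]]
      tail_units[[length(tail_units) + 1L]] <- clades[[2]]
      for (k in seq_along(clades)[-(1:2)]) {
        units[[length(units) + 1L]] <- clades[[k]]
      }
    } else {
      units[[length(units) + 1L]] <-
        if (length(clades) == 1L) clades[[1]]
        else paste0("(", paste(clades, collapse = ","), ")")
    }
  }
  units <- c(units, tail_units)
  tree <- units[[1]]
  for (u in units[-1]) tree <- paste0("(", tree, ",", u, ")")
  paste0(tree, ";")
}

#' Write a synthetic reference set to disk
#'
#' Emits the same dialects [load_framework()] reads: `reference.fasta`
#' (gapped FASTA), `taxonomy.tsv`, `reference.nwk`.  Output is
#' byte-deterministic for a fixed spec.
#'
#' @param refset an `nq_reference_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_reference_set <- function(refset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fasta")
  writeLines(paste0(">", names(refset$alignment), "\n", refset$alignment),
             fasta)
  taxp <- file.path(dir, "taxonomy.tsv")
  utils::write.table(refset$taxonomy, taxp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nwk <- file.path(dir, "reference.nwk")
  writeLines(refset$newick, nwk)
  invisible(c(fasta = fasta, taxonomy = taxp, tree = nwk))
}

#' Generate a synthetic calibration dilution series
#'
#' Emulates hand-picked calibration vials: Ct values at 1, 5, 10, 50 and
#' 100 nematodes on the taxon's true line plus Gaussian Ct noise.
#'
#' @param spec an [synthetic_spec()].
#' @param taxon a taxon named in `spec$true_curves`.
#' @param n_list nematode counts (default the 1/5/10/50/100 protocol).
#' @param replicates series per count.
#' @return data frame `assay, genus, n, ct`.
#' @export
generate_calibration_series <- function(spec, taxon,
                                        n_list = c(1, 5, 10, 50, 100),
                                        replicates = 1L) {
  row <- which(spec$true_curves$taxon == taxon)
  if (length(row) == 0L) stop("unknown taxon: ", taxon, call. = FALSE)
  a <- spec$true_curves$a[row[1]]
  b <- spec$true_curves$b[row[1]]
  n <- rep(n_list, each = replicates)
  ct <- with_seed(child_seed(spec$seed, 100 + row[1]), {
    a * log10(n) + b + rnorm(length(n), 0, spec$ct_noise_sd)
  })
  data.frame(assay = taxon, genus = paste0(taxon, "_g1"), n = n, ct = ct,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic seasonal survey
#'
#' Draws true per-taxon densities from the spec's seasonal model for
#' every composite sample (by default 4 field + 2 forest composites at
#' each of 18 occasions), converts them to Ct panels through the true
#' calibration curves plus Ct noise, and produces microscopy-style total
#' counts with log-normal observation error -- so every downstream
#' quantity has a known ground truth.  Panel Cts are emitted at
#' calibration dilution with a complete-recovery internal standard
#' (Ct 20), so [quantify_sample()] with `dilution_adjustment = 1`
#' recovers the truth.
#'
#' @param spec an [synthetic_spec()].
#' @return list with `panels` (long data frame `sample_id, site, week,
#'   assay, ct, internal_standard_ct`), `truth` (data frame `sample_id,
#'   site, week, taxon, density`), `microscopy` (data frame `sample_id,
#'   total` with observation error), `true_totals`, `curves` (named
#'   list of true `nq_calibration_curve`), and
#'   `reference_standard_ct`.
#' @export
generate_survey <- function(spec) {
  curves <- setNames(lapply(seq_len(nrow(spec$true_curves)), function(i) {
    calibration_curve(spec$true_curves$taxon[i],
                      a = spec$true_curves$a[i], b = spec$true_curves$b[i])
  }), spec$true_curves$taxon)
  grid <- do.call(rbind, lapply(spec$weeks, function(w) {
    rbind(
      data.frame(site = "field", week = w, rep = seq_len(spec$reps_field)),
      data.frame(site = "forest", week = w, rep = seq_len(spec$reps_forest))
    )
  }))
  grid$sample_id <- sprintf("%s_w%02d_r%d", grid$site, grid$week, grid$rep)

  res <- with_seed(child_seed(spec$seed, 3), {
    truth <- list(); panels <- list()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      sm <- spec$seasonal[spec$seasonal$site == g$site, ]
      mu <- sm$base[match(spec$taxa, sm$taxon)] *
        exp(sm$amp[match(spec$taxa, sm$taxon)] *
              sin(2 * pi * (g$week - sm$phase[match(spec$taxa, sm$taxon)]) / 40))
      sample_effect <- 10^rnorm(1, 0, spec$sample_effect_sd)
      d <- mu * sample_effect * rlnorm(length(mu), 0, spec$dispersion)
      ct <- vapply(seq_along(spec$taxa), function(k) {
        curves[[spec$taxa[k]]]$a * log10(d[k]) + curves[[spec$taxa[k]]]$b
      }, 0) + rnorm(length(d), 0, spec$ct_noise_sd)
      truth[[i]] <- data.frame(
        sample_id = g$sample_id, site = g$site, week = g$week,
        taxon = spec$taxa, density = d, stringsAsFactors = FALSE
      )
      panels[[i]] <- data.frame(
        sample_id = g$sample_id, site = g$site, week = g$week,
        assay = spec$taxa, ct = ct, internal_standard_ct = 20,
        stringsAsFactors = FALSE
      )
    }
    totals <- vapply(truth, function(d) sum(d$density), 0)
    microscopy <- totals * 10^rnorm(length(totals), 0, spec$obs_noise_sd)
    list(truth = do.call(rbind, truth), panels = do.call(rbind, panels),
         totals = totals, microscopy = microscopy)
  })
  list(
    panels = res$panels, truth = res$truth,
    true_totals = data.frame(sample_id = grid$sample_id,
                             total = res$totals, stringsAsFactors = FALSE),
    microscopy = data.frame(sample_id = grid$sample_id,
                            total = res$microscopy, stringsAsFactors = FALSE),
    curves = curves, reference_standard_ct = 20
  )
}
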