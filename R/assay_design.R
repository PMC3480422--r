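# Assay design: signature motif discovery, primer-pair enumeration at a
# uniform annealing temperature, specificity scoring, assay selection.

#' Default primer design constraints
#'
#' All assays share one annealing temperature so that a whole community
#' panel runs on a single plate program.
#'
#' @param ta_target design annealing temperature, degrees C.
#' @param ta_tolerance allowed deviation of a primer's Tm from
#'   `ta_target`, degrees C.
#' @param amplicon_min,amplicon_max amplicon length bounds, nt.
#' @param primer_min,primer_max primer length bounds, nt.
#' @param max_tm_diff maximum Tm difference within a pair, degrees C.
#' @param min_mismatch minimum number of mismatches every non-target
#'   must show against a signature window.
#' @return a named list of constraints.
#' @export
design_constraints <- function(ta_target = 63, ta_tolerance = 1,
                               amplicon_min = 80, amplicon_max = 400,
                               primer_min = 18, primer_max = 25,
                               max_tm_diff = 2, min_mismatch = 2) {
  list(ta_target = ta_target, ta_tolerance = ta_tolerance,
       amplicon_min = amplicon_min, amplicon_max = amplicon_max,
       primer_min = primer_min, primer_max = primer_max,
       max_tm_diff = max_tm_diff, min_mismatch = min_mismatch)
}

#' Discover taxon-specific signature windows in an alignment
#'
#' Scans the gapped alignment for windows (in ungapped coordinates of a
#' representative target sequence, reported 1-based inclusive) in which
#' all target members agree -- IUPAC ambiguity sets must intersect across
#' members -- while every non-target differs by at least
#' `constraints$min_mismatch` positions.  A position matches when the
#' ambiguity sets of primer/consensus and reference intersect; a gap in
#' any member breaks conservation, a gap in a non-target counts as a
#' mismatch.  Windows are ranked by specificity with mismatches in the
#' 3'-terminal five positions weighted first (worst non-target decides).
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (or an `nq_framework`).
#' @param target an `nq_taxon_group` or character vector of member ids.
#' @param nontargets ids of non-target sequences; default all others.
#' @param constraints see [design_constraints()]; window lengths are the
#'   primer length bounds.
#' @return data frame (class `nq_windows`) with columns `start`, `end`
#'   (1-based inclusive ungapped positions on the representative),
#'   `length`, `seq` (IUPAC consensus), `min_total_mm`, `min_3p_mm`
#'   (worst-case non-target mismatches, total and in the 3' pentamer),
#'   and list column `acols` (alignment columns of each window).  Empty
#'   when no signature exists.
#' @export
find_signature_windows <- function(alignment, target, nontargets = NULL,
                                   constraints = design_constraints()) {
  if (inherits(alignment, "nq_framework")) alignment <- alignment$alignment
  members <- if (inherits(target, "nq_taxon_group")) target$member_ids else target
  missing_m <- setdiff(members, names(alignment))
  if (length(missing_m) > 0L) {
    stop("target members absent from alignment: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (is.null(nontargets)) nontargets <- setdiff(names(alignment), members)
  if (length(nontargets) == 0L) stop("need at least one non-target", call. = FALSE)

  rep_chars <- seq_chars(alignment[[members[1]]])
  rep_cols <- which(!rep_chars %in% c("-", "."))     # alignment col per ungapped pos
  member_mat <- do.call(rbind, lapply(alignment[members], seq_chars))
  nt_mat <- do.call(rbind, lapply(alignment[nontargets], seq_chars))

  n_pos <- length(rep_cols)
  consensus <- character(n_pos)
  conserved <- logical(n_pos)
  for (j in seq_len(n_pos)) {
    s <- iupac_intersect(member_mat[, rep_cols[j]])
    if (!is.null(s)) {
      conserved[j] <- TRUE
      consensus[j] <- iupac_code_for(s)
    }
  }
  # non-target mismatch indicator per ungapped position
  mm <- matrix(FALSE, nrow = length(nontargets), ncol = n_pos)
  for (j in which(conserved)) {
    mm[, j] <- !iupac_compatible(rep(consensus[j], length(nontargets)),
                                 nt_mat[, rep_cols[j]])
  }

  out <- list()
  for (len in seq(constraints$primer_min, constraints$primer_max)) {
    if (len > n_pos) next
    for (start in seq_len(n_pos - len + 1L)) {
      idx <- start:(start + len - 1L)
      if (!all(conserved[idx])) next
      tot <- rowSums(mm[, idx, drop = FALSE])
      if (min(tot) < constraints$min_mismatch) next
      p3 <- rowSums(mm[, idx[(len - 4L):len], drop = FALSE])
      out[[length(out) + 1L]] <- list(
        start = start, end = start + len - 1L, length = len,
        seq = paste(consensus[idx], collapse = ""),
        min_total_mm = min(tot), min_3p_mm = min(p3),
        acols = rep_cols[idx]
      )
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0),
                      min_total_mm = integer(0), min_3p_mm = integer(0))
    res$acols <- list()
  } else {
    res <- data.frame(
      start = vapply(out, `[[`, 1L, "start"),
      end = vapply(out, `[[`, 1L, "end"),
      length = vapply(out, `[[`, 1L, "length"),
      seq = vapply(out, `[[`, "", "seq"),
      min_total_mm = vapply(out, `[[`, 1, "min_total_mm"),
      min_3p_mm = vapply(out, `[[`, 1, "min_3p_mm"),
      stringsAsFactors = FALSE
    )
    res$acols <- lapply(out, `[[`, "acols")
    res <- res[order(-res$min_3p_mm, -res$min_total_mm, res$start), ]
    rownames(res) <- NULL
  }
  class(res) <- c("nq_windows", "data.frame")
  res
}

#' Construct a primer pair
#'
#' @param forward_seq,reverse_seq primer sequences 5'->3' (the reverse
#'   primer is the reverse complement of its plus-strand site).
#' @param fwd_window,rev_window `(start, end)` 1-based inclusive ungapped
#'   coordinates of the two sites on the representative target.
#' @param ta design annealing temperature (degrees C).
#' @param conditions thermodynamic conditions, see [compute_tm()].
#' @param acols_fwd,acols_rev optional alignment columns of each site
#'   (needed by [score_specificity()]).
#' @return an `nq_primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq, fwd_window, rev_window,
                        ta = 63,
                        conditions = list(monovalent_cation_M = 0.05,
                                          primer_conc_M = 2e-7),
                        acols_fwd = NULL, acols_rev = NULL) {
  for (s in c(forward_seq, reverse_seq)) {
    if (nchar(s) < 15L || nchar(s) > 30L) {
      stop("primer length must be in [15, 30] nt: ", s, call. = FALSE)
    }
  }
  if (fwd_window[2] >= rev_window[1]) {
    stop("forward site must precede the reverse site", call. = FALSE)
  }
  mk <- function(seq, window, strand) {
    structure(list(
      sequence = seq, ref_window = as.integer(window), strand = strand,
      tm = compute_tm(seq, conditions),
      gc_fraction = mean(seq_chars(seq) %in% c("G", "C", "S"))
    ), class = "nq_primer")
  }
  structure(list(
    forward = mk(forward_seq, fwd_window, "forward"),
    reverse = mk(reverse_seq, rev_window, "reverse"),
    amplicon_length = as.integer(rev_window[2] - fwd_window[1] + 1L),
    ta = ta, acols_fwd = acols_fwd, acols_rev = acols_rev,
    site_rev_seq = reverse_complement(reverse_seq)
  ), class = "nq_primer_pair")
}

#' @export
print.nq_primer_pair <- function(x, ...) {
  cat(sprintf("<primer pair> F %s (Tm %.1f) / R %s (Tm %.1f), amplicon %d nt, Ta %g\n",
              x$forward$sequence, x$forward$tm,
              x$reverse$sequence, x$reverse$tm, x$amplicon_length, x$ta))
  invisible(x)
}

#' Enumerate candidate primer pairs from signature windows
#'
#' Combines every ordered pair of signature windows into a candidate
#' forward/reverse primer pair (reverse primer = reverse complement of
#' the downstream window) and keeps those whose primer Tm values fall
#' within `ta_tolerance` of the design annealing temperature, whose
#' amplicon length lies within bounds, and whose within-pair Tm
#' difference does not exceed `max_tm_diff`.  Pairs are sorted by the
#' larger deviation of the two Tm values from the target.
#'
#' @param windows an `nq_windows` table from [find_signature_windows()];
#'   a second table (e.g. conserved, non-specific flanking sites) may be
#'   supplied via `flanks` to pair a single signature window with a
#'   universal primer site.
#' @param conditions thermodynamic conditions, see [compute_tm()].
#' @param constraints see [design_constraints()].
#' @param flanks optional second `nq_windows` table.
#' @return list of `nq_primer_pair` (possibly empty).
#' @export
enumerate_primer_pairs <- function(windows,
                                   conditions = list(monovalent_cation_M = 0.05,
                                                     primer_conc_M = 2e-7),
                                   constraints = design_constraints(),
                                   flanks = NULL) {
  pool <- windows
  if (!is.null(flanks) && nrow(flanks) > 0L) {
    pool <- rbind(windows[, names(flanks)], flanks)
    pool$acols <- c(windows$acols, flanks$acols)
  }
  n <- nrow(pool)
  if (n < 2L) return(list())
  tm <- vapply(pool$seq, function(s) {
    tryCatch(compute_tm(s, conditions), error = function(e) NA_real_)
  }, 0)
  lo <- constraints$ta_target - constraints$ta_tolerance
  hi <- constraints$ta_target + constraints$ta_tolerance
  ok <- !is.na(tm) & tm >= lo & tm <= hi
  pairs <- list()
  for (i in which(ok)) {
    for (j in which(ok)) {
      if (pool$end[i] >= pool$start[j]) next     # forward must precede reverse
      amp <- pool$end[j] - pool$start[i] + 1L
      if (amp < constraints$amplicon_min || amp > constraints$amplicon_max) next
      if (abs(tm[i] - tm[j]) > constraints$max_tm_diff) next
      pairs[[length(pairs) + 1L]] <- primer_pair(
        pool$seq[i], reverse_complement(pool$seq[j]),
        c(pool$start[i], pool$end[i]), c(pool$start[j], pool$end[j]),
        ta = constraints$ta_target, conditions = conditions,
        acols_fwd = pool$acols[[i]], acols_rev = pool$acols[[j]]
      )
    }
  }
  if (length(pairs) > 1L) {
    dev <- vapply(pairs, function(p) {
      max(abs(p$forward$tm - constraints$ta_target),
          abs(p$reverse$tm - constraints$ta_target))
    }, 0)
    pairs <- pairs[order(dev)]
  }
  pairs
}

#' Score the specificity of a primer pair
#'
#' Specificity of an assay is expressed as the Ct gap between the
#' latest-amplifying target and the earliest-amplifying non-target
#' (delta Ct).  When empirical Ct values are available they define the
#' gap directly.  Otherwise an in-silico proxy is computed from
#' per-non-target mismatch counts: a non-target is predicted
#' non-amplifiable when either primer carries >= 2 mismatches in its
#' 3'-terminal five positions or >= 4 mismatches in total; if at least
#' one non-target remains amplifiable the proxy gap is 3.3 cycles per
#' mismatch of the closest amplifiable non-target (a labelled heuristic,
#' always overridden by measurements), and when none is amplifiable the
#' gap is not available (`NA`, reported as `not_available`), mirroring
#' assays whose non-targets produce no signal at all.
#'
#' @param pair an `nq_primer_pair` with alignment columns attached (as
#'   produced by [enumerate_primer_pairs()]); not needed for purely
#'   empirical scoring.
#' @param target_seqs,nontarget_seqs named aligned sequences (same
#'   alignment the pair was designed on).
#' @param empirical optional numeric `c(latest_target_ct,
#'   earliest_nontarget_ct)`.
#' @param max_target_mismatch mismatches tolerated against a target
#'   member before the pair is rejected (default 0).
#' @return an `nq_specificity`: list with `per_nontarget` (data frame of
#'   mismatch counts and `predicted_amplifiable`), `delta_ct` (cycles or
#'   `NA` = not available), `not_available`, `source`
#'   (`"in_silico"`/`"empirical"`).
#' @export
score_specificity <- function(pair, target_seqs = NULL, nontarget_seqs = NULL,
                              empirical = NULL, max_target_mismatch = 0L) {
  per_nt <- data.frame(id = character(0), mismatches_total_fwd = integer(0),
                       mismatches_3prime_fwd = integer(0),
                       mismatches_total_rev = integer(0),
                       mismatches_3prime_rev = integer(0),
                       predicted_amplifiable = logical(0))
  if (!is.null(target_seqs) || !is.null(nontarget_seqs)) {
    if (is.null(pair$acols_fwd) || is.null(pair$acols_rev)) {
      stop("pair carries no alignment columns; design it with ",
           "enumerate_primer_pairs()", call. = FALSE)
    }
    fwd <- seq_chars(pair$forward$sequence)
    revsite <- seq_chars(pair$site_rev_seq)   # plus-strand sense
    site_mm <- function(aligned_seq) {
      ch <- seq_chars(aligned_seq)
      mf <- !iupac_compatible(fwd, ch[pair$acols_fwd])
      mr <- !iupac_compatible(revsite, ch[pair$acols_rev])
      # forward primer 3' end = right end of its site; reverse primer
      # 3' end = left end of the plus-strand site
      nf <- length(mf); nr <- length(mr)
      c(tf = sum(mf), f3 = sum(mf[(nf - 4L):nf]),
        tr = sum(mr), r3 = sum(mr[1:5]))
    }
    for (id in names(target_seqs)) {
      m <- site_mm(target_seqs[[id]])
      if (m[["tf"]] > max_target_mismatch || m[["tr"]] > max_target_mismatch) {
        stop("primer pair fails to match target member ", id, call. = FALSE)
      }
    }
    if (!is.null(nontarget_seqs) && length(nontarget_seqs) > 0L) {
      rows <- lapply(names(nontarget_seqs), function(id) {
        m <- site_mm(nontarget_seqs[[id]])
        data.frame(id = id,
                   mismatches_total_fwd = m[["tf"]],
                   mismatches_3prime_fwd = m[["f3"]],
                   mismatches_total_rev = m[["tr"]],
                   mismatches_3prime_rev = m[["r3"]],
                   predicted_amplifiable =
                     !(m[["f3"]] >= 2L || m[["r3"]] >= 2L ||
                       m[["tf"]] >= 4L || m[["tr"]] >= 4L),
                   stringsAsFactors = FALSE)
      })
      per_nt <- do.call(rbind, rows)
    }
  }

  if (!is.null(empirical)) {
    if (length(empirical) != 2L || !all(is.finite(empirical))) {
      stop("empirical must be c(latest_target_ct, earliest_nontarget_ct)",
           call. = FALSE)
    }
    delta <- empirical[[2]] - empirical[[1]]
    source <- "empirical"
    na <- FALSE
  } else {
    source <- "in_silico"
    amp <- per_nt$predicted_amplifiable
    if (nrow(per_nt) == 0L || !any(amp)) {
      delta <- NA_real_
      na <- nrow(per_nt) > 0L    # non-targets exist but none amplifies
    } else {
      tot <- per_nt$mismatches_total_fwd + per_nt$mismatches_total_rev
      delta <- 3.3 * min(tot[amp])
      na <- FALSE
    }
  }
  structure(list(per_nontarget = per_nt, delta_ct = delta,
                 not_available = na, source = source),
            class = "nq_specificity")
}

#' Assess the sharpness of an annealing-temperature optimum
#'
#' Assays are selected only when their Ct-versus-Ta profile has a sharp
#' optimum at the design temperature: flat profiles (no Ta dependence)
#' and profiles whose minimum lies away from the design Ta are rejected.
#' Sharpness is the least-squares slope of Ct on Ta over the points at
#' and above the design temperature, in cycles per degree.
#'
#' @param profile data frame with columns `ta` (degrees C) and `ct`
#'   (cycles); needs points below, at and above `ta_target`.
#' @param ta_target design annealing temperature.
#' @param sharpness_threshold minimum slope (cycles/degree C) above
#'   `ta_target` to call the optimum sharp.
#' @param tolerance cycles by which the Ct at `ta_target` may exceed the
#'   profile minimum and still count as optimal.
#' @return list with `sharpness`, `ct_at_ta`, `pass`.
#' @export
assess_ta_optimum <- function(profile, ta_target = 63,
                              sharpness_threshold = 1, tolerance = 0.5) {
  if (!all(c("ta", "ct") %in% names(profile)) || nrow(profile) < 3L) {
    stop("profile needs >= 3 (ta, ct) points", call. = FALSE)
  }
  if (!any(profile$ta < ta_target) || !any(profile$ta > ta_target) ||
      !any(profile$ta == ta_target)) {
    stop("profile must include points below, at and above ", ta_target,
         " degrees C", call. = FALSE)
  }
  above <- profile[profile$ta >= ta_target, ]
  sharpness <- unname(coef(lm(ct ~ ta, data = above))[2])
  ct_at <- profile$ct[profile$ta == ta_target][1]
  pass <- sharpness >= sharpness_threshold &&
    ct_at <= min(profile$ct) + tolerance
  list(sharpness = sharpness, ct_at_ta = ct_at, pass = pass)
}

#' Select one assay per taxon from scored candidates
#'
#' Candidates whose specificity gap (delta Ct) is numerically below
#' `min_delta_ct` cycles are discarded.  Among the survivors the largest
#' gap wins, with "not available" (no non-target signal at all) ranking
#' above any numeric gap; ties are broken by the lowest Ct per unit of
#' template and finally by primer sequence, so the choice is invariant
#' under permutation of the candidate list.
#'
#' @param candidates list of candidates, each a list with elements
#'   `pair` (`nq_primer_pair`), `score` (`nq_specificity`) and
#'   `unit_template_ct` (Ct on a defined amount of target template).
#' @param taxon taxon name for the resulting assay.
#' @param min_delta_ct discard threshold in cycles (default 12).
#' @return an `nq_assay`: list with `taxon`, `pair`, `delta_ct`,
#'   `not_available`, `source`, `unit_template_ct`,
#'   `status = "selected"`, and attribute `n_discarded`.
#' @export
select_assay <- function(candidates, taxon = NA_character_, min_delta_ct = 12) {
  if (length(candidates) == 0L) stop("no candidates supplied", call. = FALSE)
  delta <- vapply(candidates, function(c) {
    d <- c$score$delta_ct
    if (is.null(d) || is.na(d)) NA_real_ else d
  }, 0)
  navail <- vapply(candidates, function(c) isTRUE(c$score$not_available), TRUE)
  unit <- vapply(candidates, function(c) c$unit_template_ct %||% NA_real_, 0)
  keep <- navail | (!is.na(delta) & delta >= min_delta_ct)
  if (!any(keep)) {
    stop("no assay passes the specificity gap filter (delta Ct >= ",
         min_delta_ct, ")", call. = FALSE)
  }
  fwd <- vapply(candidates, function(c) c$pair$forward$sequence, "")
  rev_ <- vapply(candidates, function(c) c$pair$reverse$sequence, "")
  rank_delta <- ifelse(navail, Inf, delta)
  ord <- order(!keep, -rank_delta, unit, fwd, rev_)
  best <- candidates[[ord[1]]]
  structure(list(
    taxon = taxon, pair = best$pair,
    delta_ct = best$score$delta_ct,
    not_available = isTRUE(best$score$not_available),
    source = best$score$source,
    unit_template_ct = best$unit_template_ct %||% NA_real_,
    status = "selected"
  ), class = "nq_assay", n_discarded = sum(!keep))
}
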