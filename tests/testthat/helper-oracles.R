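# Independent brute-force oracles and small fixture builders.  These
# deliberately re-derive results from first principles (enumeration,
# closed forms) and never call the implementation paths they check.

# ---- phylogeny ----

# every clade of a rooted tree as a list of tip-label sets
enumerate_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  clades <- lapply(nodes, function(nd) {
    tips <- integer(0)
    stack <- nd
    while (length(stack) > 0) {
      cur <- stack[1]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == cur, 2]
      tips <- c(tips, kids[kids <= ntip])
      stack <- c(stack, kids[kids > ntip])
    }
    sort(tree$tip.label[tips])
  })
  c(clades, as.list(tree$tip.label))   # single leaves are clades too
}

# oracle: is `members` exactly some clade of the tree?
oracle_monophyletic <- function(tree, members) {
  members <- sort(intersect(members, tree$tip.label))
  any(vapply(enumerate_clades(tree), function(cl) {
    identical(cl, members)
  }, TRUE))
}

# oracle: smallest clade containing all members, its non-member tips
oracle_intruders <- function(tree, members) {
  clades <- enumerate_clades(tree)
  containing <- Filter(function(cl) all(members %in% cl), clades)
  sizes <- vapply(containing, length, 1L)
  smallest <- containing[[which.min(sizes)]]
  setdiff(smallest, members)
}

# ---- Mann-Whitney U ----

# exact two-sided p by full enumeration of all C(n+m, n) labelings,
# doubling the smaller tail (capped at 1), plus the U statistic for x
oracle_mwu <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# ---- Welch t ----

oracle_welch_log10 <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  vx <- var(lx) / length(lx); vy <- var(ly) / length(ly)
  t <- (mean(lx) - mean(ly)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(lx) - 1) + vy^2 / (length(ly) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# ---- Mantel ----

# exhaustive-permutation Mantel p with the add-one convention, written
# independently (permutations built by recursion over expand-style index
# vectors)
oracle_mantel_p <- function(X, Y) {
  n <- nrow(X)
  ut <- upper.tri(X)
  z_obs <- sum(X[ut] * Y[ut])
  perms <- gtools_permutations(n)
  zs <- vapply(perms, function(p) {
    Xp <- X[p, p]
    sum(Xp[ut] * Y[ut])
  }, 0)
  is_identity <- vapply(perms, function(p) all(p == seq_len(n)), TRUE)
  zs <- zs[!is_identity]
  (sum(zs >= z_obs) + 1) / (length(zs) + 1)
}

gtools_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in gtools_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# ---- tiny reference framework fixture ----

# 4 aligned sequences, 2 genera (2 families), concordant 4-leaf tree
write_tiny_framework <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  seqs <- c(
    A1 = "ACGTACGTACGTACGTACGTAAAAACGTACGTACGTACGTACGTACGTACGTACGTACGT",
    A2 = "ACGTACGTACGTACGTACGTAAAAACGTACGTACGTACGTACGTACGTACGTACGTACGT",
    B1 = "ACGTACGTACGTACGTACGTCCCCACGTACGTACGTACGTACGTACG-ACGTACGTACGT",
    B2 = "ACGTACGTACGTACGTACGTCCCCACGTACGTACGTACGTACGTACG-ACGTACGTACGT"
  )
  writeLines(paste0(">", names(seqs), "\n", seqs), file.path(dir, "aln.fasta"))
  tax <- data.frame(
    id = c("A1", "A2", "B1", "B2"),
    genus = c("Alpha", "Alpha", "Beta", "Beta"),
    family = c("Alphidae", "Alphidae", "Betidae", "Betidae"),
    guild = c("B", "B", "F", "F"), cp = c(2, 2, 3, 3)
  )
  write.table(tax, file.path(dir, "tax.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("((A1,A2),(B1,B2));", file.path(dir, "tree.nwk"))
  dir
}

# sample record helper for quantify_sample
make_sample <- function(cts, id = "s1", site = "field", week = 1,
                        internal_ct = NA_real_) {
  list(sample_id = id, site = site, week = week, cts = cts,
       internal_standard_ct = internal_ct)
}
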