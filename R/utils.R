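# Shared internals: IUPAC nucleotide sets, seeded evaluation, input checks.

# IUPAC code -> set of plain bases.  '-' (gap) maps to an empty set so it
# never matches anything.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  `-` = character(0), `.` = character(0)
)

# set of plain bases -> canonical IUPAC code
SET_TO_IUPAC <- local({
  codes <- setdiff(names(IUPAC_SETS), c("U", "-", "."))
  setNames(codes, vapply(codes, function(k) {
    paste(sort(IUPAC_SETS[[k]]), collapse = "")
  }, ""))
})

iupac_set <- function(base) {
  s <- IUPAC_SETS[[toupper(base)]]
  if (is.null(s)) stop("unknown nucleotide code: '", base, "'", call. = FALSE)
  s
}

# TRUE where the ambiguity sets of two same-length base vectors intersect
iupac_compatible <- function(a, b) {
  mapply(function(x, y) length(intersect(iupac_set(x), iupac_set(y))) > 0L,
         a, b, USE.NAMES = FALSE)
}

# intersection of ambiguity sets across a character vector of codes;
# NULL when empty (i.e. positions disagree)
iupac_intersect <- function(bases) {
  s <- iupac_set(bases[[1]])
  for (b in bases[-1]) {
    s <- intersect(s, iupac_set(b))
    if (length(s) == 0L) return(NULL)
  }
  s
}

iupac_code_for <- function(set) {
  key <- paste(sort(unique(set)), collapse = "")
  code <- SET_TO_IUPAC[[key]]
  if (is.null(code)) stop("no IUPAC code for base set {", key, "}", call. = FALSE)
  code
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

degap <- function(x) gsub("[-.]", "", x)

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

reverse_complement <- function(x) {
  ch <- rev(seq_chars(x))
  out <- REV_COMP[ch]
  if (anyNA(out)) stop("cannot complement non-nucleotide character", call. = FALSE)
  paste(out, collapse = "")
}

# Expand a degenerate sequence into all plain ACGT realisations (capped).
expand_degenerate <- function(x, max_expansions = 64L) {
  sets <- lapply(seq_chars(x), iupac_set)
  n <- prod(vapply(sets, length, 1L))
  if (n == 0) stop("sequence contains a gap character", call. = FALSE)
  if (n > max_expansions) {
    stop("degenerate sequence expands to ", n, " oligos (cap ",
         max_expansions, ")", call. = FALSE)
  }
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (kept below 2^31).
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
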