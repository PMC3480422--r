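# Nearest-neighbor oligonucleotide melting temperature.

nn_table <- function() {
  if (is.null(the$nn)) {
    path <- system.file("extdata", "nn_unified_1998.csv", package = "nemaquant")
    tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    the$nn <- setNames(lapply(seq_len(nrow(tab)), function(i) {
      c(dh = tab$dh[i], ds = tab$ds[i])
    }), tab$pair)
  }
  the$nn
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Computes the duplex melting temperature Tm of a primer against its
#' perfect complement with the unified nearest-neighbor thermodynamic
#' parameter set (stacking dH/dS per dinucleotide step, terminal
#' initiation terms, self-complementarity entropy penalty; the parameter
#' table ships as a versioned data file in `extdata`).  Monovalent salt
#' enters through the entropic correction
#' dS(salt) = dS(1 M) + 0.368 (L-1) ln\[Na+\], and
#' Tm = 1000 dH / (dS + R ln(C/4)) - 273.15 with R = 1.9872 cal/(mol K),
#' where C is the total primer concentration (C/4 is the standard
#' non-self-complementary excess convention; self-complementary duplexes
#' use C/1).
#'
#' Degenerate (IUPAC) primers are expanded into their plain realisations
#' (capped at `max_expansions`) and the worst case -- the minimum Tm,
#' i.e. the weakest-binding realisation -- is returned.
#'
#' @param primer_sequence 5'->3' primer, length >= 8, IUPAC codes
#'   allowed.
#' @param conditions list with `monovalent_cation_M` (Na+-equivalent
#'   molarity, default 0.05) and `primer_conc_M` (default 2e-7, i.e.
#'   200 nM).
#' @param max_expansions expansion cap for degenerate sequences.
#' @return Tm in degrees Celsius.
#' @examples
#' compute_tm("AGCGTAGCTAGCCTAAGGCA")
#' @export
compute_tm <- function(primer_sequence,
                       conditions = list(monovalent_cation_M = 0.05,
                                         primer_conc_M = 2e-7),
                       max_expansions = 64L) {
  if (!is.character(primer_sequence) || length(primer_sequence) != 1L) {
    stop("primer_sequence must be a single string", call. = FALSE)
  }
  s <- toupper(primer_sequence)
  if (nchar(s) < 8L) stop("primer shorter than 8 nt", call. = FALSE)
  if (grepl("[^ACGTURYSWKMBDHVN]", s)) {
    stop("non-nucleotide character in primer", call. = FALSE)
  }
  na_m <- conditions$monovalent_cation_M %||% 0.05
  ct <- conditions$primer_conc_M %||% 2e-7
  if (grepl("[^ACGT]", s)) {
    return(min(vapply(expand_degenerate(s, max_expansions),
                      tm_plain, 0, na_m = na_m, ct = ct)))
  }
  tm_plain(s, na_m, ct)
}

tm_plain <- function(s, na_m, ct) {
  nn <- nn_table()
  ch <- seq_chars(s)
  L <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(L - 1L)) {
    step <- nn[[paste0(ch[i], ch[i + 1L])]]
    dh <- dh + step[["dh"]]; ds <- ds + step[["ds"]]
  }
  for (term in c(ch[1L], ch[L])) {
    init <- if (term %in% c("G", "C")) nn[["init_GC"]] else nn[["init_AT"]]
    dh <- dh + init[["dh"]]; ds <- ds + init[["ds"]]
  }
  selfcomp <- identical(s, reverse_complement(s))
  if (selfcomp) {
    ds <- ds + nn[["sym"]][["ds"]]
  }
  ds <- ds + 0.368 * (L - 1L) * log(na_m)
  x <- if (selfcomp) 1 else 4
  1000 * dh / (ds + 1.9872 * log(ct / x)) - 273.15
}

`%||%` <- function(a, b) if (is.null(a)) b else a
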