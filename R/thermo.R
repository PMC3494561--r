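# GC content and melting temperature: nearest-neighbor thermodynamics
# with salt correction, plus the classic GC/salt/length formula.

#' Thermodynamic conditions
#'
#' Ionic and strand-concentration conditions used by the melting
#' temperature calculations, plus the Tm formula the penalty function
#' should use.
#'
#' @param sodium_molar molar Na+ concentration (M); default 0.05.
#' @param strand_molar total strand concentration for the
#'   nearest-neighbor model (M); default 2.5e-7 (250 nM).
#' @param tm_method `"nn"` (nearest-neighbor, default) or `"gc_salt"`.
#' @return An object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(sodium_molar = 0.05, strand_molar = 2.5e-7,
                              tm_method = c("nn", "gc_salt")) {
  stopifnot(is.numeric(sodium_molar), sodium_molar > 0,
            is.numeric(strand_molar), strand_molar > 0)
  structure(list(sodium_molar = sodium_molar,
                 strand_molar = strand_molar,
                 tm_method = match.arg(tm_method)),
            class = "thermo_conditions")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide stack;
# a stack and its reverse complement share one duplex value.
.NN_DH <- c(
  AA = -7.9, TT = -7.9,
  AT = -7.2,
  TA = -7.2,
  CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8,
  GA = -8.2, TC = -8.2,
  CG = -10.6,
  GC = -9.8,
  GG = -8.0, CC = -8.0)
.NN_DS <- c(
  AA = -22.2, TT = -22.2,
  AT = -20.4,
  TA = -21.3,
  CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0,
  GA = -22.2, TC = -22.2,
  CG = -27.2,
  GC = -24.4,
  GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C / A.T pair
.NN_INIT_GC <- c(dH = 0.1, dS = -2.8)
.NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
# symmetry correction for self-complementary duplexes
.NN_SYM_DS <- -1.4
.GAS_R <- 1.987  # cal/(mol K)

check_primer_seq <- function(s, op, min_len = 1L) {
  b <- seq_string(s)
  if (grepl("N", b, fixed = TRUE))
    stop(op, ": sequence contains N", call. = FALSE)
  if (nchar(b) < min_len)
    stop(op, ": sequence shorter than ", min_len, " bases", call. = FALSE)
  b
}

#' GC content of a primer (%)
#'
#' @param s primer sequence ([dna_seq] or character), non-empty, no `N`.
#' @return Percentage of G+C bases, rounded half-up to 2 decimals.
#' @examples
#' gc_percent("GTGCTTCGACCGAGTATG")  # 55.56
#' @export
gc_percent <- function(s) {
  b <- check_primer_seq(s, "gc_percent")
  ch <- strsplit(b, "", fixed = TRUE)[[1]]
  round_half_up(100 * sum(ch %in% c("G", "C")) / length(ch), 2L)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Nearest-neighbor melting temperature (degrees C)
#'
#' Duplex Tm from the unified nearest-neighbor dinucleotide parameter
#' set: `Tm = dH / (dS + R ln(CT/x)) - 273.15 + 16.6 log10([Na+])`,
#' with dH and dS summed over adjacent dinucleotide stacks plus the
#' terminal initiation terms (and the symmetry entropy correction for
#' self-complementary sequences); `x` is 4 for non-self-complementary
#' sequences and 1 for self-complementary ones; R is the gas constant.
#'
#' @param s primer sequence, length >= 2, no `N`.
#' @param cond a [thermo_conditions] object.
#' @return Tm in degrees Celsius (full precision; round for display).
#' @export
tm_nearest_neighbor <- function(s, cond = thermo_conditions()) {
  b <- check_primer_seq(s, "tm_nearest_neighbor", min_len = 2L)
  ch <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1L])
  dH <- sum(.NN_DH[stacks])
  dS <- sum(.NN_DS[stacks])
  for (term in ch[c(1L, n)]) {
    init <- if (term %in% c("G", "C")) .NN_INIT_GC else .NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfcomp <- identical(b, revcomp_chr(b))
  x <- 4
  if (selfcomp) {
    dS <- dS + .NN_SYM_DS
    x <- 1
  }
  tm_k <- (dH * 1000) / (dS + .GAS_R * log(cond$strand_molar / x))
  tm_k - 273.15 + 16.6 * log10(cond$sodium_molar)
}

#' GC/salt/length melting temperature (degrees C)
#'
#' The classic empirical formula
#' `81.5 + 16.6 log10([Na+]) + 0.41 GC% - 675 / length`, offered as an
#' alternative to the nearest-neighbor model.
#'
#' @inheritParams tm_nearest_neighbor
#' @return Tm in degrees Celsius.
#' @export
tm_gc_salt <- function(s, cond = thermo_conditions()) {
  b <- check_primer_seq(s, "tm_gc_salt", min_len = 2L)
  81.5 + 16.6 * log10(cond$sodium_molar) + 0.41 * gc_percent(b) -
    675 / nchar(b)
}

# Tm under the method selected in `cond`
tm_of <- function(s, cond) {
  if (identical(cond$tm_method, "gc_salt")) tm_gc_salt(s, cond)
  else tm_nearest_neighbor(s, cond)
}
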