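# independent hand-typed copy of the unified dinucleotide parameters,
# indexed by all 16 stacks, used only as a test oracle
NN_ORACLE <- list(
  AA = c(-7.9, -22.2), AC = c(-8.4, -22.4), AG = c(-7.8, -21.0),
  AT = c(-7.2, -20.4), CA = c(-8.5, -22.7), CC = c(-8.0, -19.9),
  CG = c(-10.6, -27.2), CT = c(-7.8, -21.0), GA = c(-8.2, -22.2),
  GC = c(-9.8, -24.4), GG = c(-8.0, -19.9), GT = c(-8.4, -22.4),
  TA = c(-7.2, -21.3), TC = c(-8.2, -22.2), TG = c(-8.5, -22.7),
  TT = c(-7.9, -22.2))

oracle_tm_nn <- function(s, na = 0.05, ct = 2.5e-7) {
  v <- strsplit(s, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(v) - 1L)) {
    par <- NN_ORACLE[[paste0(v[i], v[i + 1L])]]
    dH <- dH + par[1]; dS <- dS + par[2]
  }
  for (term in c(v[1], v[length(v)])) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  rc <- paste(rev(unname(c(A = "T", T = "A", G = "C", C = "G")[v])),
              collapse = "")
  x <- 4
  if (identical(rc, s)) { dS <- dS - 1.4; x <- 1 }
  dH * 1000 / (dS + 1.987 * log(ct / x)) - 273.15 + 16.6 * log10(na)
}

test_that("GC percent reproduces the published primer table and extremes", {
  published <- c(GTGCTTCGACCGAGTATG = 55.56, ACAACCATCCAGTTAACC = 44.44,
                 GAGCACCATAAGGCAACC = 55.56, TATTCCCTTGAGGCTGAAC = 47.37,
                 ATGCTTTACGACAAAGTTTC = 35.00, TCTCAGCTAACATGTATGC = 42.11)
  for (p in names(published))
    expect_equal(gc_percent(p), published[[p]])
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GCGC"), 100)
  expect_error(gc_percent("ACNT"), "contains N")
})

test_that("nearest-neighbor Tm matches a hand-summed oracle", {
  # poly-A: nine AA stacks plus two A/T initiations, worked by hand
  dH <- 9 * (-7.9) + 2 * 2.3
  dS <- 9 * (-22.2) + 2 * 4.1
  expect_equal(tm_nearest_neighbor("AAAAAAAAAA"),
               dH * 1000 / (dS + 1.987 * log(2.5e-7 / 4)) - 273.15 +
                 16.6 * log10(0.05))

  set.seed(31)
  for (i in 1:25) {
    p <- random_primer(sample(8:26, 1))
    expect_equal(tm_nearest_neighbor(p), oracle_tm_nn(p), tolerance = 1e-9)
  }
  # self-complementary sequence exercises x = 1 and the symmetry term
  expect_equal(tm_nearest_neighbor("GCATATGC"), oracle_tm_nn("GCATATGC"))

  cond <- thermo_conditions(sodium_molar = 0.2, strand_molar = 1e-6)
  expect_equal(tm_nearest_neighbor("ACGGTCAG", cond),
               oracle_tm_nn("ACGGTCAG", na = 0.2, ct = 1e-6))
  expect_error(tm_nearest_neighbor("A"), "shorter")
})

test_that("GC/salt Tm formula evaluates as printed", {
  expect_equal(round(tm_gc_salt("GTGCTTCGACCGAGTATG"), 2), 45.18)
  # equal length + equal GC% => equal Tm under this formula
  expect_equal(tm_gc_salt("GCATATAT"), tm_gc_salt("ATATATGC"))
  # the 675/length term vanishes asymptotically
  asym <- 81.5 + 16.6 * log10(0.05) + 0.41 * 50
  expect_equal(tm_gc_salt(strrep("AGCT", 500)), asym - 675 / 2000)
  expect_lt(abs(tm_gc_salt(strrep("AGCT", 5000)) - asym),
            abs(tm_gc_salt(strrep("AGCT", 500)) - asym))
})

test_that("both Tm formulas share the duplex symmetries", {
  set.seed(52)
  for (i in 1:20) {
    p <- random_primer(sample(10:25, 1))
    expect_equal(gc_percent(p), gc_percent(reverse_complement(p)))
    expect_equal(tm_nearest_neighbor(p),
                 tm_nearest_neighbor(reverse_complement(p)),
                 tolerance = 1e-9)
    expect_equal(tm_gc_salt(p), tm_gc_salt(reverse_complement(p)))
  }
  expect_gt(tm_nearest_neighbor("GCGCGCGCGC"),
            tm_nearest_neighbor("ATATATATAT"))
})

test_that("NN Tm increases with sodium and with an appended GC stack", {
  p <- "ACGTTAGCACGT"
  nas <- c(0.01, 0.05, 0.2, 1)
  tms <- vapply(nas, function(na)
    tm_nearest_neighbor(p, thermo_conditions(sodium_molar = na)), 0)
  expect_true(all(diff(tms) > 0))

  set.seed(63)
  for (i in 1:10) {
    p <- random_primer(sample(10:20, 1))
    expect_gte(tm_nearest_neighbor(paste0(p, "GC")),
               tm_nearest_neighbor(p))
  }
})
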