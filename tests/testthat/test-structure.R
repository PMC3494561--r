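test_that("dimer scans match hand-derived cases", {
  r <- cross_dimer("ATAT", "ATAT")
  expect_equal(r$best_total_matches, 4L)   # ATAT is its own revcomp
  expect_equal(cross_dimer("AAAA", "AAAA")$best_total_matches, 0L)
  r <- cross_dimer("GGGG", "CCCC")
  expect_equal(r$best_total_matches, 4L)
  expect_equal(r$best_contiguous_run, 4L)

  expect_equal(self_dimer("ATAT")$best_total_matches, 4L)
  expect_equal(self_dimer("AAAA")$best_total_matches, 0L)
  expect_equal(self_dimer("ACGT")$best_total_matches, 4L)
})

test_that("hairpin scan matches hand-derived partitions", {
  r <- hairpin("GGGGAAAACCCC")
  expect_equal(r$best_contiguous_run, 4L)
  expect_equal(r$best_total_matches, 4L)
  expect_equal(hairpin("AAAAAAAAAAAA")$best_total_matches, 0L)
  expect_equal(hairpin("GCTTTTTTTTGC")$best_contiguous_run, 2L)
  # too short for stem + minimal loop
  expect_equal(hairpin("ACGT")$best_total_matches, 0L)
})

test_that("GC clamp is the 3'-terminal base check", {
  expect_true(gc_clamp("GTGCTTCGACCGAGTATG"))
  expect_false(gc_clamp("AAAAT"))
  expect_true(gc_clamp("C"))
})

test_that("cross-dimer is symmetric and palindromes self-anneal fully", {
  set.seed(11)
  for (i in 1:30) {
    a <- random_primer(sample(4:25, 1))
    b <- random_primer(sample(4:25, 1))
    expect_equal(cross_dimer(a, b)$best_total_matches,
                 cross_dimer(b, a)$best_total_matches)
  }
  for (i in 1:15) {
    half <- random_primer(sample(2:12, 1))
    pal <- paste0(half, reverse_complement(half))
    expect_equal(self_dimer(pal)$best_total_matches, nchar(pal))
  }
})

test_that("dimer and hairpin scanners agree with brute force", {
  set.seed(23)
  for (i in 1:60) {
    a <- random_primer(sample(4:25, 1))
    b <- random_primer(sample(4:25, 1))
    o <- oracle_dimer(a, b)
    r <- cross_dimer(a, b)
    expect_equal(r$best_total_matches, o$total)
    expect_equal(r$best_contiguous_run, o$run)
    os <- oracle_dimer(a, a)
    rs <- self_dimer(a)
    expect_equal(rs$best_total_matches, os$total)
    expect_equal(rs$best_contiguous_run, os$run)
    oh <- oracle_hairpin(a)
    rh <- hairpin(a)
    expect_equal(rh$best_total_matches, oh$total)
    expect_equal(rh$best_contiguous_run, oh$run)
  }
})

test_that("binding sites find planted occurrences on both strands", {
  set.seed(37)
  p <- random_primer(18)
  bg <- random_template_chr(200)
  t1 <- paste0(substr(bg, 1, 50), p, substr(bg, 69, 200))
  s <- binding_sites(p, t1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 51L)
  expect_equal(s$strand, "+")

  # planted twice
  t2 <- paste0(substr(bg, 1, 50), p, substr(bg, 69, 120), p)
  expect_equal(nrow(binding_sites(p, t2)), 2L)

  # reverse-complement plant is a minus-strand site
  t3 <- paste0(substr(bg, 1, 50), reverse_complement(p),
               substr(bg, 69, 200))
  s3 <- binding_sites(p, t3)
  expect_equal(s3$strand, "-")
  expect_equal(s3$start, 51L)

  # one substitution: invisible at mismatch 0, found at mismatch 1
  pm <- p
  substr(pm, 9, 9) <- setdiff(c("A", "C", "G", "T"),
                              substr(p, 9, 9))[1]
  t4 <- paste0(substr(bg, 1, 50), pm, substr(bg, 69, 200))
  expect_equal(nrow(binding_sites(p, t4, 0)), 0L)
  s4 <- binding_sites(p, t4, 1)
  expect_equal(nrow(s4), 1L)
  expect_equal(s4$mismatches, 1L)

  # N in the template never matches
  tn <- paste0(substr(bg, 1, 50), sub("^.", "N", p), substr(bg, 69, 200))
  expect_equal(nrow(binding_sites(p, tn, 0)), 0L)
  expect_equal(nrow(binding_sites(p, tn, 1)), 1L)
})

test_that("binding sites agree with naive scans under mismatches", {
  set.seed(41)
  for (i in 1:15) {
    t <- random_template_chr(sample(60:300, 1))
    p <- random_primer(sample(5:12, 1))
    mm <- sample(0:2, 1)
    got <- binding_sites(p, t, mm)
    want <- oracle_sites(p, t, mm)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("3'-anchored scans reject terminal mismatches only", {
  set.seed(43)
  p <- random_primer(16)
  bg <- random_template_chr(120)
  flip <- function(x) c(A = "C", C = "A", G = "T", T = "G")[[x]]
  # terminal (3') mismatch
  p_term <- p
  substr(p_term, 16, 16) <- flip(substr(p, 16, 16))
  t_term <- paste0(substr(bg, 1, 40), p_term, substr(bg, 57, 120))
  expect_equal(nrow(binding_sites(p, t_term, 1)), 1L)
  expect_equal(nrow(binding_sites(p, t_term, 1, anchor_3prime = TRUE)), 0L)
  # internal mismatch passes the anchor
  p_int <- p
  substr(p_int, 8, 8) <- flip(substr(p, 8, 8))
  t_int <- paste0(substr(bg, 1, 40), p_int, substr(bg, 57, 120))
  expect_equal(nrow(binding_sites(p, t_int, 1, anchor_3prime = TRUE)), 1L)
})

test_that("pair specificity detects duplicated and mirrored sites", {
  set.seed(47)
  fx <- make_fixture(300, 1, seed = 5,
                     constraints = design_constraints(product_min = 80,
                                                      product_max = 250))
  man <- fx$manifest
  expect_true(is_specific(man$f_seq, man$r_seq, fx$template))
  doubled <- dna_seq(strrep(fx$template$bases, 2), id = "doubled")
  expect_false(is_specific(man$f_seq, man$r_seq, doubled))
  mirrored <- dna_seq(paste0(fx$template$bases,
                             reverse_complement(man$f_seq)),
                      id = "mirrored")
  expect_false(is_specific(man$f_seq, man$r_seq, mirrored))
})
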