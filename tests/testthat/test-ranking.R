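cs_rank <- design_constraints(product_min = 80, product_max = 250)

# a small pool of hand-picked chromosomes with varied penalties
make_candidates <- function(fx, chs) {
  lapply(chs, function(ch)
    list(chromosome = ch,
         breakdown = evaluate_pair(ch, fx$template, cs_rank)))
}

test_that("ranking orders by penalty, then Tm difference, then position", {
  fx <- make_fixture(400, 1, seed = 6, constraints = cs_rank)
  man <- fx$manifest
  good <- pair_chromosome(man$f_start, man$f_len, man$amplicon_len,
                          man$r_len)
  # shifting the product far off the planted site degrades the penalty
  bad <- local({
    fs <- if (man$f_start > 200) 5L else 250L
    pair_chromosome(fs, 18, 100, 18)
  })
  cands <- make_candidates(fx, list(bad, good))
  rk <- rank_pairs(cands, fx$template)
  expect_equal(rk$table$rank, c(1L, 2L))
  expect_equal(rk$table$penalty[1], 0)
  expect_lt(rk$table$penalty[1], rk$table$penalty[2])
  expect_equal(rk$table$f_seq[1], man$f_seq)

  # a single candidate gets rank 1
  rk1 <- rank_pairs(cands[2], fx$template)
  expect_equal(rk1$table$rank, 1L)

  # permuting the candidate list does not change the result
  rk_perm <- rank_pairs(rev(cands), fx$template)
  expect_identical(rk$table, rk_perm$table)
})

test_that("equal penalties are broken by the smaller Tm difference", {
  fx <- make_fixture(400, 2, seed = 14, constraints = cs_rank)
  man <- fx$manifest
  chs <- lapply(seq_len(2), function(i)
    pair_chromosome(man$f_start[i], man$f_len[i], man$amplicon_len[i],
                    man$r_len[i]))
  cands <- make_candidates(fx, chs)
  rk <- rank_pairs(cands, fx$template)
  expect_true(all(rk$table$penalty == 0))
  expect_true(rk$table$tm_diff[1] <= rk$table$tm_diff[2])
})

test_that("empty candidate lists are an explicit no-feasible result", {
  t <- dna_seq(random_template_chr(200), id = "t")
  rk <- rank_pairs(list(), t)
  expect_s3_class(rk, "ranked_pairs")
  expect_equal(nrow(rk$table), 0L)
  expect_output(print(rk), "No feasible primer")
  f <- withr::local_tempfile(fileext = ".txt")
  report(rk, f)
  txt <- readLines(f)
  expect_true(any(grepl("No feasible primer pair", txt)))
  expect_true(any(grepl("constraint.primer_len_min", txt, fixed = TRUE)))
})

test_that("text reports echo settings, round-trip numbers, and are stable", {
  fx <- make_fixture(400, 1, seed = 6, constraints = cs_rank)
  man <- fx$manifest
  ch <- pair_chromosome(man$f_start, man$f_len, man$amplicon_len,
                        man$r_len)
  rk <- rank_pairs(make_candidates(fx, list(ch)), fx$template)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  report(rk, f1, constraints = cs_rank)
  report(rk, f2, constraints = cs_rank)
  expect_identical(readLines(f1), readLines(f2))

  txt <- readLines(f1)
  # all constraint fields are echoed in the header
  for (nm in c("primer_len_min", "primer_len_max", "max_len_diff",
               "tm_min", "tm_max", "max_tm_diff", "gc_min", "gc_max",
               "product_min", "product_max", "max_dimer_run",
               "max_hairpin_run", "specificity_mismatch",
               "require_gc_clamp", "region"))
    expect_true(any(grepl(paste0("constraint.", nm, " = "), txt,
                          fixed = TRUE)), info = nm)

  grab <- function(key) {
    line <- grep(paste0("^", key, ": "), txt, value = TRUE)
    sub(paste0("^", key, ": "), "", line)
  }
  r <- rk$table[1, ]
  expect_equal(grab("forward.seq"), r$f_seq)
  expect_equal(as.integer(grab("forward.length")), r$f_len)
  expect_equal(grab("forward.position"),
               paste0(r$f_start, "-", r$f_end))
  expect_equal(as.numeric(grab("forward.gc_percent")), r$gc_f)
  expect_equal(as.numeric(grab("forward.tm")), r$tm_f)
  expect_equal(as.numeric(grab("reverse.tm")), r$tm_r)
  expect_equal(as.numeric(grab("pair.tm_diff")), r$tm_diff)
  expect_equal(as.integer(grab("pair.product_size")), r$product_size)
  expect_equal(as.numeric(grab("pair.penalty")), r$penalty)
})

test_that("TSV reports parse back into the ranking table", {
  fx <- make_fixture(400, 1, seed = 6, constraints = cs_rank)
  man <- fx$manifest
  ch <- pair_chromosome(man$f_start, man$f_len, man$amplicon_len,
                        man$r_len)
  rk <- rank_pairs(make_candidates(fx, list(ch)), fx$template)
  f <- withr::local_tempfile(fileext = ".tsv")
  report(rk, f, format = "tsv")
  back <- read.delim(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$f_seq, rk$table$f_seq)
  expect_equal(back$product_size, rk$table$product_size)
  expect_equal(back$penalty, rk$table$penalty)
})
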