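test_that("initialization yields valid, mostly distinct chromosomes", {
  set.seed(5)
  t <- dna_seq(random_template_chr(1000), id = "t1k")
  cs <- design_constraints()
  params <- evolution_params()
  set.seed(9)
  pop <- initialize_population(t, cs, params)
  expect_length(pop, 50L)
  keys <- vapply(pop, function(ch) paste(ch, collapse = ","), "")
  expect_equal(length(unique(keys)), 50L)
  for (ch in pop) {
    expect_gte(ch[["f_len"]], cs$primer_len_min)
    expect_lte(ch[["f_len"]], cs$primer_len_max)
    expect_gte(ch[["r_len"]], cs$primer_len_min)
    expect_lte(ch[["r_len"]], cs$primer_len_max)
    expect_gte(ch[["amplicon_len"]], cs$product_min)
    expect_lte(ch[["amplicon_len"]], cs$product_max)
    expect_gte(ch[["amplicon_len"]], ch[["f_len"]] + ch[["r_len"]])
    expect_gte(ch[["f_start"]], 1L)
    expect_lte(ch[["f_start"]] + ch[["amplicon_len"]] - 1L, t$length)
  }
  # identical seed, identical population
  set.seed(9)
  pop2 <- initialize_population(t, cs, params)
  expect_identical(pop, pop2)
})

test_that("an undersized template is an explicit infeasibility error", {
  t <- dna_seq(random_template_chr(80), id = "short")
  expect_error(initialize_population(t, design_constraints(),
                                     evolution_params()),
               "no valid primer pair")
  expect_error(run_design(t, design_constraints()), "no valid primer pair")
})

test_that("with crossover and mutation off, offspring are copies of parents", {
  set.seed(13)
  t <- dna_seq(random_template_chr(400), id = "t")
  cs <- design_constraints(product_min = 100, product_max = 300)
  params <- evolution_params(crossover_prob = 0, mutation_prob = 0,
                             population_size = 20, algorithm = "ga")
  pop <- initialize_population(t, cs, params)
  nxt <- ga_step(pop, t, cs, params)
  keys <- vapply(pop, function(ch) paste(ch, collapse = ","), "")
  for (ch in nxt)
    expect_true(paste(ch, collapse = ",") %in% keys)
})

test_that("elitism makes the best penalty non-increasing", {
  set.seed(17)
  t <- dna_seq(random_template_chr(500), id = "t")
  cs <- design_constraints(product_min = 100, product_max = 400)
  params <- evolution_params(population_size = 20, algorithm = "ga")
  ctx <- fitness_context(t, cs)
  set.seed(21)
  pop <- initialize_population(t, cs, params)
  best <- min(vapply(pop, ctx$total, 0))
  for (g in 1:8) {
    pop <- ga_step(pop, t, cs, params, evalf = ctx$total)
    nb <- min(vapply(pop, ctx$total, 0))
    expect_lte(nb, best)
    best <- nb
  }
})

test_that("evolution is deterministic given the seed", {
  fx <- make_fixture(120, 1, seed = 3, constraints = tight_constraints())
  params <- evolution_params(runs = 2, max_generations = 15, seed = 42)
  r1 <- run_design(fx$template, tight_constraints(), params)
  r2 <- run_design(fx$template, tight_constraints(), params)
  expect_identical(lapply(r1, `[[`, "chromosome"),
                   lapply(r2, `[[`, "chromosome"))
  expect_identical(lapply(r1, `[[`, "trajectory"),
                   lapply(r2, `[[`, "trajectory"))
  # trajectories are non-increasing (elitist best-so-far)
  for (cand in r1)
    expect_true(all(diff(cand$trajectory) <= 0))
})

test_that("local search never increases the penalty and fixes its points", {
  set.seed(29)
  fx <- make_fixture(200, 1, seed = 8,
                     constraints = design_constraints(product_min = 80,
                                                      product_max = 180))
  cs <- design_constraints(product_min = 80, product_max = 180)
  ctx <- fitness_context(fx$template, cs)
  for (i in 1:25) {
    fl <- sample(18:24, 1); rl <- sample(18:24, 1)
    amp <- sample(max(80, fl + rl):180, 1)
    fs <- sample(1:(fx$template$length - amp + 1), 1)
    ch <- pair_chromosome(fs, fl, amp, rl)
    ls <- local_search(ch, fx$template, cs, evalf = ctx$total)
    expect_lte(ctx$total(ls), ctx$total(ch))
    # a local minimum is a fixed point
    expect_identical(local_search(ls, fx$template, cs, evalf = ctx$total),
                     ls)
  }
})

test_that("a zero-generation single run returns the best initial individual", {
  fx <- make_fixture(150, 1, seed = 12, constraints = tight_constraints())
  cs <- tight_constraints()
  params <- evolution_params(runs = 1, max_generations = 0, seed = 7,
                             algorithm = "ga")
  res <- run_design(fx$template, cs, params)
  expect_length(res, 1L)
  ctx <- fitness_context(fx$template, cs)
  set.seed(7 + 1)  # run index 1
  pop <- initialize_population(fx$template, cs, params)
  expect_equal(res[[1]]$breakdown$total,
               min(vapply(pop, ctx$total, 0)))
})

test_that("MA reaches the enumerated global optimum on a small template", {
  cs <- tight_constraints()
  fx <- make_fixture(110, 1, seed = 19, constraints = cs)
  opt <- enumerate_optimum(fx$template, cs)
  res <- run_design(fx$template, cs, evolution_params(seed = 23))
  best <- min(vapply(res, function(x) x$breakdown$total, 0))
  expect_equal(best, opt$best_penalty)
  # every returned chromosome is valid
  for (cand in res) {
    ch <- cand$chromosome
    expect_gte(ch[["amplicon_len"]], ch[["f_len"]] + ch[["r_len"]])
    expect_lte(ch[["f_start"]] + ch[["amplicon_len"]] - 1L,
               fx$template$length)
  }
})
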