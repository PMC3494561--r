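# GA and MA engines searching primer-pair space on a template.
# A chromosome is the 4-gene integer vector (f_start, f_len,
# amplicon_len, r_len); all operators act on that vector and repair
# invariant violations by clamping.

#' Evolutionary search parameters
#'
#' @param max_generations generations per run (default 100).
#' @param population_size individuals per generation (default 50).
#' @param crossover_prob probability of two-point crossover per parent
#'   pair (default 0.8).
#' @param mutation_prob per-gene mutation probability (default 0.05).
#' @param runs independent optimization runs; each run `i` is seeded
#'   with `seed + i` (default 5).
#' @param seed base random seed.
#' @param algorithm `"ma"` (memetic: GA plus steepest-descent local
#'   search on every individual, the default) or `"ga"`.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(max_generations = 100L, population_size = 50L,
                             crossover_prob = 0.8, mutation_prob = 0.05,
                             runs = 5L, seed = 1L,
                             algorithm = c("ma", "ga")) {
  stopifnot(max_generations >= 0L, population_size >= 2L, runs >= 1L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(max_generations = as.integer(max_generations),
                 population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 runs = as.integer(runs), seed = as.integer(seed),
                 algorithm = match.arg(algorithm)),
            class = "evolution_params")
}

# static per-gene sampling bounds; joint constraints handled by
# sampling order (lengths -> amplicon -> start) and by clamping
gene_space <- function(t, c) {
  reg <- design_region(t, c)
  reg_len <- reg$end - reg$start + 1L
  amp_lo <- max(c$product_min, 2L * c$primer_len_min)
  amp_hi <- min(c$product_max, reg_len)
  list(reg = reg, reg_len = reg_len,
       len_lo = c$primer_len_min, len_hi = c$primer_len_max,
       amp_lo = amp_lo, amp_hi = amp_hi,
       feasible = amp_lo <= amp_hi)
}

assert_feasible <- function(sp, t) {
  if (!sp$feasible)
    stop("no valid primer pair exists: design region of ", sp$reg_len,
         " bp on template '", t$id,
         "' cannot host a product in the allowed size range",
         call. = FALSE)
  invisible(sp)
}

rand_int <- function(lo, hi) lo + floor(runif(1) * (hi - lo + 1L))

# clamp a raw 4-gene vector back into the valid chromosome space
clamp_genes <- function(g, sp) {
  f_len <- min(max(g[["f_len"]], sp$len_lo), sp$len_hi)
  r_len <- min(max(g[["r_len"]], sp$len_lo), sp$len_hi)
  if (f_len + r_len > sp$amp_hi) { f_len <- sp$len_lo; r_len <- sp$len_lo }
  amp_lo <- max(sp$amp_lo, f_len + r_len)
  amp <- min(max(g[["amplicon_len"]], amp_lo), sp$amp_hi)
  f_start <- min(max(g[["f_start"]], sp$reg$start),
                 sp$reg$end - amp + 1L)
  pair_chromosome(f_start, f_len, amp, r_len)
}

sample_chromosome <- function(sp) {
  f_len <- rand_int(sp$len_lo, sp$len_hi)
  r_len <- rand_int(sp$len_lo, sp$len_hi)
  if (f_len + r_len > sp$amp_hi) { f_len <- sp$len_lo; r_len <- sp$len_lo }
  amp <- rand_int(max(sp$amp_lo, f_len + r_len), sp$amp_hi)
  f_start <- rand_int(sp$reg$start, sp$reg$end - amp + 1L)
  pair_chromosome(f_start, f_len, amp, r_len)
}

chrom_key <- function(ch) paste(ch, collapse = ",")

#' Initialize a population of primer-pair chromosomes
#'
#' Samples `population_size` valid chromosomes uniformly from the index
#' space; duplicates are re-sampled a bounded number of times.  Uses
#' the current RNG state (seed management happens in [design_primers()]).
#'
#' @param t template.
#' @param constraints a [design_constraints].
#' @param params an [evolution_params].
#' @return A list of [pair_chromosome]s.
#' @export
initialize_population <- function(t, constraints, params) {
  t <- as_dna_seq(t)
  sp <- assert_feasible(gene_space(t, constraints), t)
  pop <- vector("list", params$population_size)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(params$population_size)) {
    for (try in seq_len(25L)) {
      ch <- sample_chromosome(sp)
      k <- chrom_key(ch)
      if (is.null(seen[[k]])) break
    }
    seen[[k]] <- TRUE
    pop[[i]] <- ch
  }
  pop
}

# memoized total penalty, keyed on the 4 genes; one cache per run
make_eval_cache <- function(t, constraints, cond, weights) {
  fitness_context(t, constraints, cond, weights)$total
}

tournament_pick <- function(pop, pen) {
  i <- rand_int(1L, length(pop)); j <- rand_int(1L, length(pop))
  if (pen[i] <= pen[j]) pop[[i]] else pop[[j]]
}

mutate_genes <- function(g, sp, pm) {
  if (runif(1) < pm) g[["f_start"]] <- rand_int(sp$reg$start, sp$reg$end)
  if (runif(1) < pm) g[["f_len"]] <- rand_int(sp$len_lo, sp$len_hi)
  if (runif(1) < pm) g[["amplicon_len"]] <- rand_int(sp$amp_lo, sp$amp_hi)
  if (runif(1) < pm) g[["r_len"]] <- rand_int(sp$len_lo, sp$len_hi)
  g
}

#' One GA/MA generation
#'
#' Tournament selection (size 2), two-point crossover over the 4-gene
#' vector with probability `crossover_prob`, per-gene uniform
#' re-sampling mutation with probability `mutation_prob`, repair by
#' clamping, optional local search on every offspring (`algorithm =
#' "ma"`), and elitist generational replacement (the best individual
#' always survives).
#'
#' @param pop list of [pair_chromosome]s.
#' @inheritParams initialize_population
#' @param cond a [thermo_conditions].
#' @param weights penalty weights.
#' @param evalf optional memoized evaluator (internal reuse across
#'   generations); built on the fly when `NULL`.
#' @return The next-generation population (same size).
#' @export
ga_step <- function(pop, t, constraints, params,
                    cond = thermo_conditions(),
                    weights = default_weights(), evalf = NULL) {
  t <- as_dna_seq(t)
  sp <- gene_space(t, constraints)
  if (is.null(evalf))
    evalf <- make_eval_cache(t, constraints, cond, weights)
  pen <- vapply(pop, evalf, 0)
  elite <- pop[[which.min(pen)]]
  n <- length(pop)
  off <- vector("list", n)
  i <- 1L
  while (i <= n) {
    p1 <- tournament_pick(pop, pen)
    p2 <- tournament_pick(pop, pen)
    c1 <- unclass(p1); c2 <- unclass(p2)
    if (runif(1) < params$crossover_prob) {
      cuts <- sort(sample.int(3L, 2L))  # cut points between genes
      seg <- (cuts[1] + 1L):cuts[2]
      tmp <- c1[seg]; c1[seg] <- c2[seg]; c2[seg] <- tmp
    }
    c1 <- mutate_genes(c1, sp, params$mutation_prob)
    c2 <- mutate_genes(c2, sp, params$mutation_prob)
    off[[i]] <- clamp_genes(c1, sp)
    if (i + 1L <= n) off[[i + 1L]] <- clamp_genes(c2, sp)
    i <- i + 2L
  }
  if (identical(params$algorithm, "ma"))
    off <- lapply(off, local_search, t = t, constraints = constraints,
                  cond = cond, weights = weights, evalf = evalf)
  # elitist replacement: keep the previous best if no offspring matches it
  open <- vapply(off, evalf, 0)
  if (min(open) > evalf(elite))
    off[[which.max(open)]] <- elite
  off
}

#' Steepest-descent local search over the chromosome neighborhood
#'
#' Repeatedly evaluates all valid +/-1 neighbors of each of the four
#' genes (at most 8 candidates) and moves to the best strictly
#' improving one, until a local minimum is reached.  The returned
#' penalty is never larger than the input's.
#'
#' @param ch a valid [pair_chromosome].
#' @inheritParams ga_step
#' @return A [pair_chromosome] at a local minimum of the penalty.
#' @export
local_search <- function(ch, t, constraints,
                         cond = thermo_conditions(),
                         weights = default_weights(), evalf = NULL) {
  t <- as_dna_seq(t)
  sp <- gene_space(t, constraints)
  if (is.null(evalf))
    evalf <- make_eval_cache(t, constraints, cond, weights)
  cur <- ch
  cur_pen <- evalf(cur)
  repeat {
    if (cur_pen == 0) break
    best <- NULL; best_pen <- cur_pen
    for (g in seq_len(4L)) {
      for (d in c(-1L, 1L)) {
        cand <- unclass(cur)
        cand[g] <- cand[g] + d
        cand <- tryCatch(clamp_genes(cand, sp), error = function(e) NULL)
        if (is.null(cand) || identical(chrom_key(cand), chrom_key(cur)))
          next
        p <- evalf(cand)
        if (p < best_pen) { best <- cand; best_pen <- p }
      }
    }
    if (is.null(best)) break
    cur <- best; cur_pen <- best_pen
  }
  cur
}

# one seeded optimization run; returns best chromosome, its penalty,
# and the best-penalty trajectory across generations
evolve_run <- function(t, constraints, params, cond, weights, run_seed,
                       evalf = NULL) {
  set.seed(run_seed %% .Machine$integer.max)
  if (is.null(evalf))
    evalf <- make_eval_cache(t, constraints, cond, weights)
  pop <- initialize_population(t, constraints, params)
  if (identical(params$algorithm, "ma"))
    pop <- lapply(pop, local_search, t = t, constraints = constraints,
                  cond = cond, weights = weights, evalf = evalf)
  pen <- vapply(pop, evalf, 0)
  best_i <- which.min(pen)
  best <- pop[[best_i]]; best_pen <- pen[best_i]
  traj <- best_pen
  gen <- 0L
  while (gen < params$max_generations && best_pen > 0) {
    pop <- ga_step(pop, t, constraints, params, cond, weights, evalf)
    pen <- vapply(pop, evalf, 0)
    gi <- which.min(pen)
    if (pen[gi] < best_pen) { best <- pop[[gi]]; best_pen <- pen[gi] }
    traj <- c(traj, best_pen)
    gen <- gen + 1L
  }
  list(chromosome = best, penalty = best_pen, trajectory = traj)
}

#' Run the full multi-run GA/MA design
#'
#' Executes `params$runs` independent optimizations (run `i` seeded
#' with `params$seed + i`), keeps each run's best individual, and
#' returns the de-duplicated candidates with their penalty breakdowns.
#' A run stops early once its best penalty reaches 0, the global lower
#' bound.  The caller's RNG state is left untouched.
#'
#' @inheritParams ga_step
#' @return A list of candidates, each `list(chromosome, breakdown,
#'   trajectory)`.
#' @export
run_design <- function(t, constraints = design_constraints(),
                       params = evolution_params(),
                       cond = thermo_conditions(),
                       weights = default_weights()) {
  t <- as_dna_seq(t)
  assert_feasible(gene_space(t, constraints), t)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  ctx <- fitness_context(t, constraints, cond, weights)
  out <- list()
  seen <- character()
  for (r in seq_len(params$runs)) {
    res <- evolve_run(t, constraints, params, cond, weights,
                      params$seed + r, evalf = ctx$total)
    k <- chrom_key(res$chromosome)
    if (k %in% seen) next
    seen <- c(seen, k)
    out[[length(out) + 1L]] <-
      list(chromosome = res$chromosome,
           breakdown = ctx$breakdown(res$chromosome),
           trajectory = res$trajectory)
  }
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Enumerate every valid chromosome on a small template
#'
#' Exhaustive enumeration of the chromosome space; intended for small
#' templates and tight constraint windows where the space is a few
#' thousand points (e.g. verifying that the evolutionary search found
#' the global optimum).
#'
#' @inheritParams ga_step
#' @param max_space refuse to enumerate more than this many chromosomes.
#' @return A list with `best` (chromosome), `best_penalty`, and `n`
#'   (the number of valid chromosomes examined).
#' @export
enumerate_optimum <- function(t, constraints = design_constraints(),
                              cond = thermo_conditions(),
                              weights = default_weights(),
                              max_space = 5e5) {
  t <- as_dna_seq(t)
  sp <- assert_feasible(gene_space(t, constraints), t)
  evalf <- make_eval_cache(t, constraints, cond, weights)
  best <- NULL; best_pen <- Inf; n <- 0L
  size_guess <- (sp$len_hi - sp$len_lo + 1)^2 *
    (sp$amp_hi - sp$amp_lo + 1) * sp$reg_len
  if (size_guess > max_space)
    stop("chromosome space too large to enumerate (", size_guess, ")",
         call. = FALSE)
  for (f_len in sp$len_lo:sp$len_hi)
    for (r_len in sp$len_lo:sp$len_hi) {
      amp_lo <- max(sp$amp_lo, f_len + r_len)
      if (amp_lo > sp$amp_hi) next
      for (amp in amp_lo:sp$amp_hi)
        for (f_start in sp$reg$start:(sp$reg$end - amp + 1L)) {
          ch <- pair_chromosome(f_start, f_len, amp, r_len)
          p <- evalf(ch)
          n <- n + 1L
          if (p < best_pen) { best <- ch; best_pen <- p }
        }
    }
  list(best = best, best_penalty = best_pen, n = n)
}
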