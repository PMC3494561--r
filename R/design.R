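# User-facing entry point: design_primers() and its S3 methods.

#' Design specific-product PCR primer pairs on a template
#'
#' Runs the evolutionary (GA or memetic) search over the primer-pair
#' space of a template under the given constraints, then ranks each
#' run's best pair by penalty and Tm difference.  The search is fully
#' deterministic given `params$seed`; the caller's RNG state is
#' preserved.
#'
#' @param template a [dna_seq], a plain sequence string, or a
#'   single-record FASTA path.
#' @param constraints a [design_constraints].
#' @param params an [evolution_params] (algorithm, population,
#'   generations, runs, seed).
#' @param cond a [thermo_conditions].
#' @param weights penalty weights, see [default_weights()].
#' @return An object of class `primer_design`: the ranked pairs
#'   (`$ranking`), the raw per-run candidates (`$candidates`), and the
#'   settings used.  Methods: `print`, `summary`, `plot`, [report()].
#' @examples
#' set.seed(7)
#' t <- make_fixture(400, n_feasible = 1, seed = 11,
#'                   constraints = design_constraints(product_min = 100,
#'                                                    product_max = 300))
#' fit <- design_primers(t$template,
#'                       design_constraints(product_min = 100,
#'                                          product_max = 300),
#'                       evolution_params(runs = 2, max_generations = 30,
#'                                        seed = 3))
#' fit
#' @export
design_primers <- function(template,
                           constraints = design_constraints(),
                           params = evolution_params(),
                           cond = thermo_conditions(),
                           weights = default_weights()) {
  t <- resolve_template(template)
  cands <- run_design(t, constraints, params, cond, weights)
  ranking <- rank_pairs(cands, t, cond)
  structure(list(template = t, constraints = constraints,
                 params = params, cond = cond, weights = weights,
                 candidates = cands, ranking = ranking),
            class = "primer_design")
}

resolve_template <- function(template) {
  if (inherits(template, "dna_seq")) return(template)
  if (is.character(template) && length(template) == 1L &&
      file.exists(template)) {
    recs <- read_fasta(template)
    if (length(recs) > 1L)
      stop("multi-record FASTA: use design_batch() for high-throughput ",
           "mode", call. = FALSE)
    return(recs[[1]])
  }
  as_dna_seq(template)
}

#' @export
print.primer_design <- function(x, ...) {
  cat(sprintf("Primer design on '%s' (%d bp), %s, %d run(s), seed %d\n",
              x$template$id, x$template$length,
              toupper(x$params$algorithm), x$params$runs, x$params$seed))
  print(x$ranking, n = 3L)
  invisible(x)
}

#' @export
summary.primer_design <- function(object, ...) {
  structure(list(design = object), class = "summary.primer_design")
}

#' @export
print.summary.primer_design <- function(x, ...) {
  d <- x$design
  print(d$constraints)
  cat(sprintf("algorithm %s | population %d | generations %d | pc %g | pm %g | runs %d | seed %d\n",
              toupper(d$params$algorithm), d$params$population_size,
              d$params$max_generations, d$params$crossover_prob,
              d$params$mutation_prob, d$params$runs, d$params$seed))
  cat(sprintf("Tm: %s model, Na+ %g M, strand %g M\n",
              d$cond$tm_method, d$cond$sodium_molar, d$cond$strand_molar))
  print(d$ranking, n = nrow(d$ranking$table))
  invisible(x)
}

#' @describeIn report Report method for a full design: delegates to the
#'   ranking with the design's own constraints/parameters echoed.
#' @export
report.primer_design <- function(x, path, format = c("text", "tsv"),
                                 stamp = FALSE, ...) {
  report(x$ranking, path, constraints = x$constraints,
         params = x$params, cond = x$cond,
         format = match.arg(format), stamp = stamp)
}

#' Plot primer positions on the template
#'
#' Draws the template as a horizontal line with each ranked pair's
#' forward and reverse primers as arrows bracketing the product.
#'
#' @param x a `primer_design`.
#' @param n_pairs how many top-ranked pairs to draw.
#' @param ... ignored.
#' @export
plot.primer_design <- function(x, n_pairs = 5L, ...) {
  tab <- head(x$ranking$table, n_pairs)
  L <- x$template$length
  n <- nrow(tab)
  graphics::plot(NULL, xlim = c(1, L), ylim = c(0, n + 1),
                 xlab = "template position (bp)", ylab = "",
                 yaxt = "n", main = paste0("Primer pairs on ", x$template$id))
  graphics::segments(1, 0.5, L, 0.5, lwd = 3, col = "grey40")
  if (n == 0L) return(invisible(x))
  for (i in seq_len(n)) {
    y <- i + 0.2
    r <- tab[i, ]
    graphics::segments(r$f_start, y, r$r_end, y, col = "grey80")
    graphics::arrows(r$f_start, y, r$f_end, y, length = 0.06,
                     col = "forestgreen", lwd = 2)
    graphics::arrows(r$r_end, y, r$r_start, y, length = 0.06,
                     col = "firebrick", lwd = 2)
    graphics::text(r$r_end, y, pos = 4, cex = 0.7,
                   labels = sprintf("rank %d (%d bp)", r$rank,
                                    r$product_size))
  }
  invisible(x)
}
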