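# Design constraints, the pair-chromosome encoding, and the composite
# penalty ("fitness", lower is better) that drives the GA/MA search and
# the ranking.  A total penalty of 0 means every constraint is met.

#' Primer-design constraints
#'
#' Container for all design thresholds.  Every range is inclusive; all
#' defaults can be overridden.
#'
#' @param primer_len_min,primer_len_max primer length range (bases).
#' @param max_len_diff allowed forward/reverse length difference (bases).
#' @param tm_min,tm_max melting temperature range (degrees C).
#' @param max_tm_diff allowed Tm difference between primers (degrees C).
#' @param gc_min,gc_max GC proportion range (%).
#' @param product_min,product_max PCR product length range (bases).
#' @param max_dimer_run allowed contiguous cross-/self-dimer annealing
#'   run (bases).
#' @param max_hairpin_run allowed contiguous hairpin stem run (bases).
#' @param specificity_mismatch mismatches allowed when scanning the
#'   template for off-target binding sites (bases).
#' @param require_gc_clamp require a G or C at each primer 3' end?
#' @param region optional [region] restricting the design space on the
#'   template.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(primer_len_min = 18L, primer_len_max = 24L,
                               max_len_diff = 3L,
                               tm_min = 50, tm_max = 62, max_tm_diff = 3,
                               gc_min = 40, gc_max = 60,
                               product_min = 100L, product_max = 1000L,
                               max_dimer_run = 4L, max_hairpin_run = 4L,
                               specificity_mismatch = 0L,
                               require_gc_clamp = TRUE,
                               region = NULL) {
  c <- structure(list(primer_len_min = as.integer(primer_len_min),
                      primer_len_max = as.integer(primer_len_max),
                      max_len_diff = as.integer(max_len_diff),
                      tm_min = tm_min, tm_max = tm_max,
                      max_tm_diff = max_tm_diff,
                      gc_min = gc_min, gc_max = gc_max,
                      product_min = as.integer(product_min),
                      product_max = as.integer(product_max),
                      max_dimer_run = as.integer(max_dimer_run),
                      max_hairpin_run = as.integer(max_hairpin_run),
                      specificity_mismatch = as.integer(specificity_mismatch),
                      require_gc_clamp = isTRUE(require_gc_clamp),
                      region = region),
                 class = "design_constraints")
  validate_constraints(c)
  c
}

validate_constraints <- function(c) {
  pairs <- list(c("primer_len_min", "primer_len_max"),
                c("tm_min", "tm_max"), c("gc_min", "gc_max"),
                c("product_min", "product_max"))
  for (p in pairs)
    if (c[[p[1]]] > c[[p[2]]])
      stop("constraint ", p[1], " exceeds ", p[2], call. = FALSE)
  nn <- c("max_len_diff", "max_tm_diff", "max_dimer_run",
          "max_hairpin_run", "specificity_mismatch")
  for (f in nn)
    if (c[[f]] < 0) stop("constraint ", f, " must be >= 0", call. = FALSE)
  if (!is.null(c$region)) stopifnot(inherits(c$region, "region"))
  invisible(c)
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("<design_constraints>\n")
  for (f in setdiff(names(x), "region"))
    cat(sprintf("  %-21s %s\n", f, format(x[[f]])))
  if (!is.null(x$region))
    cat(sprintf("  %-21s %d-%d\n", "region", x$region$start, x$region$end))
  invisible(x)
}

# ---- pair chromosome -------------------------------------------------

#' Primer-pair chromosome
#'
#' Four-integer encoding of a primer pair on a template: the forward
#' primer's 1-based 5' start, the forward and reverse primer lengths,
#' and the amplicon (product) length.  Decoding: the forward primer is
#' the plus-strand subsequence starting at `f_start`; the reverse
#' primer is the reverse complement of the last `r_len` bases of the
#' amplicon.
#'
#' @param f_start forward primer 5' position (1-based).
#' @param f_len,r_len primer lengths (bases).
#' @param amplicon_len product length (bases), at least `f_len + r_len`.
#' @return An object of class `pair_chromosome` (a named integer
#'   vector).
#' @export
pair_chromosome <- function(f_start, f_len, amplicon_len, r_len) {
  g <- as.integer(c(f_start = f_start, f_len = f_len,
                    amplicon_len = amplicon_len, r_len = r_len))
  names(g) <- c("f_start", "f_len", "amplicon_len", "r_len")
  if (any(is.na(g)) || any(g < 1L))
    stop("chromosome genes must be positive integers", call. = FALSE)
  if (g[["amplicon_len"]] < g[["f_len"]] + g[["r_len"]])
    stop("amplicon shorter than the two primers", call. = FALSE)
  structure(g, class = "pair_chromosome")
}

# template region actually searched (whole template when no region set)
design_region <- function(t, c) {
  if (!is.null(c$region)) {
    if (c$region$end > t$length)
      stop("region extends beyond the template", call. = FALSE)
    c$region
  } else region(1L, t$length)
}

#' Decode a pair chromosome on a template
#'
#' @param ch a [pair_chromosome].
#' @param t template ([dna_seq]).
#' @return A list: `fwd`, `rev` (primer strings, both 5'->3'),
#'   `f_start`, `f_end`, `r_start`, `r_end` (plus-strand coordinates of
#'   both binding sites) and `product_size`.
#' @export
decode_pair <- function(ch, t) {
  t <- as_dna_seq(t)
  f_start <- ch[["f_start"]]; f_len <- ch[["f_len"]]
  amp <- ch[["amplicon_len"]]; r_len <- ch[["r_len"]]
  end <- f_start + amp - 1L
  if (end > t$length)
    stop("chromosome extends beyond the template", call. = FALSE)
  r_start <- f_start + amp - r_len
  list(fwd = substr(t$bases, f_start, f_start + f_len - 1L),
       rev = revcomp_chr(substr(t$bases, r_start, end)),
       f_start = f_start, f_end = f_start + f_len - 1L,
       r_start = r_start, r_end = end,
       product_size = amp)
}

# ---- fitness breakdown -----------------------------------------------

.PENALTY_NAMES <- c("length", "length_diff", "gc", "tm", "tm_diff",
                    "product", "cross_dimer", "self_dimer_f",
                    "self_dimer_r", "hairpin_f", "hairpin_r",
                    "gc_clamp", "specificity")

#' Default penalty weights
#'
#' One weight per constraint penalty; the total penalty is the weighted
#' sum.  Specificity violations are weighted 10, everything else 1, so
#' an off-target binding site dominates any mild property violation.
#'
#' @return Named numeric vector of weights.
#' @export
default_weights <- function() {
  w <- rep(1, length(.PENALTY_NAMES))
  names(w) <- .PENALTY_NAMES
  w["specificity"] <- 10
  w
}

fitness_breakdown <- function(penalties, weights) {
  total <- sum(weights[.PENALTY_NAMES] * penalties[.PENALTY_NAMES])
  structure(list(penalties = penalties, weights = weights, total = total),
            class = "fitness_breakdown")
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat("<fitness_breakdown> total =", format(x$total), "\n")
  nz <- x$penalties[x$penalties > 0]
  if (length(nz))
    for (nm in names(nz))
      cat(sprintf("  %-13s %g (weight %g)\n", nm, nz[[nm]], x$weights[[nm]]))
  else cat("  all constraints satisfied\n")
  invisible(x)
}

range_penalty <- function(x, lo, hi) max(0, lo - x, x - hi)
excess <- function(x, cap) max(0, x - cap)

#' Evaluate the design penalty of a primer pair
#'
#' Computes one non-negative penalty per design constraint and their
#' weighted total (lower is better; 0 iff every constraint is met).
#' Range constraints are penalized by the distance outside the
#' interval; difference constraints by the excess over the allowed
#' maximum; dimer/hairpin constraints by the excess of the contiguous
#' annealing run over the threshold; a missing GC clamp costs 1 per
#' primer; specificity costs 1 per off-target binding site beyond the
#' single intended site per primer.  Primers containing `N` get an
#' infinite total.
#'
#' @param ch a [pair_chromosome] fully inside the template (and region).
#' @param t template.
#' @param constraints a [design_constraints].
#' @param cond a [thermo_conditions] (its `tm_method` selects the Tm
#'   formula).
#' @param weights penalty weights, see [default_weights()].
#' @return A `fitness_breakdown`.
#' @export
evaluate_pair <- function(ch, t, constraints = design_constraints(),
                          cond = thermo_conditions(),
                          weights = default_weights()) {
  fitness_context(t, constraints, cond, weights)$breakdown(ch)
}

#' Memoizing fitness evaluator for one template
#'
#' Builds closures evaluating chromosomes on a fixed (template,
#' constraints, conditions) triple.  Per-primer properties (GC, Tm,
#' self-dimer, hairpin, clamp, binding-site count) are cached by
#' primer sequence and cross-dimer scans by pair, so the many
#' chromosomes sharing a primer during evolutionary search or
#' exhaustive enumeration are cheap to score.  [evaluate_pair()] is
#' the one-shot wrapper around this.
#'
#' @inheritParams evaluate_pair
#' @return A list of closures: `breakdown(ch)` (a
#'   `fitness_breakdown`) and `total(ch)` (the cached total penalty).
#' @export
fitness_context <- function(t, constraints = design_constraints(),
                            cond = thermo_conditions(),
                            weights = default_weights()) {
  t <- as_dna_seq(t)
  cs <- constraints
  reg <- design_region(t, cs)
  mm <- cs$specificity_mismatch
  rc <- revcomp_chr(t$bases)  # reverse primers read off this in O(1)
  L <- t$length
  pcache <- new.env(hash = TRUE, parent = emptyenv())
  xcache <- new.env(hash = TRUE, parent = emptyenv())
  tcache <- new.env(hash = TRUE, parent = emptyenv())

  props <- function(p) {
    v <- pcache[[p]]
    if (!is.null(v)) return(v)
    v <- if (grepl("N", p, fixed = TRUE)) list(has_n = TRUE)
    else list(has_n = FALSE, len = nchar(p), gc = gc_percent(p),
              tm = tm_of(p, cond),
              self_run = self_dimer(p)$best_contiguous_run,
              hair_run = hairpin(p)$best_contiguous_run,
              clamp = gc_clamp(p),
              n_sites = nrow(binding_sites(p, t, mm)))
    pcache[[p]] <- v
    v
  }
  cross_run <- function(f, r) {
    k <- paste0(f, "|", r)
    v <- xcache[[k]]
    if (is.null(v)) {
      v <- cross_dimer(f, r)$best_contiguous_run
      xcache[[k]] <- v
    }
    v
  }
  breakdown <- function(ch) {
    f_start <- ch[["f_start"]]; amp <- ch[["amplicon_len"]]
    if (f_start < reg$start || f_start + amp - 1L > reg$end)
      stop("chromosome outside the design region", call. = FALSE)
    r_end <- f_start + amp - 1L
    d <- list(fwd = substr(t$bases, f_start, f_start + ch[["f_len"]] - 1L),
              rev = substr(rc, L - r_end + 1L,
                           L - (r_end - ch[["r_len"]] + 1L) + 1L),
              product_size = amp)
    p <- setNames(numeric(length(.PENALTY_NAMES)), .PENALTY_NAMES)
    pf <- props(d$fwd); pr <- props(d$rev)
    if (pf$has_n || pr$has_n) {
      p["specificity"] <- Inf
      return(fitness_breakdown(p, weights))
    }
    p["length"] <-
      range_penalty(pf$len, cs$primer_len_min, cs$primer_len_max) +
      range_penalty(pr$len, cs$primer_len_min, cs$primer_len_max)
    p["length_diff"] <- excess(abs(pf$len - pr$len), cs$max_len_diff)
    p["gc"] <- range_penalty(pf$gc, cs$gc_min, cs$gc_max) +
      range_penalty(pr$gc, cs$gc_min, cs$gc_max)
    p["tm"] <- range_penalty(pf$tm, cs$tm_min, cs$tm_max) +
      range_penalty(pr$tm, cs$tm_min, cs$tm_max)
    p["tm_diff"] <- excess(abs(pf$tm - pr$tm), cs$max_tm_diff)
    p["product"] <- range_penalty(d$product_size, cs$product_min,
                                  cs$product_max)
    p["cross_dimer"] <- excess(cross_run(d$fwd, d$rev), cs$max_dimer_run)
    p["self_dimer_f"] <- excess(pf$self_run, cs$max_dimer_run)
    p["self_dimer_r"] <- excess(pr$self_run, cs$max_dimer_run)
    p["hairpin_f"] <- excess(pf$hair_run, cs$max_hairpin_run)
    p["hairpin_r"] <- excess(pr$hair_run, cs$max_hairpin_run)
    if (cs$require_gc_clamp)
      p["gc_clamp"] <- (!pf$clamp) + (!pr$clamp)
    p["specificity"] <- excess(pf$n_sites, 1L) + excess(pr$n_sites, 1L)
    fitness_breakdown(p, weights)
  }
  total <- function(ch) {
    k <- paste(ch, collapse = ",")
    v <- tcache[[k]]
    if (is.null(v)) {
      v <- breakdown(ch)$total
      tcache[[k]] <- v
    }
    v
  }
  list(breakdown = breakdown, total = total)
}
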