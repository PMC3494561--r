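# Seeded fixture generator: random templates with planted regions
# guaranteed to contain penalty-0 primer pairs under given constraints.
# Used by the test-suite and by demos; deterministic per seed.

#' Generate a random template with planted feasible primer pairs
#'
#' Builds a random-background template of the requested length and
#' plants `n_feasible` non-overlapping amplicons whose primer pairs
#' satisfy every constraint (total penalty 0).  Primer sequences are
#' rejection-sampled against the per-primer constraints (GC, Tm,
#' clamp, self-dimer, hairpin) and pair constraints (cross-dimer, Tm
#' and length difference); the finished template is verified with
#' [evaluate_pair()] and reconstructed if a rare cross-slot
#' specificity collision appears.  Fully deterministic per `seed`.
#'
#' @param length template length in bases.
#' @param n_feasible number of planted penalty-0 pairs (0 for pure
#'   background).
#' @param seed integer seed.
#' @param constraints the [design_constraints] the planted pairs must
#'   satisfy.
#' @param cond a [thermo_conditions].
#' @param gc_background background GC fraction in `[0, 1]`
#'   (default 0.5); low values give GC-poor backgrounds in which no
#'   feasible pair may exist at all.
#' @param max_tries rejection-sampling bound per primer.
#' @return A list: `template` (a [dna_seq]) and `manifest` (data frame
#'   of planted pairs: chromosome genes, primer sequences, verified
#'   penalty).
#' @export
make_fixture <- function(length, n_feasible = 1L, seed = 1L,
                         constraints = design_constraints(),
                         cond = thermo_conditions(),
                         gc_background = 0.5, max_tries = 500L) {
  length <- as.integer(length)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed %% 2147483647L)
  if (n_feasible == 0L)
    return(list(template = random_template(length, gc_background, seed),
                manifest = empty_manifest()))
  slot_w <- length %/% n_feasible
  cs <- constraints
  amp_lo <- max(cs$product_min, 2L * cs$primer_len_min)
  amp_hi <- min(cs$product_max, slot_w)
  if (amp_lo > amp_hi)
    stop("cannot plant ", n_feasible, " feasible pair(s) in ", length,
         " bp under the given constraints", call. = FALSE)
  for (attempt in seq_len(20L)) {
    chars <- random_bases(length, gc_background)
    rows <- vector("list", n_feasible)
    for (slot in seq_len(n_feasible)) {
      slot_start <- (slot - 1L) * slot_w + 1L
      pl <- plant_pair(cs, cond, amp_lo, amp_hi, max_tries)
      f_start <- slot_start + rand_int(0L, slot_w - pl$amp)
      fe <- f_start + pl$f_len - 1L
      rs <- f_start + pl$amp - pl$r_len
      re <- f_start + pl$amp - 1L
      chars[f_start:fe] <- seq_chars(pl$fwd)
      chars[rs:re] <- seq_chars(revcomp_chr(pl$rev))
      rows[[slot]] <- data.frame(
        slot = slot, f_start = f_start, f_len = pl$f_len,
        amplicon_len = pl$amp, r_len = pl$r_len,
        f_seq = pl$fwd, r_seq = pl$rev, stringsAsFactors = FALSE)
    }
    tpl <- dna_seq(paste(chars, collapse = ""),
                   id = sprintf("fixture_L%d_n%d_s%d", length,
                                n_feasible, seed))
    manifest <- do.call(rbind, rows)
    manifest$penalty <- vapply(seq_len(nrow(manifest)), function(i) {
      ch <- pair_chromosome(manifest$f_start[i], manifest$f_len[i],
                            manifest$amplicon_len[i], manifest$r_len[i])
      evaluate_pair(ch, tpl, cs, cond)$total
    }, 0)
    if (all(manifest$penalty == 0)) {
      return(list(template = tpl, manifest = manifest))
    }
  }
  stop("failed to construct a fixture with ", n_feasible,
       " feasible pair(s); constraints may be near-infeasible",
       call. = FALSE)
}

empty_manifest <- function() {
  data.frame(slot = integer(), f_start = integer(), f_len = integer(),
             amplicon_len = integer(), r_len = integer(),
             f_seq = character(), r_seq = character(),
             penalty = numeric(), stringsAsFactors = FALSE)
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_template <- function(n, gc, seed) {
  dna_seq(paste(random_bases(n, gc), collapse = ""),
          id = sprintf("fixture_L%d_n0_s%d", n, seed))
}

# one primer passing every per-primer constraint, or NULL if none of
# the draws does (e.g. a length whose Tm window is out of reach)
sample_primer <- function(len, cs, cond, tries = 40L) {
  kmin <- max(ceiling(cs$gc_min * len / 100), 1L)
  kmax <- floor(cs$gc_max * len / 100)
  if (kmin > kmax) return(NULL)
  for (i in seq_len(tries)) {
    k <- rand_int(kmin, kmax)
    pos <- c(sample.int(len - 1L, k - 1L), len)  # GC clamp at the 3' end
    ch <- ifelse(seq_len(len) %in% pos,
                 sample(c("G", "C"), len, replace = TRUE),
                 sample(c("A", "T"), len, replace = TRUE))
    p <- paste(ch, collapse = "")
    tm <- tm_of(p, cond)
    if (tm < cs$tm_min || tm > cs$tm_max) next
    if (self_dimer(p)$best_contiguous_run > cs$max_dimer_run) next
    if (hairpin(p)$best_contiguous_run > cs$max_hairpin_run) next
    return(list(seq = p, tm = tm))
  }
  NULL
}

# a primer pair + product size passing all pair-level constraints;
# lengths are re-drawn every attempt so infeasible length/Tm
# combinations are simply skipped
plant_pair <- function(cs, cond, amp_lo, amp_hi, max_tries) {
  for (i in seq_len(max_tries)) {
    f_len <- rand_int(cs$primer_len_min, cs$primer_len_max)
    r_len <- rand_int(max(cs$primer_len_min, f_len - cs$max_len_diff),
                      min(cs$primer_len_max, f_len + cs$max_len_diff))
    lo <- max(amp_lo, f_len + r_len)
    if (lo > amp_hi) next
    amp <- rand_int(lo, amp_hi)
    f <- sample_primer(f_len, cs, cond)
    if (is.null(f)) next
    r <- sample_primer(r_len, cs, cond)
    if (is.null(r)) next
    if (abs(f$tm - r$tm) > cs$max_tm_diff) next
    if (cross_dimer(f$seq, r$seq)$best_contiguous_run > cs$max_dimer_run)
      next
    return(list(fwd = f$seq, rev = r$seq, f_len = f_len, r_len = r_len,
                amp = amp))
  }
  stop("could not sample a feasible primer pair in ", max_tries,
       " tries; the constraint windows may be near-infeasible",
       call. = FALSE)
}
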