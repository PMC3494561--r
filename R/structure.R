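# Secondary-structure markers: cross-dimer, self-dimer, hairpin,
# GC clamp, and internal (template-matching) specificity.
#
# Dimer/hairpin scans are ungapped sliding alignments counting
# Watson-Crick pairs only (no G.T wobble); N never pairs.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "_")

anneal_report <- function(total = 0L, run = 0L, offset = 0L) {
  structure(list(best_total_matches = as.integer(total),
                 best_contiguous_run = as.integer(run),
                 offset = as.integer(offset)),
            class = "anneal_report")
}

#' @export
print.anneal_report <- function(x, ...) {
  cat(sprintf("<anneal_report> total %d, contiguous run %d, offset %d\n",
              x$best_total_matches, x$best_contiguous_run, x$offset))
  invisible(x)
}

longest_true_run <- function(v) {
  if (!any(v)) return(0L)
  # gap between consecutive FALSE positions (with sentinels) minus one
  b <- c(0L, which(!v), length(v) + 1L)
  max(diff(b)) - 1L
}

#' Cross-dimer scan of two primers
#'
#' Slides primer `a` along the reverse of primer `b` (antiparallel
#' annealing) and counts Watson-Crick complementary pairs at every
#' ungapped offset.  Returns the report for the offset maximizing the
#' total pair count; ties are broken toward the larger contiguous run,
#' then the smaller offset.
#'
#' @param a,b primer sequences (character or [dna_seq]), N-free.
#' @return An `anneal_report`: `best_total_matches`,
#'   `best_contiguous_run` and the `offset` at which they occur.
#' @export
cross_dimer <- function(a, b) {
  ac <- seq_chars(check_primer_seq(a, "cross_dimer"))
  bc <- rev(seq_chars(check_primer_seq(b, "cross_dimer")))
  la <- length(ac); lb <- length(bc)
  M <- outer(.COMP[ac], bc, "==")  # M[i, j]: a[i] pairs rev(b)[j]
  # an alignment offset k pairs a[i] with rev(b)[i - k]: one matrix
  # diagonal each; total matches per offset in one tabulate pass
  hit <- which(M)
  if (!length(hit)) return(anneal_report(0L, 0L, 0L))
  i <- (hit - 1L) %% la + 1L
  j <- (hit - 1L) %/% la + 1L
  tots <- tabulate(i - j + lb, nbins = la + lb - 1L)
  best_tot <- max(tots)
  best_run <- -1L; best_off <- 0L
  for (k in which(tots == best_tot) - lb) {  # ascending: smaller offset first
    ii <- seq.int(max(1L, k + 1L), min(la, lb + k))
    run <- longest_true_run(M[ii + (ii - k - 1L) * la])
    if (run > best_run) { best_run <- run; best_off <- k }
  }
  anneal_report(best_tot, best_run, best_off)
}

#' Self-dimer scan
#'
#' [cross_dimer()] of a primer against itself.
#'
#' @param a primer sequence, N-free.
#' @return An `anneal_report`.
#' @export
self_dimer <- function(a) cross_dimer(a, a)

#' Hairpin scan
#'
#' Evaluates every partition of the primer into stem1 / loop / stem2
#' with loop length at least `min_loop`, pairing the stems antiparallel
#' from the loop outward and counting Watson-Crick pairs.  Returns the
#' partition maximizing total stem pairing (ties toward the larger
#' contiguous run, then the shorter loop, then the smaller stem1).
#' Primers too short for any partition return a zero report.  The
#' report's `offset` holds the stem1 length of the best partition.
#'
#' @param a primer sequence, N-free.
#' @param min_loop minimum loop length in bases (default 3, the
#'   sterically minimal loop).
#' @return An `anneal_report`.
#' @export
hairpin <- function(a, min_loop = 3L) {
  ch <- seq_chars(check_primer_seq(a, "hairpin"))
  n <- length(ch)
  best <- anneal_report(0L, 0L, 0L)
  if (n < 2L + min_loop) return(best)
  M <- outer(.COMP[ch], ch, "==")  # M[i, j]: base i pairs base j
  best_tot <- 0L; best_run <- 0L; best_s1 <- 0L
  for (loop in seq.int(min_loop, n - 2L)) {
    for (s1 in seq_len(n - loop - 1L)) {
      s2 <- n - loop - s1
      m <- min(s1, s2)
      # pair stem1 3' end with stem2 5' end, zipping outward
      i <- s1 - seq_len(m) + 1L
      j <- s1 + loop + seq_len(m)
      hits <- M[cbind(i, j)]
      tot <- sum(hits)
      if (tot < best_tot || tot == 0L) next
      run <- longest_true_run(hits)
      if (tot > best_tot || run > best_run) {
        best_tot <- tot; best_run <- run; best_s1 <- s1
      }
    }
  }
  anneal_report(best_tot, best_run, best_s1)
}

#' GC clamp check
#'
#' `TRUE` iff the 3'-terminal base of the primer is G or C.
#'
#' @param a primer sequence, non-empty.
#' @return logical scalar.
#' @export
gc_clamp <- function(a) {
  b <- seq_string(a)
  stopifnot(nchar(b) >= 1L)
  substr(b, nchar(b), nchar(b)) %in% c("G", "C")
}

#' Primer binding sites on a template
#'
#' Scans both strands of a template for ungapped matches of a primer
#' with at most `max_mismatch` mismatching bases.  Plus-strand sites are
#' positions where the primer sequence itself matches the template;
#' minus-strand sites are positions where the primer's reverse
#' complement matches (the primer anneals to the plus strand there).
#' `N` in the template never matches.  `start` is always the leftmost
#' (smallest) plus-strand coordinate of the site, 1-based.
#'
#' @param p primer sequence, length at most the template length.
#' @param t template ([dna_seq] or character).
#' @param max_mismatch allowed mismatches per site (default 0).
#' @param anchor_3prime if `TRUE`, the primer's 3'-terminal base must
#'   match exactly even when `max_mismatch > 0` (a terminal mismatch
#'   blocks polymerase extension).
#' @return A data frame with columns `template_id`, `start`, `strand`
#'   (`"+"`/`"-"`), `mismatches`, sorted by (strand, start).
#' @export
binding_sites <- function(p, t, max_mismatch = 0L, anchor_3prime = FALSE) {
  t <- as_dna_seq(t, id = "template")
  pb <- seq_string(p)
  m <- nchar(pb)
  stopifnot(m >= 1L, m <= t$length)
  tch <- seq_chars(t)
  res <- list(
    scan_strand(pb, tch, max_mismatch, anchor_3prime, minus = FALSE),
    scan_strand(pb, tch, max_mismatch, anchor_3prime, minus = TRUE))
  out <- do.call(rbind, res)
  if (nrow(out)) {
    out <- out[order(out$strand, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  cbind(template_id = rep(t$id, nrow(out)), out)
}

# one-strand ungapped mismatch scan; window mismatch counts built by
# accumulating per-position inequality over the primer length
scan_strand <- function(pb, tch, max_mismatch, anchor_3prime, minus) {
  qb <- if (minus) revcomp_chr(pb) else pb
  q <- strsplit(qb, "", fixed = TRUE)[[1]]
  m <- length(q)
  L <- length(tch)
  W <- L - m + 1L
  mm <- integer(W)
  for (j in seq_len(m)) {
    tj <- tch[j:(j + W - 1L)]
    mm <- mm + (tj != q[j] | tj == "N" | q[j] == "N")
  }
  ok <- mm <= max_mismatch
  if (anchor_3prime) {
    # primer 3' end = last base on plus orientation, first on minus
    j3 <- if (minus) 1L else m
    t3 <- tch[j3:(j3 + W - 1L)]
    ok <- ok & t3 == q[j3] & t3 != "N"
  }
  idx <- which(ok)
  data.frame(start = idx,
             strand = rep(if (minus) "-" else "+", length(idx)),
             mismatches = mm[idx],
             stringsAsFactors = FALSE)
}

#' Single-site specificity of a primer pair on a template
#'
#' `TRUE` iff the forward primer has exactly one plus-strand binding
#' site and none on the minus strand, and the reverse primer exactly
#' one minus-strand site and none on the plus strand, within the
#' mismatch tolerance.
#'
#' @param fwd,rev forward and reverse primer sequences (both 5'->3').
#' @param t template.
#' @param max_mismatch allowed mismatches per site.
#' @return logical scalar.
#' @export
is_specific <- function(fwd, rev, t, max_mismatch = 0L) {
  sf <- binding_sites(fwd, t, max_mismatch)
  sr <- binding_sites(rev, t, max_mismatch)
  sum(sf$strand == "+") == 1L && sum(sf$strand == "-") == 0L &&
    sum(sr$strand == "-") == 1L && sum(sr$strand == "+") == 0L
}
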