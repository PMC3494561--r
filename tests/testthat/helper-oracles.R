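# Independent exhaustive reference implementations used as oracles.
# Written as plain loops, deliberately sharing no code with the package.

ORACLE_COMP <- c(A = "T", T = "A", C = "G", G = "C")

random_primer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_template_chr <- function(n) random_primer(n)

# complementarity of two single bases, Watson-Crick only
bases_pair <- function(x, y) {
  !is.na(ORACLE_COMP[x]) && ORACLE_COMP[[x]] == y
}

# longest run of TRUE by explicit counting
oracle_run <- function(hits) {
  best <- 0L; cur <- 0L
  for (h in hits) {
    cur <- if (h) cur + 1L else 0L
    if (cur > best) best <- cur
  }
  best
}

# brute-force dimer scan: a slid along reverse(b), every offset
oracle_dimer <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  la <- length(av); lb <- length(bv)
  best_tot <- 0L; best_run <- 0L; best_off <- 0L
  for (k in (-(lb - 1L)):(la - 1L)) {
    hits <- logical(0)
    for (i in seq_len(la)) {
      j <- i - k
      if (j >= 1L && j <= lb)
        hits <- c(hits, bases_pair(av[i], bv[j]))
    }
    tot <- sum(hits)
    run <- oracle_run(hits)
    if (tot > best_tot ||
        (tot == best_tot && run > best_run)) {
      best_tot <- tot; best_run <- run; best_off <- k
    }
  }
  list(total = as.integer(best_tot), run = best_run, offset = best_off)
}

# brute-force hairpin: every stem1/loop/stem2 partition, stems zipped
# from the loop outward
oracle_hairpin <- function(a, min_loop = 3L) {
  v <- strsplit(a, "")[[1]]
  n <- length(v)
  best_tot <- 0L; best_run <- 0L
  if (n < min_loop + 2L) return(list(total = 0L, run = 0L))
  for (s1 in 1:(n - min_loop - 1L)) {
    for (s2 in 1:(n - min_loop - s1)) {
      loop <- n - s1 - s2
      if (loop < min_loop) next
      m <- min(s1, s2)
      hits <- logical(m)
      for (tt in seq_len(m))
        hits[tt] <- bases_pair(v[s1 - tt + 1L], v[s1 + loop + tt])
      tot <- sum(hits)
      run <- oracle_run(hits)
      if (tot > best_tot || (tot == best_tot && run > best_run)) {
        best_tot <- tot; best_run <- run
      }
    }
  }
  list(total = as.integer(best_tot), run = best_run)
}

# naive binding-site scan: every start position, both strands,
# counting mismatches character by character; N never matches
oracle_sites <- function(p, t, max_mismatch = 0L) {
  pv <- strsplit(p, "")[[1]]
  rcv <- rev(unname(ORACLE_COMP[pv]))  # reverse complement of primer
  tv <- strsplit(t, "")[[1]]
  m <- length(pv); L <- length(tv)
  out <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") pv else rcv
    for (s in seq_len(L - m + 1L)) {
      w <- tv[s:(s + m - 1L)]
      mm <- sum(w != q | w == "N" | q == "N")
      if (mm <= max_mismatch)
        out <- rbind(out, data.frame(start = s, strand = strand,
                                     mismatches = mm,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out[order(out$strand, out$start), , drop = FALSE]
}

# brute-force amplicon pairing: every (plus fwd site, minus rev site)
# combination with fwd 5' <= rev 5' and length cap
oracle_amplicons <- function(fwd, rev, t, max_product = 4000L) {
  sf <- oracle_sites(fwd, t, 0L)
  sr <- oracle_sites(rev, t, 0L)
  a_starts <- sf$start[sf$strand == "+"]
  b_starts <- sr$start[sr$strand == "-"]
  out <- NULL
  for (a in a_starts)
    for (b in b_starts) {
      e <- b + nchar(rev) - 1L
      if (e >= a && e - a + 1L <= max_product)
        out <- rbind(out, data.frame(start = a, end = e,
                                     length = e - a + 1L))
    }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      length = integer()))
  out[order(out$start, out$length), , drop = FALSE]
}

# the tight constraint window used for small-template optimum-recovery
# studies: short primers and a 60-100 bp product fit a <=120 bp
# template; the Tm floor of 45 C reflects what 18-20-mers at 40-60% GC
# reach under 50 mM Na+
tight_constraints <- function() {
  design_constraints(primer_len_min = 18, primer_len_max = 20,
                     product_min = 60, product_max = 100,
                     tm_min = 45, tm_max = 62)
}
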