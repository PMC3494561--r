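# Candidate ranking and the plain-text / TSV report.

#' Rank designed primer pairs
#'
#' Sorts candidates by (total penalty ascending, Tm difference
#' ascending, forward start ascending) and assigns ranks 1..n; rank 1
#' is the best pair.  An empty candidate list yields an empty ranking
#' (an explicit "no feasible primer" result), not an error.
#'
#' @param candidates list of candidates as returned by [run_design()]:
#'   each `list(chromosome, breakdown)`.
#' @param t template.
#' @param cond a [thermo_conditions].
#' @param score `"lexicographic"` (default) orders by the composite
#'   key above; `"weighted"` orders by `penalty + tm_weight * tm_diff`.
#' @param tm_weight weight on the Tm difference under
#'   `score = "weighted"`.
#' @return An object of class `ranked_pairs`: a list with `table` (one
#'   data-frame row per pair: sequences, positions, lengths, GC, Tm,
#'   product size, structure markers, penalty) and `breakdowns`.
#' @export
rank_pairs <- function(candidates, t, cond = thermo_conditions(),
                       score = c("lexicographic", "weighted"),
                       tm_weight = 1) {
  t <- as_dna_seq(t)
  score <- match.arg(score)
  if (length(candidates) == 0L) {
    return(structure(list(table = empty_rank_table(),
                          breakdowns = list(), template_id = t$id),
                     class = "ranked_pairs"))
  }
  rows <- lapply(candidates, function(cand) {
    d <- decode_pair(cand$chromosome, t)
    tm_f <- tm_of(d$fwd, cond); tm_r <- tm_of(d$rev, cond)
    data.frame(
      f_seq = d$fwd, r_seq = d$rev,
      f_len = nchar(d$fwd), r_len = nchar(d$rev),
      f_start = d$f_start, f_end = d$f_end,
      r_start = d$r_start, r_end = d$r_end,
      gc_count_f = round(gc_percent(d$fwd) * nchar(d$fwd) / 100),
      gc_count_r = round(gc_percent(d$rev) * nchar(d$rev) / 100),
      gc_f = gc_percent(d$fwd), gc_r = gc_percent(d$rev),
      tm_f = round_half_up(tm_f, 2), tm_r = round_half_up(tm_r, 2),
      tm_diff = round_half_up(abs(tm_f - tm_r), 2),
      product_size = d$product_size,
      cross_dimer_run = cross_dimer(d$fwd, d$rev)$best_contiguous_run,
      self_dimer_f_run = self_dimer(d$fwd)$best_contiguous_run,
      self_dimer_r_run = self_dimer(d$rev)$best_contiguous_run,
      hairpin_f_run = hairpin(d$fwd)$best_contiguous_run,
      hairpin_r_run = hairpin(d$rev)$best_contiguous_run,
      gc_clamp_f = gc_clamp(d$fwd), gc_clamp_r = gc_clamp(d$rev),
      specific = is_specific(d$fwd, d$rev, t),
      penalty = cand$breakdown$total,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- if (score == "weighted")
    order(tab$penalty + tm_weight * tab$tm_diff, tab$f_start)
  else order(tab$penalty, tab$tm_diff, tab$f_start)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 breakdowns = lapply(candidates, `[[`, "breakdown")[ord],
                 template_id = t$id),
            class = "ranked_pairs")
}

empty_rank_table <- function() {
  data.frame(rank = integer(), f_seq = character(), r_seq = character(),
             f_len = integer(), r_len = integer(), f_start = integer(),
             f_end = integer(), r_start = integer(), r_end = integer(),
             gc_count_f = numeric(), gc_count_r = numeric(),
             gc_f = numeric(), gc_r = numeric(),
             tm_f = numeric(), tm_r = numeric(), tm_diff = numeric(),
             product_size = integer(), cross_dimer_run = integer(),
             self_dimer_f_run = integer(), self_dimer_r_run = integer(),
             hairpin_f_run = integer(), hairpin_r_run = integer(),
             gc_clamp_f = logical(), gc_clamp_r = logical(),
             specific = logical(), penalty = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.ranked_pairs <- function(x, n = 5L, ...) {
  if (nrow(x$table) == 0L) {
    cat("No feasible primer pair found for template", x$template_id, "\n")
    return(invisible(x))
  }
  cat("Ranked primer pairs for template", x$template_id, "\n")
  cols <- c("rank", "f_seq", "r_seq", "f_start", "r_end",
            "product_size", "tm_f", "tm_r", "tm_diff", "penalty")
  print(head(x$table[, cols], n))
  invisible(x)
}

#' Write a design report
#'
#' Generic: writes the full plain-text (or TSV) report for a ranking
#' or a [design_primers()] result.
#'
#' @param x object to report on.
#' @param path output file path.
#' @param ... passed to methods.
#' @return `path`, invisibly.
#' @export
report <- function(x, path, ...) UseMethod("report")

#' @describeIn report Plain-text report of a ranking: a header echoing
#'   every design constraint and algorithm parameter, then one block
#'   per pair with sequences (5'->3'), lengths, positions (from-to),
#'   GC count and GC%, Tm and Tm difference, product size, and a
#'   structure-marker line (cross-dimer / self-dimer / hairpin runs,
#'   GC clamp, specificity).  Output is byte-deterministic unless
#'   `stamp = TRUE` adds a timestamp line.
#' @param constraints,params,cond the settings to echo in the header.
#' @param format `"text"` or `"tsv"`.
#' @param stamp add a timestamp line (off by default so reports are
#'   reproducible byte-for-byte).
#' @export
report.ranked_pairs <- function(x, path, constraints = design_constraints(),
                                params = evolution_params(),
                                cond = thermo_conditions(),
                                format = c("text", "tsv"),
                                stamp = FALSE, ...) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(x$table, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  add("# Primer design report")
  if (stamp) add("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  add("template: ", x$template_id)
  add("")
  add("## Constraints")
  for (f in setdiff(names(constraints), "region"))
    add("constraint.", f, " = ", format(constraints[[f]]))
  reg <- constraints$region
  add("constraint.region = ",
      if (is.null(reg)) "full" else paste0(reg$start, "-", reg$end))
  add("")
  add("## Algorithm parameters")
  for (f in names(params)) add("param.", f, " = ", format(params[[f]]))
  add("param.sodium_molar = ", format(cond$sodium_molar))
  add("param.strand_molar = ", format(cond$strand_molar))
  add("param.tm_method = ", cond$tm_method)
  add("")
  if (nrow(x$table) == 0L) {
    add("## Result")
    add("No feasible primer pair found under the constraints above.")
  } else {
    add("## Ranked primer pairs")
    for (i in seq_len(nrow(x$table))) {
      r <- x$table[i, ]
      add("")
      add("rank: ", r$rank)
      add("forward.seq: ", r$f_seq)
      add("forward.length: ", r$f_len)
      add("forward.position: ", r$f_start, "-", r$f_end)
      add("forward.gc_count: ", r$gc_count_f)
      add("forward.gc_percent: ", sprintf("%.2f", r$gc_f))
      add("forward.tm: ", sprintf("%.2f", r$tm_f))
      add("reverse.seq: ", r$r_seq)
      add("reverse.length: ", r$r_len)
      add("reverse.position: ", r$r_start, "-", r$r_end)
      add("reverse.gc_count: ", r$gc_count_r)
      add("reverse.gc_percent: ", sprintf("%.2f", r$gc_r))
      add("reverse.tm: ", sprintf("%.2f", r$tm_r))
      add("pair.tm_diff: ", sprintf("%.2f", r$tm_diff))
      add("pair.product_size: ", r$product_size)
      add("pair.penalty: ", format(r$penalty))
      add("markers: cross_dimer_run=", r$cross_dimer_run,
          " self_dimer_f=", r$self_dimer_f_run,
          " self_dimer_r=", r$self_dimer_r_run,
          " hairpin_f=", r$hairpin_f_run,
          " hairpin_r=", r$hairpin_r_run,
          " gc_clamp_f=", if (r$gc_clamp_f) "yes" else "no",
          " gc_clamp_r=", if (r$gc_clamp_r) "yes" else "no",
          " specific=", if (r$specific) "yes" else "no")
    }
  }
  con <- file(path, open = "wb")  # fixed newlines for byte-identical output
  on.exit(close(con))
  writeLines(ln, con, sep = "\n")
  invisible(path)
}
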