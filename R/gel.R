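# Virtual gel electrophoresis: log-linear mobility model, ASCII and
# SVG renderers, and an expected-vs-observed band comparison.

#' Virtual gel model
#'
#' Log-linear agarose mobility: migration distance is proportional to
#' the negative log10 of fragment size, anchored so that `size_min`
#' runs the full lane and `size_max` stays at the well.
#'
#' @param lane_height lane length in render units (default 100).
#' @param size_min,size_max fragment sizes (bp) anchoring the scale;
#'   defaults 100 and 1500 match a standard 100-bp ladder.
#' @param ladder marker band sizes in bp (default 100, 200, ..., 1500).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(lane_height = 100, size_min = 100, size_max = 1500,
                      ladder = seq(100, 1500, by = 100)) {
  stopifnot(size_min < size_max, all(ladder > 0), lane_height > 0)
  structure(list(lane_height = lane_height, size_min = size_min,
                 size_max = size_max, ladder = sort(ladder)),
            class = "gel_model")
}

#' Migration distance of a fragment
#'
#' `d(size) = lane_height * (log10(size_max) - log10(size)) /
#' (log10(size_max) - log10(size_min))`, clipped to
#' `[0, lane_height]`.  Strictly decreasing in size within the
#' anchored range: smaller fragments run farther.
#'
#' @param size fragment size(s) in bp, positive.
#' @param m a [gel_model].
#' @return Distance(s) from the well in render units.
#' @examples
#' migration(c(496, 451, 330), gel_model())
#' @export
migration <- function(size, m = gel_model()) {
  if (any(size <= 0)) stop("fragment size must be positive", call. = FALSE)
  d <- m$lane_height * (log10(m$size_max) - log10(size)) /
    (log10(m$size_max) - log10(m$size_min))
  pmin(pmax(d, 0), m$lane_height)
}

#' Render a virtual gel
#'
#' Writes a deterministic ASCII (`format = "txt"`) or SVG image of the
#' gel: the ladder lane (`M`) first, then one lane per entry of
#' `lanes`, each band drawn at its [migration()] distance and labelled
#' with its size.  Bands in one lane closer than 1 render unit are
#' flagged as co-migrating (unresolvable on this gel).
#'
#' @param lanes named list: lane label -> numeric vector of band sizes
#'   (bp); an empty vector renders an empty labelled lane.
#' @param m a [gel_model].
#' @param path output file path.
#' @param format `"txt"` or `"svg"`.
#' @return `path`, invisibly.
#' @export
render_gel <- function(lanes, m = gel_model(), path,
                       format = c("txt", "svg")) {
  stopifnot(length(lanes) >= 1L)
  format <- match.arg(format)
  if (is.null(names(lanes)) || any(names(lanes) == ""))
    names(lanes) <- paste0("lane", seq_along(lanes))
  all_lanes <- c(list(M = m$ladder), lanes)
  comig <- comigrating(lanes, m)
  ln <- if (format == "svg") gel_svg(all_lanes, m, comig)
        else gel_txt(all_lanes, m, comig)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ln, con, sep = "\n")
  invisible(path)
}

comigrating <- function(lanes, m) {
  out <- character()
  for (nm in names(lanes)) {
    sz <- sort(lanes[[nm]])
    if (length(sz) < 2L) next
    d <- migration(sz, m)
    close_i <- which(abs(diff(d)) < 1)
    for (i in close_i)
      out <- c(out, sprintf("co-migrating: lane %s sizes %g,%g", nm,
                            sz[i], sz[i + 1L]))
  }
  out
}

gel_txt <- function(all_lanes, m, comig) {
  nr <- floor(m$lane_height) + 1L
  width <- 8L
  cells <- matrix(strrep(" ", width), nrow = nr, ncol = length(all_lanes))
  for (j in seq_along(all_lanes))
    for (s in all_lanes[[j]]) {
      r <- round(migration(s, m)) + 1L
      cells[r, j] <- sprintf("%-8s", paste0("=", s, "=") )
    }
  hdr <- paste0("dist  | ",
                paste(sprintf("%-8s", names(all_lanes)), collapse = " "))
  body <- vapply(seq_len(nr), function(r)
    paste0(sprintf("%5d | ", r - 1L), paste(cells[r, ], collapse = " ")),
    "")
  c("# virtual gel (distance in render units from the well)", hdr,
    paste(rep("-", nchar(hdr)), collapse = ""), body, comig)
}

gel_svg <- function(all_lanes, m, comig) {
  lane_w <- 60; pad <- 40; h <- m$lane_height * 3 + 2 * pad
  w <- pad * 2 + lane_w * length(all_lanes)
  ln <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  round(w), round(h)),
          sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#202030"/>',
                  round(w), round(h)))
  for (j in seq_along(all_lanes)) {
    x <- pad + (j - 1) * lane_w
    ln <- c(ln, sprintf('<text x="%d" y="%d" fill="white" font-size="12">%s</text>',
                        round(x + 8), round(pad - 10), names(all_lanes)[j]))
    for (s in all_lanes[[j]]) {
      y <- pad + migration(s, m) * 3
      ln <- c(ln,
              sprintf('<rect x="%d" y="%.1f" width="%d" height="4" fill="#e8e8f0"/>',
                      round(x), y, lane_w - 18),
              sprintf('<text x="%d" y="%.1f" fill="#aaaacc" font-size="8">%g</text>',
                      round(x + lane_w - 16), y + 4, s))
    }
  }
  if (length(comig))
    ln <- c(ln, sprintf('<!-- %s -->', comig))
  c(ln, "</svg>")
}

#' Compare expected and observed band sizes
#'
#' Virtual counterpart of running the real gel next to the prediction:
#' pairs each expected product size with an observed size (in order)
#' and reports per-band deltas in bp and in migration distance.
#'
#' @param expected,observed numeric vectors of band sizes (bp), same
#'   length.
#' @param m a [gel_model].
#' @return Data frame with `expected`, `observed`, `delta_bp`,
#'   `delta_distance`.
#' @export
compare_bands <- function(expected, observed, m = gel_model()) {
  stopifnot(length(expected) == length(observed))
  data.frame(expected = expected, observed = observed,
             delta_bp = observed - expected,
             delta_distance = migration(observed, m) - migration(expected, m))
}
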