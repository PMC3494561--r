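# Sequence model, validation, reverse complement, FASTA I/O.
# Coordinates are 1-based inclusive throughout the package.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
# IUPAC ambiguity codes coerced to N on ingest (templates from public
# records may carry them; primers must not).
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' DNA sequence record
#'
#' A validated single-stranded DNA sequence with an id label.  Bases are
#' uppercased; `U` is mapped to `T`; IUPAC ambiguity codes other than `N`
#' are coerced to `N` with a warning; any other character is an error.
#'
#' @param bases character scalar of nucleotides.
#' @param id record label.
#' @return An object of class `dna_seq`: a list with `id`, `bases`
#'   (character scalar over `A,C,G,T,N`) and `length`.
#' @examples
#' dna_seq("acgtu", id = "x")   # normalized to ACGTT
#' @export
dna_seq <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L)
  b <- toupper(bases)
  b <- gsub("U", "T", b, fixed = TRUE)
  chars <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(chars) < 1L)
    stop("sequence '", id, "': empty sequence", call. = FALSE)
  amb <- chars %in% .IUPAC_AMBIG
  if (any(amb)) {
    warning("sequence '", id, "': ", sum(amb),
            " ambiguity code(s) coerced to N", call. = FALSE)
    chars[amb] <- "N"
  }
  bad <- !(chars %in% .DNA_ALPHABET)
  if (any(bad)) {
    stop("sequence '", id, "': invalid character(s) ",
         paste(unique(chars[bad]), collapse = ", "),
         " at position(s) ", paste(head(which(bad), 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = as.character(id),
                 bases = paste(chars, collapse = ""),
                 length = length(chars)),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  b <- if (x$length > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat(sprintf("<dna_seq> %s (%d bp)\n  %s\n", x$id, x$length, b))
  invisible(x)
}

as_dna_seq <- function(x, id = "seq") {
  if (inherits(x, "dna_seq")) x else dna_seq(x, id = id)
}

#' Region restriction on a template
#'
#' 1-based inclusive bounds restricting where primers may be designed on
#' a single template.
#'
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return An object of class `region`.
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid region: need 1 <= start <= end", call. = FALSE)
  structure(list(start = start, end = end), class = "region")
}

#' Read a (multi-)FASTA file of DNA templates
#'
#' Records are returned in file order.  Lowercase is uppercased, `U`
#' becomes `T`, IUPAC ambiguity codes other than `N` become `N` with a
#' warning; anything else is a parse error naming the record.
#'
#' @param path path to a FASTA file with at least one record.
#' @return A list of [dna_seq] records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("FASTA parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA parse error in ", path, ": no records", call. = FALSE)
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("record", seq_along(set))
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (nchar(s) == 0L)
      stop("FASTA parse error in ", path, ": record '", ids[i],
           "' has an empty sequence", call. = FALSE)
    out[[i]] <- dna_seq(s, id = ids[i])
  }
  out
}

#' Write DNA records to a FASTA file
#'
#' @param seqs a [dna_seq] or list of them.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param s a [dna_seq] or plain character scalar.
#' @return Same type as the input (a `dna_seq` keeps its id with an
#'   `_rc` suffix).
#' @export
reverse_complement <- function(s) {
  if (inherits(s, "dna_seq")) {
    out <- dna_seq(revcomp_chr(s$bases), id = paste0(s$id, "_rc"))
    return(out)
  }
  revcomp_chr(s)
}

# plain-character reverse complement, vectorized over a character vector
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) {
  strsplit(if (inherits(s, "dna_seq")) s$bases else toupper(s),
           "", fixed = TRUE)[[1]]
}

seq_string <- function(s) if (inherits(s, "dna_seq")) s$bases else toupper(s)
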