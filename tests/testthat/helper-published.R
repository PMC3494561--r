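# the published validation primers and their template coordinates:
# forward 5' start, and the plus-strand position the reverse primer's
# 5' base anneals to
TABLE_PAIRS <- list(
  blaOXA_496 = list(fwd = "GTGCTTCGACCGAGTATG", f5 = 212L,
                    rev = "ACAACCATCCAGTTAACC", r5 = 707L, size = 496L),
  blaOXA_451 = list(fwd = "GAGCACCATAAGGCAACC", f5 = 274L,
                    rev = "TATTCCCTTGAGGCTGAAC", r5 = 724L, size = 451L),
  pbp_330 = list(fwd = "ATGCTTTACGACAAAGTTTC", f5 = 514L,
                 rev = "TCTCAGCTAACATGTATGC", r5 = 843L, size = 330L))

# random background with the pair planted at its published coordinates
plant_pair_template <- function(p, len = 900L, seed = 1L, id = "t") {
  set.seed(seed)
  ch <- strsplit(random_template_chr(len), "")[[1]]
  ch[p$f5:(p$f5 + nchar(p$fwd) - 1L)] <- strsplit(p$fwd, "")[[1]]
  rc <- reverse_complement(p$rev)
  ch[(p$r5 - nchar(p$rev) + 1L):p$r5] <- strsplit(rc, "")[[1]]
  dna_seq(paste(ch, collapse = ""), id = id)
}
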