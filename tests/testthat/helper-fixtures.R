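# shared fixture builders; all randomness under explicit seeds

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else ltrtracer:::with_seed(seed, draw())
}

qual_string <- function(phred) rawToChar(as.raw(as.integer(phred) + 33L))

reads_df <- function(bases, qual = NULL, prefix = "t") {
  data.frame(
    read_id = sprintf("%s%04d", prefix, seq_along(bases)),
    bases = bases,
    qualities = qual %||% strrep(qual_string(38), nchar(bases)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small two-superfamily spec set used across tests
tiny_specs <- function(copies = 10, copy_divergence = 0.02,
                       panel_divergence = 0.02) {
  rbind(
    family_spec("gA", "gypsy", "A", 4300, copies, copy_divergence,
                panel_divergence),
    family_spec("gC", "gypsy", "C", 5200, copies, copy_divergence,
                panel_divergence),
    family_spec("c1", "copia", "1", 4800, copies, copy_divergence,
                panel_divergence)
  )
}

# independent alignment oracle: Biostrings overlap alignment with the same
# scoring (match +1, mismatch -2, linear gap -3)
oracle_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b),
                                type = "overlap", substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 3)
}
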