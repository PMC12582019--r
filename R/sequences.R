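#' Oligonucleotide sequences of the G4_IX system
#'
#' The DNA sequences analyzed throughout the package: the 32-nt
#' G-quadruplex-forming motif from S. cerevisiae chromosome IX (G4_IX), its
#' G-to-C mutant that cannot form a quadruplex, and the two strands of the
#' single-molecule FRET construct (the donor-labeled strand carries the
#' G4_IX motif plus an 18-nt hybridization handle; the complementary
#' acceptor strand carries the biotin anchor). Fluorophore and biotin
#' modifications are annotated in `role`, not in the sequence. The same
#' sequences ship as FASTA in `inst/extdata/g4_sequences.fasta`.
#'
#' @return data.frame with columns `name`, `role`, `sequence` (5'->3', DNA
#'   alphabet).
#' @export
#' @examples
#' g4_sequences()$sequence[1]
g4_sequences <- function() {
  out <- data.frame(
    name = c("G4_IX", "G4_IXmut", "fret_donor_strand", "fret_acceptor_strand"),
    role = c(
      "G4 motif, chromosome IX",
      "mutant control (G-tracts disrupted)",
      "FRET strand: handle + G4_IX, 3' Cy3 donor",
      "FRET strand: complement of handle, 5' Cy5 acceptor, 3' biotin"
    ),
    sequence = c(
      "GGGTACGGTGGGTAATAAGGGAAGGTATCGGG",
      "GCGTACGGTGCGTAATAAGCGAAGGTATCGCG",
      "TGGCGACGGCAGCGACCATTTGGGTACGGTGGGTAATAAGGGAAGGTATCGGG",
      "TGGTCGCTGCCGTCGCCA"
    )
  )
  stopifnot(all(grepl("^[ACGT]+$", out$sequence)))
  out
}
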