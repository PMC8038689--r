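# Published oligo set for the DHFR exon-2-duplication minigene system: five
# editing PPRHs, the tail-only negative control, and the PCR primer pairs
# used for genotyping and mRNA analysis. Shipped as reference fixtures; the
# names are opaque labels and are never parsed for semantics.

#' Published editing-PPRH and control oligos
#'
#' The six oligos designed against the DHFR exon-duplication minigene: five
#' editing PPRHs (hairpin core + pentathymidine linker + homology tail
#' spanning the PstI edit junction) targeting polypurine tracks in the
#' promoter, exon 3 and exon 6, plus `UDPst1`, the 40-nt homology tail
#' without a hairpin core (negative-control grammar case).
#'
#' @return data.frame with columns `name`, `sequence`, `target` and
#'   `editing` (`FALSE` for the tail-only control).
#' @export
published_pprh_oligos <- function() {
  data.frame(
    name = c("LDSHpPrI1UPstI", "LDSHpPrI1UDstI", "LDSHpE6I1DPstI",
             "LDSHpE6I1UDPstI", "LDSHpE3I1UDPstI", "UDPst1"),
    sequence = c(
      "CTGCAGCCGGCGGGCCTACCTTTTTGGGGAAGGAAAAGTGGGTGACATTTTTACAGTGGGTGAAAAGGAAGGGG",
      "ACCGCGGGCATGGGCAAGGGCTGCAGCCGGCGGGCCTACCTTTTTGGGGAAGGAAAAGTGGGTGACATTTTTACAGTGGGTGAAAAGGAAGGGG",
      "CCCTTGCCCATGCCCGCGGTTTTTTAGGAGGAAAAAGGCATCAAGTTTTTGAACTACGGAAAAAGGAGGA",
      "GGTAGGCCCGCCGGCTGCAGCCCTTGCCCATGCCCGCGGTTTTTTAGGAGGAAAAAGGCATCAAGTTTTTGAACTACGGAAAAAGGAGGA",
      "GGTAGGCCCGCCGGCTGCAGCCCTTGCCCATGCCCGCGGTTTTTTGGACCAAGAGGTAAGGATTTTTAGGAATGGAGAACCAGG",
      "GGTAGGCCCGCCGGCTGCAGCCCTTGCCCATGCCCGCGGT"
    ),
    target = c("Promoter", "Promoter", "Exon 6", "Exon 6", "Exon 3", "None"),
    editing = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Published polypurine core arms
#'
#' The three hairpin arms (5' arm of each core) targeting the promoter,
#' exon 3 and exon 6 polypurine tracks. These are also the default arms the
#' synthetic minigene generator embeds.
#'
#' @return Named character vector (`Pr`, `E3`, `E6`).
#' @export
published_core_arms <- function() {
  c(Pr = "GGGGAAGGAAAAGTGGGTGACA",
    E3 = "GGACCAAGAGGTAAGGA",
    E6 = "AGGAGGAAAAAGGCATCAAG")
}

#' Published DHFR minigene primer pairs
#'
#' The four primer pairs: exon 1/exon 3 for genomic genotyping and for
#' RT-PCR of inclusion vs skip species (166 vs 116 bp), an intron-1 pair,
#' and an intron-1/intron-2 pair for unprocessed-species detection.
#'
#' @return data.frame with columns `name`, `forward`, `reverse`.
#' @export
published_primer_pairs <- function() {
  data.frame(
    name = c("exon1_exon3_genomic", "exon1_exon3_rt", "intron1",
             "intron1_intron2"),
    forward = c("AAGAACGGAGACCTTCCCTGGCCA", "AAGAACGGAGACCTTCCCTGGCCA",
                "CCGAGGCGGTTCGCTGAATC", "CCGAGGCGGTTCGCTGAATC"),
    reverse = c("GAACCAGGTTTTCCGGCCCA", "GAACCAGGTTTTCCGGCCCA",
                "CCTGTCACGTGTGCTCAGGC", "TCCCACGGGAGACTTCGCACT"),
    stringsAsFactors = FALSE
  )
}

#' The published junction homology blocks
#'
#' The 20-nt windows immediately upstream and downstream of the PstI site in
#' the wildtype minigene; the downstream window begins with `CTGCAG`.
#'
#' @return Named character vector (`up`, `down`).
#' @export
published_junction_blocks <- function() {
  c(up = "ACCGCGGGCATGGGCAAGGG",
    down = "CTGCAGCCGGCGGGCCTACC")
}
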