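#' Physicochemical constants for single-stranded DNA oligos
#'
#' Anhydrous linear ssDNA free-acid convention (a common vendor convention):
#' per-monomer masses in Da with a single terminal correction subtracted once
#' per strand.
#'
#' @param monomer_mass Named numeric, Da per incorporated nucleotide.
#' @param terminal_correction Da subtracted once (default 61.96).
#' @return An object of class `physchem_constants`.
#' @export
physchem_constants <- function(monomer_mass = c(A = 313.21, T = 304.2,
                                                C = 289.18, G = 329.21),
                               terminal_correction = 61.96) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(monomer_mass)),
            all(monomer_mass > 0), terminal_correction >= 0)
  structure(
    list(monomer_mass = monomer_mass,
         terminal_correction = terminal_correction),
    class = "physchem_constants"
  )
}

#' Molecular weight of a single-stranded DNA oligo
#'
#' Sum of monomer masses minus the terminal correction (linear,
#' single-stranded, anhydrous free acid).
#'
#' @param seq DNA string over `{A,C,G,T}` (degenerate bases are an error).
#' @param constants A [physchem_constants()].
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(seq, constants = physchem_constants()) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("molecular_weight: sequence must be concrete {A,C,G,T}", call. = FALSE)
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sum(constants$monomer_mass[v]) - constants$terminal_correction
}

#' Convert an oligo dose to molar concentration
#'
#' `nM = mass_ug / mw / volume_ml * 1e6`. Values are exact; round only at
#' display (3 ug of a 25,652 Da oligo in 1.0 mL gives 116.95, printed
#' 117 nM).
#'
#' @param mass_ug Oligo mass in micrograms (> 0).
#' @param mw Molecular weight in Da (> 0).
#' @param volume_ml Final volume in mL (> 0).
#' @return Concentration in nM.
#' @export
molarity <- function(mass_ug, mw, volume_ml) {
  stopifnot(is.numeric(mass_ug), is.numeric(mw), is.numeric(volume_ml))
  if (any(c(mass_ug, mw, volume_ml) <= 0)) {
    stop("molarity: all inputs must be positive", call. = FALSE)
  }
  mass_ug / mw / volume_ml * 1e6
}

#' GC fraction of a sequence
#'
#' @param seq Non-empty DNA string.
#' @return `(#G + #C) / length`, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("gc_content: empty sequence", call. = FALSE)
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  sum(v %in% c("G", "C")) / length(v)
}

#' Melting temperature of an oligo (quick closed forms)
#'
#' Wallace rule `2(A+T) + 4(G+C)` below 14 nt, otherwise
#' `64.9 + 41 * (#G + #C - 16.4) / length`. A QC aid only; no salt or
#' nearest-neighbour correction.
#'
#' @param seq Non-empty DNA string.
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  gc <- sum(v %in% c("G", "C"))
  at <- sum(v %in% c("A", "T"))
  if (length(v) < 14L) {
    2 * at + 4 * gc
  } else {
    64.9 + 41 * (gc - 16.4) / length(v)
  }
}

tm_method <- function(seq) {
  if (nchar(seq) < 14L) "wallace" else "gc_fraction_64.9"
}

#' Physicochemical summary of an oligo
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param constants A [physchem_constants()].
#' @return One-row data.frame: `seq`, `length`, `gc_fraction`, `mw`, `tm`,
#'   `method_tags`.
#' @export
oligo_report <- function(seq, constants = physchem_constants()) {
  data.frame(
    seq = seq,
    length = nchar(seq),
    gc_fraction = gc_content(seq),
    mw = molecular_weight(seq, constants),
    tm = melting_temperature(seq),
    method_tags = paste0("mw:anhydrous_ssDNA;tm:", tm_method(seq)),
    stringsAsFactors = FALSE
  )
}
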