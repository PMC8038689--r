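# Seeded synthetic minigene generator: a wildtype-like multi-exon minigene
# with a unique PstI site in intron 1, an exon-duplication derivative
# (cassette of intron flanks around a duplicate exon copy inserted at that
# site), and the edited reversion. Emulates the cell-model construct at
# reduced scale so the whole design pipeline is testable offline.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_occurrences <- function(seq, pattern) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(seq))
}

#' Specification of the synthetic minigene
#'
#' Defaults give a ~1.9-kb wildtype-like minigene: a 250-nt promoter-like
#' region, six exons, a 300-nt intron 1 carrying the unique `CTGCAG`
#' junction flanked by the published 20-nt homology blocks, the three
#' published polypurine arms embedded in the promoter, exon 3 and exon 6,
#' and the published exon-1/exon-3 primers planted with geometry that makes
#' the RT-PCR inclusion/skip products 166 and 116 bp. The duplication
#' cassette is 100-nt intron flanks around a duplicate copy of exon 2
#' (250 nt in total), inserted with one regenerated motif copy upstream.
#'
#' @param seed Integer seed; the generator is deterministic per seed.
#' @param n_exons Number of exons (default 6).
#' @param exon_lengths,intron_lengths Segment lengths in nt.
#' @param promoter_length Promoter-like region length in nt.
#' @param junction_intron Index of the intron carrying the junction.
#' @param embed_arms data.frame(`region`, `seq`, `offset`): arms to plant,
#'   each at `offset` within its region (`Pr` or an exon label).
#' @param cassette_flank5,cassette_flank3 Cassette intron-flank lengths.
#' @param duplicated_exon Label of the exon the cassette duplicates.
#' @param regenerate_sites `"upstream"` (default: one motif copy regenerated
#'   at the cassette's upstream edge), `"none"`, or `"both"`.
#' @param junction_offset Offset of the 40-nt junction block within the
#'   junction intron.
#' @return An object of class `minigene_spec`.
#' @export
minigene_spec <- function(seed = 42L,
                          n_exons = 6L,
                          exon_lengths = c(60L, 50L, 70L, 50L, 50L, 40L),
                          intron_lengths = c(300L, 250L, 250L, 250L, 250L),
                          promoter_length = 250L,
                          junction_intron = 1L,
                          embed_arms = NULL,
                          cassette_flank5 = 100L,
                          cassette_flank3 = 100L,
                          duplicated_exon = "E2",
                          regenerate_sites = c("upstream", "none", "both"),
                          junction_offset = 130L) {
  regenerate_sites <- match.arg(regenerate_sites)
  if (is.null(embed_arms)) {
    arms <- published_core_arms()
    embed_arms <- data.frame(
      region = c("Pr", "E3", "E6"),
      seq = unname(arms[c("Pr", "E3", "E6")]),
      offset = c(100L, 40L, 10L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(length(exon_lengths) == n_exons,
            length(intron_lengths) == n_exons - 1L,
            all(exon_lengths > 0), all(intron_lengths >= 4),
            junction_intron >= 1L, junction_intron <= n_exons - 1L)
  total <- promoter_length + sum(exon_lengths) + sum(intron_lengths)
  if (total >= 50000L) stop("minigene longer than the 50-kb guard", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_exons = as.integer(n_exons),
         exon_lengths = as.integer(exon_lengths),
         intron_lengths = as.integer(intron_lengths),
         promoter_length = as.integer(promoter_length),
         junction_intron = as.integer(junction_intron),
         embed_arms = embed_arms,
         cassette_flank5 = as.integer(cassette_flank5),
         cassette_flank3 = as.integer(cassette_flank3),
         duplicated_exon = duplicated_exon,
         regenerate_sites = regenerate_sites,
         junction_offset = as.integer(junction_offset)),
    class = "minigene_spec"
  )
}

# Segment coordinates (0-based half-open) for a spec: promoter, exons,
# introns.
minigene_layout <- function(spec) {
  pos <- spec$promoter_length
  exons <- data.frame(label = character(0), start = integer(0), end = integer(0))
  introns <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(spec$n_exons)) {
    exons <- rbind(exons, data.frame(
      label = paste0("E", i), start = pos, end = pos + spec$exon_lengths[i]
    ))
    pos <- pos + spec$exon_lengths[i]
    if (i < spec$n_exons) {
      introns <- rbind(introns, data.frame(start = pos,
                                           end = pos + spec$intron_lengths[i]))
      pos <- pos + spec$intron_lengths[i]
    }
  }
  list(exons = exons, introns = introns, total = pos)
}

#' Generate the synthetic restored (wildtype-like) minigene
#'
#' Background bases are drawn uniformly, then patched with splice sites
#' (every intron begins `GT` and ends `AG`), the 40-nt junction block (the
#' published upstream+downstream homology windows, containing the single
#' `CTGCAG`), the embedded polypurine arms and the published primer
#' footprints. Backgrounds violating any uniqueness invariant (motif exactly
#' once, each arm/homology block/primer footprint exactly once, also on the
#' derived mutant) are resampled, up to 1000 times. Deterministic per seed.
#'
#' @param spec A [minigene_spec()].
#' @return An object of class `minigene`: list with `record` (`seq_record`),
#'   `gene` ([gene_model()]), `junction` ([edit_junction()]), `cassette`
#'   (list `seq`, `flank5_len`, `exon_label`, `exon_len`, `flank3_len`) and
#'   `spec`.
#' @export
make_minigene <- function(spec = minigene_spec()) {
  stopifnot(inherits(spec, "minigene_spec"))
  lay <- minigene_layout(spec)
  blocks <- published_junction_blocks()
  jblock <- paste0(blocks[["up"]], blocks[["down"]])
  motif <- "CTGCAG"
  jint <- lay$introns[spec$junction_intron, ]
  if (jint$end - jint$start < spec$junction_offset + nchar(jblock)) {
    stop("junction intron too short for the junction block", call. = FALSE)
  }
  coord <- jint$start + spec$junction_offset + nchar(blocks[["up"]])
  primers <- published_primer_pairs()
  fwd <- primers$forward[1L]
  rcrev <- reverse_complement(primers$reverse[1L])
  ex <- lay$exons
  dup_row <- match(spec$duplicated_exon, ex$label)
  if (is.na(dup_row)) stop("duplicated_exon not in the model", call. = FALSE)

  patch <- function(chars, at0, s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars[(at0 + 1L):(at0 + length(v))] <- v
    chars
  }
  region_start <- function(region) {
    if (region == "Pr") return(0L)
    i <- match(region, ex$label)
    if (is.na(i)) stop(sprintf("embed region '%s' not in model", region),
                       call. = FALSE)
    ex$start[i]
  }

  result <- with_seed(spec$seed, {
    res <- NULL
    for (attempt in seq_len(1000L)) {
      chars <- strsplit(random_dna(lay$total), "", fixed = TRUE)[[1L]]
      for (k in seq_len(nrow(lay$introns))) {
        chars <- patch(chars, lay$introns$start[k], "GT")
        chars <- patch(chars, lay$introns$end[k] - 2L, "AG")
      }
      chars <- patch(chars, jint$start + spec$junction_offset, jblock)
      for (r in seq_len(nrow(spec$embed_arms))) {
        chars <- patch(chars,
                       region_start(spec$embed_arms$region[r]) +
                         spec$embed_arms$offset[r],
                       spec$embed_arms$seq[r])
      }
      chars <- patch(chars, ex$start[1L] + 24L, fwd)
      chars <- patch(chars, ex$start[3L] + 10L, rcrev)
      seq <- paste(chars, collapse = "")

      flank5 <- paste0(random_dna(spec$cassette_flank5 - 2L), "AG")
      flank3 <- paste0("GT", random_dna(spec$cassette_flank3 - 2L))
      exon_copy <- substr(seq, ex$start[dup_row] + 1L, ex$end[dup_row])
      cassette_seq <- paste0(flank5, exon_copy, flank3)
      ins <- switch(spec$regenerate_sites,
                    none = cassette_seq,
                    upstream = paste0(motif, cassette_seq),
                    both = paste0(motif, cassette_seq, motif))
      mutant_seq <- paste0(substr(seq, 1L, coord), ins,
                           substr(seq, coord + 1L, nchar(seq)))

      uniq <- c(blocks, spec$embed_arms$seq, fwd, rcrev)
      ok <- count_occurrences(seq, motif) == 1L &&
        all(vapply(uniq, function(p) count_occurrences(seq, p) == 1L,
                   logical(1))) &&
        count_occurrences(mutant_seq, motif) ==
          switch(spec$regenerate_sites, none = 1L, upstream = 2L, both = 3L) &&
        all(vapply(uniq, function(p) count_occurrences(mutant_seq, p) == 1L,
                   logical(1)))
      if (ok) {
        res <- list(seq = seq, cassette_seq = cassette_seq)
        break
      }
    }
    if (is.null(res)) {
      stop("could not satisfy minigene uniqueness invariants in 1000 resamples",
           call. = FALSE)
    }
    res
  })

  record <- seq_record("mg1", result$seq, "synthetic restored minigene")
  gene <- gene_model("mg1", ex, strand = "+",
                     promoter_region = c(0L, spec$promoter_length))
  junction <- edit_junction("mg1", coord, motif, "site_starts_at_junction")
  validate_junction(junction, record)
  structure(
    list(record = record, gene = gene, junction = junction,
         cassette = list(seq = result$cassette_seq,
                         flank5_len = spec$cassette_flank5,
                         exon_label = spec$duplicated_exon,
                         exon_len = spec$exon_lengths[dup_row],
                         flank3_len = spec$cassette_flank3),
         spec = spec),
    class = "minigene"
  )
}

#' Insert a duplication cassette at the edit junction
#'
#' Emulates the cloning that produced the exon-duplication construct: the
#' cassette is inserted at the junction coordinate; with
#' `regenerate_sites = "upstream"` one copy of the recognition motif is
#' regenerated at the cassette's upstream edge (with `"both"`, at both
#' edges). After insertion the two homology windows are no longer adjacent.
#'
#' @param restored Restored reference `seq_record`.
#' @param junction [edit_junction()] on `restored`.
#' @param cassette Cassette DNA string (non-empty).
#' @param regenerate_sites `"upstream"`, `"none"` or `"both"`.
#' @return The mutant `seq_record` (id suffixed `_dup`).
#' @export
apply_duplication <- function(restored, junction, cassette,
                              regenerate_sites = c("upstream", "none", "both")) {
  regenerate_sites <- match.arg(regenerate_sites)
  restored <- as_seq_record(restored)
  stopifnot(is.character(cassette), length(cassette) == 1L, nzchar(cassette))
  validate_junction(junction, restored)
  coord <- junction$coord
  ins <- switch(regenerate_sites,
                none = cassette,
                upstream = paste0(junction$motif, cassette),
                both = paste0(junction$motif, cassette, junction$motif))
  seq2 <- paste0(substr(restored$seq, 1L, coord), ins,
                 substr(restored$seq, coord + 1L, nchar(restored$seq)))
  seq_record(paste0(restored$id, "_dup"), seq2,
             "synthetic exon-duplication derivative")
}

# Gene model of the duplication derivative: exons downstream of the junction
# shift by the inserted length and the duplicated exon copy is inserted
# between, labelled <label>a, the original relabelled <label>b.
duplicated_gene_model <- function(gene, junction, cassette,
                                  regenerate_sites = "upstream",
                                  motif_len = nchar(junction$motif)) {
  pre <- switch(regenerate_sites, none = 0L, upstream = motif_len,
                both = motif_len)
  post <- if (regenerate_sites == "both") motif_len else 0L
  ins_len <- nchar(cassette$seq) + pre + post
  coord <- junction$coord
  ex <- gene$exons
  if (any(ex$start < coord & ex$end > coord)) {
    stop("junction lies inside an exon; cannot build duplication model",
         call. = FALSE)
  }
  copy_start <- coord + pre + cassette$flank5_len
  copy <- data.frame(label = paste0(cassette$exon_label, "a"),
                     start = copy_start, end = copy_start + cassette$exon_len)
  shifted <- ex
  down <- shifted$start >= coord
  shifted$start[down] <- shifted$start[down] + ins_len
  shifted$end[down] <- shifted$end[down] + ins_len
  shifted$label[shifted$label == cassette$exon_label] <-
    paste0(cassette$exon_label, "b")
  all_ex <- rbind(shifted, copy)
  all_ex <- all_ex[order(all_ex$start), , drop = FALSE]
  gene_model(paste0(gene$record_id, "_dup"), all_ex, strand = gene$strand,
             promoter_region = gene$promoter_region)
}

#' Build the mutant (exon-duplication) derivative of a synthetic minigene
#'
#' Convenience wrapper: applies the cassette duplication and derives the
#' matching gene model with the duplicated exon labelled `E2a` (cassette
#' copy) and `E2b` (original copy).
#'
#' @param mg A [make_minigene()] result.
#' @return list with `record` (mutant `seq_record`) and `gene`
#'   ([gene_model()]).
#' @export
make_mutant <- function(mg) {
  stopifnot(inherits(mg, "minigene"))
  record <- apply_duplication(mg$record, mg$junction, mg$cassette$seq,
                              mg$spec$regenerate_sites)
  gene <- duplicated_gene_model(mg$gene, mg$junction, mg$cassette,
                                mg$spec$regenerate_sites)
  validate_gene_model(gene, record)
  list(record = record, gene = gene)
}

#' Emulate the homology-templated edit
#'
#' Sequence-level emulation of the recombination outcome templated by a UD
#' homology tail: locate the unique `w`-nt upstream and downstream junction
#' windows (taken from the restored reference) in the mutant and splice out
#' everything between them, making them adjacent. Idempotent on an
#' already-restored sequence.
#'
#' @param mutant Mutant `seq_record`.
#' @param restored Restored reference `seq_record`.
#' @param junction [edit_junction()] on `restored`.
#' @param w Homology window width (default 20).
#' @return The edited `seq_record` (id suffixed `_edited`).
#' @export
apply_edit <- function(mutant, restored, junction, w = 20L) {
  mutant <- as_seq_record(mutant, id = "mutant")
  restored <- as_seq_record(restored, id = "restored")
  validate_junction(junction, restored)
  coord <- junction$coord
  w <- as.integer(w)
  if (coord < w || coord + w > nchar(restored$seq)) {
    stop("junction too close to a reference end for the homology windows",
         call. = FALSE)
  }
  U <- substr(restored$seq, coord - w + 1L, coord)
  D <- substr(restored$seq, coord + 1L, coord + w)
  subject <- Biostrings::DNAString(mutant$seq)
  um <- Biostrings::matchPattern(U, subject)
  dm <- Biostrings::matchPattern(D, subject)
  if (length(um) != 1L || length(dm) != 1L) {
    stop(sprintf(
      "homology blocks not unique in mutant: upstream found %d times, downstream %d times",
      length(um), length(dm)
    ), call. = FALSE)
  }
  u_end <- Biostrings::end(um)[1L]
  d_start <- Biostrings::start(dm)[1L]
  if (d_start <= u_end) {
    stop("downstream homology block precedes upstream block", call. = FALSE)
  }
  seq2 <- paste0(substr(mutant$seq, 1L, u_end),
                 substr(mutant$seq, d_start, nchar(mutant$seq)))
  seq_record(paste0(mutant$id, "_edited"), seq2, "edited reversion")
}

#' Write the synthetic fixture file set
#'
#' Emits, deterministically per seed: `restored.fa`, `mutant.fa`,
#' `genes.gff3` (restored and mutant models), `junction.yaml`
#' (`record`/`coord`/`motif`), `table1_oligos.tsv` (the six published
#' oligos) and `primers.tsv` (the four published primer pairs).
#'
#' @param dir Output directory (created if needed).
#' @param spec A [minigene_spec()].
#' @return Named character vector of the six file paths, invisibly.
#' @export
emit_fixtures <- function(dir, spec = minigene_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mg <- make_minigene(spec)
  mut <- make_mutant(mg)
  paths <- c(
    restored = file.path(dir, "restored.fa"),
    mutant = file.path(dir, "mutant.fa"),
    genes = file.path(dir, "genes.gff3"),
    junction = file.path(dir, "junction.yaml"),
    oligos = file.path(dir, "table1_oligos.tsv"),
    primers = file.path(dir, "primers.tsv")
  )
  write_fasta(mg$record, paths[["restored"]])
  write_fasta(mut$record, paths[["mutant"]])
  write_gene_model(list(mg$gene, mut$gene), paths[["genes"]])
  yaml::write_yaml(
    list(record = mg$junction$record_id, coord = mg$junction$coord,
         motif = mg$junction$motif),
    paths[["junction"]]
  )
  write.table(published_pprh_oligos(), paths[["oligos"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(published_primer_pairs(), paths[["primers"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
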