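#' Create a gene model
#'
#' Exon/intron structure of a record. Coordinates are 0-based half-open
#' internally (the package-wide convention); human-facing reports print
#' 1-based inclusive.
#'
#' @param record_id Identifier of the sequence the model annotates.
#' @param exons data.frame with columns `label`, `start`, `end` (0-based
#'   half-open), sorted by `start`, pairwise non-overlapping. Every intron
#'   (gap between consecutive exons) must be at least 4 nt (room for GT..AG).
#' @param strand `"+"` or `"-"`.
#' @param promoter_region Optional length-2 numeric `c(start, end)` (0-based
#'   half-open).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(record_id, exons, strand = "+", promoter_region = NULL) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  stopifnot(is.data.frame(exons), all(c("label", "start", "end") %in% names(exons)))
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[, c("label", "start", "end")]
  exons$label <- as.character(exons$label)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
    stop("exon intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (is.unsorted(exons$start, strictly = TRUE)) {
    stop("exons must be sorted by start", call. = FALSE)
  }
  if (nrow(exons) > 1L) {
    gaps <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(gaps < 0L)) stop("overlapping exons in gene model", call. = FALSE)
    if (any(gaps < 4L)) {
      stop("intron shorter than 4 nt between consecutive exons", call. = FALSE)
    }
  }
  if (!is.null(promoter_region)) {
    stopifnot(length(promoter_region) == 2L, promoter_region[1] < promoter_region[2])
    promoter_region <- as.integer(promoter_region)
  }
  structure(
    list(record_id = record_id, strand = strand, exons = exons,
         promoter_region = promoter_region),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand), %d exons\n",
              x$record_id, x$strand, nrow(x$exons)))
  # reports are 1-based inclusive
  ex <- x$exons
  cat(paste0(sprintf("  %s: %d-%d", ex$label, ex$start + 1L, ex$end),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Check a gene model against its sequence record
#'
#' Exon bounds are checked lazily, at first use against a concrete record.
#'
#' @param gene A `gene_model`.
#' @param record A `seq_record`.
#' @return `gene`, invisibly; errors if any exon lies outside the record.
#' @export
validate_gene_model <- function(gene, record) {
  stopifnot(inherits(gene, "gene_model"), inherits(record, "seq_record"))
  n <- nchar(record$seq)
  if (any(gene$exons$end > n)) {
    stop(sprintf("exon outside record bounds (record '%s' has %d nt)",
                 record$id, n), call. = FALSE)
  }
  invisible(gene)
}

#' Read a gene model from GFF3 or BED
#'
#' GFF3 exon features (1-based inclusive) and BED intervals (0-based
#' half-open) are both converted to the internal 0-based half-open
#' convention. A GFF3 `promoter` feature, when present, populates
#' `promoter_region`.
#'
#' @param path Path to the annotation file.
#' @param fmt `"gff3"` or `"bed"`.
#' @param record_id Restrict to features on this sequence (default: the first
#'   seqname in the file).
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path, fmt = c("gff3", "bed"), record_id = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = if (fmt == "gff3") "gff3" else "bed")
  if (length(gr) == 0L) stop("no features in annotation file", call. = FALSE)
  if (is.null(record_id)) record_id <- as.character(GenomicRanges::seqnames(gr)[1L])
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == record_id]
  md <- S4Vectors::mcols(gr)
  promoter <- NULL
  if (fmt == "gff3") {
    is_prom <- !is.null(md$type) & as.character(md$type) == "promoter"
    if (any(is_prom)) {
      pg <- gr[is_prom][1L]
      promoter <- c(GenomicRanges::start(pg) - 1L, GenomicRanges::end(pg))
    }
    gr <- gr[as.character(md$type) == "exon"]
    md <- S4Vectors::mcols(gr)
    labels <- if (!is.null(md$Name) && !all(is.na(md$Name))) {
      as.character(md$Name)
    } else if (!is.null(md$ID)) as.character(md$ID) else
      paste0("exon", seq_along(gr))
  } else {
    labels <- if (!is.null(md$name)) as.character(md$name) else
      paste0("exon", seq_along(gr))
  }
  if (length(gr) == 0L) stop("no exon features for record", call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr)[1L])
  if (strand == "*") strand <- "+"
  # GRanges is 1-based inclusive regardless of source format (rtracklayer
  # shifts BED on import), so the conversion below covers both.
  ex <- data.frame(
    label = labels,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$start), , drop = FALSE]
  gene_model(record_id, ex, strand = strand, promoter_region = promoter)
}

#' Write a gene model as GFF3
#'
#' Inverse of [read_gene_model()]: exon features (plus a `promoter` feature
#' when present) in 1-based inclusive GFF3 coordinates. The GFF3 -> internal
#' -> GFF3 round trip is the identity on `(label, start, end)`.
#'
#' @param gene A `gene_model` (or list of them, written to one file).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_model <- function(gene, path) {
  genes <- if (inherits(gene, "gene_model")) list(gene) else gene
  rows <- do.call(rbind, lapply(genes, function(g) {
    ex <- g$exons
    df <- data.frame(
      seqnames = g$record_id, start = ex$start + 1L, end = ex$end,
      strand = g$strand, type = "exon",
      ID = paste0(g$record_id, ":", ex$label), Name = ex$label,
      stringsAsFactors = FALSE
    )
    if (!is.null(g$promoter_region)) {
      df <- rbind(df, data.frame(
        seqnames = g$record_id, start = g$promoter_region[1] + 1L,
        end = g$promoter_region[2], strand = g$strand, type = "promoter",
        ID = paste0(g$record_id, ":promoter"), Name = "promoter",
        stringsAsFactors = FALSE
      ))
    }
    df
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$source <- "pprhtools"
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Name <- rows$Name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Define an edit junction
#'
#' The point between two bases where an insertion was made (and where, after
#' editing, the upstream and downstream homology windows become adjacent).
#' Under the default policy the recognition motif starts exactly at the
#' junction, i.e. `record[coord : coord + nchar(motif))` matches the motif;
#' this is the convention under which the printed upstream 20-mer excludes
#' the site and the downstream 20-mer begins with it.
#'
#' @param record_id Identifier of the (restored) reference record.
#' @param coord 0-based junction coordinate (a position between bases).
#' @param motif IUPAC recognition motif (default `"CTGCAG"`, PstI).
#' @param motif_policy One of `"site_starts_at_junction"`,
#'   `"site_ends_at_junction"`, `"none"`.
#' @return An object of class `edit_junction`.
#' @export
edit_junction <- function(record_id, coord, motif = "CTGCAG",
                          motif_policy = c("site_starts_at_junction",
                                           "site_ends_at_junction", "none")) {
  motif_policy <- match.arg(motif_policy)
  stopifnot(is.numeric(coord), length(coord) == 1L, coord >= 0)
  structure(
    list(record_id = record_id, coord = as.integer(coord),
         motif = toupper(motif), motif_policy = motif_policy),
    class = "edit_junction"
  )
}

#' Check an edit junction against a record
#'
#' @param junction An `edit_junction`.
#' @param record A `seq_record`.
#' @return `junction`, invisibly; errors if the coordinate is out of range or
#'   the motif policy is violated.
#' @export
validate_junction <- function(junction, record) {
  stopifnot(inherits(junction, "edit_junction"), inherits(record, "seq_record"))
  n <- nchar(record$seq)
  coord <- junction$coord
  if (coord < 0L || coord > n) {
    stop(sprintf("junction coord %d outside record (0..%d)", coord, n),
         call. = FALSE)
  }
  m <- junction$motif
  k <- nchar(m)
  if (junction$motif_policy == "site_starts_at_junction") {
    window <- substr(record$seq, coord + 1L, coord + k)
    if (nchar(window) < k || !iupac_matches(window, m)) {
      stop(sprintf("motif %s does not start at junction coord %d", m, coord),
           call. = FALSE)
    }
  } else if (junction$motif_policy == "site_ends_at_junction") {
    if (coord < k) stop("junction too close to record start for motif policy",
                        call. = FALSE)
    window <- substr(record$seq, coord - k + 1L, coord)
    if (!iupac_matches(window, m)) {
      stop(sprintf("motif %s does not end at junction coord %d", m, coord),
           call. = FALSE)
    }
  }
  invisible(junction)
}

# Does the concrete sequence `seq` match the same-length IUPAC pattern?
iupac_matches <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  length(Biostrings::matchPattern(
    pattern, Biostrings::DNAString(seq), fixed = FALSE
  )) > 0L
}
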