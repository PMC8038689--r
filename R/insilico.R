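#' Scan a sequence for restriction/recognition sites
#'
#' All matches of an IUPAC motif, reported as 0-based start positions on the
#' + strand. A palindromic motif (e.g. `CTGCAG`) has identical site sets on
#' the two strands and is reported once, on `+`; a non-palindromic motif
#' additionally yields `-` strand rows (positions of the reverse-complement
#' match on the + coordinate system).
#'
#' @param seq DNA string or `seq_record`.
#' @param motif IUPAC motif, length >= 4.
#' @return data.frame with columns `pos` (0-based start, ascending within
#'   strand) and `strand`.
#' @export
find_restriction_sites <- function(seq, motif) {
  if (inherits(seq, "seq_record")) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(motif)) stop("empty motif", call. = FALSE)
  if (nchar(motif) < 4L) stop("motif must be at least 4 nt", call. = FALSE)
  motif <- toupper(motif)
  subject <- Biostrings::DNAString(seq)
  hit0 <- function(pattern) {
    if (nchar(pattern) > nchar(seq)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(pattern, subject, fixed = FALSE)) - 1L
  }
  plus <- hit0(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (rc == motif) {
    return(data.frame(pos = plus, strand = rep("+", length(plus)),
                      stringsAsFactors = FALSE))
  }
  minus <- hit0(rc)
  data.frame(
    pos = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    stringsAsFactors = FALSE
  )
}

# 0-based starts of primer binding sites. `rc_site = TRUE` looks for the
# reverse primer's footprint (reverse complement on the template). With
# mismatches allowed, the 3'-terminal 3 nt must still match exactly.
primer_sites <- function(template_seq, primer, max_mismatch, rc_site = FALSE) {
  pat <- if (rc_site) reverse_complement(primer) else primer
  if (nchar(pat) > nchar(template_seq)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(template_seq),
                                max.mismatch = max_mismatch)
  starts <- Biostrings::start(m)
  if (max_mismatch > 0L && length(starts)) {
    k <- nchar(pat)
    ok <- vapply(starts, function(s) {
      hit <- substr(template_seq, s, s + k - 1L)
      if (rc_site) {
        substr(hit, 1L, 3L) == substr(pat, 1L, 3L) # rev primer 3' end
      } else {
        substr(hit, k - 2L, k) == substr(pat, k - 2L, k)
      }
    }, logical(1))
    starts <- starts[ok]
  }
  starts - 1L
}

#' Virtual PCR
#'
#' Predicts amplicons from one primer pair on a single template. A product is
#' emitted for every pairing of a forward site with a reverse site whose
#' 3'-end lies strictly right of the forward 5'-end, up to `max_len`. Product
#' length follows the standard convention: forward 5'-end through reverse
#' 5'-end on the bottom strand (both primer footprints included). With
#' `max_mismatch > 0` the 3'-terminal 3 nt of each primer must match exactly.
#'
#' @param template `seq_record` (or DNA string) template.
#' @param fwd,rev Primer sequences, >= 15 nt, concrete bases only.
#' @param max_len Maximum product length (default 5000).
#' @param max_mismatch 0, 1 or 2 mismatches per primer (default 0).
#' @return data.frame of amplicons sorted by length: `template_id`, `fwd`,
#'   `rev`, `start`, `end` (0-based half-open), `length`, `product_seq`.
#' @export
virtual_pcr <- function(template, fwd, rev, max_len = 5000L, max_mismatch = 0L) {
  template <- as_seq_record(template, id = "template")
  fwd <- toupper(fwd)
  rev <- toupper(rev)
  for (p in c(fwd, rev)) {
    if (grepl("[^ACGT]", p)) {
      stop("degenerate or non-ACGT base in primer", call. = FALSE)
    }
    if (nchar(p) < 15L) stop("primers must be >= 15 nt", call. = FALSE)
  }
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2", call. = FALSE)
  f_sites <- primer_sites(template$seq, fwd, max_mismatch, rc_site = FALSE)
  r_sites <- primer_sites(template$seq, rev, max_mismatch, rc_site = TRUE)
  out <- list()
  for (f in f_sites) {
    for (r in r_sites) {
      if (f >= r) next # fwd 5'-end must lie strictly left of rev 3'-end
      end <- r + nchar(rev)
      len <- end - f
      if (len > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        template_id = template$id, fwd = fwd, rev = rev,
        start = f, end = end, length = len,
        product_seq = substr(template$seq, f + 1L, end),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(template_id = character(0), fwd = character(0),
                      rev = character(0), start = integer(0), end = integer(0),
                      length = integer(0), product_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$length, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

intron_seq <- function(record, gene, k) {
  ex <- gene$exons
  if (k < 1L || k > nrow(ex) - 1L) {
    stop(sprintf("unknown intron index %d", k), call. = FALSE)
  }
  substr(record$seq, ex$end[k] + 1L, ex$start[k + 1L])
}

parse_event <- function(ev, gene) {
  if (grepl("^skip:", ev)) {
    label <- sub("^skip:", "", ev)
    if (!label %in% gene$exons$label) {
      stop(sprintf("unknown exon label '%s'", label), call. = FALSE)
    }
    list(type = "skip", label = label)
  } else if (grepl("^retain:", ev)) {
    k <- as.integer(sub("^retain:", "", ev))
    if (is.na(k) || k < 1L || k > nrow(gene$exons) - 1L) {
      stop(sprintf("unknown intron index in event '%s'", ev), call. = FALSE)
    }
    list(type = "retain", k = k)
  } else {
    stop(sprintf("unknown event '%s' (use 'skip:<label>' or 'retain:<k>')", ev),
         call. = FALSE)
  }
}

#' Enumerate spliced isoforms of a gene model
#'
#' Emits the canonical isoform (all exons spliced, no introns) plus one
#' isoform per requested event. Each event is a character vector of
#' `"skip:<exon label>"` and/or `"retain:<intron index>"` terms applied
#' jointly, so combinations are generated only when requested explicitly.
#' Duplicate-exon models (e.g. `E2a`/`E2b`) support skipping either copy.
#'
#' @param record `seq_record` carrying the gene.
#' @param gene [gene_model()] on `record`.
#' @param events list of character vectors, e.g.
#'   `list("skip:E2b", "retain:1", c("skip:E2b", "retain:1"))`.
#' @return list of isoforms; each is a list with `label`, `exon_labels` and
#'   `seq` (the concatenation of its exon sequences, plus retained-intron
#'   sequence where requested).
#' @export
enumerate_isoforms <- function(record, gene, events = list()) {
  record <- as_seq_record(record)
  validate_gene_model(gene, record)
  ex <- gene$exons
  build <- function(evs, label) {
    parsed <- lapply(evs, parse_event, gene = gene)
    skipped <- vapply(
      parsed[vapply(parsed, function(p) p$type == "skip", logical(1))],
      function(p) p$label, character(1)
    )
    retained <- vapply(
      parsed[vapply(parsed, function(p) p$type == "retain", logical(1))],
      function(p) p$k, integer(1)
    )
    parts <- character(0)
    kept <- character(0)
    for (i in seq_len(nrow(ex))) {
      if (!ex$label[i] %in% skipped) {
        parts <- c(parts, substr(record$seq, ex$start[i] + 1L, ex$end[i]))
        kept <- c(kept, ex$label[i])
      }
      if (i %in% retained) {
        parts <- c(parts, intron_seq(record, gene, i))
        kept <- c(kept, paste0("I", i))
      }
    }
    list(label = label, exon_labels = kept, seq = paste(parts, collapse = ""))
  }
  out <- list(build(character(0), "canonical"))
  for (evs in events) {
    out[[length(out) + 1L]] <- build(evs, paste(evs, collapse = "+"))
  }
  out
}

#' RT-PCR band table for a set of isoforms
#'
#' Applies [virtual_pcr()] to each isoform's cDNA and tabulates the product
#' size per isoform (`NA` when a primer site is missing), sorted by length
#' descending — gel order, largest band on top. When an isoform yields
#' several products the shortest (dominant) one is reported.
#'
#' @param isoforms Output of [enumerate_isoforms()].
#' @param fwd,rev Primer pair.
#' @param max_mismatch Passed to [virtual_pcr()].
#' @return data.frame with columns `isoform`, `exons`, `length`.
#' @export
rtpcr_band_table <- function(isoforms, fwd, rev, max_mismatch = 0L) {
  rows <- lapply(isoforms, function(iso) {
    amp <- virtual_pcr(seq_record(iso$label, iso$seq), fwd, rev,
                       max_mismatch = max_mismatch)
    data.frame(
      isoform = iso$label,
      exons = paste(iso$exon_labels, collapse = ","),
      length = if (nrow(amp)) amp$length[1L] else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
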