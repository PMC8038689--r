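#' Build a reverse-Hoogsteen hairpin core
#'
#' The core is `arm + loop + reverse(arm)`: the second arm is the plain
#' character reverse of the first (mirror repeat), never the reverse
#' complement — the structural signature of intramolecular reverse-Hoogsteen
#' pairing. Pyrimidine interruptions in the arm are kept verbatim and
#' mirrored into the second arm.
#'
#' @param track A track row/list with a `seq` field (e.g. one row of
#'   [scan_polypurine_tracks()] output), or a plain arm string.
#' @param loop_len Loop length in nt (all `T`; default 5, minimum 3).
#' @return An object of class `hairpin_core` with fields `arm`, `loop`,
#'   `full_core`.
#' @export
build_core <- function(track, loop_len = 5L) {
  arm <- if (is.character(track)) track else as.character(track$seq)
  stopifnot(length(arm) == 1L, nzchar(arm))
  loop_len <- as.integer(loop_len)
  if (loop_len < 3L) stop("loop_len < 3: hairpin cannot close", call. = FALSE)
  if (grepl("N", arm, fixed = TRUE)) {
    stop("arm contains N: designs must be concrete", call. = FALSE)
  }
  if (grepl("[^ACGT]", arm)) stop("arm must be over {A,C,G,T}", call. = FALSE)
  loop <- strrep("T", loop_len)
  structure(
    list(arm = arm, loop = loop,
         full_core = paste0(arm, loop, str_reverse(arm))),
    class = "hairpin_core"
  )
}

#' @export
print.hairpin_core <- function(x, ...) {
  cat(sprintf("<hairpin_core> arm %d nt | loop %d nt\n  5'-%s-3'\n",
              nchar(x$arm), nchar(x$loop), x$full_core))
  invisible(x)
}

#' Build a homology tail spanning an edit junction
#'
#' Extracts the `w`-nt windows immediately upstream and downstream of the
#' junction on the *restored* (post-edit) reference, where the two windows
#' are contiguous. `up_seq`/`down_seq` always denote the + strand genomic
#' windows; on the `-` strand the tail is their reverse complement (windows
#' reverse-complemented and swapped) so that it reads 5'->3' on the minus
#' strand. Under the default junction policy the downstream window begins
#' with the recognition motif and the upstream window excludes it.
#'
#' @param record The restored reference `seq_record`.
#' @param junction An [edit_junction()] valid on `record`.
#' @param mode `"UD"` (both windows), `"U"` (upstream only) or `"D"`
#'   (downstream only).
#' @param w Window width in nt (default 20).
#' @param tail_strand Strand on which the tail reads 5'->3' (`"+"` or `"-"`).
#' @return An object of class `homology_tail` with fields `up_seq`,
#'   `down_seq` (+ strand windows), `tail_strand`, `mode`, `w` and
#'   `tail_sequence` (length `w`, `w` or `2w`).
#' @export
build_tail <- function(record, junction, mode = c("UD", "U", "D"), w = 20L,
                       tail_strand = c("+", "-")) {
  mode <- match.arg(mode)
  tail_strand <- match.arg(tail_strand)
  record <- as_seq_record(record)
  w <- as.integer(w)
  if (w < 1L) stop("degenerate window: w must be >= 1", call. = FALSE)
  validate_junction(junction, record)
  n <- nchar(record$seq)
  coord <- junction$coord
  if (coord < w || coord + w > n) {
    stop(sprintf("junction at %d closer than w=%d to a record end", coord, w),
         call. = FALSE)
  }
  up <- substr(record$seq, coord - w + 1L, coord)
  down <- substr(record$seq, coord + 1L, coord + w)
  tail_sequence <- if (tail_strand == "+") {
    switch(mode, UD = paste0(up, down), U = up, D = down)
  } else {
    switch(mode,
           UD = reverse_complement(paste0(up, down)),
           U = reverse_complement(up),
           D = reverse_complement(down))
  }
  structure(
    list(up_seq = up, down_seq = down, tail_strand = tail_strand,
         mode = mode, w = w, tail_sequence = tail_sequence),
    class = "homology_tail"
  )
}

#' Assemble a complete editing PPRH
#'
#' `full_seq = tail + linker + arm + loop + reverse(arm)`: the homology tail
#' sits at the 5' end, joined to the hairpin core by a pentathymidine linker
#' (the long-distance design). Without a tail the molecule is a plain
#' silencing PPRH and no linker is added.
#'
#' @param core A [build_core()] result.
#' @param tail A [build_tail()] result, or `NULL` for a plain PPRH.
#' @param linker_len Linker length in nt (all `T`; default 5). Ignored when
#'   `tail` is `NULL`.
#' @param name Optional design name.
#' @return An object of class `editing_pprh` with fields `name`, `tail`,
#'   `linker`, `core`, `full_seq`.
#' @export
assemble_editing_pprh <- function(core, tail = NULL, linker_len = 5L,
                                  name = NULL) {
  stopifnot(inherits(core, "hairpin_core"))
  if (!is.null(tail) && !inherits(tail, "homology_tail")) {
    stop("tail must be a homology_tail or NULL", call. = FALSE)
  }
  linker <- if (is.null(tail)) NULL else strrep("T", as.integer(linker_len))
  full_seq <- if (is.null(tail)) {
    core$full_core
  } else {
    paste0(tail$tail_sequence, linker, core$full_core)
  }
  structure(
    list(name = name, tail = tail, linker = linker, core = core,
         full_seq = full_seq),
    class = "editing_pprh"
  )
}

#' @export
print.editing_pprh <- function(x, ...) {
  cat(sprintf("<editing_pprh>%s %d nt\n  5'-%s-3'\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nchar(x$full_seq), x$full_seq))
  invisible(x)
}

# All start positions (1-based) of exact 5-T windows inside maximal T-runs of
# length >= 5.
five_t_placements <- function(chars) {
  rl <- rle(chars == "T")
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  out <- integer(0)
  for (k in which(rl$values & rl$lengths >= 5L)) {
    out <- c(out, starts[k]:(ends[k] - 4L))
  }
  out
}

#' Decompose an oligo against the editing-PPRH grammar
#'
#' Enumerates every placement of one or two exact 5-T windows inside maximal
#' T-runs of length >= 5 (two windows = linker + loop, one window = loop
#' only) and accepts a partition iff the 3' arm is the character reverse of
#' the 5' arm and the arm is at least `min_arm` nt. A tail ending in T fused
#' to the linker forms a 6-T run; the mirror constraint disambiguates the
#' split. When several partitions pass, the longest arm wins, then the
#' longest tail, then the leftmost linker.
#'
#' @param seq Oligo sequence over `{A,C,G,T}`.
#' @param min_arm Minimum arm length accepted (default 10; below this,
#'   spurious mirror partitions become common in random sequence).
#' @return On success, a list with `ok = TRUE` and components `tail` (`NULL`
#'   for a plain PPRH), `linker` (`NULL` iff no tail), `arm1`, `loop`,
#'   `arm2`. On failure, `ok = FALSE`, a `reason`, and `best_rejected`: the
#'   highest-scoring rejected partition and the constraint it violated.
#' @export
decompose_pprh <- function(seq, min_arm = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}", call. = FALSE)
  min_arm <- as.integer(min_arm)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  placements <- five_t_placements(chars)
  if (!length(placements)) {
    return(list(ok = FALSE, reason = "no 5-T run (no loop candidate)",
                best_rejected = NULL))
  }
  cand <- list()
  add <- function(tail, linker, arm1, loop_pos, arm2, p1) {
    cand[[length(cand) + 1L]] <<- list(
      tail = tail, linker = linker, arm1 = arm1, arm2 = arm2,
      loop_pos = loop_pos, p1 = p1
    )
  }
  # one window: plain PPRH, loop only
  for (p in placements) {
    arm1 <- substr(seq, 1L, p - 1L)
    arm2 <- substr(seq, p + 5L, n)
    if (nzchar(arm1) && nzchar(arm2)) add(NULL, NULL, arm1, p, arm2, p)
  }
  # two windows: tail + linker + arm1 + loop + arm2
  for (p1 in placements) {
    tail <- substr(seq, 1L, p1 - 1L)
    if (!nzchar(tail)) next
    for (p2 in placements[placements >= p1 + 5L + 1L]) {
      arm1 <- substr(seq, p1 + 5L, p2 - 1L)
      arm2 <- substr(seq, p2 + 5L, n)
      if (nzchar(arm1) && nzchar(arm2)) add(tail, "TTTTT", arm1, p2, arm2, p1)
    }
  }
  violated <- function(p) {
    if (nchar(p$arm1) != nchar(p$arm2) || p$arm2 != str_reverse(p$arm1)) {
      "arm2 is not the character reverse of arm1"
    } else if (nchar(p$arm1) < min_arm) {
      sprintf("arm shorter than min_arm = %d", min_arm)
    } else {
      NA_character_
    }
  }
  viol <- vapply(cand, violated, character(1))
  valid <- which(is.na(viol))
  score <- function(p) c(nchar(p$arm1), if (is.null(p$tail)) 0L else nchar(p$tail), -p$p1)
  if (!length(valid)) {
    sc <- vapply(cand, function(p) {
      # favour the partition that came closest: mirror matches beat length
      mirror <- nchar(p$arm1) == nchar(p$arm2) && p$arm2 == str_reverse(p$arm1)
      as.numeric(mirror) * 1e6 + nchar(p$arm1)
    }, numeric(1))
    b <- cand[[which.max(sc)]]
    return(list(
      ok = FALSE, reason = "no valid partition",
      best_rejected = list(tail = b$tail, linker = b$linker, arm1 = b$arm1,
                           loop = "TTTTT", arm2 = b$arm2,
                           violated = viol[[which.max(sc)]])
    ))
  }
  scores <- t(vapply(cand[valid], score, numeric(3)))
  best <- valid[order(-scores[, 1L], -scores[, 2L], -scores[, 3L])[1L]]
  p <- cand[[best]]
  list(ok = TRUE, tail = p$tail, linker = p$linker, arm1 = p$arm1,
       loop = "TTTTT", arm2 = p$arm2)
}

# Does `tail_seq` map exactly onto the restored reference around the
# junction, in any mode/strand, as a contiguous homology tail?
tail_maps_to_reference <- function(tail_seq, reference, junction) {
  lens <- nchar(tail_seq)
  trials <- list(list(mode = "U", w = lens), list(mode = "D", w = lens))
  if (lens %% 2L == 0L) {
    trials <- c(trials, list(list(mode = "UD", w = lens %/% 2L)))
  }
  for (tr in trials) {
    for (strand in c("+", "-")) {
      t <- tryCatch(
        build_tail(reference, junction, tr$mode, tr$w, strand),
        error = function(e) NULL
      )
      if (!is.null(t) && t$tail_sequence == tail_seq) return(TRUE)
    }
  }
  FALSE
}

#' Validate an oligo against the editing-PPRH design grammar
#'
#' Aggregated QC verdict (never an exception): decomposability, mirror arms,
#' loop/linker lengths, arm purity, whether the tail maps contiguously onto
#' the restored reference around the junction, presence of the recognition
#' motif in the tail, and the exact-match off-target count of the arm in the
#' reference (both strands). A non-decomposable oligo that still carries the
#' recognition motif (and, when a reference is supplied, maps across the
#' junction) is flagged `tail_only` — the tail-without-core control grammar.
#'
#' @param seq Oligo sequence.
#' @param config A [scan_config()] (purity gate used for `arm_purity_ok`).
#' @param reference Optional restored reference `seq_record`.
#' @param junction Optional [edit_junction()] on `reference`.
#' @param motif Recognition motif (default `"CTGCAG"`).
#' @param min_arm Passed to [decompose_pprh()].
#' @return One-row data.frame of verdict fields.
#' @export
validate_pprh <- function(seq, config = scan_config(), reference = NULL,
                          junction = NULL, motif = "CTGCAG", min_arm = 10L) {
  d <- decompose_pprh(seq, min_arm = min_arm)
  has_tail <- d$ok && !is.null(d$tail)
  tail_seq <- if (has_tail) d$tail else if (!d$ok) seq else NA_character_
  arm_purity <- if (d$ok) track_stats(d$arm1)$purine_fraction else NA_real_
  motif_in_tail <- if (!is.na(tail_seq)) grepl(motif, tail_seq, fixed = TRUE) else FALSE
  tail_maps <- NA
  offtargets <- NA_integer_
  if (!is.null(reference)) {
    reference <- as_seq_record(reference)
    if (!is.null(junction) && !is.na(tail_seq)) {
      tail_maps <- tail_maps_to_reference(tail_seq, reference, junction)
    }
    if (d$ok) {
      subject <- Biostrings::DNAString(reference$seq)
      offtargets <- Biostrings::countPattern(d$arm1, subject) +
        Biostrings::countPattern(reverse_complement(d$arm1), subject)
    }
  }
  tail_only <- !d$ok && motif_in_tail &&
    (is.na(tail_maps) || isTRUE(tail_maps))
  data.frame(
    seq = seq,
    length = nchar(seq),
    decomposable = d$ok,
    mirror_ok = d$ok,
    tail_only = tail_only,
    arm_len = if (d$ok) nchar(d$arm1) else NA_integer_,
    arm_purity = arm_purity,
    arm_purity_ok = if (d$ok) arm_purity >= config$min_purity else NA,
    loop_len = if (d$ok) nchar(d$loop) else NA_integer_,
    linker_len = if (has_tail) nchar(d$linker) else NA_integer_,
    tail_len = if (has_tail) nchar(d$tail) else
      if (tail_only) nchar(seq) else NA_integer_,
    motif_in_tail = motif_in_tail,
    tail_maps = tail_maps,
    offtarget_count = offtargets,
    stringsAsFactors = FALSE
  )
}

# Human-readable label of the region containing 0-based position `pos`.
region_label <- function(gene, pos) {
  if (!is.null(gene$promoter_region) &&
      pos >= gene$promoter_region[1] && pos < gene$promoter_region[2]) {
    return("Pr")
  }
  ex <- gene$exons
  hit <- which(pos >= ex$start & pos < ex$end)
  if (length(hit)) return(ex$label[hit[1L]])
  if (nrow(ex) > 1L) {
    for (k in seq_len(nrow(ex) - 1L)) {
      if (pos >= ex$end[k] && pos < ex$start[k + 1L]) return(paste0("I", k))
    }
  }
  "Flank"
}

# Index of the intron containing 0-based position `pos`, or NA.
intron_index <- function(gene, pos) {
  ex <- gene$exons
  if (nrow(ex) < 2L) return(NA_integer_)
  for (k in seq_len(nrow(ex) - 1L)) {
    if (pos >= ex$end[k] && pos <= ex$start[k + 1L]) return(k)
  }
  NA_integer_
}

#' Generate ranked editing-PPRH candidates for a junction
#'
#' Pipeline: scan polypurine tracks on `record` (the mutant reference), build
#' a hairpin core per track, build the homology tail on the restored
#' reference (both tail orientations are emitted, + first, since the rule
#' mapping core-target strand to tail strand is under-determined), assemble,
#' validate, and rank by purity (desc), arm length (desc), distance of the
#' track midpoint to the junction (asc), then position. Names follow the
#' `LDSHp<region>I<k><mode><motif>` labelling style and are opaque labels,
#' never parsed.
#'
#' @param record Mutant reference `seq_record` (scanned for tracks).
#' @param restored_record Restored (post-edit) reference `seq_record`.
#' @param junction [edit_junction()] on `restored_record`.
#' @param gene [gene_model()] annotating `record` (used for region labels).
#' @param config A [scan_config()].
#' @param w Tail window width (default 20).
#' @param mode Tail mode (default `"UD"`).
#' @param tail_strands Tail orientations to emit (default both, `+` first).
#' @param motif_name Label for the recognition motif in design names.
#' @return data.frame of ranked designs (zero rows if no tracks are found):
#'   name, region, track strand/coords, arm, purity, tail, tail_strand,
#'   full_seq, offtarget_count, valid.
#' @export
design_candidates <- function(record, restored_record, junction, gene,
                              config = scan_config(), w = 20L, mode = "UD",
                              tail_strands = c("+", "-"), motif_name = "PstI") {
  record <- as_seq_record(record)
  restored_record <- as_seq_record(restored_record, id = "restored")
  validate_junction(junction, restored_record)
  tracks <- scan_polypurine_tracks(record, config)
  if (nrow(tracks) == 0L) {
    message("design_candidates: no polypurine tracks found")
    return(data.frame())
  }
  jk <- intron_index(gene, min(junction$coord, max(gene$exons$end)))
  jlab <- if (is.na(jk)) "J" else paste0("I", jk)
  rows <- list()
  for (ti in seq_len(nrow(tracks))) {
    tr <- tracks[ti, ]
    core <- build_core(tr, loop_len = 5L)
    region <- region_label(gene, (tr$start + tr$end) %/% 2L)
    for (ts in tail_strands) {
      tail <- build_tail(restored_record, junction, mode, w, ts)
      pprh <- assemble_editing_pprh(core, tail, linker_len = 5L)
      verdict <- validate_pprh(pprh$full_seq, config,
                               reference = restored_record,
                               junction = junction, motif = junction$motif)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("LDSHp", region, jlab, mode, motif_name,
                      if (ts == "-") "m" else ""),
        region = region,
        track_strand = tr$strand,
        start = tr$start, end = tr$end,
        arm = tr$seq,
        purity = tr$purine_fraction,
        tail = tail$tail_sequence,
        tail_strand = ts,
        full_seq = pprh$full_seq,
        offtarget_count = verdict$offtarget_count,
        valid = verdict$decomposable && isTRUE(verdict$tail_maps),
        dist = abs((tr$start + tr$end) / 2 - junction$coord),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$purity, -nchar(out$arm), out$dist, out$start,
                   match(out$tail_strand, c("+", "-"))), , drop = FALSE]
  out$dist <- NULL
  out$name <- make.unique(out$name, sep = "_")
  rownames(out) <- NULL
  out
}
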