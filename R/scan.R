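#' Scanner configuration for polypurine tracks
#'
#' Gates a candidate track must pass. Defaults are the loosest gates that
#' admit all three published core arms (lengths 17/20/22, purine fractions
#' 0.82-0.87, longest pyrimidine run 2).
#'
#' @param min_track_len Minimum track length in nt (>= 8; default 15).
#' @param min_purity Minimum purine fraction on the track's own strand
#'   (0.5-1.0; default 0.80).
#' @param max_pyr_run Maximum run of consecutive pyrimidines inside a track
#'   (default 2).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(min_track_len = 15L, min_purity = 0.80, max_pyr_run = 2L) {
  min_track_len <- as.integer(min_track_len)
  max_pyr_run <- as.integer(max_pyr_run)
  if (min_track_len < 8L) stop("min_track_len must be >= 8", call. = FALSE)
  if (min_purity < 0.5 || min_purity > 1.0) {
    stop("min_purity must be in [0.5, 1.0]", call. = FALSE)
  }
  if (max_pyr_run < 0L) stop("max_pyr_run must be >= 0", call. = FALSE)
  structure(
    list(min_track_len = min_track_len, min_purity = min_purity,
         max_pyr_run = max_pyr_run),
    class = "scan_config"
  )
}

empty_tracks <- function() {
  data.frame(
    record_id = character(0), strand = character(0),
    start = integer(0), end = integer(0), seq = character(0),
    length = integer(0), purine_fraction = numeric(0),
    max_pyr_run = integer(0), n_interruptions = integer(0),
    stringsAsFactors = FALSE
  )
}

track_stats <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pyr <- v %in% c("C", "T")
  rl <- rle(pyr)
  pyr_runs <- rl$lengths[rl$values]
  list(
    purine_fraction = sum(!pyr) / length(v),
    max_pyr_run = if (length(pyr_runs)) max(pyr_runs) else 0L,
    n_interruptions = length(pyr_runs)
  )
}

# Maximal valid windows on one strand, 1-based (start, end) inclusive.
# Positions with N (or any non-ACGT) cannot be inside a window.
scan_chars <- function(chars, config) {
  n <- length(chars)
  out <- matrix(integer(0), ncol = 2L)
  if (n < config$min_track_len) return(out)
  pur <- chars %in% c("A", "G")
  valid <- chars %in% c("A", "C", "G", "T")
  pyr <- valid & !pur
  # length of the pyrimidine run ending at each position
  rl <- rle(pyr)
  run <- sequence(rl$lengths)
  run[!pyr] <- 0L
  # a window ending at or beyond one of these positions is invalid
  bad <- which(run > config$max_pyr_run | !valid)
  P <- cumsum(pur)
  starts <- which(pur)
  if (!length(starts)) return(out)
  # frontier(i): last usable end position for a window starting at i
  frontier <- rep(n, length(starts))
  if (length(bad)) {
    idx <- findInterval(starts, bad)
    has_next <- idx < length(bad)
    frontier[has_next] <- bad[idx[has_next] + 1L] - 1L
  }
  res_start <- integer(0)
  res_end <- integer(0)
  for (si in seq_along(starts)) {
    i <- starts[si]
    jmin <- i + config$min_track_len - 1L
    fr <- frontier[si]
    if (fr < jmin) next
    js <- starts[starts >= jmin & starts <= fr]
    if (!length(js)) next
    ok <- (P[js] - P[i] + 1L) / (js - i + 1L) >= config$min_purity
    if (!any(ok)) next
    res_start <- c(res_start, i)
    res_end <- c(res_end, max(js[ok]))
  }
  if (!length(res_start)) return(out)
  # drop windows contained in a valid window with an earlier start
  keep <- logical(length(res_start))
  best <- -1L
  for (r in seq_along(res_start)) {
    if (res_end[r] > best) {
      keep[r] <- TRUE
      best <- res_end[r]
    }
  }
  cbind(res_start[keep], res_end[keep])
}

tracks_from_windows <- function(windows, strand, chars_on_strand, n, record_id) {
  if (nrow(windows) == 0L) return(empty_tracks())
  rows <- lapply(seq_len(nrow(windows)), function(r) {
    i <- windows[r, 1L]
    j <- windows[r, 2L]
    seq <- paste(chars_on_strand[i:j], collapse = "")
    st <- track_stats(seq)
    if (strand == "+") {
      start0 <- i - 1L
      end0 <- j
    } else {
      start0 <- n - j
      end0 <- n - i + 1L
    }
    data.frame(
      record_id = record_id, strand = strand, start = start0, end = end0,
      seq = seq, length = j - i + 1L,
      purine_fraction = st$purine_fraction,
      max_pyr_run = st$max_pyr_run, n_interruptions = st$n_interruptions,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

sort_tracks <- function(df) {
  df <- df[order(match(df$strand, c("+", "-")), df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find maximal polypurine tracks on both strands
#'
#' Returns every maximal track satisfying the gates in `config`, on both
#' strands. A track is trimmed to purine boundaries (first and last base are
#' purines on its own strand) and maximal: it is not contained in any larger
#' window that also satisfies the gates. Windows containing `N` are skipped.
#' A polypurine track on one strand implies a polypyrimidine (not polypurine)
#' region opposite it, so the same interval is reported on both strands only
#' if both strands independently pass the gates.
#'
#' @param record A `seq_record` (or plain DNA string).
#' @param config A [scan_config()].
#' @return data.frame with one row per track: `record_id`, `strand`,
#'   `start`/`end` (0-based half-open on the + strand), `seq` (5'->3' on the
#'   track's own strand), `length`, `purine_fraction`, `max_pyr_run`,
#'   `n_interruptions`. Sorted + strand first, then ascending start. A record
#'   shorter than `min_track_len` yields zero rows, not an error.
#' @export
scan_polypurine_tracks <- function(record, config = scan_config()) {
  record <- as_seq_record(record)
  stopifnot(inherits(config, "scan_config"))
  n <- nchar(record$seq)
  fwd_chars <- strsplit(record$seq, "", fixed = TRUE)[[1L]]
  rev_seq <- reverse_complement(record$seq)
  rev_chars <- strsplit(rev_seq, "", fixed = TRUE)[[1L]]
  plus <- tracks_from_windows(scan_chars(fwd_chars, config), "+",
                              fwd_chars, n, record$id)
  minus <- tracks_from_windows(scan_chars(rev_chars, config), "-",
                               rev_chars, n, record$id)
  sort_tracks(rbind(plus, minus))
}

# Enumerate valid windows on one strand the slow, literal way: walk every
# (start, end) pair keeping running counts. Independent oracle for scan_chars.
brute_chars <- function(chars, config) {
  n <- length(chars)
  wins <- list()
  for (i in seq_len(n)) {
    ci <- chars[i]
    if (!(ci %in% c("A", "G"))) next
    pcount <- 0L
    runlen <- 0L
    maxrun <- 0L
    for (j in i:n) {
      cj <- chars[j]
      if (!(cj %in% c("A", "C", "G", "T"))) break
      if (cj %in% c("A", "G")) {
        pcount <- pcount + 1L
        runlen <- 0L
      } else {
        runlen <- runlen + 1L
        if (runlen > maxrun) maxrun <- runlen
      }
      if (maxrun > config$max_pyr_run) break
      len <- j - i + 1L
      if (cj %in% c("A", "G") && len >= config$min_track_len &&
          pcount / len >= config$min_purity) {
        wins[[length(wins) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(wins)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, wins)
  # literal pairwise containment filter
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1L] <= m[r, 1L] & m[, 2L] >= m[r, 2L] &
           (m[, 1L] != m[r, 1L] | m[, 2L] != m[r, 2L]))
  }, logical(1))
  m[keep, , drop = FALSE]
}

#' Brute-force polypurine track enumeration (test oracle)
#'
#' Enumerates every purine-bounded substring on both strands, filters by the
#' [scan_config()] gates and keeps maximal windows. Output is set-equal to
#' [scan_polypurine_tracks()]; kept deliberately naive as an independent
#' oracle and guarded to short sequences.
#'
#' @inheritParams scan_polypurine_tracks
#' @return Same shape as [scan_polypurine_tracks()].
#' @export
brute_force_tracks <- function(record, config = scan_config()) {
  record <- as_seq_record(record)
  if (nchar(record$seq) > 2000L) {
    stop("brute_force_tracks refuses sequences longer than 2000 nt",
         call. = FALSE)
  }
  n <- nchar(record$seq)
  fwd_chars <- strsplit(record$seq, "", fixed = TRUE)[[1L]]
  rev_chars <- strsplit(reverse_complement(record$seq), "", fixed = TRUE)[[1L]]
  plus <- tracks_from_windows(brute_chars(fwd_chars, config), "+",
                              fwd_chars, n, record$id)
  minus <- tracks_from_windows(brute_chars(rev_chars, config), "-",
                               rev_chars, n, record$id)
  sort_tracks(rbind(plus, minus))
}

#' Write tracks as BED6
#'
#' One line per track; `name` is `track1..trackN` in row order, `score` is
#' `round(1000 * purine_fraction)`, the strand column carries the track
#' strand.
#'
#' @param tracks data.frame from [scan_polypurine_tracks()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracks_bed <- function(tracks, path) {
  if (nrow(tracks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tracks$record_id,
    ranges = IRanges::IRanges(start = tracks$start + 1L, end = tracks$end),
    strand = tracks$strand,
    name = paste0("track", seq_len(nrow(tracks))),
    score = round(1000 * tracks$purine_fraction)
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
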