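# Shared fixtures, built once per test run. Everything is generated in code;
# no files are read from disk.

oligos6 <- published_pprh_oligos()
editing5 <- oligos6[oligos6$editing, ]
arms3 <- published_core_arms()
blocks2 <- published_junction_blocks()
primers4 <- published_primer_pairs()

# default synthetic minigene and its duplication derivative
mg42 <- make_minigene(minigene_spec(seed = 42))
mut42 <- make_mutant(mg42)

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# purine-rich arm with up to `n_pyr` interior pyrimidine interruptions
random_arm <- function(len, n_pyr = 2L) {
  v <- sample(c("A", "G"), len, replace = TRUE)
  k <- sample(0:n_pyr, 1L)
  if (k > 0L && len > 2L) {
    at <- sample(2:(len - 1L), k)
    v[at] <- sample(c("C", "T"), k, replace = TRUE)
  }
  paste(v, collapse = "")
}

# a homology tail over a random junction context, built with the real
# constructor (motif policy disabled)
random_tail <- function(w = sample(8:20, 1L), strand = sample(c("+", "-"), 1L)) {
  ctx <- seq_record("ctx", random_dna_str(2L * w))
  j <- edit_junction("ctx", w, motif_policy = "none")
  build_tail(ctx, j, "UD", w, strand)
}

# independent IUPAC restriction-site oracle: literal position-by-position
# comparison against the expanded code table
iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_motif_positions <- function(seq, motif) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mv <- strsplit(motif, "", fixed = TRUE)[[1L]]
  k <- length(mv)
  hits <- integer(0)
  if (length(sv) < k) return(hits)
  for (p in 1:(length(sv) - k + 1L)) {
    ok <- TRUE
    for (q in 1:k) {
      if (!sv[p + q - 1L] %in% iupac_table[[mv[q]]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, p - 1L)
  }
  hits
}
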