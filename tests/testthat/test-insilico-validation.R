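test_that("restriction scan finds palindromic sites once, ascending", {
  ud <- oligos6$sequence[oligos6$name == "UDPst1"]
  sites <- find_restriction_sites(ud, "CTGCAG")
  expect_equal(sites$pos, 14L)
  expect_equal(sites$strand, "+")
  expect_equal(nrow(find_restriction_sites("AAAA", "CTGCAG")), 0L)
  expect_equal(find_restriction_sites("CTGCAGCTGCAG", "CTGCAG")$pos, c(0L, 6L))
  expect_error(find_restriction_sites("ACGT", ""), "empty")
  expect_error(find_restriction_sites("ACGT", "CTG"), "at least 4")
})

test_that("non-palindromic motifs report minus-strand matches", {
  # GGTCTC is not its own reverse complement (GAGACC)
  s <- paste0("AAAA", "GGTCTC", "AAAA", "GAGACC", "AAAA")
  sites <- find_restriction_sites(s, "GGTCTC")
  expect_equal(sites$pos[sites$strand == "+"], 4L)
  expect_equal(sites$pos[sites$strand == "-"], 14L)
})

test_that("IUPAC codes in motifs are honoured", {
  # CTGCAR = CTGCAA or CTGCAG
  s <- "CTGCAATTTTCTGCAGTTTTCTGCAC"
  sites <- find_restriction_sites(s, "CTGCAR")
  expect_equal(sort(sites$pos[sites$strand == "+"]), c(0L, 10L))
})

test_that("restriction scan matches a naive enumeration oracle", {
  set.seed(515)
  for (k in 1:30) {
    s <- random_dna_str(300)
    for (motif in c("CTGCAG", "GGTCTC", "RAAT", "CANNTG")) {
      got <- find_restriction_sites(s, motif)
      expect_equal(sort(got$pos[got$strand == "+"]),
                   naive_motif_positions(s, motif),
                   label = paste("motif", motif))
    }
  }
})

test_that("palindromic site sets mirror under reverse complement", {
  set.seed(616)
  motif <- "CTGCAG"
  for (k in 1:20) {
    s <- random_dna_str(400)
    fwd <- find_restriction_sites(s, motif)$pos
    rev <- find_restriction_sites(reverse_complement(s), motif)$pos
    expect_equal(sort(fwd), sort(400 - rev - nchar(motif)))
  }
})

test_that("virtual PCR amplifies between correctly oriented primer sites", {
  set.seed(33)
  fwd <- random_dna_str(20)
  rev <- random_dna_str(20)
  mid <- random_dna_str(60)
  tpl <- seq_record("t", paste0(fwd, mid, reverse_complement(rev)))
  amp <- virtual_pcr(tpl, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 100L)
  expect_equal(amp$product_seq, tpl$seq)
  expect_equal(amp$start, 0L)
  expect_equal(amp$end, 100L)
  # template invariants of the amplicon record
  expect_equal(substr(tpl$seq, amp$start + 1, amp$start + 20), fwd)
  expect_equal(substr(tpl$seq, amp$end - 19, amp$end), reverse_complement(rev))
  # reverse site left of forward site: no product
  flipped <- seq_record("f", paste0(reverse_complement(rev), mid, fwd))
  expect_equal(nrow(virtual_pcr(flipped, fwd, rev)), 0L)
  # max_len gate
  expect_equal(nrow(virtual_pcr(tpl, fwd, rev, max_len = 99)), 0L)
})

test_that("inserting K bases between primer sites lengthens the product by K", {
  set.seed(34)
  fwd <- random_dna_str(18)
  rev <- random_dna_str(18)
  for (K in c(1L, 37L, 200L)) {
    base <- paste0(fwd, random_dna_str(40), reverse_complement(rev))
    l0 <- virtual_pcr(seq_record("a", base), fwd, rev)$length
    # same middle, K extra bases inserted right before the rev footprint
    mid <- substr(base, 19, 58)
    plus <- paste0(fwd, mid, random_dna_str(K), reverse_complement(rev))
    l1 <- virtual_pcr(seq_record("b", plus), fwd, rev)$length
    expect_equal(l1, l0 + K)
  }
})

test_that("mismatched priming requires an exact 3' anchor", {
  set.seed(35)
  fwd <- random_dna_str(20)
  rev <- random_dna_str(20)
  tpl_chars <- strsplit(paste0(fwd, random_dna_str(50),
                               reverse_complement(rev)), "")[[1]]
  # one mismatch in the middle of the forward footprint
  tpl_chars[10] <- setdiff(c("A", "C", "G", "T"), tpl_chars[10])[1]
  tpl <- seq_record("t", paste(tpl_chars, collapse = ""))
  expect_equal(nrow(virtual_pcr(tpl, fwd, rev, max_mismatch = 0)), 0L)
  expect_equal(nrow(virtual_pcr(tpl, fwd, rev, max_mismatch = 1)), 1L)
  # a mismatch in the 3'-terminal 3 nt kills priming even with allowance
  tpl_chars2 <- strsplit(paste0(fwd, random_dna_str(50),
                                reverse_complement(rev)), "")[[1]]
  tpl_chars2[20] <- setdiff(c("A", "C", "G", "T"), tpl_chars2[20])[1]
  tpl2 <- seq_record("t2", paste(tpl_chars2, collapse = ""))
  expect_equal(nrow(virtual_pcr(tpl2, fwd, rev, max_mismatch = 2)), 0L)
  expect_error(virtual_pcr(tpl, "ACGTACGTACGTACGN", rev), "degenerate")
  expect_error(virtual_pcr(tpl, "ACGTACGTACGT", rev), ">= 15")
  expect_error(virtual_pcr(tpl, fwd, rev, max_mismatch = 3), "max_mismatch")
})

test_that("isoform enumeration concatenates exons and honours events", {
  rec <- mut42$record
  gene <- mut42$gene
  isos <- enumerate_isoforms(rec, gene)
  expect_length(isos, 1L)
  expect_equal(isos[[1]]$label, "canonical")
  expect_equal(nchar(isos[[1]]$seq),
               sum(gene$exons$end - gene$exons$start))

  isos <- enumerate_isoforms(rec, gene, list("skip:E2b", "skip:E2a", "retain:1"))
  labs <- vapply(isos, function(i) i$label, "")
  expect_equal(labs, c("canonical", "skip:E2b", "skip:E2a", "retain:1"))
  len <- vapply(isos, function(i) nchar(i$seq), 0L)
  copy_len <- 50L
  expect_equal(len[1] - len[2], copy_len)
  expect_equal(len[1] - len[3], copy_len)
  expect_gt(len[4], len[1]) # retained intron is strictly longer
  # retained intron sits between E1 and its successor and splices in verbatim
  expect_equal(isos[[4]]$exon_labels[1:3], c("E1", "I1", "E2a"))
  # explicit combination event
  both <- enumerate_isoforms(rec, gene, list(c("skip:E2b", "retain:1")))[[2]]
  expect_equal(nchar(both$seq), len[4] - copy_len)
  expect_error(enumerate_isoforms(rec, gene, list("skip:E9")), "unknown exon")
  expect_error(enumerate_isoforms(rec, gene, list("retain:9")), "unknown intron")
})

test_that("RT-PCR band table reproduces the 166 vs 116 bp inclusion/skip pair", {
  isos <- enumerate_isoforms(mut42$record, mut42$gene,
                             list("skip:E2b", "retain:1", "skip:E1"))
  bands <- rtpcr_band_table(isos, primers4$forward[1], primers4$reverse[1])
  expect_equal(bands$length[bands$isoform == "canonical"], 166L)
  expect_equal(bands$length[bands$isoform == "skip:E2b"], 116L)
  # gel order: largest product on top, missing-site isoforms at the bottom
  expect_equal(bands$isoform[1], "retain:1")
  expect_gt(bands$length[1], 166L)
  expect_true(is.na(bands$length[bands$isoform == "skip:E1"]))
  expect_false(is.unsorted(-bands$length[!is.na(bands$length)]))
})
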