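test_that("build_core mirrors the arm around a pentathymidine loop", {
  core <- build_core(arms3[["E6"]])
  expect_equal(core$full_core,
               "AGGAGGAAAAAGGCATCAAGTTTTTGAACTACGGAAAAAGGAGGA")
  core <- build_core(arms3[["Pr"]])
  # the 3' arm is the plain reverse, never the reverse complement
  expect_equal(substring(core$full_core, 28, 49), "ACAGTGGGTGAAAAGGAAGGGG")
  expect_equal(build_core("AAAA")$full_core, "AAAATTTTTAAAA")
  expect_equal(nchar(build_core("AAAA", loop_len = 7)$full_core), 15L)
  expect_error(build_core("AAAA", loop_len = 2), "cannot close")
  expect_error(build_core("AANA"), "N")
})

test_that("build_tail extracts the published windows around the junction", {
  expect_equal(build_tail(mg42$record, mg42$junction, "UD", 20, "+")$tail_sequence,
               paste0(blocks2[["up"]], blocks2[["down"]]))
  expect_equal(build_tail(mg42$record, mg42$junction, "UD", 20, "-")$tail_sequence,
               oligos6$sequence[oligos6$name == "UDPst1"])
  expect_equal(build_tail(mg42$record, mg42$junction, "U", 20, "+")$tail_sequence,
               blocks2[["up"]])
  expect_equal(build_tail(mg42$record, mg42$junction, "U", 20, "-")$tail_sequence,
               reverse_complement(blocks2[["up"]]))
  expect_equal(build_tail(mg42$record, mg42$junction, "D", 20, "+")$tail_sequence,
               blocks2[["down"]])
  # the downstream window begins with the recognition motif
  expect_match(build_tail(mg42$record, mg42$junction, "D", 20, "+")$tail_sequence,
               "^CTGCAG")
  expect_error(build_tail(mg42$record, mg42$junction, "UD", 0), "degenerate")
  near_end <- seq_record("r", "AAAAACTGCAGAAAA")
  j <- edit_junction("r", 5)
  expect_error(build_tail(near_end, j, "UD", 20), "closer than")
})

test_that("assembly reproduces the published editing PPRHs byte-identically", {
  tails <- list(
    LDSHpPrI1UPstI = build_tail(mg42$record, mg42$junction, "D", 20, "+"),
    LDSHpPrI1UDstI = build_tail(mg42$record, mg42$junction, "UD", 20, "+"),
    LDSHpE6I1DPstI = build_tail(mg42$record, mg42$junction, "U", 20, "-"),
    LDSHpE6I1UDPstI = build_tail(mg42$record, mg42$junction, "UD", 20, "-"),
    LDSHpE3I1UDPstI = build_tail(mg42$record, mg42$junction, "UD", 20, "-")
  )
  cores <- list(
    LDSHpPrI1UPstI = "Pr", LDSHpPrI1UDstI = "Pr", LDSHpE6I1DPstI = "E6",
    LDSHpE6I1UDPstI = "E6", LDSHpE3I1UDPstI = "E3"
  )
  for (nm in names(tails)) {
    pprh <- assemble_editing_pprh(build_core(arms3[[cores[[nm]]]]), tails[[nm]])
    expect_equal(pprh$full_seq, oligos6$sequence[oligos6$name == nm],
                 label = nm)
  }
})

test_that("assembly without a tail yields the plain hairpin with no linker", {
  core <- build_core(arms3[["E3"]])
  pprh <- assemble_editing_pprh(core, tail = NULL)
  expect_equal(pprh$full_seq, core$full_core)
  expect_null(pprh$linker)
})

test_that("total length follows |tail| + 5 + 2|arm| + 5", {
  expect_equal(nchar(editing5$sequence), c(74L, 94L, 70L, 90L, 84L))
  for (i in seq_len(nrow(editing5))) {
    d <- decompose_pprh(editing5$sequence[i])
    expect_equal(nchar(editing5$sequence[i]),
                 nchar(d$tail) + 5L + 2L * nchar(d$arm1) + 5L)
  }
})

test_that("all published editing PPRHs decompose to mirror arms and reassemble", {
  expected_arm <- c("GGGGAAGGAAAAGTGGGTGACA", "GGGGAAGGAAAAGTGGGTGACA",
                    "AGGAGGAAAAAGGCATCAAG", "AGGAGGAAAAAGGCATCAAG",
                    "GGACCAAGAGGTAAGGA")
  expected_tail_len <- c(20L, 40L, 20L, 40L, 40L)
  for (i in seq_len(nrow(editing5))) {
    d <- decompose_pprh(editing5$sequence[i])
    expect_true(d$ok, label = editing5$name[i])
    expect_equal(d$arm1, expected_arm[i])
    expect_equal(d$arm2, sapply(lapply(strsplit(d$arm1, ""), rev),
                                paste, collapse = ""))
    expect_equal(nchar(d$tail), expected_tail_len[i])
    expect_equal(d$loop, "TTTTT")
    expect_equal(d$linker, "TTTTT")
    expect_equal(paste0(d$tail, d$linker, d$arm1, d$loop, d$arm2),
                 editing5$sequence[i])
  }
})

test_that("a tail ending in T fused to the linker (6-T run) is disambiguated", {
  d <- decompose_pprh(oligos6$sequence[oligos6$name == "LDSHpE6I1DPstI"])
  expect_equal(d$tail, "CCCTTGCCCATGCCCGCGGT") # keeps its terminal T
  expect_equal(d$arm1, "AGGAGGAAAAAGGCATCAAG") # does not inherit a leading T
})

test_that("non-hairpin sequences fail decomposition with a structured reason", {
  d <- decompose_pprh("AAAATTTTTGGGG", min_arm = 4)
  expect_false(d$ok)
  expect_match(d$best_rejected$violated, "reverse")
  d <- decompose_pprh(oligos6$sequence[oligos6$name == "UDPst1"])
  expect_false(d$ok)
  expect_match(d$reason, "5-T")
  set.seed(77)
  d <- decompose_pprh(random_dna_str(74))
  expect_false(d$ok)
})

test_that("decompose is the inverse of assemble over randomized designs", {
  set.seed(424)
  for (k in 1:100) {
    arm <- random_arm(sample(10:24, 1))
    tail <- random_tail()
    pprh <- assemble_editing_pprh(build_core(arm), tail)
    d <- decompose_pprh(pprh$full_seq)
    expect_true(d$ok)
    expect_equal(d$arm1, arm)
    expect_equal(d$tail, tail$tail_sequence)
    expect_equal(paste0(d$tail, d$linker, d$arm1, d$loop, d$arm2),
                 pprh$full_seq)
  }
})

test_that("validate_pprh separates editing PPRHs from the tail-only control", {
  for (i in seq_len(nrow(editing5))) {
    v <- validate_pprh(editing5$sequence[i], reference = mg42$record,
                       junction = mg42$junction)
    expect_true(v$decomposable, label = editing5$name[i])
    expect_true(v$mirror_ok)
    expect_false(v$tail_only)
    expect_true(v$tail_maps)
    expect_true(v$motif_in_tail == grepl("CTGCAG", substr(
      editing5$sequence[i], 1, v$tail_len
    )))
    expect_equal(v$offtarget_count, 1L) # the intended target itself
  }
  v <- validate_pprh(oligos6$sequence[6], reference = mg42$record,
                     junction = mg42$junction)
  expect_false(v$decomposable)
  expect_true(v$tail_only)
  expect_true(v$tail_maps)
  set.seed(9)
  v <- validate_pprh(random_dna_str(74))
  expect_false(v$decomposable)
  expect_false(v$tail_only)
})

test_that("design_candidates recovers the embedded targets and ranks deterministically", {
  des <- design_candidates(mut42$record, mg42$record, mg42$junction, mut42$gene)
  expect_gte(nrow(des), 3L)
  expect_true(all(des$valid))
  # each embedded arm is inside some candidate's track arm
  for (arm in arms3) {
    expect_true(any(grepl(arm, des$arm, fixed = TRUE) & des$track_strand == "+"))
  }
  # region labels of the top embedded targets
  expect_setequal(intersect(c("Pr", "E3", "E6"), des$region), c("Pr", "E3", "E6"))
  # both tail orientations are emitted per track, + first
  expect_true(all(c("+", "-") %in% des$tail_strand))
  # deterministic: same call twice gives identical output
  expect_identical(des,
                   design_candidates(mut42$record, mg42$record, mg42$junction,
                                     mut42$gene))
  # every emitted design follows the grammar around the published tail
  expect_true(all(vapply(des$full_seq,
                         function(s) decompose_pprh(s)$ok, logical(1))))
})

test_that("design_candidates returns an empty set when no tracks exist", {
  pyr <- seq_record("p", strrep("CA", 200))
  expect_message(
    des <- design_candidates(pyr, mg42$record, mg42$junction, mg42$gene),
    "no polypurine tracks"
  )
  expect_equal(nrow(des), 0L)
})

test_that("identical equidistant tracks break ties by position, leftmost first", {
  arm <- arms3[["E6"]] # 20-mer
  bg <- strsplit(strrep("CT", 500), "", fixed = TRUE)[[1]]
  # junction coord is 460: place the two copies with midpoints 460 -+ 100
  for (at in c(350, 550)) bg[(at + 1):(at + 20)] <- strsplit(arm, "")[[1]]
  rec <- seq_record("two", paste(bg, collapse = ""))
  des <- design_candidates(rec, mg42$record, mg42$junction, mg42$gene)
  same <- des[des$arm == arm & des$tail_strand == "+", ]
  expect_equal(nrow(same), 2L)
  expect_equal(same$start, c(350L, 550L))
})
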