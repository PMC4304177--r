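make_parsed <- function(seq, defects = defect_spec(), ...) {
  parse_pdb(make_chain_fixture(seq, defects, ...)$text)[[1]]
}

test_that("restore_modres renames mapped residues and flags them", {
  ch <- make_parsed("ACDEFGHMKL",
    defect_spec(modres = data.frame(position = 8L, mod_code = "MSE",
                                    std_code = "MET")))
  out <- restore_modres(ch)
  expect_identical(out$residues$res_name[8], "MET")
  expect_true(out$residues$is_modified[8])
  # chains without modified residues pass through unchanged
  ch2 <- make_parsed("ACDEF")
  expect_identical(restore_modres(ch2), ch2)
})

test_that("unmapped non-standard residues contribute X to the coord sequence", {
  ch <- make_parsed("ACDEF", defect_spec(x_positions = 3L))
  out <- restore_modres(ch)
  expect_identical(coord_sequence(out), "ACXEF")
})

test_that("prune_atoms removes atoms beyond the standard composition", {
  ch <- make_parsed("ACDEF",
    defect_spec(extra_atoms = data.frame(position = 2L, name = "ZZ1")))
  out <- prune_atoms(restore_modres(ch))
  expect_identical(attr(out, "n_pruned"), 1L)
  expect_false("ZZ1" %in% out$atoms$name)
  # a residue with exactly the standard set is untouched
  ch2 <- make_parsed("ACDEF")
  out2 <- prune_atoms(restore_modres(ch2))
  expect_identical(attr(out2, "n_pruned"), 0L)
  expect_identical(out2$atoms$name, ch2$atoms$name)
})

test_that("the selenium atom of a restored selenomethionine is pruned", {
  ch <- make_parsed("ACDEFGHMKL",
    defect_spec(modres = data.frame(position = 8L, mod_code = "MSE",
                                    std_code = "MET")))
  out <- prune_atoms(restore_modres(ch))
  expect_false("SE" %in% out$atoms$name)
  expect_identical(attr(out, "n_pruned"), 1L)
})

test_that("terminal OXT is kept on the final residue only", {
  ch <- make_parsed("ACDEF", defect_spec(oxt_last = TRUE))
  out <- prune_atoms(restore_modres(ch))
  oxt_res <- out$atoms$res_idx[out$atoms$name == "OXT"]
  expect_identical(oxt_res, 5L)
  # an OXT planted mid-chain is beyond the composition and removed
  ch2 <- make_parsed("ACDEF",
    defect_spec(extra_atoms = data.frame(position = 2L, name = "OXT")))
  out2 <- prune_atoms(restore_modres(ch2))
  expect_false(any(out2$atoms$name == "OXT" & out2$atoms$res_idx == 2L))
})

test_that("select_altloc keeps the first conformation in file order", {
  ch <- make_parsed("ACDEF",
    defect_spec(altloc_atoms = data.frame(position = 2L, name = "CA",
                                          n_variants = 2L)))
  first_ca <- ch$atoms[ch$atoms$res_idx == 2L & ch$atoms$name == "CA", ]
  expect_identical(nrow(first_ca), 2L)
  out <- select_altloc(ch)
  kept <- out$atoms[out$atoms$res_idx == 2L & out$atoms$name == "CA", ]
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$y, first_ca$y[1])  # first variant, not the shifted one
  expect_identical(attr(out, "n_altloc_removed"), 1L)
  expect_true(all(out$atoms$alt_loc == " "))
  # no alternates: identity apart from blanked alt_loc
  ch2 <- make_parsed("ACDEF")
  out2 <- select_altloc(ch2)
  expect_identical(out2$atoms$serial, ch2$atoms$serial)
})

test_that("every atom name appears once after altloc resolution", {
  ch <- make_parsed("ACD",
    defect_spec(altloc_atoms = data.frame(position = 1:3, name = "CA",
                                          n_variants = 3L)))
  out <- select_altloc(ch)
  key <- paste(out$atoms$res_idx, out$atoms$name)
  expect_false(anyDuplicated(key) > 0)
})

test_that("alignment reproduces the hand-enumerated examples", {
  a1 <- align_ref_coord("ACDEFG", "ACDEFG")
  expect_identical(a1$map, 1:6)
  expect_identical(nrow(a1$missing_regions), 0L)
  expect_length(a1$mismatches, 0L)

  a2 <- align_ref_coord("ACDEFGHIK", "ACDHIK")
  expect_identical(a2$map, c(1L, 2L, 3L, 7L, 8L, 9L))
  expect_identical(a2$missing_regions,
                   data.frame(start = 4L, end = 6L))

  # a mismatch is anchored rather than forced into a gap
  a3 <- align_ref_coord("ACMEF", "ACLEF")
  expect_identical(a3$map, 1:5)
  expect_identical(a3$mismatches, 3L)
  expect_identical(nrow(a3$missing_regions), 0L)
})

test_that("alignment agrees with the exhaustive placement oracle", {
  set.seed(5)
  ab <- c("A", "C", "G", "T")
  for (rep in 1:300) {
    n <- sample(4:12, 1)
    m <- sample.int(n, 1)
    ref <- paste(sample(ab, n, TRUE), collapse = "")
    coord <- paste(sample(ab, m, TRUE), collapse = "")
    got <- align_ref_coord(ref, coord)
    want <- oracle_align(ref, coord)
    expect_identical(got$map, want$map)
    expect_identical(got$n_matches, want$n_matches)
  }
})

test_that("alignment rejects coord longer than ref and flags zero matches", {
  expect_error(align_ref_coord("ACD", "ACDE"), "longer than")
  expect_error(align_ref_coord("", "A"), "empty")
  expect_true(align_ref_coord("AAAA", "CC")$zero_match)
})

test_that("reindex numbers residues by reference position from one", {
  ch <- make_parsed("ACDEFGHIKL")
  ch$residues$res_num <- ch$residues$res_num + 41L  # author numbering at 42
  res <- clean_chain(ch)
  expect_identical(res$chain$residues$res_num, 1:10)
  expect_true(all(res$chain$residues$ins_code == " "))
  # with a missing interior region the numbering keeps reference gaps
  ch2 <- make_parsed("ACDEFGHIKL",
    defect_spec(missing_regions = data.frame(start = 4L, end = 5L)))
  res2 <- clean_chain(ch2)
  expect_identical(res2$chain$residues$res_num, c(1:3, 6:10))
})

test_that("filters fire on CA-only, short and X-rich chains with strict bounds", {
  params <- clean_params()
  ca <- clean_chain(make_parsed(strrep("A", 40), defect_spec(ca_only = TRUE)))
  expect_identical(ca$filter$reasons, "CA_ONLY")

  s29 <- clean_chain(make_parsed(substr(strrep("ACDEFGHIKL", 3), 1, 29)))
  expect_identical(s29$filter$reasons, "TOO_SHORT")
  s30 <- clean_chain(make_parsed(substr(strrep("ACDEFGHIKL", 3), 1, 30)))
  expect_true(s30$filter$kept)

  # 3 X of 30 residues = 0.10 exactly: kept (strictly greater removes)
  ch10 <- make_parsed(substr(strrep("ACDEFGHIKL", 3), 1, 30),
                      defect_spec(x_positions = c(2L, 12L, 22L)))
  expect_true(clean_chain(ch10)$filter$kept)
  ch13 <- make_parsed(substr(strrep("ACDEFGHIKL", 3), 1, 30),
                      defect_spec(x_positions = c(2L, 6L, 12L, 22L)))
  expect_identical(clean_chain(ch13)$filter$reasons, "TOO_MANY_X")
})

test_that("clean_chain is idempotent and conserves coordinates", {
  ch <- make_parsed("ACDEFGHMKLMNPQRSTVWY",
    defect_spec(missing_regions = data.frame(start = 11L, end = 13L),
                modres = data.frame(position = 8L, mod_code = "MSE",
                                    std_code = "MET"),
                altloc_atoms = data.frame(position = 2L, name = "CA",
                                          n_variants = 2L)))
  r1 <- clean_chain(ch)
  r2 <- clean_chain(r1$chain)
  expect_identical(r2$chain, r1$chain)
  expect_identical(r2$filter, r1$filter)
  key <- function(at) paste(at$x, at$y, at$z)
  expect_true(all(key(r1$chain$atoms) %in% key(ch$atoms)))
})
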