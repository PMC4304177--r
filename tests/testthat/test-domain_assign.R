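hit_row <- function(e, z, qs = 1L, qe = 50L, addr = "A.1.1.1",
                    id = "T01", tlen = 100L) {
  data.frame(target_id = id, target_address = addr, e_value = e,
             z_score = z, query_start = qs, query_end = qe,
             target_len = tlen, stringsAsFactors = FALSE)
}

empty_hits_df <- function() hit_row(1, 1)[integer(0), ]

test_that("hit filtering applies both gates strictly at the sequence stage", {
  p <- assign_params()
  expect_identical(nrow(filter_hits(hit_row(0.005, 5.0), p, "SEQ")), 1L)
  expect_identical(nrow(filter_hits(hit_row(0.02, 6.0), p, "SEQ")), 0L)
  expect_identical(nrow(filter_hits(hit_row(0.005, 4.5), p, "SEQ")), 0L)
  expect_identical(nrow(filter_hits(hit_row(0.01, 6.0), p, "SEQ")), 0L)
  # structure stage ignores the E-value
  expect_identical(nrow(filter_hits(hit_row(0.5, 5.0), p, "STRUCT")), 1L)
  expect_identical(nrow(filter_hits(hit_row(0.5, 4.5), p, "STRUCT")), 0L)
  expect_identical(nrow(filter_hits(empty_hits_df(), p, "SEQ")), 0L)
})

test_that("best hit is picked by Z-score, target length, then id", {
  hits <- rbind(hit_row(0.001, 5.0, id = "Ta"), hit_row(0.001, 6.2, id = "Tb"))
  expect_identical(pick_best_hit(hits)$target_id, "Tb")
  tie <- rbind(hit_row(0.001, 6.0, id = "Ta", tlen = 100L),
               hit_row(0.001, 6.0, id = "Tb", tlen = 150L))
  expect_identical(pick_best_hit(tie)$target_id, "Tb")
  tie2 <- rbind(hit_row(0.001, 6.0, id = "Tb", tlen = 100L),
                hit_row(0.001, 6.0, id = "Ta", tlen = 100L))
  expect_identical(pick_best_hit(tie2)$target_id, "Ta")
  expect_identical(pick_best_hit(hit_row(1, 1))$target_id, "T01")
  expect_error(pick_best_hit(empty_hits_df()), "no hits")
})

test_that("a full-span hit yields a single addressed segment", {
  bk <- make_hit_script(data.frame(start = 1L, end = 200L,
                                   address = "B.34.9.1"))
  da <- assign_domains(200L, bk)
  expect_identical(da$segments,
                   data.frame(start = 1L, end = 200L,
                              address = "B.34.9.1",
                              stringsAsFactors = FALSE))
})

test_that("long unassigned tails recurse, short ones merge", {
  # 60-residue tail (> 30) is re-searched; a second scripted hit covers it
  bk <- make_hit_script(data.frame(start = c(1L, 125L), end = c(120L, 180L),
                                   address = c("A.1.1.1", "C.2.1.5")))
  da <- assign_domains(180L, bk)
  expect_identical(da$segments$address, c("A.1.1.1", "C.2.1.5"))
  # the 4-residue gap between the hits is absorbed by the longer domain
  expect_identical(da$segments$start, c(1L, 125L))
  expect_identical(da$segments$end, c(124L, 180L))

  # 30-residue tail: merged into the neighboring domain, not recursed
  calls <- new.env(); calls$n <- 0L
  base <- make_hit_script(data.frame(start = 1L, end = 150L,
                                     address = "A.1.1.1"))
  counting <- function(s, e) { calls$n <- calls$n + 1L; base(s, e) }
  da30 <- assign_domains(180L, counting)
  expect_identical(calls$n, 1L)
  expect_identical(da30$segments,
                   data.frame(start = 1L, end = 180L, address = "A.1.1.1",
                              stringsAsFactors = FALSE))

  # 31-residue tail: recursed; with no further hits it stays unassigned
  calls$n <- 0L
  base31 <- make_hit_script(data.frame(start = 1L, end = 149L,
                                       address = "A.1.1.1"))
  counting31 <- function(s, e) { calls$n <- calls$n + 1L; base31(s, e) }
  da31 <- assign_domains(180L, counting31)
  expect_identical(calls$n, 2L)
  expect_identical(da31$segments$address, c("A.1.1.1", "UNASSIGNED"))
  expect_identical(da31$segments$start, c(1L, 150L))
})

test_that("queries with no surviving hits are fully unassigned", {
  da <- assign_domains(100L, make_hit_script(NULL))
  expect_identical(da$segments$address, "UNASSIGNED")
  # hits failing the gates behave like no hits
  weak <- make_hit_script(data.frame(start = 1L, end = 100L,
                                     address = "A.1.1.1", e_value = 0.5,
                                     z_score = 3.0))
  da2 <- assign_domains(100L, weak)
  expect_identical(da2$segments$address, "UNASSIGNED")
})

test_that("the structure stage is consulted only when sequence search fails", {
  seq_bk <- make_hit_script(NULL)
  struct_bk <- make_hit_script(data.frame(start = 1L, end = 80L,
                                          address = "D.15.1.1",
                                          e_value = 10, z_score = 7))
  da <- assign_domains(80L, seq_bk, struct_bk)
  expect_identical(da$segments$address, "D.15.1.1")
  # when the sequence stage produces a survivor the structure hits are unused
  seq_hit <- make_hit_script(data.frame(start = 1L, end = 80L,
                                        address = "A.1.1.1"))
  struct_other <- make_hit_script(data.frame(start = 1L, end = 80L,
                                             address = "C.2.1.5",
                                             z_score = 99))
  da2 <- assign_domains(80L, seq_hit, struct_other)
  expect_identical(da2$segments$address, "A.1.1.1")
})

test_that("merge absorbs short gaps into the longer neighboring domain", {
  da <- structure(list(
    segments = data.frame(start = c(1L, 101L, 121L),
                          end = c(100L, 120L, 300L),
                          address = c("A.1.1.1", "UNASSIGNED", "B.34.9.1"),
                          stringsAsFactors = FALSE),
    query_len = 300L), class = "domain_assignment")
  out <- merge_short_regions(da)
  expect_identical(out$segments,
                   data.frame(start = c(1L, 101L), end = c(100L, 300L),
                              address = c("A.1.1.1", "B.34.9.1"),
                              stringsAsFactors = FALSE))
  # equal-length neighbors: the preceding domain absorbs the gap
  tie <- structure(list(
    segments = data.frame(start = c(1L, 101L, 121L),
                          end = c(100L, 120L, 220L),
                          address = c("A.1.1.1", "UNASSIGNED", "B.34.9.1"),
                          stringsAsFactors = FALSE),
    query_len = 220L), class = "domain_assignment")
  out_tie <- merge_short_regions(tie)
  expect_identical(out_tie$segments$end[1], 120L)
  # terminal gaps join their only neighbor
  lead <- structure(list(
    segments = data.frame(start = c(1L, 11L), end = c(10L, 200L),
                          address = c("UNASSIGNED", "A.1.1.1"),
                          stringsAsFactors = FALSE),
    query_len = 200L), class = "domain_assignment")
  expect_identical(merge_short_regions(lead)$segments$start, 1L)
  # an all-unassigned chain is left alone
  none <- structure(list(
    segments = data.frame(start = 1L, end = 20L, address = "UNASSIGNED",
                          stringsAsFactors = FALSE),
    query_len = 20L), class = "domain_assignment")
  expect_identical(merge_short_regions(none)$segments$address, "UNASSIGNED")
})

test_that("assigned addresses always follow the SCOP address pattern", {
  set.seed(12)
  for (rep in 1:25) {
    qlen <- sample(40:200, 1)
    hits <- random_hit_table(qlen, sample(1:4, 1),
                             rng_pool_e = c(1e-4, 1e-3, 5e-3),
                             rng_pool_z = c(5, 6, 7.5))
    da <- assign_domains(qlen, make_hit_script(hits))
    assigned <- setdiff(da$segments$address, "UNASSIGNED")
    if (length(assigned)) {
      expect_true(all(grepl("^[A-Za-z]+\\.\\d+\\.\\d+\\.\\d+$", assigned)))
    }
  }
})

test_that("raising the Z threshold never adds assigned residues", {
  set.seed(13)
  for (rep in 1:20) {
    qlen <- sample(60:200, 1)
    hits <- random_hit_table(qlen, 4L,
                             rng_pool_e = c(1e-4, 5e-3),
                             rng_pool_z = c(4.6, 5.5, 6.5, 8))
    bk <- make_hit_script(hits)
    counts <- vapply(c(4.5, 5.0, 6.0, 7.0), function(z) {
      da <- assign_domains(qlen, bk, params = assign_params(z_min = z))
      seg <- da$segments[da$segments$address != "UNASSIGNED", , drop = FALSE]
      sum(seg$end - seg$start + 1L)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("segments always partition the query exactly", {
  set.seed(14)
  for (rep in 1:30) {
    qlen <- sample(31:150, 1)
    hits <- random_hit_table(qlen, sample(0:4, 1),
                             rng_pool_e = c(1e-3, 0.02),
                             rng_pool_z = c(4, 5, 6))
    da <- assign_domains(qlen, make_hit_script(hits))
    seg <- da$segments
    expect_identical(seg$start[1], 1L)
    expect_identical(seg$end[nrow(seg)], qlen)
    if (nrow(seg) > 1L) {
      expect_identical(seg$start[-1], seg$end[-nrow(seg)] + 1L)
    }
  }
})

test_that("the multi-domain overlap evaluation utility scores 80% coverage", {
  pred <- data.frame(start = c(1L, 81L), end = c(80L, 200L),
                     address = c("A.1.1.1", "B.34.9.1"))
  refd <- data.frame(start = c(1L, 101L), end = c(100L, 200L),
                     address = c("A.1.1.1", "B.34.9.1"))
  got <- domain_overlap_correct(pred, refd)
  expect_identical(got, c(TRUE, TRUE))   # 80/100 and 100/100
  refd2 <- data.frame(start = 1L, end = 101L, address = "A.1.1.1")
  expect_false(domain_overlap_correct(pred, refd2))  # 80/101 < 0.8
})
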