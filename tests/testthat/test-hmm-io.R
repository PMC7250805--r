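tblout_fixture <- c(
  "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
  "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
  "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- --- --- --- --- --- --- --- --- ---------------------",
  "seqA                 -          profX                PF00001      1.2e-30   98.7   0.1   2.2e-30   97.1   0.1 1.1   1   0   0   1   1   1   1 hypothetical protein",
  "seqB                 -          profY                PF00002      3.4e-05   12.5   0.0   5.1e-05   11.9   0.0 1.0   1   0   0   1   1   1   1 -"
)

test_that("tblout parsing extracts full-sequence score and E-value in both orientations", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(tblout_fixture, path)
  rec <- read_tblout(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$sequence_id, c("seqA", "seqB"))
  expect_equal(rec$profile_id, c("profX", "profY"))
  expect_equal(rec$score, c(98.7, 12.5))
  expect_equal(rec$evalue, c(1.2e-30, 3.4e-05))
  scan <- read_tblout(path, orientation = "hmmscan")
  expect_equal(scan$sequence_id, c("profX", "profY"))
  expect_equal(scan$profile_id, c("seqA", "seqB"))
})

test_that("comment-only files give empty records and malformed lines name their line number", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(tblout_fixture[1:3], path)
  expect_equal(nrow(read_tblout(path)), 0)
  writeLines(c(tblout_fixture[1:4], "seqC - profZ PF9 oops 12.0"), path)
  expect_error(read_tblout(path), "line 5")
  writeLines(c("seqC - profZ"), path)
  expect_error(read_tblout(path), "line 1")
  expect_error(read_tblout(file.path(tempdir(), "nope.tbl")), "no such file")
})

test_that("matrix assembly imputes, keeps the best duplicate hit, and is order-independent", {
  rec <- data.frame(
    sequence_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    profile_id = c("pA", "pB", "pC", "pA", "pB", "pB"),
    score = c(10, 20, 30, 5.5, 5.0, 7.5),
    evalue = 0
  )
  fmap <- c(pA = "FA", pB = "FB", pC = "FC")
  sm <- suppressMessages(build_score_matrix(rec, fmap))
  expect_s3_class(sm, "score_matrix")
  expect_equal(dim(sm$values), c(2L, 3L))
  expect_equal(unname(sm$values["s1", ]), c(10, 20, 30))
  expect_equal(unname(sm$values["s2", "FB"]), 7.5) # max of duplicates
  expect_equal(unname(sm$values["s2", "FC"]), 0) # imputed
  expect_equal(attr(sm, "imputed"), 1L)
  shuffled <- rec[c(5, 3, 6, 1, 4, 2), ]
  expect_equal(suppressMessages(build_score_matrix(shuffled, fmap))$values, sm$values)
  expect_error(build_score_matrix(rec, c(pA = "FA", pB = "FB")), "min\\|A\\| = 3")
  # a sequence hit by too few profiles is dropped
  rec2 <- rbind(rec, data.frame(
    sequence_id = "s3", profile_id = "pA", score = 1, evalue = 0
  ))
  sm2 <- suppressMessages(build_score_matrix(rec2, fmap))
  expect_equal(attr(sm2, "dropped"), "s3")
})

test_that("score matrices round-trip losslessly through TSV", {
  sim <- tiny_sim(separation = 2, per = 4, seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(sim$scores, path)
  back <- read_score_matrix(path)
  expect_equal(back$values, sim$scores$values, tolerance = 1e-12)
  expect_identical(back$labels, sim$scores$labels)
})

test_that("label tables apply the SSI > 1.00 training filter when the column is present", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence_id\tfunction_label\tssi",
    "s1\tFA\t1.5",
    "s2\tFB\t0.8",
    "s3\tFC\t1.01"
  ), path)
  labs <- suppressMessages(read_labels(path))
  expect_equal(labs, c(s1 = "FA", s3 = "FC"))
  writeLines(c("sequence_id\tfunction_label", "s1\tFA"), path)
  expect_equal(read_labels(path), c(s1 = "FA"))
  writeLines(c("id\tlabel", "s1\tFA"), path)
  expect_error(read_labels(path), "columns")
})

test_that("FASTA ids are read for universe bookkeeping", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq1 some description", "MKT", ">seq2", "MAR"), path)
  expect_equal(read_fasta_ids(path), c("seq1", "seq2"))
})
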