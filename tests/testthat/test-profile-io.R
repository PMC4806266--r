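test_that("read_pssm recovers the written matrix and reorders columns", {
  f <- withr::local_tempfile(fileext = ".pssm")
  write_fixture_pssm(f, "ACD", matrix(0L, 3, 20))
  prof <- read_pssm(f, "p")
  expect_s3_class(prof, "pssm_profile")
  expect_equal(unname(prof$scores), matrix(0, 3, 20))
  expect_equal(prof$residues, "ACD")

  # score lands in the column named in the file header even when the header
  # order is permuted
  perm <- rev(canonical)
  scores <- matrix(0L, 1, 20)
  scores[1, 1] <- 2L   # first column of the permuted header, i.e. V
  f2 <- withr::local_tempfile(fileext = ".pssm")
  write_fixture_pssm(f2, "A", scores, column_order = perm)
  prof2 <- read_pssm(f2, "p")
  expect_equal(unname(prof2$scores[1, "V"]), 2)
  expect_equal(unname(prof2$scores[1, "A"]), 0)
})

test_that("read_pssm round-trips random integer matrices", {
  set.seed(3)
  res <- paste(sample(canonical, 12, replace = TRUE), collapse = "")
  m <- matrix(sample(-9L:9L, 12 * 20, replace = TRUE), 12, 20)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_fixture_pssm(f, res, m)
  prof <- read_pssm(f, "p")
  expect_equal(unname(prof$scores), m + 0)
  expect_equal(prof$residues, res)
})

test_that("malformed PSSM rows are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "title", paste(canonical, collapse = " "),
               paste(c("1", "A", rep("0", 19)), collapse = " ")), f)
  expect_error(read_pssm(f), "line 4")

  f2 <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "title", paste(canonical, collapse = " "),
               paste(c("1", "A", "x", rep("0", 19)), collapse = " ")), f2)
  expect_error(read_pssm(f2), "non-numeric")
})

test_that("read_ss2 parses states and rejects unknown letters", {
  f <- withr::local_tempfile(fileext = ".ss2")
  write_fixture_ss2(f, "AAAAAAAAA", "HHHHHHHHH")
  prof <- read_ss2(f, "p")
  expect_equal(prof$states, "HHHHHHHHH")

  empty <- withr::local_tempfile(fileext = ".ss2")
  file.create(empty)
  expect_error(read_ss2(empty), "no secondary-structure rows")

  bad <- withr::local_tempfile(fileext = ".ss2")
  write_fixture_ss2(bad, "AAA", "HGH")
  expect_error(read_ss2(bad), "unknown secondary-structure state")
})

test_that("read_disorder parses probabilities, marks and thresholds", {
  f <- withr::local_tempfile(fileext = ".diso")
  write_fixture_diso(f, "AAA", c(0, 0, 0))
  prof <- read_disorder(f, "p")
  expect_equal(prof$calls, c(0L, 0L, 0L))

  f2 <- withr::local_tempfile(fileext = ".diso")
  write_fixture_diso(f2, "AA", c(0.9, 0.2))
  expect_equal(read_disorder(f2)$calls, c(1L, 0L))

  f3 <- withr::local_tempfile(fileext = ".diso")
  write_fixture_diso(f3, "AA", c(0.9, 0.2), marks = c("*", "."))
  expect_equal(read_disorder(f3)$calls, c(1L, 0L))

  f4 <- withr::local_tempfile(fileext = ".diso")
  writeLines("1 A 1.2", f4)
  expect_error(read_disorder(f4), "outside \\[0, 1\\]")
})

test_that("slice_profile aligns rows to the window and zero-fills padding", {
  seqn <- "MAAAYAAAAC"
  m <- matrix(seq_len(10 * 20), 10, 20, dimnames = list(NULL, canonical))
  prof <- make_profiles("p", seqn, scores = m,
                        probs = seq(0.1, 1, by = 0.1))
  win_mid <- list(protein_id = "p", center = 5L, residues = "MAAAYAAAA")
  s <- slice_profile(prof$pssm, win_mid)
  expect_equal(unname(s$scores), unname(m[1:9, ]))
  expect_false(any(s$padded))

  # tyrosine at position 5 with xi = 4 touches position 1; shift center so
  # the window starts before the protein
  prof2 <- make_profiles("p", "YAAAAAAA",
                         scores = matrix(1, 8, 20),
                         probs = rep(0.7, 8))
  win_edge <- list(protein_id = "p", center = 1L, residues = "XXXXYAAAA")
  s2 <- slice_profile(prof2$pssm, win_edge)
  expect_equal(s2$padded, c(rep(TRUE, 4), rep(FALSE, 5)))
  expect_equal(unname(s2$scores[1:4, ]), matrix(0, 4, 20))
  expect_equal(unname(s2$scores[5:9, ]), matrix(1, 5, 20))

  d2 <- slice_profile(prof2$diso, win_edge)
  expect_equal(d2$probabilities, c(rep(0, 4), rep(0.7, 5)))
  ss2 <- slice_profile(prof2$ss, win_edge)
  expect_equal(ss2$states, rep("C", 9))
  expect_equal(ss2$padded[1:4], rep(TRUE, 4))
})

test_that("slice_profile rejects windows from another protein", {
  prof <- make_profiles("p", "AAAAYAAAA")
  win <- list(protein_id = "other", center = 5L)
  expect_error(slice_profile(prof$pssm, win), "does not match")
})

test_that("slices always have window length regardless of position", {
  prof <- make_profiles("p", "YAYAYAYAY")
  for (ctr in c(1L, 3L, 5L, 9L)) {
    win <- list(protein_id = "p", center = ctr)
    expect_length(slice_profile(prof$diso, win)$probabilities, 9)
    expect_equal(nrow(slice_profile(prof$pssm, win)$scores), 9)
  }
})

test_that("load_profiles reports missing files by protein", {
  d <- withr::local_tempdir()
  expect_error(load_profiles(d, "nope"), "nope")
})
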