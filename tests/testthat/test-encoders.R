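test_that("PSSM aggregation sums scores into native-residue rows", {
  # all-padding window contributes nothing
  expect_equal(encode_pssm_block(strrep("X", 9), matrix(1, 9, 20)),
               rep(0, 400))

  # uniform score 2 in column A: the eight A positions sum into cell
  # (A -> A) = 16 and the central tyrosine into cell (Y -> A) = 2
  rows <- matrix(0, 9, 20, dimnames = list(NULL, canonical))
  rows[, "A"] <- 2
  v <- encode_pssm_block("AAAAYAAAA", rows)
  names(v) <- feature_names()[1:400]
  expect_equal(unname(v["pssm_A_to_A"]), 16)
  expect_equal(unname(v["pssm_Y_to_A"]), 2)
  expect_equal(sum(v), 18)
  expect_equal(sum(v != 0), 2)
})

test_that("PSSM aggregation conserves the total input score", {
  set.seed(21)
  for (rep in 1:10) {
    res <- c(sample(canonical, 4, replace = TRUE), "Y",
             sample(canonical, 4, replace = TRUE))
    n_pad <- sample(0:3, 1)
    if (n_pad > 0) res[seq_len(n_pad)] <- "X"
    rows <- matrix(rnorm(180), 9, 20)
    v <- encode_pssm_block(paste(res, collapse = ""), rows)
    expect_equal(sum(v), sum(rows[res != "X", ]))
  }
})

test_that("secondary-structure statistics follow count/run/percentage rules", {
  expect_equal(encode_ss_block(rep("H", 9)),
               c(9, 0, 0, 9, 0, 0, 100, 0, 0))
  expect_equal(encode_ss_block(c(rep("H", 3), rep("C", 3), rep("E", 3))),
               c(3, 3, 3, 3, 3, 3, 100 / 3, 100 / 3, 100 / 3))
  # fully padded window degenerates to zeros
  expect_equal(encode_ss_block(rep("C", 9), padded = rep(TRUE, 9)),
               rep(0, 9))
  # padding breaks runs: H H <pad> H -> two runs of H
  st <- c("H", "H", "C", "H", "E", "E", "C", "C", "C")
  pad <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  v <- encode_ss_block(st, pad)
  expect_equal(v[1], 3)          # Tnum_H
  expect_equal(v[4], 3 / 2)      # Avelen_H: 3 positions over 2 runs
  expect_equal(sum(v[7:9]), 100) # Comper sums to 100 over non-padded
  expect_error(encode_ss_block(c(rep("H", 8), "G")), "H, E or C")
})

test_that("disorder block is the identity on aligned probabilities", {
  p <- seq(0.1, 0.9, by = 0.1)
  expect_equal(encode_disorder_block(p), p)
  expect_equal(encode_disorder_block(rep(0, 9)), rep(0, 9))
  expect_error(encode_disorder_block(rep(0, 8)), "expected 9")
})

test_that("physicochemical block looks residues up position-major", {
  expect_equal(encode_physchem_block(strrep("X", 9)), rep(0, 54))
  v <- encode_physchem_block("AAAAYAAAA")
  expect_length(v, 54)
  sc <- physchem_scales()
  a_vals <- vapply(sc, `[[`, numeric(1), "A")
  y_vals <- vapply(sc, `[[`, numeric(1), "Y")
  expect_equal(unname(v[1:6]), unname(a_vals))        # position 1 = A
  expect_equal(unname(v[25:30]), unname(y_vals))      # position 5 = Y
  expect_error(encode_physchem_block("AAAABAAAA"), "outside")
})

test_that("each physicochemical scale covers exactly the 20 residues", {
  for (sc in physchem_scales()) {
    expect_setequal(names(sc), canonical)
    expect_true(all(is.finite(sc)))
  }
})

test_that("fuse_blocks enforces the 400/9/9/54 layout", {
  v <- fuse_blocks(rep(0, 400), rep(0, 9), rep(0, 9), rep(0, 54))
  expect_length(v, 472)
  expect_equal(unname(v), rep(0, 472))
  expect_equal(names(v), feature_names())
  expect_error(fuse_blocks(rep(0, 399), rep(0, 9), rep(0, 9), rep(0, 54)),
               "width")
  layout <- feature_layout()
  expect_equal(layout$width, c(400L, 9L, 9L, 54L))
  expect_equal(sum(layout$width), 472L)
  expect_equal(layout$share_pct[layout$block == "pssm"], 100 * 400 / 472)
})

test_that("encode_dataset is deterministic and validates profiles", {
  proteins <- data.frame(id = c("a", "b"),
                         sequence = c("MAAAYAAAAC", "CCYCCCCCCC"))
  ann <- data.frame(protein_id = "a", position = 5L, label = 1L)
  windows <- build_windows(proteins, ann)
  profiles <- list(a = make_profiles("a", proteins$sequence[1]),
                   b = make_profiles("b", proteins$sequence[2]))
  enc1 <- encode_dataset(windows, profiles)
  enc2 <- encode_dataset(windows, profiles)
  expect_identical(enc1$x, enc2$x)
  expect_equal(dim(enc1$x), c(2L, 472L))
  expect_equal(rownames(enc1$x), c("a:5", "b:3"))
  expect_equal(enc1$y, c(1L, 0L))

  expect_error(encode_dataset(windows, profiles["a"]), "b")
  empty <- windows[0, ]
  expect_equal(dim(encode_dataset(empty, profiles)$x), c(0L, 472L))
})

test_that("feature TSV round-trips the matrix and labels", {
  proteins <- data.frame(id = "a", sequence = "MAAAYAAAAC")
  ann <- data.frame(protein_id = "a", position = 5L, label = 1L)
  windows <- build_windows(proteins, ann)
  enc <- encode_dataset(windows,
                        list(a = make_profiles("a", proteins$sequence)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(enc, f)
  back <- read_feature_tsv(f)
  expect_equal(back$x, enc$x)
  expect_equal(back$y, enc$y)
})
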