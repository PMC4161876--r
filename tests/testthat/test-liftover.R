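test_that("TSS windows are centered, clipped and id-preserving", {
  tt <- tibble::tibble(id = "r1", chrom = "c1", tss = 1000)
  w <- build_tss_windows(tt, 200)
  expect_equal(c(w$start, w$end), c(900, 1100))

  w <- build_tss_windows(tibble::tibble(id = "r2", chrom = "c1", tss = 50), 200)
  expect_equal(c(w$start, w$end), c(0, 150))

  expect_error(build_tss_windows(tt, 199), "even")

  # one window per TSS with ids preserved, at the full catalogue size
  many <- tibble::tibble(id = sprintf("r%03d", 1:955), chrom = "c1",
                         tss = seq(1000, by = 500, length.out = 955))
  w <- build_tss_windows(many)
  expect_equal(nrow(w), 955L)
  expect_equal(w$id, many$id)
  expect_true(all(w$end - w$start == 200))
})

test_that("identity chains map intervals onto themselves", {
  cs <- identity_chain(10000)
  iv <- tibble::tibble(id = "x", chrom = "c1", start = 123, end = 456)
  res <- lift_intervals(iv, cs)
  expect_equal(res$status, "mapped")
  expect_equal(c(res$tgt_start, res$tgt_end), c(123, 456))
  expect_equal(res$mapped_fraction, 1.0)
})

test_that("intervals inside source gaps are unmapped", {
  cs <- mk_chain_set(list(list(
    id = 1L, score = 10, src_chrom = "c1", tgt_chrom = "t1", strand = "+",
    blocks = data.frame(src_start = c(0, 500), src_end = c(100, 600),
                        tgt_start = c(0, 100), tgt_end = c(100, 200))
  )))
  res <- lift_intervals(
    tibble::tibble(id = "g", chrom = "c1", start = 200, end = 300), cs
  )
  expect_equal(res$status, "unmapped")
  expect_equal(res$mapped_fraction, 0)
})

test_that("lift agrees with the per-base brute-force oracle on random chains", {
  set.seed(101)
  for (rep in 1:5) {
    cs <- random_chain_set()
    ivs <- tibble::tibble(
      id = sprintf("i%03d", 1:60),
      chrom = sample(c("c1", "c2"), 60, TRUE),
      start = sample(0:5200, 60, TRUE)
    )
    ivs$end <- ivs$start + sample(5:250, 60, TRUE)
    res <- lift_intervals(ivs, cs, min_match = 0.9)
    for (i in seq_len(nrow(ivs))) {
      oracle <- brute_lift(ivs$chrom[i], ivs$start[i], ivs$end[i], cs,
                           min_match = 0.9)
      expect_equal(res$status[i], oracle$status)
      if (!is.na(oracle$tgt_start)) {
        expect_equal(res$tgt_start[i], oracle$tgt_start)
        expect_equal(res$tgt_end[i], oracle$tgt_end)
        expect_equal(res$chain_id[i], oracle$chain_id)
        expect_equal(res$mapped_fraction[i], oracle$mapped_fraction)
      }
    }
  }
})

test_that("minus-strand lifting round-trips through the reverse chain", {
  n <- 1000
  flip <- mk_chain_set(list(list(
    id = 1L, score = 10, src_chrom = "c1", tgt_chrom = "c1", strand = "-",
    blocks = data.frame(src_start = 0, src_end = n, tgt_start = 0, tgt_end = n)
  )))
  iv <- tibble::tibble(id = "w", chrom = "c1", start = 100, end = 220,
                       strand = "+")
  once <- lift_intervals(iv, flip)
  expect_equal(once$status, "mapped")
  expect_equal(once$tgt_strand, "-")
  expect_equal(c(once$tgt_start, once$tgt_end), c(n - 220, n - 100))
  twice <- lift_intervals(
    tibble::tibble(id = "w", chrom = "c1", start = once$tgt_start,
                   end = once$tgt_end, strand = once$tgt_strand),
    flip
  )
  expect_equal(c(twice$tgt_start, twice$tgt_end), c(iv$start, iv$end))
  expect_equal(twice$tgt_strand, "+")
})

test_that("raising min_match at fixed gap tolerance only downgrades to low_coverage", {
  set.seed(77)
  for (rep in 1:3) {
    cs <- random_chain_set()
    ivs <- tibble::tibble(
      id = sprintf("i%02d", 1:40), chrom = sample(c("c1", "c2"), 40, TRUE),
      start = sample(0:5000, 40, TRUE)
    )
    ivs$end <- ivs$start + sample(10:200, 40, TRUE)
    lo <- lift_intervals(ivs, cs, min_match = 0.5, gap_tolerance = 10)
    hi <- lift_intervals(ivs, cs, min_match = 0.99, gap_tolerance = 10)
    was_mapped <- lo$status == "mapped"
    expect_true(all(hi$status[was_mapped] %in% c("mapped", "low_coverage")))
    still <- was_mapped & hi$status == "mapped"
    expect_equal(hi$tgt_start[still], lo$tgt_start[still])
    expect_equal(hi$tgt_end[still], lo$tgt_end[still])
    expect_true(all(hi$status[!was_mapped] == lo$status[!was_mapped]))
  }
})

test_that("collision dedup keeps the first window and reports the rest", {
  cs <- identity_chain(10000)
  w <- tibble::tibble(id = c("a", "b"), chrom = "c1",
                      start = c(100, 400), end = c(300, 600), strand = "+")
  out <- lift_windows_dedup(w, cs)
  expect_length(out$discarded, 0)

  # three windows engineered onto identical target coordinates
  cs3 <- mk_chain_set(list(
    list(id = 1L, score = 30, src_chrom = "c1", tgt_chrom = "t1", strand = "+",
         blocks = data.frame(src_start = 100, src_end = 300,
                             tgt_start = 5000, tgt_end = 5200)),
    list(id = 2L, score = 20, src_chrom = "c1", tgt_chrom = "t1", strand = "+",
         blocks = data.frame(src_start = 1100, src_end = 1300,
                             tgt_start = 5000, tgt_end = 5200)),
    list(id = 3L, score = 10, src_chrom = "c1", tgt_chrom = "t1", strand = "+",
         blocks = data.frame(src_start = 2100, src_end = 2300,
                             tgt_start = 5000, tgt_end = 5200))
  ))
  w3 <- tibble::tibble(id = c("a", "b", "c"), chrom = "c1",
                       start = c(100, 1100, 2100), end = c(300, 1300, 2300),
                       strand = "+")
  out <- lift_windows_dedup(w3, cs3)
  expect_equal(out$discarded, c("b", "c"))
  expect_equal(out$results$discarded, c(FALSE, TRUE, TRUE))
})
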