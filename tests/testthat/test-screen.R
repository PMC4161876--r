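test_that("pooling sums the selected libraries and validates the subset", {
  counts <- tibble::tibble(
    id = rep(c("a", "b"), each = 2),
    library = rep(c("l1", "l2"), 2),
    count = c(3L, 4L, 1L, 0L)
  )
  expect_equal(pool_counts(counts, "l1")$pooled_count, c(3L, 1L))
  pooled <- pool_counts(counts, c("l1", "l2"))
  expect_equal(pooled$pooled_count[pooled$id == "a"], 7L)
  expect_error(pool_counts(counts, character(0)), "non-empty")
  expect_error(pool_counts(counts, "l9"), "l9")

  # random fixture against independent summation
  set.seed(13)
  big <- tidyr::expand_grid(id = sprintf("w%02d", 1:20),
                            library = sprintf("l%d", 1:4)) |>
    dplyr::mutate(count = rpois(dplyr::n(), 30))
  sub <- c("l2", "l4")
  got <- pool_counts(big, sub)
  want <- tapply(
    big$count[big$library %in% sub], big$id[big$library %in% sub], sum
  )
  expect_equal(got$pooled_count, as.vector(want[got$id]))
})

test_that("the third-quartile filter uses a strict cutover", {
  same <- rep(7, 10)
  qf <- quartile_filter(same)
  expect_equal(qf$q3, 7)
  expect_false(any(qf$flags))

  qf <- quartile_filter(1:100)
  expect_equal(qf$q3, 75.25)
  expect_equal(sum(qf$flags), 25L)

  qf_nr <- quartile_filter(1:100, method = "nearest")
  expect_equal(qf_nr$q3, 75)
  expect_equal(sum(qf_nr$flags), 25L)

  expect_error(quartile_filter(1:3), "at least 4")

  # permutation invariance of the quartile
  set.seed(14)
  x <- rpois(50, 40)
  expect_equal(quartile_filter(x)$q3, quartile_filter(sample(x))$q3)
})

test_that("the absolute cutoff is strict and has a permissive zero limit", {
  expect_false(absolute_cutoff_filter(100, 100))
  expect_true(absolute_cutoff_filter(101, 100))
  counts <- c(0, 1, 5)
  expect_equal(absolute_cutoff_filter(counts, 0), c(FALSE, TRUE, TRUE))
})

test_that("artifact flagging distinguishes gene, pseudogene and empty space", {
  ann <- tibble::tibble(
    locus_id = c("g1", "ps1"), chrom = "chrT",
    start = c(1000L, 9000L), end = c(2000L, 10000L), strand = "+",
    tss = c(1000L, 9000L), biotype = c("gene", "pseudogene")
  )
  w <- tibble::tibble(
    tgt_chrom = "chrT",
    tgt_start = c(1500, 50000, 9100), tgt_end = c(1700, 50200, 9300)
  )
  expect_equal(flag_artifacts(w, ann), c(FALSE, TRUE, TRUE))
  expect_equal(flag_artifacts(w, ann, pseudogene_is_artifact = FALSE),
               c(FALSE, TRUE, FALSE))
  # proximity radius rescues near-but-not-overlapping windows
  w2 <- tibble::tibble(tgt_chrom = "chrT", tgt_start = 2500, tgt_end = 2700)
  expect_true(flag_artifacts(w2, ann))
  expect_false(flag_artifacts(w2, ann, max_distance = 1000))
})

test_that("TSS positions classify by signed upstream distance", {
  # plus-strand locus [10000, 12000)
  cls <- function(pos, strand = "+") {
    classify_tss_position(pos, 10000, 12000, strand)
  }
  expect_equal(cls(10000), "at_annotated_start")
  expect_equal(cls(10040), "at_annotated_start")
  expect_equal(cls(9000), "upstream_proximal")   # d = 1000
  expect_equal(cls(4000), "upstream_far_discard") # d = 6000
  expect_equal(cls(11000), "intragenic")
  expect_equal(cls(11900), "three_prime_end")
  expect_equal(cls(9800), "unclassified")         # gap between tolerances
  expect_equal(cls(NA), "unclassified")

  # minus-strand locus: upstream means larger coordinates
  clsm <- function(pos) classify_tss_position(pos, 10000, 12000, "-")
  expect_equal(clsm(11999), "at_annotated_start")
  expect_equal(clsm(13000), "upstream_proximal")
  expect_equal(clsm(18500), "upstream_far_discard")
  expect_equal(clsm(10100), "three_prime_end")
  expect_equal(clsm(11000), "intragenic")
})

test_that("the full cascade recovers planted candidates and flags decoys", {
  cfg <- simulation_config(seed = 61)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  w <- build_tss_windows(
    dplyr::select(g$src_annotation, id = locus_id, chrom, tss, strand)
  )
  scr <- run_screen(ctss, w, g$chains, g$tgt_annotation,
                    library_subset = sort(unique(ctss$library)))
  cand <- tidy(scr)
  truth <- g$truth

  planted <- truth$id[truth$expressed & truth$mapped & !truth$collision_second]
  expect_setequal(cand$id[cand$verdict == "candidate"], planted)
  decoys <- truth$id[truth$decoy]
  expect_setequal(cand$id[cand$artifact], decoys)
  expect_equal(sort(scr$discarded), sort(truth$id[truth$collision_second]))

  # verdict consistency with the flags
  expect_true(all(cand$above_abs_cutoff[cand$verdict == "candidate"]))
  expect_true(all(
    cand$pooled_count[which(cand$above_abs_cutoff)] > scr$params$abs_cutoff
  ))

  # determinism of the whole cascade
  scr2 <- run_screen(simulate_ctss(cfg, g), w, g$chains, g$tgt_annotation,
                     library_subset = sort(unique(ctss$library)))
  expect_identical(tidy(scr2), cand)
})

test_that("background-only libraries yield no candidates", {
  cfg <- simulation_config(seed = 62, n_expressed = 0, collision_pairs = 0,
                           background_rate = 0.002, decoy_tpm = 0)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  w <- build_tss_windows(
    dplyr::select(g$src_annotation, id = locus_id, chrom, tss, strand)
  )
  scr <- run_screen(ctss, w, g$chains, g$tgt_annotation,
                    library_subset = sort(unique(ctss$library)))
  expect_equal(unname(scr$stage_counts["n_candidates"]), 0L)
})

test_that("raising the absolute cutoff never adds a candidate", {
  cfg <- simulation_config(seed = 63)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  w <- build_tss_windows(
    dplyr::select(g$src_annotation, id = locus_id, chrom, tss, strand)
  )
  libs <- sort(unique(ctss$library))
  prev <- NULL
  for (cutoff in c(50, 150, 400, 1000)) {
    scr <- run_screen(ctss, w, g$chains, g$tgt_annotation,
                      library_subset = libs, abs_cutoff = cutoff)
    ids <- tidy(scr)$id[tidy(scr)$verdict == "candidate"]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("screen accessors expose stage counts, q3 and plots", {
  cfg <- simulation_config(seed = 64, n_libraries = 2)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  w <- build_tss_windows(
    dplyr::select(g$src_annotation, id = locus_id, chrom, tss, strand)
  )
  scr <- run_screen(ctss, w, g$chains, g$tgt_annotation,
                    library_subset = sort(unique(ctss$library)))
  gl <- glance(scr)
  expect_equal(gl$n_windows, nrow(w))
  expect_equal(gl$q3, scr$q3)
  expect_s3_class(autoplot(scr), "ggplot")
  expect_output(print(scr), "candidate screen")
  # per-library count columns ride along the candidate table
  expect_true(all(c("n_lib01", "n_lib02") %in% names(tidy(scr))))
})
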