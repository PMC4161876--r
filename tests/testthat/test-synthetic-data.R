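test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 11)
  g1 <- simulate_genomes(cfg)
  g2 <- simulate_genomes(cfg)
  expect_identical(g1$truth, g2$truth)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_chain(g1$chains, f1); write_chain(g2$chains, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(simulate_ctss(cfg, g1), simulate_ctss(cfg, g2))
  expect_identical(simulate_calcium(cfg)$traces, simulate_calcium(cfg)$traces)
})

test_that("library totals equal the requested depth exactly", {
  cfg <- simulation_config(seed = 3, depth_per_library = 20000)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  tot <- library_totals(ctss)
  expect_equal(tot$total_tags, rep(20000L, cfg$n_libraries))
})

test_that("no expression and no background gives empty libraries", {
  cfg <- simulation_config(
    seed = 5, n_expressed = 0, n_pseudogenes = 0, collision_pairs = 0,
    background_rate = 0
  )
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  expect_equal(nrow(ctss), 0L)
})

test_that("planted collisions produce exactly the designed duplicate lifts", {
  cfg0 <- simulation_config(seed = 21, collision_pairs = 0)
  g0 <- simulate_genomes(cfg0)
  w0 <- build_tss_windows(
    dplyr::select(g0$src_annotation, id = locus_id, chrom, tss, strand)
  )
  out0 <- lift_windows_dedup(w0, g0$chains)
  expect_length(out0$discarded, 0)

  cfg3 <- simulation_config(seed = 21, collision_pairs = 3)
  g3 <- simulate_genomes(cfg3)
  w3 <- build_tss_windows(
    dplyr::select(g3$src_annotation, id = locus_id, chrom, tss, strand)
  )
  out3 <- lift_windows_dedup(w3, g3$chains)
  truth_seconds <- g3$truth$id[g3$truth$collision_second]
  expect_equal(sort(out3$discarded), sort(truth_seconds))
  # each discarded window shares coordinates with its designated partner
  res <- out3$results
  for (k in seq_along(truth_seconds)) {
    second <- res[res$id == truth_seconds[k], ]
    partner_id <- g3$truth$collision_partner[g3$truth$id == truth_seconds[k]]
    partner <- res[res$id == partner_id, ]
    expect_equal(second$tgt_start, partner$tgt_start)
    expect_equal(second$tgt_end, partner$tgt_end)
    expect_equal(second$tgt_strand, partner$tgt_strand)
    expect_false(partner$discarded)
  }
})

test_that("planted promoter shapes show the requested tag dispersion", {
  cfg <- simulation_config(seed = 31, n_receptors = 30, n_expressed = 20,
                           collision_pairs = 0, unmapped_receptors = 0,
                           depth_per_library = 2e5)
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  loci <- g$tgt_annotation |>
    dplyr::semi_join(
      g$truth |> dplyr::filter(expressed) |>
        dplyr::select(locus_id = tgt_id),
      by = "locus_id"
    )
  prof <- promoter_profiles(
    ctss, loci |> dplyr::select(id = locus_id, chrom, start, end, strand)
  ) |>
    dplyr::left_join(
      g$truth |> dplyr::select(id = tgt_id, shape), by = "id"
    ) |>
    dplyr::filter(total_tags >= 200)
  sharp <- prof |> dplyr::filter(shape == "sharp")
  broad <- prof |> dplyr::filter(shape == "broad")
  expect_gt(nrow(sharp), 0); expect_gt(nrow(broad), 0)
  expect_true(all(sharp$dominant_fraction >= 0.85))
  expect_true(all(broad$iq_width >= cfg$broad_width / 2 &
                    broad$iq_width <= 2 * cfg$broad_width))
})

test_that("a planted sharp promoter realises its expected TPM", {
  cfg <- simulation_config(
    seed = 8, n_receptors = 1, n_expressed = 1, n_pseudogenes = 0,
    collision_pairs = 0, unmapped_receptors = 0, n_libraries = 1,
    depth_per_library = 1e6, expressed_tpm = 4.29, sharp_fraction = 1,
    background_rate = 0
  )
  g <- simulate_genomes(cfg)
  ctss <- simulate_ctss(cfg, g)
  cnt <- sum5end(ctss, g$tgt_annotation)
  realized <- tpm(cnt$count, library_totals(ctss)$total_tags)
  sd_tpm <- sqrt(1e6 * 4.29e-6)  # binomial SD of the count, on the TPM scale
  expect_lt(abs(realized - 4.29), 3 * sd_tpm)
})

test_that("calcium truth matches the configured population design", {
  # responder_fraction 0: all flat up to channel noise
  cfg0 <- simulation_config(seed = 41, responder_fraction = 0)
  ca0 <- simulate_calcium(cfg0)
  expect_false(any(ca0$truth$responder))
  calls0 <- calcium_calls(ca0$traces, cfg0$stim_on, cfg0$stim_off)
  expect_true(all(calls0$peak_pct < 15))

  # responder_fraction 1 with no noise: every trace crosses any threshold
  cfg1 <- simulation_config(seed = 42, responder_fraction = 1,
                            channel_noise_sd = 0)
  ca1 <- simulate_calcium(cfg1)
  calls1 <- calcium_calls(ca1$traces, cfg1$stim_on, cfg1$stim_off)
  expect_true(all(calls1$peak_pct > 20))
  expect_true(all(calls1$responder))

  # n = 37 at fraction 11/37: expected responder count is 11
  counts <- vapply(1:20, function(s) {
    sum(simulate_calcium(simulation_config(seed = 100 + s))$truth$responder)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 11), 3 * sqrt(11 * (26 / 37)) / sqrt(20))
})

test_that("simulated files parse cleanly through every reader", {
  dir <- withr::local_tempdir()
  out <- simulate_dataset(simulation_config(seed = 51, n_libraries = 2), dir)
  ctss <- read_ctss(out$paths$lib01)
  expect_gt(nrow(ctss), 0)
  cs <- read_chain(out$paths$chain)
  expect_equal(nrow(cs$chains), nrow(out$genomes$chains$chains))
  expect_equal(nrow(read_bed(out$paths$src_bed)),
               nrow(out$genomes$src_annotation))
  expect_equal(nrow(read_bed(out$paths$tgt_bed)),
               nrow(out$genomes$tgt_annotation))
  expect_equal(sort(names(read_fasta(out$paths$fasta))),
               sort(names(out$msa)))
  expect_equal(nrow(read_ct_table(out$paths$ct)), nrow(out$ct$ct))
  expect_equal(nrow(read_traces(out$paths$traces)), nrow(out$calcium$traces))
})
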