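#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' Defaults encode the study conditions the pipeline is exercised under:
#' three collision pairs of receptor windows lifting to identical
#' coordinates, pseudogene decoy loci with spurious tag pile-ups, broad
#' promoters dispersed over ~100 bp, and calcium responders with amplitude
#' 80.5 +/- 26 percent dR/R0 at a responder fraction of 11/37.
#'
#' @param seed Integer seed; all generators are fully deterministic given it.
#' @param n_receptors Source-genome receptor loci.
#' @param n_pseudogenes Target-genome pseudogene decoy loci (each hit by a
#'   lifted window).
#' @param n_libraries CAGE libraries to simulate.
#' @param depth_per_library Total tags per library (the TPM denominator).
#' @param n_expressed Receptors with a planted expressed promoter in the
#'   target genome.
#' @param expressed_tpm Planted expression level(s), TPM: a length-2 vector
#'   is a log-uniform range to draw from; any other length gives exact
#'   per-receptor values (recycled).
#' @param sharp_fraction Fraction of expressed promoters that are sharp;
#'   the rest are broad.
#' @param broad_width Width (bp) over which broad promoters disperse
#'   initiation (default 100).
#' @param background_rate Poisson background, tags per annotated bp per
#'   library.
#' @param collision_pairs Window pairs engineered to lift to identical
#'   target coordinates (default 3).
#' @param unmapped_receptors Receptors with no chain to the target genome.
#' @param flip_fraction Fraction of homolog loci on the target minus strand.
#' @param decoy_tpm Pile-up level (TPM) at pseudogene decoys.
#' @param decoy_library_fraction Fraction of libraries showing the decoy
#'   pile-up.
#' @param locus_length,window_width Locus and TSS-window sizes, bp.
#' @param responder_fraction,n_traces Calcium population design (defaults
#'   11/37).
#' @param response_mean,response_sd Responder amplitude distribution,
#'   percent dR/R0 (defaults 80.5 / 26).
#' @param trace_duration,sample_interval Recording length and sampling
#'   period, seconds (sampled every 3 s).
#' @param stim_on,stim_off Stimulus window, seconds.
#' @param channel_noise_sd Gaussian noise SD added to each fluorescence
#'   channel (arbitrary units; channels are ~80-100).
#' @param baseline_r0 True baseline ratio.
#' @param ct_fold_changes Named vector of planted expression fold changes,
#'   one target gene each (default `c(TG1 = 4, TG2 = 1, TG3 = 0.25)`).
#' @param ct_noise_sd Per-well Ct noise SD, cycles (default 0.2).
#' @param ct_replicates Biological samples per group (default 3).
#' @param ct_tech_reps Technical replicates per well (default 2).
#' @param n_reference_genes Internal-control genes (default 3).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_receptors = 24L, n_pseudogenes = 5L,
                              n_libraries = 3L, depth_per_library = 1e5,
                              n_expressed = 12L,
                              expressed_tpm = c(1500, 4000),
                              sharp_fraction = 0.7,
                              broad_width = 100L,
                              background_rate = 0.005,
                              collision_pairs = 3L,
                              unmapped_receptors = 2L,
                              flip_fraction = 0.25,
                              decoy_tpm = 2000,
                              decoy_library_fraction = 1,
                              locus_length = 1000L, window_width = 200L,
                              responder_fraction = 11 / 37, n_traces = 37L,
                              response_mean = 80.5, response_sd = 26,
                              trace_duration = 300, sample_interval = 3,
                              stim_on = 60, stim_off = 120,
                              channel_noise_sd = 1, baseline_r0 = 0.8,
                              ct_fold_changes = c(TG1 = 4, TG2 = 1, TG3 = 0.25),
                              ct_noise_sd = 0.2, ct_replicates = 3L,
                              ct_tech_reps = 2L, n_reference_genes = 3L) {
  cfg <- as.list(environment())
  for (nm in c("n_receptors", "n_pseudogenes", "n_libraries", "n_expressed",
               "collision_pairs", "unmapped_receptors", "n_traces",
               "ct_replicates", "ct_tech_reps", "n_reference_genes")) {
    check_scalar_number(cfg[[nm]], nm, min = 0)
  }
  for (nm in c("sharp_fraction", "flip_fraction", "decoy_library_fraction",
               "responder_fraction")) {
    check_scalar_number(cfg[[nm]], nm, min = 0, max = 1)
  }
  check_scalar_number(cfg$depth_per_library, "depth_per_library", min = 0)
  check_scalar_number(cfg$background_rate, "background_rate", min = 0)
  check_scalar_number(cfg$broad_width, "broad_width", min = 2)
  if (cfg$n_expressed + cfg$collision_pairs + cfg$unmapped_receptors >
        cfg$n_receptors) {
    abort("n_expressed + collision_pairs + unmapped_receptors exceeds n_receptors")
  }
  if (cfg$collision_pairs > cfg$n_expressed && cfg$collision_pairs > 0) {
    abort("collision pairs borrow their first member from the expressed set; need collision_pairs <= n_expressed")
  }
  if (cfg$stim_on >= cfg$stim_off) abort("stim_on must be before stim_off")
  structure(cfg, class = "sim_config")
}

# internal: build one chain mapping an anchored source region to the target.
# sizes/dsrc/dtgt follow the chain-block grammar (alignment order); the
# anchor source base is guaranteed to map to anchor_tgt on the given strand.
sim_chain <- function(chain_id, score, src_chrom, src0, sizes, dsrc, dtgt,
                      tgt_chrom, genome_size, strand, anchor_src, anchor_tgt) {
  stopifnot(length(dsrc) == length(sizes) - 1, length(dtgt) == length(sizes) - 1)
  s_starts <- src0 + cumsum(c(0, sizes[-length(sizes)] + dsrc))
  u_starts <- cumsum(c(0, sizes[-length(sizes)] + dtgt))  # alignment-order target offsets
  k <- which(anchor_src >= s_starts & anchor_src < s_starts + sizes)[1]
  if (is.na(k)) abort("chain anchor falls in a gap")
  u_anchor <- u_starts[k] + (anchor_src - s_starts[k])
  span <- sum(sizes) + sum(dtgt)
  if (strand == "+") {
    tgt0 <- anchor_tgt - u_anchor
    b_start <- tgt0 + u_starts
    b_end <- b_start + sizes
    t_lo <- tgt0; t_hi <- tgt0 + span
  } else {
    tgt0 <- anchor_tgt + u_anchor + 1
    b_end <- tgt0 - u_starts
    b_start <- b_end - sizes
    t_lo <- tgt0 - span; t_hi <- tgt0
  }
  if (t_lo < 0) abort("chain target coordinates fall below 0")
  list(
    chain = tibble(
      chain_id = chain_id, score = score,
      src_chrom = src_chrom, src_size = genome_size,
      src_start = src0, src_end = src0 + sum(sizes) + sum(dsrc),
      tgt_chrom = tgt_chrom, tgt_size = genome_size, tgt_strand = strand,
      tgt_start = t_lo, tgt_end = t_hi
    ),
    blocks = tibble(
      chain_id = chain_id, src_start = s_starts, src_end = s_starts + sizes,
      tgt_start = b_start, tgt_end = b_end
    )
  )
}

#' Simulate source and target genomes with a connecting chain set
#'
#' Lays out receptor loci on a source genome and homolog loci (plus
#' pseudogene decoys) on a target genome, and builds the alignment chains
#' connecting them: each mapped locus gets a multi-block chain (with an
#' aligned 20-bp indel outside the promoter window, and a configurable
#' fraction of strand flips); a configurable subset of receptors is left
#' unmapped; and exactly `collision_pairs` pairs of source TSS windows are
#' engineered to lift to identical target coordinates by pointing the second
#' member's chain at the first member's target window.
#'
#' @param config A [simulation_config()].
#' @return A list with `src_annotation`, `tgt_annotation` (tibbles in
#'   [read_bed()] layout), `chains` (a [chain_set()]), `truth` (per-locus
#'   ground truth: role, shape, planted TPM, target TSS) and `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_r <- config$n_receptors; n_p <- config$n_pseudogenes
  L <- config$locus_length; W <- config$window_width
  spacing <- 20000L
  genome_size <- 5e6

  # roles by index: expressed first, then collision seconds, then unmapped
  expressed <- seq_len(n_r) <= config$n_expressed
  coll_second <- seq_len(n_r) > config$n_expressed &
    seq_len(n_r) <= config$n_expressed + config$collision_pairs
  coll_first_idx <- seq_len(config$collision_pairs)  # partners, expressed
  unmapped <- seq_len(n_r) > config$n_expressed + config$collision_pairs &
    seq_len(n_r) <= config$n_expressed + config$collision_pairs +
      config$unmapped_receptors

  n_sharp <- round(config$sharp_fraction * config$n_expressed)
  shape <- rep(NA_character_, n_r)
  shape[expressed] <- c(
    rep("sharp", n_sharp), rep("broad", config$n_expressed - n_sharp)
  )

  tpm_spec <- config$expressed_tpm
  planted_tpm <- rep(NA_real_, n_r)
  if (config$n_expressed > 0) {
    planted_tpm[expressed] <- if (length(tpm_spec) == 2L) {
      exp(runif(config$n_expressed, log(tpm_spec[1]), log(tpm_spec[2])))
    } else {
      rep_len(tpm_spec, config$n_expressed)
    }
  }

  src_start <- 1000L + (seq_len(n_r + n_p) - 1L) * spacing
  src_ann <- tibble(
    locus_id = c(sprintf("mOR%03d", seq_len(n_r)),
                 if (n_p > 0) sprintf("mPS%02d", seq_len(n_p))),
    chrom = "chrS", start = src_start, end = src_start + L,
    strand = "+", tss = src_start, biotype = "gene"
  )

  tgt_strand <- ifelse(runif(n_r + n_p) < config$flip_fraction, "-", "+")
  tgt_start <- 5000L + (seq_len(n_r + n_p) - 1L) * spacing
  # keep pseudogene decoys well away from gene loci
  tgt_start[seq_len(n_p) + n_r] <- 2e6 + (seq_len(n_p) - 1L) * spacing
  tgt_ann <- tibble(
    locus_id = c(sprintf("hOR%03d", seq_len(n_r)),
                 if (n_p > 0) sprintf("hPS%02d", seq_len(n_p))),
    chrom = "chrT", start = tgt_start, end = tgt_start + L,
    strand = tgt_strand,
    tss = ifelse(tgt_strand == "+", tgt_start, tgt_start + L - 1L),
    biotype = c(rep("gene", n_r), rep("pseudogene", n_p))
  )
  if (any(head(sort(src_ann$start), -1) + L > sort(src_ann$start)[-1]) ||
      any(head(sort(tgt_ann$start), -1) + L > sort(tgt_ann$start)[-1])) {
    abort("infeasible geometry: simulated loci overlap")
  }

  # chains: mapped receptors (not collision seconds, not unmapped) + decoys
  main_mapped <- which(!(coll_second | unmapped))
  main_mapped <- c(main_mapped, n_r + seq_len(n_p))
  parts <- purrr::map(seq_along(main_mapped), function(j) {
    i <- main_mapped[j]
    sim_chain(
      chain_id = j, score = 1e6 - j * 10,
      src_chrom = "chrS", src0 = src_ann$start[i] - 400L,
      sizes = c(1200L, 600L), dsrc = 20L, dtgt = 20L,
      tgt_chrom = "chrT", genome_size = genome_size,
      strand = tgt_ann$strand[i],
      anchor_src = src_ann$tss[i], anchor_tgt = tgt_ann$tss[i]
    )
  })
  # collision chains: window of the second member -> first member's window hull
  n_main <- length(main_mapped)
  coll_parts <- purrr::map(seq_len(config$collision_pairs), function(k) {
    j <- which(coll_second)[k]
    i <- coll_first_idx[k]
    sim_chain(
      chain_id = n_main + k, score = 1e4 - k,
      src_chrom = "chrS", src0 = src_ann$tss[j] - W / 2,
      sizes = W, dsrc = integer(0), dtgt = integer(0),
      tgt_chrom = "chrT", genome_size = genome_size,
      strand = tgt_ann$strand[i],
      anchor_src = src_ann$tss[j], anchor_tgt = tgt_ann$tss[i]
    )
  })
  parts <- c(parts, coll_parts)
  chains <- chain_set(
    purrr::map_dfr(parts, "chain"),
    purrr::map_dfr(parts, "blocks")
  )

  truth <- tibble(
    id = src_ann$locus_id,
    tgt_id = tgt_ann$locus_id,
    decoy = c(rep(FALSE, n_r), rep(TRUE, n_p)),
    expressed = c(expressed, rep(FALSE, n_p)),
    shape = c(shape, rep(NA_character_, n_p)),
    planted_tpm = c(planted_tpm,
                    rep(config$decoy_tpm, n_p)),
    mapped = c(!unmapped, rep(TRUE, n_p)),
    collision_second = c(coll_second, rep(FALSE, n_p)),
    collision_partner = {
      cp <- rep(NA_character_, n_r + n_p)
      cp[which(coll_second)] <- src_ann$locus_id[coll_first_idx]
      cp
    },
    src_tss = src_ann$tss,
    tgt_tss = tgt_ann$tss,
    tgt_strand = tgt_ann$strand
  )
  truth$planted_tpm[!truth$expressed & !truth$decoy] <- NA_real_

  list(
    src_annotation = src_ann, tgt_annotation = tgt_ann,
    chains = chains, truth = truth, config = config
  )
}

#' Simulate CTSS libraries over the target genome
#'
#' Draws, per library, a single multinomial of `depth_per_library` tags over
#' (i) planted promoters of expressed receptors — sharp promoters put >= 90
#' percent of their locus tags at the dominant TSS, broad promoters disperse
#' tags uniformly over `broad_width` bp into the locus; (ii) localized
#' spurious pile-ups on pseudogene decoys in a subset of libraries; (iii)
#' uniform Poisson-like background over all annotated loci; and (iv) a bulk
#' remainder bin standing in for the rest of the transcriptome, so each
#' library's total is exactly its depth and planted TPM expectations are
#' exact.
#'
#' @param config A [simulation_config()].
#' @param genomes Output of [simulate_genomes()].
#' @return A stacked CTSS tibble (`library`, `chrom`, `pos`, `strand`,
#'   `count`) parseable by every screen stage.
#' @export
simulate_ctss <- function(config, genomes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  depth <- config$depth_per_library
  if (depth == 0 && config$n_expressed > 0) {
    abort("depth 0 with nonzero expression requested")
  }
  tgt <- genomes$tgt_annotation
  truth <- genomes$truth
  bw <- config$broad_width

  bins_of <- function(row) {
    tss <- row$tgt_tss; s <- row$tgt_strand
    w <- config$depth_per_library * row$planted_tpm / 1e6
    if (row$shape == "sharp") {
      minor <- if (s == "+") tss + 1:20 else tss - 1:20
      tibble(
        pos = c(tss, minor), strand = s,
        weight = c(0.92 * w, rep(0.08 * w / 20, 20))
      )
    } else {
      spread <- if (s == "+") tss + 0:(bw - 1) else tss - 0:(bw - 1)
      tibble(pos = spread, strand = s, weight = w / bw)
    }
  }
  expr_rows <- truth |> filter(.data$expressed)
  expr_bins <- purrr::map_dfr(seq_len(nrow(expr_rows)), function(i) {
    bins_of(expr_rows[i, ]) |> mutate(chrom = "chrT")
  })

  decoy_rows <- truth |> filter(.data$decoy)
  decoy_bins <- purrr::map_dfr(seq_len(nrow(decoy_rows)), function(i) {
    r <- decoy_rows[i, ]
    a <- tgt$start[tgt$locus_id == r$tgt_id] + 300L
    tibble(
      chrom = "chrT", pos = a + 0:29, strand = r$tgt_strand,
      weight = depth * r$planted_tpm / 1e6 / 30
    )
  })

  bg_bins <- purrr::map_dfr(seq_len(nrow(tgt)), function(i) {
    tibble(
      chrom = "chrT", pos = seq.int(tgt$start[i], tgt$end[i] - 1L),
      strand = tgt$strand[i], weight = config$background_rate
    )
  })

  bulk_bins <- tibble(
    chrom = "chrT", pos = seq.int(4e6, 4e6 + 999), strand = "+", weight = 0
  )

  n_decoy_libs <- ceiling(config$decoy_library_fraction * config$n_libraries)
  purrr::map_dfr(seq_len(config$n_libraries), function(l) {
    bins <- bind_rows(
      expr_bins,
      if (l <= n_decoy_libs && nrow(decoy_bins) > 0) decoy_bins,
      bg_bins, bulk_bins
    )
    assigned <- sum(bins$weight)
    if (assigned > depth) {
      abort("planted expression exceeds library depth")
    }
    if (assigned == 0) {
      # nothing planted and no background: an empty library, not bulk filler
      return(tibble(
        library = character(), chrom = character(), pos = integer(),
        strand = character(), count = integer()
      ))
    }
    bins$weight[bins$weight == 0 & bins$chrom == "chrT" & bins$pos >= 4e6] <-
      (depth - assigned) / 1000
    counts <- as.vector(rmultinom(1, size = depth, prob = bins$weight))
    bins |>
      mutate(count = counts, library = sprintf("lib%02d", l)) |>
      filter(.data$count >= 1L) |>
      group_by(.data$library, .data$chrom, .data$pos, .data$strand) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      select("library", "chrom", "pos", "strand", "count") |>
      arrange(.data$chrom, .data$pos, .data$strand)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates calibrator and test samples over reference and target genes.
#' Each target gene carries one planted expression fold change (test versus
#' calibrator): its test-sample Ct is shifted by `-log2(fold)` cycles.
#' Gaussian per-well noise is added to every technical replicate.
#'
#' @param config A [simulation_config()].
#' @return A list: `ct` (long tibble `sample`, `gene`, `replicate`, `ct`),
#'   `reference_genes`, `calibrator_samples`, and `truth` (planted fold per
#'   target gene).
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  folds <- config$ct_fold_changes
  if (is.null(names(folds))) names(folds) <- sprintf("TG%d", seq_along(folds))
  refs <- sprintf("REF%d", seq_len(config$n_reference_genes))
  cal <- sprintf("CAL%d", seq_len(config$ct_replicates))
  trt <- sprintf("TRT%d", seq_len(config$ct_replicates))
  ref_base <- 20 + seq_len(config$n_reference_genes) - 1
  target_dct <- 5  # true delta-Ct of each target gene in calibrators

  grid <- tidyr::expand_grid(
    sample = c(cal, trt),
    gene = c(refs, names(folds)),
    replicate = seq_len(config$ct_tech_reps)
  )
  grid$true_ct <- ifelse(
    grid$gene %in% refs,
    ref_base[match(grid$gene, refs)],
    mean(ref_base) + target_dct -
      ifelse(grid$sample %in% trt, log2(folds[grid$gene]), 0)
  )
  grid$ct <- grid$true_ct + rnorm(nrow(grid), sd = config$ct_noise_sd)
  list(
    ct = grid |> select("sample", "gene", "replicate", "ct"),
    reference_genes = refs,
    calibrator_samples = cal,
    truth = tibble(gene = names(folds), fold = unname(folds))
  )
}

#' Simulate ratiometric calcium traces
#'
#' Draws a population of fura-2 traces sampled every `sample_interval`
#' seconds: a `responder_fraction` of cells respond to the stimulus with an
#' amplitude drawn from Normal(`response_mean`, `response_sd`) percent dR/R0,
#' onset shortly after stimulus onset and a half-peak duration of 1-2
#' minutes; the rest stay at baseline. Gaussian noise is added to each
#' fluorescence channel before ratioing.
#'
#' @param config A [simulation_config()].
#' @return A list: `traces` (tibble `trace_id`, `time`, `f340`, `f380`) and
#'   `truth` (per-trace responder flag, amplitude, onset, duration).
#' @export
simulate_calcium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  times <- seq(0, config$trace_duration, by = config$sample_interval)
  rise <- 6; fall <- 30
  res <- purrr::map(seq_len(config$n_traces), function(i) {
    responder <- runif(1) < config$responder_fraction
    amp <- if (responder) max(rnorm(1, config$response_mean, config$response_sd), 5) else 0
    onset <- config$stim_on + runif(1, 0, 10)
    dur <- runif(1, 60, 120)
    hold <- max(dur - (rise + fall) / 2, 5)
    u <- (times - onset)
    s <- ifelse(
      u < 0, 0,
      ifelse(u < rise, u / rise,
             ifelse(u < rise + hold, 1,
                    pmax(0, 1 - (u - rise - hold) / fall)))
    )
    if (!responder) s <- 0
    r <- config$baseline_r0 * (1 + amp / 100 * s)
    f380 <- 100 - 20 * s * amp / 100 + rnorm(length(times), sd = config$channel_noise_sd)
    f380 <- pmax(f380, 1)
    f340 <- r * (100 - 20 * s * amp / 100) +
      rnorm(length(times), sd = config$channel_noise_sd)
    list(
      trace = tibble(
        trace_id = sprintf("cell%02d", i), time = times,
        f340 = f340, f380 = f380
      ),
      truth = tibble(
        trace_id = sprintf("cell%02d", i), responder = responder,
        amplitude = amp, onset_time = onset, duration = dur
      )
    )
  })
  list(
    traces = purrr::map_dfr(res, "trace"),
    truth = purrr::map_dfr(res, "truth")
  )
}

#' Simulate a protein alignment on a known tree
#'
#' Evolves gap-free amino-acid sequences down a given topology: each site
#' mutates independently on each edge with probability `change_prob` to a
#' different uniformly chosen residue. Low `change_prob` yields alignments
#' whose maximum-parsimony topology is the generating topology.
#'
#' @param tree An [ape::phylo] tree (its edge directions are followed).
#' @param n_sites Alignment length.
#' @param change_prob Per-site per-edge substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences (one per tip).
#' @export
simulate_msa <- function(tree, n_sites = 300, change_prob = 0.05, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ntip <- length(tree$tip.label)
  E <- tree$edge[rev(postorder_edges(tree$edge)), , drop = FALSE]  # preorder
  seqs <- vector("list", ntip + tree$Nnode)
  root <- E[1, 1]
  seqs[[root]] <- sample(aa, n_sites, replace = TRUE)
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    s <- seqs[[p]]
    mut <- runif(n_sites) < change_prob
    if (any(mut)) {
      s[mut] <- vapply(
        s[mut], function(old) sample(setdiff(aa, old), 1), character(1)
      )
    }
    seqs[[ch]] <- s
  }
  setNames(
    vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), character(1)),
    tree$tip.label
  )
}

#' Write a complete synthetic dataset to disk
#'
#' Runs every generator under one seed and writes all pipeline inputs in
#' their external formats: per-library CTSS files, the chain file, source
#' and target BED annotations, the window list, a protein family FASTA, the
#' Ct table, the calcium traces and the ground-truth tables.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory objects.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- simulate_genomes(config)
  ctss <- simulate_ctss(config, genomes)
  ct <- simulate_ct_table(config)
  ca <- simulate_calcium(config)

  paths <- list()
  for (lib in unique(ctss$library)) {
    p <- file.path(dir, paste0(lib, ".ctss"))
    write_ctss(ctss |> filter(.data$library == lib), p)
    paths[[lib]] <- p
  }
  paths$chain <- write_chain(genomes$chains, file.path(dir, "src_to_tgt.chain"))
  paths$src_bed <- write_bed(genomes$src_annotation, file.path(dir, "source_loci.bed"))
  paths$tgt_bed <- write_bed(genomes$tgt_annotation, file.path(dir, "target_loci.bed"))
  readr::write_tsv(genomes$truth, file.path(dir, "truth.tsv"))
  paths$truth <- file.path(dir, "truth.tsv")
  paths$ct <- write_ct_table(ct$ct, file.path(dir, "ct_table.tsv"))
  paths$traces <- write_traces(ca$traces, file.path(dir, "calcium_traces.tsv"))

  set.seed(config$seed + 4L)
  fam_tree <- ape::rtree(8)
  msa <- simulate_msa(fam_tree, n_sites = 120, change_prob = 0.08,
                      seed = config$seed + 5L)
  paths$fasta <- write_fasta(msa, file.path(dir, "protein_family.fasta"))

  invisible(list(
    paths = paths, genomes = genomes, ctss = ctss, ct = ct, calcium = ca,
    msa = msa
  ))
}
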