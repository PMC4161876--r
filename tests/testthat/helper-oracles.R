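# Independent oracles and fixture builders shared across tests. These are
# deliberately written without reusing package internals: the brute-force
# lift maps every base on its own, the NW scorer is a plain quadratic DP,
# and chain fixtures are assembled directly as tibbles.

# build a chain_set from a list of block specs
# each spec: list(id, score, src_chrom, tgt_chrom, strand, blocks = data.frame(src_start, src_end, tgt_start, tgt_end))
mk_chain_set <- function(specs, genome_size = 1e6) {
  chains <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(
      chain_id = s$id, score = s$score,
      src_chrom = s$src_chrom, src_size = genome_size,
      src_start = min(s$blocks$src_start), src_end = max(s$blocks$src_end),
      tgt_chrom = s$tgt_chrom, tgt_size = genome_size, tgt_strand = s$strand,
      tgt_start = min(s$blocks$tgt_start), tgt_end = max(s$blocks$tgt_end)
    )
  })
  blocks <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(chain_id = s$id, tibble::as_tibble(s$blocks))
  })
  chain_set(chains, blocks)
}

# a single identity chain over [0, len) on one chromosome
identity_chain <- function(len = 10000, chrom = "c1") {
  mk_chain_set(list(list(
    id = 1L, score = 100, src_chrom = chrom, tgt_chrom = chrom, strand = "+",
    blocks = data.frame(src_start = 0, src_end = len, tgt_start = 0, tgt_end = len)
  )))
}

# random multi-block chains for property tests; coordinates built in
# alignment order, independently of the package's own generator
random_chain_set <- function(n_chains = 6, max_blocks = 8) {
  specs <- lapply(seq_len(n_chains), function(i) {
    nb <- sample(1:max_blocks, 1)
    sizes <- sample(1:50, nb, replace = TRUE)
    dsrc <- if (nb > 1) sample(0:20, nb - 1, replace = TRUE) else integer(0)
    dtgt <- if (nb > 1) sample(0:20, nb - 1, replace = TRUE) else integer(0)
    src0 <- sample(0:5000, 1)
    tgt0 <- sample(20000:40000, 1)
    strand <- sample(c("+", "-"), 1)
    s_starts <- src0 + cumsum(c(0, head(sizes, -1) + dsrc))
    u_starts <- cumsum(c(0, head(sizes, -1) + dtgt))
    if (strand == "+") {
      t_start <- tgt0 + u_starts
      t_end <- t_start + sizes
    } else {
      t_end <- tgt0 - u_starts
      t_start <- t_end - sizes
    }
    list(
      id = i, score = sample(1:1000, 1),
      src_chrom = sample(c("c1", "c2"), 1), tgt_chrom = "t1",
      strand = strand,
      blocks = data.frame(
        src_start = s_starts, src_end = s_starts + sizes,
        tgt_start = t_start, tgt_end = t_end
      )
    )
  })
  mk_chain_set(specs)
}

# per-base brute-force lift: maps every base of [start, end) independently
# through the best chain's blocks, then derives the status
brute_lift <- function(chrom, start, end, chains, min_match = 0.95,
                       gap_tolerance = NULL) {
  ct <- chains$chains
  cand <- ct[ct$src_chrom == chrom & ct$src_start < end & ct$src_end > start, ]
  width <- end - start
  none <- list(status = "unmapped", tgt_start = NA_real_, tgt_end = NA_real_,
               chain_id = NA_integer_, mapped_fraction = 0)
  if (nrow(cand) == 0) return(none)
  cand <- cand[order(-cand$score, cand$chain_id), ]
  best <- cand[1, ]
  b <- chains$blocks[chains$blocks$chain_id == best$chain_id, ]
  tpos <- numeric(0)
  for (p in seq.int(start, end - 1)) {
    j <- which(p >= b$src_start & p < b$src_end)
    if (length(j) == 1) {
      off <- p - b$src_start[j]
      tpos <- c(tpos, if (best$tgt_strand == "+") b$tgt_start[j] + off
                else b$tgt_end[j] - 1 - off)
    }
  }
  if (length(tpos) == 0) return(none)
  lo <- min(tpos); hi <- max(tpos) + 1
  tol <- if (is.null(gap_tolerance)) floor(width * (1 - min_match)) else gap_tolerance
  frac <- length(tpos) / width
  status <- if ((hi - lo) - length(tpos) > tol) "split"
    else if (frac < min_match) "low_coverage"
    else "mapped"
  list(status = status, tgt_start = lo, tgt_end = hi,
       chain_id = best$chain_id, mapped_fraction = frac)
}

# plain quadratic Needleman-Wunsch score (match/mismatch/linear gap)
nw_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n); M[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(
        M[i, j] + if (A[i] == B[j]) match else mismatch,
        M[i, j + 1] + gap,
        M[i + 1, j] + gap
      )
    }
  }
  M[n + 1, m + 1]
}

# exhaustive parsimony optimum via phangorn (independent of the package)
exhaustive_mp_score <- function(msa) {
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(mat) <- names(msa)
  pd <- phangorn::phyDat(mat, type = "AA")
  trees <- phangorn::allTrees(length(msa), rooted = FALSE,
                              tip.label = names(msa))
  min(phangorn::parsimony(trees, pd))
}

# random gap-free protein alignment
random_msa <- function(n_taxa, n_sites, alphabet = c("A", "C", "D", "E", "G")) {
  stats::setNames(
    replicate(n_taxa, paste(sample(alphabet, n_sites, TRUE), collapse = "")),
    paste0("t", seq_len(n_taxa))
  )
}

# small CTSS tibble builder
mk_ctss <- function(pos, count, chrom = "chr1", strand = "+", library = "lib1") {
  tibble::tibble(library = library, chrom = chrom, pos = as.integer(pos),
                 strand = strand, count = as.integer(count))
}
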