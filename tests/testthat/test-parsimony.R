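test_that("complete deletion removes exactly the columns with gaps or missing data", {
  msa <- c(a = "MKTW", b = "MKTW", c = "MKTW")
  expect_equal(remove_gap_columns(msa), msa)

  msa2 <- c(a = "MKTW", b = "M-TW", c = "MKTW")
  expect_equal(unname(remove_gap_columns(msa2)), c("MTW", "MTW", "MTW"))

  # random alignments against an independent per-column scan
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(3:6, 1); len <- sample(10:40, 1)
    chars <- c("A", "C", "D", "-", "?", "X")
    mat <- matrix(sample(chars, n * len, TRUE, prob = c(5, 5, 5, 1, 1, 1)),
                  nrow = n)
    msa_r <- stats::setNames(apply(mat, 1, paste, collapse = ""),
                             paste0("s", 1:n))
    keep <- vapply(seq_len(len), function(j) {
      !any(mat[, j] %in% c("-", "?", "X", "."))
    }, logical(1))
    if (!any(keep)) {
      expect_error(remove_gap_columns(msa_r), "no alignment columns")
    } else {
      got <- remove_gap_columns(msa_r)
      expect_equal(nchar(got[[1]]), sum(keep))
      expect_equal(unname(got),
                   unname(apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")))
    }
  }
})

test_that("Fitch scoring reproduces forced change counts and invariances", {
  tr <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(fitch_score(tr, c(A = "M", B = "M", C = "M", D = "M")), 0)
  # one column A,A,G,G on ((A,B),(C,D)): exactly one change
  expect_equal(fitch_score(tr, c(A = "A", B = "A", C = "G", D = "G")), 1)
  # grouping the unlike pairs needs two changes
  tr2 <- ape::unroot(ape::read.tree(text = "((A,C),(B,D));"))
  expect_equal(fitch_score(tr2, c(A = "A", B = "A", C = "G", D = "G")), 2)

  expect_error(fitch_score(tr, c(A = "A", B = "A", C = "G", Z = "G")),
               "differ")

  # invariance under re-rooting and label permutation
  set.seed(16)
  msa <- random_msa(6, 30)
  base <- ape::unroot(ape::rtree(6, tip.label = names(msa)))
  s0 <- fitch_score(base, msa)
  for (og in names(msa)[1:3]) {
    rooted <- ape::root(base, outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_score(rooted, msa), s0)
  }
  expect_equal(fitch_score(base, msa[sample(names(msa))]), s0)
})

test_that("Fitch scores agree with an independent parsimony implementation", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    msa <- random_msa(n, sample(10:60, 1))
    tr <- ape::unroot(ape::rtree(n, tip.label = names(msa)))
    mat <- do.call(rbind, strsplit(unname(msa), ""))
    rownames(mat) <- names(msa)
    pd <- phangorn::phyDat(mat, type = "AA")
    expect_equal(fitch_score(tr, msa),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("random addition is deterministic and bounded by the optimum", {
  msa3 <- random_msa(3, 20)
  t1 <- random_addition_tree(msa3, seed = 1)
  t2 <- random_addition_tree(msa3, seed = 99)
  expect_setequal(t1$tip.label, names(msa3))
  expect_equal(t1$Nnode, 1L)  # the unique unrooted 3-taxon topology
  expect_equal(t2$Nnode, 1L)

  set.seed(18)
  msa <- random_msa(6, 25)
  a <- random_addition_tree(msa, seed = 5)
  b <- random_addition_tree(msa, seed = 5)
  expect_equal(ape::dist.topo(ape::unroot(a), ape::unroot(b)), 0,
               ignore_attr = TRUE)
  opt <- exhaustive_mp_score(msa)
  expect_gte(attr(a, "score"), opt)
})

test_that("NNI hill climbing only descends and stops at local optima", {
  set.seed(19)
  msa <- random_msa(6, 30)
  start <- random_addition_tree(msa, seed = 2)
  out <- cni_search(start, msa)
  expect_lte(attr(out, "score"), attr(start, "score"))
  # a second pass from the local optimum changes nothing
  again <- cni_search(out, msa)
  expect_equal(attr(again, "score"), attr(out, "score"))
  expect_equal(ape::dist.topo(ape::unroot(again), ape::unroot(out)), 0,
               ignore_attr = TRUE)

  # 4 taxa: a tree already at the optimum is returned unchanged
  msa4 <- c(A = "AAAA", B = "AAAA", C = "GGGG", D = "GGGG")
  best4 <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  res4 <- cni_search(best4, msa4)
  expect_equal(attr(res4, "score"), 4)
  expect_equal(ape::dist.topo(ape::unroot(res4), best4), 0, ignore_attr = TRUE)
})

test_that("mp_search recovers generating topologies and exhaustive optima", {
  # topology recovery at low mutation rate
  set.seed(20)
  gen <- ape::rtree(6)
  msa <- simulate_msa(gen, n_sites = 200, change_prob = 0.03, seed = 7)
  fit <- mp_search(msa, replicates = 5, seed = 3)
  expect_equal(
    ape::dist.topo(ape::unroot(gen), ape::unroot(fit$trees[[1]])), 0,
    ignore_attr = TRUE
  )

  # 7-taxon random alignment: score matches the 945-topology enumeration
  set.seed(21)
  msa7 <- random_msa(7, 30)
  fit7 <- mp_search(msa7, replicates = 10, seed = 4)
  expect_equal(fit7$score, exhaustive_mp_score(msa7))

  # replicates = 1 reproduces a single addition + refinement run
  fit1 <- mp_search(msa7, replicates = 1, seed = 9)
  set.seed(9)
  single <- cni_search(random_addition_tree(msa7), msa7)
  expect_equal(fit1$score, attr(single, "score"))
  expect_equal(
    ape::dist.topo(ape::unroot(fit1$trees[[1]]), ape::unroot(single)), 0,
    ignore_attr = TRUE
  )

  # full reproducibility under a fixed seed
  fit7b <- mp_search(msa7, replicates = 10, seed = 4)
  expect_equal(fit7b$score, fit7$score)
  expect_equal(fit7b$replicate_scores, fit7$replicate_scores)

  gl <- glance(fit7)
  expect_equal(gl$n_taxa, 7L)
  td <- tidy(fit7)
  expect_equal(nrow(td), 10L)
  expect_true(any(td$is_best))
})

test_that("percent identity follows the alignment-column definition", {
  expect_equal(percent_identity("MKTAYIAK", "MKTAYIAK"), 100)
  expect_equal(percent_identity("ACDEFGHIKL", "ACDEFGHIKV"), 90)

  # terminal overhangs are excluded from the denominator
  expect_equal(percent_identity("AAACDEF", "CDEF"), 100)

  # alignment scores match an independent quadratic DP on random pairs
  set.seed(22)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "D", "E"), sample(5:15, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "E"), sample(5:15, 1), TRUE), collapse = "")
    letters_ab <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
    sm <- matrix(0, length(letters_ab), length(letters_ab),
                 dimnames = list(letters_ab, letters_ab))
    diag(sm) <- 1
    bio <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 1
    )
    expect_equal(Biostrings::score(bio), nw_score(a, b))
  }

  expect_error(percent_identity("", "ACD"), "non-empty")

  pm <- percent_identity_matrix(c(x = "ACDE", y = "ACDE", z = "ACDD"))
  expect_equal(nrow(pm), 3L)
  expect_equal(pm$identity[pm$seq_a == "x" & pm$seq_b == "y"], 100)
})
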