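# Maximum-parsimony machinery over ape::phylo trees. Character states are
# encoded as bit masks so Fitch set operations vectorise over alignment
# columns; identical columns are collapsed to weighted site patterns.

GAP_SYMBOLS <- c("-", "?", "X", ".")

msa_matrix <- function(msa) {
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    abort("alignment sequences must have unique names")
  }
  if (length(unique(nchar(msa))) != 1L) {
    abort("aligned sequences must all have the same length")
  }
  mat <- do.call(rbind, strsplit(toupper(unname(msa)), ""))
  rownames(mat) <- names(msa)
  mat
}

#' Remove alignment columns with gaps or missing data
#'
#' Complete deletion: every column in which any sequence carries a gap or
#' missing-data symbol (`-`, `?`, `X`, `.`) is removed; the order of the
#' remaining columns is preserved. Parsimony scoring requires a gap-free
#' alignment, so this is applied before tree search.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @return The alignment restricted to complete columns, as a named character
#'   vector. Errors if no column survives.
#' @export
remove_gap_columns <- function(msa) {
  mat <- msa_matrix(msa)
  keep <- colSums(matrix(mat %in% GAP_SYMBOLS, nrow = nrow(mat))) == 0L
  if (!any(keep)) abort("no alignment columns left after gap/missing removal")
  setNames(apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""), names(msa))
}

# bit-encode an alignment into unique site patterns with weights
encode_patterns <- function(msa) {
  mat <- msa_matrix(msa)
  if (any(mat %in% GAP_SYMBOLS)) {
    abort("alignment contains gaps/missing data; apply remove_gap_columns() first")
  }
  syms <- sort(unique(as.vector(mat)))
  if (length(syms) > 30L) abort("more than 30 distinct residue symbols")
  code <- matrix(bitwShiftL(1L, match(mat, syms) - 1L), nrow = nrow(mat),
                 dimnames = list(rownames(mat), NULL))
  key <- apply(mat, 2, paste, collapse = "")
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  list(states = code[, first, drop = FALSE], weights = weights,
       taxa = rownames(mat))
}

# child-before-parent edge ordering via depth-first traversal; works on any
# valid edge matrix regardless of row order or node numbering conventions
postorder_edges <- function(edge) {
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  root <- setdiff(edge[, 1], edge[, 2])[1]
  out <- integer(nrow(edge))
  m <- 0L
  visit <- function(rows) {
    for (r in rows) {
      ch_rows <- kids[[as.character(edge[r, 2])]]
      if (!is.null(ch_rows)) visit(ch_rows)
      m <<- m + 1L
      out[m] <<- r
    }
  }
  visit(kids[[as.character(root)]])
  out
}

fitch_score_enc <- function(tree, enc) {
  ntip <- length(tree$tip.label)
  npat <- length(enc$weights)
  idx <- match(tree$tip.label, enc$taxa)
  if (anyNA(idx)) abort("tree tip labels do not match alignment names")
  S <- matrix(0L, nrow = ntip + tree$Nnode, ncol = npat)
  S[seq_len(ntip), ] <- enc$states[idx, , drop = FALSE]
  filled <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
  score <- 0
  E <- tree$edge[postorder_edges(tree$edge), , drop = FALSE]
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    if (!filled[p]) {
      S[p, ] <- S[ch, ]
      filled[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      z <- inter == 0L
      if (any(z)) {
        score <- score + sum(enc$weights[z])
        inter[z] <- bitwOr(S[p, z], S[ch, z])
      }
      S[p, ] <- inter
    }
  }
  score
}

#' Fitch parsimony score of a tree
#'
#' Sums over alignment columns the minimum number of unordered, unit-cost
#' state changes required on the tree (Fitch small parsimony). The single
#' degree-3 basal node of an unrooted binary tree is handled by folding its
#' children sequentially, which equals rooting the tree along any of its
#' edges.
#'
#' @param tree An [ape::phylo] tree whose tip labels equal the alignment
#'   names.
#' @param msa Named character vector of equal-length, gap-free aligned
#'   sequences (see [remove_gap_columns()]).
#' @return Integer parsimony score (0 for identical sequences).
#' @export
fitch_score <- function(tree, msa) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, names(msa))) {
    abort("tree tip labels and alignment names differ")
  }
  fitch_score_enc(tree, encode_patterns(msa))
}

# All nearest-neighbour-interchange rearrangements of an (unrooted-style)
# binary tree: two per internal edge.
nni_neighbors <- function(tree) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  internal <- which(E[, 2] > ntip)
  out <- vector("list", 2L * length(internal))
  m <- 0L
  for (i in internal) {
    a <- E[i, 1]; b <- E[i, 2]
    x_row <- which(E[, 1] == a & E[, 2] != b)[1]
    y_rows <- which(E[, 1] == b)
    for (y_row in y_rows) {
      E2 <- E
      E2[y_row, 1] <- a
      E2[x_row, 1] <- b
      t2 <- tree
      t2$edge <- E2
      m <- m + 1L
      out[[m]] <- t2
    }
  }
  out[seq_len(m)]
}

#' Stepwise random-addition starting tree
#'
#' Builds a starting topology by inserting taxa one at a time in random
#' order, each on the edge that minimises the Fitch score of the partial
#' tree (first minimum on ties, in edge order). This is the classical
#' random-addition heuristic used to seed parsimony searches.
#'
#' @param msa Gap-free named alignment (>= 3 sequences).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [mp_search()]).
#' @return An [ape::phylo] topology with a `score` attribute.
#' @export
random_addition_tree <- function(msa, seed = NULL) {
  if (length(msa) < 3L) abort("need at least 3 sequences")
  if (!is.null(seed)) set.seed(seed)
  enc_full <- encode_patterns(msa)
  ord <- sample.int(length(msa))
  labels <- names(msa)[ord]
  tree <- structure(
    list(
      edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
      tip.label = labels[1:3], Nnode = 1L
    ),
    class = "phylo"
  )
  for (t in seq_along(labels)[-(1:3)]) {
    sub_enc <- encode_patterns(msa[labels[1:t]])
    best <- NULL; best_score <- Inf
    for (e in seq_len(nrow(tree$edge))) {
      cand <- insert_tip(tree, e, labels[t])
      s <- fitch_score_enc(cand, sub_enc)
      if (s < best_score) {
        best <- cand; best_score <- s
      }
    }
    tree <- best
  }
  attr(tree, "score") <- fitch_score_enc(tree, enc_full)
  tree
}

# insert a new tip in the middle of edge `edge_row`, renumbering nodes to
# keep tips 1..n and the basal node at n+1
insert_tip <- function(tree, edge_row, label) {
  n <- length(tree$tip.label)
  E <- tree$edge
  E[E > n] <- E[E > n] + 1L
  new_tip <- n + 1L
  new_node <- n + tree$Nnode + 2L
  u <- E[edge_row, 1]; v <- E[edge_row, 2]
  E[edge_row, ] <- c(u, new_node)
  E <- rbind(E, c(new_node, v), c(new_node, new_tip))
  structure(
    list(edge = E, tip.label = c(tree$tip.label, label),
         Nnode = tree$Nnode + 1L),
    class = "phylo"
  )
}

#' Close-neighbour-interchange hill climbing
#'
#' Local search over the close-neighbour-interchange neighbourhood: all
#' topologies within topological distance 4 of the current tree, i.e. up to
#' two nearest-neighbour interchanges. At search level 0 the first strictly
#' improving neighbour is accepted (single interchanges are scanned before
#' double ones) and the search restarts from it, until no close neighbour
#' improves the Fitch score. The returned score never exceeds the input
#' tree's score.
#'
#' @param tree Starting [ape::phylo] topology.
#' @param msa Gap-free named alignment.
#' @param level Search level; the bounded level-0 neighbourhood is
#'   implemented.
#' @return The locally optimal tree with a `score` attribute.
#' @export
cni_search <- function(tree, msa, level = 0) {
  check_scalar_number(level, "level", min = 0)
  enc <- encode_patterns(msa)
  cur <- tree
  cur_score <- fitch_score_enc(cur, enc)
  repeat {
    improved <- FALSE
    single <- nni_neighbors(cur)
    for (nb in single) {
      s <- fitch_score_enc(nb, enc)
      if (s < cur_score) {
        cur <- nb; cur_score <- s; improved <- TRUE
        break
      }
    }
    if (!improved) {
      for (nb in single) {
        for (nb2 in nni_neighbors(nb)) {
          s <- fitch_score_enc(nb2, enc)
          if (s < cur_score) {
            cur <- nb2; cur_score <- s; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  attr(cur, "score") <- cur_score
  cur
}

#' Maximum-parsimony tree search
#'
#' Runs `replicates` independent searches, each a random-addition starting
#' tree ([random_addition_tree()]) refined by close-neighbour-interchange
#' hill climbing ([cni_search()]), and keeps the best-scoring topology;
#' distinct topologies tying for the best score are all reported.
#'
#' @param msa Named alignment; columns with gaps/missing data are removed
#'   first (complete deletion).
#' @param replicates Number of random-addition replicates (default 10).
#' @param seed Integer seed making the whole search reproducible.
#' @return An object of class `mp_fit`: list with `trees` (a `multiPhylo` of
#'   best topologies), `score`, `replicate_scores`, and alignment summaries.
#'   Methods: [tidy()], [glance()], `print()`; write trees with
#'   [write_newick()].
#' @export
mp_search <- function(msa, replicates = 10, seed = 1) {
  check_scalar_number(replicates, "replicates", min = 1)
  msa_clean <- remove_gap_columns(msa)
  set.seed(seed)
  trees <- vector("list", replicates)
  scores <- numeric(replicates)
  for (r in seq_len(replicates)) {
    start <- random_addition_tree(msa_clean)
    final <- cni_search(start, msa_clean)
    trees[[r]] <- final
    scores[r] <- attr(final, "score")
  }
  best_score <- min(scores)
  best <- trees[scores == best_score]
  uniq <- list(best[[1]])
  if (length(best) > 1L && length(msa) >= 4L) {
    for (tr in best[-1]) {
      dup <- any(vapply(
        uniq, function(u) ape::dist.topo(ape::unroot(u), ape::unroot(tr)) == 0,
        logical(1)
      ))
      if (!dup) uniq <- c(uniq, list(tr))
    }
  }
  structure(
    list(
      trees = structure(uniq, class = "multiPhylo"),
      score = best_score,
      replicate_scores = scores,
      replicates = replicates,
      seed = seed,
      n_taxa = length(msa),
      n_sites = nchar(msa_clean[[1]]),
      n_sites_input = nchar(msa[[1]])
    ),
    class = "mp_fit"
  )
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(sprintf(
    "<mp_fit> maximum parsimony: %d taxa, %d gap-free sites (of %d)\n",
    x$n_taxa, x$n_sites, x$n_sites_input
  ))
  cat(sprintf(
    "  best score %d over %d replicates (%d tying topolog%s)\n",
    x$score, x$replicates, length(x$trees),
    if (length(x$trees) == 1L) "y" else "ies"
  ))
  invisible(x)
}

#' @rdname mp_search
#' @param x,object An `mp_fit` object.
#' @param ... Unused.
#' @method tidy mp_fit
#' @export
tidy.mp_fit <- function(x, ...) {
  tibble(
    replicate = seq_len(x$replicates),
    score = x$replicate_scores,
    is_best = x$replicate_scores == x$score
  )
}

#' @rdname mp_search
#' @method glance mp_fit
#' @export
glance.mp_fit <- function(x, ...) {
  tibble(
    score = x$score, n_trees = length(x$trees), replicates = x$replicates,
    n_taxa = x$n_taxa, n_sites = x$n_sites, seed = x$seed
  )
}

#' Pairwise percent identity
#'
#' Globally aligns two protein sequences (Needleman-Wunsch; by default
#' match +1, mismatch 0, linear gap -1) and reports
#' `matches / aligned columns * 100`, excluding terminal-gap columns from the
#' denominator so length overhangs do not dilute the identity.
#'
#' @param seq_a,seq_b Non-empty sequences (character scalars).
#' @param match_score,mismatch_score Alignment scores (defaults +1 / 0).
#' @param gap_cost Linear gap penalty, subtracted per gap position
#'   (default 1).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b, match_score = 1,
                             mismatch_score = 0, gap_cost = 1) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    abort("sequences must be non-empty")
  }
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  letters_ab <- sort(unique(strsplit(paste0(seq_a, seq_b), "")[[1]]))
  sm <- matrix(
    mismatch_score, length(letters_ab), length(letters_ab),
    dimnames = list(letters_ab, letters_ab)
  )
  diag(sm) <- match_score
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = gap_cost
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_col <- p == "-" | s == "-"
  core <- which(!gap_col)
  lead <- if (length(core)) core[1] - 1L else 0L
  trail <- if (length(core)) length(p) - core[length(core)] else 0L
  keep <- seq_along(p) > lead & seq_along(p) <= length(p) - trail
  if (!any(keep)) return(0)
  100 * sum(p[keep] == s[keep]) / sum(keep)
}

#' Pairwise percent-identity matrix
#'
#' @param seqs Named character vector of sequences.
#' @param ... Passed to [percent_identity()].
#' @return A long tibble `seq_a`, `seq_b`, `identity` over unordered pairs.
#' @export
percent_identity_matrix <- function(seqs, ...) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  pairs <- utils::combn(names(seqs), 2)
  tibble(
    seq_a = pairs[1, ], seq_b = pairs[2, ],
    identity = purrr::map2_dbl(
      pairs[1, ], pairs[2, ],
      function(a, b) percent_identity(seqs[[a]], seqs[[b]], ...)
    )
  )
}
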