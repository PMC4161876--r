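#' Read a CTSS tag table
#'
#' Reads a CAGE transcription start site (CTSS) table in the 4-column
#' tab-separated dialect `chrom  pos  strand  count`, where `pos` is the
#' 0-based position of a tag's 5' end and `count` the number of tags whose 5'
#' ends fall exactly there on that strand. One file holds one library.
#'
#' @param path Path to a CTSS file. May be empty (zero records).
#' @param library_id Library identifier stored in the `library` column;
#'   defaults to the file name without extension.
#' @return A tibble with columns `library`, `chrom`, `pos`, `strand`, `count`,
#'   sorted by `(chrom, pos, strand)`. `sum(count)` is the library's total tag
#'   count and the denominator of [tpm()].
#' @seealso [write_ctss()], [count_tags()], [tpm()]
#' @export
read_ctss <- function(path, library_id = NULL) {
  if (!file.exists(path)) abort(sprintf("CTSS file not found: %s", path))
  library_id <- library_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(
      library = character(), chrom = character(), pos = integer(),
      strand = character(), count = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed CTSS line %d in %s: expected 4 tab-separated fields", bad[1], path))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  count <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(pos) | is.na(count))
  if (length(bad) > 0L) {
    abort(sprintf("malformed CTSS line %d in %s: non-integer pos or count", bad[1], path))
  }
  if (any(count < 0L)) {
    abort(sprintf("CTSS line %d in %s: negative tag count", which(count < 0L)[1], path))
  }
  check_strand(m[, 3])
  tibble(
    library = library_id, chrom = m[, 1], pos = pos, strand = m[, 3],
    count = count
  ) |>
    filter(.data$count >= 1L) |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Write a CTSS tag table
#'
#' @param ctss A CTSS tibble as returned by [read_ctss()] or
#'   [simulate_ctss()] (a single library).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(ctss, path) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(ctss)))
  writeLines(
    sprintf("%s\t%d\t%s\t%d", ctss$chrom, ctss$pos, ctss$strand, ctss$count),
    path
  )
  invisible(path)
}

# ---- UCSC chain files -------------------------------------------------------

#' Construct a chain set
#'
#' A `chain_set` holds parsed pairwise genome-alignment chains: per-chain
#' metadata and per-block aligned intervals. All coordinates are stored
#' 0-based half-open on the plus strand of both genomes; for minus-strand
#' chains the conversion from strand-local chain coordinates happens at parse
#' time, and each block of a minus-strand chain maps source base `s` to target
#' base `tgt_end - 1 - (s - src_start)`.
#'
#' @param chains Tibble with columns `chain_id`, `score`, `src_chrom`,
#'   `src_size`, `src_start`, `src_end`, `tgt_chrom`, `tgt_size`,
#'   `tgt_strand`, `tgt_start`, `tgt_end`.
#' @param blocks Tibble with columns `chain_id`, `src_start`, `src_end`,
#'   `tgt_start`, `tgt_end` (one row per aligned block, equal widths).
#' @return An object of class `chain_set`.
#' @export
chain_set <- function(chains, blocks) {
  need_c <- c(
    "chain_id", "score", "src_chrom", "src_size", "src_start", "src_end",
    "tgt_chrom", "tgt_size", "tgt_strand", "tgt_start", "tgt_end"
  )
  need_b <- c("chain_id", "src_start", "src_end", "tgt_start", "tgt_end")
  stopifnot(all(need_c %in% names(chains)), all(need_b %in% names(blocks)))
  if (nrow(blocks) > 0 && any(blocks$src_end - blocks$src_start < 1L)) {
    abort("chain blocks must have size >= 1")
  }
  if (nrow(blocks) > 0 &&
      any((blocks$src_end - blocks$src_start) != (blocks$tgt_end - blocks$tgt_start))) {
    abort("chain block source and target widths differ")
  }
  structure(
    list(chains = as_tibble(chains), blocks = as_tibble(blocks)),
    class = "chain_set"
  )
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf(
    "<chain_set> %d chain(s), %d block(s)\n",
    nrow(x$chains), nrow(x$blocks)
  ))
  print(x$chains, n = 5)
  invisible(x)
}

#' Read a UCSC chain file
#'
#' Parses the UCSC chain format (`chain score tName tSize tStrand tStart tEnd
#' qName qSize qStrand qStart qEnd id` headers followed by `size dt dq` block
#' lines). In lift-over chains the `t` genome is the source assembly being
#' lifted *from* and the `q` genome the target being lifted *to*; they are
#' stored here as `src_*` and `tgt_*`. Minus-strand target coordinates are
#' converted to plus-strand half-open intervals at parse time. Block
#' arithmetic is validated against each chain's declared spans.
#'
#' @param path Path to a chain file.
#' @return A [chain_set()].
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) abort(sprintf("chain file not found: %s", path))
  lines <- readLines(path)
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L) abort(sprintf("no chain headers in %s", path))
  chains <- vector("list", length(hdr_idx))
  blocks <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[k]]), "\\s+")[[1]]
    if (length(h) != 13L) {
      abort(sprintf("malformed chain header at line %d in %s", hdr_idx[k], path))
    }
    score <- as.numeric(h[2])
    t_chrom <- h[3]; t_size <- as.numeric(h[4]); t_strand <- h[5]
    t_start <- as.numeric(h[6]); t_end <- as.numeric(h[7])
    q_chrom <- h[8]; q_size <- as.numeric(h[9]); q_strand <- h[10]
    q_start <- as.numeric(h[11]); q_end <- as.numeric(h[12])
    id <- as.integer(h[13])
    if (t_strand != "+") {
      abort(sprintf("chain %d: source (t) strand must be '+'", id))
    }
    body <- lines[(hdr_idx[k] + 1L):(bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    parts <- strsplit(trimws(body), "\\s+")
    sizes <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    dt <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[2]) else 0, numeric(1))
    dq <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[3]) else 0, numeric(1))
    if (length(parts[[length(parts)]]) != 1L) {
      abort(sprintf("chain %d: last block line must carry only a size", id))
    }
    if (any(sizes < 1)) abort(sprintf("chain %d: block sizes must be >= 1", id))
    src_b <- t_start + cumsum(c(0, head(sizes + dt, -1)))
    q_b <- q_start + cumsum(c(0, head(sizes + dq, -1)))
    if (src_b[length(src_b)] + sizes[length(sizes)] != t_end ||
        q_b[length(q_b)] + sizes[length(sizes)] != q_end) {
      abort(sprintf("chain %d in %s: blocks do not sum to declared spans", id, path))
    }
    if (q_strand == "+") {
      tgt_b_start <- q_b
      tgt_b_end <- q_b + sizes
      tgt_start <- q_start; tgt_end <- q_end
    } else {
      tgt_b_start <- q_size - (q_b + sizes)
      tgt_b_end <- q_size - q_b
      tgt_start <- q_size - q_end; tgt_end <- q_size - q_start
    }
    chains[[k]] <- tibble(
      chain_id = id, score = score,
      src_chrom = t_chrom, src_size = t_size, src_start = t_start, src_end = t_end,
      tgt_chrom = q_chrom, tgt_size = q_size, tgt_strand = q_strand,
      tgt_start = tgt_start, tgt_end = tgt_end
    )
    blocks[[k]] <- tibble(
      chain_id = id,
      src_start = src_b, src_end = src_b + sizes,
      tgt_start = tgt_b_start, tgt_end = tgt_b_end
    )
  }
  chain_set(bind_rows(chains), bind_rows(blocks))
}

#' Write a UCSC chain file
#'
#' Inverse of [read_chain()]: plus-strand block coordinates are converted back
#' to strand-local chain coordinates, so `write_chain()` followed by
#' [read_chain()] reproduces the block structure exactly.
#'
#' @param x A [chain_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(x, path) {
  stopifnot(inherits(x, "chain_set"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  out <- character(0)
  for (i in seq_len(nrow(x$chains))) {
    ch <- x$chains[i, ]
    b <- x$blocks[x$blocks$chain_id == ch$chain_id, , drop = FALSE]
    b <- b[order(b$src_start), , drop = FALSE]
    sizes <- b$src_end - b$src_start
    if (ch$tgt_strand == "+") {
      q_b <- b$tgt_start
      q_start <- ch$tgt_start; q_end <- ch$tgt_end
    } else {
      q_b <- ch$tgt_size - b$tgt_end
      q_start <- ch$tgt_size - ch$tgt_end; q_end <- ch$tgt_size - ch$tgt_start
    }
    hdr <- paste(
      "chain", fmt(ch$score), ch$src_chrom, fmt(ch$src_size), "+",
      fmt(ch$src_start), fmt(ch$src_end), ch$tgt_chrom, fmt(ch$tgt_size),
      ch$tgt_strand, fmt(q_start), fmt(q_end), fmt(ch$chain_id)
    )
    n <- length(sizes)
    if (n > 1L) {
      dt <- b$src_start[-1] - (b$src_start[-n] + sizes[-n])
      dq <- q_b[-1] - (q_b[-n] + sizes[-n])
      body <- c(
        paste(fmt(sizes[-n]), fmt(dt), fmt(dq), sep = "\t"),
        fmt(sizes[n])
      )
    } else {
      body <- fmt(sizes)
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- BED annotation ---------------------------------------------------------

#' Read locus annotations from BED
#'
#' Reads BED6 (`chrom start end name score strand`, 0-based half-open) with an
#' optional 7th column giving the biotype (`gene` or `pseudogene`; default
#' `gene`). The annotated TSS is derived from the strand convention: `start`
#' for plus-strand loci, `end - 1` for minus-strand loci.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `biotype`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  tbl <- readr::read_tsv(
    path, col_names = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(tbl) < 6L) abort(sprintf("%s: need at least 6 BED columns", path))
  ann <- tibble(
    locus_id = tbl[[4]],
    chrom = tbl[[1]],
    start = as.integer(tbl[[2]]),
    end = as.integer(tbl[[3]]),
    strand = tbl[[6]],
    biotype = if (ncol(tbl) >= 7L) tbl[[7]] else "gene"
  )
  check_interval(ann$chrom, ann$start, ann$end)
  check_strand(ann$strand)
  if (anyDuplicated(ann$locus_id)) abort(sprintf("%s: duplicated locus ids", path))
  if (!all(ann$biotype %in% c("gene", "pseudogene"))) {
    abort(sprintf("%s: biotype must be 'gene' or 'pseudogene'", path))
  }
  ann |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    select("locus_id", "chrom", "start", "end", "strand", "tss", "biotype")
}

#' Write locus annotations to BED
#'
#' Writes BED6 plus a 7th biotype column (see [read_bed()]).
#'
#' @param annotation Annotation tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  writeLines(
    sprintf(
      "%s\t%d\t%d\t%s\t0\t%s\t%s",
      annotation$chrom, annotation$start, annotation$end,
      annotation$locus_id, annotation$strand, annotation$biotype
    ),
    path
  )
  invisible(path)
}

# ---- sequences and trees ----------------------------------------------------

#' Read sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (labels from the headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must be named")
  }
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Write / read a tree in newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; topology
#' round-trips exactly.
#'
#' @param tree An [ape::phylo] tree.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` an
#'   `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

# ---- tabular artifacts ------------------------------------------------------

#' Write / read a candidate table
#'
#' Tab-separated with a header line; the screening cascade's per-window
#' record (see [run_screen()]).
#'
#' @param table Candidate tibble.
#' @param path File path.
#' @return `write_candidates()` returns `path` invisibly; `read_candidates()`
#'   a tibble.
#' @export
write_candidates <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a long-format Ct table
#'
#' Tab-separated with columns `sample`, `gene`, `replicate`, `ct`.
#'
#' @param ct_table Ct tibble.
#' @param path File path.
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()` a
#'   tibble.
#' @export
write_ct_table <- function(ct_table, path) {
  readr::write_tsv(ct_table, path)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(sample = as.character(.data$sample), gene = as.character(.data$gene))
}

#' Write / read two-channel fluorescence traces
#'
#' Tab-separated with columns `trace_id`, `time`, `f340`, `f380` (time in
#' seconds, fluorescence in arbitrary units).
#'
#' @param traces Trace tibble.
#' @param path File path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_tsv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(trace_id = as.character(.data$trace_id))
}
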