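# Colinear (syntenic) block detection: sparse dynamic-programming chaining
# of homolog hits on gene-rank coordinates, with a Poisson chain-probability
# significance model.

.canonical_hits <- function(hits) {
  if (all(c("query", "subject") %in% names(hits))) return(hits)
  if (ncol(hits) >= 12 && is.numeric(hits[[3]])) {
    names(hits)[1:12] <- .BLAST_COLS
    return(hits)
  }
  stop("hits must have columns 'query' and 'subject' (BLAST tabular dialect)")
}

#' Detect colinear blocks between two gene-order tables
#'
#' Chains homolog hits into maximal runs of gene pairs whose ranks are
#' strictly monotonic on both chromosomes (parallel or antiparallel), with
#' consecutive pairs separated by at most `max_gap` ranks on each
#' chromosome and at least `min_pairs` pairs per block.  Within each
#' chromosome pair, chains are extracted greedily (longest first; ties by
#' smaller rank span, then leftmost start) and each hit is assigned to at
#' most one block.  When `A` and `B` are the same genome (paralogy mode),
#' self pairs are dropped and each block is emitted once.
#'
#' @param hits homolog hits: data frame with `query` (gene in `A`),
#'   `subject` (gene in `B`), and optionally `evalue`; 12-column BLAST
#'   tabular input is accepted as-is
#' @param A,B [genome_table()]s
#' @param max_gap maximum rank separation of neighbouring pairs
#' @param min_pairs minimum colinear pairs per block
#' @param max_evalue E-value filter applied to `hits`
#' @return object of class `colinear_blocks`: list with `blocks` (one row
#'   per block: id, chromosome pair, orientation, n_pairs, rank spans,
#'   p_value, median_ks placeholder) and `pairs` (gene pairs per block)
#' @export
detect_blocks <- function(hits, A, B, max_gap = 50L, min_pairs = 4L,
                          max_evalue = 1e-5) {
  stopifnot(inherits(A, "genome_table"), inherits(B, "genome_table"))
  hits <- .canonical_hits(hits)
  if ("evalue" %in% names(hits))
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  self_mode <- identical(A$taxon, B$taxon)
  empty <- function() {
    structure(list(
      blocks = data.frame(block_id = integer(), chr_a = character(),
                          chr_b = character(), orientation = character(),
                          n_pairs = integer(), start_a = integer(),
                          end_a = integer(), start_b = integer(),
                          end_b = integer(), p_value = numeric(),
                          median_ks = numeric(), stringsAsFactors = FALSE),
      pairs = data.frame(block_id = integer(), gene_a = character(),
                         gene_b = character(), rank_a = integer(),
                         rank_b = integer(), stringsAsFactors = FALSE),
      taxon_a = A$taxon, taxon_b = B$taxon,
      max_gap = max_gap, min_pairs = min_pairs), class = "colinear_blocks")
  }
  if (!nrow(hits)) return(empty())

  ia <- match(hits$query, A$genes$id)
  ib <- match(hits$subject, B$genes$id)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(hits$query[is.na(ia)], hits$subject[is.na(ib)]))
    stop("hit refers to unknown gene id(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  h <- data.frame(gene_a = hits$query, gene_b = hits$subject,
                  chr_a = A$genes$chr[ia], rank_a = A$genes$rank[ia],
                  chr_b = B$genes$chr[ib], rank_b = B$genes$rank[ib],
                  stringsAsFactors = FALSE)
  if (self_mode) {
    h <- h[h$gene_a != h$gene_b, , drop = FALSE]
    # one canonical orientation per unordered pair
    swap <- (h$chr_a > h$chr_b) | (h$chr_a == h$chr_b & h$rank_a > h$rank_b)
    h[swap, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
      h[swap, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
    h <- h[!duplicated(h[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  if (!nrow(h)) return(empty())

  chr_sizes_a <- table(A$genes$chr)
  chr_sizes_b <- table(B$genes$chr)
  groups <- split(h, list(h$chr_a, h$chr_b), drop = TRUE)
  groups <- groups[order(names(groups))]
  all_blocks <- list(); all_pairs <- list(); bid <- 0L
  for (g in groups) {
    n_bg <- nrow(g)
    la <- as.integer(chr_sizes_a[[g$chr_a[1]]])
    lb <- as.integer(chr_sizes_b[[g$chr_b[1]]])
    repeat {
      if (nrow(g) < min_pairs) break
      ch_par <- .best_chain(g$rank_a, g$rank_b, max_gap, antiparallel = FALSE)
      ch_anti <- .best_chain(g$rank_a, g$rank_b, max_gap, antiparallel = TRUE)
      ch <- .pick_chain(ch_par, ch_anti)
      if (is.null(ch) || length(ch$idx) < min_pairs) break
      bid <- bid + 1L
      sel <- g[ch$idx, , drop = FALSE]
      sel <- sel[order(sel$rank_a), , drop = FALSE]
      all_blocks[[bid]] <- data.frame(
        block_id = bid, chr_a = sel$chr_a[1], chr_b = sel$chr_b[1],
        orientation = if (ch$antiparallel) "antiparallel" else "parallel",
        n_pairs = nrow(sel),
        start_a = min(sel$rank_a), end_a = max(sel$rank_a),
        start_b = min(sel$rank_b), end_b = max(sel$rank_b),
        p_value = .chain_p_value(nrow(sel), n_bg, la, lb, max_gap),
        median_ks = NA_real_, stringsAsFactors = FALSE)
      all_pairs[[bid]] <- data.frame(
        block_id = bid, gene_a = sel$gene_a, gene_b = sel$gene_b,
        rank_a = sel$rank_a, rank_b = sel$rank_b, stringsAsFactors = FALSE)
      g <- g[-ch$idx, , drop = FALSE]
    }
  }
  out <- empty()
  if (bid > 0L) {
    blocks <- do.call(rbind, all_blocks)
    ord <- order(blocks$chr_a, blocks$chr_b, blocks$start_a)
    blocks <- blocks[ord, , drop = FALSE]
    id_map <- setNames(seq_len(nrow(blocks)), blocks$block_id)
    blocks$block_id <- as.integer(id_map[as.character(blocks$block_id)])
    pairs <- do.call(rbind, all_pairs)
    pairs$block_id <- as.integer(id_map[as.character(pairs$block_id)])
    pairs <- pairs[order(pairs$block_id, pairs$rank_a), , drop = FALSE]
    rownames(blocks) <- rownames(pairs) <- NULL
    out$blocks <- blocks
    out$pairs <- pairs
  }
  out
}

# Longest strictly monotone chain under the gap constraint (DP).
# Ties are broken by smaller total rank span, then smaller summed rank
# coordinate sum(x+y), then smaller summed diagonal offset sum|x-y| —
# additive, genome-swap-invariant criteria that both this DP and the
# exhaustive test oracle can optimise exactly.
# Returns list(idx, len, span, s1, s2, antiparallel) or NULL.
.best_chain <- function(rank_a, rank_b, max_gap, antiparallel = FALSE) {
  n <- length(rank_a)
  if (n == 0L) return(NULL)
  y <- if (antiparallel) -rank_b else rank_b
  ord <- order(rank_a, y)
  x <- rank_a[ord]; yy <- y[ord]; yraw <- rank_b[ord]
  k1 <- x + yraw; k2 <- abs(x - yraw)
  len <- rep(1L, n); parent <- rep(0L, n); span <- rep(0L, n)
  s1 <- k1; s2 <- k2
  for (i in seq_len(n)) {
    j <- i - 1L
    while (j >= 1L && x[i] - x[j] <= max_gap) {
      dx <- x[i] - x[j]; dy <- yy[i] - yy[j]
      if (dx >= 1L && dy >= 1L && dy <= max_gap) {
        cl <- len[j] + 1L
        cs <- span[j] + dx + dy
        c1 <- s1[j] + k1[i]
        c2 <- s2[j] + k2[i]
        if (cl > len[i] ||
            (cl == len[i] && (cs < span[i] ||
              (cs == span[i] && (c1 < s1[i] ||
                (c1 == s1[i] && c2 < s2[i])))))) {
          len[i] <- cl; parent[i] <- j; span[i] <- cs; s1[i] <- c1; s2[i] <- c2
        }
      }
      j <- j - 1L
    }
  }
  best <- which(len == max(len))
  best <- best[order(span[best], s1[best], s2[best], k1[best], k2[best])][1]
  idx <- integer(0); i <- best
  while (i > 0L) { idx <- c(i, idx); i <- parent[i] }
  list(idx = ord[idx], len = len[best], span = span[best],
       s1 = s1[best], s2 = s2[best], antiparallel = antiparallel)
}

.pick_chain <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (b$len > a$len ||
      (b$len == a$len && (b$span < a$span ||
        (b$span == a$span && (b$s1 < a$s1 ||
          (b$s1 == a$s1 && b$s2 < a$s2)))))) b else a
}

# Poisson approximation of the chain probability.  With N hits on an
# la x lb rank grid, each chain extension must land in the max_gap^2
# successor window, giving per-step intensities (N-k) g^2 / (la lb)
# (sampling without replacement), shrunk by an edge factor for starts too
# close to the grid boundary; the expected number of left-maximal monotone
# chains of >= m pairs over both orientations is then
# E = 2 N prod(step intensities) edge^(m-1) (1 - mu), and p = 1 - exp(-E).
.chain_p_value <- function(m, n_hits, la, lb, max_gap) {
  if (n_hits <= 0) {
    warning("zero-density background; p-value set to 0")
    return(0)
  }
  g <- as.numeric(max_gap)
  cells <- as.numeric(la) * as.numeric(lb)
  mu <- n_hits * g^2 / cells
  if (mu >= 1) return(1)
  steps <- pmax(n_hits - seq_len(m - 1), 0) * g^2 / cells
  if (any(steps == 0)) return(0)
  edge <- max(0, (1 - g / (2 * as.numeric(la)))) *
    max(0, (1 - g / (2 * as.numeric(lb))))
  logE <- log(2) + log(n_hits) + sum(log(steps)) +
    (m - 1) * log(max(edge, 1e-12)) + log1p(-mu)
  if (logE > 700) return(1)
  1 - exp(-exp(logE))
}

#' Significance of a colinear block
#'
#' Poisson chain-probability model in the spirit of ColinearScan: the
#' p-value is the probability of observing at least one monotone chain of
#' the block's length among `n_hits` homolog hits scattered uniformly on the
#' chromosome pair's rank grid.  Decreases monotonically with block length
#' at fixed hit density.
#'
#' @param block a row of `blocks` from [detect_blocks()], or the number of
#'   colinear pairs
#' @param n_hits background hit count on the chromosome pair
#' @param len_a,len_b gene counts of the two chromosomes
#' @param max_gap gap constraint used in chaining
#' @return p-value in \[0, 1\]
#' @export
score_block_significance <- function(block, n_hits, len_a, len_b,
                                     max_gap = 50L) {
  m <- if (is.numeric(block)) block else block$n_pairs
  .chain_p_value(m, n_hits, len_a, len_b, max_gap)
}

#' @export
print.colinear_blocks <- function(x, ...) {
  cat(sprintf("%d colinear block(s) between %s and %s (%d gene pairs)\n",
              nrow(x$blocks), x$taxon_a, x$taxon_b, nrow(x$pairs)))
  if (nrow(x$blocks)) print(utils::head(x$blocks, 10))
  invisible(x)
}

#' Write blocks (and their gene pairs) as TSV
#' @param blocks a `colinear_blocks`
#' @param path output file for the block table; the gene-pair table goes to
#'   `<path>.pairs`
#' @export
write_blocks_tsv <- function(blocks, path) {
  write.table(blocks$blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(blocks$pairs, paste0(path, ".pairs"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
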