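# Reference-anchored multi-genome alignment tables, missing-gene
# (fractionation) counts, and the region-similarity statistic used to test
# shared vs independent polyploidy.

#' Build a reference-anchored alignment table
#'
#' Rows are the reference genes in order; each target genome contributes as
#' many columns as its orthology depth (e.g. 3 durian and 5 cotton columns
#' on a grape reference).  Ortholog-labelled blocks are assigned to columns
#' by interval-graph coloring on their reference rank intervals (longest
#' block first; overlapping blocks get different columns), so blocks from
#' one post-event subgenome tend to share a column; cells hold the target
#' gene colinear with the reference gene.
#'
#' @param reference the reference [genome_table()]
#' @param target_blocks named list (per target genome) of classified blocks
#'   from [classify_blocks_by_ks()], with the reference as side A
#' @param depths optional named integer vector of column counts per target;
#'   defaults to each target's maximum overlap depth
#' @param label block label to align (`"ortholog"`; `"outparalog"` gives an
#'   outparalogous table)
#' @return object of class `alignment_table`: list with `ref_genes`, and
#'   per target a character matrix (reference genes x columns, `NA` =
#'   fractionated/absent) plus the block-to-column assignment
#' @export
build_alignment_table <- function(reference, target_blocks, depths = NULL,
                                  label = "ortholog") {
  stopifnot(inherits(reference, "genome_table"))
  ref <- reference$genes
  out <- list(reference = reference$taxon, ref_genes = ref$id,
              targets = list())
  for (tgt in names(target_blocks)) {
    blocks <- target_blocks[[tgt]]
    bl <- blocks$blocks
    if (is.null(bl$label)) stop("blocks for ", tgt, " are not classified")
    keep <- bl$label == label
    bl <- bl[keep, , drop = FALSE]
    pr <- blocks$pairs[blocks$pairs$block_id %in% bl$block_id, , drop = FALSE]

    # interval-graph coloring per reference chromosome, longest block first
    bl <- bl[order(-bl$n_pairs), , drop = FALSE]
    col_of <- integer(nrow(bl))
    if (nrow(bl)) {
      occupied <- list()  # per column: data frame of chr/intervals
      for (i in seq_len(nrow(bl))) {
        placed <- FALSE
        for (cc in seq_along(occupied)) {
          occ <- occupied[[cc]]
          clash <- any(occ$chr == bl$chr_a[i] &
                         occ$lo <= bl$end_a[i] & occ$hi >= bl$start_a[i])
          if (!clash) {
            occupied[[cc]] <- rbind(occ, data.frame(
              chr = bl$chr_a[i], lo = bl$start_a[i], hi = bl$end_a[i]))
            col_of[i] <- cc; placed <- TRUE; break
          }
        }
        if (!placed) {
          occupied[[length(occupied) + 1L]] <- data.frame(
            chr = bl$chr_a[i], lo = bl$start_a[i], hi = bl$end_a[i])
          col_of[i] <- length(occupied)
        }
      }
    }
    n_col <- if (!is.null(depths) && tgt %in% names(depths))
      as.integer(depths[[tgt]]) else max(col_of, 1L)
    overflow <- col_of > n_col
    if (any(overflow)) {
      warning(sum(overflow), " block(s) for ", tgt,
              " exceed ", n_col, " columns; assigned to the overflow column")
      col_of[overflow] <- n_col
    }
    mat <- matrix(NA_character_, nrow = nrow(ref), ncol = n_col,
                  dimnames = list(ref$id, paste0(tgt, "_", seq_len(n_col))))
    block_col <- setNames(col_of, bl$block_id)
    ri <- match(pr$gene_a, ref$id)
    ci <- block_col[as.character(pr$block_id)]
    ok <- !is.na(ri) & !is.na(ci)
    mat[cbind(ri[ok], ci[ok])] <- pr$gene_b[ok]
    out$targets[[tgt]] <- list(matrix = mat,
                               block_columns = data.frame(
                                 block_id = bl$block_id, column = col_of))
  }
  structure(out, class = "alignment_table")
}

#' @export
print.alignment_table <- function(x, ...) {
  cat(sprintf("Alignment table on reference '%s' (%d genes)\n",
              x$reference, length(x$ref_genes)))
  for (tgt in names(x$targets)) {
    m <- x$targets[[tgt]]$matrix
    cat(sprintf("  %-7s %d column(s), fill %.1f%%\n", tgt, ncol(m),
                100 * mean(!is.na(m))))
  }
  invisible(x)
}

#' Fraction of reference genes missing from all columns of a target
#'
#' The whole-genome fractionation statistic: the share of reference genes
#' with no colinear gene in any of the target's homologous regions.
#'
#' @param table an `alignment_table`
#' @param target target genome name (default: all targets)
#' @return named numeric vector of missing fractions in \[0, 1\]
#' @export
count_missing <- function(table, target = NULL) {
  stopifnot(inherits(table, "alignment_table"))
  tgts <- if (is.null(target)) names(table$targets) else target
  vapply(tgts, function(tgt) {
    m <- table$targets[[tgt]]$matrix
    if (nrow(m) == 0L) return(NA_real_)
    mean(rowSums(!is.na(m)) == 0L)
  }, numeric(1))
}

#' Region similarity between two alignment-table columns
#'
#' For a durian column dz and a cotton column gr over the same reference
#' gene set, the similarity is the fraction of gr-filled reference
#' positions that are also dz-filled: |dz AND gr| / |gr|.  Near-1 values
#' across matched columns indicate shared post-event ancestry (common
#' fractionation pattern); uniformly low values indicate independent
#' events.
#'
#' @param dz_col,gr_col logical or character vectors (cells/fill indicators
#'   over the same reference positions)
#' @return similarity in \[0, 1\], or `NA` if `gr_col` is empty
#' @export
region_similarity <- function(dz_col, gr_col) {
  if (length(dz_col) != length(gr_col))
    stop("columns must cover the same reference gene set")
  dz <- if (is.logical(dz_col)) dz_col else !is.na(dz_col)
  gr <- if (is.logical(gr_col)) gr_col else !is.na(gr_col)
  if (!any(gr)) return(NA_real_)
  sum(dz & gr) / sum(gr)
}

#' All-pairs region-similarity matrix between two targets
#'
#' Computes [region_similarity()] for every column pair of two targets
#' (e.g. the 3 x 5 durian x cotton combinations), the best match per dz
#' column, and the margin between best and second-best.
#'
#' @param table an `alignment_table`
#' @param target_a,target_b the two target genomes (columns of `target_a`
#'   play the dz role)
#' @return list with `matrix` (similarities), `best_mean` (mean best-match
#'   similarity over `target_a` columns) and `margin_mean` (mean
#'   best-minus-second margin)
#' @export
similarity_profile <- function(table, target_a, target_b) {
  ma <- table$targets[[target_a]]$matrix
  mb <- table$targets[[target_b]]$matrix
  if (is.null(ma) || is.null(mb)) stop("unknown target genome")
  sim <- matrix(NA_real_, ncol(ma), ncol(mb),
                dimnames = list(colnames(ma), colnames(mb)))
  for (i in seq_len(ncol(ma)))
    for (j in seq_len(ncol(mb)))
      sim[i, j] <- region_similarity(ma[, i], mb[, j])
  best <- apply(sim, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  second <- apply(sim, 1, function(r) {
    r <- sort(r[!is.na(r)], decreasing = TRUE)
    if (length(r) >= 2) r[2] else NA_real_
  })
  list(matrix = sim, best = best,
       best_mean = mean(best, na.rm = TRUE),
       margin_mean = mean(best - second, na.rm = TRUE))
}

#' Write an alignment table as TSV
#' @param table an `alignment_table`
#' @param path output file (reference gene id column followed by all target
#'   columns; empty cells are `.`)
#' @export
write_alignment_tsv <- function(table, path) {
  mats <- lapply(table$targets, `[[`, "matrix")
  df <- data.frame(ref_gene = table$ref_genes, stringsAsFactors = FALSE)
  for (m in mats) {
    m[is.na(m)] <- "."
    df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
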