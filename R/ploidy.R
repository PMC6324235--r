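# Ploidy-level inference from homologous-gene dotplots: Ks-based
# classification of blocks into orthologous vs outparalogous, and depth
# profiling of homologous-region counts per reference window.

#' Classify colinear blocks as orthologous or outparalogous by median Ks
#'
#' Blocks with median Ks below `ortholog_max` are orthologous (produced by
#' the speciation), above `outparalog_min` outparalogous (produced by the
#' shared hexaploidization); blocks between the thresholds, or exactly at
#' one, are ambiguous and excluded from ratio counting.
#'
#' @param blocks a `colinear_blocks` with `median_ks` filled (see
#'   [block_median_ks()])
#' @param ortholog_max,outparalog_min Ks thresholds; must satisfy
#'   `ortholog_max <= outparalog_min`
#' @return `blocks` with a `label` column (`ortholog`, `outparalog`,
#'   `ambiguous`)
#' @export
classify_blocks_by_ks <- function(blocks, ortholog_max = 0.95,
                                  outparalog_min = 1.30) {
  if (ortholog_max > outparalog_min)
    stop("thresholds inverted: ortholog_max must not exceed outparalog_min")
  med <- blocks$blocks$median_ks
  lab <- rep("ambiguous", length(med))
  lab[!is.na(med) & med < ortholog_max] <- "ortholog"
  lab[!is.na(med) & med > outparalog_min] <- "outparalog"
  blocks$blocks$label <- lab
  blocks
}

# Merge blocks that are complements of one chromosome breakage or
# rearrangement: same chromosome pair, compatible (non-overlapping, nearby)
# rank intervals on both genomes.  Returns a region id per block row.
.merge_block_regions <- function(bl, merge_gap) {
  n <- nrow(bl)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  adjacent <- function(lo1, hi1, lo2, hi2)
    (lo2 > hi1 & lo2 - hi1 <= merge_gap) | (lo1 > hi2 & lo1 - hi2 <= merge_gap)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (bl$chr_a[i] != bl$chr_a[j] || bl$chr_b[i] != bl$chr_b[j]) next
      if (adjacent(bl$start_a[i], bl$end_a[i], bl$start_a[j], bl$end_a[j]) &&
          adjacent(bl$start_b[i], bl$end_b[i], bl$start_b[j], bl$end_b[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Depth profile: homologous-region counts per reference window
#'
#' Partitions each reference chromosome into windows of `window` genes and
#' counts, per window, the distinct orthologous and outparalogous target
#' regions whose blocks overlap it.  Blocks on the same chromosome pair
#' that are rank-adjacent on both genomes (complements produced by a
#' chromosome breakage or local rearrangement) are merged into one region
#' first.  The modal counts over windows with at least one hit give the
#' orthology and outparalogy ratios (1 reference region : mode target
#' regions), the dotplot-derived estimate of relative ploidy.
#'
#' @param reference the reference [genome_table()] (side A of the blocks)
#' @param blocks classified blocks from [classify_blocks_by_ks()]
#' @param window window size in genes
#' @param merge_gap maximum rank gap when merging complement blocks
#' @return object of class `depth_profile`: list with `windows` (per-window
#'   counts), `orthology_ratio`, `outparalogy_ratio` (modal counts), and the
#'   window parameters
#' @export
depth_profile <- function(reference, blocks, window = 20L, merge_gap = 50L) {
  stopifnot(inherits(reference, "genome_table"))
  bl <- blocks$blocks
  if (is.null(bl$label)) stop("blocks must be classified first")
  bl <- bl[bl$label %in% c("ortholog", "outparalog"), , drop = FALSE]

  chrs <- unique(reference$genes$chr)
  sizes <- table(reference$genes$chr)
  win_list <- list()
  for (ch in chrs) {
    n <- as.integer(sizes[[ch]])
    starts <- seq(0L, n - 1L, by = window)
    win_list[[ch]] <- data.frame(chr = ch, win_start = starts,
                                 win_end = pmin(starts + window, n),
                                 stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, win_list)
  wins$n_ortholog <- 0L
  wins$n_outparalog <- 0L
  rownames(wins) <- NULL

  if (nrow(bl)) {
    bl$region <- NA_integer_
    for (lab in c("ortholog", "outparalog")) {
      sub <- which(bl$label == lab)
      if (length(sub))
        bl$region[sub] <- paste0(lab, "_", .merge_block_regions(
          bl[sub, , drop = FALSE], merge_gap))
    }
    for (w in seq_len(nrow(wins))) {
      ov <- bl$chr_a == wins$chr[w] &
        bl$start_a < wins$win_end[w] & bl$end_a >= wins$win_start[w]
      wins$n_ortholog[w] <-
        length(unique(bl$region[ov & bl$label == "ortholog"]))
      wins$n_outparalog[w] <-
        length(unique(bl$region[ov & bl$label == "outparalog"]))
    }
  }
  modal <- function(v) {
    v <- v[v > 0L]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])
  }
  structure(list(windows = wins,
                 orthology_ratio = modal(wins$n_ortholog),
                 outparalogy_ratio = modal(wins$n_outparalog),
                 reference = reference$taxon, target = blocks$taxon_b,
                 window = window, merge_gap = merge_gap),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile: %s (reference) vs %s, %d windows of %d genes\n",
              x$reference, x$target, nrow(x$windows), x$window))
  cat(sprintf("  modal orthology ratio   1:%s\n",
              format(x$orthology_ratio)))
  cat(sprintf("  modal outparalogy ratio 1:%s\n",
              format(x$outparalogy_ratio)))
  invisible(x)
}

#' Categorise homolog hits for dotplotting
#'
#' Marks, per query gene, the best hit (highest bit score; ties by identity
#' then subject id), the next `n_secondary` hits as secondary, and the rest
#' as other — the red/blue/gray convention of homologous-gene dotplots.
#'
#' @param hits hit data frame (see [detect_blocks()] for accepted layouts)
#' @param n_secondary secondary hits per query
#' @return `hits` with a `category` column
#' @export
categorize_hits <- function(hits, n_secondary = 4L) {
  hits <- .canonical_hits(hits)
  if (is.null(hits$bits)) hits$bits <- hits$pident
  ord <- order(hits$query, -hits$bits,
               -if (is.null(hits$pident)) hits$bits else hits$pident,
               hits$subject)
  hits <- hits[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  hits$category <- ifelse(idx == 1L, "best",
                          ifelse(idx <= 1L + n_secondary, "secondary", "other"))
  rownames(hits) <- NULL
  hits
}

#' Render a homologous-gene dotplot
#'
#' Scatter of gene-rank coordinates with best hits in red, secondary in
#' blue, others in gray, and detected blocks overlaid and annotated with
#' their median Ks.  Chromosomes are laid out consecutively with boundary
#' lines.
#'
#' @param hits categorised hits (see [categorize_hits()]; plain hits are
#'   categorised on the fly)
#' @param A,B the two [genome_table()]s (A on the x axis)
#' @param blocks optional `colinear_blocks` with `median_ks`
#' @param path output file; `.svg` and/or `.png` written according to
#'   `formats`
#' @param formats subset of `c("svg", "png")`
#' @return (invisibly) the written file paths
#' @export
render_dotplot <- function(hits, A, B, blocks = NULL, path,
                           formats = c("svg", "png")) {
  formats <- match.arg(formats, several.ok = TRUE)
  hits <- if (nrow(hits)) categorize_hits(hits) else hits
  offs <- function(gt) {
    sizes <- table(gt$genes$chr)
    off <- cumsum(c(0, as.numeric(sizes)))
    setNames(off[-length(off)], names(sizes))
  }
  off_a <- offs(A); off_b <- offs(B)
  tot_a <- nrow(A$genes); tot_b <- nrow(B$genes)
  draw <- function() {
    graphics::plot(NULL, xlim = c(0, max(1, tot_a)), ylim = c(0, max(1, tot_b)),
                   xlab = paste(A$taxon, "gene rank"),
                   ylab = paste(B$taxon, "gene rank"),
                   main = sprintf("%s vs %s homologous gene dotplot",
                                  A$taxon, B$taxon))
    graphics::abline(v = off_a[-1], h = off_b[-1], col = "gray85")
    if (nrow(hits)) {
      ia <- match(hits$query, A$genes$id)
      ib <- match(hits$subject, B$genes$id)
      x <- off_a[A$genes$chr[ia]] + A$genes$rank[ia]
      y <- off_b[B$genes$chr[ib]] + B$genes$rank[ib]
      col <- c(best = "red", secondary = "blue", other = "gray60")[hits$category]
      graphics::points(x, y, pch = 16, cex = 0.3, col = col)
    }
    if (!is.null(blocks) && nrow(blocks$blocks)) {
      bl <- blocks$blocks
      for (i in seq_len(nrow(bl))) {
        x0 <- off_a[bl$chr_a[i]] + bl$start_a[i]
        x1 <- off_a[bl$chr_a[i]] + bl$end_a[i]
        yy <- if (bl$orientation[i] == "parallel")
          c(bl$start_b[i], bl$end_b[i]) else c(bl$end_b[i], bl$start_b[i])
        y0 <- off_b[bl$chr_b[i]] + yy[1]
        y1 <- off_b[bl$chr_b[i]] + yy[2]
        graphics::segments(x0, y0, x1, y1, col = "black", lwd = 1.2)
        graphics::text((x0 + x1) / 2, (y0 + y1) / 2,
                       labels = sprintf("Ks=%.2f", bl$median_ks[i]),
                       cex = 0.5, pos = 3)
      }
    }
  }
  out <- character(0)
  base <- sub("\\.(svg|png)$", "", path)
  if ("svg" %in% formats) {
    f <- paste0(base, ".svg")
    grDevices::svg(f, width = 7, height = 7)
    draw(); grDevices::dev.off()
    out <- c(out, f)
  }
  if ("png" %in% formats) {
    f <- paste0(base, ".png")
    ok <- tryCatch({
      grDevices::png(f, width = 900, height = 900)
      draw(); grDevices::dev.off(); TRUE
    }, error = function(e) { try(grDevices::dev.off(), silent = TRUE); FALSE })
    if (ok) out <- c(out, f)
  }
  invisible(out)
}
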