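# Ks/Ka estimation (Nei-Gojobori) and Ks age-distribution mixture fitting.

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both CDSs, aligns the proteins globally, and back-translates
#' the alignment to codons.  Gapped columns are dropped, so the result is a
#' pair of equal-length codon vectors suitable for [nei_gojobori()].
#'
#' @param cds_a,cds_b coding sequences (character strings or
#'   [Biostrings::DNAString]); length must be a multiple of 3 with no
#'   internal stop codon
#' @param id_a,id_b optional sequence names used in error messages
#' @return object of class `codon_alignment`: list with integer codon
#'   vectors `a` and `b` (codons indexed 1..64) and the ungapped column count
#' @export
align_codons <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  enc <- lapply(list(cds_a, cds_b), function(x) as.character(x))
  ids <- c(id_a, id_b)
  cod <- vector("list", 2)
  for (k in 1:2) {
    s <- toupper(gsub("U", "T", enc[[k]]))
    if (nchar(s) %% 3 != 0)
      stop("length of CDS '", ids[k], "' is not a multiple of 3")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    idx <- .codon_index(cods)
    if (anyNA(idx))
      stop("CDS '", ids[k], "' contains non-ACGT characters")
    aa <- .codon_table()$aa[idx]
    if (any(aa[-length(aa)] == "*"))
      stop("CDS '", ids[k], "' contains an internal stop codon")
    if (aa[length(aa)] == "*") idx <- idx[-length(idx)]
    cod[[k]] <- idx
  }
  prot <- vapply(cod, function(idx)
    paste(.codon_table()$aa[idx], collapse = ""), character(1))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot[1]), Biostrings::AAString(prot[2]),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  structure(list(a = cod[[1]][ia[keep]], b = cod[[2]][ib[keep]],
                 n_codons = sum(keep), id_a = id_a, id_b = id_b),
            class = "codon_alignment")
}

#' Nei-Gojobori estimate of synonymous and nonsynonymous divergence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over the two
#' sequences, counts observed differences averaged over minimal mutational
#' pathways, and applies the Jukes-Cantor correction
#' d = -(3/4) log(1 - 4p/3) to the proportions ps and pn.  Proportions at or
#' beyond the correction's domain (p >= 3/4) yield an `NA` estimate flagged
#' as saturated.
#'
#' @param alignment a `codon_alignment` from [align_codons()], or a list with
#'   integer codon vectors `a` and `b` of equal length (gap-free)
#' @return object of class `ks_estimate`: list with `ks`, `ka`, `S`, `N`,
#'   `sd_count`, `nd_count`, `ps`, `pn`, `saturated_ks`, `saturated_ka`
#' @export
#' @examples
#' aln <- list(a = .codon_index(c("GGG", "GGA")), b = .codon_index(c("GGG", "GGG")))
#' nei_gojobori(aln)$ks  # -(3/4) log(1/3) = 0.8240
nei_gojobori <- function(alignment) {
  a <- alignment$a; b <- alignment$b
  if (length(a) != length(b)) stop("codon vectors differ in length")
  tab <- .ng_tables()
  stops <- .codon_table()$is_stop
  if (any(stops[a]) || any(stops[b])) stop("alignment contains a stop codon")
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  N <- 3 * length(a) - S
  sd_count <- sum(tab$SD[cbind(a, b)])
  nd_count <- sum(tab$ND[cbind(a, b)])
  ps <- if (S > 0) sd_count / S else 0
  pn <- if (N > 0) nd_count / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  structure(list(ks = jc(ps), ka = jc(pn), S = S, N = N,
                 sd_count = sd_count, nd_count = nd_count, ps = ps, pn = pn,
                 saturated_ks = ps >= 0.75, saturated_ka = pn >= 0.75),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("Ks = %s  Ka = %s  (S = %.2f, N = %.2f)\n",
              format(x$ks, digits = 4), format(x$ka, digits = 4), x$S, x$N))
  invisible(x)
}

#' Vectorised Ks/Ka for many gene pairs
#'
#' Fast path for sets of pre-aligned coding sequences (for example simulator
#' output, where all genes share one codon frame and length).  For unequal
#' lengths the pair is aligned with [align_codons()] first.
#'
#' @param cds named list/vector of coding sequences, or an integer codon
#'   matrix (genes x codons) with rownames
#' @param pairs data frame with columns `gene_a`, `gene_b`
#' @param method `"auto"` aligns only unequal-length pairs; `"align"` always
#'   aligns; `"direct"` requires equal lengths
#' @return `pairs` with columns `ks`, `ka`, `S`, `N` appended
#' @export
ks_pairs <- function(cds, pairs, method = c("auto", "direct", "align")) {
  method <- match.arg(method)
  if (is.matrix(cds)) {
    mat <- cds
  } else {
    cds <- as.list(cds)
    lens <- vapply(cds, nchar, integer(1))
    if (method != "align" && length(unique(lens)) == 1L) {
      mat <- do.call(rbind, lapply(cds, function(s) {
        .codon_index(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
      }))
      rownames(mat) <- names(cds)
    } else {
      if (method == "direct") stop("sequences differ in length; cannot use method = 'direct'")
      res <- lapply(seq_len(nrow(pairs)), function(i) {
        aln <- align_codons(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]],
                            pairs$gene_a[i], pairs$gene_b[i])
        est <- nei_gojobori(aln)
        c(est$ks, est$ka, est$S, est$N)
      })
      res <- do.call(rbind, res)
      pairs$ks <- res[, 1]; pairs$ka <- res[, 2]
      pairs$S <- res[, 3]; pairs$N <- res[, 4]
      return(pairs)
    }
  }
  ia <- match(pairs$gene_a, rownames(mat))
  ib <- match(pairs$gene_b, rownames(mat))
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    stop("unknown gene id(s) in pairs: ", paste(head(bad, 5), collapse = ", "))
  }
  tab <- .ng_tables()
  L <- ncol(mat)
  n <- nrow(pairs)
  ks <- ka <- S <- N <- numeric(n)
  chunk <- 4000L
  site_per_gene <- rowSums(matrix(tab$syn_sites[mat], nrow = nrow(mat)))
  for (start in seq(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    A <- mat[ia[idx], , drop = FALSE]
    B <- mat[ib[idx], , drop = FALSE]
    sdc <- rowSums(matrix(tab$SD[cbind(as.vector(A), as.vector(B))], nrow = length(idx)))
    ndc <- rowSums(matrix(tab$ND[cbind(as.vector(A), as.vector(B))], nrow = length(idx)))
    Si <- (site_per_gene[ia[idx]] + site_per_gene[ib[idx]]) / 2
    Ni <- 3 * L - Si
    ps <- sdc / Si; pn <- ndc / Ni
    ks[idx] <- ifelse(ps >= 0.75, NA_real_,
                      -0.75 * log(pmax(1 - 4 * ps / 3, 1e-300)))
    ka[idx] <- ifelse(pn >= 0.75, NA_real_,
                      -0.75 * log(pmax(1 - 4 * pn / 3, 1e-300)))
    S[idx] <- Si; N[idx] <- Ni
  }
  pairs$ks <- ks; pairs$ka <- ka; pairs$S <- S; pairs$N <- N
  pairs
}

#' Decompose a Ks sample into Gaussian components
#'
#' Reproduces the kernel-density-plus-curve-fitting approach: a Gaussian
#' kernel density (default bandwidth 0.05) is evaluated on a fixed grid over
#' \[0, 3\], and a sum of Gaussian components is fitted to that density curve
#' by least squares.  The number of components is the smallest for which the
#' coefficient of determination R^2 reaches `r2_min`; components are
#' returned sorted by mean, and the component with the largest weight is
#' marked as the principal one representing the underlying event.
#'
#' @param ks numeric vector of Ks values; non-finite values and values
#'   outside \[0, `ks_max`\] are dropped as saturated noise
#' @param bandwidth kernel standard deviation (Ks units)
#' @param r2_min target goodness of fit
#' @param max_components largest number of components tried
#' @param min_n minimum usable sample size
#' @param ks_max upper end of the evaluation grid
#' @param grid_n number of grid points
#' @return object of class `ks_peak_fit`: list with `components` (data frame
#'   mean/sd/weight), `r2`, `n_components`, `principal`, `bandwidth`,
#'   `converged`, `n`, plus the fitted `grid`/`density`/`fitted` curves
#' @export
fit_ks_distribution <- function(ks, bandwidth = 0.05, r2_min = 0.95,
                                max_components = 4L, min_n = 50L,
                                ks_max = 3, grid_n = 300L) {
  ks <- ks[is.finite(ks) & ks >= 0 & ks <= ks_max]
  if (length(ks) < min_n)
    stop("need at least ", min_n, " finite Ks values (got ", length(ks), ")")
  den <- density(ks, bw = bandwidth, from = 0, to = ks_max, n = grid_n)
  x <- den$x; y <- den$y
  ss_tot <- sum((y - mean(y))^2)

  gauss_mix <- function(par, k) {
    w <- par[seq_len(k)]
    m <- par[k + seq_len(k)]
    s <- par[2 * k + seq_len(k)]
    rowSums(vapply(seq_len(k), function(j) w[j] * dnorm(x, m[j], s[j]),
                   numeric(length(x))))
  }

  # Initial means: highest local maxima of the KDE, padded with quantiles.
  local_max <- which(diff(sign(diff(y))) == -2) + 1L
  local_max <- local_max[order(y[local_max], decreasing = TRUE)]
  best <- NULL
  for (k in seq_len(max_components)) {
    m0 <- x[local_max]
    if (length(m0) < k) m0 <- c(m0, quantile(ks, seq(0.15, 0.85, length.out = k)))
    m0 <- m0[seq_len(k)]
    s0 <- rep(max(bandwidth, sd(ks) / (2 * k)), k)
    w0 <- rep(1 / k, k)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(w0, m0, s0),
        fn = function(par) y - gauss_mix(par, k),
        lower = c(rep(0, k), rep(0, k), rep(bandwidth / 10, k)),
        upper = c(rep(Inf, k), rep(ks_max, k), rep(ks_max, k)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- 1 - sum(fit$fvec^2) / ss_tot
    if (is.null(best) || r2 > best$r2) {
      best <- list(par = fit$par, k = k, r2 = r2)
    }
    if (r2 >= r2_min) break
  }
  if (is.null(best)) stop("mixture fitting failed for all component counts")
  k <- best$k
  comp <- data.frame(mean = best$par[k + seq_len(k)],
                     sd = best$par[2 * k + seq_len(k)],
                     weight = best$par[seq_len(k)])
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, r2 = best$r2, n_components = k,
                 principal = which.max(comp$weight), bandwidth = bandwidth,
                 converged = best$r2 >= r2_min, n = length(ks),
                 grid = x, density = y, fitted = gauss_mix(best$par, k)),
            class = "ks_peak_fit")
}

#' @export
print.ks_peak_fit <- function(x, ...) {
  cat(sprintf("Ks mixture fit: %d component(s), R^2 = %.4f (n = %d)%s\n",
              x$n_components, x$r2, x$n,
              if (x$converged) "" else "  [R^2 target not reached]"))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %s mean %.3f  sd %.3f  weight %.3f\n",
                if (i == x$principal) "*" else " ",
                comp$mean[i], comp$sd[i], comp$weight[i]))
  invisible(x)
}

#' Principal peak of a fitted Ks mixture
#' @param fit a `ks_peak_fit`
#' @return mean of the highest-weight component
#' @export
principal_peak <- function(fit) fit$components$mean[fit$principal]

#' Median Ks of each colinear block
#'
#' The median of the finite Ks values of a block's gene pairs (even counts:
#' mean of the central two).  Blocks whose pairs are all saturated get `NA`.
#'
#' @param blocks a `colinear_blocks` object (see [detect_blocks()])
#' @param estimates data frame with `gene_a`, `gene_b`, `ks` (e.g. from
#'   [ks_pairs()])
#' @return `blocks` with a `median_ks` column filled in
#' @export
block_median_ks <- function(blocks, estimates) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ks_map <- setNames(estimates$ks, key(estimates$gene_a, estimates$gene_b))
  pk <- ks_map[key(blocks$pairs$gene_a, blocks$pairs$gene_b)]
  med <- tapply(pk, blocks$pairs$block_id, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else median(v)
  })
  blocks$blocks$median_ks <- as.numeric(med[as.character(blocks$blocks$block_id)])
  blocks$pairs$ks <- as.numeric(pk)
  blocks
}
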