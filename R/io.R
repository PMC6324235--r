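# Gene-order tables and standard-format I/O (BED dialect, GFF3, 12-column
# BLAST tabular, FASTA via Biostrings).

#' Construct a gene-order table
#'
#' The central gene-order container: one row per gene with its chromosome,
#' 0-based rank along the chromosome, strand and bp coordinates (0-based,
#' half-open).  Ranks within each chromosome must be consecutive from 0 and
#' gene ids unique.
#'
#' @param genes data frame with columns `id`, `chr`, `rank`, `strand`,
#'   `start`, `end` (a `rank` column is derived from `start` order if
#'   missing)
#' @param taxon genome label
#' @return object of class `genome_table`
#' @export
genome_table <- function(genes, taxon) {
  req <- c("id", "chr", "strand", "start", "end")
  if (!all(req %in% names(genes)))
    stop("genes must have columns ", paste(req, collapse = ", "))
  genes <- genes[order(genes$chr, genes$start), , drop = FALSE]
  if (!"rank" %in% names(genes))
    genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chr,
                                        FUN = seq_along)) - 1L
  genes <- genes[order(genes$chr, genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$id))
    stop("duplicated gene id(s): ",
         paste(head(unique(genes$id[duplicated(genes$id)]), 3), collapse = ", "))
  ok <- tapply(genes$rank, genes$chr, function(r) identical(as.integer(r),
                                                            seq_along(r) - 1L))
  if (!all(unlist(ok)))
    stop("ranks must be consecutive integers from 0 within each chromosome")
  structure(list(taxon = taxon, genes = genes), class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("Genome '%s': %d genes on %d chromosomes\n", x$taxon,
              nrow(x$genes), length(unique(x$genes$chr))))
  invisible(x)
}

#' Read a gene-order table from BED
#'
#' Expects the 6-column BED dialect (chrom, start, end, name, score,
#' strand), 0-based half-open; gene rank is the start-coordinate order
#' within each chromosome.
#'
#' @param path BED file
#' @param taxon genome label (defaults to the file name stem)
#' @return a [genome_table()]
#' @export
read_gene_bed <- function(path, taxon = sub("\\..*$", "", basename(path))) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs at least 4 columns")
  genes <- data.frame(id = df[[4]], chr = df[[1]],
                      strand = if (ncol(df) >= 6) df[[6]] else "+",
                      start = df[[2]], end = df[[3]],
                      stringsAsFactors = FALSE)
  genome_table(genes, taxon)
}

#' Read a gene-order table from GFF3
#'
#' Maps `gene` features (their `ID` attribute) to the gene-order table;
#' GFF3 1-based closed coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file
#' @param taxon genome label
#' @param feature feature type to extract
#' @return a [genome_table()]
#' @export
read_gff3_genes <- function(path, taxon = sub("\\..*$", "", basename(path)),
                            feature = "gene") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) >= 9]
  df <- data.frame(chr = vapply(f, `[[`, character(1), 1),
                   type = vapply(f, `[[`, character(1), 3),
                   start = as.numeric(vapply(f, `[[`, character(1), 4)),
                   end = as.numeric(vapply(f, `[[`, character(1), 5)),
                   strand = vapply(f, `[[`, character(1), 7),
                   attr = vapply(f, `[[`, character(1), 9),
                   stringsAsFactors = FALSE)
  df <- df[df$type == feature, , drop = FALSE]
  if (!nrow(df)) stop("no '", feature, "' features in ", path)
  id <- sub(".*ID=([^;]+).*", "\\1", df$attr)
  genes <- data.frame(id = id, chr = df$chr, strand = df$strand,
                      start = df$start - 1, end = df$end,
                      stringsAsFactors = FALSE)
  genome_table(genes, taxon)
}

.BLAST_COLS <- c("query", "subject", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bits")

#' Read homolog hits from 12-column BLAST tabular output
#'
#' @param path tabular file (outfmt-6 dialect)
#' @param max_evalue retain hits with E-value at or below this threshold
#' @return data frame with columns `query`, `subject`, `pident`, ...,
#'   `evalue`, `bits`; self-hits are dropped
#' @export
read_blast_tab <- function(path, max_evalue = 1e-5) {
  if (file.size(path) == 0L) {
    df <- data.frame(query = character(), subject = character(),
                     pident = numeric(), length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), bits = numeric())
    return(df)
  }
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 tab-separated columns")
  names(df)[1:12] <- .BLAST_COLS
  df <- df[df$evalue <= max_evalue & df$query != df$subject, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene-order table as BED
#' @param gt a `genome_table`
#' @param path output file
#' @export
write_gene_bed <- function(gt, path) {
  g <- gt$genes
  write.table(data.frame(g$chr, g$start, g$end, g$id, 0L, g$strand),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- simulated homolog hits -------------------------------------------------

#' Simulated all-vs-all homolog hits between two genomes
#'
#' Emits one hit per true homolog pair (genes sharing an ancestral locus) in
#' the 12-column BLAST tabular dialect.  Percent identity is computed from
#' the simulated sequences; E-value and bit score are deterministic monotone
#' functions of identity and alignment length (E capped at 1e-6, so every
#' emitted hit passes the pipeline's E <= 1e-5 filter).
#'
#' @param sim a `polyploid_sim` from [simulate_genomes()]
#' @param taxon_a,taxon_b taxa to compare (equal for within-genome
#'   paralogy; each unordered pair emitted once)
#' @return data frame in 12-column BLAST layout (canonical column names)
#' @export
sim_hits <- function(sim, taxon_a, taxon_b = taxon_a) {
  stopifnot(inherits(sim, "polyploid_sim"))
  tp <- true_pairs(sim$truth, taxon_a, taxon_b)
  if (!nrow(tp)) {
    return(setNames(data.frame(matrix(nrow = 0, ncol = 12)), .BLAST_COLS))
  }
  A <- sim$seqs[[taxon_a]]; B <- sim$seqs[[taxon_b]]
  nt <- .ng_tables()$NTDIFF
  ia <- match(tp$gene_a, rownames(A)); ib <- match(tp$gene_b, rownames(B))
  L <- ncol(A)
  mm <- rowSums(matrix(nt[cbind(as.vector(A[ia, , drop = FALSE]),
                                as.vector(B[ib, , drop = FALSE]))],
                       nrow = nrow(tp)))
  len <- 3L * L
  pident <- round(100 * (1 - mm / len), 2)
  bits <- round(2 * len * pident / 100)
  evalue <- signif(pmin(1e-6, 10^(-pident * len / 2500)), 3)
  data.frame(query = tp$gene_a, subject = tp$gene_b, pident = pident,
             length = len, mismatch = mm, gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = evalue, bits = bits, stringsAsFactors = FALSE)
}

#' Write a simulated data set to standard files
#'
#' Writes, per taxon, a CDS FASTA and a BED gene-order table; per genome
#' pair (including self-comparisons), a 12-column tabular hit file; plus the
#' ground-truth gene table (`truth.tsv`) and the scenario configuration
#' (`config.yaml`).
#'
#' @param sim a `polyploid_sim`
#' @param outdir output directory (created if needed)
#' @param pairs list of 2-element character vectors selecting the hit files
#'   to write; default: all within- and between-genome combinations
#' @return (invisibly) named list of written paths
#' @export
emit_outputs <- function(sim, outdir, pairs = NULL) {
  stopifnot(inherits(sim, "polyploid_sim"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  taxa <- names(sim$genomes)
  paths <- list()
  for (tx in taxa) {
    fa <- file.path(outdir, paste0(tx, ".cds.fasta"))
    Biostrings::writeXStringSet(sim_cds(sim, tx), fa)
    bed <- file.path(outdir, paste0(tx, ".bed"))
    write_gene_bed(sim$genomes[[tx]], bed)
    paths[[paste0(tx, "_fasta")]] <- fa
    paths[[paste0(tx, "_bed")]] <- bed
  }
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(taxa)), diag = TRUE), arr.ind = TRUE)
    pairs <- lapply(seq_len(nrow(idx)),
                    function(i) c(taxa[idx[i, 1]], taxa[idx[i, 2]]))
  }
  for (p in pairs) {
    hits <- sim_hits(sim, p[1], p[2])
    hp <- file.path(outdir, paste0("hits_", p[1], "_", p[2], ".tsv"))
    write.table(hits, hp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths[[paste0("hits_", p[1], "_", p[2])]] <- hp
  }
  tp <- file.path(outdir, "truth.tsv")
  write.table(sim$truth$genes, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- tp
  cfgp <- file.path(outdir, "config.yaml")
  cfg <- sim$config
  cfg$events <- lapply(cfg$events, unclass)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), cfgp)
  paths$config <- cfgp
  invisible(paths)
}
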