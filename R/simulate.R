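# Recursive-polyploidy genome simulator.
#
# The simulator walks the fixed species tree top-down carrying a genome
# state (gene table + optional codon matrix).  Polyploidy events replicate
# the state, retention thins non-parental copies, and sequences accumulate
# Jukes-Cantor substitutions at third codon positions of fourfold-degenerate
# codon families, so the expected Nei-Gojobori Ks between two genes equals
# the rate-scaled path length separating them on the true gene tree.
# History decisions and sequence mutations use two independent RNG streams
# derived from the seed, so gene content is identical whether or not
# sequences are evolved.

.rng_streams <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed); env$hist <- get(".Random.seed", globalenv())
  set.seed((seed + 7919L) %% .Machine$integer.max); env$seq <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  env
}

.with_stream <- function(streams, which, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams[[which]], globalenv())
  on.exit({
    streams[[which]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

# Jukes-Cantor kernel on third codon positions: each site changes to a
# specific other nucleotide with probability (1 - exp(-4d/3))/4.
.mutate_third <- function(mat, d) {
  if (d <= 0) return(mat)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  n <- length(mat)
  hit <- which(runif(n) < p_change)
  if (length(hit)) {
    cur <- (mat[hit] - 1L) %% 4L
    new <- (cur + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    mat[hit] <- mat[hit] - cur + new
  }
  mat
}

# Nonsynonymous drift: swap the codon's fourfold family (positions 1-2)
# with a symmetric K-state kernel; third positions are untouched and no
# stop codon can arise.
.mutate_family <- function(mat, d) {
  if (d <= 0) return(mat)
  ff <- .fourfold_codons()                    # families x 4
  K <- nrow(ff)
  fam_of <- integer(64); fam_of[] <- NA_integer_
  for (f in seq_len(K)) fam_of[ff[f, ]] <- f
  p_change <- ((K - 1) / K) * (1 - exp(-K * d / (K - 1)))
  n <- length(mat)
  hit <- which(runif(n) < p_change)
  if (length(hit)) {
    cur <- fam_of[mat[hit]]
    shift <- sample.int(K - 1L, length(hit), replace = TRUE)
    new <- (cur - 1L + shift) %% K + 1L
    third <- (mat[hit] - 1L) %% 4L + 1L
    mat[hit] <- ff[cbind(new, third)]
  }
  mat
}

.ancestral_state <- function(cfg, with_seqs, streams) {
  n <- cfg$n_ancestral_genes
  per_chr <- ceiling(n / cfg$n_chromosomes)
  chr <- sprintf("c%02d", rep(seq_len(cfg$n_chromosomes), each = per_chr)[seq_len(n)])
  pos <- as.numeric(stats::ave(seq_len(n), chr, FUN = seq_along))
  genes <- data.frame(id = sprintf("g%04d", seq_len(n)),
                      anc = sprintf("g%04d", seq_len(n)),
                      chr = chr, pos = pos, strand = "+",
                      prov = "", stringsAsFactors = FALSE)
  seqs <- NULL
  if (with_seqs) {
    seqs <- .with_stream(streams, "seq", {
      ff <- .fourfold_codons()
      fam <- sample.int(nrow(ff), n * cfg$codon_length, replace = TRUE)
      third <- sample.int(4L, n * cfg$codon_length, replace = TRUE)
      matrix(ff[cbind(fam, third)], nrow = n)
    })
  }
  list(genes = genes, seqs = seqs)
}

.evolve_segment <- function(state, delta, rate, cfg, streams) {
  if (is.null(state$seqs) || delta <= 0) return(state)
  d <- delta * rate
  state$seqs <- .with_stream(streams, "seq", {
    s <- .mutate_third(state$seqs, d)
    .mutate_family(s, d * cfg$ka_ratio)
  })
  state
}

.apply_event <- function(state, ev, cfg, streams) {
  m <- ev$multiplicity
  tag <- tolower(ev$name)
  copies <- vector("list", m)
  for (k in seq_len(m)) {
    g <- state$genes
    g$id <- paste0(g$id, "-", tag, k)
    g$chr <- paste0(g$chr, "-", tag, k)
    g$prov <- paste0(g$prov, ifelse(g$prov == "", "", ">"), ev$name, ":", k)
    keep <- if (k == 1L) rep(TRUE, nrow(g)) else
      .with_stream(streams, "hist",
                   runif(nrow(g)) < cfg$retention_prob)
    copies[[k]] <- list(genes = g[keep, , drop = FALSE],
                        seqs = if (!is.null(state$seqs))
                          state$seqs[keep, , drop = FALSE])
  }
  list(genes = do.call(rbind, lapply(copies, `[[`, "genes")),
       seqs = if (!is.null(state$seqs))
         do.call(rbind, lapply(copies, `[[`, "seqs")))
}

.descend_branch <- function(state, branch, d_from, cfg, streams) {
  iv <- .branch_intervals(cfg)
  d_bottom <- iv[[branch]][1]
  rate <- cfg$rate_multipliers[[branch]]
  evs <- Filter(function(e) e$branch == branch, cfg$events)
  if (length(evs)) evs <- evs[order(-vapply(evs, `[[`, numeric(1), "time"))]
  for (e in evs) {
    d_ev <- e$time / 2
    state <- .evolve_segment(state, d_from - d_ev, rate, cfg, streams)
    state <- .apply_event(state, e, cfg, streams)
    d_from <- d_ev
  }
  state <- .evolve_segment(state, d_from - d_bottom, rate, cfg, streams)
  state
}

.finalize_tip <- function(state, taxon, cfg, streams) {
  g <- state$genes
  seqs <- state$seqs

  # lineage-specific gene loss, never removing the last copy of a locus
  q <- cfg$lineage_loss[[taxon]]
  if (q > 0) {
    keep <- .with_stream(streams, "hist", runif(nrow(g)) >= q)
    first_of_locus <- !duplicated(g$anc)
    lost_all <- !g$anc %in% g$anc[keep]
    keep[first_of_locus & lost_all] <- TRUE
    g <- g[keep, , drop = FALSE]
    if (!is.null(seqs)) seqs <- seqs[keep, , drop = FALSE]
  }

  # tandem duplications: adjacent copy, diverged by tandem_ks
  if (cfg$tandem_rate > 0) {
    dup <- .with_stream(streams, "hist", which(runif(nrow(g)) < cfg$tandem_rate))
    if (length(dup)) {
      td <- g[dup, , drop = FALSE]
      td$id <- paste0(td$id, "-td2")
      td$pos <- td$pos + 0.4
      td$prov <- paste0(td$prov, ifelse(td$prov == "", "", ">"), "TD:2")
      g <- rbind(g, td)
      if (!is.null(seqs)) {
        new <- .with_stream(streams, "seq", {
          s <- .mutate_third(seqs[dup, , drop = FALSE], cfg$tandem_ks)
          .mutate_family(s, cfg$tandem_ks * cfg$ka_ratio)
        })
        seqs <- rbind(seqs, new)
      }
    }
  }

  # segmental inversions: reverse gene order, flip strand
  n_inv <- .with_stream(streams, "hist", rpois(1L, cfg$inversion_rate))
  if (n_inv > 0) {
    for (i in seq_len(n_inv)) {
      .with_stream(streams, "hist", {
        ch <- sample(unique(g$chr), 1L)
        on_chr <- which(g$chr == ch)
        on_chr <- on_chr[order(g$pos[on_chr])]
        if (length(on_chr) >= 2L) {
          ij <- sort(sample(length(on_chr), 2L))
          seg <- on_chr[ij[1]:ij[2]]
          g$pos[seg] <- rev(g$pos[seg])
          g$strand[seg] <- ifelse(g$strand[seg] == "+", "-", "+")
        }
      })
    }
  }

  ord <- order(g$chr, g$pos)
  g <- g[ord, , drop = FALSE]
  if (!is.null(seqs)) seqs <- seqs[ord, , drop = FALSE]
  rank <- as.integer(stats::ave(seq_len(nrow(g)), g$chr, FUN = seq_along)) - 1L
  span <- cfg$codon_length * 3L
  out <- data.frame(id = paste(taxon, g$id, sep = "_"),
                    chr = paste(taxon, g$chr, sep = "_"),
                    rank = rank, strand = g$strand,
                    start = rank * (span + 1000L),
                    end = rank * (span + 1000L) + span,
                    stringsAsFactors = FALSE)
  truth <- data.frame(gene = out$id, taxon = taxon, chr = out$chr,
                      rank = rank, anc = g$anc, provenance = g$prov,
                      stringsAsFactors = FALSE)
  if (!is.null(seqs)) rownames(seqs) <- out$id
  list(table = genome_table(out, taxon), truth = truth, seqs = seqs)
}

.run_simulation <- function(cfg, with_seqs) {
  streams <- .rng_streams(cfg$seed)
  iv <- .branch_intervals(cfg)
  root_events <- Filter(function(e) e$branch == "root", cfg$events)
  d0 <- max(c(iv$root[1], vapply(root_events, function(e) e$time / 2, numeric(1))))
  state <- .ancestral_state(cfg, with_seqs, streams)
  state <- .descend_branch(state, "root", d0, cfg, streams)
  tips <- list()
  grape <- .descend_branch(state, "grape", iv$root[1], cfg, streams)
  tips$grape <- .finalize_tip(grape, "grape", cfg, streams)
  mal <- .descend_branch(state, "stem_mal", iv$root[1], cfg, streams)
  cacao <- .descend_branch(mal, "cacao", iv$stem_mal[1], cfg, streams)
  tips$cacao <- .finalize_tip(cacao, "cacao", cfg, streams)
  dc <- .descend_branch(mal, "stem_dc", iv$stem_mal[1], cfg, streams)
  durian <- .descend_branch(dc, "durian", iv$stem_dc[1], cfg, streams)
  tips$durian <- .finalize_tip(durian, "durian", cfg, streams)
  cotton <- .descend_branch(dc, "cotton", iv$stem_dc[1], cfg, streams)
  tips$cotton <- .finalize_tip(cotton, "cotton", cfg, streams)

  truth <- structure(list(
    genes = do.call(rbind, lapply(tips, `[[`, "truth")),
    events = cfg$events, split_ks = cfg$split_ks,
    rate_multipliers = cfg$rate_multipliers,
    tandem_ks = cfg$tandem_ks), class = "truth_set")
  rownames(truth$genes) <- NULL
  genomes <- lapply(tips, `[[`, "table")
  seqs <- if (with_seqs) lapply(tips, `[[`, "seqs")
  list(genomes = genomes, truth = truth, seqs = seqs)
}

#' Simulate gene content and order under recursive polyploidization
#'
#' Walks the four-taxon phylogeny applying the configured polyploidy events,
#' retention thinning, lineage-specific loss, tandem duplication and
#' inversions, and returns one ordered gene table per extant taxon plus the
#' ground truth (ancestral locus and event provenance of every gene).
#'
#' @param config a [sim_config()]
#' @return list with `genomes` (named list of `genome_table`), `truth`
#'   (a `truth_set`), and `config`
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  res <- .run_simulation(config, with_seqs = FALSE)
  list(genomes = res$genomes, truth = res$truth, config = config)
}

#' Evolve coding sequences along the true gene trees
#'
#' Re-runs the simulation traversal of `config` (same seed, so the gene
#' content matches `genomes` exactly) while accumulating substitutions:
#' third positions of fourfold-degenerate codons evolve under Jukes-Cantor
#' with rate-multiplier-scaled branch lengths, and codon families drift at
#' `ka_ratio` times the synonymous rate.  Sequences contain no stop codons
#' and the expected Ks between two genes equals the rate-scaled path length
#' separating them.
#'
#' @param genomes,truth output of [simulate_history()]
#' @param config the same `sim_config` used for the history
#' @return named list (per taxon) of integer codon matrices (genes x codons)
#'   with gene ids as rownames; decode with [sim_cds()]
#' @export
evolve_sequences <- function(genomes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$codon_length < 50L)
    stop("codon_length < 50 is too short for stable Ks estimation")
  res <- .run_simulation(config, with_seqs = TRUE)
  for (tx in names(genomes)) {
    if (!identical(genomes[[tx]]$genes$id, res$genomes[[tx]]$genes$id))
      stop("genomes do not match this config/seed (taxon ", tx, ")")
  }
  res$seqs
}

#' Simulate a full data set (history + sequences)
#'
#' @param config a [sim_config()]
#' @return object of class `polyploid_sim`: list with `genomes`, `truth`,
#'   `seqs`, `config`
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$codon_length < 50L)
    stop("codon_length < 50 is too short for stable Ks estimation")
  res <- .run_simulation(config, with_seqs = TRUE)
  structure(list(genomes = res$genomes, truth = res$truth, seqs = res$seqs,
                 config = config), class = "polyploid_sim")
}

#' @export
print.polyploid_sim <- function(x, ...) {
  cat("Simulated polyploid genomes:\n")
  for (tx in names(x$genomes))
    cat(sprintf("  %-7s %5d genes on %3d chromosomes\n", tx,
                nrow(x$genomes[[tx]]$genes),
                length(unique(x$genomes[[tx]]$genes$chr))))
  invisible(x)
}

#' Decode simulated codon matrices to DNA sequences
#'
#' @param sim a `polyploid_sim` (or the list returned by
#'   [evolve_sequences()])
#' @param taxon taxon name
#' @return a [Biostrings::DNAStringSet] of CDSs
#' @export
sim_cds <- function(sim, taxon) {
  seqs <- if (inherits(sim, "polyploid_sim")) sim$seqs else sim
  mat <- seqs[[taxon]]
  if (is.null(mat)) stop("no sequences for taxon '", taxon, "'")
  dna <- apply(mat, 1L, function(r) paste(.codon_string(r), collapse = ""))
  Biostrings::DNAStringSet(setNames(dna, rownames(mat)))
}
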