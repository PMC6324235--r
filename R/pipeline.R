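# End-to-end orchestration: simulate (or load) genomes, detect colinear
# blocks, estimate Ks, fit age distributions, correct rates and date
# events, profile ploidy depth, build alignment/fractionation tables, and
# classify gene trees.  Every stage writes plain-text results under the
# output directory and is recorded in a JSON run manifest.

#' Assemble a pipeline configuration
#'
#' @param scenario simulation scenario name (see [scenario_config()]), or
#'   `NULL` when `inputs` are given
#' @param inputs optional list for pre-existing data: `taxa` (named list
#'   with `bed` and `cds` paths per genome) and `hits` (named list
#'   `"A__B"` of tabular hit files); exactly one of `scenario`/`inputs`
#' @param reference reference genome for profiling and alignment
#' @param outdir output directory
#' @param seed integer seed for simulation and bootstrapping
#' @param n_ancestral_genes simulated ancestral gene count
#' @param max_evalue,max_gap,min_pairs colinearity thresholds
#' @param bandwidth,r2_min Ks fitting parameters
#' @param ortholog_max,outparalog_min Ks classification thresholds
#' @param window depth-profile window (genes)
#' @param calibration_mya ECH calibration age range
#' @param bootstrap_n,support_min gene-tree parameters
#' @param sim_overrides list of further [sim_config()] overrides
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(scenario = "ech_dsh", inputs = NULL,
                            reference = "grape", outdir = tempfile("ploidscan_"),
                            seed = 1L, n_ancestral_genes = 200L,
                            max_evalue = 1e-5, max_gap = 50L, min_pairs = 4L,
                            bandwidth = 0.05, r2_min = 0.95,
                            ortholog_max = 0.92, outparalog_min = 0.97,
                            window = 20L, calibration_mya = c(115, 130),
                            bootstrap_n = 100L, support_min = 70,
                            sim_overrides = list()) {
  if (is.null(scenario) == is.null(inputs))
    stop("exactly one of 'scenario' or 'inputs' must be given")
  stopifnot(max_evalue > 0, max_gap > 0, min_pairs > 0, bandwidth > 0,
            r2_min > 0, window > 0, all(calibration_mya > 0))
  structure(list(scenario = scenario, inputs = inputs, reference = reference,
                 outdir = outdir, seed = as.integer(seed),
                 n_ancestral_genes = as.integer(n_ancestral_genes),
                 max_evalue = max_evalue, max_gap = max_gap,
                 min_pairs = min_pairs, bandwidth = bandwidth,
                 r2_min = r2_min, ortholog_max = ortholog_max,
                 outparalog_min = outparalog_min, window = window,
                 calibration_mya = calibration_mya,
                 bootstrap_n = as.integer(bootstrap_n),
                 support_min = support_min, sim_overrides = sim_overrides),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$calibration_mya))
    args$calibration_mya <- as.numeric(unlist(args$calibration_mya))
  do.call(pipeline_config, args)
}

.fit_peak_or_null <- function(ks, cfg, min_n = 50L) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < min_n) return(NULL)
  tryCatch(fit_ks_distribution(ks, bandwidth = cfg$bandwidth,
                               r2_min = cfg$r2_min, min_n = min_n),
           error = function(e) NULL)
}

#' Run the full paleopolyploidy pipeline
#'
#' Executes simulate/load, colinearity, Ks estimation, distribution
#' fitting, Ks-based block classification with depth profiling, alignment
#' and fractionation tables, rate correction with event dating, and gene
#' trees.  All results are written as TSV/JSON (plus an SVG dotplot and
#' Newick trees) under `config$outdir`, together with `manifest.json`.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with the in-memory results of every stage
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  res <- list(config = cfg)
  fail <- function(stage, msg) stop("pipeline stage '", stage, "' failed: ",
                                    msg, call. = FALSE)

  # -- stage: simulate / load ------------------------------------------------
  if (!is.null(cfg$scenario)) {
    sim_args <- c(list(name = cfg$scenario,
                       n_ancestral_genes = cfg$n_ancestral_genes,
                       seed = cfg$seed), cfg$sim_overrides)
    sim <- simulate_genomes(do.call(scenario_config, sim_args))
    datadir <- file.path(cfg$outdir, "data")
    emit_outputs(sim, datadir)
    # round-trip through the emitted files so the pipeline consumes the
    # same formats real data would arrive in
    genomes <- lapply(names(sim$genomes), function(tx)
      read_gene_bed(file.path(datadir, paste0(tx, ".bed")), tx))
    names(genomes) <- names(sim$genomes)
    cds <- sim$seqs
    hit_of <- function(a, b) {
      p <- file.path(datadir, paste0("hits_", a, "_", b, ".tsv"))
      p2 <- file.path(datadir, paste0("hits_", b, "_", a, ".tsv"))
      if (file.exists(p)) read_blast_tab(p, cfg$max_evalue)
      else if (file.exists(p2)) {
        h <- read_blast_tab(p2, cfg$max_evalue)
        h[, c("query", "subject")] <- h[, c("subject", "query")]
        h
      } else NULL
    }
    res$sim <- sim
    stages <- c(stages, "simulate")
  } else {
    genomes <- lapply(names(cfg$inputs$taxa), function(tx)
      read_gene_bed(cfg$inputs$taxa[[tx]]$bed, tx))
    names(genomes) <- names(cfg$inputs$taxa)
    cds <- lapply(names(cfg$inputs$taxa), function(tx) {
      fa <- Biostrings::readDNAStringSet(cfg$inputs$taxa[[tx]]$cds)
      setNames(as.character(fa), names(fa))
    })
    names(cds) <- names(cfg$inputs$taxa)
    hit_of <- function(a, b) {
      key <- paste0(a, "__", b); key2 <- paste0(b, "__", a)
      p <- cfg$inputs$hits[[key]]
      if (is.null(p)) {
        p <- cfg$inputs$hits[[key2]]
        if (is.null(p)) return(NULL)
        h <- read_blast_tab(p, cfg$max_evalue)
        h[, c("query", "subject")] <- h[, c("subject", "query")]
        return(h)
      }
      read_blast_tab(p, cfg$max_evalue)
    }
    stages <- c(stages, "load")
  }
  ref <- cfg$reference
  if (!ref %in% names(genomes)) fail("load", paste("no reference genome", ref))
  taxa <- names(genomes)
  targets <- setdiff(taxa, ref)

  # -- stage: colinearity ----------------------------------------------------
  blocks <- list()
  for (tx in targets) {
    h <- hit_of(ref, tx)
    if (!is.null(h))
      blocks[[paste0(ref, "__", tx)]] <-
        detect_blocks(h, genomes[[ref]], genomes[[tx]],
                      max_gap = cfg$max_gap, min_pairs = cfg$min_pairs,
                      max_evalue = cfg$max_evalue)
  }
  for (tx in taxa) {
    h <- hit_of(tx, tx)
    if (!is.null(h))
      blocks[[paste0(tx, "__", tx)]] <-
        detect_blocks(h, genomes[[tx]], genomes[[tx]],
                      max_gap = cfg$max_gap, min_pairs = cfg$min_pairs,
                      max_evalue = cfg$max_evalue)
  }
  # outgroup ortholog contrasts needed by the step-2 rate correction
  if (all(c("cacao", "durian", "cotton") %in% taxa)) {
    for (tx in intersect(c("durian", "cotton"), targets)) {
      key <- paste0("cacao__", tx)
      h <- hit_of("cacao", tx)
      if (is.null(blocks[[key]]) && !is.null(h))
        blocks[[key]] <- detect_blocks(h, genomes[["cacao"]], genomes[[tx]],
                                       max_gap = cfg$max_gap,
                                       min_pairs = cfg$min_pairs,
                                       max_evalue = cfg$max_evalue)
    }
  }
  if (!length(blocks)) fail("colinearity", "no hit tables available")
  stages <- c(stages, "colinearity")

  # -- stage: Ks -------------------------------------------------------------
  for (key in names(blocks)) {
    tx2 <- strsplit(key, "__", fixed = TRUE)[[1]]
    pr <- blocks[[key]]$pairs
    if (!nrow(pr)) next
    if (identical(tx2[1], tx2[2])) {
      est <- ks_pairs(cds[[tx2[1]]],
                      data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b))
    } else {
      both <- rbind_seqs(cds[[tx2[1]]], cds[[tx2[2]]])
      est <- ks_pairs(both, data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b))
    }
    blocks[[key]] <- block_median_ks(blocks[[key]], est)
    write_blocks_tsv(blocks[[key]],
                     file.path(cfg$outdir, paste0("blocks_", key, ".tsv")))
  }
  res$blocks <- blocks
  stages <- c(stages, "ks")

  # -- stage: fitting --------------------------------------------------------
  fits <- list()
  for (key in names(blocks)) {
    ks <- blocks[[key]]$pairs$ks
    f <- .fit_peak_or_null(ks, cfg)
    if (!is.null(f)) fits[[key]] <- f
  }
  fit_tab <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(sample = k, component = seq_len(f$n_components),
               mean = f$components$mean, sd = f$components$sd,
               weight = f$components$weight, r2 = f$r2,
               principal = seq_len(f$n_components) == f$principal)
  }))
  if (!is.null(fit_tab))
    write.table(fit_tab, file.path(cfg$outdir, "ks_fits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  res$fits <- fits
  stages <- c(stages, "fitting")

  # -- stage: ploidy profiling ----------------------------------------------
  # classify every cross-genome block set by median Ks; depth profiles are
  # computed on the reference
  for (key in names(blocks)) {
    tx2 <- strsplit(key, "__", fixed = TRUE)[[1]]
    if (tx2[1] != tx2[2])
      blocks[[key]] <- classify_blocks_by_ks(blocks[[key]], cfg$ortholog_max,
                                             cfg$outparalog_min)
  }
  res$blocks <- blocks
  profiles <- list()
  classified <- list()
  for (tx in targets) {
    key <- paste0(ref, "__", tx)
    if (is.null(blocks[[key]])) next
    cb <- blocks[[key]]
    classified[[tx]] <- cb
    profiles[[tx]] <- depth_profile(genomes[[ref]], cb, window = cfg$window,
                                    merge_gap = cfg$max_gap)
  }
  if (length(profiles)) {
    ptab <- data.frame(target = names(profiles),
                       orthology = vapply(profiles, `[[`, integer(1),
                                          "orthology_ratio"),
                       outparalogy = vapply(profiles, function(p)
                         if (is.na(p$outparalogy_ratio)) NA_integer_
                         else p$outparalogy_ratio, integer(1)))
    write.table(ptab, file.path(cfg$outdir, "depth_ratios.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(classified)) {
    tx1 <- names(classified)[1]
    render_dotplot(hit_of(ref, tx1), genomes[[ref]], genomes[[tx1]],
                   classified[[tx1]],
                   file.path(cfg$outdir, paste0("dotplot_", ref, "_", tx1)),
                   formats = "svg")
  }
  res$profiles <- profiles
  res$classified <- classified
  stages <- c(stages, "ploidy")

  # -- stage: fractionation --------------------------------------------------
  if (length(classified)) {
    atab <- build_alignment_table(genomes[[ref]], classified)
    write_alignment_tsv(atab, file.path(cfg$outdir, "alignment_table.tsv"))
    missing <- count_missing(atab)
    write.table(data.frame(target = names(missing), missing_fraction = missing),
                file.path(cfg$outdir, "fractionation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$alignment <- atab
    res$missing <- missing
    if (all(c("durian", "cotton") %in% names(atab$targets)))
      res$similarity <- similarity_profile(atab, "durian", "cotton")
  }
  stages <- c(stages, "fractionation")

  # -- stage: correction and dating -----------------------------------------
  dating <- .dating_stage(blocks, fits, cfg)
  if (!is.null(dating$table))
    write.table(dating$table, file.path(cfg$outdir, "event_dates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  res$dating <- dating
  stages <- c(stages, "correction_dating")

  # -- stage: trees ----------------------------------------------------------
  tree_tab <- NULL
  if (!is.null(res$sim)) {
    groups <- make_homolog_groups(res$sim)
    if (length(groups)) {
      tree_tab <- classify_groups(groups, bootstrap_n = cfg$bootstrap_n,
                                  seed = cfg$seed,
                                  support_min = cfg$support_min)
      writeLines(tree_tab$newick, file.path(cfg$outdir, "gene_trees.nwk"))
      write.table(tree_tab[, c("anc", "type", "pattern")],
                  file.path(cfg$outdir, "tree_topologies.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res$trees <- tree_tab
  stages <- c(stages, "trees")

  manifest <- list(package = "ploidscan",
                   version = as.character(utils::packageVersion("ploidscan")),
                   r_version = R.version.string,
                   seed = cfg$seed, scenario = cfg$scenario,
                   reference = ref, stages_completed = stages,
                   thresholds = list(max_evalue = cfg$max_evalue,
                                     max_gap = cfg$max_gap,
                                     min_pairs = cfg$min_pairs,
                                     bandwidth = cfg$bandwidth,
                                     r2_min = cfg$r2_min,
                                     ortholog_max = cfg$ortholog_max,
                                     outparalog_min = cfg$outparalog_min,
                                     window = cfg$window,
                                     calibration_mya = cfg$calibration_mya,
                                     support_min = cfg$support_min))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# Correction + dating from fitted within-genome paralog distributions.
# The oldest component of each lineage's paralog Ks sample is its ECH
# peak; a younger component counts as a post-speciation event peak only if
# it sits clearly below the ECH peak (< 0.5x).
.dating_stage <- function(blocks, fits, cfg) {
  key_self <- function(tx) paste0(tx, "__", tx)
  ech <- list(); young <- list()
  for (tx in c("grape", "cacao", "durian", "cotton")) {
    f <- fits[[key_self(tx)]]
    if (is.null(f)) next
    comp <- f$components
    ech[[tx]] <- comp$mean[nrow(comp)]
    if (nrow(comp) > 1 && comp$mean[1] < 0.5 * ech[[tx]])
      young[[tx]] <- comp$mean[1]
  }
  if (is.null(ech$grape))
    return(list(table = NULL, note = "no grape paralog sample; dating skipped"))
  c1 <- vapply(names(ech), function(tx)
    step1_coefficient(ech$grape, ech[[tx]]), numeric(1))

  # step-1-corrected outgroup ortholog peaks for the step-2 contrast
  ortho_peak <- function(a, b) {
    key <- paste0(a, "__", b); key2 <- paste0(b, "__", a)
    bl <- if (!is.null(blocks[[key]])) blocks[[key]] else blocks[[key2]]
    if (is.null(bl) || is.null(bl$blocks$label)) return(NULL)
    idx <- bl$blocks$block_id[bl$blocks$label == "ortholog"]
    ks <- bl$pairs$ks[bl$pairs$block_id %in% idx]
    f <- .fit_peak_or_null(ks, cfg)
    if (is.null(f)) NULL else principal_peak(f)
  }
  c2 <- NULL
  mu_dc <- mu_cc <- NULL
  if (all(c("durian", "cotton", "cacao") %in% names(c1))) {
    raw_dc <- ortho_peak("cacao", "durian")
    raw_cc <- ortho_peak("cacao", "cotton")
    if (!is.null(raw_dc) && !is.null(raw_cc)) {
      mu_dc <- correct_between(raw_dc, c1[["cacao"]], c1[["durian"]])
      mu_cc <- correct_between(raw_cc, c1[["cacao"]], c1[["cotton"]])
      c2 <- mu_dc / mu_cc
    }
  }

  rows <- list()
  ech_cal <- ech$grape
  for (tx in names(young)) {
    peak <- young[[tx]] * c1[[tx]]
    if (identical(tx, "cotton") && !is.null(c2))
      peak <- step2_correction(peak, mu_cc, mu_dc, "duplicate")$ks
    ev <- date_event(peak, ech_cal, cfg$calibration_mya[1],
                     cfg$calibration_mya[2],
                     event = paste0(tx, "_duplication"))
    rows[[tx]] <- data.frame(event = ev$event, lineage = tx,
                             corrected_peak = peak,
                             date_lo_mya = ev$date_mya[1],
                             date_hi_mya = ev$date_mya[2])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  list(table = tab, ech_peaks = unlist(ech), step1 = c1, step2 = c2,
       mu_durian_outgroup = mu_dc, mu_cotton_outgroup = mu_cc,
       note = if (is.null(tab)) "no post-speciation event peak detected")
}

#' Combine two named CDS sets / codon matrices
#' @keywords internal
#' @export
rbind_seqs <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) return(rbind(a, b))
  c(as.list(a), as.list(b))
}
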