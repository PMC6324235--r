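# The recursive-polyploidy genome simulator.

test_that("copy numbers multiply through events when retention is 1", {
  hist <- simulate_history(scenario_config("ech_only", n_ancestral_genes = 100L,
                                           seed = 2L))
  for (tx in names(hist$genomes))
    expect_equal(nrow(hist$genomes[[tx]]$genes), 300L)

  hist2 <- simulate_history(scenario_config("ech_dsh", n_ancestral_genes = 60L,
                                            seed = 2L))
  expect_equal(nrow(hist2$genomes$durian$genes), 60L * 9L)
  expect_equal(nrow(hist2$genomes$grape$genes), 60L * 3L)
  expect_equal(nrow(hist2$genomes$cacao$genes), 60L * 3L)

  hist3 <- simulate_history(scenario_config("full", n_ancestral_genes = 40L,
                                            seed = 2L))
  expect_equal(nrow(hist3$genomes$cotton$genes), 40L * 15L)

  # per-locus copy-number conservation
  tab <- table(hist2$truth$genes$anc, hist2$truth$genes$taxon)
  expect_true(all(tab[, "durian"] == 9L))
  expect_true(all(tab[, "grape"] == 3L))
})

test_that("invalid configurations are rejected", {
  expect_error(polyploidy_event("X", "durian", 1, 0.1), "multiplicity")
  expect_error(polyploidy_event("X", "mars", 3, 0.1), "unknown branch")
  expect_error(sim_config(events = list(polyploidy_event("X", "durian", 3, 0.5))),
               "does not fall on branch")
  expect_error(sim_config(retention_prob = 0), "retention_prob")
  expect_error(sim_config(split_ks = c(grape = 0.2, cacao = 0.25, cotton = 0.22)),
               "decreasing")
  cfg <- scenario_config("ech_only", n_ancestral_genes = 20L, codon_length = 30L)
  expect_error(simulate_genomes(cfg), "codon_length")
})

test_that("mean retained gene count matches the brute-force expectation", {
  # ECH only, retention 0.5: per locus 1 kept parent + Binomial(2, 0.5)
  # extras.  Expectation and variance by enumeration of the 4 outcomes.
  p <- 0.5
  outcomes <- expand.grid(c1 = c(0, 1), c2 = c(0, 1))
  probs <- p^(outcomes$c1 + outcomes$c2) * (1 - p)^(2 - outcomes$c1 - outcomes$c2)
  copies <- 1 + outcomes$c1 + outcomes$c2
  e_copies <- sum(probs * copies)
  v_copies <- sum(probs * copies^2) - e_copies^2
  n_loci <- 400L; n_seeds <- 20L
  counts <- vapply(seq_len(n_seeds), function(s) {
    h <- simulate_history(scenario_config("ech_only", n_ancestral_genes = n_loci,
                                          seed = 100L + s, retention_prob = p))
    nrow(h$genomes$grape$genes)
  }, numeric(1))
  se <- sqrt(v_copies * n_loci / n_seeds)
  expect_lt(abs(mean(counts) - e_copies * n_loci), 3 * se)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- scenario_config("ech_dsh", n_ancestral_genes = 30L, seed = 9L,
                         tandem_rate = 0.05, inversion_rate = 1)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$seqs, s2$seqs)
  d1 <- tempfile(); d2 <- tempfile()
  emit_outputs(s1, d1); emit_outputs(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # gene content identical whether or not sequences are evolved
  h <- simulate_history(cfg)
  expect_identical(h$truth$genes, s1$truth$genes)
  seqs <- evolve_sequences(h$genomes, h$truth, cfg)
  expect_identical(seqs, s1$seqs)
})

test_that("tandem duplicates are adjacent and diverge by tandem_ks", {
  cfg <- scenario_config("ech_only", n_ancestral_genes = 80L, seed = 13L,
                         tandem_rate = 0.2, tandem_ks = 0)
  sim <- simulate_genomes(cfg)
  tp <- true_pairs(sim$truth, "durian")
  td <- tp[tp$relation == "tandem", , drop = FALSE]
  expect_gt(nrow(td), 0)
  g <- sim$genomes$durian$genes
  for (i in seq_len(nrow(td))) {
    ra <- g[g$id == td$gene_a[i], ]
    rb <- g[g$id == td$gene_b[i], ]
    expect_equal(ra$chr, rb$chr)
    expect_equal(abs(ra$rank - rb$rank), 1L)
    # tandem_ks = 0: copies identical at the tip
    expect_identical(sim$seqs$durian[td$gene_a[i], ],
                     sim$seqs$durian[td$gene_b[i], ])
  }
})

test_that("true pair relations are consistent with provenance and counts", {
  sim <- shared_sim("full", n_ancestral_genes = 150L, seed = 42L)
  tp_dd <- true_pairs(sim$truth, "durian")
  # per locus: C(9,2) = 36 durian pairs, 9 within-DSH-triple... relations:
  # 9 ECH paralog pairs occur between different ECH copies (3*3*... ) check
  # totals per locus instead: 36 pairs = 9 dsh within + 27 ech between
  per_locus <- table(tp_dd$anc, tp_dd$relation)
  expect_true(all(per_locus[, "dsh_paralog"] == 9L))
  expect_true(all(per_locus[, "ech_paralog"] == 27L))
  # independent re-derivation of labels from provenance strings
  idx <- sample(nrow(tp_dd), 50)
  prov <- setNames(sim$truth$genes$provenance, sim$truth$genes$gene)
  for (i in idx) {
    pa <- prov[[tp_dd$gene_a[i]]]; pb <- prov[[tp_dd$gene_b[i]]]
    ech_a <- sub(".*ECH:(\\d).*", "\\1", pa); ech_b <- sub(".*ECH:(\\d).*", "\\1", pb)
    expected <- if (ech_a != ech_b) "ech_paralog" else "dsh_paralog"
    expect_equal(tp_dd$relation[i], expected)
  }
  # cross-genome: grape vs durian = 3 orthologs + 6 outparalogs per grape gene
  tp_gd <- true_pairs(sim$truth, "grape", "durian")
  cnt <- table(tp_gd$relation) / nrow(sim$genomes$grape$genes)
  expect_equal(unname(cnt[["ortholog"]]), 3)
  expect_equal(unname(cnt[["ech_outparalog"]]), 6)
})

test_that("expected Ks tracks the rate-scaled true-tree path length", {
  # orthologs diverging at the cacao split with unit rates: expected Ks 0.3
  cfg <- sim_config(n_ancestral_genes = 120L, seed = 17L,
                    split_ks = c(grape = 0.8, cacao = 0.3, cotton = 0.15),
                    events = list(), rate_multipliers = c(cotton = 1))
  sim <- simulate_genomes(cfg)
  tp <- true_pairs(sim$truth, "cacao", "durian")
  est <- ks_pairs(rbind(sim$seqs$cacao, sim$seqs$durian),
                  tp[, c("gene_a", "gene_b")])
  expect_equal(mean(est$ks), 0.3, tolerance = 0.03)

  # cotton elevated: fitted cotton-cacao vs durian-cacao peak ratio matches
  # the closed-form path-length oracle within 10%
  cfg2 <- sim_config(n_ancestral_genes = 150L, seed = 18L,
                     events = list(), rate_multipliers = c(cotton = 1.64))
  sim2 <- simulate_genomes(cfg2)
  tp_cc <- true_pairs(sim2$truth, "cacao", "cotton")
  tp_dc <- true_pairs(sim2$truth, "cacao", "durian")
  est_cc <- ks_pairs(rbind(sim2$seqs$cacao, sim2$seqs$cotton),
                     tp_cc[, c("gene_a", "gene_b")])
  est_dc <- ks_pairs(rbind(sim2$seqs$cacao, sim2$seqs$durian),
                     tp_dc[, c("gene_a", "gene_b")])
  peak_cc <- principal_peak(fit_ks_distribution(est_cc$ks))
  peak_dc <- principal_peak(fit_ks_distribution(est_dc$ks))
  pred_cc <- oracle_expected_ks(sim2$truth, tp_cc$gene_a[1], tp_cc$gene_b[1],
                                tp_cc$divergence_ks[1])
  pred_dc <- oracle_expected_ks(sim2$truth, tp_dc$gene_a[1], tp_dc$gene_b[1],
                                tp_dc$divergence_ks[1])
  expect_equal(peak_cc / peak_dc, pred_cc / pred_dc, tolerance = 0.10)
  # sanity: the oracle itself reflects the elevated cotton branch
  expect_gt(pred_cc, pred_dc)
})

test_that("estimated Ks increases with divergence time (monotonicity)", {
  # mean estimated Ks per divergence class, over the many distinct
  # rate-scaled coalescence depths the scenario produces
  sim <- shared_sim("full", n_ancestral_genes = 150L, seed = 42L)
  combos <- list(c("durian", "durian"), c("cotton", "cotton"),
                 c("grape", "durian"), c("cacao", "durian"),
                 c("cacao", "cotton"), c("durian", "cotton"))
  cls_x <- numeric(0); cls_y <- numeric(0)
  set.seed(6)
  for (cb in combos) {
    tp <- true_pairs(sim$truth, cb[1], cb[2])
    tp <- tp[sample(nrow(tp), min(200, nrow(tp))), ]
    seqs <- if (cb[1] == cb[2]) sim$seqs[[cb[1]]] else
      rbind(sim$seqs[[cb[1]]], sim$seqs[[cb[2]]])
    est <- ks_pairs(seqs, tp[, c("gene_a", "gene_b")])
    expected <- vapply(seq_len(nrow(tp)), function(i)
      oracle_expected_ks(sim$truth, tp$gene_a[i], tp$gene_b[i],
                         tp$divergence_ks[i]), numeric(1))
    for (v in unique(expected)) {
      cls_x <- c(cls_x, v)
      cls_y <- c(cls_y, mean(est$ks[expected == v], na.rm = TRUE))
    }
  }
  expect_gte(length(unique(cls_x)), 6L)
  rho <- cor(cls_x, cls_y, method = "spearman")
  expect_gt(rho, 0.95)
  # and the class means themselves sit on the oracle expectation
  expect_equal(cls_y, cls_x, tolerance = 0.05)
})

test_that("emitted files round-trip and hit tables have the right shape", {
  sim <- shared_sim("full", n_ancestral_genes = 150L, seed = 42L)
  out <- tempfile("emit_")
  emit_outputs(sim, out, pairs = list(c("durian", "durian"),
                                      c("grape", "durian")))
  for (tx in names(sim$genomes)) {
    fa <- Biostrings::readDNAStringSet(file.path(out, paste0(tx, ".cds.fasta")))
    bed <- read_gene_bed(file.path(out, paste0(tx, ".bed")), tx)
    expect_equal(length(fa), nrow(bed$genes))
    expect_identical(bed$genes[, c("id", "chr", "rank")],
                     sim$genomes[[tx]]$genes[, c("id", "chr", "rank")])
  }
  hits <- read_blast_tab(file.path(out, "hits_durian_durian.tsv"))
  expect_true(all(hits$evalue <= 1e-5))
  # a 9-copy durian locus yields C(9,2) = 36 intra-durian hit pairs
  anc <- sub("-.*$", "", sub("^durian_", "", hits$query))
  expect_true(all(table(anc) == 36L))
})
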