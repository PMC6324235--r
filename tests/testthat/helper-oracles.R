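# Independent oracles and shared fixtures for the test suite.

.NT4 <- c("T", "C", "A", "G")

encode_codons <- function(s)
  ploidscan:::.codon_index(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))

# ---- independent Nei-Gojobori oracle (string-based, recursive) -------------
# Re-derives site and difference counts directly from the genetic code by
# explicit enumeration on codon strings, with the standard convention:
# changes to stops are nonsynonymous, pathways through stops are excluded
# unless every pathway is blocked.
oracle_ng <- function(codons_a, codons_b) {
  gc_map <- Biostrings::GENETIC_CODE
  aa <- function(codon) unname(gc_map[codon])
  syn_sites_one <- function(codon) {
    s <- 0
    for (pos in 1:3) for (nt in setdiff(.NT4, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (aa(mut) != "*" && aa(mut) == aa(codon)) s <- s + 1 / 3
    }
    s
  }
  diff_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    paths <- list()
    recurse <- function(cur, remaining, sd, nd, blocked) {
      if (!length(remaining)) {
        paths[[length(paths) + 1L]] <<- list(sd = sd, nd = nd, blocked = blocked)
        return(invisible())
      }
      for (k in seq_along(remaining)) {
        p <- remaining[k]
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- aa(nxt) != "*" && aa(cur) != "*" && aa(nxt) == aa(cur)
        recurse(nxt, remaining[-k], sd + as.integer(syn),
                nd + as.integer(!syn), blocked || aa(nxt) == "*")
      }
    }
    recurse(c1, pos, 0, 0, FALSE)
    ok <- Filter(function(p) !p$blocked, paths)
    if (!length(ok)) ok <- paths
    c(mean(vapply(ok, `[[`, numeric(1), "sd")),
      mean(vapply(ok, `[[`, numeric(1), "nd")))
  }
  S <- (sum(vapply(codons_a, syn_sites_one, numeric(1))) +
          sum(vapply(codons_b, syn_sites_one, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- rowSums(mapply(diff_counts, codons_a, codons_b))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(d[1] / S), ka = jc(d[2] / N), S = S, N = N)
}

# random sense-codon pair generator (arbitrary codons, no stops)
random_codon_pair <- function(n_codons, p_mut = 0.25) {
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(ploidscan:::.codon_string(1:64), stops)
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  mut <- runif(n_codons) < p_mut
  b[mut] <- sample(sense, sum(mut), replace = TRUE)
  list(a = a, b = b)
}

# ---- independent chain-search oracle ---------------------------------------
# Exhaustive best-chain search by memoised recursion over the explicit
# successor graph, with the same declared tie rules (length, then total
# span, then leftmost start), and greedy extraction.
oracle_best_chain <- function(x, y, g, antiparallel = FALSE) {
  n <- length(x)
  if (!n) return(NULL)
  yy <- if (antiparallel) -y else y
  succ <- lapply(seq_len(n), function(i)
    which(x - x[i] >= 1 & x - x[i] <= g & yy - yy[i] >= 1 & yy - yy[i] <= g))
  # memo: per node the best (len, span, sum(x+y), sum|x-y|) of chains
  # starting there
  memo <- vector("list", n)
  memo_next <- rep(0L, n)
  better <- function(a, b) {
    # is candidate a better than b?
    if (a[1] != b[1]) return(a[1] > b[1])
    if (a[2] != b[2]) return(a[2] < b[2])
    if (a[3] != b[3]) return(a[3] < b[3])
    a[4] < b[4]
  }
  best_from <- function(i) {
    if (!is.null(memo[[i]])) return(memo[[i]])
    best <- c(1, 0, x[i] + y[i], abs(x[i] - y[i])); bn <- 0L
    for (j in succ[[i]]) {
      r <- best_from(j)
      cand <- c(1 + r[1], r[2] + (x[j] - x[i]) + abs(yy[j] - yy[i]),
                x[i] + y[i] + r[3], abs(x[i] - y[i]) + r[4])
      if (better(cand, best)) { best <- cand; bn <- j }
    }
    memo[[i]] <<- best; memo_next[i] <<- bn
    best
  }
  for (i in seq_len(n)) best_from(i)
  tup <- do.call(rbind, memo)
  starts <- which(tup[, 1] == max(tup[, 1]))
  starts <- starts[order(tup[starts, 2], tup[starts, 3], tup[starts, 4],
                         x[starts] + y[starts], abs(x[starts] - y[starts]))]
  i <- starts[1]; idx <- integer(0)
  while (i > 0L) { idx <- c(idx, i); i <- memo_next[i] }
  s <- starts[1]
  list(idx = idx, len = tup[s, 1], span = tup[s, 2],
       s1 = tup[s, 3], s2 = tup[s, 4])
}

oracle_extract_blocks <- function(x, y, g, min_pairs) {
  keep <- seq_along(x)
  lens <- integer(0)
  pick <- function(a, b) {
    if (is.null(b)) return(a)
    if (b$len > a$len ||
        (b$len == a$len && (b$span < a$span ||
          (b$span == a$span && (b$s1 < a$s1 ||
            (b$s1 == a$s1 && b$s2 < a$s2)))))) b else a
  }
  repeat {
    if (length(keep) < min_pairs) break
    cp <- oracle_best_chain(x[keep], y[keep], g, FALSE)
    ca <- oracle_best_chain(x[keep], y[keep], g, TRUE)
    ch <- pick(cp, ca)
    if (ch$len < min_pairs) break
    lens <- c(lens, ch$len)
    keep <- keep[-ch$idx]
  }
  lens
}

# ---- expected-Ks path-length oracle ----------------------------------------
# Closed form from the ground truth: expected Ks of a pair = integral of the
# branch rate over both root-to-tip paths below the coalescence point.
oracle_expected_ks <- function(truth, gene_a, gene_b, divergence_ks) {
  g <- truth$genes
  rate <- truth$rate_multipliers
  dg <- truth$split_ks[["grape"]] / 2
  da <- truth$split_ks[["cacao"]] / 2
  dc <- truth$split_ks[["cotton"]] / 2
  seg <- list(grape = rbind(c(dg, Inf, rate[["root"]]), c(0, dg, rate[["grape"]])),
              cacao = rbind(c(dg, Inf, rate[["root"]]),
                            c(da, dg, rate[["stem_mal"]]),
                            c(0, da, rate[["cacao"]])),
              durian = rbind(c(dg, Inf, rate[["root"]]),
                             c(da, dg, rate[["stem_mal"]]),
                             c(dc, da, rate[["stem_dc"]]),
                             c(0, dc, rate[["durian"]])),
              cotton = rbind(c(dg, Inf, rate[["root"]]),
                             c(da, dg, rate[["stem_mal"]]),
                             c(dc, da, rate[["stem_dc"]]),
                             c(0, dc, rate[["cotton"]])))
  side <- function(gene) {
    tx <- sub("_.*$", "", gene)
    h <- divergence_ks / 2
    s <- seg[[tx]]
    sum(pmax(0, pmin(s[, 2], h) - s[, 1]) * s[, 3])
  }
  side(gene_a) + side(gene_b)
}

# ---- shared expensive fixtures (built once per test run) -------------------
.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function(name, ...) {
  key <- paste0(name, "_", digest_args(list(...)))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_genomes(scenario_config(name, ...))
  .fixture_env[[key]]
}

digest_args <- function(x) paste(deparse(x), collapse = "")

# Ks peak of a truth-labelled pair sample (used by correction/recovery tests)
truth_peak <- function(sim, ta, tb, rel, n = 600, seed = 5) {
  tp <- true_pairs(sim$truth, ta, tb)
  tp <- tp[tp$relation == rel, , drop = FALSE]
  set.seed(seed)
  if (nrow(tp) > n) tp <- tp[sample(nrow(tp), n), , drop = FALSE]
  seqs <- if (ta == tb) sim$seqs[[ta]] else rbind(sim$seqs[[ta]], sim$seqs[[tb]])
  est <- ks_pairs(seqs, tp[, c("gene_a", "gene_b")])
  principal_peak(fit_ks_distribution(est$ks))
}

# Full two-step correction recovery on the 'full' scenario, cached.
recovery_results <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  sim <- shared_sim("full", n_ancestral_genes = 150L, seed = 42L)
  mu_ech <- c(grape = truth_peak(sim, "grape", "grape", "ech_paralog"),
              cacao = truth_peak(sim, "cacao", "cacao", "ech_paralog"),
              durian = truth_peak(sim, "durian", "durian", "ech_paralog"),
              cotton = truth_peak(sim, "cotton", "cotton", "ech_paralog"))
  c1 <- vapply(names(mu_ech), function(tx)
    step1_coefficient(mu_ech[["grape"]], mu_ech[[tx]]), numeric(1))
  raw_dc <- truth_peak(sim, "cacao", "durian", "ortholog")
  raw_cc <- truth_peak(sim, "cacao", "cotton", "ortholog")
  mu_dc <- correct_between(raw_dc, c1[["cacao"]], c1[["durian"]])
  mu_cc <- correct_between(raw_cc, c1[["cacao"]], c1[["cotton"]])
  dsh <- truth_peak(sim, "durian", "durian", "dsh_paralog") * c1[["durian"]]
  gsd_step1 <- truth_peak(sim, "cotton", "cotton", "gsd_paralog") * c1[["cotton"]]
  gsd <- step2_correction(gsd_step1, mu_cc, mu_dc, "duplicate")$ks
  .fixture_env$recovery <- list(sim = sim, mu_ech = mu_ech, c1 = c1,
                                raw_dc = raw_dc, raw_cc = raw_cc,
                                mu_dc = mu_dc, mu_cc = mu_cc,
                                dsh = dsh, gsd_step1 = gsd_step1, gsd = gsd)
  .fixture_env$recovery
}

# ech_dsh end-to-end profile (blocks + Ks + classification + depth), cached.
profile_scenario <- function(name, n_genes = 200L, seed = 1L,
                             targets = "durian", retention = 1, ...) {
  key <- paste0("prof_", name, n_genes, seed, retention,
                paste(targets, collapse = ""))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  sim <- simulate_genomes(scenario_config(name, n_ancestral_genes = n_genes,
                                          seed = seed,
                                          retention_prob = retention, ...))
  out <- list(sim = sim, profiles = list(), blocks = list())
  for (tgt in targets) {
    h <- sim_hits(sim, "grape", tgt)
    bl <- detect_blocks(h, sim$genomes$grape, sim$genomes[[tgt]])
    est <- ks_pairs(rbind(sim$seqs$grape, sim$seqs[[tgt]]),
                    bl$pairs[, c("gene_a", "gene_b")])
    bl <- block_median_ks(bl, est)
    bl <- classify_blocks_by_ks(bl, ortholog_max = 0.92, outparalog_min = 0.97)
    out$blocks[[tgt]] <- bl
    out$profiles[[tgt]] <- depth_profile(sim$genomes$grape, bl)
  }
  .fixture_env[[key]] <- out
  out
}

# Distortion fractions at three duplicate-era rate levels, cached.
distortion_fracs <- function() {
  if (!is.null(.fixture_env$distortion)) return(.fixture_env$distortion)
  frac_by_rate <- function(r, seed = 7L) {
    sim <- shared_sim("full", n_ancestral_genes = 40L, seed = seed,
                      rate_multipliers = c(cotton = r, durian = r),
                      codon_length = 150L,
                      split_ks = c(grape = 0.80, cacao = 0.26, cotton = 0.20))
    tab <- classify_groups(make_homolog_groups(sim), bootstrap_n = 60L,
                           seed = seed)
    c(nonA = mean(tab$type != "A"),
      sep = mean(tab$pattern == "separate_clusters"),
      oto = mean(tab$pattern == "one_to_one"))
  }
  .fixture_env$distortion <- list(r1 = frac_by_rate(1), r2 = frac_by_rate(2.5),
                                  r3 = frac_by_rate(5))
  .fixture_env$distortion
}
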