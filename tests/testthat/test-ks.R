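# Nei-Gojobori estimation and Ks mixture fitting.

test_that("hand-counted two-codon example gives the textbook Ks", {
  aln <- list(a = encode_codons("GGGGGA"), b = encode_codons("GGGGGG"))
  est <- nei_gojobori(aln)
  expect_equal(est$S, 2)
  expect_equal(est$N, 4)
  # one synonymous third-position difference: ps = 1/2, Ks = -0.75 log(1/3)
  expect_equal(est$ks, -0.75 * log(1 / 3), tolerance = 1e-6)
  expect_equal(est$ks, 0.8240, tolerance = 1e-4)
  expect_equal(est$ka, 0)
})

test_that("identical sequences give Ks = Ka = 0 and S + N = 3 codons", {
  set.seed(3)
  p <- random_codon_pair(100, p_mut = 0)
  est <- nei_gojobori(list(a = encode_codons(paste(p$a, collapse = "")),
                           b = encode_codons(paste(p$b, collapse = ""))))
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
  expect_equal(est$S + est$N, 300)
})

test_that("estimates agree with an independent string-based oracle", {
  set.seed(11)
  for (rep in 1:12) {
    p <- random_codon_pair(60, p_mut = 0.3)
    est <- nei_gojobori(list(a = encode_codons(paste(p$a, collapse = "")),
                             b = encode_codons(paste(p$b, collapse = ""))))
    ref <- oracle_ng(p$a, p$b)
    expect_equal(est$ks, ref$ks, tolerance = 1e-9)
    expect_equal(est$ka, ref$ka, tolerance = 1e-9)
    expect_equal(est$S, ref$S, tolerance = 1e-9)
  }
})

test_that("estimates match a reference implementation on frozen pairs", {
  # dS/dN computed with an independent published NG86 implementation on
  # sequences whose mutational pathways avoid stop codons (where the
  # pathway-exclusion conventions of all implementations coincide)
  frozen <- list(
    list(a = "GCTGCTCCACCCCCGCCGCCTGTAACTGCTGTAGCGCCAGCCCCAACGGCTCCACCTGCACCCACAGTAGTAGCGACAGCTGTCACTGTTGCCCCAACGGTAGCACCAGCAGTCACGCCTCCACCCGCACCCCCCGTCGTGGTTCCCGCGGCCGTAGCCGTACCTACCGTTGCTACACCTGCTCCAGTCCCAGCAACTGCTCCTACGGCGGTCCCTCCTGCCGTGGTGGTGCCTACCCCC",
         b = "GCTGCTCCACCCCCGCCGACTACGGTAGCTGTCGCGCCAGCCCCAACGGCTCCAGTCGCACCCACAGTAGTAGCGACAGCTGTCACTCCGGCCCCAACGGTAGCACCAACCGTCACGCCTCCACCCACCCCCCCCGTCGCAACACCCGCGGCCGTAGCCCCCCCTGCCGTTGCTACGCCTCCAACCGTCCCAGCAACTGCTCCTGCCGCGGTCCCTCCTGCCGTGGTTGTGCCTGTCCCC",
         ds = 0.212989, dn = 0.153170),
    list(a = "GCCACCACGACCCCAGTGGCTGCTCCCACTGCAACACCTCCTGCAGCTGCCCCCACGACTCCAACTGCAGCTCCCGCGGCGCCCGTACCGGCAGTTGTGACAGCGGTAACAGTTACTGTTACAGCCACTCCCCCTGTCGCTGTCGTCACACCGACCCCCGCAGTCGCCCCGCCAGTGGCGCCCACTACTACGGTACCACCCACGGTAGTGCCTCCTCCTGTAGTCGCTCCCACGCCGCCCACAGTCACAGCCCCAACCCCCGTGCCTGCGGTTCCGGCTGTGCCGGCAGTACCCCCCGCAACGACTACAGTCGCTGTTACCCCCCCTGTTACCACCACCGTGGCGGCCGTAGTCACGCCC",
         b = "GCCACCACGACCCCAACTGCTGCTCCCACCGCAACACCTCCTGCCGCTACTGTGACGACTCCACCCGCAACTGCCGTCGCGCCCGTACCGGCAGTAGTGGCGGTGGTACCCCCGACTGTACCGGCCACTCCCACTGTCGCTGTCGTTACACCGACCCCCGCAACTACCACGACGGTGGCGCCCGTCACTCCGGTACCACCCACGGTAGTGCCTCCTCCCACAGTCGCTGTTACGCCGACGACAGTCACAGCCCCAACCCCCCCGGTCACAGTTACCGCTGCACCGGCAGTAGCTGTTGCAACGACTACAGTCGCTGTTACCACCCCTACTACCACCACCGTTGTAGCCGTAGTTACAGTG",
         ds = 0.314589, dn = 0.216688),
    list(a = "GTTGCCACCCCCCCTACCCCCGCCGTGACCCCCGCCGCTGTGGTAACTACCACTCCCACTGTGGTCGTAACTGCGGCTCCTACCGCGCCAACCGCAACTACTCCCGCAACCCCTCCAACACCTCCGACGGTACCGGCCCCTGTTACAGCTGTAGTTGCCGTAGCCGCAGTGGTAGTTCCAGTACCGACCCCAGTGCCTACTACCCCCCCAGTAGTGACAGTTCCAACCGCTACAGTCGCAACTGCGACGCCAACGCCTGTCACACCGCCAGCCGCGCCCACGCCCACCGTTGTTACGCCTCCTGCCGTCGTAACAACCACGCCCACAGTGACCGTCACAGCCCCACCCGTCCCCGTAGCGGCTGCCGCTACGGCTACTGTGCCAACGCCTGTAACTGTGGTTACGGCTACACCGGTGACCACTGCCCCTCCTCCTACCGTTACTCCTCCG",
         b = "GTTGCCGCCCCCACGGCGGTAGCCGTGACCCCCGTAGCTGTGACGACTACCGTTCCCACTGTGGTCGTAACTGCGGCTGTCACCGCCCCTACCGCAACTGTTCCCGCAGTCCCTCCAACACCTCCGACGACGCCGGTCCCTGTTACAGCTGTAGTTACTGTAGCCGCAACCGTAGTTCCAACTGTTCCGACAGTGCCTACTACCCCTCCAGTAGTGACAGTTCCAACCGTCACAGTCGCAACTGCGACGCCAACGCCTGTCACACCGCCACCGGCGCCCACGCCCACCGTAGTCGCGCCTCCTACAGTCGTAACAACCACGCCCACACCCACCACGACAGCGCCACCCGTCCCCGTAGCAGCTGCCGCTACGGCTACTGCGGCCACGCCTCCAGTGGTGGTTACGGCTACACCTGTGCCGACTACGCCTGTCCCTCCGGTTACTGTTACT",
         ds = 0.243298, dn = 0.192066))
  for (f in frozen) {
    est <- nei_gojobori(list(a = encode_codons(f$a), b = encode_codons(f$b)))
    expect_equal(est$ks, f$ds, tolerance = 5e-5)
    expect_equal(est$ka, f$dn, tolerance = 5e-5)
  }
})

test_that("Nei-Gojobori is symmetric and flags saturation", {
  set.seed(21)
  for (rep in 1:5) {
    p <- random_codon_pair(80, p_mut = 0.4)
    a <- encode_codons(paste(p$a, collapse = ""))
    b <- encode_codons(paste(p$b, collapse = ""))
    e1 <- nei_gojobori(list(a = a, b = b))
    e2 <- nei_gojobori(list(a = b, b = a))
    expect_equal(e1$ks, e2$ks)
    expect_equal(e1$ka, e2$ka)
  }
  # force ps >= 3/4: fourfold-family codons with all third positions changed
  a <- encode_codons(strrep("GGA", 20))
  b <- encode_codons(strrep("GGC", 20))
  est <- nei_gojobori(list(a = a, b = b))
  expect_true(est$saturated_ks)
  expect_true(is.na(est$ks))
})

test_that("codon alignment handles identity, insertions and bad input", {
  s <- "ATGGCTGCTCCAGTTGGTACCGCA"
  aln <- align_codons(s, s)
  expect_equal(aln$a, aln$b)
  est <- nei_gojobori(aln)
  expect_equal(est$ks, 0)

  # one inserted codon in b: gapped column dropped, rest identical
  b_ins <- paste0(substr(s, 1, 12), "AAA", substr(s, 13, nchar(s)))
  aln2 <- align_codons(s, b_ins)
  expect_equal(aln2$n_codons, nchar(s) / 3)
  expect_equal(aln2$a, aln2$b)

  expect_error(align_codons("ATGGC", s), "multiple of 3")
  expect_error(align_codons("ATGTAAGGG", s, id_a = "geneX"), "geneX")
})

test_that("ks_pairs matches nei_gojobori and reports unknown ids", {
  set.seed(8)
  mats <- lapply(1:6, function(i) random_codon_pair(50, 0.2))
  mat <- do.call(rbind, lapply(mats, function(p) encode_codons(paste(p$a, collapse = ""))))
  rownames(mat) <- paste0("g", 1:6)
  pairs <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g5"))
  est <- ks_pairs(mat, pairs)
  for (i in 1:2) {
    ref <- nei_gojobori(list(a = mat[pairs$gene_a[i], ], b = mat[pairs$gene_b[i], ]))
    expect_equal(est$ks[i], ref$ks)
    expect_equal(est$ka[i], ref$ka)
  }
  expect_error(ks_pairs(mat, data.frame(gene_a = "g1", gene_b = "nope")),
               "unknown gene id")
})

test_that("mixture fitting recovers single and double peaks", {
  set.seed(31)
  one <- fit_ks_distribution(rnorm(2000, 0.5, 0.05))
  expect_equal(one$n_components, 1L)
  expect_equal(one$components$mean, 0.50, tolerance = 0.01)
  expect_gte(one$r2, 0.95)

  two <- fit_ks_distribution(c(rnorm(2500, 0.24, 0.03), rnorm(2500, 1.38, 0.16)))
  expect_equal(two$n_components, 2L)
  expect_lt(abs(two$components$mean[1] - 0.24), 0.02)
  expect_lt(abs(two$components$mean[2] - 1.38), 0.05)
  expect_gte(two$r2, 0.95)
  # the fitted mixture reproduces the KDE curve at the acceptance R^2
  ss <- 1 - sum((two$density - two$fitted)^2) /
    sum((two$density - mean(two$density))^2)
  expect_gte(ss, 0.95)

  expect_error(fit_ks_distribution(rnorm(20, 0.5, 0.05)), "at least")
})

test_that("well-separated component means are recovered across seeds", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- c(rnorm(1500, 0.3, 0.04), rnorm(1500, 0.9, 0.06))
    fit <- fit_ks_distribution(x)
    expect_lt(abs(fit$components$mean[1] - 0.3), 0.05)
    expect_lt(abs(fit$components$mean[fit$n_components] - 0.9), 0.05)
  }
})

test_that("block median Ks follows the even/odd median convention", {
  blocks <- list(blocks = data.frame(block_id = 1:2, median_ks = NA_real_),
                 pairs = data.frame(block_id = c(1, 1, 1, 2, 2, 2, 2),
                                    gene_a = paste0("a", 1:7),
                                    gene_b = paste0("b", 1:7)))
  est <- data.frame(gene_a = paste0("a", 1:7), gene_b = paste0("b", 1:7),
                    ks = c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4, 0.5))
  out <- block_median_ks(blocks, est)
  expect_equal(out$blocks$median_ks, c(0.3, 0.35))

  # random blocks vs a sort-based oracle
  set.seed(4)
  ks <- runif(40)
  bid <- sample(1:5, 40, replace = TRUE)
  blocks2 <- list(blocks = data.frame(block_id = 1:5, median_ks = NA_real_),
                  pairs = data.frame(block_id = bid,
                                     gene_a = paste0("a", 1:40),
                                     gene_b = paste0("b", 1:40)))
  est2 <- data.frame(gene_a = paste0("a", 1:40), gene_b = paste0("b", 1:40),
                     ks = ks)
  out2 <- block_median_ks(blocks2, est2)
  oracle_med <- function(v) {
    v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  for (b in 1:5)
    expect_equal(out2$blocks$median_ks[b], oracle_med(ks[bid == b]))
})
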