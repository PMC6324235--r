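# Ks-based block classification, depth profiling, dotplots.

fake_blocks <- function(median_ks, chr_a = "g_c1", chr_b = NULL,
                        start_a = NULL, end_a = NULL) {
  n <- length(median_ks)
  if (is.null(chr_b)) chr_b <- paste0("d_c", seq_len(n))
  if (is.null(start_a)) start_a <- rep(0L, n)
  if (is.null(end_a)) end_a <- rep(49L, n)
  structure(list(
    blocks = data.frame(block_id = seq_len(n), chr_a = chr_a, chr_b = chr_b,
                        orientation = "parallel", n_pairs = 10L,
                        start_a = start_a, end_a = end_a,
                        start_b = 0L, end_b = 49L, p_value = 0,
                        median_ks = median_ks, stringsAsFactors = FALSE),
    pairs = data.frame(block_id = integer(), gene_a = character(),
                       gene_b = character(), rank_a = integer(),
                       rank_b = integer()),
    taxon_a = "g", taxon_b = "d"), class = "colinear_blocks")
}

test_that("blocks are classified by median Ks with boundary -> ambiguous", {
  bl <- classify_blocks_by_ks(fake_blocks(c(0.3, 1.5)), 0.95, 1.30)
  expect_equal(bl$blocks$label, c("ortholog", "outparalog"))
  bl2 <- classify_blocks_by_ks(fake_blocks(c(0.95, 1.30, 1.1, NA)), 0.95, 1.30)
  expect_equal(bl2$blocks$label,
               c("ambiguous", "ambiguous", "ambiguous", "ambiguous"))
  expect_error(classify_blocks_by_ks(fake_blocks(0.3), 1.3, 0.95), "inverted")
})

test_that("block labels agree with the simulation ground truth", {
  prof <- profile_scenario("ech_dsh", n_genes = 200L, seed = 1L)
  bl <- prof$blocks$durian
  tp <- true_pairs(prof$sim$truth, "grape", "durian")
  true_lab <- setNames(ifelse(tp$relation == "ortholog", "ortholog",
                              "outparalog"),
                       paste(tp$gene_a, tp$gene_b))
  pair_lab <- true_lab[paste(bl$pairs$gene_a, bl$pairs$gene_b)]
  block_true <- tapply(pair_lab, bl$pairs$block_id, function(v)
    names(which.max(table(v))))
  called <- setNames(bl$blocks$label, bl$blocks$block_id)
  agree <- called[names(block_true)] == block_true
  expect_gte(mean(agree), 0.95)
})

test_that("no-loss depth profiles recover the model ploidy ratios", {
  # shared hexaploidization + durian triplication: 1:3 orthology, 1:6
  # outparalogy on a grape reference
  p_dsh <- profile_scenario("ech_dsh", n_genes = 200L, seed = 1L)
  expect_equal(p_dsh$profiles$durian$orthology_ratio, 3L)
  expect_equal(p_dsh$profiles$durian$outparalogy_ratio, 6L)
  # shared event only: 1:1 and 1:2
  p_ech <- profile_scenario("ech_only", n_genes = 120L, seed = 3L)
  expect_equal(p_ech$profiles$durian$orthology_ratio, 1L)
  expect_equal(p_ech$profiles$durian$outparalogy_ratio, 2L)
  # shared event + durian tetraploidization: 1:2 and 1:4
  p_wgd <- profile_scenario("ech_wgd", n_genes = 120L, seed = 3L)
  expect_equal(p_wgd$profiles$durian$orthology_ratio, 2L)
  expect_equal(p_wgd$profiles$durian$outparalogy_ratio, 4L)
})

test_that("ratios equal the analytic event-multiplicity products (no loss)", {
  # orthology = product of multiplicities after the split on the target
  # branch; outparalogy = orthology x (ECH multiplicity - 1)
  cases <- list(ech_only = c(1L, 2L), ech_wgd = c(2L, 4L), ech_dsh = c(3L, 6L))
  for (nm in names(cases)) {
    p <- profile_scenario(nm, n_genes = 120L, seed = 3L)
    expect_equal(p$profiles$durian$orthology_ratio, cases[[nm]][1],
                 label = paste(nm, "orthology"))
    expect_equal(p$profiles$durian$outparalogy_ratio, cases[[nm]][2],
                 label = paste(nm, "outparalogy"))
  }
})

test_that("modal ratios are robust to 30% gene loss across seeds", {
  hits3 <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    prof <- profile_scenario("ech_dsh", n_genes = 120L, seed = 500L + s,
                             retention = 0.7)
    if (identical(prof$profiles$durian$orthology_ratio, 3L)) hits3 <- hits3 + 1L
  }
  expect_gte(hits3 / n_seeds, 0.8)
})

test_that("breakage complements merge into one region", {
  # one durian region split across two blocks on the same chromosome pair
  bl <- fake_blocks(c(0.3, 0.3, 0.3), chr_b = c("d_c1", "d_c1", "d_c2"),
                    start_a = c(0L, 30L, 0L), end_a = c(24L, 49L, 49L))
  bl$blocks$start_b <- c(0L, 26L, 0L); bl$blocks$end_b <- c(24L, 49L, 49L)
  bl <- classify_blocks_by_ks(bl, 0.95, 1.30)
  ref <- genome_table(data.frame(id = paste0("g", 1:50), chr = "g_c1",
                                 strand = "+", start = (1:50) * 100,
                                 end = (1:50) * 100 + 50), "g")
  dp <- depth_profile(ref, bl, window = 50L, merge_gap = 50L)
  # d_c1 fragments merge into one region; d_c2 is separate: depth 2, not 3
  expect_equal(dp$windows$n_ortholog, 2L)
})

test_that("hit categorisation keeps exactly one best hit per query", {
  set.seed(14)
  hits <- data.frame(query = rep(paste0("q", 1:5), each = 4),
                     subject = paste0("s", sample(100, 20)),
                     pident = runif(20, 60, 100),
                     evalue = 1e-30, bits = runif(20, 100, 500))
  cat_hits <- categorize_hits(hits, n_secondary = 2L)
  tab <- table(cat_hits$query, cat_hits$category)
  expect_true(all(tab[, "best"] == 1L))
  expect_true(all(tab[, "secondary"] == 2L))
  best <- cat_hits[cat_hits$category == "best", ]
  agg <- tapply(hits$bits, hits$query, max)
  expect_equal(as.numeric(agg[best$query]), best$bits)
})

test_that("dotplots render valid SVG with block annotations", {
  out <- tempfile("dot_")
  A <- genome_table(data.frame(id = paste0("a", 1:10), chr = "c1",
                               strand = "+", start = (1:10) * 100,
                               end = (1:10) * 100 + 50), "qq")
  B <- genome_table(data.frame(id = paste0("b", 1:10), chr = "c1",
                               strand = "+", start = (1:10) * 100,
                               end = (1:10) * 100 + 50), "ss")
  # empty hit set: a valid (empty-axes) image
  f0 <- render_dotplot(data.frame(query = character(),
                                  subject = character()),
                       A, B, NULL, paste0(out, "_empty"), formats = "svg")
  expect_true(file.exists(f0[1]))
  expect_gt(file.info(f0[1])$size, 500)

  # three annotated blocks appear in the SVG text
  hits <- data.frame(query = paste0("a", 1:9), subject = paste0("b", 1:9),
                     pident = 90, evalue = 1e-30, bits = 100)
  bl <- fake_blocks(c(0.21, 0.22, 0.23), chr_a = "qq_c1",
                    chr_b = rep("ss_c1", 3),
                    start_a = c(0L, 3L, 6L), end_a = c(2L, 5L, 8L))
  bl$blocks$chr_a <- "c1"; bl$blocks$chr_b <- "c1"
  bl$blocks$start_b <- c(0L, 3L, 6L); bl$blocks$end_b <- c(2L, 5L, 8L)
  f1 <- render_dotplot(hits, A, B, bl, paste0(out, "_blocks"),
                       formats = "svg")
  svg_text <- paste(readLines(f1[1], warn = FALSE), collapse = "")
  # svg() renders text as glyph paths, so count block overlay segments via
  # the line elements plus the file growing with annotations
  expect_gt(file.info(f1[1])$size, file.info(f0[1])$size)
  expect_true(grepl("<svg", svg_text))
})

test_that("dotplot diagonal count is consistent with the depth profile", {
  prof <- profile_scenario("ech_dsh", n_genes = 120L, seed = 3L)
  bl <- prof$blocks$durian
  # distinct durian chromosomes overlapping one grape chromosome on the
  # rendered overlay = ortholog + outparalog region counts
  ch <- bl$blocks$chr_a[1]
  on_chr <- bl$blocks[bl$blocks$chr_a == ch & bl$blocks$label != "ambiguous", ]
  expect_equal(length(unique(on_chr$chr_b[on_chr$label == "ortholog"])),
               prof$profiles$durian$orthology_ratio)
  expect_equal(length(unique(on_chr$chr_b[on_chr$label == "outparalog"])),
               prof$profiles$durian$outparalogy_ratio)
})
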