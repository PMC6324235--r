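# Gene trees of colinear homolog groups: distance-based reconstruction
# (NJ / UPGMA) with column-resampling bootstrap, classification of the
# cacao gene's position into the four topology types, and the
# cluster-vs-1:1 pattern test for shared vs independent polyploidy.

.taxon_of <- function(labels) sub("_.*$", "", labels)

#' Assemble homolog groups from a simulation
#'
#' Groups genes by ancestral locus and keeps loci providing one grape gene
#' (the outgroup), one cacao ortholog, at least `min_cotton` cotton and
#' `min_durian` durian orthologs; surplus genes are truncated
#' deterministically (by gene id).
#'
#' @param sim a `polyploid_sim`
#' @param min_cotton,min_durian minimum (and kept) paralog counts
#' @param max_groups optional cap on the number of groups
#' @return list of `homolog_group` objects (fields `anc`, `seqs` — integer
#'   codon matrix with gene rownames — and `taxa`)
#' @export
make_homolog_groups <- function(sim, min_cotton = 3L, min_durian = 2L,
                                max_groups = Inf) {
  stopifnot(inherits(sim, "polyploid_sim"))
  g <- sim$truth$genes
  groups <- list()
  for (anc in sort(unique(g$anc))) {
    sub <- g[g$anc == anc, , drop = FALSE]
    sub <- sub[order(sub$gene), , drop = FALSE]
    pick <- function(tx, n) head(sub$gene[sub$taxon == tx], n)
    sel <- c(pick("grape", 1L), pick("cacao", 1L),
             pick("cotton", min_cotton), pick("durian", min_durian))
    if (length(sel) != 2L + min_cotton + min_durian) next
    mats <- lapply(sel, function(id) sim$seqs[[.taxon_of(id)]][id, ])
    seqs <- do.call(rbind, mats)
    rownames(seqs) <- sel
    groups[[length(groups) + 1L]] <-
      structure(list(anc = anc, seqs = seqs, taxa = .taxon_of(sel)),
                class = "homolog_group")
    if (length(groups) >= max_groups) break
  }
  groups
}

# Pairwise distance matrix from an integer codon matrix.
.codon_dist <- function(seqs, model = c("p", "jc")) {
  model <- match.arg(model)
  nt <- .ng_tables()$NTDIFF
  n <- nrow(seqs); L <- 3 * ncol(seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- sum(nt[cbind(seqs[i, ], seqs[j, ])]) / L
      v <- if (model == "jc") {
        if (p >= 0.75) 5 else -0.75 * log(1 - 4 * p / 3)
      } else p
      d[i, j] <- d[j, i] <- v
    }
  }
  as.dist(d)
}

#' Build a rooted gene tree with bootstrap supports
#'
#' Computes pairwise distances (p-distance by default, Jukes-Cantor
#' optional), reconstructs the tree by neighbour joining or UPGMA, roots it
#' on the grape gene, and attaches bootstrap percentages obtained by
#' resampling alignment codon columns.
#'
#' @param group a `homolog_group`, or an integer codon matrix with gene ids
#'   as rownames
#' @param method `"nj"` or `"upgma"`
#' @param model distance model
#' @param bootstrap_n bootstrap replicates (0 disables)
#' @param seed RNG seed for the resampling
#' @return object of class `gene_tree`: list with `tree` (an [ape::phylo]
#'   rooted on grape, node labels = bootstrap percentages), `method`,
#'   `model`
#' @export
build_tree <- function(group, method = c("nj", "upgma"), model = c("p", "jc"),
                       bootstrap_n = 100L, seed = 1L) {
  method <- match.arg(method); model <- match.arg(model)
  seqs <- if (inherits(group, "homolog_group")) group$seqs else group
  if (is.null(dim(seqs)) || ncol(seqs) == 0L)
    stop("degenerate alignment: no usable columns")
  taxa <- .taxon_of(rownames(seqs))
  if (!"grape" %in% taxa) stop("group lacks the grape outgroup")
  out_leaf <- rownames(seqs)[taxa == "grape"][1]
  build <- function(mat) {
    d <- .codon_dist(mat, model)
    tr <- if (method == "nj") ape::nj(d) else phangorn::upgma(d)
    ape::root(tr, outgroup = out_leaf, resolve.root = TRUE)
  }
  tree <- build(seqs)
  if (bootstrap_n > 0L) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    boots <- lapply(seq_len(bootstrap_n), function(b) {
      build(seqs[, sample.int(ncol(seqs), replace = TRUE), drop = FALSE])
    })
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    tree$node.label <- round(100 * cnt / bootstrap_n)
  }
  structure(list(tree = tree, method = method, model = model,
                 bootstrap_n = bootstrap_n), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("%s gene tree (%s-distance), %d leaves\n",
              toupper(x$method), x$model, length(x$tree$tip.label)))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

.leaves_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

#' Classify a gene tree by the cacao gene's position
#'
#' With the tree rooted on the grape outgroup, the four types are:
#' type A (expected phylogeny) — cacao is sister to the clade of all cotton
#' and durian genes; type B — cacao falls inside the durian cluster (the
#' smallest clade containing cacao and every durian gene holds no cotton
#' gene); type C — likewise for cotton; type D — cacao is mixed in with
#' cotton and durian genes without being outgroup to them.
#'
#' @param tree a `gene_tree` or rooted [ape::phylo] containing one grape
#'   and one cacao leaf plus cotton/durian leaves
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`
#' @export
classify_topology <- function(tree) {
  tr <- if (inherits(tree, "gene_tree")) tree$tree else tree
  taxa <- .taxon_of(tr$tip.label)
  for (tx in c("grape", "cacao", "cotton", "durian"))
    if (!tx %in% taxa) stop("tree lacks taxon '", tx, "'")
  n_tip <- length(tr$tip.label)
  cacao_tip <- which(taxa == "cacao")[1]
  clades <- lapply(seq_len(tr$Nnode), function(i)
    .leaves_under(tr, n_tip + i))

  # A: cacao sister to all cotton + durian
  parent <- tr$edge[tr$edge[, 2] == cacao_tip, 1]
  sib_taxa <- taxa[setdiff(.leaves_under(tr, parent), cacao_tip)]
  sib_taxa <- sib_taxa[sib_taxa != "grape"]
  if (length(sib_taxa) == sum(taxa %in% c("cotton", "durian")) &&
      all(sib_taxa %in% c("cotton", "durian"))) return("A")

  smallest_containing <- function(tips) {
    ok <- Filter(function(cl) all(tips %in% cl), clades)
    sizes <- vapply(ok, length, integer(1))
    ok[[which.min(sizes)]]
  }
  dur_clade <- smallest_containing(c(cacao_tip, which(taxa == "durian")))
  if (!any(taxa[dur_clade] == "cotton")) return("B")
  cot_clade <- smallest_containing(c(cacao_tip, which(taxa == "cotton")))
  if (!any(taxa[cot_clade] == "durian")) return("C")
  "D"
}

#' Cluster pattern of cotton and durian genes under bootstrap support
#'
#' Considering only clades with bootstrap support of at least
#' `support_min`, reports `"separate_clusters"` when all durian genes (or
#' all cotton genes) form an exclusive supported clade — the signature of
#' independent polyploidies; `"one_to_one"` when durian and cotton genes
#' pair off into supported two-leaf mixed clades — the signature of a
#' shared event; `"other"` otherwise.
#'
#' @param tree a `gene_tree` (node labels = bootstrap percentages)
#' @param support_min bootstrap threshold (percent)
#' @return `"separate_clusters"`, `"one_to_one"` or `"other"`
#' @export
cluster_pattern <- function(tree, support_min = 70) {
  tr <- if (inherits(tree, "gene_tree")) tree$tree else tree
  taxa <- .taxon_of(tr$tip.label)
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  supports <- suppressWarnings(as.numeric(tr$node.label))
  if (is.null(tr$node.label)) supports <- rep(100, n_node)
  clades <- lapply(seq_len(n_node), function(i) .leaves_under(tr, n_tip + i))
  supported <- which(!is.na(supports) & supports >= support_min)
  n_dur <- sum(taxa == "durian"); n_cot <- sum(taxa == "cotton")
  for (i in supported) {
    cl <- taxa[clades[[i]]]
    cl <- cl[cl != "grape"]
    if (length(cl) && all(cl == "durian") && sum(cl == "durian") == n_dur)
      return("separate_clusters")
    if (length(cl) && all(cl == "cotton") && sum(cl == "cotton") == n_cot)
      return("separate_clusters")
  }
  cherries <- 0L
  for (i in supported) {
    cl <- taxa[clades[[i]]]
    if (length(cl) == 2L && sum(cl == "durian") == 1L && sum(cl == "cotton") == 1L)
      cherries <- cherries + 1L
  }
  if (cherries >= min(n_dur, n_cot)) return("one_to_one")
  "other"
}

#' Topology-type and cluster-pattern summary over many groups
#'
#' @param groups list of `homolog_group`s
#' @param method,model,bootstrap_n,seed forwarded to [build_tree()]
#' @param support_min forwarded to [cluster_pattern()]
#' @return data frame with one row per group: `anc`, `type`, `pattern`,
#'   `newick`
#' @export
classify_groups <- function(groups, method = "nj", model = "p",
                            bootstrap_n = 100L, seed = 1L,
                            support_min = 70) {
  rows <- lapply(seq_along(groups), function(i) {
    gt <- build_tree(groups[[i]], method = method, model = model,
                     bootstrap_n = bootstrap_n, seed = seed + i)
    data.frame(anc = groups[[i]]$anc, type = classify_topology(gt),
               pattern = cluster_pattern(gt, support_min),
               newick = ape::write.tree(gt$tree), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
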