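# Ground-truth relations between simulated genes, derived from event
# provenance alone: two genes coalesce at the deepest shared event whose
# copy labels differ, otherwise at the speciation separating their taxa
# (orthologs), otherwise at a tandem duplication.

.split_between <- function(ta, tb) {
  if (ta == tb) return(NA_character_)
  if ("grape" %in% c(ta, tb)) return("grape")
  if ("cacao" %in% c(ta, tb)) return("cacao")
  "cotton"
}

.prov_copy <- function(prov, event_name) {
  m <- regmatches(prov, regexpr(paste0("(?:^|>)", event_name, ":\\d+"), prov))
  out <- rep(1L, length(prov))
  has <- lengths(regmatches(prov, gregexpr(paste0("(?:^|>)", event_name, ":"), prov))) > 0
  out[has] <- as.integer(sub(".*:", "", m))
  out
}

#' True homology relations between two simulated genomes
#'
#' Enumerates all gene pairs sharing an ancestral locus between (or within)
#' taxa and labels each with the event at which the pair coalesces:
#' `ortholog` (speciation), `<event>_outparalog` (cross-genome pairs from a
#' shared polyploidy), `<event>_paralog` (within-genome pairs), or `tandem`.
#'
#' @param truth a `truth_set` from [simulate_history()]
#' @param taxon_a,taxon_b taxon names; equal for within-genome paralogy
#'   (each unordered pair reported once)
#' @return data frame with `gene_a`, `gene_b`, `anc`, `mrca` (event name,
#'   `"speciation"` or `"TD"`), `relation`, and `divergence_ks` (unit-rate
#'   Ks-time at the coalescence point)
#' @export
true_pairs <- function(truth, taxon_a, taxon_b = taxon_a) {
  stopifnot(inherits(truth, "truth_set"))
  ga <- truth$genes[truth$genes$taxon == taxon_a, , drop = FALSE]
  gb <- truth$genes[truth$genes$taxon == taxon_b, , drop = FALSE]
  if (!nrow(ga) || !nrow(gb)) stop("unknown or empty taxon")
  pr <- merge(ga[, c("gene", "anc", "provenance")],
              gb[, c("gene", "anc", "provenance")],
              by = "anc", suffixes = c("_a", "_b"))
  if (taxon_a == taxon_b) pr <- pr[pr$gene_a < pr$gene_b, , drop = FALSE]
  if (!nrow(pr)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      anc = character(), mrca = character(),
                      relation = character(), divergence_ks = numeric()))
  }
  same_taxon <- taxon_a == taxon_b
  split_name <- .split_between(taxon_a, taxon_b)
  split_ks <- if (same_taxon) 0 else truth$split_ks[[split_name]]

  la <- .lineage_branches[[taxon_a]]
  lb <- .lineage_branches[[taxon_b]]
  shared <- Filter(function(e) e$branch %in% la && e$branch %in% lb, truth$events)
  if (length(shared))
    shared <- shared[order(-vapply(shared, `[[`, numeric(1), "time"))]

  mrca <- rep(NA_character_, nrow(pr))
  div <- rep(NA_real_, nrow(pr))
  for (e in shared) {
    ca <- .prov_copy(pr$provenance_a, e$name)
    cb <- .prov_copy(pr$provenance_b, e$name)
    hit <- is.na(mrca) & ca != cb
    mrca[hit] <- e$name
    div[hit] <- e$time
  }
  if (same_taxon) {
    ta <- .prov_copy(pr$provenance_a, "TD")
    tb <- .prov_copy(pr$provenance_b, "TD")
    hit <- is.na(mrca) & ta != tb
    mrca[hit] <- "TD"
    div[hit] <- truth$tandem_ks
  }
  left <- is.na(mrca)
  if (same_taxon && any(left))
    stop("internal error: indistinguishable within-genome gene pair")
  mrca[left] <- "speciation"
  div[left] <- split_ks

  relation <- ifelse(mrca == "speciation", "ortholog",
              ifelse(mrca == "TD", "tandem",
                     paste0(tolower(mrca), if (same_taxon) "_paralog"
                            else "_outparalog")))
  data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b, anc = pr$anc,
             mrca = mrca, relation = relation, divergence_ks = div,
             stringsAsFactors = FALSE)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Simulation ground truth:", nrow(x$genes), "extant genes,",
      length(unique(x$genes$anc)), "ancestral loci\n")
  tab <- table(x$genes$taxon)
  for (tx in names(tab)) cat(sprintf("  %-7s %d genes\n", tx, tab[[tx]]))
  invisible(x)
}
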