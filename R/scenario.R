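# Simulation scenarios: a fixed four-taxon phylogeny
# (grape,(cacao,(durian,cotton))) with polyploidy events placed on named
# branches.  Branch positions and event times are expressed in expected-Ks
# units at unit substitution rate: the expected synonymous divergence of two
# lineages separating at depth d is 2d, and an event at time t produces
# duplicates with expected pairwise Ks = t (before any rate elevation).

.TAXA <- c("grape", "cacao", "durian", "cotton")
.BRANCHES <- c("root", "stem_mal", "stem_dc", .TAXA)

#' Define a polyploidy event
#'
#' @param name unique event label, e.g. `"ECH"` (the eudicot-common
#'   hexaploidization), `"DSH"`, `"GSD"`
#' @param branch branch carrying the event: one of `"root"`, `"stem_mal"`
#'   (cacao+durian+cotton stem), `"stem_dc"` (durian+cotton stem),
#'   `"grape"`, `"cacao"`, `"durian"`, `"cotton"`
#' @param multiplicity genome copies after the event (3 = triplication /
#'   hexaploidization, 2 = whole-genome duplication, 5 = decaploidization)
#' @param time event age in expected-Ks units at unit rate (the expected Ks
#'   between the duplicates it creates)
#' @return list of class `polyploidy_event`
#' @export
polyploidy_event <- function(name, branch, multiplicity, time) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!branch %in% .BRANCHES)
    stop("event '", name, "' placed on unknown branch '", branch, "'")
  if (multiplicity < 2)
    stop("event '", name, "' has multiplicity < 2")
  if (time <= 0) stop("event '", name, "' must have positive time")
  structure(list(name = name, branch = branch,
                 multiplicity = as.integer(multiplicity), time = time),
            class = "polyploidy_event")
}

#' Build a simulation configuration
#'
#' @param n_ancestral_genes genes in the pre-polyploidy ancestral genome
#' @param n_chromosomes ancestral chromosome count
#' @param split_ks named numeric: expected Ks (unit rate) between lineages
#'   diverging at each speciation — `grape` (grape vs the Malvaceae stem),
#'   `cacao`, `cotton` (durian vs cotton); must be strictly decreasing
#' @param events list of [polyploidy_event()]s
#' @param retention_prob retention probability per post-event duplicate gene
#'   (the parental copy of each locus is always retained)
#' @param tandem_rate per-gene probability of a tandem duplication on each
#'   terminal branch
#' @param tandem_ks expected Ks between a tandem pair
#' @param inversion_rate expected number of segmental inversions per
#'   terminal branch (Poisson)
#' @param lineage_loss named per-taxon probability that a gene is lost along
#'   the terminal branch (never removes the last copy of a locus)
#' @param rate_multipliers named per-branch substitution-rate scalars;
#'   branches not named keep rate 1
#' @param codon_length codons per gene
#' @param ka_ratio nonsynonymous/synonymous rate ratio used when evolving
#'   sequences
#' @param seed integer seed; a fixed seed makes all outputs byte-identical
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_ancestral_genes = 200L, n_chromosomes = 4L,
                       split_ks = c(grape = 0.80, cacao = 0.25, cotton = 0.22),
                       events = list(),
                       retention_prob = 1, tandem_rate = 0, tandem_ks = 0.05,
                       inversion_rate = 0,
                       lineage_loss = c(grape = 0, cacao = 0, durian = 0, cotton = 0),
                       rate_multipliers = c(cotton = 1),
                       codon_length = 500L, ka_ratio = 0.2, seed = 1L) {
  if (retention_prob <= 0 || retention_prob > 1)
    stop("retention_prob must be in (0, 1]")
  if (!all(c("grape", "cacao", "cotton") %in% names(split_ks)))
    stop("split_ks needs entries grape, cacao, cotton")
  split_ks <- split_ks[c("grape", "cacao", "cotton")]
  if (any(split_ks <= 0) || any(diff(split_ks) >= 0))
    stop("split_ks must be positive and strictly decreasing (grape > cacao > cotton)")
  rates <- setNames(rep(1, length(.BRANCHES)), .BRANCHES)
  if (length(rate_multipliers)) {
    if (is.null(names(rate_multipliers)) ||
        !all(names(rate_multipliers) %in% .BRANCHES))
      stop("rate_multipliers must be named by branch")
    rates[names(rate_multipliers)] <- rate_multipliers
  }
  if (any(rates <= 0)) stop("rate multipliers must be positive")
  loss <- setNames(rep(0, 4), .TAXA)
  if (length(lineage_loss)) loss[names(lineage_loss)] <- lineage_loss
  events <- lapply(events, function(e) {
    if (!inherits(e, "polyploidy_event")) do.call(polyploidy_event, e) else e
  })
  nm <- vapply(events, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("event names must be unique")
  cfg <- structure(list(
    n_ancestral_genes = as.integer(n_ancestral_genes),
    n_chromosomes = as.integer(n_chromosomes),
    split_ks = split_ks, events = events,
    retention_prob = retention_prob, tandem_rate = tandem_rate,
    tandem_ks = tandem_ks, inversion_rate = inversion_rate,
    lineage_loss = loss, rate_multipliers = rates,
    codon_length = as.integer(codon_length), ka_ratio = ka_ratio,
    seed = as.integer(seed)), class = "sim_config")
  .validate_event_placement(cfg)
  cfg
}

# Branch depth intervals in half-Ks units (depth = time/2).
.branch_intervals <- function(cfg) {
  dg <- cfg$split_ks[["grape"]] / 2
  da <- cfg$split_ks[["cacao"]] / 2
  dc <- cfg$split_ks[["cotton"]] / 2
  list(root = c(dg, Inf), stem_mal = c(da, dg), stem_dc = c(dc, da),
       grape = c(0, dg), cacao = c(0, da), durian = c(0, dc), cotton = c(0, dc))
}

.validate_event_placement <- function(cfg) {
  iv <- .branch_intervals(cfg)
  for (e in cfg$events) {
    d <- e$time / 2
    rng <- iv[[e$branch]]
    if (d <= rng[1] || d > rng[2] + 1e-12)
      stop("event '", e$name, "' at Ks-time ", e$time,
           " does not fall on branch '", e$branch, "'")
  }
  invisible(cfg)
}

# Branches on the root-to-tip path of each taxon, in top-down order.
.lineage_branches <- list(
  grape = c("root", "grape"),
  cacao = c("root", "stem_mal", "cacao"),
  durian = c("root", "stem_mal", "stem_dc", "durian"),
  cotton = c("root", "stem_mal", "stem_dc", "cotton"))

#' Preset simulation scenarios
#'
#' Named study conditions used throughout the package:
#' \describe{
#'   \item{`no_event`}{no polyploidy; four diploid genomes.}
#'   \item{`ech_only`}{the shared eudicot-common hexaploidization (ECH,
#'     triplication at Ks-time 1.04) and nothing later.}
#'   \item{`ech_wgd`}{ECH plus a durian-lineage whole-genome duplication at
#'     Ks-time 0.17.}
#'   \item{`ech_dsh`}{ECH plus a durian-lineage hexaploidization (DSH,
#'     triplication) at Ks-time 0.17.}
#'   \item{`full`}{ECH + DSH + a cotton-lineage decaploidization (GSD,
#'     multiplicity 5) at Ks-time 0.12, with the cotton branch evolving
#'     1.64x faster.}
#'   \item{`shared_triplication`}{ECH plus a single triplication on the
#'     durian+cotton stem (the shared-event alternative model).}
#' }
#'
#' @param name scenario name
#' @param n_ancestral_genes,seed forwarded to [sim_config()]
#' @param ... further overrides forwarded to [sim_config()]
#' @return a `sim_config`
#' @export
scenario_config <- function(name = c("ech_dsh", "ech_only", "ech_wgd", "full",
                                     "shared_triplication", "no_event"),
                            n_ancestral_genes = 200L, seed = 1L, ...) {
  name <- match.arg(name)
  ech <- polyploidy_event("ECH", "root", 3, 1.04)
  ev <- switch(name,
    no_event = list(),
    ech_only = list(ech),
    ech_wgd = list(ech, polyploidy_event("WGD", "durian", 2, 0.17)),
    ech_dsh = list(ech, polyploidy_event("DSH", "durian", 3, 0.17)),
    full = list(ech, polyploidy_event("DSH", "durian", 3, 0.17),
                polyploidy_event("GSD", "cotton", 5, 0.12)),
    shared_triplication = list(ech, polyploidy_event("SHT", "stem_dc", 3, 0.235)))
  rates <- if (name == "full") c(cotton = 1.64) else c(cotton = 1)
  args <- list(n_ancestral_genes = n_ancestral_genes, seed = seed,
               events = ev, rate_multipliers = rates)
  args <- utils::modifyList(args, list(...))
  cfg <- do.call(sim_config, args)
  cfg$scenario <- name
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Polyploid genome simulation", if (!is.null(x$scenario))
    paste0("(scenario '", x$scenario, "')"), "\n")
  cat(sprintf("  %d ancestral genes on %d chromosomes; %d codons per gene\n",
              x$n_ancestral_genes, x$n_chromosomes, x$codon_length))
  cat(sprintf("  splits (Ks): grape %.3f, cacao %.3f, durian-cotton %.3f\n",
              x$split_ks[1], x$split_ks[2], x$split_ks[3]))
  for (e in x$events)
    cat(sprintf("  event %s: x%d on %s at Ks-time %.3f\n",
                e$name, e$multiplicity, e$branch, e$time))
  cat(sprintf("  retention %.2f, tandem %.3f, inversions %.2f, seed %d\n",
              x$retention_prob, x$tandem_rate, x$inversion_rate, x$seed))
  elev <- x$rate_multipliers[x$rate_multipliers != 1]
  if (length(elev))
    cat("  rate multipliers:", paste(names(elev), elev, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
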