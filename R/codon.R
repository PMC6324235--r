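# Codon machinery shared by the simulator and the Ks estimator.
#
# Codons are encoded as integers 1..64 with nucleotide order T, C, A, G:
# index = 16*(n1-1) + 4*(n2-1) + n3.  All site/difference bookkeeping for
# Nei-Gojobori runs off lookup tables built once per session.

.NT <- c("T", "C", "A", "G")

#' Encode a codon character vector as integers 1..64
#' @param codons character vector of 3-letter codons
#' @return integer vector
#' @keywords internal
.codon_index <- function(codons) {
  m <- match(c(substr(codons, 1, 1), substr(codons, 2, 2), substr(codons, 3, 3)),
             .NT)
  n <- length(codons)
  16L * (m[seq_len(n)] - 1L) + 4L * (m[n + seq_len(n)] - 1L) + m[2L * n + seq_len(n)]
}

#' Decode integer codon indices to 3-letter strings
#' @keywords internal
.codon_string <- function(idx) {
  i1 <- (idx - 1L) %/% 16L + 1L
  i2 <- ((idx - 1L) %/% 4L) %% 4L + 1L
  i3 <- (idx - 1L) %% 4L + 1L
  paste0(.NT[i1], .NT[i2], .NT[i3])
}

# All 64 codons in index order and their amino acids (standard code).
.codon_table <- function() {
  cache <- .ploidscan_cache
  if (!is.null(cache$codon_tab)) return(cache$codon_tab)
  codons <- .codon_string(1:64)
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  cache$codon_tab <- list(codons = codons, aa = aa, is_stop = aa == "*")
  cache$codon_tab
}

# Single-position neighbours of a codon: 9 codons one substitution away.
.codon_neighbours <- function(idx) {
  out <- integer(0)
  for (pos in 1:3) {
    step <- c(16L, 4L, 1L)[pos]
    cur <- ((idx - 1L) %/% step) %% 4L
    for (k in 0:3) {
      if (k != cur) out <- c(out, idx + (k - cur) * step)
    }
  }
  out
}

#' Nei-Gojobori lookup tables
#'
#' Builds (and caches) the per-codon synonymous site counts and the
#' pathway-averaged synonymous/nonsynonymous difference matrices used by
#' [nei_gojobori()].  Sites: for each codon position the fraction of the
#' three possible point changes that preserve the amino acid (changes to a
#' stop codon count as nonsynonymous).  Differences between two codons are
#' averaged over all minimal mutational pathways; pathways passing through a
#' stop codon are excluded unless every pathway does.
#'
#' @return list with `syn_sites` (length 64), `SD` and `ND` (64 x 64
#'   matrices), `NTDIFF` (64 x 64 nucleotide mismatch counts)
#' @keywords internal
.ng_tables <- function() {
  cache <- .ploidscan_cache
  if (!is.null(cache$ng)) return(cache$ng)
  tab <- .codon_table()
  aa <- tab$aa
  stop_cod <- tab$is_stop

  syn_sites <- numeric(64)
  for (i in 1:64) {
    if (stop_cod[i]) { syn_sites[i] <- NA_real_; next }
    nb <- .codon_neighbours(i)
    syn <- aa[nb] == aa[i] & !stop_cod[nb]
    syn_sites[i] <- sum(syn) / 3
  }

  # Positions at which two codons differ.
  diff_positions <- function(a, b) {
    pa <- c((a - 1L) %/% 16L, ((a - 1L) %/% 4L) %% 4L, (a - 1L) %% 4L)
    pb <- c((b - 1L) %/% 16L, ((b - 1L) %/% 4L) %% 4L, (b - 1L) %% 4L)
    which(pa != pb)
  }
  set_position <- function(cod, pos, target) {
    step <- c(16L, 4L, 1L)[pos]
    cur <- ((cod - 1L) %/% step) %% 4L
    tgt <- ((target - 1L) %/% step) %% 4L
    cod + (tgt - cur) * step
  }

  SD <- matrix(0, 64, 64)
  ND <- matrix(0, 64, 64)
  NTDIFF <- matrix(0L, 64, 64)
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = {
                  p <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
                  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 3L), ])
                  storage.mode(p) <- "integer"
                  p
                })
  for (i in 1:64) {
    if (stop_cod[i]) next
    for (j in 1:64) {
      if (stop_cod[j] || i == j) next
      dp <- diff_positions(i, j)
      NTDIFF[i, j] <- length(dp)
      pm <- perms[[as.character(length(dp))]]
      path_sd <- numeric(0); path_nd <- numeric(0)
      path_sd_all <- numeric(0); path_nd_all <- numeric(0)
      for (r in seq_len(nrow(pm))) {
        cur <- i; sdc <- 0; ndc <- 0; blocked <- FALSE
        for (pos in dp[pm[r, seq_along(dp)]]) {
          nxt <- set_position(cur, pos, j)
          if (stop_cod[nxt]) blocked <- TRUE
          if (!stop_cod[nxt] && !stop_cod[cur] && aa[nxt] == aa[cur]) {
            sdc <- sdc + 1
          } else {
            ndc <- ndc + 1
          }
          cur <- nxt
        }
        path_sd_all <- c(path_sd_all, sdc); path_nd_all <- c(path_nd_all, ndc)
        if (!blocked) { path_sd <- c(path_sd, sdc); path_nd <- c(path_nd, ndc) }
      }
      if (length(path_sd) == 0L) { path_sd <- path_sd_all; path_nd <- path_nd_all }
      SD[i, j] <- mean(path_sd)
      ND[i, j] <- mean(path_nd)
    }
  }
  cache$ng <- list(syn_sites = syn_sites, SD = SD, ND = ND, NTDIFF = NTDIFF)
  cache$ng
}

# Fourfold-degenerate codon families used by the sequence simulator: the
# six families (first two nucleotides) whose members keep the amino acid
# under any third-position change AND have no synonymous single-step
# neighbour outside the family (this excludes CTN leucine and CGN
# arginine, whose first-position changes can be synonymous and would
# inflate Nei-Gojobori synonymous site counts).  Every member counts
# exactly one synonymous site, so the expected Ks of a simulated pair
# equals the rate-scaled path length separating it.
.FOURFOLD_PREFIX <- c("GT", "TC", "CC", "AC", "GC", "GG")

.fourfold_codons <- function() {
  idx <- outer((match(substr(.FOURFOLD_PREFIX, 1, 1), .NT) - 1L) * 16L +
                 (match(substr(.FOURFOLD_PREFIX, 2, 2), .NT) - 1L) * 4L,
               1:4, `+`)
  matrix(as.integer(idx), nrow = length(.FOURFOLD_PREFIX))  # family x third-nt
}
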