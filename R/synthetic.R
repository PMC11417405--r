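#' Random sharp planted motifs for simulation
#'
#' Generates reference-like PPMs with mostly high-information columns (one
#' dominant base), resembling the sharp consensus models a recruitment
#' array is designed from. Deterministic for a given seed.
#'
#' @param n Number of motifs.
#' @param L Motif length in nt (default 10).
#' @param seed RNG seed.
#' @param p_major Probability mass of the dominant base in a sharp column
#'   (default 0.85).
#' @param frac_medium Fraction of columns drawn as medium-information
#'   (two bases sharing most of the mass; default 0.2).
#' @param max_base_frac Upper bound on the fraction of positions sharing
#'   one dominant base (default 0.5). Curated nonredundant motif libraries
#'   are sequence-diverse; extremely low-complexity motifs (e.g. long
#'   G-runs) are also the known weak spot of column-shuffle significance
#'   nulls, so the generator bounds composition rather than emulate them.
#' @return Named list of [ref_motif()] objects (`planted_01`, ...).
#' @export
make_planted_motifs <- function(n, L = 10, seed = 1, p_major = 0.85,
                                frac_medium = 0.2, max_base_frac = 0.5) {
  set.seed(seed)
  out <- list()
  for (m in seq_len(n)) {
    repeat {
      majors <- sample.int(4L, L, replace = TRUE)
      if (max(tabulate(majors, 4L)) <= floor(max_base_frac * L)) break
    }
    mat <- matrix(0, L, 4)
    for (i in seq_len(L)) {
      major <- majors[i]
      if (stats::runif(1) < frac_medium) {
        minor <- sample(setdiff(1:4, major), 1L)
        row <- rep(0.04, 4)
        row[major] <- 0.50
        row[minor] <- 0.42
      } else {
        row <- rep((1 - p_major) / 3, 4)
        row[major] <- p_major
      }
      mat[i, ] <- row
    }
    id <- sprintf("planted_%02d", m)
    out[[id]] <- ref_motif(id, mat)
  }
  out
}

#' Simulation ground truth
#'
#' Bundles the planted motifs, per-probe-set recruitment gains and noise
#' parameters that fully determine (with a seed) the expected output of a
#' simulated recruitment experiment. The probe energy model is
#' mismatch-additive: `E(probe) = sum_i eps_i(base_i)` with
#' `eps_i(k) = -log(P_ik / max_k P_ik)`, so the consensus probe has E = 0
#' and Boltzmann occupancy `e^{-E}` scales the recruitment signal.
#'
#' @param ppms Named list of planted PPMs, keyed by probe-set id.
#' @param gains Named numeric vector of recruitment gains `g >= 0` per
#'   probe set (unnamed probe sets default to 0; `g = 0` sets are true
#'   negatives).
#' @param bg_meanlog,bg_sdlog Log-normal background fluorescence parameters
#'   (defaults `log(300)`, 0.3).
#' @param spot_cv Multiplicative spot noise coefficient of variation
#'   (default 0.1).
#' @param n_spots Replicate spots per probe (default 5).
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(ppms, gains = numeric(0), bg_meanlog = log(300),
                      bg_sdlog = 0.3, spot_cv = 0.1, n_spots = 5) {
  if (any(gains < 0)) stop("recruitment gains must be >= 0")
  structure(list(ppms = ppms, gains = gains, bg_meanlog = bg_meanlog,
                 bg_sdlog = bg_sdlog, spot_cv = spot_cv,
                 n_spots = n_spots),
            class = "sim_truth")
}

# mismatch-additive probe energy against the planted PPM
probe_energy <- function(site_seq, ppm_mat) {
  idx <- encode_dna(site_seq)
  eps <- -log(ppm_mat / apply(ppm_mat, 1L, max))
  sum(eps[cbind(seq_along(idx), idx)])
}

#' Simulate a recruitment PBM experiment
#'
#' Spot fluorescence is `B * (1 + g * e^{-E(probe)}) * eta`, with `B` a
#' per-probe log-normal background draw, `g` the probe set's recruitment
#' gain, `E` the mismatch-additive probe energy against the planted PPM,
#' and `eta` multiplicative log-normal spot noise. Background probes (and
#' probe sets without a planted PPM or gain) have `g = 0`. Bit-identical
#' for a given seed; a fixed seed across different gain settings yields
#' paired (common-random-numbers) experiments.
#'
#' @param design An `array_design`.
#' @param truth A [sim_truth()].
#' @param seed RNG seed.
#' @param cof,condition,replicate Metadata stamped on the output.
#' @return A `fluor_table` with one row per (probe, spot).
#' @export
simulate_pbm <- function(design, truth, seed = 1, cof = "COF",
                         condition = "cond", replicate = 1L) {
  probes <- design$probes
  n <- nrow(probes)
  set.seed(seed)
  B <- stats::rlnorm(n, truth$bg_meanlog, truth$bg_sdlog)
  sdlog_spot <- sqrt(log(1 + truth$spot_cv^2))
  occ <- numeric(n)
  for (pid in names(truth$ppms)) {
    g <- truth$gains[pid]
    if (is.na(g) || g == 0) next
    sel <- which(probes$probeset_id == pid)
    if (length(sel) == 0L) next
    pset <- design$probesets[[pid]]
    emap <- vapply(pset$probes$site_seq, probe_energy, numeric(1),
                   ppm_matrix(truth$ppms[[pid]]))
    names(emap) <- pset$probes$probe_id
    occ[sel] <- g * exp(-emap[probes$probe_id[sel]])
  }
  eta <- matrix(stats::rlnorm(n * truth$n_spots, -sdlog_spot^2 / 2,
                              sdlog_spot), n, truth$n_spots)
  fl <- B * (1 + occ) * eta
  fluor_table(data.frame(probe_id = rep(probes$probe_id, truth$n_spots),
                         spot = rep(seq_len(truth$n_spots), each = n),
                         channel = "635",
                         fluorescence = as.vector(fl),
                         stringsAsFactors = FALSE),
              cof = cof, condition = condition, replicate = replicate)
}

#' Paired ground truths for a condition-shift experiment
#'
#' Assigns each planted probe set a gained / lost / conserved label and
#' builds the two per-condition gain settings accordingly: gained probe
#' sets have `g1 = g_low, g2 = g_high`; lost the reverse; conserved
#' `g1 = g2 = g_high`. Unlisted probe sets are negatives in both.
#'
#' @param ppms Named list of planted PPMs keyed by probe-set id.
#' @param plan Named character vector probe-set id -> label in
#'   `c("gained", "lost", "conserved")`.
#' @param g_high,g_low High / low recruitment gains (defaults 32, 0).
#' @param ... Passed to [sim_truth()] (noise parameters).
#' @return List with `truth1`, `truth2`, and the `plan`.
#' @export
simulate_condition_shift <- function(ppms, plan, g_high = 32, g_low = 0,
                                     ...) {
  bad <- setdiff(plan, c("gained", "lost", "conserved"))
  if (length(bad)) stop("unknown plan label(s): ", paste(bad, collapse = ", "))
  g1 <- g2 <- stats::setNames(rep(0, length(ppms)), names(ppms))
  for (pid in names(plan)) {
    lab <- plan[[pid]]
    if (lab == "gained") { g1[pid] <- g_low; g2[pid] <- g_high }
    if (lab == "lost") { g1[pid] <- g_high; g2[pid] <- g_low }
    if (lab == "conserved") { g1[pid] <- g_high; g2[pid] <- g_high }
  }
  list(truth1 = sim_truth(ppms, g1, ...), truth2 = sim_truth(ppms, g2, ...),
       plan = plan)
}

#' Simulate a small genome with planted promoter motif sites
#'
#' Builds one random-background contig with evenly spaced genes. For each
#' promoter, consensus sites of the requested TF clusters are planted at
#' non-overlapping random offsets (bounded re-draws). The promoter's
#' acetylation peak score follows the stated linear model
#' `level = a + b * k + N(0, sd)` (floored at 0.1), where `k` is the number
#' of distinct planted recruiting clusters; every promoter also gets an
#' open-chromatin (ATAC) peak so unacetylated promoters are retained with
#' level 0 when `k = 0` draws a near-zero level.
#'
#' @param site_plan List (one element per promoter) of character vectors of
#'   cluster ids to plant (may be empty).
#' @param cluster_motifs Named list: cluster id -> [ref_motif()] whose
#'   consensus is planted.
#' @param acet_a,acet_b,acet_sd Acetylation model intercept, slope per
#'   distinct cluster, and noise SD (defaults 3, 2, 0.5).
#' @param promoter_up,promoter_down Promoter extents (defaults 500 / 100).
#' @param spacing Distance between consecutive TSSs (default 2000).
#' @param seed RNG seed.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `tss` (data
#'   frame), `h3k27ac`, `atac` (peak data frames), `diffbind` (empty
#'   template), and `truth` (per-promoter planted clusters and levels).
#' @export
simulate_genome <- function(site_plan, cluster_motifs, acet_a = 3,
                            acet_b = 2, acet_sd = 0.5, promoter_up = 500,
                            promoter_down = 100, spacing = 2000, seed = 1) {
  set.seed(seed)
  n_prom <- length(site_plan)
  contig_len <- spacing * (n_prom + 1L)
  seq <- sample(DNA_BASES, contig_len, replace = TRUE)
  tss_pos <- spacing * seq_len(n_prom)  # 0-based TSS positions
  prom_start <- tss_pos - promoter_up
  prom_end <- tss_pos + promoter_down
  plen <- promoter_up + promoter_down
  truth <- vector("list", n_prom)
  for (p in seq_len(n_prom)) {
    clusters <- unique(site_plan[[p]])
    placed <- integer(0)  # occupied offsets within the promoter
    sites <- list()
    for (cl in site_plan[[p]]) {
      cons <- consensus_from_ppm(cluster_motifs[[cl]])$sequence
      Lm <- nchar(cons)
      ok <- FALSE
      for (try in 1:200) {
        off <- sample.int(plen - Lm + 1L, 1L)
        if (!any(off:(off + Lm - 1L) %in% placed)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place non-overlapping sites in promoter ", p)
      placed <- c(placed, off:(off + Lm - 1L))
      seq[(prom_start[p] + off):(prom_start[p] + off + Lm - 1L)] <-
        strsplit(cons, "")[[1]]
      sites[[length(sites) + 1L]] <- list(cluster = cl, offset = off)
    }
    k <- length(clusters)
    # promoters with no recruiting clusters are open but unacetylated
    level <- if (k == 0L) 0 else
      max(acet_a + acet_b * k + stats::rnorm(1, 0, acet_sd), 0.1)
    truth[[p]] <- list(clusters = clusters, k = k, level = level,
                       sites = sites)
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- "chrS"
  levels <- vapply(truth, `[[`, numeric(1), "level")
  h3k27ac <- data.frame(contig = "chrS", start = prom_start,
                        end = prom_end,
                        name = sprintf("acpk_%03d", seq_len(n_prom)),
                        score = levels, stringsAsFactors = FALSE)
  h3k27ac <- h3k27ac[levels > 0, , drop = FALSE]
  atac <- data.frame(contig = "chrS", start = prom_start, end = prom_end,
                     name = sprintf("atpk_%03d", seq_len(n_prom)),
                     score = 1, stringsAsFactors = FALSE)
  list(genome = genome,
       tss = data.frame(gene = sprintf("gene_%03d", seq_len(n_prom)),
                        contig = "chrS", tss = tss_pos, strand = "+",
                        stringsAsFactors = FALSE),
       h3k27ac = h3k27ac, atac = atac,
       diffbind = data.frame(contig = character(0), start = integer(0),
                             end = integer(0), log2fc = numeric(0)),
       truth = truth)
}
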