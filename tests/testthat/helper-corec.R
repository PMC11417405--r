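# shared fixtures and independent brute-force oracles for the test suite

# random probability matrix with rows summing to 1
random_ppm <- function(L, seed = NULL, alpha = 1) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(L * 4, alpha), L, 4)
  m <- g / rowSums(g)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

# brute-force best ungapped alignment: plain loops over every offset and
# orientation, per-column distance computed directly
oracle_best_ed <- function(Q, Tm, min_overlap = 5) {
  rc <- function(m) {
    out <- m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
    colnames(out) <- colnames(m)
    out
  }
  best <- Inf
  for (ori in 1:2) {
    Tx <- if (ori == 1) Tm else rc(Tm)
    for (off in -(nrow(Q)):(nrow(Tx))) {
      ds <- c()
      for (i in seq_len(nrow(Q))) {
        j <- i + off
        if (j >= 1 && j <= nrow(Tx))
          ds <- c(ds, sqrt(sum((Q[i, ] - Tx[j, ])^2)))
      }
      if (length(ds) >= min_overlap) best <- min(best, mean(ds))
    }
  }
  best
}

# brute-force complete-linkage agglomeration: repeatedly merge the pair of
# clusters with the smallest maximal inter-member distance while it does
# not exceed the cut height
oracle_complete_linkage <- function(dmat, cut) {
  ids <- rownames(dmat)
  clusters <- as.list(ids)
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- max(dmat[clusters[[a]], clusters[[b]]])
      if (is.null(best) || d < best$d) best <- list(a = a, b = b, d = d)
    }
    if (best$d > cut) break
    clusters[[best$a]] <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters[[best$b]] <- NULL
  }
  # canonical form: sorted members, clusters ordered by first member
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, character(1), 1))]
}

# exhaustive single-window PWM tail probabilities: enumerate all 4^L windows
oracle_pwm_tail <- function(S) {
  L <- nrow(S)
  grids <- do.call(expand.grid, rep(list(1:4), L))
  scores <- apply(grids, 1L, function(ix) sum(S[cbind(seq_len(L), ix)]))
  function(s) mean(scores >= s)
}

# exhaustive two-sided Wilcoxon rank-sum p-value over all group assignments
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  W_obs <- sum(rank(pooled)[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  Ws <- apply(combos, 2L, function(ix) sum(rank(pooled)[ix]))
  mu <- mean(Ws)
  min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
}

# all-pairs interval overlap oracle (0-based half-open)
oracle_overlaps <- function(q, s) {
  hits <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$contig[i] == s$contig[j] && q$start[i] < s$end[j] &&
          s$start[j] < q$end[i])
        hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (length(hits) == 0L) matrix(integer(0), 0, 2) else do.call(rbind, hits)
}

# small simulated experiment shared by several tests: design + high-gain
# truth over `n` planted 12-mers
tiny_sim <- function(n = 4, gain = 32, seed = 7, n_background = 150) {
  planted <- make_planted_motifs(n, L = 12, seed = seed)
  set.seed(seed + 1)
  genome <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""))
  names(genome) <- "bg_contig"
  design <- build_array_design(planted, background_genome = genome,
                               n_background = n_background, seed = seed)
  gains <- stats::setNames(rep(gain, length(design$probesets)),
                           names(design$probesets))
  list(planted = planted, design = design,
       truth = sim_truth(planted[names(design$probesets)], gains))
}
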