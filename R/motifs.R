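#' Build the delta-z recruitment motif for a probe set
#'
#' The z-score matrix `z_ik` holds, for each position `i` of the consensus
#' site and base `k`, the z-score of the probe carrying base `k` at position
#' `i`: the SV probe for non-consensus bases, and the consensus probe's
#' single z-score re-used at every position's consensus-base cell. The
#' per-position reference `mu_i` is the median of the four variants and
#' `delta_ik = z_ik - mu_i`, a binding-energy-matrix-like description of how
#' each substitution changes recruitment.
#'
#' @param z A `z_profile` covering all probes of the set.
#' @param pset A `probe_set` from [enumerate_sv_probes()].
#' @return A `corec_delta_z` object: list with `probeset_id`, `consensus`,
#'   `z_matrix` (L x 4), `mu` (length L), `delta` (L x 4).
#' @export
build_delta_z <- function(z, pset) {
  zmap <- stats::setNames(z$z, z$probe_id)
  missing <- setdiff(pset$probes$probe_id, names(zmap))
  if (length(missing))
    stop("z-profile is missing probe(s): ", paste(missing, collapse = ", "))
  chars <- strsplit(pset$consensus, "")[[1]]
  L <- length(chars)
  zm <- matrix(NA_real_, L, 4L, dimnames = list(NULL, DNA_BASES))
  cons_id <- pset$probes$probe_id[pset$probes$category == "consensus"]
  zm[cbind(seq_len(L), match(chars, DNA_BASES))] <- zmap[[cons_id]]
  sv <- pset$probes[pset$probes$category == "sv", ]
  zm[cbind(sv$sv_position, match(sv$sv_base, DNA_BASES))] <-
    zmap[sv$probe_id]
  mu <- apply(zm, 1L, stats::median)
  structure(list(probeset_id = pset$probeset_id, consensus = pset$consensus,
                 z_matrix = zm, mu = mu, delta = zm - mu),
            class = "corec_delta_z")
}

#' Motif strength of a probe set
#'
#' The median z-score of the `n_top` top-scoring probes of the consensus +
#' SV probe set (default 10, roughly the top 15% of a 10-mer's 31 probes).
#' An aggregate, cell-specific measure of how strongly the profiled cofactor
#' is recruited to DNA sites matching this motif.
#'
#' @param z A `z_profile`.
#' @param pset A `probe_set`.
#' @param n_top Number of top probes (default 10). Sets with fewer probes
#'   use all of them, with a warning.
#' @return List with `ms` (the motif strength) and `contributing_probe_ids`.
#' @export
motif_strength <- function(z, pset, n_top = 10) {
  ids <- pset$probes$probe_id
  if (length(ids) == 0L) stop("empty probe set")
  zmap <- stats::setNames(z$z, z$probe_id)
  missing <- setdiff(ids, names(zmap))
  if (length(missing))
    stop("z-profile is missing probe(s): ", paste(missing, collapse = ", "))
  zz <- zmap[ids]
  if (length(zz) < n_top) {
    warning("probe set ", pset$probeset_id, " has only ", length(zz),
            " probes; motif strength uses all of them")
    n_top <- length(zz)
  }
  ord <- order(zz, decreasing = TRUE)
  top <- ord[seq_len(n_top)]
  list(ms = stats::median(zz[top]),
       contributing_probe_ids = unname(ids[top]))
}

#' Adaptive Boltzmann scaling for the z-to-probability transform
#'
#' The z-score change caused by a nucleotide substitution scales with the
#' overall recruitment strength, so a fixed Boltzmann temperature would
#' over-sharpen weak motifs and over-flatten strong ones. beta is therefore
#' set per motif from its motif strength MS:
#' \deqn{\beta = 4 \ \mathrm{if}\ MS \le 0;\quad
#'       \beta = 4 - 0.5\,MS \ \mathrm{if}\ 0 < MS < 6;\quad
#'       \beta = 1 \ \mathrm{if}\ MS \ge 6.}
#' The function is continuous and non-increasing with range `[1, 4]`.
#'
#' @param ms Motif strength (finite numeric; vectorised).
#' @return beta value(s).
#' @export
corec_beta <- function(ms) {
  if (any(is.na(ms))) stop("motif strength must not be NA/NaN")
  ifelse(ms <= 0, 4, ifelse(ms >= 6, 1, 4 - 0.5 * ms))
}

#' Boltzmann probability matrix from a delta-z motif
#'
#' Row-wise softmax of `beta * z`:
#' \deqn{P_{ik} = e^{\beta z_{ik}} / \sum_k e^{\beta z_{ik}},}
#' numerically stabilised by row-max subtraction. Because the per-row
#' reference `mu_i` is constant within a row, using `delta` instead of `z`
#' gives the identical matrix.
#'
#' @param motif A `corec_delta_z` (or a bare L x 4 z-matrix).
#' @param beta Positive Boltzmann scaling.
#' @return A `corec_ppm` object: list with `id`, `matrix` (L x 4 rows
#'   summing to 1), `beta`, `ms` (NA unless set by [build_corec_motif()]),
#'   `meta`.
#' @export
ppm_from_z <- function(motif, beta) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  zm <- if (is.matrix(motif)) motif else motif$z_matrix
  s <- beta * zm
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  P <- e / rowSums(e)
  colnames(P) <- DNA_BASES
  structure(list(id = if (is.matrix(motif)) "motif" else motif$probeset_id,
                 matrix = P, beta = beta, ms = NA_real_, meta = NULL),
            class = "corec_ppm")
}

#' Full recruitment motif for one probe set
#'
#' Convenience wrapper: delta-z motif, motif strength, adaptive beta, and
#' Boltzmann probability matrix in one object.
#'
#' @param z A `z_profile`.
#' @param pset A `probe_set`.
#' @param n_top Top probes used for the motif strength.
#' @return A `corec_ppm` with `ms`, `beta`, `delta_z` and experiment `meta`
#'   (taken from the z-profile) filled in.
#' @export
build_corec_motif <- function(z, pset, n_top = 10) {
  dz <- build_delta_z(z, pset)
  msr <- motif_strength(z, pset, n_top)
  beta <- corec_beta(msr$ms)
  ppm <- ppm_from_z(dz, beta)
  ppm$ms <- msr$ms
  ppm$contributing_probe_ids <- msr$contributing_probe_ids
  ppm$delta_z <- dz
  ppm$meta <- attr(z, "meta")
  ppm
}

#' @export
print.corec_ppm <- function(x, ...) {
  cat(sprintf("corec_ppm %s: L=%d, MS=%.3g, beta=%.3g\n",
              x$id, nrow(x$matrix), x$ms, x$beta))
  invisible(x)
}

#' Per-position information content of a probability matrix
#'
#' Uniform-background two-bit convention: `IC_i = 2 + sum_k P_ik log2 P_ik`
#' (zero probabilities contribute zero).
#'
#' @param ppm A `corec_ppm`, `ref_motif` or bare matrix.
#' @return Numeric vector of per-position IC in bits.
#' @export
information_content <- function(ppm) {
  P <- ppm_matrix(ppm)
  pl <- ifelse(P > 0, P * log2(P), 0)
  2 + rowSums(pl)
}

#' Motif quality filter
#'
#' A recruitment motif passes when its motif strength exceeds
#' `ms_threshold` and the minimum of the mean information content over all
#' windows of `window` consecutive positions exceeds `ic_threshold`. Motifs
#' shorter than `window` average over all positions.
#'
#' @param ppm A `corec_ppm` (must carry `ms`; pass `ms` explicitly
#'   otherwise).
#' @param ms_threshold Motif strength threshold (default 0.4).
#' @param ic_threshold Windowed mean IC threshold in bits (default 1.0).
#' @param window Window width in positions (default 5).
#' @param ms Motif strength override.
#' @return List with `pass` (logical), `reasons` (character), `ms`,
#'   `min_window_ic`.
#' @export
quality_filter <- function(ppm, ms_threshold = 0.4, ic_threshold = 1.0,
                           window = 5, ms = ppm$ms) {
  ic <- information_content(ppm)
  L <- length(ic)
  w <- min(window, L)
  win_means <- vapply(seq_len(L - w + 1L),
                      function(i) mean(ic[i:(i + w - 1L)]), numeric(1))
  min_ic <- min(win_means)
  reasons <- character(0)
  if (!(ms > ms_threshold))
    reasons <- c(reasons, sprintf("motif strength %.3g <= %.3g", ms,
                                  ms_threshold))
  if (!(min_ic > ic_threshold))
    reasons <- c(reasons, sprintf("min windowed IC %.3g <= %.3g", min_ic,
                                  ic_threshold))
  list(pass = length(reasons) == 0L, reasons = reasons, ms = ms,
       min_window_ic = min_ic)
}
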