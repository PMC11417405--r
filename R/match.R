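#' Euclidean distance between motifs at shared coordinates
#'
#' For two probability matrices over the same consensus + SV coordinates
#' (equal length, no alignment), the per-column Euclidean distance
#' `sqrt(sum_k (P_ik - Q_ik)^2)` is averaged over columns (`normalize =
#' "mean"`, the default, which makes the replicate/condition thresholds 0.4
#' and 0.25 length-independent) or summed (`normalize = "sum"`).
#'
#' @param P,Q `corec_ppm` / `ref_motif` objects or bare matrices of equal
#'   length.
#' @param normalize `"mean"` (default) or `"sum"`.
#' @return The ED statistic (non-negative scalar).
#' @export
ed_same_coords <- function(P, Q, normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  Pm <- ppm_matrix(P)
  Qm <- ppm_matrix(Q)
  if (nrow(Pm) != nrow(Qm))
    stop("motif length mismatch (", nrow(Pm), " vs ", nrow(Qm), ")")
  d <- sqrt(rowSums((Pm - Qm)^2))
  if (normalize == "mean") mean(d) else sum(d)
}

# Lq x Lt matrix of Euclidean distances between query columns (rows of Q)
# and target columns (rows of Tm)
column_distance_matrix <- function(Q, Tm) {
  cross <- Q %*% t(Tm)
  d2 <- outer(rowSums(Q^2), rowSums(Tm^2), "+") - 2 * cross
  sqrt(pmax(d2, 0))
}

# all ungapped alignment offsets with >= min_overlap aligned columns;
# query position i aligns to target position i + off
alignment_offsets <- function(Lq, Lt, min_overlap) {
  if (min_overlap > min(Lq, Lt)) return(integer(0))
  seq(-(Lq - min_overlap), Lt - min_overlap)
}

#' Best ungapped alignment between two motifs
#'
#' Slides the query over the target at every offset with at least
#' `min_overlap` aligned columns, in both orientations (the `-` orientation
#' compares against the reverse complement of the target), and returns the
#' alignment with the lowest mean per-column Euclidean distance. Only
#' overlapping columns contribute; overhangs carry no penalty.
#'
#' @param query,target Motif objects or matrices.
#' @param min_overlap Minimum aligned columns (default 5).
#' @return List with `ed`, `offset`, `orientation` (`"+"`/`"-"`),
#'   `overlap`; or `NULL` when no alignment satisfies the overlap.
#' @export
best_ed_alignment <- function(query, target, min_overlap = 5) {
  Q <- ppm_matrix(query)
  Tm <- ppm_matrix(target)
  best <- NULL
  for (ori in c("+", "-")) {
    Tori <- if (ori == "+") Tm else revcomp_ppm(Tm)
    D <- column_distance_matrix(Q, Tori)
    for (off in alignment_offsets(nrow(Q), nrow(Tori), min_overlap)) {
      qi <- max(1L, 1L - off):min(nrow(Q), nrow(Tori) - off)
      ed <- mean(D[cbind(qi, qi + off)])
      if (is.null(best) || ed < best$ed - 1e-12) {
        best <- list(ed = ed, offset = off, orientation = ori,
                     overlap = length(qi))
      }
    }
  }
  best
}

#' Compare a recruitment motif to a reference library
#'
#' For every reference motif, finds the best ungapped alignment ED
#' ([best_ed_alignment()]) and assigns a raw p-value from a seeded
#' Monte-Carlo null in which the query's columns are shuffled and the ED is
#' re-evaluated at the observed best alignment (same offset and
#' orientation): `p = (1 + #\{null ED <= observed\}) / (n_null + 1)`. This
#' conditional permutation null asks whether the observed column-to-column
#' correspondence is better than a random assignment of the query's own
#' columns; re-optimising the alignment for every shuffle would instead let
#' short chance alignments of a motif's own columns dominate the null.
#' Adjusted p-values follow the library-size (Bonferroni) convention
#' `p_adj = min(1, p * #refs)`, and matches with `p_adj < p_adj_cutoff` are
#' flagged significant.
#'
#' @param query A `corec_ppm` (or any motif object).
#' @param refs Named list of reference motifs.
#' @param min_overlap Minimum aligned columns (default 5).
#' @param n_null Number of column shuffles (default 10000).
#' @param seed RNG seed for the shuffles.
#' @param p_adj_cutoff Significance cutoff on the adjusted p (default 0.01).
#' @return Data frame with one row per admissible reference: `query_id`,
#'   `target_id`, `ed`, `offset`, `orientation`, `overlap`, `p`, `p_adj`,
#'   `significant`. Empty (with a warning) when no reference admits the
#'   overlap.
#' @export
compare_to_reference <- function(query, refs, min_overlap = 5,
                                 n_null = 10000, seed = 1,
                                 p_adj_cutoff = 0.01) {
  Q <- ppm_matrix(query)
  Lq <- nrow(Q)
  ids <- names(refs) %||% vapply(refs, motif_id, character(1))
  admissible <- vapply(refs, function(r) min_overlap <= min(Lq,
    nrow(ppm_matrix(r))), logical(1))
  if (!any(admissible)) {
    warning("no reference motif admits an overlap of ", min_overlap)
    return(data.frame(query_id = character(0), target_id = character(0),
                      ed = numeric(0), offset = integer(0),
                      orientation = character(0), overlap = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  set.seed(seed)
  perms <- t(replicate(n_null, sample.int(Lq)))
  nrefs <- sum(admissible)
  rows <- vector("list", nrefs)
  k <- 0L
  for (ri in which(admissible)) {
    Tm <- ppm_matrix(refs[[ri]])
    obs <- best_ed_alignment(Q, Tm, min_overlap)
    Tori <- if (obs$orientation == "+") Tm else revcomp_ppm(Tm)
    D <- column_distance_matrix(Q, Tori)
    off <- obs$offset
    qi <- max(1L, 1L - off):min(Lq, nrow(Tori) - off)
    vals <- matrix(D[cbind(as.vector(perms[, qi, drop = FALSE]),
                           rep(qi + off, each = n_null))],
                   n_null, length(qi))
    null_ed <- rowMeans(vals)
    p <- (1 + sum(null_ed <= obs$ed + 1e-12)) / (n_null + 1)
    k <- k + 1L
    rows[[k]] <- data.frame(query_id = motif_id(query),
                            target_id = ids[ri], ed = obs$ed,
                            offset = obs$offset,
                            orientation = obs$orientation,
                            overlap = obs$overlap, p = p,
                            p_adj = min(1, p * nrefs),
                            significant = min(1, p * nrefs) < p_adj_cutoff,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate consistency filter
#'
#' A probe set's recruitment motif is considered replicated when at least
#' one pair of replicate motifs (same consensus + SV coordinates) agrees
#' with ED below `threshold`. Single-member groups are never replicated.
#'
#' @param members List of `corec_ppm` replicate motifs for one probe set.
#' @param threshold Replicate ED threshold (default 0.4).
#' @return A `replicate_group`: list with `probeset_id`, `cof`, `condition`,
#'   `members`, `replicated`, `ed_pairs` (pairwise ED matrix), `ms` (max
#'   member motif strength), `assigned_cluster` and `best_match` (filled by
#'   [assign_cluster()]).
#' @export
replicate_filter <- function(members, threshold = 0.4) {
  if (length(members) < 1L) stop("need at least one member motif")
  ids <- unique(vapply(members, `[[`, character(1), "id"))
  if (length(ids) != 1L)
    stop("replicate members span several probe sets: ",
         paste(ids, collapse = ", "))
  n <- length(members)
  edm <- matrix(0, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      edm[i, j] <- edm[j, i] <- ed_same_coords(members[[i]], members[[j]])
    }
  }
  replicated <- n >= 2L && any(edm[upper.tri(edm)] < threshold)
  meta <- members[[1]]$meta %||% list()
  structure(list(probeset_id = ids, cof = meta$cof %||% NA_character_,
                 condition = meta$condition %||% NA_character_,
                 members = members, replicated = replicated,
                 ed_pairs = edm,
                 ms = max(vapply(members, `[[`, numeric(1), "ms")),
                 assigned_cluster = NULL, best_match = NULL),
            class = "replicate_group")
}

#' Cross-condition motif conservation
#'
#' Two replicate groups for the same probe set (one per condition or cell
#' type) are conserved when any cross-condition pair of member motifs has
#' ED below `threshold`.
#'
#' @param group1,group2 `replicate_group` objects (both replicated).
#' @param threshold Cross-condition ED threshold (default 0.25).
#' @return Logical.
#' @export
condition_conserved <- function(group1, group2, threshold = 0.25) {
  if (group1$probeset_id != group2$probeset_id)
    stop("groups describe different probe sets (", group1$probeset_id,
         " vs ", group2$probeset_id, ")")
  for (a in group1$members) for (b in group2$members) {
    if (ed_same_coords(a, b) < threshold) return(TRUE)
  }
  FALSE
}

#' Assign a replicate group to a TF motif cluster
#'
#' Among all members' significant reference matches, the single match with
#' the lowest adjusted p-value decides: the group is assigned the cluster
#' containing that reference motif. Ties are broken by lower ED, then
#' lexicographic target id. With no significant match the group stays
#' unassigned.
#'
#' @param group A replicated `replicate_group`.
#' @param matches List of [compare_to_reference()] data frames, one per
#'   member.
#' @param clusters A `tf_cluster_set` ([build_tf_clusters()]).
#' @return The group with `assigned_cluster` (cluster id or `NA`) and
#'   `best_match` (one-row data frame or `NULL`) filled in.
#' @export
assign_cluster <- function(group, matches, clusters) {
  all_m <- do.call(rbind, matches)
  sig <- all_m[all_m$significant, , drop = FALSE]
  if (is.null(sig) || nrow(sig) == 0L) {
    group$assigned_cluster <- NA_character_
    group$best_match <- NULL
    return(group)
  }
  ord <- order(sig$p_adj, sig$ed, sig$target_id)
  best <- sig[ord[1L], , drop = FALSE]
  cl <- cluster_of_motif(clusters, best$target_id)
  if (is.na(cl))
    warning("best match ", best$target_id, " belongs to no cluster")
  group$assigned_cluster <- cl
  group$best_match <- best
  group
}

#' Write motif matches as TSV
#'
#' @param matches A [compare_to_reference()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
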