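#' Assemble the COF x condition x TF-cluster recruitment matrix
#'
#' Each cell holds the maximum motif strength over all replicate groups that
#' passed the quality and replicate filters and were assigned to that TF
#' cluster in that COF / condition experiment, with the contributing probe
#' sets recorded as provenance.
#'
#' @param groups List of assigned `replicate_group` objects
#'   ([assign_cluster()]); unassigned or unreplicated groups are skipped.
#' @return A `recruitment_matrix`: long-format data frame with columns
#'   `cof`, `condition`, `cluster`, `ms`, `probesets`.
#' @export
build_matrix <- function(groups) {
  keep <- Filter(function(g) isTRUE(g$replicated) &&
                   !is.null(g$assigned_cluster) &&
                   !is.na(g$assigned_cluster), groups)
  if (length(keep) == 0L) {
    return(structure(data.frame(cof = character(0), condition = character(0),
                                cluster = character(0), ms = numeric(0),
                                probesets = character(0),
                                stringsAsFactors = FALSE),
                     class = c("recruitment_matrix", "data.frame")))
  }
  tab <- do.call(rbind, lapply(keep, function(g) {
    data.frame(cof = g$cof, condition = g$condition,
               cluster = g$assigned_cluster, ms = g$ms,
               probesets = g$probeset_id, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(ms ~ cof + condition + cluster, tab, max)
  prov <- stats::aggregate(probesets ~ cof + condition + cluster, tab,
                           function(x) paste(sort(unique(x)), collapse = ","))
  out <- merge(agg, prov, by = c("cof", "condition", "cluster"))
  out <- out[order(out$cof, out$condition, out$cluster), ]
  rownames(out) <- NULL
  structure(out, class = c("recruitment_matrix", "data.frame"))
}

#' Gained / lost / conserved status across two conditions
#'
#' For each (COF, TF cluster) interaction: `gained` when present only in the
#' second condition, `lost` when present only in the first, `conserved` when
#' present in both and the across-condition motif filter
#' ([condition_conserved()]) holds. Interactions present in both conditions
#' whose motifs diverge across conditions are reported as `discordant`.
#'
#' @param matrix A `recruitment_matrix` restricted to two conditions.
#' @param conditions Character vector of length 2 giving condition order
#'   (condition 1, condition 2); defaults to sorted unique conditions.
#' @param conserved_flags Optional named logical vector keyed
#'   `"<cof>|<cluster>"` from the across-condition ED filter; interactions
#'   present in both conditions default to conserved when no flag is given.
#' @return An `interaction_calls` object: data frame with `cof`, `cluster`,
#'   `status`, `ms1`, `ms2`, `delta_ms`, plus `counts` and `fractions`
#'   attributes.
#' @export
call_condition_status <- function(matrix, conditions = NULL,
                                  conserved_flags = NULL) {
  conds <- conditions %||% sort(unique(matrix$condition))
  if (length(conds) != 2L)
    stop("pairwise API: exactly 2 conditions required (got ",
         length(conds), ")")
  m1 <- matrix[matrix$condition == conds[1], ]
  m2 <- matrix[matrix$condition == conds[2], ]
  keys <- unique(rbind(m1[c("cof", "cluster")], m2[c("cof", "cluster")]))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    cof <- keys$cof[i]; cl <- keys$cluster[i]
    ms1 <- m1$ms[m1$cof == cof & m1$cluster == cl]
    ms2 <- m2$ms[m2$cof == cof & m2$cluster == cl]
    p1 <- length(ms1) > 0L
    p2 <- length(ms2) > 0L
    status <- if (p1 && p2) {
      flag <- (conserved_flags %||% logical(0))[paste(cof, cl, sep = "|")]
      if (length(flag) == 0 || is.na(flag) || isTRUE(unname(flag)))
        "conserved" else "discordant"
    } else if (p2) "gained" else "lost"
    data.frame(cof = cof, cluster = cl, status = status,
               ms1 = if (p1) ms1 else NA_real_,
               ms2 = if (p2) ms2 else NA_real_,
               delta_ms = (if (p2) ms2 else 0) - (if (p1) ms1 else 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  counts <- table(factor(out$status, levels = c("gained", "lost",
                                                "conserved", "discordant")))
  structure(out, counts = as.vector(counts[1:3]),
            count_table = counts, fractions = as.vector(counts) / nrow(out),
            conditions = conds,
            class = c("interaction_calls", "data.frame"))
}

#' Classify per-cluster recruitment response across COFs
#'
#' Given the interaction calls for the COFs (e.g. KATs) recruiting each TF
#' cluster between two conditions, assigns one class per cluster:
#' \describe{
#'   \item{strongly_induced}{every recruiting COF has delta MS > `threshold`}
#'   \item{partially_induced}{at least two COFs have delta MS > `threshold`
#'     and at least one other COF is constitutive}
#'   \item{diminished}{at least two COFs have delta MS < -`threshold` and at
#'     least one other COF is constitutive}
#'   \item{kat_specific}{exactly one COF recruits the cluster}
#'   \item{none}{anything else}
#' }
#' "Constitutive" means present and conserved in both conditions with
#' `|delta MS| <= threshold`.
#'
#' @param calls An `interaction_calls` data frame.
#' @param threshold Delta motif strength threshold (default 1.5).
#' @return Data frame with `cluster`, `class`, `n_cofs`.
#' @export
classify_response <- function(calls, threshold = 1.5) {
  out <- lapply(split(calls, calls$cluster), function(cc) {
    d <- cc$delta_ms
    constitutive <- cc$status == "conserved" & abs(d) <= threshold
    cls <- if (all(d > threshold)) {
      "strongly_induced"
    } else if (sum(d > threshold) >= 2L && any(constitutive)) {
      "partially_induced"
    } else if (sum(d < -threshold) >= 2L && any(constitutive)) {
      "diminished"
    } else if (nrow(cc) == 1L) {
      "kat_specific"
    } else "none"
    data.frame(cluster = cc$cluster[1], class = cls, n_cofs = nrow(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Constitutively promiscuous TF clusters
#'
#' Clusters recruited by strictly more than `kat_min_exclusive` COFs with
#' motif strength strictly above `ms_min` in both conditions.
#'
#' @param matrix A `recruitment_matrix` over two conditions.
#' @param ms_min Motif strength threshold (default 3; strict >).
#' @param kat_min_exclusive COF-count threshold (default 4; strict >).
#' @param conditions Optional pair of condition labels.
#' @return Character vector of promiscuous cluster ids.
#' @export
promiscuity <- function(matrix, ms_min = 3, kat_min_exclusive = 4,
                        conditions = NULL) {
  conds <- conditions %||% sort(unique(matrix$condition))
  if (length(conds) != 2L) stop("exactly 2 conditions required")
  qual <- matrix[matrix$ms > ms_min, ]
  out <- character(0)
  for (cl in unique(qual$cluster)) {
    sub <- qual[qual$cluster == cl, ]
    both <- intersect(sub$cof[sub$condition == conds[1]],
                      sub$cof[sub$condition == conds[2]])
    if (length(both) > kat_min_exclusive) out <- c(out, cl)
  }
  sort(out)
}

#' Annotate interactions as previously reported or unreported
#'
#' An interaction (COF, TF cluster) counts as reported when any TF mapped to
#' that cluster has a protein-protein interaction edge with that COF in the
#' supplied edge list.
#'
#' @param matrix A `recruitment_matrix` (or any data frame with `cof` and
#'   `cluster` columns).
#' @param ppi_edges Data frame with columns `tf_gene` and `cof`.
#' @param tf_to_cluster Named character vector mapping TF gene -> cluster id
#'   (built via [map_motif_to_cluster()] over the TF's motifs).
#' @return The unique (cof, cluster) pairs with a logical `reported` column.
#' @export
annotate_novelty <- function(matrix, ppi_edges, tf_to_cluster) {
  pairs <- unique(matrix[, c("cof", "cluster")])
  covered <- unique(data.frame(
    cof = ppi_edges$cof,
    cluster = unname(tf_to_cluster[ppi_edges$tf_gene]),
    stringsAsFactors = FALSE))
  covered <- covered[!is.na(covered$cluster), ]
  pairs$reported <- paste(pairs$cof, pairs$cluster) %in%
    paste(covered$cof, covered$cluster)
  rownames(pairs) <- NULL
  pairs
}

#' Permutation test for cell-type specificity of recruitment
#'
#' Input is a binary presence matrix with TF clusters as rows and
#' experiments (COF x cell type) as columns, plus the cell-type label of
#' each column. The observed statistic is the number of clusters present
#' (in any experiment) in exactly one of the two cell types. The null
#' permutes each row's entries across columns independently, and the
#' z-score `(obs - null mean) / null SD` measures how much more cell-type
#' specific the observed matrix is than label-scrambled data.
#'
#' @param presence Binary/logical matrix, clusters x experiment columns.
#' @param cell_type Character vector, one cell-type label per column
#'   (exactly two distinct values).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return List with `observed`, `null_mean`, `null_sd`, `z`, `n_perm`.
#' @export
row_permutation_test <- function(presence, cell_type, n_perm = 10000,
                                 seed = 1) {
  presence <- (as.matrix(presence) != 0)
  types <- unique(cell_type)
  if (length(types) != 2L) stop("exactly 2 cell types required")
  if (length(cell_type) != ncol(presence))
    stop("one cell-type label per column required")
  i1 <- which(cell_type == types[1])
  i2 <- which(cell_type == types[2])
  stat <- function(m) {
    p1 <- rowSums(m[, i1, drop = FALSE]) > 0
    p2 <- rowSums(m[, i2, drop = FALSE]) > 0
    sum(xor(p1, p2))
  }
  obs <- stat(presence)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- presence
    for (r in seq_len(nrow(perm))) perm[r, ] <- perm[r, sample.int(ncol(perm))]
    stat(perm)
  }, numeric(1))
  s <- stats::sd(null)
  if (!is.finite(s) || s == 0)
    stop("degenerate presence matrix: permutation null has zero variance")
  list(observed = obs, null_mean = mean(null), null_sd = s,
       z = (obs - mean(null)) / s, n_perm = n_perm)
}

#' Write a recruitment matrix as long-format TSV
#'
#' @param matrix A `recruitment_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recruitment_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
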