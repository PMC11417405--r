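#' Motif comparison p-value to clustering distance
#'
#' `d = max(15 + log10(p), 0)`: comparisons more significant than 1e-15
#' collapse to distance 0 and non-significant comparisons (p = 1) sit at the
#' maximum distance 15.
#'
#' @param p Comparison p-value(s) in (0, 1].
#' @return Distance(s) in `[0, 15]`.
#' @export
motif_distance <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  pmax(15 + log10(p), 0)
}

#' Complete-linkage motif clustering at a cut height
#'
#' Agglomerative clustering in which two clusters merge only while the
#' maximal pairwise distance between their members (complete linkage) does
#' not exceed `cut_height`. Implemented with [stats::hclust()] +
#' [stats::cutree()]. Cluster ids are relabelled deterministically by the
#' lexicographically smallest member id so the partition is invariant to
#' input order.
#'
#' @param dist_matrix Symmetric distance matrix with zero diagonal and
#'   member ids as dimnames.
#' @param cut_height Merge threshold (required; distances above it never
#'   merge).
#' @param names Optional named character vector of human-readable cluster
#'   labels keyed by cluster id.
#' @return A `tf_cluster_set`: list with `clusters` (named list, cluster id
#'   -> member motif ids), `names`, and `motif_to_cluster` (named lookup
#'   vector).
#' @export
complete_linkage <- function(dist_matrix, cut_height, names = NULL) {
  dist_matrix <- as.matrix(dist_matrix)
  if (!isTRUE(all.equal(dist_matrix, t(dist_matrix), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dist_matrix)) > 1e-8))
    stop("distance matrix must have a zero diagonal")
  ids <- rownames(dist_matrix) %||% as.character(seq_len(nrow(dist_matrix)))
  if (nrow(dist_matrix) == 1L) {
    membership <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(dist_matrix), method = "complete")
    membership <- stats::cutree(hc, h = cut_height)
    names(membership) <- ids
  }
  groups <- split(names(membership), membership)
  groups <- groups[order(vapply(groups, min, character(1)))]
  cluster_ids <- sprintf("C%03d", seq_along(groups))
  clusters <- stats::setNames(lapply(groups, sort), cluster_ids)
  tf_cluster_set(clusters, names)
}

#' Construct a TF cluster set
#'
#' @param clusters Named list: cluster id -> character vector of member
#'   motif ids (a partition; members must not repeat across clusters).
#' @param names Optional named labels per cluster id.
#' @return A `tf_cluster_set` object.
#' @export
tf_cluster_set <- function(clusters, names = NULL) {
  members <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(members))
    stop("clusters must partition the motif set (duplicated member)")
  if (any(lengths(clusters) == 0L)) stop("clusters must be non-empty")
  lookup <- stats::setNames(rep(base::names(clusters), lengths(clusters)),
                            members)
  structure(list(clusters = clusters, names = names,
                 motif_to_cluster = lookup),
            class = "tf_cluster_set")
}

#' @export
print.tf_cluster_set <- function(x, ...) {
  cat(sprintf("tf_cluster_set: %d clusters over %d motifs\n",
              length(x$clusters), length(x$motif_to_cluster)))
  invisible(x)
}

#' Cluster containing a motif
#'
#' @param clusters A `tf_cluster_set`.
#' @param id Motif id.
#' @return Cluster id, or `NA` when the motif is not clustered.
#' @export
cluster_of_motif <- function(clusters, id) {
  cl <- clusters$motif_to_cluster[id]
  if (is.na(cl)) NA_character_ else unname(cl)
}

#' Build TF motif clusters from a reference library
#'
#' All-versus-all motif comparison ([compare_to_reference()]); p-values are
#' symmetrised by taking the smaller of the two directed comparisons,
#' converted to distances with [motif_distance()], and clustered with
#' [complete_linkage()].
#'
#' @param refs Named list of reference motifs.
#' @param cut_height Complete-linkage merge threshold (required).
#' @param min_overlap,n_null,seed Passed to [compare_to_reference()].
#' @return A `tf_cluster_set` (with the pairwise distance matrix attached as
#'   attribute `dist`).
#' @export
build_tf_clusters <- function(refs, cut_height, min_overlap = 5,
                              n_null = 10000, seed = 1) {
  ids <- names(refs)
  if (is.null(ids)) stop("reference library must be a named list")
  n <- length(refs)
  pmat <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    res <- compare_to_reference(refs[[i]], refs, min_overlap, n_null,
                                seed + i - 1L)
    pmat[i, res$target_id] <- res$p
  }
  psym <- pmin(pmat, t(pmat))
  dmat <- motif_distance(psym)
  diag(dmat) <- 0
  out <- complete_linkage(dmat, cut_height)
  attr(out, "dist") <- dmat
  out
}

#' Map an external motif onto existing TF clusters
#'
#' Compares the motif to every clustered reference motif and assigns the
#' cluster of the best (lowest raw p) target when that p-value is below
#' `p_cutoff`; otherwise the motif stays unmapped.
#'
#' @param motif A motif object.
#' @param clusterset A `tf_cluster_set`.
#' @param refs Named list of the clustered reference motifs.
#' @param p_cutoff Raw p-value cutoff (default 0.0005).
#' @param min_overlap,n_null,seed Passed to [compare_to_reference()].
#' @return Cluster id, or `NULL` when no target passes the cutoff.
#' @export
map_motif_to_cluster <- function(motif, clusterset, refs, p_cutoff = 0.0005,
                                 min_overlap = 5, n_null = 10000, seed = 1) {
  refs <- refs[names(refs) %in% names(clusterset$motif_to_cluster)]
  if (length(refs) == 0L) stop("no reference motifs overlap the cluster set")
  res <- compare_to_reference(motif, refs, min_overlap, n_null, seed)
  if (nrow(res) == 0L) return(NULL)
  ord <- order(res$p, res$ed, res$target_id)
  best <- res[ord[1L], ]
  if (best$p < p_cutoff) cluster_of_motif(clusterset, best$target_id)
  else NULL
}

#' Write / read TF cluster definitions as TSV
#'
#' Columns: `cluster_id`, `name`, `member`.
#'
#' @param clusters A `tf_cluster_set`.
#' @param path File path.
#' @return `path` (write) or a `tf_cluster_set` (read).
#' @export
write_clusters <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = rep(names(clusters$clusters), lengths(clusters$clusters)),
    name = rep(unname(vapply(names(clusters$clusters), function(id) {
      (clusters$names %||% character(0))[id] %|na|% id
    }, character(1))), lengths(clusters$clusters)),
    member = unlist(clusters$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  clusters <- split(tab$member, tab$cluster_id)
  nm <- tab$name[!duplicated(tab$cluster_id)]
  names(nm) <- tab$cluster_id[!duplicated(tab$cluster_id)]
  tf_cluster_set(clusters, nm)
}
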