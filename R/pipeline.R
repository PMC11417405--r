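#' Default pipeline thresholds
#'
#' The filter and significance thresholds used throughout the analysis,
#' exposed in one place so a run configuration contains no hidden
#' constants: motif strength > 0.4 and windowed IC > 1.0 bits (quality
#' filter), replicate ED < 0.4, across-condition ED < 0.25, adjusted match
#' p < 0.01 with minimum overlap 5, response delta motif strength 1.5,
#' promiscuity > 4 COFs at motif strength > 3, occurrence p floor 1e-5.
#'
#' @return Named list of threshold values.
#' @export
corec_defaults <- function() {
  list(ms_threshold = 0.4, ic_threshold = 1.0, ic_window = 5,
       ed_replicate = 0.4, ed_condition = 0.25, p_adj = 0.01,
       min_overlap = 5, n_null = 10000, n_top = 10,
       delta_ms = 1.5, promiscuity_ms = 3, promiscuity_kats = 4,
       p_floor = 1e-5)
}

#' Run the full recruitment-motif pipeline
#'
#' Orchestrates design loading, quantification, motif construction, quality
#' / replicate / condition filtering, reference matching, cluster
#' assignment, and network assembly from a single configuration, writing
#' all stage outputs plus a JSON manifest (seeds, input checksums, package
#' version) into a run directory.
#'
#' The configuration (a list, or path to a YAML file) understands:
#' \describe{
#'   \item{out_dir}{run directory (required)}
#'   \item{seed}{integer seed for all randomised steps}
#'   \item{design}{directory containing `probes.tsv`
#'     (see [write_design()])}
#'   \item{refs}{MEME-format reference motif library}
#'   \item{clusters}{cluster TSV ([write_clusters()]), or omitted with
#'     `cluster_cut` set to build clusters from `refs`}
#'   \item{cluster_cut}{complete-linkage cut height when building clusters}
#'   \item{experiments}{list of records `fluor` (TSV path), `cof`,
#'     `condition`, `replicate`}
#'   \item{thresholds}{overrides merged over [corec_defaults()]}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return Invisibly, a list with `groups` (assigned replicate groups),
#'   `matrix` (recruitment matrix), `calls` (interaction calls when exactly
#'   two conditions are present), `manifest`.
#' @export
run_corec_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("out_dir", "design", "refs", "experiments")) {
    if (is.null(config[[field]]))
      stop("config is missing required field: ", field)
  }
  thr <- utils::modifyList(corec_defaults(), config$thresholds %||% list())
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- c(design = file.path(config$design, "probes.tsv"),
              refs = config$refs,
              vapply(config$experiments, `[[`, character(1), "fluor"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  design <- read_design(config$design)
  refs <- read_meme(config$refs)
  clusters <- if (!is.null(config$clusters)) {
    read_clusters(config$clusters)
  } else if (!is.null(config$cluster_cut)) {
    build_tf_clusters(refs, config$cluster_cut,
                      min_overlap = thr$min_overlap, n_null = thr$n_null,
                      seed = seed)
  } else stop("config needs either 'clusters' or 'cluster_cut'")

  # quantify every experiment and build quality-passing motifs per
  # (cof, condition, replicate, probeset)
  motifs_by_group <- list()
  for (exp in config$experiments) {
    fl <- read_fluor(exp$fluor, cof = exp$cof, condition = exp$condition,
                     replicate = exp$replicate %||% 1L)
    z <- corec_quantify(fl, design)
    write_z_profile(z, file.path(out_dir, sprintf("z_%s_%s_r%s.tsv",
                                                  exp$cof, exp$condition,
                                                  exp$replicate %||% 1L)))
    for (pid in names(design$probesets)) {
      m <- build_corec_motif(z, design$probesets[[pid]], thr$n_top)
      if (!quality_filter(m, thr$ms_threshold, thr$ic_threshold,
                          thr$ic_window)$pass) next
      key <- paste(exp$cof, exp$condition, pid, sep = "|")
      motifs_by_group[[key]] <- c(motifs_by_group[[key]], list(m))
    }
  }

  # replicate filter, reference matching, cluster assignment
  groups <- list()
  i <- 0L
  for (key in names(motifs_by_group)) {
    g <- replicate_filter(motifs_by_group[[key]], thr$ed_replicate)
    if (!g$replicated) next
    matches <- lapply(seq_along(g$members), function(j) {
      compare_to_reference(g$members[[j]], refs, thr$min_overlap,
                           thr$n_null, seed + j, thr$p_adj)
    })
    g <- assign_cluster(g, matches, clusters)
    i <- i + 1L
    groups[[key]] <- g
  }

  mat <- build_matrix(groups)
  write_recruitment_matrix(mat, file.path(out_dir,
                                          "recruitment_matrix.tsv"))
  meme_out <- file.path(out_dir, "corec_motifs.meme")
  write_meme(unlist(lapply(groups, `[[`, "members"), recursive = FALSE),
             meme_out)

  conds <- sort(unique(mat$condition))
  calls <- NULL
  if (length(conds) == 2L) {
    flags <- condition_flags(groups, mat, conds, thr$ed_condition)
    calls <- call_condition_status(mat, conds, flags)
    utils::write.table(as.data.frame(calls),
                       file.path(out_dir, "interaction_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "corec",
                   version = as.character(utils::packageVersion("corec")),
                   seed = seed, thresholds = thr,
                   conditions = conds,
                   n_groups = length(groups),
                   inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(groups = groups, matrix = mat, calls = calls,
                 clusters = clusters, manifest = manifest))
}

# across-condition conservation flags for every (cof, cluster) present in
# both conditions: conserved when any probe set contributing to the cell
# has cross-condition replicate groups with a member pair at ED < threshold
condition_flags <- function(groups, mat, conds, threshold = 0.25) {
  flags <- logical(0)
  cells <- unique(mat[, c("cof", "cluster")])
  for (i in seq_len(nrow(cells))) {
    cof <- cells$cof[i]; cl <- cells$cluster[i]
    in1 <- mat$condition == conds[1] & mat$cof == cof & mat$cluster == cl
    in2 <- mat$condition == conds[2] & mat$cof == cof & mat$cluster == cl
    if (!any(in1) || !any(in2)) next
    ps1 <- strsplit(mat$probesets[in1], ",")[[1]]
    ps2 <- strsplit(mat$probesets[in2], ",")[[1]]
    ok <- FALSE
    for (pid in intersect(ps1, ps2)) {
      g1 <- groups[[paste(cof, conds[1], pid, sep = "|")]]
      g2 <- groups[[paste(cof, conds[2], pid, sep = "|")]]
      if (!is.null(g1) && !is.null(g2) &&
          condition_conserved(g1, g2, threshold)) { ok <- TRUE; break }
    }
    flags[paste(cof, cl, sep = "|")] <- ok
  }
  flags
}
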