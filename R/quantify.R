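#' Read a probe-level fluorescence table
#'
#' Expects a TSV with header and columns `probe_id`, `spot`, `channel`,
#' `fluorescence` (linear units, strictly positive). Experiment metadata
#' (cofactor, condition, array replicate) can be attached as attributes.
#'
#' @param path TSV file path.
#' @param cof,condition,replicate Optional experiment metadata.
#' @return A `fluor_table` data frame with a `meta` attribute.
#' @export
read_fluor <- function(path, cof = NA_character_, condition = NA_character_,
                       replicate = NA_integer_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "spot", "channel", "fluorescence")
  if (!all(need %in% names(tab)))
    stop("fluorescence table must have columns: ", paste(need, collapse = ", "))
  fluor_table(tab, cof, condition, replicate)
}

#' Construct a fluorescence table from a data frame
#'
#' @param tab Data frame with columns `probe_id`, `spot`, `channel`,
#'   `fluorescence`.
#' @param cof,condition,replicate Experiment metadata.
#' @return A `fluor_table` data frame.
#' @export
fluor_table <- function(tab, cof = NA_character_, condition = NA_character_,
                        replicate = NA_integer_) {
  if (any(!is.finite(tab$fluorescence)) || any(tab$fluorescence <= 0))
    stop("fluorescence values must be finite and > 0")
  structure(tab,
            meta = list(cof = cof, condition = condition,
                        replicate = replicate),
            class = c("fluor_table", "data.frame"))
}

#' Aggregate replicate spots to probe-level log fluorescence
#'
#' Per probe, the median fluorescence over replicate spots is taken and
#' natural-log transformed. Probes with fewer spots than expected are kept
#' (median over what is available) with a warning.
#'
#' @param table A `fluor_table` (or compatible data frame).
#' @param expected_spots Spots expected per probe (default 5); `NULL` skips
#'   the completeness warning.
#' @return Data frame with columns `probe_id` and `log_f`; metadata carried
#'   through in the `meta` attribute.
#' @export
aggregate_spots <- function(table, expected_spots = 5) {
  if (any(table$fluorescence <= 0)) stop("nonpositive fluorescence")
  med <- tapply(table$fluorescence, table$probe_id, stats::median)
  if (!is.null(expected_spots)) {
    nspots <- tapply(table$fluorescence, table$probe_id, length)
    short <- names(nspots)[nspots < expected_spots]
    if (length(short))
      warning(length(short), " probe(s) have fewer than ", expected_spots,
              " spots (e.g. ", short[1], "); median over available spots")
  }
  out <- data.frame(probe_id = names(med), log_f = log(as.numeric(med)),
                    stringsAsFactors = FALSE)
  attr(out, "meta") <- attr(table, "meta")
  out
}

#' Background fluorescence statistics
#'
#' Mean and sample standard deviation of the log fluorescence of background
#' probes, used to standardise every probe on the same array.
#'
#' @param log_f Probe-level log fluorescence ([aggregate_spots()] output).
#' @param design The `array_design`, used to identify background probes.
#' @return List with `mu_bg`, `sigma_bg`, `n_bg`.
#' @export
background_stats <- function(log_f, design) {
  bg_ids <- design$probes$probe_id[design$probes$category == "background"]
  f <- log_f$log_f[log_f$probe_id %in% bg_ids]
  if (length(f) < 2L) stop("need at least 2 background probes (got ",
                           length(f), ")")
  s <- stats::sd(f)
  if (s <= 0) stop("background fluorescence has zero variance")
  list(mu_bg = mean(f), sigma_bg = s, n_bg = length(f))
}

#' Recruitment z-scores
#'
#' z = (f - mu_bg) / sigma_bg for every probe, where f is the probe's log
#' fluorescence and mu_bg, sigma_bg describe the background probes of the
#' same array.
#'
#' @param log_f Probe-level log fluorescence.
#' @param bg [background_stats()] output.
#' @return A `z_profile` data frame with columns `probe_id`, `log_f`, `z`.
#' @export
compute_z <- function(log_f, bg) {
  stopifnot(is.finite(bg$mu_bg), bg$sigma_bg > 0)
  out <- data.frame(probe_id = log_f$probe_id, log_f = log_f$log_f,
                    z = (log_f$log_f - bg$mu_bg) / bg$sigma_bg,
                    stringsAsFactors = FALSE)
  structure(out, meta = attr(log_f, "meta"), bg = bg,
            class = c("z_profile", "data.frame"))
}

#' Fluorescence table to z-profile in one step
#'
#' @param table A `fluor_table`.
#' @param design The `array_design`.
#' @param expected_spots Spots expected per probe.
#' @return A `z_profile` data frame.
#' @export
corec_quantify <- function(table, design,
                           expected_spots = design$replicate_spots) {
  log_f <- aggregate_spots(table, expected_spots)
  compute_z(log_f, background_stats(log_f, design))
}

#' Write / read a z-profile TSV
#'
#' @param z A `z_profile`.
#' @param path File path.
#' @return `path` (write) or a `z_profile` (read).
#' @export
write_z_profile <- function(z, path) {
  utils::write.table(as.data.frame(z), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_z_profile
#' @export
read_z_profile <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  structure(tab, class = c("z_profile", "data.frame"))
}
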