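#' Reference motif container
#'
#' A reference motif is a position probability matrix (PPM) over the DNA
#' alphabet, with per-position base probabilities in A, C, G, T column order.
#'
#' @param id Motif identifier (unique within a library).
#' @param matrix Numeric `L x 4` matrix of base probabilities; rows must sum
#'   to 1 (tolerance 1e-6) and entries lie in `[0, 1]`.
#' @param name Human-readable motif name; defaults to `id`.
#' @return An object of class `ref_motif`: a list with elements `id`, `name`
#'   and `matrix` (columns named A, C, G, T).
#' @export
ref_motif <- function(id, matrix, name = id) {
  matrix <- validate_ppm_matrix(matrix)
  structure(list(id = as.character(id), name = as.character(name),
                 matrix = matrix),
            class = "ref_motif")
}

#' @export
print.ref_motif <- function(x, ...) {
  cat(sprintf("ref_motif %s (%s), length %d\n", x$id, x$name, nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Validate a position probability matrix
#'
#' @param matrix Numeric `L x 4` matrix.
#' @param tol Row-sum tolerance.
#' @return The matrix with columns named A, C, G, T, invisibly validated.
#' @export
validate_ppm_matrix <- function(matrix, tol = 1e-6) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L)
    stop("PPM must have 4 columns (A, C, G, T)")
  if (nrow(matrix) < 1L)
    stop("PPM must have at least one row")
  if (any(!is.finite(matrix)) || any(matrix < -tol) || any(matrix > 1 + tol))
    stop("PPM entries must lie in [0, 1]")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("PPM rows must sum to 1 (worst deviation %.3g)",
                 max(abs(rs - 1))))
  colnames(matrix) <- DNA_BASES
  rownames(matrix) <- NULL
  matrix
}

# pull the probability matrix out of whatever motif-ish object we were given
ppm_matrix <- function(x) {
  if (is.matrix(x)) return(validate_ppm_matrix(x))
  if (inherits(x, c("ref_motif", "corec_ppm"))) return(x$matrix)
  if (is.list(x) && !is.null(x$matrix)) return(x$matrix)
  stop("cannot extract a probability matrix from object of class ",
       paste(class(x), collapse = "/"))
}

motif_id <- function(x, default = "motif") {
  if (is.list(x) && !is.null(x$id)) x$id else default
}

#' Reverse-complement a probability matrix
#'
#' Column order is reversed and bases are complemented (A<->T, C<->G).
#'
#' @param matrix `L x 4` probability matrix in A, C, G, T order.
#' @return The reverse-complement matrix.
#' @export
revcomp_ppm <- function(matrix) {
  m <- matrix[rev(seq_len(nrow(matrix))), COMP_IDX, drop = FALSE]
  colnames(m) <- DNA_BASES
  rownames(m) <- NULL
  m
}

#' Read motifs in MEME minimal format
#'
#' Parses the minimal MEME motif text format: a `MEME version` header,
#' optional `ALPHABET`/`strands`/background lines, then blocks of
#' `MOTIF id name` followed by a `letter-probability matrix:` line and `w`
#' rows of 4 probabilities.
#'
#' @param path Path to a MEME-format text file.
#' @return A named list of [ref_motif()] objects (names are motif ids).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (length(motif_at) == 0L)
    stop("no MOTIF records found in ", path)
  out <- list()
  for (start in motif_at) {
    hdr <- strsplit(trimws(lines[start]), "\\s+")[[1]]
    id <- hdr[2]
    name <- if (length(hdr) >= 3) paste(hdr[-(1:2)], collapse = " ") else id
    lp <- start
    repeat {
      lp <- lp + 1L
      if (lp > length(lines)) stop("motif ", id, ": no probability matrix")
      if (grepl("^letter-probability matrix", lines[lp])) break
      if (grepl("^MOTIF\\s+", lines[lp]))
        stop("motif ", id, ": no probability matrix")
    }
    w <- NA_integer_
    wm <- regmatches(lines[lp], regexec("w=\\s*([0-9]+)", lines[lp]))[[1]]
    if (length(wm) == 2) w <- as.integer(wm[2])
    rows <- list()
    i <- lp
    while (length(rows) < (if (is.na(w)) Inf else w)) {
      i <- i + 1L
      if (i > length(lines)) break
      tl <- trimws(lines[i])
      if (tl == "" || grepl("^(MOTIF|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (length(vals) != 4 || any(is.na(vals))) break
      rows[[length(rows) + 1L]] <- vals
    }
    if (length(rows) == 0L) stop("motif ", id, ": empty probability matrix")
    mat <- do.call(rbind, rows)
    # renormalise tiny rounding slack typical of printed MEME files
    mat <- mat / rowSums(mat)
    out[[id]] <- ref_motif(id, mat, name)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' CoRec recruitment motifs ([build_corec_motif()]) are written with their
#' motif strength and beta recorded on the MOTIF name line as
#' `MS=<ms>;beta=<beta>`.
#'
#' @param motifs A list of [ref_motif()] or `corec_ppm` objects (or a single
#'   one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, c("ref_motif", "corec_ppm"))) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    mat <- ppm_matrix(m)
    name <- if (inherits(m, "corec_ppm")) {
      sprintf("MS=%.6g;beta=%.6g", m$ms, m$beta)
    } else m$name %||% motif_id(m)
    writeLines(sprintf("MOTIF %s %s", motif_id(m), name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(mat)), con)
    writeLines(apply(mat, 1L, function(r) paste(sprintf("%.6f", r),
                                                collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs in JASPAR PFM text format
#'
#' Parses the JASPAR position frequency matrix format: `>ID name` headers
#' followed by four lines `A [ 1 2 3 ]` (brackets optional), one per base.
#' Counts are converted to probabilities by column normalisation.
#'
#' @param path Path to a JASPAR PFM text file.
#' @param pseudocount Added to every count before normalisation (default 0).
#' @return A named list of [ref_motif()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0) {
  lines <- readLines(path, warn = FALSE)
  hdr_at <- grep("^>", lines)
  if (length(hdr_at) == 0L) stop("no JASPAR records found in ", path)
  out <- list()
  for (h in seq_along(hdr_at)) {
    start <- hdr_at[h]
    end <- if (h < length(hdr_at)) hdr_at[h + 1] - 1L else length(lines)
    hdr <- strsplit(sub("^>\\s*", "", lines[start]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) >= 2) paste(hdr[-1], collapse = " ") else id
    block <- lines[(start + 1L):end]
    block <- block[trimws(block) != ""]
    if (length(block) < 4L) stop("motif ", id, ": expected 4 base rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    })
    if (length(unique(lengths(rows))) != 1L || anyNA(unlist(rows)))
      stop("motif ", id, ": malformed count rows")
    counts <- t(do.call(rbind, rows)) + pseudocount  # L x 4, rows A C G T
    mat <- counts / rowSums(counts)
    out[[id]] <- ref_motif(id, mat, name)
  }
  out
}
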