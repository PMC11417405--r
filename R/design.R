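#' Collapse a reference motif to its consensus site
#'
#' Takes the maximal-probability base at every position. Ties are broken
#' deterministically in A < C < G < T order so that repeated runs over the
#' same library always produce the same design.
#'
#' @param motif A [ref_motif()] or bare `L x 4` probability matrix.
#' @return A `consensus_site` object: list with `source_motif_id` and
#'   `sequence` (character, alphabet ACGT, length = motif length).
#' @export
consensus_from_ppm <- function(motif) {
  mat <- ppm_matrix(motif)
  seq <- paste(DNA_BASES[max.col(mat, ties.method = "first")], collapse = "")
  structure(list(source_motif_id = motif_id(motif), sequence = seq),
            class = "consensus_site")
}

site_sequence <- function(x) {
  if (inherits(x, "consensus_site")) x$sequence else as.character(x)
}

# best ungapped alignment identity between two sequences: matches divided by
# the shorter length, maximised over all offsets with >= 1 overlapping base
# (both strands optionally)
ungapped_identity <- function(a, b, both_strands = FALSE) {
  one_strand <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    la <- length(av); lb <- length(bv)
    best <- 0
    for (off in seq(-(la - 1L), lb - 1L)) {
      ia <- max(1L, 1L - off):min(la, lb - off)
      ib <- ia + off
      m <- sum(av[ia] == bv[ib])
      best <- max(best, m / min(la, lb))
    }
    best
  }
  best <- one_strand(a, b)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    best <- max(best, one_strand(a, rc))
  }
  best
}

#' Filter consensus sites for equivalence
#'
#' Greedy, order-preserving dedup of consensus sites: the first occurrence is
#' retained and a later candidate is dropped when, against any retained site,
#' both its best ungapped alignment identity (matches / shorter length) and
#' its shorter/longer length ratio exceed `identity_cutoff`. The length
#' condition keeps composite sites (e.g. a dimer half-site plus a full site)
#' distinct even when the shorter one aligns perfectly inside the longer.
#'
#' @param sites List of `consensus_site` objects or character vector.
#' @param identity_cutoff Retain unless both identity and length ratio are
#'   strictly greater than this (default 0.9).
#' @param both_strands Also consider the reverse-complement alignment
#'   (default `FALSE`).
#' @return The retained subset of `sites`, in input order.
#' @export
filter_equivalent <- function(sites, identity_cutoff = 0.9,
                              both_strands = FALSE) {
  if (length(sites) < 1L) stop("need at least one site")
  seqs <- vapply(sites, site_sequence, character(1))
  keep <- logical(length(sites))
  for (i in seq_along(sites)) {
    dup <- FALSE
    for (j in which(keep)) {
      lr <- min(nchar(seqs[i]), nchar(seqs[j])) /
        max(nchar(seqs[i]), nchar(seqs[j]))
      if (lr > identity_cutoff &&
          ungapped_identity(seqs[i], seqs[j], both_strands) > identity_cutoff) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  sites[keep]
}

#' Enumerate the consensus + single-variant probe set for a site
#'
#' For a consensus site of length `L`, the probe set holds the consensus
#' probe plus all `3L` single-nucleotide-variant (SV) probes, each differing
#' from the consensus at exactly one position.
#'
#' @param site A `consensus_site` or character sequence (length 1..34).
#' @param probeset_id Identifier for the probe set; defaults to the source
#'   motif id or the sequence itself.
#' @return A `probe_set` object: list with `probeset_id`, `consensus`, and a
#'   data frame `probes` with columns `probe_id`, `category`
#'   (consensus / sv), `sv_position`, `sv_base`, `site_seq` (3L + 1 rows).
#' @export
enumerate_sv_probes <- function(site, probeset_id = NULL) {
  seq <- site_sequence(site)
  L <- nchar(seq)
  if (L < 1L || L > 34L)
    stop("site length must be between 1 and 34 nt (got ", L, ")")
  if (grepl("[^ACGT]", seq)) stop("site alphabet must be ACGT")
  if (is.null(probeset_id)) {
    probeset_id <- if (inherits(site, "consensus_site") &&
                       nzchar(site$source_motif_id)) {
      site$source_motif_id
    } else seq
  }
  chars <- strsplit(seq, "")[[1]]
  recs <- list(data.frame(probe_id = paste0(probeset_id, "_cons"),
                          category = "consensus",
                          sv_position = NA_integer_, sv_base = NA_character_,
                          site_seq = seq, stringsAsFactors = FALSE))
  for (i in seq_len(L)) {
    for (b in setdiff(DNA_BASES, chars[i])) {
      v <- chars
      v[i] <- b
      recs[[length(recs) + 1L]] <- data.frame(
        probe_id = sprintf("%s_sv%02d%s", probeset_id, i, b),
        category = "sv", sv_position = i, sv_base = b,
        site_seq = paste(v, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  structure(list(probeset_id = probeset_id, consensus = seq,
                 probes = do.call(rbind, recs)),
            class = "probe_set")
}

#' Assemble a 60-nt microarray probe
#'
#' Probe architecture: 2-nt `GC` cap + 34-nt binding-site window + 24-nt
#' common primer. Sites shorter than 34 nt are centred in the window and
#' padded symmetrically with a fixed neutral flank (default a repeating
#' `TA` pattern; for odd padding the extra base goes 3' of the site). The
#' flank depends only on the site length, so all probes of a probe set share
#' identical sequence outside the variable site.
#'
#' @param site Character site sequence, at most 34 nt.
#' @param primer 24-nt common primer sequence.
#' @param flank_pattern Repeating pattern used to pad short sites.
#' @return The 60-nt probe sequence.
#' @export
assemble_probe <- function(site, primer, flank_pattern = "TA") {
  site <- site_sequence(site)
  L <- nchar(site)
  if (L > 34L) stop("site longer than the 34-nt window (", L, " nt)")
  if (nchar(primer) != 24L) stop("primer must be exactly 24 nt")
  paste0("GC", pad_site34(site, flank_pattern), primer)
}

# centre a site in the 34-nt window; extra pad base goes 3'
pad_site34 <- function(site, flank_pattern = "TA") {
  L <- nchar(site)
  pad <- 34L - L
  left <- pad %/% 2L
  right <- pad - left
  tmpl <- strrep(flank_pattern, ceiling(34 / nchar(flank_pattern)))
  paste0(substr(tmpl, 1L, left), site, substr(tmpl, 1L, right))
}

#' Sample background probes from a genome
#'
#' Draws `n` distinct 34-nt windows uniformly over all valid positions of the
#' supplied genome (windows containing non-ACGT characters are rejected) and
#' assembles them into 60-nt probes. Deterministic for a given seed.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param n Number of background probes (default 261).
#' @param seed Integer RNG seed.
#' @param primer 24-nt common primer.
#' @return Data frame with columns `probe_id`, `category` ("background"),
#'   `sv_position`, `sv_base` (NA), `site_seq` (34 nt), `full_sequence`
#'   (60 nt), `contig`, `start` (1-based window start).
#' @export
sample_background_probes <- function(genome, n = 261, seed = 1,
                                     primer = default_primer()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  widths <- Biostrings::width(genome)
  if (all(widths < 34L)) stop("no genome contig is at least 34 nt")
  nwin <- pmax(widths - 34L + 1L, 0L)
  if (n == 0L) {
    return(data.frame(probe_id = character(0), category = character(0),
                      sv_position = integer(0), sv_base = character(0),
                      site_seq = character(0), full_sequence = character(0),
                      contig = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (sum(nwin) < n)
    stop("genome too short: ", sum(nwin), " candidate windows for ", n,
         " probes")
  set.seed(seed)
  chosen <- integer(0)
  tries <- 0L
  while (length(chosen) < n) {
    tries <- tries + 1L
    if (tries > 50L) stop("could not find ", n, " valid background windows")
    cand <- sample.int(sum(nwin), min(sum(nwin), 4L * n))
    cand <- setdiff(unique(c(chosen, cand)), integer(0))
    # map flat index -> (contig, start) and keep ACGT-only windows
    cum <- cumsum(nwin)
    ci <- findInterval(cand - 1L, c(0L, cum), rightmost.closed = FALSE)
    st <- cand - c(0L, cum)[ci]
    sq <- as.character(Biostrings::subseq(genome[ci], start = st,
                                          width = 34L))
    ok <- !grepl("[^ACGT]", sq)
    chosen <- utils::head(cand[ok], n)
  }
  cum <- cumsum(nwin)
  ci <- findInterval(chosen - 1L, c(0L, cum), rightmost.closed = FALSE)
  st <- chosen - c(0L, cum)[ci]
  sq <- as.character(Biostrings::subseq(genome[ci], start = st, width = 34L))
  data.frame(probe_id = sprintf("bg_%04d", seq_len(n)),
             category = "background",
             sv_position = NA_integer_, sv_base = NA_character_,
             site_seq = sq,
             full_sequence = paste0("GC", sq, primer),
             contig = names(genome)[ci] %||% as.character(ci),
             start = st, stringsAsFactors = FALSE)
}

#' Default common primer sequence
#'
#' A fixed 24-nt primer used when none is supplied; real designs should pass
#' their own.
#' @return A 24-nt character string.
#' @export
default_primer <- function() "GTCTTGATTCGCTTGACGCTGCTG"

#' Build a CoRec array design
#'
#' Full design pipeline: collapse reference motifs to consensus sites, filter
#' near-equivalent sites, enumerate consensus + SV probe sets, assemble 60-nt
#' probes, and sample background probes.
#'
#' @param motifs Named list of [ref_motif()] objects.
#' @param primer 24-nt common primer.
#' @param background_genome Optional [Biostrings::DNAStringSet] or FASTA path
#'   from which background probes are sampled.
#' @param n_background Number of background probes (default 261).
#' @param seed RNG seed for background sampling.
#' @param identity_cutoff Equivalence-filter cutoff (default 0.9).
#' @param replicate_spots Spots printed per probe (default 5).
#' @param flank_pattern Neutral flank pattern for sub-34-nt sites.
#' @return An `array_design` object: list with `probes` (one row per probe:
#'   `probe_id`, `probeset_id`, `category`, `sv_position`, `sv_base`,
#'   `site34`, `full_sequence`), `probesets` (list of `probe_set`),
#'   `replicate_spots`, and `primer`.
#' @export
build_array_design <- function(motifs, primer = default_primer(),
                               background_genome = NULL, n_background = 261,
                               seed = 1, identity_cutoff = 0.9,
                               replicate_spots = 5,
                               flank_pattern = "TA") {
  sites <- lapply(motifs, consensus_from_ppm)
  sites <- filter_equivalent(sites, identity_cutoff)
  psets <- lapply(sites, enumerate_sv_probes)
  names(psets) <- vapply(psets, `[[`, character(1), "probeset_id")
  probe_tab <- do.call(rbind, lapply(psets, function(ps) {
    data.frame(probe_id = ps$probes$probe_id,
               probeset_id = ps$probeset_id,
               category = ps$probes$category,
               sv_position = ps$probes$sv_position,
               sv_base = ps$probes$sv_base,
               site34 = vapply(ps$probes$site_seq, pad_site34, character(1),
                               flank_pattern, USE.NAMES = FALSE),
               full_sequence = vapply(ps$probes$site_seq, assemble_probe,
                                      character(1), primer, flank_pattern,
                                      USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(background_genome) && n_background > 0) {
    bg <- sample_background_probes(background_genome, n_background, seed,
                                   primer)
    bg$probeset_id <- "background"
    probe_tab <- rbind(probe_tab,
                       bg[, c("probe_id", "probeset_id", "category",
                              "sv_position", "sv_base", "site_seq",
                              "full_sequence")] |>
                         (\(d) {names(d)[names(d) == "site_seq"] <- "site34"; d})())
  }
  rownames(probe_tab) <- NULL
  if (anyDuplicated(probe_tab$probe_id))
    stop("duplicate probe ids in design")
  structure(list(probes = probe_tab, probesets = psets,
                 replicate_spots = replicate_spots, primer = primer),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf(
    "array_design: %d probe sets, %d probes (%d background), %d spots/probe\n",
    length(x$probesets), nrow(x$probes),
    sum(x$probes$category == "background"), x$replicate_spots))
  invisible(x)
}

#' Write an array design to disk
#'
#' Writes `probes.tsv` (one probe per row) and `probes.fasta` (full 60-nt
#' sequences) into `dir`.
#'
#' @param design An `array_design`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(design$probes, file.path(dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(design$probes$full_sequence)
  names(seqs) <- design$probes$probe_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "probes.fasta"))
  invisible(dir)
}

#' Read an array design written by [write_design()]
#'
#' @param dir Directory containing `probes.tsv`.
#' @param replicate_spots Spots per probe recorded in the design.
#' @return An `array_design` object (probe sets reconstructed from the
#'   table).
#' @export
read_design <- function(dir, replicate_spots = 5) {
  tab <- utils::read.table(file.path(dir, "probes.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(sv_position = "integer"))
  psets <- list()
  for (pid in unique(tab$probeset_id[tab$category != "background"])) {
    sub <- tab[tab$probeset_id == pid, ]
    # recover the un-padded site from the SV positions (1..L); padding is
    # centred, so the site occupies window positions left+1 .. left+L
    L <- max(sub$sv_position, na.rm = TRUE)
    left <- (34L - L) %/% 2L
    psets[[pid]] <- structure(
      list(probeset_id = pid,
           consensus = substr(sub$site34[sub$category == "consensus"],
                              left + 1L, left + L),
           probes = data.frame(probe_id = sub$probe_id,
                               category = sub$category,
                               sv_position = sub$sv_position,
                               sv_base = sub$sv_base,
                               site_seq = substr(sub$site34, left + 1L,
                                                 left + L),
                               stringsAsFactors = FALSE)),
      class = "probe_set")
  }
  primer <- substr(tab$full_sequence[1], 37L, 60L)
  structure(list(probes = tab, probesets = psets,
                 replicate_spots = replicate_spots, primer = primer),
            class = "array_design")
}
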