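#' Log-odds PWM model with an exact p-value table
#'
#' Converts a probability matrix to log2 odds against a uniform 0.25
#' background with a fractional pseudocount:
#' `log2((P + pc * 0.25) / (1 + pc) / 0.25)`. Column scores are discretised
#' to integers at `granularity`, and the exact distribution of the total
#' score of a single window under an i.i.d. uniform background is computed
#' by dynamic-programming convolution, giving exact tail p-values for any
#' attainable score.
#'
#' @param ppm A motif object or `L x 4` probability matrix.
#' @param pseudocount Fractional pseudocount (default 0.01).
#' @param granularity Score discretisation step (default 1e-3).
#' @return A `pwm_model`: list with `id`, `lo` (log-odds matrix), `S`
#'   (integer scores), `granularity`, `min_total`, `tail` (tail probability
#'   indexed from `min_total`).
#' @export
logodds_from_ppm <- function(ppm, pseudocount = 0.01, granularity = 1e-3) {
  P <- ppm_matrix(ppm)
  # probabilities floored at 1e-12 so a zero cell with zero pseudocount
  # yields a very negative, finite score instead of -Inf
  lo <- log2(pmax((P + pseudocount * 0.25) / (1 + pseudocount), 1e-12) /
               0.25)
  S <- round(lo / granularity)
  storage.mode(S) <- "integer"
  # DP over positions: distribution of the window score, uniform base model
  mins <- apply(S, 1L, min)
  dist <- 1
  cur_min <- 0L
  for (i in seq_len(nrow(S))) {
    span <- max(S[i, ]) - mins[i]
    new <- numeric(length(dist) + span)
    for (k in 1:4) {
      sh <- S[i, k] - mins[i]
      idx <- (1L + sh):(length(dist) + sh)
      new[idx] <- new[idx] + 0.25 * dist
    }
    dist <- new
    cur_min <- cur_min + mins[i]
  }
  tail <- rev(cumsum(rev(dist)))
  structure(list(id = motif_id(ppm), lo = lo, S = S,
                 granularity = granularity, min_total = cur_min,
                 tail = tail),
            class = "pwm_model")
}

as_pwm_model <- function(x, ...) {
  if (inherits(x, "pwm_model")) x else logodds_from_ppm(x, ...)
}

# exact P(window score >= s_int) for integer score(s)
pwm_tail_p <- function(model, s_int) {
  idx <- s_int - model$min_total + 1L
  idx <- pmin(pmax(idx, 1L), length(model$tail) + 1L)
  c(model$tail, 0)[idx]
}

# integer window scores of a PWM over a coded sequence (codes 1..4, NA for
# non-ACGT); non-ACGT positions take the worst (minimum) column score
window_scores <- function(codes, S) {
  L <- nrow(S)
  n <- length(codes) - L + 1L
  if (n < 1L) return(integer(0))
  Sx <- cbind(S, apply(S, 1L, min))  # 5th column: worst base, used for N
  codes[is.na(codes)] <- 5L
  sc <- integer(n)
  for (i in seq_len(L)) sc <- sc + unname(Sx[i, codes[i:(i + n - 1L)]])
  sc
}

encode_dna <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
}

# scores of all windows on both strands: list(fwd, rev) integer vectors,
# index = window start on the forward strand
scan_both_strands <- function(seq, model) {
  codes <- encode_dna(seq)
  Src <- model$S[rev(seq_len(nrow(model$S))), COMP_IDX, drop = FALSE]
  list(fwd = window_scores(codes, model$S),
       rev = window_scores(codes, Src))
}

#' Best motif occurrence in a sequence
#'
#' Slides the PWM over both strands and returns the single best-scoring
#' window with its exact single-window p-value (tail probability of the
#' score under an i.i.d. uniform background). Ties prefer the forward
#' strand, then the leftmost position. Non-ACGT bases score as the worst
#' base of the column.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param pwm A `pwm_model` (or a motif, converted with defaults).
#' @return List with `score` (log2 odds, discretised), `position` (1-based
#'   window start on the forward strand), `strand`, `p`.
#' @export
best_occurrence <- function(seq, pwm) {
  model <- as_pwm_model(pwm)
  sc <- scan_both_strands(seq, model)
  if (length(sc$fwd) == 0L)
    stop("sequence shorter than the motif (", nrow(model$S), " nt)")
  bf <- which.max(sc$fwd)
  br <- which.max(sc$rev)
  if (sc$fwd[bf] >= sc$rev[br]) {
    best <- list(score_int = sc$fwd[bf], position = bf, strand = "+")
  } else {
    best <- list(score_int = sc$rev[br], position = br, strand = "-")
  }
  list(score = best$score_int * model$granularity,
       position = best$position, strand = best$strand,
       p = pwm_tail_p(model, best$score_int))
}

#' Motif score of a genomic region
#'
#' `-log10(p)` of the single best occurrence ([best_occurrence()]), or 0
#' when no occurrence reaches `p <= p_floor`.
#'
#' @param seq Region sequence.
#' @param pwm A `pwm_model` or motif.
#' @param p_floor Occurrence p-value floor (default 1e-5).
#' @return Non-negative region score.
#' @export
region_score <- function(seq, pwm, p_floor = 1e-5) {
  b <- best_occurrence(seq, pwm)
  if (b$p <= p_floor) -log10(b$p) else 0
}

#' Motif-cluster score of a region
#'
#' All motifs of a TF cluster are scored and the maximum region score is
#' used, so a cluster hit is whichever member motif matches best.
#'
#' @param seq Region sequence.
#' @param motifs List of `pwm_model`s or motifs (cluster members).
#' @param p_floor Occurrence p-value floor.
#' @return Maximum member region score.
#' @export
cluster_score <- function(seq, motifs, p_floor = 1e-5) {
  if (length(motifs) == 0L) stop("cluster has no motifs")
  max(vapply(motifs, function(m) region_score(seq, m, p_floor), numeric(1)))
}

#' Count non-overlapping motif occurrences
#'
#' Greedy left-to-right count of non-overlapping windows (either strand)
#' with occurrence p-value at or below `p_floor`.
#'
#' @param seq Region sequence.
#' @param pwm A `pwm_model` or motif.
#' @param p_floor Occurrence p-value floor (default 1e-5).
#' @return Integer site count.
#' @export
count_sites <- function(seq, pwm, p_floor = 1e-5) {
  model <- as_pwm_model(pwm)
  sc <- scan_both_strands(seq, model)
  if (length(sc$fwd) == 0L) return(0L)
  best <- pmax(sc$fwd, sc$rev)
  hit <- pwm_tail_p(model, best) <= p_floor
  L <- nrow(model$S)
  n <- 0L
  next_free <- 1L
  for (i in which(hit)) {
    if (i >= next_free) {
      n <- n + 1L
      next_free <- i + L
    }
  }
  n
}

#' Define strand-aware promoter windows around TSSs
#'
#' The promoter is the region from `up` bp upstream to `down` bp downstream
#' of the transcription start site, strand-aware, in 0-based half-open
#' coordinates: `[tss - up, tss + down)` on `+` and `[tss - down, tss + up)`
#' on `-`. Only the first TSS per gene is used; windows are clipped to
#' contig bounds with a warning.
#'
#' @param tss Data frame with columns `gene`, `contig`, `tss` (0-based
#'   position), `strand` (`+`/`-`).
#' @param up,down Upstream / downstream extents (defaults 500 / 100).
#' @param contig_lengths Optional named vector of contig lengths for
#'   clipping.
#' @return Data frame `gene`, `contig`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @export
define_promoters <- function(tss, up = 500, down = 100,
                             contig_lengths = NULL) {
  tss <- tss[!duplicated(tss$gene), ]
  if (any(!tss$strand %in% c("+", "-")))
    stop("unknown strand for gene(s): ",
         paste(tss$gene[!tss$strand %in% c("+", "-")], collapse = ", "))
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$tss - up, tss$tss - down)
  end <- ifelse(plus, tss$tss + down, tss$tss + up)
  clipped <- start < 0
  start <- pmax(start, 0)
  if (!is.null(contig_lengths)) {
    lim <- unname(contig_lengths[tss$contig])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  if (any(clipped))
    warning(sum(clipped), " promoter window(s) clipped at contig bounds")
  data.frame(gene = tss$gene, contig = tss$contig, start = start,
             end = end, strand = tss$strand, stringsAsFactors = FALSE)
}

# 0-based half-open interval data frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$contig,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Promoter acetylation levels from peak overlaps
#'
#' Each promoter's acetylation level is the maximum score (-log10 p) of any
#' overlapping H3K27ac peak (>= 1 bp overlap). Promoters without an H3K27ac
#' peak but overlapping an ATAC (open-chromatin) peak are scored 0;
#' promoters overlapping neither are dropped.
#'
#' @param promoters [define_promoters()] output.
#' @param h3k27ac Data frame `contig`, `start`, `end`, `score` (0-based
#'   half-open; score = -log10 p).
#' @param atac Data frame `contig`, `start`, `end`.
#' @return The retained promoters with an `acetylation` column.
#' @export
promoter_acetylation <- function(promoters, h3k27ac, atac) {
  pg <- as_granges0(promoters)
  level <- rep(NA_real_, nrow(promoters))
  if (nrow(h3k27ac) > 0) {
    ov <- GenomicRanges::findOverlaps(pg, as_granges0(h3k27ac))
    if (length(ov)) {
      mx <- tapply(h3k27ac$score[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
      level[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  if (nrow(atac) > 0) {
    ov <- GenomicRanges::findOverlaps(pg, as_granges0(atac))
    open <- unique(S4Vectors::queryHits(ov))
    level[open][is.na(level[open])] <- 0
  }
  out <- promoters[!is.na(level), , drop = FALSE]
  out$acetylation <- level[!is.na(level)]
  rownames(out) <- NULL
  out
}

#' Classify promoter acetylation change
#'
#' A promoter is `induced` when it overlaps any differential region with
#' log2 fold change >= `induced_fc`, else `unchanged` when it overlaps a
#' region with log2 fold change <= `unchanged_fc`, else `unclassified`.
#' Overlapping both kinds resolves to `induced` (a gene with some changing
#' and some static peaks is treated as changing).
#'
#' @param promoters [define_promoters()] output.
#' @param diffbind Data frame `contig`, `start`, `end`, `log2fc`.
#' @param induced_fc,unchanged_fc Class thresholds (defaults 1.5 / 0.1).
#' @return The promoters with a `change_class` column.
#' @export
classify_promoter_change <- function(promoters, diffbind, induced_fc = 1.5,
                                     unchanged_fc = 0.1) {
  cls <- rep("unclassified", nrow(promoters))
  if (nrow(diffbind) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(promoters),
                                      as_granges0(diffbind))
    q <- S4Vectors::queryHits(ov)
    fc <- diffbind$log2fc[S4Vectors::subjectHits(ov)]
    ind <- unique(q[fc >= induced_fc])
    unc <- setdiff(unique(q[fc <= unchanged_fc]), ind)
    cls[ind] <- "induced"
    cls[unc] <- "unchanged"
  }
  promoters$change_class <- cls
  promoters
}

#' Motif and cluster counts in a promoter
#'
#' Counts qualifying motif hits (region score > 0, i.e. best occurrence at
#' p <= `p_floor`) among the member motifs of the supplied TF clusters, plus
#' the number of distinct clusters with at least one hit — the heterotypic
#' motif-group size.
#'
#' @param seq Promoter sequence.
#' @param cluster_motifs Named list: cluster id -> list of `pwm_model`s or
#'   motifs.
#' @param p_floor Occurrence p-value floor.
#' @return Named numeric vector `c(n_motifs, n_clusters)`.
#' @export
motif_group_counts <- function(seq, cluster_motifs, p_floor = 1e-5) {
  n_motifs <- 0L
  n_clusters <- 0L
  for (cl in cluster_motifs) {
    hits <- sum(vapply(cl, function(m) region_score(seq, m, p_floor) > 0,
                       logical(1)))
    n_motifs <- n_motifs + hits
    if (hits > 0L) n_clusters <- n_clusters + 1L
  }
  c(n_motifs = n_motifs, n_clusters = n_clusters)
}

#' Two-sided rank-sum enrichment test
#'
#' Wilcoxon rank-sum comparison of motif scores between two groups of
#' genomic elements: exact for small tie-free samples, normal approximation
#' with tie correction otherwise (via [stats::wilcox.test()]).
#'
#' @param scores_a,scores_b Numeric score vectors (both non-empty).
#' @return Two-sided p-value.
#' @export
enrichment_test <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L)
    stop("both score groups must be non-empty")
  suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                      alternative = "two.sided"))$p.value
}

#' Extract a region's sequence from a genome
#'
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Character sequence.
#' @export
region_sequence <- function(genome, contig, start, end) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  as.character(Biostrings::subseq(genome[[contig]], start = start + 1L,
                                  end = end))
}

#' Read a BED file of peaks
#'
#' BED4+/BED6-style TSV without header: chrom, start, end, then optionally
#' name and score. The score column carries -log10 p peak scores.
#'
#' @param path BED file path.
#' @return Data frame `contig`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("malformed BED: fewer than 3 columns")
  out <- data.frame(contig = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else
    sprintf("peak_%d", seq_len(nrow(tab)))
  out$score <- if (ncol(tab) >= 5L) as.numeric(tab[[5]]) else NA_real_
  if (any(out$end < out$start)) stop("malformed BED: end < start")
  out
}

#' Write peaks as BED
#'
#' @param peaks Data frame `contig`, `start`, `end` and optionally `name`,
#'   `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  tab <- data.frame(peaks$contig, peaks$start, peaks$end,
                    peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks))),
                    peaks$score %||% 0)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
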