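det_ppm <- function(bases) {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, length(idx), 4)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

test_that("log-odds matrices behave at the uniform and deterministic extremes", {
  uni <- logodds_from_ppm(matrix(0.25, 4, 4))
  expect_true(all(abs(uni$lo) < 1e-12))
  det <- logodds_from_ppm(det_ppm("A"), pseudocount = 0)
  expect_equal(unname(det$lo[1, "A"]), 2)  # log2(4)
  set.seed(17)
  for (i in 1:10) {
    r <- random_ppm(1)
    lo <- logodds_from_ppm(r)$lo
    expect_gt(max(lo), 0)
    expect_lt(min(lo), 0)
  }
})

test_that("the consensus of a deterministic PWM scores p = 4^-L", {
  for (L in c(3, 6, 10)) {
    set.seed(L)
    cons <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    pwm <- logodds_from_ppm(det_ppm(cons))
    hit <- best_occurrence(cons, pwm)
    expect_equal(hit$p, 4^-L, tolerance = 1e-12)
    expect_equal(hit$position, 1)
  }
})

test_that("max-strand scanning is symmetric under reverse complement", {
  set.seed(18)
  pwm <- logodds_from_ppm(random_ppm(6))
  seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  expect_equal(best_occurrence(seq, pwm)$score,
               best_occurrence(rc, pwm)$score, tolerance = 1e-12)
  expect_error(best_occurrence("ACG", pwm), "shorter")
})

test_that("DP p-values equal exhaustive enumeration over all 4^5 windows", {
  set.seed(19)
  for (trial in 1:3) {
    pwm <- logodds_from_ppm(random_ppm(5))
    oracle <- oracle_pwm_tail(pwm$S)
    # check the tail at attainable window scores and at grid points between
    attained <- apply(as.matrix(expand.grid(rep(list(1:4), 5))), 1,
                      function(ix) sum(pwm$S[cbind(1:5, ix)]))
    probe_ints <- unique(c(sample(attained, 15),
                           round(seq(pwm$min_total,
                                     pwm$min_total + length(pwm$tail) - 1,
                                     length.out = 10))))
    for (s in probe_ints) {
      expect_equal(corec:::pwm_tail_p(pwm, s), oracle(s), tolerance = 1e-9)
    }
  }
})

test_that("region scores floor at p = 1e-5 and use the single best occurrence", {
  gpwm <- logodds_from_ppm(det_ppm("GGGGGGGGGG"))
  expect_equal(region_score(strrep("T", 50), gpwm), 0)
  set.seed(20)
  bg <- paste(sample(c("A", "C"), 80, TRUE), collapse = "")
  cons <- "GTGTGGGCTG"
  pwm10 <- logodds_from_ppm(det_ppm(cons))
  one_site <- paste0(substr(bg, 1, 40), cons, substr(bg, 41, 80))
  s1 <- region_score(one_site, pwm10)
  expect_equal(s1, -log10(4^-10), tolerance = 1e-9)
  expect_gt(s1, 5)
  two_sites <- paste0(cons, substr(bg, 1, 30), cons, substr(bg, 41, 80))
  expect_equal(region_score(two_sites, pwm10), s1)
  # planting the consensus can only increase a region's score
  expect_gte(s1, region_score(paste0(substr(bg, 1, 40), substr(bg, 41, 80),
                                     strrep("A", 10)), pwm10))
})

test_that("cluster scores take the maximum over member motifs", {
  cons <- "GTGTGGGCTG"
  pwm <- logodds_from_ppm(det_ppm(cons))
  other <- logodds_from_ppm(det_ppm("CACACACACA"))
  seq <- paste0(strrep("T", 20), cons, strrep("T", 20))
  expect_equal(cluster_score(seq, list(pwm, pwm)),
               region_score(seq, pwm))
  expect_equal(cluster_score(seq, list(other)), 0)
  expect_equal(cluster_score(seq, list(other, pwm)),
               region_score(seq, pwm))
  expect_error(cluster_score(seq, list()), "no motifs")
})

test_that("site counting is greedy, non-overlapping, left to right", {
  cons <- "GTGTGGGCTG"
  pwm <- logodds_from_ppm(det_ppm(cons))
  expect_equal(count_sites(strrep("T", 60), pwm), 0L)
  two <- paste0(strrep("T", 5), cons, strrep("T", 10), cons, strrep("T", 5))
  expect_equal(count_sites(two, pwm), 2L)
  # an overlap construction: a G-run holds three perfect overlapping hits
  # of a G-run motif, but greedy non-overlap counting reports one
  ovl_pwm <- logodds_from_ppm(det_ppm(strrep("G", 10)))
  expect_equal(count_sites(paste0(strrep("T", 5), strrep("G", 12),
                                  strrep("T", 5)), ovl_pwm), 1L)
})

test_that("promoter windows are strand-aware, half-open, and clipped", {
  tss <- data.frame(gene = c("g1", "g2"), contig = "chr1",
                    tss = c(10000, 10000), strand = c("+", "-"))
  pr <- define_promoters(tss[1, ])
  expect_equal(c(pr$start, pr$end), c(9500, 10100))
  pr2 <- define_promoters(tss[2, ])
  expect_equal(c(pr2$start, pr2$end), c(9900, 10500))
  expect_equal(pr$end - pr$start, 600)
  expect_warning(pr3 <- define_promoters(
    data.frame(gene = "g3", contig = "chr1", tss = 200, strand = "+")),
    "clipped")
  expect_equal(c(pr3$start, pr3$end), c(0, 300))
  expect_error(define_promoters(
    data.frame(gene = "g4", contig = "chr1", tss = 500, strand = ".")),
    "strand")
  # only the first TSS per gene is used
  dup <- define_promoters(data.frame(gene = "g", contig = "chr1",
                                     tss = c(5000, 9000),
                                     strand = "+"))
  expect_equal(nrow(dup), 1)
  expect_equal(dup$start, 4500)
})

test_that("promoter acetylation takes the max peak, 0 for ATAC-only, drop otherwise", {
  prom <- data.frame(gene = c("a", "b", "c"), contig = "chr1",
                     start = c(100, 1000, 2000), end = c(700, 1600, 2600),
                     strand = "+")
  ac <- data.frame(contig = "chr1", start = c(150, 400), end = c(250, 500),
                   score = c(3, 7))
  atac <- data.frame(contig = "chr1", start = c(120, 1100),
                     end = c(220, 1200))
  out <- promoter_acetylation(prom, ac, atac)
  expect_equal(out$gene, c("a", "b"))
  expect_equal(out$acetylation, c(7, 0))
})

test_that("the overlap engine agrees with the all-pairs oracle", {
  set.seed(23)
  q <- data.frame(gene = sprintf("g%d", 1:30),
                  contig = sample(c("c1", "c2"), 30, TRUE),
                  start = sample(0:5000, 30), strand = "+")
  q$end <- q$start + sample(50:500, 30, TRUE)
  s <- data.frame(contig = sample(c("c1", "c2"), 40, TRUE),
                  start = sample(0:5000, 40))
  s$end <- s$start + sample(20:400, 40, TRUE)
  s$score <- runif(40, 1, 10)
  got <- promoter_acetylation(q, s, s[0, ])
  oracle_hits <- oracle_overlaps(q, s)
  expect_setequal(got$gene, q$gene[unique(oracle_hits[, 1])])
  for (i in unique(oracle_hits[, 1])) {
    expect_equal(got$acetylation[got$gene == q$gene[i]],
                 max(s$score[oracle_hits[oracle_hits[, 1] == i, 2]]))
  }
})

test_that("promoter change classes resolve multi-peak conflicts to induced", {
  prom <- data.frame(gene = c("a", "b", "c"), contig = "chr1",
                     start = c(0, 1000, 2000), end = c(600, 1600, 2600),
                     strand = "+")
  db <- data.frame(contig = "chr1",
                   start = c(100, 1100, 2100, 2200),
                   end = c(200, 1200, 2200, 2300),
                   log2fc = c(2.0, 0.05, 2.0, 0.05))
  out <- classify_promoter_change(prom, db)
  expect_equal(out$change_class, c("induced", "unchanged", "induced"))
})

test_that("motif group counts track total hits and distinct clusters", {
  cons <- c("GTGTGGGCTG", "CACCAACTTG", "TTGACGTCAT", "GGAATTTCCC",
            "ACGCGTGCAT")
  pwms <- lapply(cons, function(s) logodds_from_ppm(det_ppm(s)))
  names(pwms) <- sprintf("C%d", 1:5)
  empty <- strrep("T", 80)
  expect_equal(unname(motif_group_counts(empty, list(C1 = pwms[1]))),
               c(0, 0))
  # three member motifs of one cluster all present -> (3, 1)
  seq3 <- paste0(cons[1], strrep("T", 12), cons[2], strrep("T", 12), cons[3])
  one_cluster <- list(CX = pwms[1:3])
  expect_equal(unname(motif_group_counts(seq3, one_cluster)), c(3, 1))
  # five distinct clusters
  seq5 <- paste(c(rbind(cons, strrep("T", 11))), collapse = "")
  five <- lapply(1:5, function(i) pwms[i])
  names(five) <- names(pwms)
  expect_equal(unname(motif_group_counts(seq5, five)), c(5, 5))
})

test_that("rank-sum enrichment matches exhaustive permutation and is symmetric", {
  expect_equal(enrichment_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(enrichment_test(c(10, 11, 12), c(1, 2, 3)), 0.1)
  expect_gte(enrichment_test(c(1, 2, 3), c(1, 2, 3)), 0.99)
  set.seed(29)
  for (i in 1:5) {
    a <- runif(sample(3:5, 1))
    b <- runif(sample(3:5, 1))
    expect_equal(enrichment_test(a, b), oracle_wilcoxon(a, b),
                 tolerance = 1e-9)
  }
  expect_error(enrichment_test(numeric(0), 1), "non-empty")
})
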