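test_that("same-coordinate ED matches closed forms and both normalisations", {
  P <- random_ppm(6, seed = 1)
  expect_equal(ed_same_coords(P, P), 0)
  Q1 <- matrix(c(1, 0, 0, 0), 1)
  U1 <- matrix(0.25, 1, 4)
  expect_equal(ed_same_coords(U1, Q1), sqrt(0.75^2 + 3 * 0.25^2))
  expect_equal(ed_same_coords(U1, Q1), sqrt(0.75))
  Q <- random_ppm(6, seed = 2)
  expect_equal(ed_same_coords(P, Q), ed_same_coords(Q, P))
  expect_equal(ed_same_coords(P, Q, normalize = "sum"),
               6 * ed_same_coords(P, Q))
  expect_error(ed_same_coords(P, random_ppm(5)), "length mismatch")
})

test_that("same-coordinate ED satisfies the metric axioms on random triples", {
  set.seed(33)
  for (i in 1:25) {
    a <- random_ppm(4); b <- random_ppm(4); c <- random_ppm(4)
    dab <- ed_same_coords(a, b)
    dbc <- ed_same_coords(b, c)
    dac <- ed_same_coords(a, c)
    expect_gte(dab, 0)
    expect_equal(dab, ed_same_coords(b, a))
    expect_lte(dac, dab + dbc + 1e-12)
  }
  expect_equal(ed_same_coords(random_ppm(3, seed = 4),
                              random_ppm(3, seed = 4)), 0)
})

test_that("best-offset ED equals exhaustive enumeration for small motifs", {
  set.seed(44)
  for (i in 1:20) {
    Lq <- sample(3:6, 1); Lt <- sample(3:6, 1)
    mo <- sample(2:min(Lq, Lt), 1)
    Q <- random_ppm(Lq); Tm <- random_ppm(Lt)
    got <- best_ed_alignment(Q, Tm, min_overlap = mo)
    expect_equal(got$ed, oracle_best_ed(Q, Tm, min_overlap = mo),
                 tolerance = 1e-12)
  }
})

test_that("reference comparison finds exact and reverse-complement matches", {
  refs <- lapply(1:5, function(i) ref_motif(sprintf("R%d", i),
                                            random_ppm(8, seed = 100 + i)))
  names(refs) <- sprintf("R%d", 1:5)
  q <- ref_motif("q", refs$R3$matrix)
  res <- compare_to_reference(q, refs, n_null = 499, seed = 2)
  hit <- res[res$target_id == "R3", ]
  expect_equal(hit$ed, 0)
  expect_equal(hit$orientation, "+")
  expect_equal(hit$offset, 0)
  expect_equal(hit$p, 1 / 500)  # minimum attainable
  expect_equal(hit$p_adj, 5 / 500)

  qrc <- ref_motif("qrc", revcomp_ppm(refs$R3$matrix))
  rc <- compare_to_reference(qrc, refs, n_null = 499, seed = 2)
  expect_equal(rc$ed[rc$target_id == "R3"], 0)
  expect_equal(rc$orientation[rc$target_id == "R3"], "-")
})

test_that("reverse-complementing the query flips orientations but not EDs", {
  refs <- list(R1 = ref_motif("R1", random_ppm(7, seed = 7)))
  q <- random_ppm(7, seed = 8)
  a <- compare_to_reference(ref_motif("a", q), refs, n_null = 99, seed = 1)
  b <- compare_to_reference(ref_motif("b", revcomp_ppm(q)), refs,
                            n_null = 99, seed = 1)
  expect_equal(a$ed, b$ed, tolerance = 1e-12)
  expect_true(a$orientation != b$orientation)
})

test_that("Monte-Carlo p-values are reproducible and converge across seeds", {
  refs <- lapply(1:4, function(i) ref_motif(sprintf("R%d", i),
                                            random_ppm(8, seed = 200 + i)))
  names(refs) <- sprintf("R%d", 1:4)
  q <- ref_motif("q", 0.7 * refs$R2$matrix + 0.3 * random_ppm(8, seed = 300))
  r1 <- compare_to_reference(q, refs, n_null = 999, seed = 5)
  r2 <- compare_to_reference(q, refs, n_null = 999, seed = 5)
  expect_identical(r1, r2)
  p5 <- r1$p[r1$target_id == "R1"]
  p6 <- compare_to_reference(q, refs, n_null = 999, seed = 6)
  p6 <- p6$p[p6$target_id == "R1"]
  expect_lt(abs(p5 - p6),
            4 * sqrt(p5 * (1 - p5) / 999) + 2e-3)
})

test_that("a planted reference is significant and beats all decoys", {
  refs <- make_planted_motifs(20, L = 12, seed = 70)
  sim <- tiny_sim(n = 1, gain = 32, seed = 70)
  fl <- simulate_pbm(sim$design, sim$truth, seed = 12)
  pid <- names(sim$design$probesets)[1]
  q <- build_corec_motif(corec_quantify(fl, sim$design),
                         sim$design$probesets[[pid]])
  res <- compare_to_reference(q, refs, n_null = 2999, seed = 3)
  planted <- res[res$target_id == pid, ]
  expect_lt(planted$p_adj, 0.01)
  expect_true(all(res$ed[res$target_id != pid] > planted$ed))
})

test_that("replicate filtering requires one close pair at shared coordinates", {
  mk <- function(mat, ms = 3) structure(list(id = "ps1", matrix = mat,
                                             beta = 2, ms = ms,
                                             meta = list(cof = "P300",
                                                         condition = "rest")),
                                        class = "corec_ppm")
  A <- random_ppm(6, seed = 9)
  expect_true(replicate_filter(list(mk(A), mk(A)))$replicated)
  expect_false(replicate_filter(list(mk(A)))$replicated)
  det1 <- matrix(0, 6, 4); det1[, 1] <- 1
  det2 <- matrix(0, 6, 4); det2[, 3] <- 1
  close <- 0.9 * A + 0.1 * random_ppm(6, seed = 10)
  g <- replicate_filter(list(mk(A), mk(close), mk(det2)))
  expect_true(g$replicated)
  expect_true(any(g$ed_pairs[upper.tri(g$ed_pairs)] >= 0.4))
  # and the group's motif strength is the maximum over members
  expect_equal(replicate_filter(list(mk(A, 2), mk(A, 5)))$ms, 5)
})

test_that("condition conservation needs one cross-condition pair under 0.25", {
  mk <- function(mat, id = "ps1") structure(list(id = id, matrix = mat,
                                                 beta = 2, ms = 3,
                                                 meta = list()),
                                            class = "corec_ppm")
  A <- random_ppm(6, seed = 11)
  B <- random_ppm(6, seed = 12)
  g_same <- replicate_filter(list(mk(A), mk(A)))
  expect_true(condition_conserved(g_same, g_same))
  g_far <- replicate_filter(list(mk(B), mk(B)))
  if (ed_same_coords(A, B) >= 0.25)
    expect_false(condition_conserved(g_same, g_far))
  # one pair at ED just under the threshold suffices
  eps <- A + (0.24 / ed_same_coords(A, B)) * (B - A)
  g_near <- replicate_filter(list(mk(eps), mk(B)))
  expect_true(condition_conserved(g_same, g_near))
  g_other <- replicate_filter(list(mk(A, "ps2"), mk(A, "ps2")))
  expect_error(condition_conserved(g_same, g_other), "different probe sets")
})

test_that("cluster assignment follows the single best adjusted p-value", {
  clusters <- tf_cluster_set(list(C1 = c("R1", "R2"), C2 = "R3"))
  mk_group <- function() {
    m <- structure(list(id = "ps", matrix = random_ppm(6, seed = 14),
                        beta = 2, ms = 3, meta = list()),
                   class = "corec_ppm")
    replicate_filter(list(m, m))
  }
  match_row <- function(target, p_adj, ed = 0.2) {
    data.frame(query_id = "ps", target_id = target, ed = ed, offset = 0L,
               orientation = "+", overlap = 6L, p = p_adj / 3,
               p_adj = p_adj, significant = p_adj < 0.01,
               stringsAsFactors = FALSE)
  }
  g <- assign_cluster(mk_group(), list(match_row("R1", 1e-6)), clusters)
  expect_equal(g$assigned_cluster, "C1")
  g2 <- assign_cluster(mk_group(), list(match_row("R1", 0.5)), clusters)
  expect_true(is.na(g2$assigned_cluster))
  # two members matching different clusters: 1e-6 beats 1e-4
  g3 <- assign_cluster(mk_group(),
                       list(match_row("R3", 1e-4), match_row("R2", 1e-6)),
                       clusters)
  expect_equal(g3$assigned_cluster, "C1")
  # ties on p_adj break by lower ED, then target id
  g4 <- assign_cluster(mk_group(),
                       list(match_row("R3", 1e-6, ed = 0.1),
                            match_row("R1", 1e-6, ed = 0.3)),
                       clusters)
  expect_equal(g4$assigned_cluster, "C2")
})
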