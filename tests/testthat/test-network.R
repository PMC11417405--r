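mk_group <- function(pid, cof, condition, ms, cluster = "C1",
                     replicated = TRUE) {
  structure(list(probeset_id = pid, cof = cof, condition = condition,
                 members = list(), replicated = replicated,
                 ed_pairs = matrix(0, 1, 1), ms = ms,
                 assigned_cluster = cluster, best_match = NULL),
            class = "replicate_group")
}

test_that("the recruitment matrix records the max motif strength per cell", {
  m <- build_matrix(list(mk_group("p1", "P300", "rest", 4.2)))
  expect_equal(nrow(m), 1)
  expect_equal(m$ms, 4.2)
  m2 <- build_matrix(list(mk_group("p1", "P300", "rest", 3),
                          mk_group("p2", "P300", "rest", 5)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$ms, 5)
  expect_equal(m2$probesets, "p1,p2")
  expect_equal(nrow(build_matrix(list())), 0)
  # unassigned or unreplicated groups never reach the matrix
  m3 <- build_matrix(list(mk_group("p1", "P300", "rest", 3,
                                   cluster = NA_character_),
                          mk_group("p2", "P300", "rest", 3,
                                   replicated = FALSE)))
  expect_equal(nrow(m3), 0)
})

test_that("condition status partitions interactions and reports fractions", {
  groups <- c(
    lapply(sprintf("g%d", 1:3), mk_group, cof = "KAT1", condition = "stim",
           ms = 5),
    lapply(sprintf("l%d", 1:2), function(p)
      mk_group(p, "KAT2", "rest", 4, cluster = paste0("CL_", p))),
    unlist(lapply(sprintf("c%d", 1:5), function(p) {
      list(mk_group(p, "KAT3", "rest", 4, cluster = paste0("CC_", p)),
           mk_group(p, "KAT3", "stim", 4, cluster = paste0("CC_", p)))
    }), recursive = FALSE))
  groups[[1]]$assigned_cluster <- "GA"
  groups[[2]]$assigned_cluster <- "GB"
  groups[[3]]$assigned_cluster <- "GC"
  mat <- build_matrix(groups)
  calls <- call_condition_status(mat, conditions = c("rest", "stim"))
  expect_equal(sum(calls$status == "gained"), 3)
  expect_equal(sum(calls$status == "lost"), 2)
  expect_equal(sum(calls$status == "conserved"), 5)
  expect_equal(attr(calls, "fractions")[1:3], c(0.3, 0.2, 0.5))
  expect_equal(sum(attr(calls, "counts")), nrow(calls))
  expect_error(call_condition_status(mat, conditions = c("a", "b", "c")),
               "2 conditions")
  # a both-present cell whose motifs diverge across conditions is flagged
  flags <- c("KAT3|CC_c1" = FALSE)
  calls2 <- call_condition_status(mat, c("rest", "stim"), flags)
  expect_equal(sum(calls2$status == "discordant"), 1)
  expect_equal(sum(calls2$status == "conserved"), 4)
})

test_that("response classes follow the delta-motif-strength rule table", {
  mk_calls <- function(cluster, status, ms1, ms2) {
    data.frame(cof = sprintf("K%d", seq_along(status)), cluster = cluster,
               status = status, ms1 = ms1, ms2 = ms2,
               delta_ms = ifelse(is.na(ms2), 0, ms2) -
                 ifelse(is.na(ms1), 0, ms1),
               stringsAsFactors = FALSE)
  }
  strong <- mk_calls("A", rep("gained", 3), c(NA, NA, NA), c(2.0, 1.6, 3.1))
  expect_equal(classify_response(strong)$class, "strongly_induced")
  single <- mk_calls("B", "conserved", 3, 3.2)
  expect_equal(classify_response(single)$class, "kat_specific")
  partial <- mk_calls("C", c("gained", "gained", "conserved"),
                      c(NA, NA, 4.0), c(2.0, 1.8, 4.1))
  expect_equal(classify_response(partial)$class, "partially_induced")
  dimin <- mk_calls("D", c("lost", "lost", "conserved"),
                    c(2.0, 1.8, 4.0), c(NA, NA, 4.1))
  expect_equal(classify_response(dimin)$class, "diminished")
  none <- mk_calls("E", c("gained", "conserved"), c(NA, 4.0), c(2.0, 4.1))
  expect_equal(classify_response(none)$class, "none")
  # classes partition: one class per cluster
  all_calls <- rbind(strong, single, partial, dimin, none)
  res <- classify_response(all_calls)
  expect_equal(sort(res$cluster), c("A", "B", "C", "D", "E"))
  expect_true(all(res$class %in% c("strongly_induced", "partially_induced",
                                   "diminished", "kat_specific", "none")))
})

test_that("promiscuity requires more than four COFs above strength 3 in both conditions", {
  mk_mat <- function(n_kats, ms = 5, ms_last = ms) {
    do.call(rbind, lapply(seq_len(n_kats), function(k) {
      data.frame(cof = sprintf("K%d", k), condition = c("rest", "stim"),
                 cluster = "CL", ms = if (k == n_kats) ms_last else ms,
                 probesets = "p", stringsAsFactors = FALSE)
    }))
  }
  expect_equal(promiscuity(mk_mat(5)), "CL")
  expect_equal(promiscuity(mk_mat(4)), character(0))
  # strictness: ms exactly 3 does not qualify, leaving 5 of 6 -> promiscuous
  expect_equal(promiscuity(mk_mat(6, ms_last = 3.0)), "CL")
  expect_equal(promiscuity(mk_mat(5, ms_last = 3.0)), character(0))
})

test_that("novelty annotation is driven by PPI edges through the cluster map", {
  mat <- data.frame(cof = c("COF_y", "COF_y", "COF_z"),
                    cluster = c("C", "D", "C"), stringsAsFactors = FALSE)
  tf_map <- c(TF_x = "C", TF_w = "D")
  edges <- data.frame(tf_gene = "TF_x", cof = "COF_y",
                      stringsAsFactors = FALSE)
  ann <- annotate_novelty(mat, edges, tf_map)
  expect_true(ann$reported[ann$cof == "COF_y" & ann$cluster == "C"])
  expect_equal(sum(!ann$reported), 2)
  empty <- annotate_novelty(mat, data.frame(tf_gene = character(0),
                                            cof = character(0)), tf_map)
  expect_false(any(empty$reported))
  # 10 interactions, 4 covered by edges -> 6 unreported
  mat10 <- data.frame(cof = "K", cluster = sprintf("C%02d", 1:10),
                      stringsAsFactors = FALSE)
  map10 <- stats::setNames(sprintf("C%02d", 1:4), sprintf("T%d", 1:4))
  edges4 <- data.frame(tf_gene = sprintf("T%d", 1:4), cof = "K",
                       stringsAsFactors = FALSE)
  expect_equal(sum(!annotate_novelty(mat10, edges4, map10)$reported), 6)
})

test_that("the row-permutation z-score matches the exact per-row enumeration", {
  # two cell types, two experiment columns each
  set.seed(77)
  presence <- matrix(rbinom(20 * 4, 1, 0.5), 20, 4)
  ct <- c("jurkat", "jurkat", "sudhl4", "sudhl4")
  res <- row_permutation_test(presence, ct, n_perm = 4000, seed = 3)
  # exact null: rows are independent; enumerate all 4! column permutations
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  p_row <- apply(presence, 1, function(r) {
    mean(apply(perms, 1, function(p) {
      xor(any(r[p[1:2]] == 1), any(r[p[3:4]] == 1))
    }))
  })
  exact_mean <- sum(p_row)
  exact_sd <- sqrt(sum(p_row * (1 - p_row)))
  expect_lt(abs(res$null_mean - exact_mean), 4 * exact_sd / sqrt(4000) + 0.05)
  expect_lt(abs(res$null_sd - exact_sd), 0.15)
  expect_equal(res$z, (res$observed - res$null_mean) / res$null_sd)
})

test_that("row-permutation direction and degeneracy behave as expected", {
  # identical presence across cell types: observed 0, z <= 0
  pres_same <- cbind(c(1, 1, 0, 1, 0, 1), c(0, 1, 1, 0, 1, 1),
                     c(1, 1, 0, 1, 0, 1), c(0, 1, 1, 0, 1, 1))
  ct <- c("a", "a", "b", "b")
  res <- row_permutation_test(pres_same, ct, n_perm = 2000, seed = 1)
  expect_equal(res$observed, 0)
  expect_lte(res$z, 0)
  # fully anti-correlated: every cluster specific to one cell type
  pres_anti <- cbind(rep(1, 6), rep(1, 6), rep(0, 6), rep(0, 6))
  res2 <- row_permutation_test(pres_anti, ct, n_perm = 2000, seed = 1)
  expect_gt(res2$z, 0)
  # all-ones matrix: statistic invariant -> zero-variance error
  expect_error(row_permutation_test(matrix(1, 4, 4), ct, n_perm = 100),
               "zero variance")
})
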