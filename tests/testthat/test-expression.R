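# Consensus-NMF subtyping, cluster assignment, GSEA, signature scores and
# survival stratification.

planted_cohort <- function(noise_sd = 0, n = 24, k = 3, hazards = rep(0.1, 3),
                           seed = 1, ...) {
  simulate_expression_cohort(expression_spec(
    n_samples = n, n_genes = 60, k_true = k, noise_sd = noise_sd,
    hazards = hazards, seed = seed, ...))
}

test_that("consensus NMF recovers planted structure", {
  # noiseless blocks: perfect stability at the planted rank, exact labels
  ec <- planted_cohort(noise_sd = 0)
  mm <- nmf_metagenes(ec$expression, k_range = 2:4, restarts = 10,
                      seed = 3, top_n = Inf)
  expect_gte(unname(mm$cophenetic["k3"]), 0.99)
  expect_gte(unname(mm$dispersion["k3"]), 0.99)
  cl <- assign_clusters(mm$fits$k3$H, paste0("NMF", 1:3))
  # assignments match planted blocks exactly (up to metagene relabeling)
  tab <- table(cl$cluster, ec$labels$cluster)
  expect_equal(sum(apply(tab, 2, max)), ncol(ec$expression))
  # at realistic noise the stability rule selects the planted rank
  ec2 <- planted_cohort(noise_sd = 0.5, n = 30, seed = 6)
  mm2 <- nmf_metagenes(ec2$expression, k_range = 2:5, restarts = 10,
                       seed = 3, top_n = Inf)
  expect_equal(mm2$k, 3)
  cl2 <- assign_clusters(mm2, rownames(mm2$H))
  tab2 <- table(cl2$cluster, ec2$labels$cluster)
  expect_equal(sum(apply(tab2, 2, max)), 30)
})

test_that("rank-1 input falls back to min k with a warning", {
  mat <- outer(runif(40, 1, 2), runif(12, 1, 2)) # rank 1, no cluster structure
  expect_warning(
    mm <- nmf_metagenes(mat, k_range = 2:3, restarts = 5, seed = 2,
                        top_n = Inf, threshold = 0.999),
    "falling back"
  )
  expect_equal(mm$k, 2)
})

test_that("more restarts never worsen the best objective", {
  ec <- planted_cohort(noise_sd = 0.8, seed = 5)
  obj_of <- function(restarts) {
    mm <- nmf_metagenes(ec$expression, k_range = 3, restarts = restarts,
                        seed = 11, top_n = Inf)
    mm$fits$k3$objective
  }
  expect_lte(obj_of(10), obj_of(1))
})

test_that("cluster assignment: dominance, normal metagenes, ties", {
  h <- rbind(NMF1 = c(0.1, 0.0, 0.4), NMF2 = c(0.9, 0.1, 0.4),
             NMF3 = c(0.0, 0.0, 0.1), NORM = c(0.2, 0.8, 0.2))
  colnames(h) <- c("a", "b", "c")
  res <- suppressWarnings(
    assign_clusters(h, c("NMF1", "NMF2", "NMF3")))
  expect_equal(res$cluster[res$sample_id == "a"], "NMF2")
  # dominant normal metagene -> UNASSIGNED
  expect_equal(res$cluster[res$sample_id == "b"], "UNASSIGNED")
  # exact tie between tumor metagenes -> UNASSIGNED with warning
  expect_warning(assign_clusters(h[, "c", drop = FALSE],
                                 c("NMF1", "NMF2", "NMF3")), "tie")
  expect_equal(res$cluster[res$sample_id == "c"], "UNASSIGNED")
  # assigned + unassigned partition the cohort
  expect_equal(nrow(res), 3)
  expect_error(assign_clusters(h, character(0)), "empty")
})

test_that("tumor-specific metagenes are those with higher tumor activity", {
  ec <- planted_cohort(noise_sd = 0.1, normal_clusters = 3, seed = 4)
  mm <- nmf_metagenes(ec$expression, k_range = 3, restarts = 10, seed = 6,
                      top_n = Inf)
  types <- setNames(ec$labels$type, ec$labels$sample_id)
  tumor_ids <- designate_tumor_metagenes(mm, types)
  expect_length(tumor_ids, 2)
  cl <- assign_clusters(mm, tumor_ids) |>
    dplyr::rename(assigned = "cluster")
  joined <- dplyr::left_join(cl, ec$labels, by = "sample_id")
  # normal-cluster samples end up unassigned; tumor samples assigned
  expect_gt(sum(joined$type == "normal"), 0)
  expect_true(all(joined$assigned[joined$type == "normal"] == "UNASSIGNED"))
  expect_true(all(joined$assigned[joined$type == "tumor"] != "UNASSIGNED"))
})

test_that("GSEA: extreme sets, monotone invariance, fgsea agreement", {
  scores <- setNames(seq(5, -5, length.out = 1000), sprintf("g%04d", 1:1000))
  top <- preranked_gsea(scores, names(scores)[1:10], nperm = 200, seed = 1)
  expect_gt(top$es, 0.9)
  expect_lt(top$p, 0.02)
  bottom <- preranked_gsea(scores, names(scores)[991:1000], nperm = 200,
                           seed = 1)
  expect_lt(bottom$es, -0.9)
  # weight 0 ES invariant under any strictly monotone transform
  set.seed(2)
  sc <- setNames(rnorm(300), sprintf("h%03d", 1:300))
  gs <- sample(names(sc), 40)
  es0 <- preranked_gsea(sc, gs, nperm = 10, weight_p = 0, seed = 1)$es
  es0_t <- preranked_gsea(exp(sc) + 3, gs, nperm = 10, weight_p = 0,
                          seed = 1)$es
  expect_equal(es0, es0_t, tolerance = 1e-12)
  # weight 1 ES invariant under positive scaling
  es1 <- preranked_gsea(sc, gs, nperm = 10, weight_p = 1, seed = 1)$es
  es1_s <- preranked_gsea(sc * 7, gs, nperm = 10, weight_p = 1, seed = 1)$es
  expect_equal(es1, es1_s, tolerance = 1e-12)
  # independent implementation agreement on the ES (fgsea, classic mode)
  f <- suppressWarnings(fgsea::fgsea(list(set = gs), sc, nperm = 100,
                                     gseaParam = 1))
  expect_equal(es1, f$ES, tolerance = 1e-6)
  expect_error(preranked_gsea(sc, c("none1", "none2")), "disjoint")
})

test_that("signature scores hit +/-1 at template extremes and split groups", {
  genes <- sprintf("g%02d", 1:20)
  up <- genes[1:10]; down <- genes[11:20]
  set.seed(3)
  base <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(genes, sprintf("s%02d", 1:10)))
  # plant one sample exactly on the template, one exactly opposite
  z_target <- c(rep(2, 10), rep(-2, 10))
  base[, 1] <- base[, 1] - rowMeans(base) # keep variance sane
  mat <- base
  mat[, 1] <- rowMeans(base) + z_target * 3
  mat[, 2] <- rowMeans(base) - z_target * 3
  res <- signature_score(mat, up, down, mode = "correlation")
  expect_gt(res$score[1], 0.9)
  expect_lt(res$score[2], -0.9)
  expect_true(all(abs(res$score) <= 1 + 1e-12))
  md <- signature_score(mat, up, down, mode = "mean_diff")
  expect_gt(md$score[1], 0)
  expect_lt(md$score[2], 0)
  # empty down set allowed (mean of up only)
  only_up <- signature_score(mat, up, mode = "mean_diff")
  expect_equal(nrow(only_up), 10)
  expect_error(signature_score(mat, c("absent1", "absent2")), "no signature")
  # planted high-scoring subgroup recovered by median split
  agree <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      m2 <- matrix(rnorm(20 * 30), 20, 30,
                   dimnames = list(genes, sprintf("t%02d", 1:30)))
      hi <- 1:15
      m2[1:10, hi] <- m2[1:10, hi] + 2    # up genes high
      m2[11:20, hi] <- m2[11:20, hi] - 2  # down genes low
    })
    sc <- signature_score(m2, up, down, mode = "correlation")
    split_hi <- sc$sample_id[sc$score > median(sc$score)]
    acc <- length(intersect(split_hi, sprintf("t%02d", hi))) / 15
    if (acc >= 0.9) agree <- agree + 1
  }
  expect_gte(agree, 18)
})

test_that("survival stratification delegates to log-rank and emits KM steps", {
  ec <- planted_cohort(noise_sd = 0.2, n = 90, hazards = c(0.1, 0.1, 0.8),
                       seed = 9)
  cl <- tibble::tibble(sample_id = ec$labels$sample_id,
                       cluster = paste0("C", ec$labels$cluster))
  res <- stratify_and_survive(cl, ec$survival)
  expect_equal(res$test$df, 2)
  expect_lt(res$test$p, 0.05)
  expect_setequal(unique(res$km$group), c("C1", "C2", "C3"))
  expect_true(all(res$km$surv >= 0 & res$km$surv <= 1))
  expect_true(all(tapply(res$km$surv, res$km$group,
                         function(s) all(diff(s) <= 1e-12))))
  # median split of a continuous score: ties go low
  sc <- tibble::tibble(sample_id = ec$labels$sample_id,
                       score = rep(c(1, 2), length.out = 90))
  res2 <- stratify_and_survive(sc, ec$survival)
  expect_equal(res2$test$df, 1)
  # single group errors
  one <- tibble::tibble(sample_id = ec$labels$sample_id, cluster = "all")
  expect_error(stratify_and_survive(one, ec$survival), "2 non-empty")
})
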