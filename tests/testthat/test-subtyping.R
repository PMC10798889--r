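test_that("scale_to_1_2 maps per-protein ranges onto [1, 2]", {
  m <- rbind(a = c(-2, 0, 2), b = c(5, 5, 5), c = c(0.1, 0.9, 0.5))
  colnames(m) <- c("x", "y", "z")
  s <- scale_to_1_2(m)
  expect_equal(unname(s["a", ]), c(1, 1.5, 2))
  expect_equal(unname(s["b", ]), c(1.5, 1.5, 1.5))  # constant -> midpoint
  expect_equal(min(s["c", ]), 1)
  expect_equal(max(s["c", ]), 2)
  # rank order preserved within each protein
  expect_identical(order(s["c", ]), order(m["c", ]))
  expect_error(scale_to_1_2(m[0, , drop = FALSE]), "empty")
})

test_that("NMF recovers exact low-rank structure and decreases its objective", {
  withr::with_seed(8, {
    u <- runif(12, 0.5, 2)
    v <- runif(9, 0.5, 2)
  })
  X <- outer(u, v)
  runs <- nmf_factorize(X, k = 1, n_runs = 3, seed = 2, check_every = 1)
  expect_lt(min(vapply(runs, `[[`, numeric(1), "objective")),
            1e-6 * sum(X))
  for (r in runs) {
    expect_true(all(diff(r$trace) <= 1e-8))          # monotone non-increasing
    expect_true(all(r$W >= 0), all(r$H >= 0))
  }
  # block-diagonal planted partition, k = 2
  B <- matrix(0.01, 10, 8)
  B[1:5, 1:4] <- 3
  B[6:10, 5:8] <- 3
  colnames(B) <- paste0("s", 1:8)
  runs2 <- nmf_factorize(B + 0.05, k = 2, n_runs = 5, seed = 3)
  best <- runs2[[which.min(vapply(runs2, `[[`, numeric(1), "objective"))]]
  lab <- apply(best$H, 2, which.max)
  expect_equal(length(unique(lab[1:4])), 1L)
  expect_equal(length(unique(lab[5:8])), 1L)
  expect_false(lab[1] == lab[5])
  expect_error(nmf_factorize(X - 1, k = 1), "strictly positive")
})

test_that("consensus matrix and cophenetic behave as specified", {
  fake_run <- function(lab, k) {
    H <- matrix(0.01, k, length(lab))
    H[cbind(lab, seq_along(lab))] <- 1
    list(W = matrix(1, 3, k), H = H)
  }
  stable <- replicate(4, fake_run(c(1, 1, 2, 2), 2), simplify = FALSE)
  cc <- consensus_and_cophenetic(stable)
  expect_true(all(cc$C %in% c(0, 1)))
  expect_equal(cc$cophenetic, 1)
  expect_true(isSymmetric(cc$C))
  expect_equal(unname(diag(cc$C)), rep(1, 4))
  # random labelings on 20 samples are unstable: cophenetic clearly below 0.9
  runs <- withr::with_seed(14, {
    replicate(12, fake_run(sample(1:3, 20, replace = TRUE), 3),
              simplify = FALSE)
  })
  cc2 <- consensus_and_cophenetic(runs)
  expect_lt(cc2$cophenetic, 0.9)
  expect_error(consensus_and_cophenetic(stable[1]), "at least 2 runs")
})

test_that("silhouette matches hand values and the brute-force oracle", {
  # two tight clusters: within-distance 0, between 10
  D <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10),
             c(10, 10, 0, 0), c(10, 10, 0, 0))
  expect_equal(silhouette_score(c(1, 1, 2, 2), D), 1)
  expect_error(silhouette_score(c(1, 1, 1, 1), D), "2 clusters")
  withr::with_seed(6, {
    for (i in 1:50) {
      n <- sample(5:12, 1)
      pts <- matrix(rnorm(n * 2), n)
      D <- as.matrix(dist(pts))
      lab <- sample(1:sample(2:4, 1), n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      expect_equal(silhouette_score(lab, D), oracle_silhouette(lab, D),
                   tolerance = 1e-10)
    }
  })
  # random labels on exchangeable data have silhouette near 0
  sil <- withr::with_seed(15, {
    pts <- matrix(rnorm(80), 40)
    mean(replicate(20, silhouette_score(sample(1:2, 40, replace = TRUE),
                                        as.matrix(dist(pts)))))
  })
  expect_lt(abs(sil), 0.1)
})

test_that("model selection recovers a small planted k and labels", {
  cfg <- small_config(seed = 42, n_controls = 40, n_ad = 90, n_proteins = 120,
                      signature_size = 25, missing_plex_fraction = 0.02)
  cohort <- generate_cohort(cfg)
  res <- run_discovery_pipeline(cohort$intensity, cohort$metadata,
                                k_range = 2:5, n_runs = 8, seed = 42)
  model <- res$model
  expect_equal(model$selected_k, 3L)
  expect_gt(model$metrics$silhouette[model$metrics$k == 3], 0.5)
  truth <- cohort$truth$subtype
  ad <- names(truth)[!is.na(truth)]
  expect_gte(adjusted_rand_index(model$patient_labels[ad], truth[ad]), 0.9)
  # dual clustering: every sample exactly one label; argmax semantics
  expect_setequal(names(model$patient_labels), ad)
  h <- model$best_run$H
  expect_identical(unname(model$patient_labels),
                   unname(apply(h, 2, which.max)))
  # determinism of the full model selection
  res2 <- run_discovery_pipeline(cohort$intensity, cohort$metadata,
                                 k_range = 2:5, n_runs = 8, seed = 42)
  expect_identical(model$metrics, res2$model$metrics)
  expect_identical(model$patient_labels, res2$model$patient_labels)
})

test_that("argmax labeling breaks ties toward the lowest component", {
  run <- list(W = rbind(p1 = c(0.4, 0.4), p2 = c(0.1, 0.9)),
              H = cbind(s1 = c(0.9, 0.1), s2 = c(0.5, 0.5)))
  cl <- assign_dual_clusters(run)
  expect_equal(unname(cl$patient_labels), c(1L, 1L))
  expect_equal(unname(cl$protein_labels), c(1L, 2L))
  expect_identical(cl$ties$patients, "s2")
  expect_identical(cl$ties$proteins, "p1")
})

test_that("consensus structure is invariant under sample reordering", {
  # random initializations are drawn per column, so the consensus matrix is
  # reproducible up to the permutation at the level of the partition it
  # encodes: on separated data the derived clustering is identical.
  cfg <- small_config(seed = 23, n_controls = 12, n_ad = 36, n_proteins = 60,
                      signature_size = 15)
  cohort <- generate_cohort(cfg)
  norm <- normalize_cohort(cohort$intensity, cohort$metadata)
  ad <- cohort$metadata$sample_id[cohort$metadata$group == "AD"]
  X <- scale_to_1_2(norm, samples = ad)
  runs <- nmf_factorize(X, 3, n_runs = 6, seed = 4)
  C <- consensus_and_cophenetic(runs)$C
  perm <- withr::with_seed(5, sample(ncol(X)))
  runs_p <- nmf_factorize(X[, perm], 3, n_runs = 6, seed = 4)
  C_p <- consensus_and_cophenetic(runs_p)$C
  expect_true(isSymmetric(C_p))
  expect_equal(unname(diag(C_p)), rep(1, ncol(X)))
  lab <- cutree(hclust(as.dist(1 - C), "average"), k = 3)
  lab_p <- cutree(hclust(as.dist(1 - C_p), "average"), k = 3)
  expect_equal(adjusted_rand_index(lab[colnames(C_p)], lab_p), 1)
})
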