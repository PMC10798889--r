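profiling_fixture <- function(seed = 41, n_controls = 20, n_ad = 40) {
  withr::with_seed(seed, {
    ids <- c(sprintf("c%02d", seq_len(n_controls)),
             sprintf("a%02d", seq_len(n_ad)))
    grp <- rep(c("control", "AD"), c(n_controls, n_ad))
    labels <- stats::setNames(sample(1:2, n_ad, replace = TRUE),
                              ids[grp == "AD"])
    meta <- read_metadata(data.frame(
      sample_id = ids, group = grp,
      cognitive_state = ifelse(grp == "control", "NC", "dementia"),
      tau_status = ifelse(grp == "control", "normal", "abnormal"),
      age = round(rnorm(length(ids), 65, 7), 1),
      sex = sample(c("f", "m"), length(ids), replace = TRUE)))
    values <- matrix(rnorm(6 * length(ids)), 6,
                     dimnames = list(sprintf("P%d", 1:6), ids))
    # P1: planted subtype-1 effect of +2 control-s.d.
    values["P1", names(labels)[labels == 1]] <-
      values["P1", names(labels)[labels == 1]] + 2
    norm <- structure(list(values = values,
                           excluded = data.frame(protein = character(0),
                                                 reason = character(0))),
                      class = "normalized_matrix")
    list(norm = norm, labels = labels, meta = meta)
  })
}

test_that("EMM contrasts equal raw group differences without covariates", {
  fx <- profiling_fixture()
  tab <- differential_abundance(fx$norm, fx$labels, fx$meta)
  expect_s3_class(tab, "differential_table")
  v <- fx$norm$values["P1", ]
  g1 <- names(fx$labels)[fx$labels == 1]
  ctrl <- fx$meta$sample_id[fx$meta$group == "control"]
  raw_diff <- mean(v[g1]) - mean(v[ctrl])
  row <- tab[tab$protein == "P1" & tab$group1 == "subtype1" &
               tab$group2 == "control", ]
  expect_equal(row$effect, raw_diff, tolerance = 1e-10)
  expect_lt(row$p, 0.01)
  expect_identical(row$direction, "up")
  # subtype-subtype contrast present under contrasts = "all"
  expect_true(any(tab$group1 == "subtype1" & tab$group2 == "subtype2"))
})

test_that("inclusion rule excludes proteins with < 5 observations in a group", {
  fx <- profiling_fixture()
  g2 <- names(fx$labels)[fx$labels == 2]
  fx$norm$values["P2", g2[-(1:4)]] <- NA  # leave exactly 4 subtype-2 values
  tab <- differential_abundance(fx$norm, fx$labels, fx$meta)
  p2 <- tab[tab$protein == "P2", ]
  expect_true(all(!p2$included))
  expect_true(all(is.na(p2$effect)))
  expect_match(p2$reason[1], "fewer_than_5")
  expect_true(all(tab[tab$protein == "P1", "included"]))
})

test_that("covariate adjustment leaves effects unchanged for balanced covariates", {
  fx <- profiling_fixture(seed = 43)
  plain <- differential_abundance(fx$norm, fx$labels, fx$meta)
  adj <- differential_abundance(fx$norm, fx$labels, fx$meta,
                                covariates = c("age", "sex"))
  key <- c("protein", "group1", "group2")
  m <- merge(plain, adj, by = key)
  # age/sex were drawn independently of group: effects agree closely
  expect_lt(max(abs(m$effect.x - m$effect.y)), 0.35)
  expect_gt(cor(m$effect.x, m$effect.y), 0.98)
  # with a constant covariate the fit is rank-deficient -> flagged, not fatal
  fx$meta$age <- 65
  cst <- differential_abundance(fx$norm, fx$labels, fx$meta,
                                covariates = "age")
  expect_true(all(cst$reason[!cst$included] == "rank_deficient_design"))
})

test_that("estimated marginal means reduce to group means and resist centering", {
  fx <- profiling_fixture(seed = 47)
  ids <- colnames(fx$norm$values)
  group <- factor(ifelse(ids %in% names(fx$labels),
                         paste0("subtype", fx$labels[ids]), "control"))
  dat <- data.frame(y = fx$norm$values["P1", ], group = group,
                    age = fx$meta$age[match(ids, fx$meta$sample_id)])
  fit0 <- lm(y ~ group, dat)
  emm0 <- estimated_marginal_means(fit0, "group", dat)
  expect_equal(emm0[["control"]],
               mean(dat$y[dat$group == "control"]), tolerance = 1e-10)
  fit1 <- lm(y ~ group + age, dat)
  emm1 <- estimated_marginal_means(fit1, "group", dat)
  dat2 <- dat
  dat2$age <- dat2$age - mean(dat2$age)    # centering must not move contrasts
  fit2 <- lm(y ~ group + age, dat2)
  emm2 <- estimated_marginal_means(fit2, "group", dat2)
  expect_equal(diff(emm1), diff(emm2), tolerance = 1e-10)
})

test_that("hypergeometric enrichment matches hand value and pmf enumeration", {
  # universe of 4, hits 2, term exactly the hits -> p = 1/6
  tab <- hypergeometric_enrichment(c("a", "b"), c("a", "b", "c", "d"),
                                   list(t1 = c("a", "b")))
  expect_equal(tab$p, 1 / 6, tolerance = 1e-12)
  # disjoint term: overlap 0 is the minimum -> p = 1
  tab0 <- hypergeometric_enrichment(c("a"), c("a", "b", "c", "d"),
                                    list(t1 = c("b", "c")))
  expect_equal(tab0$p, 1, tolerance = 1e-12)
  expect_error(hypergeometric_enrichment("x", c("a", "b"), list(t = "a")),
               "subset of the universe")
  expect_error(hypergeometric_enrichment(character(0), character(0),
                                         list(t = "a")), "empty universe")
  withr::with_seed(53, {
    for (i in 1:100) {
      uni <- paste0("g", 1:sample(8:20, 1))
      hits <- sample(uni, sample(1:5, 1))
      term <- sample(uni, sample(1:6, 1))
      p <- hypergeometric_enrichment(hits, uni, list(tt = term))$p
      k <- length(intersect(hits, term))
      expect_equal(p, oracle_hyper_tail(k, length(hits),
                                        length(uni) - length(hits),
                                        length(term)),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the hand example and reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
  withr::with_seed(59, {
    for (i in 1:100) {
      p <- runif(sample(1:40, 1))
      q <- bh_fdr(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
    }
  })
})

test_that("a planted signature set is the most enriched among random sets", {
  withr::with_seed(61, {
    uni <- paste0("g", 1:200)
    signature <- sample(uni, 25)
    # hits: most of the signature plus background noise
    hits <- unique(c(sample(signature, 20), sample(setdiff(uni, signature), 10)))
    p_sig <- hypergeometric_enrichment(hits, uni, list(s = signature))$p
    p_rand <- replicate(100, {
      hypergeometric_enrichment(hits, uni, list(r = sample(uni, 25)))$p
    })
    expect_true(p_sig < min(p_rand))
  })
})

test_that("null contrasts reject at the nominal rate", {
  withr::with_seed(71, {
    n_ctrl <- 30
    n_ad <- 60
    ids <- c(sprintf("c%02d", 1:n_ctrl), sprintf("a%02d", 1:n_ad))
    labels <- stats::setNames(rep(1:2, each = n_ad / 2), ids[-(1:n_ctrl)])
    meta <- read_metadata(data.frame(
      sample_id = ids, group = rep(c("control", "AD"), c(n_ctrl, n_ad)),
      cognitive_state = rep(c("NC", "dementia"), c(n_ctrl, n_ad)),
      tau_status = rep(c("normal", "abnormal"), c(n_ctrl, n_ad))))
    values <- matrix(rnorm(400 * length(ids)), 400,
                     dimnames = list(sprintf("P%03d", 1:400), ids))
  })
  norm <- structure(list(values = values,
                         excluded = data.frame(protein = character(0),
                                               reason = character(0))),
                    class = "normalized_matrix")
  tab <- differential_abundance(norm, labels, meta)
  rate <- mean(tab$p < 0.05, na.rm = TRUE)
  m <- sum(!is.na(tab$p))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m) + 0.01)
})
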