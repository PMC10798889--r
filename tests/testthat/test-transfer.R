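test_that("panel matching nests by descending overlap", {
  disc <- paste0("P", 1:10)
  sets <- list(big = paste0("P", 1:9), small = paste0("P", c(1:4, 11)),
               mid = paste0("P", 1:6))
  panels <- match_panels(disc, sets)
  expect_s3_class(panels, "panel_set")
  expect_identical(names(panels), c("big", "mid", "small"))
  expect_identical(panels$big, paste0("P", 1:9))
  expect_identical(panels$mid, paste0("P", 1:6))
  expect_identical(panels$small, paste0("P", 1:4))
  sizes <- vapply(panels, length, integer(1))
  expect_true(all(diff(sizes) <= 0))  # non-increasing along the nesting
  # identical protein set -> single panel equals the discovery set
  one <- match_panels(disc, list(same = disc))
  expect_identical(one$same, disc)
  expect_error(match_panels(disc, list(alien = "Q1")), "alien")
})

test_that("replication scaling anchors to the cohort's own controls", {
  withr::with_seed(63, {
    ids <- c(paste0("c", 1:6), paste0("a", 1:6))
    meta <- read_metadata(data.frame(
      sample_id = ids, group = rep(c("control", "AD"), each = 6),
      cognitive_state = rep(c("NC", "dementia"), each = 6),
      tau_status = rep(c("normal", "abnormal"), each = 6)))
    m <- matrix(rnorm(3 * 12, 10), 3, dimnames = list(paste0("P", 1:3), ids))
  })
  z <- scale_replication(m, meta)
  ctrl <- paste0("c", 1:6)
  expect_equal(unname(rowMeans(z[, ctrl])), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z[, ctrl], 1, sd)), rep(1, 3), tolerance = 1e-12)
  # a cohort-wide multiplicative raw factor (additive in log2) cancels exactly
  expect_equal(scale_replication(m + 3, meta), z, tolerance = 1e-12)
  flat <- m
  flat[2, ctrl] <- 7
  expect_warning(z2 <- scale_replication(flat, meta), "zero control s.d.")
  expect_false("P2" %in% rownames(z2))
})

test_that("SCUT balances classes to the mean count", {
  withr::with_seed(67, {
    x <- rbind(matrix(rnorm(10 * 2), 10), matrix(rnorm(50 * 2, 4), 50))
    y <- rep(c("a", "b"), c(10, 50))
  })
  bal <- scut_balance(x, y, seed = 5)
  expect_equal(as.integer(table(bal$labels)), c(30L, 30L))  # mean rule
  # synthetic minority points lie on segments between original members
  minority <- bal$features[bal$labels == "a", ][11:30, , drop = FALSE]
  orig <- x[y == "a", ]
  hull_ok <- apply(minority, 1, function(p) {
    p[1] >= min(orig[, 1]) - 1e-9 && p[1] <= max(orig[, 1]) + 1e-9 &&
      p[2] >= min(orig[, 2]) - 1e-9 && p[2] <= max(orig[, 2]) + 1e-9
  })
  expect_true(all(hull_ok))
  # each synthetic point is collinear with some pair of original points
  on_segment <- apply(minority, 1, function(p) {
    for (i in seq_len(nrow(orig) - 1)) {
      for (j in (i + 1):nrow(orig)) {
        v <- orig[j, ] - orig[i, ]
        w <- p - orig[i, ]
        t1 <- if (abs(v[1]) > 1e-12) w[1] / v[1] else w[2] / v[2]
        if (t1 >= -1e-9 && t1 <= 1 + 1e-9 &&
            max(abs(w - t1 * v)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))
  # undersampled majority members are original rows
  maj <- bal$features[bal$labels == "b", ]
  expect_true(all(apply(maj, 1, function(p) {
    any(colSums(abs(t(x[y == "b", ]) - p)) < 1e-12)
  })))
  # already balanced input keeps sizes
  bal2 <- scut_balance(x[1:20, ], rep(c("a", "b"), each = 10), seed = 5)
  expect_equal(as.integer(table(bal2$labels)), c(10L, 10L))
  expect_error(scut_balance(x, rep(c("a", "b"), c(1, 59))), ">= 2 members")
  # determinism
  bal3 <- scut_balance(x, y, seed = 5)
  expect_identical(bal$features, bal3$features)
})

transfer_fixture <- function(seed = 71, n_per = 30, p = 12, shift = 4) {
  withr::with_seed(seed, {
    k <- 3
    centers <- matrix(rnorm(k * p), k) * shift
    x <- do.call(rbind, lapply(1:k, function(c2) {
      matrix(rnorm(n_per * p), n_per) + matrix(centers[c2, ], n_per, p,
                                               byrow = TRUE)
    }))
    colnames(x) <- paste0("P", 1:p)
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    y <- rep(paste0("subtype", 1:k), each = n_per)
    list(x = x, y = y)
  })
}

test_that("random forests learn separable subtypes and are deterministic", {
  fx <- transfer_fixture()
  panels <- match_panels(colnames(fx$x), list(all = colnames(fx$x)))
  ens <- train_subtype_classifiers(fx$x, fx$y, panels, n_repeats = 4,
                                   ntree = 120, seed = 9)
  expect_gte(held_out_accuracy(ens)[["all"]], 0.9)
  ens2 <- train_subtype_classifiers(fx$x, fx$y, panels, n_repeats = 4,
                                    ntree = 120, seed = 9)
  expect_identical(vapply(ens$repeats, `[[`, numeric(1), "accuracy"),
                   vapply(ens2$repeats, `[[`, numeric(1), "accuracy"))
  pred <- predict_subtypes(ens, fx$x)
  pred2 <- predict_subtypes(ens2, fx$x)
  expect_identical(pred$probabilities, pred2$probabilities)
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, nrow(fx$x)),
               tolerance = 1e-12)
  expect_gte(mean(pred$labels == fx$y), 0.95)
  # argmax semantics
  expect_identical(unname(pred$labels),
                   colnames(pred$probabilities)[max.col(pred$probabilities,
                                                        ties.method = "first")])
})

test_that("prediction uses the largest panel covered by the replication set", {
  fx <- transfer_fixture(seed = 73)
  panels <- match_panels(colnames(fx$x),
                         list(rich = colnames(fx$x),
                              poor = colnames(fx$x)[1:5]))
  ens <- train_subtype_classifiers(fx$x, fx$y, panels, n_repeats = 2,
                                   ntree = 80, seed = 11)
  pred_poor <- predict_subtypes(ens, fx$x[, 1:5])
  expect_identical(pred_poor$panel, "poor")
  pred_rich <- predict_subtypes(ens, fx$x)
  expect_identical(pred_rich$panel, "rich")
  expect_error(predict_subtypes(ens, fx$x[, 1:3]), "no panel")
})

test_that("label-permuted training yields chance-level accuracy", {
  fx <- transfer_fixture(seed = 79, n_per = 40)
  y_perm <- withr::with_seed(80, sample(fx$y))
  panels <- match_panels(colnames(fx$x), list(all = colnames(fx$x)))
  ens <- train_subtype_classifiers(fx$x, y_perm, panels, n_repeats = 5,
                                   ntree = 100, seed = 13)
  acc <- held_out_accuracy(ens)[["all"]]
  expect_lt(abs(acc - 1 / 3), 0.12)
})
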