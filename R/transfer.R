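# Cross-cohort subtype transfer: nested protein panels maximizing overlap
# with the replication cohorts, class-balanced (SCUT: SMOTE oversampling +
# clustered undersampling) random-forest ensembles trained on repeated 80/20
# splits of the discovery cohort, and max-probability label assignment in
# replication cohorts scaled to their own controls.

#' Nested protein panels matched to replication cohorts
#'
#' Starting from the replication set with the largest overlap with the
#' discovery proteins (ties broken lexicographically by cohort name), each
#' panel is the running intersection, so panels are nested with
#' non-increasing size; at most four panels are formed. A replication cohort
#' is later served by the largest panel fully contained in its protein set.
#'
#' @param discovery_proteins character vector.
#' @param replication_protein_sets named list of character vectors.
#' @param max_panels cap on the number of panels (default 4).
#' @return An object of class `panel_set`: named list of protein panels in
#'   nesting order.
#' @export
match_panels <- function(discovery_proteins, replication_protein_sets,
                         max_panels = 4) {
  stopifnot(length(discovery_proteins) > 0,
            length(replication_protein_sets) > 0)
  nms <- names(replication_protein_sets)
  if (is.null(nms)) {
    nms <- paste0("cohort", seq_along(replication_protein_sets))
    names(replication_protein_sets) <- nms
  }
  overlap <- vapply(replication_protein_sets, function(s) {
    length(intersect(discovery_proteins, s))
  }, integer(1))
  ord <- order(-overlap, nms)
  panels <- list()
  current <- discovery_proteins
  for (cohort in nms[ord]) {
    current <- intersect(current, replication_protein_sets[[cohort]])
    if (!length(current)) {
      stop(sprintf("empty panel intersection at cohort '%s'", cohort),
           call. = FALSE)
    }
    panels[[cohort]] <- current
    if (length(panels) >= max_panels) break
  }
  structure(panels, class = "panel_set")
}

#' Scale a replication matrix to its own controls
#'
#' Per-protein z-scaling of log2 values anchored on the replication cohort's
#' own control samples, so cohort-wide multiplicative batch factors cancel
#' exactly. Proteins with zero control s.d. are dropped with a warning.
#'
#' @param values numeric matrix of log2 protein values
#'   (proteins x samples), or a `normalized_matrix` already on the control-z
#'   scale (returned unchanged).
#' @param meta a `sample_metadata` naming the cohort's controls.
#' @return A proteins x samples matrix of control-z values.
#' @export
scale_replication <- function(values, meta) {
  if (inherits(values, "normalized_matrix")) return(values$values)
  meta <- read_metadata(meta)
  ctrl <- intersect(colnames(values), meta$sample_id[meta$group == "control"])
  if (length(ctrl) < 2) stop("need >= 2 replication controls", call. = FALSE)
  mu <- rowMeans(values[, ctrl, drop = FALSE], na.rm = TRUE)
  sd <- apply(values[, ctrl, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  bad <- is.na(sd) | sd == 0
  if (any(bad)) {
    warning(sprintf("%d protein(s) with zero control s.d. dropped", sum(bad)),
            call. = FALSE)
  }
  (values[!bad, , drop = FALSE] - mu[!bad]) / sd[!bad]
}

# k nearest same-class neighbours (excluding self) by Euclidean distance.
# Always returns an nrow(x) x k matrix (apply() drops dimensions at k = 1).
knn_indices <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  if (is.null(dim(nn))) nn <- matrix(nn, nrow = 1)
  t(nn)
}

#' SCUT class balancing (SMOTE up, clustered undersampling down)
#'
#' Every class is brought to the mean of the original class counts
#' (rounded): minority classes are oversampled with SMOTE (synthetic points
#' drawn uniformly on segments between a member and one of its `k` nearest
#' same-class neighbours); majority classes are undersampled by k-means
#' clustering into the target number of clusters and keeping the member
#' nearest each cluster center.
#'
#' @param features numeric matrix (samples x features).
#' @param labels class labels, one per row; every class needs >= 2 members.
#' @param k SMOTE neighbourhood size (default 5).
#' @param seed integer seed.
#' @return A list with balanced `features` and `labels`.
#' @export
scut_balance <- function(features, labels, k = 5, seed = 1L) {
  features <- as.matrix(features)
  if (anyNA(features)) {
    stop("features contain missing values; balance complete panels only",
         call. = FALSE)
  }
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2)) stop("every class needs >= 2 members (SMOTE undefined)",
                            call. = FALSE)
  target <- round(mean(counts))
  with_seed(seed, {
    parts <- lapply(names(counts), function(cl) {
      x <- features[labels == cl, , drop = FALSE]
      n <- nrow(x)
      if (n == target) {
        x
      } else if (n < target) {
        kk <- min(k, n - 1)
        nn <- knn_indices(x, kk)
        extra <- t(vapply(seq_len(target - n), function(j) {
          i <- sample.int(n, 1)
          nb <- nn[i, sample.int(kk, 1)]
          u <- stats::runif(1)
          x[i, ] + u * (x[nb, ] - x[i, ])
        }, numeric(ncol(x))))
        rbind(x, extra)
      } else {
        km <- suppressWarnings(
          stats::kmeans(x, centers = target, iter.max = 50, nstart = 1))
        keep <- vapply(seq_len(target), function(c2) {
          members <- which(km$cluster == c2)
          d <- rowSums((x[members, , drop = FALSE] -
                          matrix(km$centers[c2, ], length(members),
                                 ncol(x), byrow = TRUE))^2)
          members[which.min(d)]
        }, integer(1))
        x[keep, , drop = FALSE]
      }
    })
    list(features = do.call(rbind, parts),
         labels = rep(names(counts), each = target))
  })
}

#' Train class-balanced random-forest ensembles on nested panels
#'
#' Per repeat: one stratagem-free random 80/20 split (re-drawn, at most 10
#' times, if a subtype is absent from training) shared across all panels;
#' the training portion is SCUT-balanced; one forest of `ntree` trees is
#' grown per panel (`mtry = floor(sqrt(p))`, unlimited depth); held-out
#' accuracy is recorded per panel.
#'
#' @param features numeric matrix (samples x proteins), e.g. t() of a
#'   normalized matrix restricted to AD samples.
#' @param labels subtype labels, one per row (named or aligned by order).
#' @param panels a [match_panels()] `panel_set` (or list of protein vectors).
#' @param n_repeats number of train/test repeats (default 100).
#' @param ntree trees per forest (default 1000).
#' @param seed integer seed.
#' @param train_fraction training fraction of each split (default 0.8).
#' @return An object of class `classifier_ensemble` with per-repeat forests,
#'   held-out accuracies, class levels, panels and configuration.
#' @export
train_subtype_classifiers <- function(features, labels, panels,
                                      n_repeats = 100, ntree = 1000,
                                      seed = 1L, train_fraction = 0.8) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (!is.null(names(labels)) && !is.null(rownames(features))) {
    if (!setequal(names(labels), rownames(features))) {
      stop("label names do not match feature rownames", call. = FALSE)
    }
    labels <- labels[rownames(features)]  # align by sample id, not position
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y <- match(labels, classes) - 1L
  if (!inherits(panels, "panel_set")) class(panels) <- "panel_set"
  for (pn in names(panels)) {
    miss <- setdiff(panels[[pn]], colnames(features))
    if (length(miss)) {
      stop(sprintf("panel '%s' proteins absent from features: %s", pn,
                   paste(utils::head(miss, 3), collapse = ", ")), call. = FALSE)
    }
  }
  n <- nrow(features)
  n_train <- round(train_fraction * n)
  repeats <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      train_idx <- NULL
      for (try in 1:10) {
        cand <- sample.int(n, n_train)
        tab <- table(labels[cand])
        # every subtype present with >= 2 members (SMOTE needs 2)
        if (setequal(names(tab), classes) && all(tab >= 2)) {
          train_idx <- cand
          break
        }
      }
      if (is.null(train_idx)) {
        stop("could not draw a training split containing every subtype",
             call. = FALSE)
      }
      test_idx <- setdiff(seq_len(n), train_idx)
      bal_seed <- sample.int(.Machine$integer.max, 1)
      rf_seed <- sample.int(.Machine$integer.max, 1)
      forests <- list()
      accuracy <- numeric(0)
      for (pn in names(panels)) {
        cols <- panels[[pn]]
        bal <- scut_balance(features[train_idx, cols, drop = FALSE],
                            labels[train_idx], seed = bal_seed)
        ytr <- match(bal$labels, classes) - 1L
        forest <- .rf_train(bal$features, ytr, length(classes),
                            as.integer(ntree),
                            max(1L, floor(sqrt(length(cols)))), 1L,
                            as.double(rf_seed))
        votes <- .rf_votes(forest, features[test_idx, cols, drop = FALSE],
                           length(classes))
        pred <- classes[max.col(votes, ties.method = "first")]
        forests[[pn]] <- forest
        accuracy[pn] <- mean(pred == labels[test_idx])
      }
      list(train_idx = train_idx, forests = forests, accuracy = accuracy)
    })
  })
  structure(list(repeats = repeats, classes = classes, panels = panels,
                 ntree = ntree, n_repeats = n_repeats, seed = seed),
            class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  acc <- held_out_accuracy(x)
  cat(sprintf("classifier_ensemble: %d repeats x %d panels, ntree = %d\n",
              x$n_repeats, length(x$panels), x$ntree))
  print(round(acc, 3))
  invisible(x)
}

#' Mean held-out accuracy per panel
#' @param ensemble a `classifier_ensemble`.
#' @return Named numeric vector, one entry per panel.
#' @export
held_out_accuracy <- function(ensemble) {
  accs <- t(vapply(ensemble$repeats, `[[`,
                   numeric(length(ensemble$panels)), "accuracy"))
  colMeans(matrix(accs, ncol = length(ensemble$panels),
                  dimnames = list(NULL, names(ensemble$panels))))
}

#' Predict subtypes in a replication cohort
#'
#' Uses the largest panel fully contained in the replication protein set;
#' class probabilities are the mean of per-repeat forest vote fractions and
#' each sample is assigned the subtype with the highest probability (ties to
#' the lowest class index, flagged).
#'
#' @param ensemble a `classifier_ensemble`.
#' @param features replication matrix (samples x proteins, control-z scale,
#'   see [scale_replication()]).
#' @param aggregate `"mean"` (default, over all repeats) or `"best"`
#'   (single repeat with highest held-out accuracy).
#' @return A list with `labels`, `probabilities` (rows sum to 1), `panel`
#'   (name used), `ties`.
#' @export
predict_subtypes <- function(ensemble, features,
                             aggregate = c("mean", "best")) {
  aggregate <- match.arg(aggregate)
  features <- as.matrix(features)
  available <- colnames(features)
  usable <- names(ensemble$panels)[vapply(ensemble$panels, function(p) {
    all(p %in% available)
  }, logical(1))]
  if (!length(usable)) stop("no panel is covered by the replication proteins",
                            call. = FALSE)
  sizes <- vapply(ensemble$panels[usable], length, integer(1))
  panel_name <- usable[which.max(sizes)]
  cols <- ensemble$panels[[panel_name]]
  K <- length(ensemble$classes)
  reps <- ensemble$repeats
  if (aggregate == "best") {
    best <- which.max(vapply(reps, function(r) r$accuracy[[panel_name]],
                             numeric(1)))
    reps <- reps[best]
  }
  probs <- matrix(0, nrow(features), K)
  for (r in reps) {
    probs <- probs + .rf_votes(r$forests[[panel_name]],
                               features[, cols, drop = FALSE], K)
  }
  probs <- probs / length(reps)
  dimnames(probs) <- list(rownames(features), ensemble$classes)
  idx <- max.col(probs, ties.method = "first")
  ties <- apply(probs, 1, function(p) sum(p == max(p)) > 1)
  labels <- stats::setNames(ensemble$classes[idx], rownames(features))
  list(labels = labels, probabilities = probs, panel = panel_name,
       ties = names(which(ties)))
}
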