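# Consensus NMF subtyping. Selected proteins are rescaled into [1, 2],
# factorized with multiplicative KL updates over repeated random restarts,
# and the number of subtypes is chosen by balancing the cophenetic
# coefficient, a twofold fit improvement over a randomized reference, and a
# silhouette above 0.5 -- the same three-criterion rule used for the
# discovery cohort.

#' Rescale each protein into \[1, 2\]
#'
#' Per-protein affine map `x -> 1 + (x - min) / (max - min)`, keeping relative
#' values intact while making the matrix strictly positive for NMF.
#' Constant proteins map to 1.5.
#'
#' @param norm a `normalized_matrix` or plain numeric matrix
#'   (proteins x samples).
#' @param proteins optional subset of protein ids (rows).
#' @param samples optional subset of sample ids (columns).
#' @return A numeric matrix with per-row values in \[1, 2\].
#' @export
scale_to_1_2 <- function(norm, proteins = NULL, samples = NULL) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.null(proteins)) values <- values[proteins, , drop = FALSE]
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  if (nrow(values) == 0) stop("empty protein subset", call. = FALSE)
  if (anyNA(values)) stop("scale_to_1_2 requires complete values", call. = FALSE)
  t(apply(values, 1, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(1.5, length(x)))
    1 + (x - rng[1]) / (rng[2] - rng[1])
  }))
}

#' Repeated seeded NMF runs
#'
#' Each run starts from an independent random uniform initialization (drawn
#' from the R RNG under `seed`) and iterates multiplicative updates
#' minimizing generalized KL divergence (or squared Frobenius error with
#' `objective = "frobenius"`) until the relative objective change falls
#' below `tol` or `max_iter` is reached. The objective is non-increasing
#' across iterations by construction of the updates.
#'
#' @param X strictly positive numeric matrix (features x samples).
#' @param k factorization rank, `2 <= k < min(dim(X))` (k = 1 allowed for
#'   fit baselines).
#' @param n_runs number of random restarts.
#' @param seed integer seed.
#' @param max_iter,tol,check_every convergence controls.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @return A list of runs, each with `W`, `H`, `objective`, `trace`,
#'   `converged`, `iterations`.
#' @export
nmf_factorize <- function(X, k, n_runs = 30, seed = 1L, max_iter = 2000,
                          tol = 1e-6, check_every = 10,
                          objective = c("kl", "frobenius"), warn = TRUE) {
  objective <- match.arg(objective)
  if (any(X <= 0)) stop("X must be strictly positive for NMF", call. = FALSE)
  if (k < 1 || k >= min(dim(X))) stop("k out of range", call. = FALSE)
  n <- nrow(X)
  m <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  with_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      W0 <- matrix(stats::runif(n * k, min = 0.1, max = 1), n, k) * scale0
      H0 <- matrix(stats::runif(k * m, min = 0.1, max = 1), k, m) * scale0
      run <- .nmf_run(X, W0, H0, as.integer(max_iter), tol,
                      as.integer(check_every), objective == "frobenius")
      if (!run$converged && warn) {
        warning(sprintf("NMF run %d (k = %d) did not converge in %d iterations",
                        r, k, max_iter), call. = FALSE)
      }
      dimnames(run$W) <- list(rownames(X), NULL)
      dimnames(run$H) <- list(NULL, colnames(X))
      run
    })
  })
}

run_labels <- function(run) apply(run$H, 2, which.max)

#' Consensus matrix and cophenetic coefficient over NMF runs
#'
#' `C[i, j]` is the fraction of runs in which samples *i* and *j* share the
#' argmax component of `H`. The cophenetic coefficient is the Pearson
#' correlation between the consensus distances `1 - C` and the cophenetic
#' distances of average-linkage hierarchical clustering on `1 - C`; perfectly
#' stable runs give 1 by convention.
#'
#' @param runs a list of runs from [nmf_factorize()] (at least 2).
#' @return A list with `C` (samples x samples) and `cophenetic`.
#' @export
consensus_and_cophenetic <- function(runs) {
  if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
  labels <- vapply(runs, run_labels, integer(ncol(runs[[1]]$H)))
  m <- nrow(labels)
  C <- matrix(0, m, m)
  for (r in seq_len(ncol(labels))) {
    C <- C + outer(labels[, r], labels[, r], "==")
  }
  C <- C / ncol(labels)
  dimnames(C) <- list(colnames(runs[[1]]$H), colnames(runs[[1]]$H))
  d <- stats::as.dist(1 - C)
  coph <- if (stats::sd(d) == 0) {
    1  # all runs identical (or identically unstable): perfect agreement
  } else {
    hc <- stats::hclust(d, method = "average")
    suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  }
  list(C = C, cophenetic = coph)
}

#' Silhouette score
#'
#' Mean over samples of `(b - a) / max(a, b)`, with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster. Members of singleton clusters contribute 0.
#'
#' @param labels cluster labels (>= 2 distinct clusters).
#' @param D symmetric distance matrix with zero diagonal.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  stopifnot(nrow(D) == n, ncol(D) == n)
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters", call. = FALSE)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)  # singleton
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(cl[cl != labels[i]], function(c2) {
      mean(D[i, labels == c2])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Row-wise (per-protein) independent permutation of the sample values:
# the randomized reference used for the fit-improvement ratio.
permute_rows <- function(X, seed) {
  with_seed(seed, {
    Xp <- t(apply(X, 1, sample))
    dimnames(Xp) <- dimnames(X)
    Xp
  })
}

#' Consensus NMF with three-criterion model selection
#'
#' For each candidate rank k the procedure computes (i) the cophenetic
#' coefficient of the consensus matrix over `n_runs` restarts, (ii) the
#' silhouette (on the consensus distance `1 - C`, with consensus-derived
#' labels) and (iii) the fit-improvement ratio
#' `rho(k) = (fit(k-1) - fit(k)) / (fit_rand(k-1) - fit_rand(k))`, where
#' `fit` is the best-run objective on `X` and `fit_rand` the same on a
#' per-protein permuted copy of `X`. Ranks with silhouette > 0.5 and
#' `rho >= 2` are admissible; among them the rank maximizing the cophenetic
#' coefficient is selected (ties to the smallest k). With no admissible rank,
#' `selected_k` is `NA` and the full metric table is returned for the caller
#' to judge.
#'
#' @param X strictly positive matrix (proteins x samples), e.g. from
#'   [scale_to_1_2()].
#' @param k_range candidate ranks (default 2:10).
#' @param n_runs NMF restarts per rank (default 30).
#' @param seed integer seed.
#' @param n_runs_random restarts for the randomized-reference fits. Only the
#'   best-run objective enters the improvement ratio (no consensus statistic
#'   is computed on permuted data) and the permuted objective landscape is
#'   flat, so the best-of-m estimate stabilizes with fewer restarts; default
#'   `max(5, ceiling(n_runs / 2))`.
#' @param ... further arguments for [nmf_factorize()].
#' @return An object of class `subtype_model`: list with `metrics`
#'   (per-k data.frame), `selected_k`, `consensus` (for the selected k),
#'   `best_run` (W, H), `patient_labels`, `protein_labels`, `k_range`,
#'   `runs` (per-k best objectives) and `seed`.
#' @export
select_k <- function(X, k_range = 2:10, n_runs = 30, seed = 1L,
                     n_runs_random = max(5, ceiling(n_runs / 2)), ...) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 2, max(k_range) < min(dim(X)))
  nonconverged <- 0L
  Xr <- permute_rows(X, derive_seed(seed, 7L))
  k_all <- c(min(k_range) - 1L, k_range)
  fit <- fit_rand <- stats::setNames(rep(NA_real_, length(k_all)),
                                     as.character(k_all))
  coph <- sil <- stats::setNames(rep(NA_real_, length(k_range)),
                                 as.character(k_range))
  consensus <- list()
  best_runs <- list()
  for (k in k_all) {
    runs <- nmf_factorize(X, k, n_runs = n_runs,
                          seed = derive_seed(seed, 11L * k), warn = FALSE, ...)
    nonconverged <- nonconverged +
      sum(!vapply(runs, `[[`, logical(1), "converged"))
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    fit[as.character(k)] <- min(objs)
    if (k %in% k_range) {
      best_runs[[as.character(k)]] <- runs[[which.min(objs)]]
      cc <- consensus_and_cophenetic(runs)
      coph[as.character(k)] <- cc$cophenetic
      consensus[[as.character(k)]] <- cc$C
      lab <- stats::cutree(stats::hclust(stats::as.dist(1 - cc$C),
                                         method = "average"), k = k)
      sil[as.character(k)] <- if (length(unique(lab)) < 2) {
        NA_real_
      } else {
        silhouette_score(lab, 1 - cc$C)
      }
    }
    runs_r <- nmf_factorize(Xr, k, n_runs = n_runs_random,
                            seed = derive_seed(seed, 13L * k), warn = FALSE,
                            ...)
    fit_rand[as.character(k)] <- min(vapply(runs_r, `[[`, numeric(1),
                                            "objective"))
  }
  rho <- vapply(k_range, function(k) {
    dk <- fit[as.character(k - 1L)] - fit[as.character(k)]
    dr <- fit_rand[as.character(k - 1L)] - fit_rand[as.character(k)]
    if (!is.finite(dr) || dr <= 0) {
      if (is.finite(dk) && dk > 0) Inf else NA_real_
    } else {
      dk / dr
    }
  }, numeric(1))
  metrics <- data.frame(k = k_range, fit = fit[as.character(k_range)],
                        fit_rand = fit_rand[as.character(k_range)],
                        cophenetic = coph, silhouette = sil,
                        improvement_ratio = rho, row.names = NULL)
  admissible <- !is.na(metrics$silhouette) & metrics$silhouette > 0.5 &
    !is.na(metrics$improvement_ratio) & metrics$improvement_ratio >= 2
  selected_k <- if (any(admissible)) {
    adm <- metrics[admissible, ]
    adm$k[which.max(adm$cophenetic)]  # ties: which.max takes the smallest k
  } else {
    NA_integer_
  }
  model <- structure(
    list(metrics = metrics, admissible = admissible, selected_k = selected_k,
         consensus = if (!is.na(selected_k)) consensus[[as.character(selected_k)]],
         best_run = if (!is.na(selected_k)) best_runs[[as.character(selected_k)]],
         best_runs = best_runs, k_range = k_range, seed = seed,
         n_nonconverged = nonconverged),
    class = "subtype_model")
  if (!is.na(selected_k)) {
    clusters <- assign_dual_clusters(model)
    model$patient_labels <- clusters$patient_labels
    model$protein_labels <- clusters$protein_labels
    model$ties <- clusters$ties
  }
  model
}

#' Dual cluster assignment from the selected NMF solution
#'
#' Patients are labeled by the argmax component of their `H` column; proteins
#' by the argmax component of their `W` row. Ties break toward the lowest
#' component index and are recorded.
#'
#' @param model a `subtype_model` with `selected_k` set, or a single NMF run.
#' @return A list with `patient_labels`, `protein_labels` and `ties`.
#' @export
assign_dual_clusters <- function(model) {
  run <- if (inherits(model, "subtype_model")) {
    if (is.na(model$selected_k)) stop("selected_k not set", call. = FALSE)
    model$best_run
  } else {
    model
  }
  patient <- apply(run$H, 2, which.max)
  protein <- apply(run$W, 1, which.max)
  tie_p <- apply(run$H, 2, function(h) sum(h == max(h)) > 1)
  tie_w <- apply(run$W, 1, function(w) sum(w == max(w)) > 1)
  list(patient_labels = patient, protein_labels = protein,
       ties = list(patients = names(which(tie_p)),
                   proteins = names(which(tie_w))))
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype_model\n")
  print(x$metrics, digits = 4)
  cat(sprintf("selected k: %s\n",
              ifelse(is.na(x$selected_k), "none admissible", x$selected_k)))
  invisible(x)
}

#' Discovery pipeline: normalize, screen, subtype
#'
#' Convenience wrapper running [normalize_cohort()],
#' [select_ad_proteins()], [scale_to_1_2()] on the AD samples of the selected
#' panel, and [select_k()].
#'
#' @param intensity an `intensity_matrix`.
#' @param meta a `sample_metadata`.
#' @param alpha screening threshold.
#' @param k_range,n_runs,seed,... passed to [select_k()].
#' @return A list with `norm`, `selection`, `model`.
#' @export
run_discovery_pipeline <- function(intensity, meta, alpha = 0.05,
                                   k_range = 2:10, n_runs = 30, seed = 1L,
                                   ...) {
  meta <- read_metadata(meta)
  norm <- normalize_cohort(intensity, meta)
  selection <- select_ad_proteins(norm, meta, alpha = alpha)
  panel <- selection$protein[selection$selected]
  if (length(panel) < max(k_range) + 1) {
    stop("too few selected proteins for the requested k range", call. = FALSE)
  }
  ad_ids <- intersect(colnames(norm$values),
                      meta$sample_id[meta$group == "AD"])
  X <- scale_to_1_2(norm, proteins = panel, samples = ad_ids)
  model <- select_k(X, k_range = k_range, n_runs = n_runs, seed = seed, ...)
  list(norm = norm, selection = selection, model = model)
}
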