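# Biological characterization of subtypes: per-protein linear-model contrasts
# of each subtype against controls (and against each other) via estimated
# marginal means, optionally adjusted for age and sex, plus generic
# hypergeometric term-set enrichment with BH-FDR control.

#' Estimated marginal means of a factor in a fitted linear model
#'
#' Model-predicted response per factor level with every other covariate held
#' at its observed distribution (numeric covariates effectively at their
#' grand means, factor covariates averaged proportionally): the prediction
#' for level *l* is the average model prediction over the fitted data with
#' the factor set to *l* everywhere.
#'
#' @param fit an `lm` fit.
#' @param factor_name name of the factor term.
#' @param data the data the model was fitted on.
#' @return A named numeric vector of EMMs, one per observed factor level.
#' @export
estimated_marginal_means <- function(fit, factor_name, data) {
  levs <- levels(factor(data[[factor_name]]))
  beta <- stats::coef(fit)
  out <- vapply(levs, function(l) {
    nd <- data
    nd[[factor_name]] <- factor(rep(l, nrow(nd)), levels = levs)
    X <- stats::model.matrix(stats::terms(fit), nd)
    mean(X[, names(beta), drop = FALSE] %*% beta)
  }, numeric(1))
  stats::setNames(out, levs)
}

# EMM contrast (level1 - level2) with its two-tailed p-value from the model's
# error distribution.
emm_contrast <- function(fit, factor_name, data, level1, level2) {
  levs <- levels(factor(data[[factor_name]]))
  rowmean_for <- function(l) {
    nd <- data
    nd[[factor_name]] <- factor(rep(l, nrow(nd)), levels = levs)
    colMeans(stats::model.matrix(stats::terms(fit), nd))
  }
  cvec <- rowmean_for(level1) - rowmean_for(level2)
  beta <- stats::coef(fit)
  cvec <- cvec[names(beta)]
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% stats::vcov(fit) %*% cvec))
  df <- stats::df.residual(fit)
  t <- est / se
  list(estimate = est, se = se,
       p = 2 * stats::pt(-abs(t), df = df))
}

#' Per-protein differential abundance across subtypes
#'
#' Ordinary least squares of protein level on the group factor
#' (control + subtypes), optionally adjusted for covariates; contrasts are
#' estimated-marginal-mean differences (two-tailed). Since the input is
#' control-z-scored, effects are in control-s.d. units. A protein enters a
#' contrast only when every group has at least `min_obs` non-missing
#' observations (default 5); otherwise it is reported with
#' `included = FALSE`. Subtype-level p-values are reported unadjusted:
#' these are post hoc descriptive comparisons.
#'
#' @param norm a `normalized_matrix` (proteins may contain missing values).
#' @param labels named vector of subtype labels for AD samples (names =
#'   sample ids); control samples are taken from `meta`.
#' @param meta a `sample_metadata`.
#' @param covariates optional character vector of metadata columns
#'   (e.g. `c("age", "sex")`).
#' @param contrasts `"vs_control"` for subtype-control contrasts only, or
#'   `"all"` (default) to add subtype-subtype contrasts.
#' @param min_obs per-group inclusion threshold.
#' @return A `data.frame` of class `differential_table` with columns
#'   `protein`, `group1`, `group2`, `effect`, `se`, `p`, `direction`,
#'   `included`, `reason`; attribute `covariates`.
#' @export
differential_abundance <- function(norm, labels, meta, covariates = NULL,
                                   contrasts = c("all", "vs_control"),
                                   min_obs = 5) {
  contrasts <- match.arg(contrasts)
  meta <- read_metadata(meta)
  values <- norm$values
  ctrl_ids <- intersect(colnames(values), meta$sample_id[meta$group == "control"])
  lab_ids <- intersect(colnames(values), names(labels))
  group <- c(stats::setNames(rep("control", length(ctrl_ids)), ctrl_ids),
             stats::setNames(paste0("subtype", labels[lab_ids]), lab_ids))
  ids <- names(group)
  subtypes <- sort(unique(group[group != "control"]))
  if (!length(subtypes)) stop("labels cover no subtype", call. = FALSE)
  pairs <- rbind(
    do.call(rbind, lapply(subtypes, function(s) c(s, "control"))),
    if (contrasts == "all" && length(subtypes) > 1) {
      t(utils::combn(subtypes, 2))
    }
  )
  covar_df <- meta[match(ids, meta$sample_id), covariates, drop = FALSE]
  rows <- vector("list", nrow(values))
  for (i in seq_len(nrow(values))) {
    y <- values[i, ids]
    ok <- !is.na(y)
    if (length(covariates)) ok <- ok & stats::complete.cases(covar_df)
    counts <- table(group[ok])
    enough <- all(c("control", subtypes) %in% names(counts)) &&
      all(counts[c("control", subtypes)] >= min_obs)
    base <- data.frame(protein = rownames(values)[i],
                       group1 = pairs[, 1], group2 = pairs[, 2],
                       stringsAsFactors = FALSE)
    if (!enough) {
      base$effect <- NA_real_
      base$se <- NA_real_
      base$p <- NA_real_
      base$direction <- NA_character_
      base$included <- FALSE
      base$reason <- sprintf("fewer_than_%d_obs_in_a_group", min_obs)
      rows[[i]] <- base
      next
    }
    dat <- data.frame(y = y[ok],
                      group = factor(group[ok],
                                     levels = c("control", subtypes)),
                      covar_df[ok, , drop = FALSE])
    fml <- stats::as.formula(paste("y ~ group",
                                   if (length(covariates)) {
                                     paste("+", paste(covariates, collapse = " + "))
                                   } else ""))
    fit <- stats::lm(fml, data = dat)
    if (anyNA(stats::coef(fit))) {
      base$effect <- NA_real_
      base$se <- NA_real_
      base$p <- NA_real_
      base$direction <- NA_character_
      base$included <- FALSE
      base$reason <- "rank_deficient_design"
      rows[[i]] <- base
      next
    }
    cts <- lapply(seq_len(nrow(pairs)), function(j) {
      emm_contrast(fit, "group", dat, pairs[j, 1], pairs[j, 2])
    })
    base$effect <- vapply(cts, `[[`, numeric(1), "estimate")
    base$se <- vapply(cts, `[[`, numeric(1), "se")
    base$p <- vapply(cts, `[[`, numeric(1), "p")
    base$direction <- ifelse(base$effect > 0, "up",
                             ifelse(base$effect < 0, "down", "none"))
    base$included <- TRUE
    base$reason <- NA_character_
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  attr(out, "covariates") <- covariates
  class(out) <- c("differential_table", "data.frame")
  out
}

#' One-sided hypergeometric over-representation test per term set
#'
#' For each term, tests whether the hit set is enriched in the term's
#' proteins relative to the universe (Fisher's exact one-sided tail);
#' p-values are BH-adjusted across terms.
#'
#' @param hits character vector, a subset of `universe` (e.g. proteins up
#'   in a subtype at p < 0.05).
#' @param universe character vector of all compared proteins.
#' @param term_sets named list of character vectors, or a two-column
#'   data.frame (term, protein). Terms are intersected with the universe;
#'   empty ones are skipped.
#' @return A `data.frame` of class `enrichment_table` with columns `term`,
#'   `hits_in_set`, `set_size`, `hits_total`, `universe_size`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(hits, universe, term_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  if (length(setdiff(hits, universe))) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  if (is.data.frame(term_sets)) {
    term_sets <- split(as.character(term_sets[[2]]),
                       as.character(term_sets[[1]]))
  }
  rows <- lapply(names(term_sets), function(tm) {
    set <- intersect(unique(term_sets[[tm]]), universe)
    if (!length(set)) return(NULL)
    k <- length(intersect(hits, set))
    # P(X >= k), X ~ Hypergeometric(hits in universe, drawn = |set|)
    p <- stats::phyper(k - 1, m = length(hits),
                       n = length(universe) - length(hits),
                       k = length(set), lower.tail = FALSE)
    data.frame(term = tm, hits_in_set = k, set_size = length(set),
               hits_total = length(hits), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), hits_in_set = integer(0),
                      set_size = integer(0), hits_total = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0))
  } else {
    out$q <- bh_fdr(out$p)
  }
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector with values in (0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}
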