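# AD-related protein screening: Kruskal-Wallis rank tests of AD vs control,
# overall and stratified by cognitive state and tau status, with the union of
# any-stratum significance defining the clustering panel.

#' Kruskal-Wallis rank test
#'
#' H computed from mid-ranks with the standard tie correction; the p-value is
#' the upper tail of the chi-squared distribution with (groups - 1) degrees
#' of freedom.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; at least two groups.
#' @return A list with elements `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  g <- unique(groups)
  if (length(g) < 2) stop("kruskal_wallis needs at least 2 groups", call. = FALSE)
  n <- length(values)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p.value = 1))
  }
  r <- rank(values)
  rank_sums <- tapply(r, groups, sum)
  n_g <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(rank_sums^2 / n_g) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / tie_corr
  list(statistic = H,
       p.value = stats::pchisq(H, df = length(g) - 1, lower.tail = FALSE))
}

selection_strata <- function(meta) {
  is_ad <- meta$group == "AD"
  list(
    overall = is_ad | meta$group == "control",
    NC = (is_ad & meta$cognitive_state == "NC") | meta$group == "control",
    MCI = (is_ad & meta$cognitive_state == "MCI") | meta$group == "control",
    dementia = (is_ad & meta$cognitive_state == "dementia") | meta$group == "control",
    tau_normal = (is_ad & meta$tau_status == "normal") | meta$group == "control",
    tau_abnormal = (is_ad & meta$tau_status == "abnormal") | meta$group == "control"
  )
}

#' Select AD-related proteins by stratified Kruskal-Wallis screening
#'
#' Restricts to proteins observed in the complete sample, then tests AD vs
#' control per protein: overall, within each cognitive stage (that AD stratum
#' against the full control group) and within each tau status. A protein is
#' selected when any stratum's p-value falls below `alpha` (unadjusted:
#' this is a screening step, not an inference).
#'
#' @param norm a `normalized_matrix`.
#' @param meta a `sample_metadata`.
#' @param alpha significance threshold in (0, 1\].
#' @return A `data.frame` of class `selection_result` with per-protein H and
#'   p columns per stratum and a logical `selected` column; attributes
#'   `alpha` and `n_selected`.
#' @export
select_ad_proteins <- function(norm, meta, alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"), alpha > 0, alpha <= 1)
  meta <- read_metadata(meta)
  meta <- meta[match(colnames(norm$values), meta$sample_id), ]
  complete <- rowSums(is.na(norm$values)) == 0
  values <- norm$values[complete, , drop = FALSE]
  strata <- selection_strata(meta)
  res <- data.frame(protein = rownames(values), stringsAsFactors = FALSE)
  p_any <- rep(FALSE, nrow(values))
  for (st in names(strata)) {
    idx <- strata[[st]]
    grp <- meta$group[idx]
    if (length(unique(grp[!is.na(grp)])) < 2 || sum(idx & meta$group == "AD") == 0) {
      warning(sprintf("stratum '%s' empty; skipped", st), call. = FALSE)
      res[[paste0("H_", st)]] <- NA_real_
      res[[paste0("p_", st)]] <- NA_real_
      next
    }
    tests <- apply(values[, idx, drop = FALSE], 1, function(v) {
      kw <- kruskal_wallis(v, grp)
      c(kw$statistic, kw$p.value)
    })
    res[[paste0("H_", st)]] <- tests[1, ]
    res[[paste0("p_", st)]] <- tests[2, ]
    p_any <- p_any | (!is.na(tests[2, ]) & (tests[2, ] < alpha | alpha >= 1))
  }
  res$selected <- p_any
  attr(res, "alpha") <- alpha
  attr(res, "n_selected") <- sum(res$selected)
  class(res) <- c("selection_result", "data.frame")
  res
}
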