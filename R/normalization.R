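# Two-step internal reference scaling (IRS) for TMT reporter intensities,
# adapted to the median: (1) equalize channel medians within each plex to the
# reference channels, (2) per-protein cross-plex correction anchored on the
# pooled reference channels, then log2 + z-scaling to the control group.

layout_for <- function(x) x$layout

ref_keys_of <- function(layout, plex) {
  layout$key[layout$plex_id == plex & layout$role == "reference"]
}

#' Within-plex channel scaling to the reference channels
#'
#' Each channel in a plex is multiplied by `target / channel_summary`, where
#' `channel_summary` is the median (or, with `method = "sum"`, the total) of
#' the channel's non-missing protein intensities and `target` is the mean of
#' the two reference channels' summaries in that plex. After this step all
#' channel medians within a plex equal the plex target, removing per-channel
#' loading differences.
#'
#' @param m an `intensity_matrix`.
#' @param method `"median"` (default, outlier-robust) or `"sum"`
#'   (classic grand-total IRS).
#' @return A rescaled `intensity_matrix` with a `"within_plex_factors"`
#'   attribute recording the per-channel correction factors.
#' @export
within_plex_scale <- function(m, method = c("median", "sum")) {
  stopifnot(inherits(m, "intensity_matrix"))
  method <- match.arg(method)
  layout <- m$layout
  values <- m$values
  summarize <- if (method == "median") {
    function(col) stats::median(col, na.rm = TRUE)
  } else {
    function(col) sum(col, na.rm = TRUE)
  }
  factors <- stats::setNames(rep(NA_real_, ncol(values)), colnames(values))
  for (pl in unique(layout$plex_id)) {
    keys <- layout$key[layout$plex_id == pl]
    summ <- vapply(keys, function(k) summarize(values[, k]), numeric(1))
    all_missing <- vapply(keys, function(k) all(is.na(values[, k])), logical(1))
    if (any(all_missing)) {
      warning(sprintf("plex '%s': channel(s) with all-missing values excluded: %s",
                      pl, paste(keys[all_missing], collapse = ", ")),
              call. = FALSE)
      summ[all_missing] <- NA_real_
    }
    rk <- ref_keys_of(layout, pl)
    if (anyNA(summ[rk])) {
      stop(sprintf("plex '%s': reference channel missing or empty", pl),
           call. = FALSE)
    }
    if (any(summ == 0, na.rm = TRUE)) {
      stop(sprintf("plex '%s': degenerate channel with zero %s", pl, method),
           call. = FALSE)
    }
    target <- mean(summ[rk])
    f <- target / summ
    for (k in keys[!all_missing]) {
      values[, k] <- values[, k] * f[[k]]
      factors[[k]] <- f[[k]]
    }
  }
  out <- intensity_matrix(values, layout)
  attr(out, "within_plex_factors") <- factors
  out
}

#' Between-plex internal reference scaling
#'
#' For each protein, the pooled internal-standard level in plex *p* is
#' `r_p`, the arithmetic mean of the two reference-channel values. The plex
#' correction factor is `G / r_p`, with `G` the geometric mean of `r_p` over
#' the plexes in which the protein is observed; all of the protein's channels
#' in plex *p* are multiplied by it. After correction the reference value of
#' a protein is identical (= `G`) in every plex. Proteins with no reference
#' observation in any plex are excluded, mirroring the exclusion of proteins
#' lacking internal standards.
#'
#' @param m an `intensity_matrix`, already scaled with [within_plex_scale()].
#' @return An `intensity_matrix` restricted to proteins with internal
#'   standards, with attributes `"excluded_proteins"` (data.frame of protein,
#'   reason) and `"irs_factors"` (proteins x plexes matrix of correction
#'   factors).
#' @export
between_plex_irs <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  layout <- m$layout
  values <- m$values
  plexes <- unique(layout$plex_id)
  ref1 <- vapply(plexes, function(pl) ref_keys_of(layout, pl)[1], character(1))
  ref2 <- vapply(plexes, function(pl) ref_keys_of(layout, pl)[2], character(1))
  # proteins x plexes matrix of pooled reference values
  refval <- (values[, ref1, drop = FALSE] + values[, ref2, drop = FALSE]) / 2
  colnames(refval) <- plexes
  excluded <- data.frame(protein = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  zero_ref <- which(refval == 0, arr.ind = TRUE)
  if (nrow(zero_ref)) {
    # zero pooled standard in a plex: drop that protein's plex block
    for (i in seq_len(nrow(zero_ref))) {
      prot <- rownames(refval)[zero_ref[i, 1]]
      pl <- plexes[zero_ref[i, 2]]
      values[prot, layout$key[layout$plex_id == pl]] <- NA_real_
      refval[zero_ref[i, 1], zero_ref[i, 2]] <- NA_real_
      excluded <- rbind(excluded, data.frame(
        protein = prot, reason = sprintf("zero_reference_in_%s", pl)))
    }
  }
  no_ref <- rowSums(!is.na(refval)) == 0
  if (any(no_ref)) {
    excluded <- rbind(excluded, data.frame(
      protein = rownames(values)[no_ref], reason = "no_internal_standard"))
  }
  G <- apply(refval, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_real_ else geometric_mean(r)
  })
  factors <- G / refval  # proteins x plexes
  for (p in seq_along(plexes)) {
    keys <- layout$key[layout$plex_id == plexes[p]]
    f <- factors[, p]
    f[is.na(f)] <- 1
    values[, keys] <- values[, keys, drop = FALSE] * f
  }
  keep <- !no_ref
  out <- intensity_matrix(values[keep, , drop = FALSE], layout)
  attr(out, "excluded_proteins") <- excluded
  attr(out, "irs_factors") <- factors[keep, , drop = FALSE]
  out
}

#' Log2 transform and z-scale to the control group
#'
#' Drops the reference channels, maps channels to sample ids, log2-transforms
#' and scales each protein by the mean and s.d. of its non-missing control
#' values, so that positive and negative values mean higher and lower than
#' normal. Proteins with fewer than two non-missing controls or zero control
#' s.d. are excluded with a reason.
#'
#' @param m an `intensity_matrix` (typically after [between_plex_irs()]).
#' @param meta a `sample_metadata` covering the layout's samples.
#' @return An object of class `normalized_matrix`: list with `values`
#'   (proteins x samples, log2 control-z), `excluded` (protein, reason),
#'   `control_stats` (per-protein log2 control mean and s.d.).
#' @export
log2_zscore_to_controls <- function(m, meta) {
  stopifnot(inherits(m, "intensity_matrix"))
  meta <- read_metadata(meta)
  layout <- m$layout
  smp <- layout[layout$role == "sample", ]
  missing_meta <- setdiff(smp$sample_id, meta$sample_id)
  if (length(missing_meta)) {
    stop(sprintf("samples missing from metadata: %s",
                 paste(utils::head(missing_meta, 5), collapse = ", ")),
         call. = FALSE)
  }
  values <- m$values[, smp$key, drop = FALSE]
  colnames(values) <- smp$sample_id
  if (any(values <= 0, na.rm = TRUE)) {
    stop("all intensities must be positive before log2 transform", call. = FALSE)
  }
  lv <- log2(values)
  ctrl_ids <- intersect(meta$sample_id[meta$group == "control"], colnames(lv))
  if (length(ctrl_ids) < 2) stop("need at least 2 control samples", call. = FALSE)
  ctrl <- lv[, ctrl_ids, drop = FALSE]
  n_ok <- rowSums(!is.na(ctrl))
  mu <- rowMeans(ctrl, na.rm = TRUE)
  sd <- apply(ctrl, 1, stats::sd, na.rm = TRUE)
  excluded <- data.frame(protein = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  few <- n_ok < 2
  degenerate <- !few & (is.na(sd) | sd == 0)
  if (any(few)) {
    excluded <- rbind(excluded, data.frame(protein = rownames(lv)[few],
                                           reason = "fewer_than_2_controls"))
  }
  if (any(degenerate)) {
    excluded <- rbind(excluded, data.frame(protein = rownames(lv)[degenerate],
                                           reason = "zero_control_sd"))
  }
  keep <- !few & !degenerate
  z <- (lv[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  structure(list(values = z, excluded = excluded,
                 control_stats = data.frame(protein = rownames(lv)[keep],
                                            mean_log2 = mu[keep],
                                            sd_log2 = sd[keep])),
            class = "normalized_matrix")
}

#' Full normalization pipeline
#'
#' [within_plex_scale()] then [between_plex_irs()] then
#' [log2_zscore_to_controls()], with all exclusion provenance merged.
#'
#' @inheritParams within_plex_scale
#' @inheritParams log2_zscore_to_controls
#' @return A `normalized_matrix` whose `excluded` table covers every stage.
#' @export
normalize_cohort <- function(m, meta, method = c("median", "sum")) {
  step1 <- within_plex_scale(m, method = match.arg(method))
  step2 <- between_plex_irs(step1)
  norm <- log2_zscore_to_controls(step2, meta)
  norm$excluded <- rbind(attr(step2, "excluded_proteins"), norm$excluded)
  norm
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d proteins x %d samples (%d excluded)\n",
              nrow(x$values), ncol(x$values), nrow(x$excluded)))
  invisible(x)
}

#' Write / read a normalized matrix
#' @param norm a `normalized_matrix` (or, for reading, a path).
#' @param path delimited file.
#' @param sep field delimiter.
#' @export
write_normalized_matrix <- function(norm, path, sep = "\t") {
  df <- data.frame(protein = rownames(norm$values), norm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("NA", ""))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(values = values,
                 excluded = data.frame(protein = character(0),
                                       reason = character(0)),
                 control_stats = NULL),
            class = "normalized_matrix")
}
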