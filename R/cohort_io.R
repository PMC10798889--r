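# Tabular I/O and validation for the cohort artifacts: plex layouts, reporter
# intensity matrices, sample metadata, and subtype assignment tables. All
# formats are plain delimited text (TSV canonical, CSV via `sep`).

CHANNEL_SEP <- "."

channel_key <- function(plex_id, channel_id) {
  paste(plex_id, channel_id, sep = CHANNEL_SEP)
}

#' Construct and validate a TMT plex layout
#'
#' A plex layout maps every reporter channel of every 16-channel plex to its
#' role: a study sample (with its sample identifier) or one of the two pooled
#' reference channels used for internal reference scaling.
#'
#' @param plex_id,channel_id,role,sample_id vectors of equal length; `role` is
#'   `"sample"` or `"reference"`; `sample_id` is `NA` for reference channels.
#' @return A `data.frame` of class `plex_layout` with columns
#'   `plex_id`, `channel_id`, `role`, `sample_id` and a `key` column
#'   (`plex.channel`) used as intensity-matrix column names.
#' @export
plex_layout <- function(plex_id, channel_id, role, sample_id = NA_character_) {
  layout <- data.frame(
    plex_id = as.character(plex_id),
    channel_id = as.character(channel_id),
    role = tolower(as.character(role)),
    sample_id = as.character(sample_id),
    stringsAsFactors = FALSE
  )
  if (!all(layout$role %in% c("sample", "reference"))) {
    stop("layout roles must be 'sample' or 'reference'", call. = FALSE)
  }
  layout$sample_id[layout$role == "reference"] <- NA_character_
  layout$key <- channel_key(layout$plex_id, layout$channel_id)
  if (anyDuplicated(layout$key)) {
    stop("duplicated (plex_id, channel_id) pair: a channel is mapped twice",
         call. = FALSE)
  }
  per_plex <- split(layout, layout$plex_id)
  for (pl in per_plex) {
    n_ref <- sum(pl$role == "reference")
    n_smp <- sum(pl$role == "sample")
    if (n_ref != 2L) {
      stop(sprintf("plex '%s' has %d reference channels; exactly 2 required",
                   pl$plex_id[1], n_ref), call. = FALSE)
    }
    if (n_smp > 14L) {
      stop(sprintf("plex '%s' has %d sample channels; at most 14 allowed",
                   pl$plex_id[1], n_smp), call. = FALSE)
    }
  }
  ids <- layout$sample_id[layout$role == "sample"]
  if (anyDuplicated(ids)) {
    stop("duplicated sample_id across the layout", call. = FALSE)
  }
  if (anyNA(ids)) {
    stop("sample channels must carry a sample_id", call. = FALSE)
  }
  class(layout) <- c("plex_layout", "data.frame")
  layout
}

#' @rdname plex_layout
#' @param path file to read or write.
#' @param sep field delimiter (tab canonical; use `","` for CSV).
#' @export
read_plex_layout <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  req <- c("plex_id", "channel_id", "role")
  if (!all(req %in% names(df))) {
    stop("layout file must have columns plex_id, channel_id, role", call. = FALSE)
  }
  if (is.null(df$sample_id)) df$sample_id <- NA_character_
  plex_layout(df$plex_id, df$channel_id, df$role, df$sample_id)
}

#' @rdname plex_layout
#' @param layout a `plex_layout`.
#' @export
write_plex_layout <- function(layout, path, sep = "\t") {
  utils::write.table(layout[c("plex_id", "channel_id", "role", "sample_id")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reporter intensity matrix
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   channels in columns named by `plex.channel` keys from the layout.
#'   Values are non-negative raw reporter intensities; `NA` marks missing
#'   (protein not quantified), which for TMT data occurs in whole-plex blocks.
#' @param layout the `plex_layout` the columns refer to.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `layout`.
#' @export
intensity_matrix <- function(values, layout) {
  stopifnot(is.matrix(values), inherits(layout, "plex_layout"))
  if (is.null(rownames(values))) stop("values must have protein rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    stop("duplicated protein ID in intensity matrix", call. = FALSE)
  }
  unknown <- setdiff(colnames(values), layout$key)
  if (length(unknown)) {
    stop(sprintf("layout mismatch: columns not in layout: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  missing_ch <- setdiff(layout$key, colnames(values))
  if (length(missing_ch)) {
    stop(sprintf("layout mismatch: layout channels absent from matrix: %s",
                 paste(utils::head(missing_ch, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative reporter intensity", call. = FALSE)
  }
  values <- values[, layout$key, drop = FALSE]
  # missingness should be plex-consistent (whole-plex blocks per protein)
  plex_of <- layout$plex_id[match(colnames(values), layout$key)]
  for (pl in unique(plex_of)) {
    block <- values[, plex_of == pl, drop = FALSE]
    nmiss <- rowSums(is.na(block))
    partial <- nmiss > 0 & nmiss < ncol(block)
    if (any(partial)) {
      warning(sprintf(
        "%d protein(s) have partial (non-block) missingness in plex '%s'",
        sum(partial), pl), call. = FALSE)
      break
    }
  }
  structure(list(values = values, layout = layout), class = "intensity_matrix")
}

#' Read / write a reporter intensity matrix
#'
#' The file is a rectangular delimited table whose first column holds protein
#' accessions and whose remaining columns are named by `plex.channel` keys
#' matching the layout. Missing values are empty cells or `NA` (never 0:
#' zero is a legal intensity).
#'
#' @param path delimited text file.
#' @param layout a [plex_layout()].
#' @param sep field delimiter.
#' @return An `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path, layout, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  prot <- as.character(df[[1]])
  if (anyDuplicated(prot)) stop("duplicated protein ID in file", call. = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- prot
  intensity_matrix(values, layout)
}

#' @rdname read_intensity_matrix
#' @param x an `intensity_matrix`.
#' @export
write_intensity_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(protein = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d channels (%d plexes)\n",
              nrow(x$values), ncol(x$values), length(unique(x$layout$plex_id))))
  invisible(x)
}

normalize_enum <- function(x, levels, what) {
  idx <- match(tolower(as.character(x)), tolower(levels))
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    stop(sprintf("unknown %s level: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  levels[idx]
}

#' Read and validate sample metadata
#'
#' Required columns: `sample_id`, `group` (`control`/`AD`), `cognitive_state`
#' (`NC`/`MCI`/`dementia`), `tau_status` (`normal`/`abnormal`). Optional:
#' `age`, `sex` (`f`/`m`), `cohort_id`, `ttau`. Enum levels are matched
#' case-insensitively. By study design controls must have normal cognition
#' and normal tau.
#'
#' @param path delimited file, or a `data.frame` to validate in place.
#' @param sep field delimiter.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
read_metadata <- function(path, sep = "\t") {
  df <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", ""))
  }
  req <- c("sample_id", "group", "cognitive_state", "tau_status")
  if (!all(req %in% names(df))) {
    stop(sprintf("metadata must contain columns: %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  df$group <- normalize_enum(df$group, c("control", "AD"), "group")
  df$cognitive_state <- normalize_enum(df$cognitive_state,
                                       c("NC", "MCI", "dementia"),
                                       "cognitive_state")
  df$tau_status <- normalize_enum(df$tau_status, c("normal", "abnormal"),
                                  "tau_status")
  if (!is.null(df$sex)) df$sex <- normalize_enum(df$sex, c("f", "m"), "sex")
  if (!is.null(df$age)) df$age <- as.numeric(df$age)
  ctrl <- df$group == "control"
  if (any(ctrl & (df$cognitive_state != "NC" | df$tau_status != "normal"),
          na.rm = TRUE)) {
    stop("controls must have cognitive_state NC and tau_status normal",
         call. = FALSE)
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname read_metadata
#' @param meta a `sample_metadata`.
#' @export
write_metadata <- function(meta, path, sep = "\t") {
  utils::write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize TMT MAPT reporter abundance to the Innotest t-tau scale
#'
#' Linear conversion calibrated between TMT microtubule-associated protein tau
#' (MAPT) reporter abundance and Innotest ELISA total tau:
#' `t-tau = -309.16 + 0.01 * MAPT` (pg/ml).
#'
#' @param mapt_abundance non-negative numeric vector of MAPT abundances,
#'   on whatever TMT scale the caller's calibration used.
#' @return Innotest-scale t-tau in pg/ml.
#' @export
convert_mapt_to_ttau <- function(mapt_abundance) {
  if (any(mapt_abundance < 0, na.rm = TRUE)) {
    stop("MAPT abundance must be non-negative", call. = FALSE)
  }
  -309.16 + 0.01 * mapt_abundance
}

#' Write / read per-sample subtype assignments
#'
#' @param labels vector of subtype labels, one per sample, named by sample id.
#' @param probabilities numeric matrix (samples x subtypes) of class
#'   probabilities; rows must sum to 1 within `1e-6`.
#' @param path delimited file.
#' @param sep field delimiter.
#' @return `write_subtype_assignments` invisibly returns the path;
#'   `read_subtype_assignments` returns a list with `labels` and
#'   `probabilities`.
#' @export
write_subtype_assignments <- function(labels, probabilities, path, sep = "\t") {
  probabilities <- as.matrix(probabilities)
  if (length(labels) != nrow(probabilities)) {
    stop("one probability row per label required", call. = FALSE)
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    stop("probabilities must sum to 1 per sample (tolerance 1e-6)", call. = FALSE)
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- rownames(probabilities)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  if (is.null(colnames(probabilities))) {
    colnames(probabilities) <- paste0("subtype", seq_len(ncol(probabilities)))
  }
  df <- data.frame(sample_id = ids, subtype = as.vector(labels),
                   probabilities, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subtype_assignments
#' @export
read_subtype_assignments <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  probs <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(probs) <- df$sample_id
  labels <- df$subtype
  names(labels) <- df$sample_id
  list(labels = labels, probabilities = probs)
}
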