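# Synthetic TMT cohort generator. The generative model plants K patient
# subtypes, each defined by a signature of up/down-shifted proteins on the
# log2 scale, randomizes samples over 16-channel plexes (14 samples + 2 pooled
# reference channels), and applies multiplicative per-plex batch and
# per-channel loading factors -- the technical structure internal reference
# scaling is designed to remove.

# Clinical anchors for the planted covariates (age, sex, cognitive state and a
# t-tau-like biomarker) follow the discovery cohort's published descriptive
# table, so that stratified screening and biomarker direction checks are
# meaningful on synthetic data.
SUBTYPE_AGE_MEAN <- c(64.7, 69.4, 64.5, 64.3, 66.2)
SUBTYPE_MALE_P <- c(0.45, 0.49, 0.42, 0.65, 0.73)
SUBTYPE_STAGE_P <- rbind(
  c(37, 27, 36), c(26, 23, 52), c(4, 12, 83), c(19, 21, 60), c(14, 34, 52)
) / 100
SUBTYPE_TTAU_MEAN <- c(592, 765, 882, 301, 469)
SUBTYPE_TTAU_SD <- c(340, 447, 367, 166, 297)
CONTROL_TTAU_MEAN <- 199
CONTROL_TTAU_SD <- 88
TTAU_CUTOFF <- 375  # pg/ml; t-tau above this counts as abnormal

#' Configuration of a synthetic CSF TMT cohort
#'
#' Defaults describe the cohort structure the pipeline was designed for:
#' 187 controls and 419 amyloid-positive individuals across three cognitive
#' stages, five planted subtypes with the discovery cohort's relative sizes,
#' ~1,300 fully usable proteins, and 16-channel plexes with 14 samples plus
#' 2 pooled reference channels.
#'
#' @param n_controls,n_ad numbers of control and AD samples.
#' @param k_true number of planted subtypes.
#' @param subtype_proportions length-`k_true` simplex vector of subtype
#'   prevalences.
#' @param n_proteins number of proteins.
#' @param signature_size proteins per subtype signature.
#' @param effect_size mean log2 shift of signature proteins in residual-s.d.
#'   units (the planted log2 shift is `effect_size * noise_sd`, i.e. a
#'   control-z shift of approximately `effect_size`).
#' @param batch_sd s.d. of the per-plex log-scale multiplicative batch factor.
#' @param channel_sd s.d. of the per-channel log-scale loading factor.
#' @param noise_sd residual log2-scale s.d.
#' @param missing_plex_fraction fraction of (protein, plex) blocks set missing.
#' @param signature_overlap fraction of each signature shared with the next
#'   subtype's signature (0 = disjoint signatures).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_controls = 187, n_ad = 419, k_true = 5,
                             subtype_proportions = c(137, 124, 24, 78, 56) / 419,
                             n_proteins = 1300, signature_size = 60,
                             effect_size = 2, batch_sd = 0.25,
                             channel_sd = 0.1, noise_sd = 0.3,
                             missing_plex_fraction = 0.02,
                             signature_overlap = 0, seed = 1L) {
  cfg <- list(n_controls = n_controls, n_ad = n_ad, k_true = k_true,
              subtype_proportions = subtype_proportions,
              n_proteins = n_proteins, signature_size = signature_size,
              effect_size = effect_size, batch_sd = batch_sd,
              channel_sd = channel_sd, noise_sd = noise_sd,
              missing_plex_fraction = missing_plex_fraction,
              signature_overlap = signature_overlap, seed = as.integer(seed))
  stopifnot(n_controls > 0, n_ad > 0, k_true >= 1, n_proteins > 0,
            signature_size > 0, effect_size >= 0, batch_sd >= 0,
            channel_sd >= 0, noise_sd >= 0,
            missing_plex_fraction >= 0, missing_plex_fraction <= 1,
            signature_overlap >= 0, signature_overlap <= 1,
            length(subtype_proportions) == k_true)
  if (abs(sum(subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must sum to 1", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Strong-separation preset used by the recovery benchmarks
#'
#' The reduced, well-separated world in which planted-subtype recovery is
#' asserted: ~400 proteins treated as an already fully-observed panel
#' (no plex-level missingness), effect size 2 residual s.d., noise 0.3,
#' about 400 AD samples and 180 controls.
#'
#' @param seed integer seed.
#' @param n_proteins,n_ad,n_controls optional overrides of the preset sizes.
#' @return A `synthetic_config`.
#' @export
strong_separation_config <- function(seed = 1L, n_proteins = 400, n_ad = 400,
                                     n_controls = 180) {
  synthetic_config(n_controls = n_controls, n_ad = n_ad, k_true = 5,
                   n_proteins = n_proteins, signature_size = 60,
                   effect_size = 2, noise_sd = 0.3, batch_sd = 0.25,
                   channel_sd = 0.1, missing_plex_fraction = 0, seed = seed)
}

# Draw the planted signatures: a proteins x k matrix with entries -1/0/+1.
draw_signatures <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    k <- cfg$k_true
    sz <- cfg$signature_size
    n_overlap <- round(cfg$signature_overlap * sz)
    need <- k * sz - if (k > 1) k * n_overlap else 0
    if (need > cfg$n_proteins) {
      stop("signatures do not fit in n_proteins", call. = FALSE)
    }
    proteins <- sprintf("P%05d", seq_len(cfg$n_proteins))
    S <- matrix(0L, cfg$n_proteins, k, dimnames = list(proteins, NULL))
    pool <- sample(cfg$n_proteins)
    blocks <- vector("list", k)
    pos <- 1
    for (s in seq_len(k)) {
      take <- sz - if (s > 1 && n_overlap > 0) n_overlap else 0
      own <- pool[pos:(pos + take - 1)]
      pos <- pos + take
      shared <- if (s > 1 && n_overlap > 0) {
        utils::tail(blocks[[s - 1]], n_overlap)
      } else {
        integer(0)
      }
      blocks[[s]] <- c(shared, own)
      S[blocks[[s]], s] <- sample(c(-1L, 1L), sz, replace = TRUE)
    }
    S
  })
}

generate_cohort_core <- function(cfg, signatures, protein_subset, cohort_seed,
                                 strict, cohort_id) {
  proteins <- rownames(signatures)[protein_subset]
  S <- signatures[protein_subset, , drop = FALSE]
  np <- length(proteins)
  n <- cfg$n_controls + cfg$n_ad
  with_seed(cohort_seed, {
    # --- sample identities and planted clinical covariates -----------------
    k <- cfg$k_true
    subtype <- sample.int(k, cfg$n_ad, replace = TRUE,
                          prob = cfg$subtype_proportions)
    ids <- c(sprintf("%s_ctrl%04d", cohort_id, seq_len(cfg$n_controls)),
             sprintf("%s_ad%04d", cohort_id, seq_len(cfg$n_ad)))
    group <- rep(c("control", "AD"), c(cfg$n_controls, cfg$n_ad))
    idx5 <- function(v) v[pmin(subtype, length(v))]  # recycle anchors if k > 5
    age_mean <- c(rep(64.0, cfg$n_controls), idx5(SUBTYPE_AGE_MEAN))
    age <- round(stats::rnorm(n, age_mean, c(rep(11.8, cfg$n_controls),
                                             rep(8, cfg$n_ad))), 1)
    male_p <- c(rep(0.59, cfg$n_controls), idx5(SUBTYPE_MALE_P))
    sex <- ifelse(stats::runif(n) < male_p, "m", "f")
    stage <- character(n)
    stage[group == "control"] <- "NC"
    stage_p <- SUBTYPE_STAGE_P[pmin(subtype, nrow(SUBTYPE_STAGE_P)), , drop = FALSE]
    stage_p <- stage_p / rowSums(stage_p)
    stage[group == "AD"] <- vapply(seq_len(cfg$n_ad), function(i) {
      sample(c("NC", "MCI", "dementia"), 1, prob = stage_p[i, ])
    }, character(1))
    # t-tau-like biomarker; controls truncated to the normal range by design
    ttau <- numeric(n)
    ttau[group == "control"] <- {
      x <- stats::rnorm(cfg$n_controls, CONTROL_TTAU_MEAN, CONTROL_TTAU_SD)
      while (any(x >= TTAU_CUTOFF | x < 0)) {
        bad <- x >= TTAU_CUTOFF | x < 0
        x[bad] <- stats::rnorm(sum(bad), CONTROL_TTAU_MEAN, CONTROL_TTAU_SD)
      }
      x
    }
    ttau[group == "AD"] <- pmax(
      stats::rnorm(cfg$n_ad, idx5(SUBTYPE_TTAU_MEAN), idx5(SUBTYPE_TTAU_SD)), 10)
    tau_status <- ifelse(group == "control", "normal",
                         ifelse(ttau >= TTAU_CUTOFF, "abnormal", "normal"))
    meta <- data.frame(sample_id = ids, group = group, cognitive_state = stage,
                       tau_status = tau_status, age = age, sex = sex,
                       cohort_id = cohort_id, ttau = round(ttau, 1),
                       stringsAsFactors = FALSE)
    class(meta) <- c("sample_metadata", "data.frame")

    # --- plex layout: randomize samples over plexes of 14 ------------------
    if (strict && n %% 14L != 0L) {
      stop("strict mode: sample count is not a multiple of 14", call. = FALSE)
    }
    n_plex <- ceiling(n / 14)
    perm <- sample(n)
    plex_of_sample <- integer(n)
    plex_of_sample[perm] <- rep(seq_len(n_plex), each = 14L)[seq_len(n)]
    plex_ids <- sprintf("plex%02d", seq_len(n_plex))
    layout_rows <- do.call(rbind, lapply(seq_len(n_plex), function(p) {
      members <- ids[plex_of_sample == p]
      data.frame(
        plex_id = plex_ids[p],
        channel_id = sprintf("ch%02d", seq_len(length(members) + 2L)),
        role = c(rep("sample", length(members)), "reference", "reference"),
        sample_id = c(members, NA, NA), stringsAsFactors = FALSE)
    }))
    layout <- plex_layout(layout_rows$plex_id, layout_rows$channel_id,
                          layout_rows$role, layout_rows$sample_id)

    # --- protein abundances -------------------------------------------------
    base <- stats::rnorm(np, mean = 20, sd = 1.5)  # log2 units, log-normal raw
    delta <- cfg$effect_size * cfg$noise_sd        # planted log2 shift
    shift <- matrix(0, np, n)
    ad_cols <- which(group == "AD")
    shift[, ad_cols] <- S[, subtype, drop = FALSE] * delta
    log2_signal <- base + shift +
      matrix(stats::rnorm(np * n, 0, cfg$noise_sd), np, n)
    raw <- 2^log2_signal
    colnames(raw) <- ids
    rownames(raw) <- proteins

    # --- assemble channels; pooled references; batch + loading factors ----
    values <- matrix(NA_real_, np, nrow(layout),
                     dimnames = list(proteins, layout$key))
    batch <- exp(stats::rnorm(n_plex, 0, cfg$batch_sd))
    for (p in seq_len(n_plex)) {
      members <- ids[plex_of_sample == p]
      block <- raw[, members, drop = FALSE]
      ref_profile <- rowMeans(block)  # pooled mean of the plex's samples
      keys <- layout$key[layout$plex_id == plex_ids[p]]
      roles <- layout$role[layout$plex_id == plex_ids[p]]
      smp_keys <- keys[roles == "sample"]
      ref_keys <- keys[roles == "reference"]
      loading <- exp(stats::rnorm(length(smp_keys), 0, cfg$channel_sd))
      ref_loading <- exp(stats::rnorm(1, 0, cfg$channel_sd))  # shared by both refs
      values[, smp_keys] <- block %*% diag(loading, length(smp_keys)) * batch[p]
      for (rk in ref_keys) values[, rk] <- ref_profile * ref_loading * batch[p]
    }

    # --- plex-level missing blocks -----------------------------------------
    if (cfg$missing_plex_fraction > 0) {
      miss <- matrix(stats::runif(np * n_plex) < cfg$missing_plex_fraction,
                     np, n_plex)
      all_missing <- rowSums(miss) == n_plex
      if (any(all_missing)) {  # keep every protein observed somewhere
        keep <- sample.int(n_plex, sum(all_missing), replace = TRUE)
        miss[cbind(which(all_missing), keep)] <- FALSE
      }
      for (p in seq_len(n_plex)) {
        keys <- layout$key[layout$plex_id == plex_ids[p]]
        values[miss[, p], keys] <- NA_real_
      }
    }

    truth_subtype <- c(rep(NA_integer_, cfg$n_controls), subtype)
    names(truth_subtype) <- ids
    truth <- list(subtype = truth_subtype, signatures = S,
                  log2_shift = delta, warnings = character(0))
    class(truth) <- "ground_truth"
    list(intensity = intensity_matrix(values, layout), layout = layout,
         metadata = meta, truth = truth)
  })
}

#' Generate a synthetic discovery cohort
#'
#' @param config a [synthetic_config()].
#' @param strict error (instead of part-filling the last plex) when the sample
#'   count is not a multiple of 14.
#' @return A list of class `synthetic_cohort` with elements `intensity`
#'   (an `intensity_matrix`), `layout`, `metadata` and `truth` (planted
#'   subtype labels, signature matrix and log2 shift).
#' @export
generate_cohort <- function(config, strict = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  S <- draw_signatures(config)
  out <- generate_cohort_core(config, S, seq_len(config$n_proteins),
                              derive_seed(config$seed, 2L), strict, "disc")
  class(out) <- "synthetic_cohort"
  out
}

#' Generate a replication cohort sharing the discovery signatures
#'
#' A new, independently sampled cohort whose planted subtype signatures are
#' identical (in membership, direction and magnitude) to the discovery
#' cohort's on the proteins retained, emulating a replication study that
#' detects only a subset of the discovery proteome.
#'
#' @param config the discovery [synthetic_config()]; signatures are
#'   re-derived from its seed.
#' @param panel_fraction fraction in (0, 1] of proteins retained.
#' @param seed seed of the replication draws (samples, batches, panel).
#' @param cohort_id label stored in the metadata.
#' @return A `synthetic_cohort`.
#' @export
generate_replication_cohort <- function(config, panel_fraction = 1, seed = NULL,
                                        cohort_id = "rep") {
  stopifnot(inherits(config, "synthetic_config"),
            panel_fraction > 0, panel_fraction <= 1)
  if (is.null(seed)) seed <- derive_seed(config$seed, 99L)
  S <- draw_signatures(config)
  keep <- with_seed(derive_seed(seed, 3L), {
    sort(sample.int(config$n_proteins, floor(panel_fraction * config$n_proteins)))
  })
  out <- generate_cohort_core(config, S, keep, derive_seed(seed, 4L),
                              strict = FALSE, cohort_id = cohort_id)
  if (!any(S[keep, ] != 0)) {
    out$truth$warnings <- c(out$truth$warnings,
                            "no signature protein survived the panel subset")
    warning("no signature protein survived the panel subset", call. = FALSE)
  }
  class(out) <- "synthetic_cohort"
  out
}

#' Subtype-recovery power over a grid of cohort sizes
#'
#' For each cohort size, generates `n_reps` seeded cohorts, runs the full
#' normalize -> select -> subtype pipeline, and reports the mean adjusted Rand
#' index of the recovered patient labels against the planted truth and the
#' fraction of runs whose model selection picks the planted number of
#' subtypes. The control:AD ratio of `config` is preserved.
#'
#' @param config a [synthetic_config()] template.
#' @param n_grid integer vector of total cohort sizes.
#' @param n_reps replicates per size.
#' @param seed master seed.
#' @param k_range,n_runs model-selection settings passed to [select_k()].
#' @return A `data.frame` with columns `n`, `mean_ari`, `frac_k_true`,
#'   `n_failed`.
#' @export
subtype_recovery_power <- function(config, n_grid, n_reps = 5, seed = 1L,
                                   k_range = 2:10, n_runs = 10) {
  stopifnot(n_reps >= 1)
  ctrl_frac <- config$n_controls / (config$n_controls + config$n_ad)
  rows <- lapply(n_grid, function(n) {
    aris <- numeric(0)
    k_hits <- logical(0)
    failed <- 0L
    for (r in seq_len(n_reps)) {
      cfg_r <- config
      cfg_r$n_controls <- max(4L, round(n * ctrl_frac))
      cfg_r$n_ad <- n - cfg_r$n_controls
      cfg_r$seed <- derive_seed(seed, n * 1000L + r)
      res <- tryCatch({
        cohort <- generate_cohort(cfg_r)
        model <- run_discovery_pipeline(cohort$intensity, cohort$metadata,
                                        k_range = k_range, n_runs = n_runs,
                                        seed = cfg_r$seed)$model
        truth <- cohort$truth$subtype
        ad <- names(truth)[!is.na(truth)]
        list(ari = adjusted_rand_index(model$patient_labels[ad], truth[ad]),
             k_hit = isTRUE(model$selected_k == config$k_true))
      }, error = function(e) NULL)
      if (is.null(res)) {
        failed <- failed + 1L
      } else {
        aris <- c(aris, res$ari)
        k_hits <- c(k_hits, res$k_hit)
      }
    }
    data.frame(n = n, mean_ari = mean(aris), frac_k_true = mean(k_hits),
               n_failed = failed)
  })
  do.call(rbind, rows)
}
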