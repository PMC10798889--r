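# Small fixtures built in code.

# A hand-sized layout: `n_plex` plexes of `n_samples_per` samples + 2 refs.
tiny_layout <- function(n_plex = 2, n_samples_per = 3) {
  rows <- do.call(rbind, lapply(seq_len(n_plex), function(p) {
    data.frame(
      plex_id = sprintf("plex%02d", p),
      channel_id = sprintf("ch%02d", seq_len(n_samples_per + 2)),
      role = c(rep("sample", n_samples_per), "reference", "reference"),
      sample_id = c(sprintf("s%02d", (p - 1) * n_samples_per +
                              seq_len(n_samples_per)), NA, NA))
  }))
  plex_layout(rows$plex_id, rows$channel_id, rows$role, rows$sample_id)
}

tiny_metadata <- function(layout, n_controls = 3) {
  ids <- layout$sample_id[layout$role == "sample"]
  grp <- rep("AD", length(ids))
  grp[seq_len(n_controls)] <- "control"
  read_metadata(data.frame(
    sample_id = ids, group = grp,
    cognitive_state = ifelse(grp == "control", "NC", "dementia"),
    tau_status = ifelse(grp == "control", "normal", "abnormal"),
    age = 65, sex = "f", stringsAsFactors = FALSE))
}

# Deterministic positive intensity matrix on a tiny layout.
tiny_intensity <- function(layout, n_proteins = 4, seed = 7) {
  keys <- layout$key
  values <- withr::with_seed(seed, {
    matrix(exp(rnorm(n_proteins * length(keys), 10, 0.4)),
           n_proteins, length(keys),
           dimnames = list(sprintf("P%03d", seq_len(n_proteins)), keys))
  })
  intensity_matrix(values, layout)
}

# Small, fast generator config for module tests.
small_config <- function(seed = 11, ...) {
  defaults <- list(n_controls = 24, n_ad = 60, k_true = 3,
                   subtype_proportions = c(0.4, 0.35, 0.25), n_proteins = 90,
                   signature_size = 18, effect_size = 2, noise_sd = 0.3,
                   batch_sd = 0.25, channel_sd = 0.1,
                   missing_plex_fraction = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
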