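# Seeded generator of multi-project abundance datasets with the structure
# the analysis assumes: several cohorts with project-specific batch and
# depth effects, zero-inflated skewed abundances, and a minority of signal
# features whose means are ordered along the healthy -> small adenoma ->
# adenoma -> CRC axis (functional mode) or shifted for CRC only (taxonomic
# mode).

#' Generator configuration
#'
#' Abundances follow a zero-inflated log-normal:
#' `a(i,j) = B(i,j) * exp(mu_j + b_{p(i),j} + log(e_{c(i),j}) + eps_ij)` with
#' `mu_j ~ N(0, base_log_mean_sd)` a feature baseline, `b` a project-specific
#' batch offset `~ N(0, batch_sd)`, `e` the per-condition multiplier on
#' signal features (1 on null features), `eps ~ N(0, noise_sd)` sample noise
#' and `B ~ Bernoulli(1 - zero_inflation)` a dropout mask. One project may
#' emulate a shallow-sequenced cohort: its values are scaled by
#' `depth_factor` and drawn with an elevated zero-inflation probability.
#'
#' @param n_projects Number of cohorts.
#' @param samples_per_condition Named integer vector, samples per condition
#'   in every project (conditions from the metadata vocabulary).
#' @param n_features,n_signal Total features and how many carry signal
#'   (`n_signal <= n_features`).
#' @param effect_profile Named multiplier per condition applied to signal
#'   features; must cover every condition in `samples_per_condition`.
#' @param base_log_mean_sd,batch_sd,noise_sd Log-scale standard deviations.
#' @param abundance_scale Global multiplicative scale of the profile
#'   (default 50), putting values on the count scale of length-normalized
#'   read counts rather than around 1, so the downstream `log(1+x)`
#'   transform operates in its logarithmic regime as it does on real
#'   profiles.
#' @param zero_inflation Dropout probability in `[0, 1]`.
#' @param low_depth_project Project index emulating a low-depth cohort, or
#'   `NA` for none.
#' @param depth_factor Multiplicative depth of the low-depth project, in
#'   `(0, 1]`.
#' @param low_depth_zero_inflation Dropout probability used in the low-depth
#'   project.
#' @param namespace Feature namespace of the generated profiles.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_projects = 7L,
                             samples_per_condition = c(
                               healthy = 25L, crc = 25L,
                               adenoma = 5L, small_adenoma = 5L
                             ),
                             n_features = 500L,
                             n_signal = 30L,
                             effect_profile = c(
                               healthy = 1, small_adenoma = 1.7,
                               adenoma = 2.8, crc = 6
                             ),
                             base_log_mean_sd = 1,
                             batch_sd = 0.4,
                             noise_sd = 1,
                             abundance_scale = 50,
                             zero_inflation = 0.1,
                             low_depth_project = 1L,
                             depth_factor = 0.25,
                             low_depth_zero_inflation = 0.25,
                             namespace = "kegg",
                             seed = 1L) {
  cfg <- list(
    n_projects = as.integer(n_projects),
    samples_per_condition = samples_per_condition,
    n_features = as.integer(n_features),
    n_signal = as.integer(n_signal),
    effect_profile = effect_profile,
    base_log_mean_sd = base_log_mean_sd,
    batch_sd = batch_sd,
    noise_sd = noise_sd,
    abundance_scale = abundance_scale,
    zero_inflation = zero_inflation,
    low_depth_project = low_depth_project,
    depth_factor = depth_factor,
    low_depth_zero_inflation = low_depth_zero_inflation,
    namespace = match.arg(namespace, PROFILE_NAMESPACES),
    seed = as.integer(seed)
  )
  if (cfg$n_signal > cfg$n_features) stop("n_signal must be <= n_features")
  if (cfg$n_projects < 1L) stop("need at least one project")
  bad <- setdiff(names(cfg$samples_per_condition), CONDITION_LEVELS)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(cfg$samples_per_condition < 0)) stop("sample counts must be >= 0")
  missing_eff <- setdiff(
    names(cfg$samples_per_condition)[cfg$samples_per_condition > 0],
    names(cfg$effect_profile)
  )
  if (length(missing_eff)) {
    stop("effect_profile missing condition(s): ",
         paste(missing_eff, collapse = ", "))
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1 ||
      cfg$low_depth_zero_inflation < 0 || cfg$low_depth_zero_inflation > 1) {
    stop("zero-inflation probabilities must lie in [0, 1]")
  }
  if (!is.na(cfg$low_depth_project) &&
      (cfg$depth_factor <= 0 || cfg$depth_factor > 1)) {
    stop("depth_factor must lie in (0, 1]")
  }
  structure(cfg, class = "generator_config")
}

#' Default study conditions for the two profile regimes
#'
#' Functional mode plants condition-ordered multipliers
#' `1 < e_small < e_adenoma < e_crc` on the signal features, emulating a
#' gradual functional shift along the lesion axis; taxonomic mode plants a
#' CRC-only shift (`e_small = e_adenoma = 1`), emulating taxa that change
#' only close to the tumor condition. Taxonomic mode is downstream
#' discretized with 2 bins, functional with 20.
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
functional_mode_config <- function(seed = 1L) {
  generator_config(namespace = "kegg", seed = seed)
}

#' @rdname functional_mode_config
#' @export
taxonomic_mode_config <- function(seed = 1L) {
  generator_config(
    effect_profile = c(healthy = 1, small_adenoma = 1, adenoma = 1, crc = 6),
    zero_inflation = 0.25, low_depth_zero_inflation = 0.4,
    namespace = "taxonomic", seed = seed
  )
}

feature_id_stem <- function(namespace) {
  switch(namespace, kegg = "K%05d", eggnog = "OG%04d", taxonomic = "taxon_%04d")
}

#' Generate a synthetic multi-project dataset
#'
#' @param config A [generator_config()].
#' @return A list with elements `dataset` (a [profile_dataset()]) and
#'   `truth` (class `planted_truth`: the signal feature ids, the effect
#'   profile actually applied, and the generator seed).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    d <- config$n_features
    feats <- sprintf(feature_id_stem(config$namespace), seq_len(d))
    signal <- sort(sample.int(d, config$n_signal))
    spc <- config$samples_per_condition[config$samples_per_condition > 0]
    conditions <- rep(names(spc), times = spc)
    n_per_project <- length(conditions)

    mu <- rnorm(d, 0, config$base_log_mean_sd)
    log_effect <- matrix(0, nrow = n_per_project, ncol = d)
    log_effect[, signal] <- log(config$effect_profile[conditions])

    blocks <- vector("list", config$n_projects)
    meta <- vector("list", config$n_projects)
    for (p in seq_len(config$n_projects)) {
      project <- sprintf("P%d", p)
      low <- !is.na(config$low_depth_project) && p == config$low_depth_project
      zi <- if (low) config$low_depth_zero_inflation else config$zero_inflation
      depth <- if (low) config$depth_factor else 1
      b <- rnorm(d, 0, config$batch_sd)
      eps <- matrix(rnorm(n_per_project * d, 0, config$noise_sd),
                    nrow = n_per_project)
      mask <- matrix(rbinom(n_per_project * d, 1L, 1 - zi),
                     nrow = n_per_project)
      vals <- mask * exp(
        matrix(mu, n_per_project, d, byrow = TRUE) +
          matrix(b, n_per_project, d, byrow = TRUE) +
          log_effect + eps
      ) * (config$abundance_scale * depth)
      rownames(vals) <- sprintf("%s_S%03d", project, seq_len(n_per_project))
      colnames(vals) <- feats
      blocks[[p]] <- vals
      meta[[p]] <- data.frame(
        sample_id = rownames(vals),
        project_id = project,
        condition = conditions,
        comorbidity = FALSE,
        stringsAsFactors = FALSE
      )
    }
    dataset <- profile_dataset(
      profile_matrix(do.call(rbind, blocks), config$namespace),
      do.call(rbind, meta)
    )
    truth <- structure(
      list(
        signal_feature_ids = feats[signal],
        effect_profile = config$effect_profile,
        seed = config$seed
      ),
      class = "planted_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}
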