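# Programmatic fixtures: everything is generated in code at test time.

# A small but still well-powered study: 3 projects, 60 features, 8 planted.
# Effects are stronger than the full-scale defaults so that selection keeps
# its power at the reduced per-fold sample sizes used in unit tests.
tiny_config <- function(seed = 1L, mode = c("functional", "taxonomic"),
                        ...) {
  mode <- match.arg(mode)
  base <- if (mode == "functional") {
    functional_mode_config(seed)
  } else {
    taxonomic_mode_config(seed)
  }
  effects <- if (mode == "functional") {
    c(healthy = 1, small_adenoma = 2, adenoma = 4, crc = 10)
  } else {
    # taxonomic dropout (0.25) costs more F-test power, so the planted
    # fold change is larger to keep the tiny fixture well-powered
    c(healthy = 1, small_adenoma = 1, adenoma = 1, crc = 20)
  }
  overrides <- modifyList(
    list(n_projects = 3L,
         samples_per_condition = c(healthy = 20L, crc = 20L,
                                   adenoma = 6L, small_adenoma = 6L),
         n_features = 60L, n_signal = 8L, low_depth_project = NA,
         effect_profile = effects),
    list(...)
  )
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

tiny_dataset <- function(seed = 1L, ...) {
  generate_dataset(tiny_config(seed, ...))
}

# Fast pipeline settings for tests that fit many models.
fast_config <- function(...) {
  pipeline_config(n_epochs = 300L, ...)
}

# Pure-noise dataset: all condition multipliers 1.
null_config <- function(seed = 1L, ...) {
  tiny_config(
    seed,
    effect_profile = c(healthy = 1, small_adenoma = 1, adenoma = 1, crc = 1),
    ...
  )
}

# Hand-built two-class dataset from an explicit matrix.
dataset_from_matrix <- function(values, conditions,
                                project = rep("P1", nrow(values)),
                                namespace = "kegg",
                                comorbidity = rep(FALSE, nrow(values))) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
  }
  profile_dataset(
    profile_matrix(values, namespace),
    data.frame(sample_id = rownames(values), project_id = project,
               condition = conditions, comorbidity = comorbidity,
               stringsAsFactors = FALSE)
  )
}

write_profile_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
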