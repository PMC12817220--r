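#' Write a flash family to the CSV + JSON interchange format
#'
#' One wide CSV per family — first column `time_s` (seconds from the first
#' sample), one column per sweep named `<condition>__<intensity>__<sweep>__
#' <retina_id>` — plus a JSON sidecar carrying the metadata a reader needs
#' to reconstruct the family (voltage unit, sample rate, flash timing, and
#' the per-column retina/genotype/age annotations).
#'
#' @param family A [flash_family()].
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_family <- function(family, path) {
  stopifnot(inherits(family, "flash_family"))
  tb <- tibble::as_tibble(family)
  n <- length(tb$samples[[1]])
  time_s <- (seq_len(n) - 1) / sample_rate(family)
  cols <- sprintf("%s__%s__%d__%s", tb$condition,
                  format(tb$intensity, trim = TRUE, scientific = FALSE),
                  tb$sweep, tb$retina_id)
  wide <- tibble::as_tibble(stats::setNames(tb$samples, cols))
  wide <- dplyr::bind_cols(tibble::tibble(time_s = time_s), wide)
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  readr::write_csv(wide, csv_path)
  meta <- list(
    format = "ergdissect-family",
    version = 1L,
    voltage_unit = "uV",
    time_unit = "s",
    sample_rate = sample_rate(family),
    t0_flash = t0_flash(family),
    flash_duration = attr(family, "flash_duration"),
    columns = purrr::pmap(
      list(cols, tb$retina_id, tb$genotype, tb$age_class, tb$age_days,
           tb$condition, tb$intensity, tb$sweep),
      function(col, rid, gt, ac, ad, cond, i, sw) {
        list(column = col, retina_id = rid, genotype = gt, age_class = ac,
             age_days = ad, condition = cond, intensity = i, sweep = sw)
      }))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a flash family from the CSV + JSON interchange format
#'
#' Counterpart of [write_family()]. The sidecar is validated field by
#' field; a missing unit or sample rate is an error, never a silent
#' default.
#'
#' @param path Path without extension (expects `<path>.csv` and
#'   `<path>.json`).
#' @return A [flash_family()].
#' @export
read_family <- function(path) {
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  if (!file.exists(csv_path) || !file.exists(json_path)) {
    rlang::abort(sprintf("Expected %s and %s.", csv_path, json_path),
                 class = "erg_io_error")
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  for (field in c("voltage_unit", "sample_rate", "t0_flash",
                  "flash_duration", "columns")) {
    if (is.null(meta[[field]])) {
      rlang::abort(sprintf("Sidecar is missing required field `%s`.", field),
                   class = "erg_io_error")
    }
  }
  if (!identical(meta$voltage_unit, "uV")) {
    rlang::abort(sprintf("Unsupported voltage unit `%s` (expected uV).",
                         meta$voltage_unit), class = "erg_io_error")
  }
  wide <- readr::read_csv(csv_path, show_col_types = FALSE,
                          progress = FALSE)
  cols <- purrr::map_chr(meta$columns, "column")
  if (!identical(sort(cols), sort(setdiff(names(wide), "time_s")))) {
    rlang::abort("CSV trace columns do not match the sidecar column list.",
                 class = "erg_io_error")
  }
  sweeps <- purrr::map_dfr(meta$columns, function(cm) {
    tibble::tibble(
      retina_id = cm$retina_id, genotype = cm$genotype,
      age_class = cm$age_class, age_days = as.integer(cm$age_days),
      condition = cm$condition, intensity = as.numeric(cm$intensity),
      sweep = as.integer(cm$sweep),
      samples = list(wide[[cm$column]]))
  })
  flash_family(sweeps, sample_rate = meta$sample_rate,
               t0_flash = meta$t0_flash,
               flash_duration = meta$flash_duration)
}

#' Default pipeline configuration
#'
#' A named list validated by [run_pipeline()]: the top-level seed, the
#' simulation settings, the genotype/age-class grid, and statistics
#' options. Serialisable to/from YAML with [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed Top-level integer seed; all randomness in the run derives
#'   from it.
#' @param genotypes,age_classes Study grid.
#' @param n_retinas Retinas per genotype per age class.
#' @param sim Arguments forwarded to [sim_config()].
#' @param fix_n Optional fixed Hill slope.
#' @param correct Multiplicity correction for per-intensity comparisons.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       genotypes = erg_genotypes(),
                       age_classes = erg_age_classes(),
                       n_retinas = 8,
                       sim = list(),
                       fix_n = NULL,
                       correct = "none") {
  structure(list(seed = as.integer(seed), genotypes = genotypes,
                 age_classes = age_classes, n_retinas = n_retinas,
                 sim = sim, fix_n = fix_n, correct = correct),
            class = "run_config")
}

validate_run_config <- function(config) {
  known <- c("seed", "genotypes", "age_classes", "n_retinas", "sim",
             "fix_n", "correct")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "erg_config_error")
  }
  if (length(config$genotypes) == 0) {
    rlang::abort("Config must list at least one genotype.",
                 class = "erg_config_error")
  }
  bad <- setdiff(config$genotypes, erg_genotypes())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown genotype(s): ", paste(bad, collapse = ", ")),
                 class = "erg_config_error")
  }
  bad_age <- setdiff(config$age_classes, erg_age_classes())
  if (length(bad_age) > 0) {
    rlang::abort(paste0("Unknown age class(es): ",
                        paste(bad_age, collapse = ", ")),
                 class = "erg_config_error")
  }
  if (!is.numeric(config$n_retinas) || config$n_retinas < 1) {
    rlang::abort("`n_retinas` must be >= 1.", class = "erg_config_error")
  }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character(0))])
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full dissection pipeline
#'
#' For every configured age class: simulate the study arm, average sweeps,
#' derive components, measure amplitudes, fit Hill functions per retina,
#' then compare genotypes per intensity and per parameter, compute
#' proportionality records, and aggregate the developmental trajectory
#' across age classes. Entirely deterministic for a fixed config:
#' re-running writes byte-identical tables.
#'
#' @param config A [run_config()] or a YAML path.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as tidy CSVs plus a `provenance.json` (package version,
#'   config hash, seed, per-stage row counts).
#' @param verbose Print per-stage progress counts.
#' @return Named list of tibbles: `amplitudes`, `fits`, `per_intensity`,
#'   `parameters`, `proportionality`, `proportionality_summary`,
#'   `trajectory`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  sim_cfg <- do.call(sim_config, config$sim)

  per_age <- purrr::map(config$age_classes, function(ac) {
    fam <- simulate_study(genotypes = config$genotypes, age_class = ac,
                          n_retinas = config$n_retinas, config = sim_cfg,
                          seed = config$seed + match(ac, erg_age_classes()))
    say("[%s] simulated %d sweeps from %d retinas", ac, nrow(fam),
        dplyr::n_distinct(fam$retina_id))
    comp <- derive_components(average_sweeps(fam))
    amps <- primary_amplitudes(measure_components(comp))
    fits <- fit_hill_all(amps, fix_n = config$fix_n)
    say("[%s] %d fits (%d converged)", ac, nrow(fits), sum(fits$converged))
    list(amplitudes = amps, fits = fits)
  })
  amplitudes <- purrr::map_dfr(per_age, "amplitudes")
  fits <- purrr::map_dfr(per_age, "fits")

  per_intensity <- amplitudes %>%
    dplyr::group_by(.data$age_class) %>%
    dplyr::group_modify(function(df, key) {
      compare_per_intensity(df, correct = config$correct)
    }) %>%
    dplyr::ungroup()
  parameters <- fits %>%
    dplyr::group_by(.data$age_class) %>%
    dplyr::group_modify(function(df, key) compare_parameters(df)) %>%
    dplyr::ungroup()
  prop <- fits %>%
    dplyr::group_by(.data$age_class) %>%
    dplyr::group_modify(function(df, key) proportionality(df)) %>%
    dplyr::ungroup()
  prop_summary <- prop %>%
    dplyr::group_by(.data$age_class) %>%
    dplyr::group_modify(function(df, key) {
      proportionality_deviation(df, seed = config$seed)
    }) %>%
    dplyr::ungroup()
  traj <- trajectory(fits)

  results <- list(amplitudes = amplitudes, fits = fits,
                  per_intensity = per_intensity, parameters = parameters,
                  proportionality = prop,
                  proportionality_summary = prop_summary,
                  trajectory = traj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(results, function(tb, nm) {
      readr::write_csv(tb, file.path(out_dir, paste0(nm, ".csv")))
    })
    prov <- list(
      package = "ergdissect",
      version = as.character(utils::packageVersion("ergdissect")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      rows = purrr::map_int(results, nrow))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results
}
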