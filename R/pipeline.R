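# End-to-end pipeline driver and command-line entry points. Configuration
# is JSON (see the README for the schema); outputs are tidy CSV tables plus
# a run log with versions, seed and config hash.

read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  stopifnot(is.list(cfg))
  cfg
}

cohort_spec_from_config <- function(cc, seed) {
  sl <- cc$slide_spec %||% list()
  sl_args <- sl
  for (nm in c("stromal_intensity", "intraepithelial_intensity"))
    if (!is.null(sl_args[[nm]])) sl_args[[nm]] <- unlist(sl_args[[nm]])
  sspec <- do.call(slide_spec, sl_args)
  cohort_spec(n_cases = cc$n_cases %||% 5, n_controls = cc$n_controls %||% 5,
              slide_spec = sspec,
              patient_sd_log = cc$patient_sd_log %||% 1.0,
              case_effect = unlist(cc$case_effect %||% 1),
              seed = cc$seed %||% seed)
}

#' Run the full profiling pipeline from a JSON config
#'
#' Config keys: either `cohort` (a synthetic cohort spec: `n_cases`,
#' `n_controls`, `patient_sd_log`, `case_effect`, `slide_spec = {...}`) or
#' `slides` (a list of `{cell_csv, geometry, patient_id}`) plus
#' `metadata_csv`; `analyses`, any of `"density"`, `"ratio"`, `"proximity"`,
#' `"tls"`, `"stats"` (empty = metadata echo + log only); `out_dir`;
#' `seed`; optional `params` (`radius_um`, `formula_mode`, `n_perm`, TLS
#' detector settings). Writes one CSV per analysis plus `metadata.csv` and
#' `run_log.txt`; identical config + seed reproduce every table
#' byte-for-byte. Stage errors are rethrown with the patient id in the
#' message; tables computed before the failure are already on disk.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @return invisibly, the named vector of written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- cfg$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  analyses <- unlist(cfg$analyses %||% character(0))
  params <- cfg$params %||% list()
  n_perm <- params$n_perm %||% 10000
  formula_mode <- params$formula_mode %||% "strict"
  radius_um <- params$radius_um %||% 25

  if (!is.null(cfg$cohort)) {
    cohort <- generate_cohort(cohort_spec_from_config(cfg$cohort, seed))
    slides <- lapply(cohort, `[[`, "slide")
    metadata <- do.call(rbind, lapply(cohort, `[[`, "metadata"))
  } else if (!is.null(cfg$slides)) {
    slides <- lapply(cfg$slides, function(s)
      read_slide(s$cell_csv, s$geometry, patient_id = s$patient_id))
    metadata <- read_metadata(cfg$metadata_csv %||%
                                stop("config needs metadata_csv"))
  } else stop("config needs either 'cohort' or 'slides'")

  paths <- c(metadata = file.path(out_dir, "metadata.csv"))
  write_metadata(metadata, paths[["metadata"]])

  per_patient <- function(fn, label) {
    do.call(rbind, lapply(slides, function(sl)
      tryCatch(fn(sl), error = function(e)
        stop(sprintf("%s failed for patient %s: %s", label, sl$patient_id,
                     conditionMessage(e)), call. = FALSE))))
  }
  densities <- ratios <- proximity <- tls <- NULL
  if ("density" %in% analyses || "ratio" %in% analyses ||
      "stats" %in% analyses) {
    densities <- per_patient(function(sl)
      compute_densities(sl, formula_mode = formula_mode), "density")
    paths["density"] <- file.path(out_dir, "densities.csv")
    write.csv(densities, paths[["density"]], row.names = FALSE, na = "")
  }
  if ("ratio" %in% analyses || "stats" %in% analyses) {
    ratios <- compute_ratios(densities)
    paths["ratio"] <- file.path(out_dir, "ratios.csv")
    write.csv(ratios, paths[["ratio"]], row.names = FALSE, na = "")
  }
  if ("proximity" %in% analyses || "stats" %in% analyses) {
    proximity <- per_patient(function(sl)
      proximity_index(sl, radius_um = radius_um,
                      formula_mode = formula_mode), "proximity")
    paths["proximity"] <- file.path(out_dir, "proximity.csv")
    write.csv(proximity, paths[["proximity"]], row.names = FALSE, na = "")
  }
  if ("tls" %in% analyses || "stats" %in% analyses) {
    tls <- per_patient(function(sl) {
      zone <- do.call(detect_zone_tls,
                      c(list(sl), params$zone_tls %||% list()))
      gc_ <- if ("cd8ki67" %in% sl$assay_set)
        do.call(detect_gc_tls, c(list(sl), params$gc_tls %||% list()))
      else zone[0, ]
      area <- sum(sl$geometry$area_mm2[ANALYSIS_COMPARTMENTS])
      tls_density(rbind(zone, gc_), area, sl$patient_id)
    }, "tls")
    paths["tls"] <- file.path(out_dir, "tls.csv")
    write.csv(tls, paths[["tls"]], row.names = FALSE, na = "")
  }
  if ("stats" %in% analyses) {
    feats <- build_feature_table(densities, ratios, proximity, tls)
    stats_tab <- contrast_suite(feats, metadata, n_perm = n_perm,
                                seed = seed,
                                stratum = params$stratum %||% NULL)
    paths["stats"] <- file.path(out_dir, "stats.csv")
    write.csv(stats_tab, paths[["stats"]], row.names = FALSE, na = "")
  }

  log_path <- file.path(out_dir, "run_log.txt")
  cfg_hash <- if (is.character(config)) unname(tools::md5sum(config))
              else "inline-config"
  writeLines(c(
    sprintf("dcisime %s on R %s.%s", as.character(packageVersion("dcisime")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", seed),
    sprintf("config: %s", cfg_hash),
    sprintf("analyses: %s", paste(analyses, collapse = ", ")),
    sprintf("patients: %d", length(slides)),
    sprintf("outputs: %s", paste(basename(unname(paths)), collapse = ", "))
  ), log_path)
  paths["log"] <- log_path
  invisible(paths)
}

#' Command-line interface
#'
#' `dcis_cli(c("simulate", "slide", "--spec", "spec.json", "--out", "dir",
#' "--seed", "7"))` writes a simulated slide (cells CSV + GeoJSON);
#' `simulate cohort` writes one slide per patient plus `metadata.csv`;
#' `simulate raters` writes a score matrix CSV;
#' `profile run --config cfg.json` runs [run_pipeline()]. Spec JSON files
#' hold the arguments of the corresponding `*_spec()` constructor.
#'
#' @param args character vector, defaults to the command line.
#' @return invisibly, output path(s).
#' @export
dcis_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  if (length(args) < 2) stop(
    "usage: simulate slide|cohort|raters --spec <json> --out <dir> ",
    "[--seed <int>] | profile run --config <json>")
  verb <- args[1]; noun <- args[2]
  if (verb == "profile" && noun == "run")
    return(run_pipeline(opt("--config") %||% stop("--config required")))
  if (verb != "simulate") stop("unknown command: ", verb)
  out <- opt("--out") %||% stop("--out required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(opt("--seed", "1"))
  spec_file <- opt("--spec")
  spec_args <- if (is.null(spec_file)) list() else read_config(spec_file)
  spec_args$seed <- seed
  if (noun == "slide") {
    for (nm in c("stromal_intensity", "intraepithelial_intensity"))
      if (!is.null(spec_args[[nm]])) spec_args[[nm]] <- unlist(spec_args[[nm]])
    sl <- generate_slide(do.call(slide_spec, spec_args))
    write_slide(sl, file.path(out, "cells.csv"),
                file.path(out, "geometry.geojson"))
    return(invisible(out))
  }
  if (noun == "cohort") {
    spec_args2 <- spec_args
    if (!is.null(spec_args2$slide_spec))
      spec_args2$slide_spec <- do.call(slide_spec, spec_args2$slide_spec)
    if (!is.null(spec_args2$case_effect))
      spec_args2$case_effect <- unlist(spec_args2$case_effect)
    cohort <- generate_cohort(do.call(cohort_spec, spec_args2))
    for (p in cohort)
      write_slide(p$slide,
                  file.path(out, paste0(p$slide$patient_id, "_cells.csv")),
                  file.path(out, paste0(p$slide$patient_id, ".geojson")))
    write_metadata(do.call(rbind, lapply(cohort, `[[`, "metadata")),
                   file.path(out, "metadata.csv"))
    return(invisible(out))
  }
  if (noun == "raters") {
    m <- simulate_rater_scores(do.call(rater_sim_spec, spec_args))
    write.csv(as.data.frame(m), file.path(out, "rater_scores.csv"))
    return(invisible(out))
  }
  stop("unknown simulate target: ", noun)
}
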