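#' Full-pipeline run configuration
#'
#' A single config drives phantom generation, fat quantification, Cobb
#' measurement, rater simulation + reliability analysis, and the cohort
#' correlation study. All randomness derives from the mandatory top-level
#' `seed` (stage seeds are derived deterministically from it unless a
#' stage block carries its own).
#'
#' @param out_dir run directory (created; numeric outputs are
#'   append-only).
#' @param seed mandatory integer master seed.
#' @param phantom,cohort,raters named lists of arguments to
#'   [phantom_spec()], [cohort_spec()] and [rater_noise_spec()].
#' @param fat_quant named list of arguments to [fat_quant_config()].
#' @param exclusions named list of arguments to [exclusion_rules()].
#' @param bootstrap_B bootstrap replicates for the reliability CI.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, seed, phantom = list(), cohort = list(),
                       raters = list(), fat_quant = list(),
                       exclusions = list(), bootstrap_B = 2000) {
  if (missing(seed) || is.null(seed))
    stop("config validation: seed is required")
  stopifnot_scalar_num(seed, "seed")
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config validation: out_dir is required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 phantom = phantom, cohort = cohort, raters = raters,
                 fat_quant = fat_quant, exclusions = exclusions,
                 bootstrap_B = bootstrap_B),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config` object (validated).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config validation: seed is required")
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

.stage <- function(name, log_con, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  msg <- sprintf("[%s] stage %-12s %.2fs",
                 format(Sys.time(), "%H:%M:%S"), name,
                 proc.time()[["elapsed"]] - t0)
  writeLines(msg, log_con)
  message(msg)
  res
}

#' Run the full synthetic-data pipeline
#'
#' Stages: phantom generation (volume, labels, ground truth, endplates) ->
#' fat quantification -> Cobb measurement -> cohort generation -> rater
#' simulation + reliability statistics -> correlation tables. Every run
#' writes a config snapshot and a library-version manifest next to its
#' outputs; re-running the same config reproduces all numeric outputs
#' bit-for-bit.
#'
#' @param cfg a [run_config()] or path to a JSON config.
#' @return the run directory, invisibly; outputs: `phantom/`,
#'   `metrics.csv`, `cobb.csv`, `cohort.csv`, `rater_matrix.csv`,
#'   `reliability.json`, `correlations.csv`, `stratified.csv`,
#'   `sensitivity.csv`, `config.json`, `manifest.json`, `log.txt`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "log.txt"), "a")
  on.exit(close(log_con))
  seeds <- derive_seeds(cfg$seed, 4L)

  ph_args <- cfg$phantom
  ph_args$seed <- ph_args$seed %||% seeds[1]
  ph <- .stage("phantom", log_con, {
    p <- generate_phantom(do.call(phantom_spec, ph_args))
    write_phantom(p, file.path(out, "phantom"))
    p
  })

  fq <- do.call(fat_quant_config, cfg$fat_quant)
  .stage("quantify", log_con, {
    metrics <- quantify_all(ph$volume, ph$labels, fq)
    metrics <- cbind(case_id = "phantom", metrics)
    utils::write.csv(metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
  })

  .stage("cobb", log_con, {
    res <- cobb_angle(ph$endplates)
    utils::write.csv(
      data.frame(case_id = "phantom", angle_deg = res$angle_deg,
                 planted_deg = cobb_from_phantom(ph$spec),
                 superior_inclination_deg = res$superior_inclination_deg,
                 inferior_inclination_deg = res$inferior_inclination_deg),
      file.path(out, "cobb.csv"), row.names = FALSE)
  })

  co_args <- cfg$cohort
  co_args$seed <- co_args$seed %||% seeds[2]
  cohort <- .stage("cohort", log_con, {
    co <- generate_cohort(do.call(cohort_spec, co_args))
    utils::write.csv(co, file.path(out, "cohort.csv"), row.names = FALSE)
    co
  })

  ra_args <- cfg$raters
  ra_args$seed <- ra_args$seed %||% seeds[3]
  .stage("reliability", log_con, {
    rm_ <- simulate_raters(cohort$cobb_mean, do.call(rater_noise_spec, ra_args))
    utils::write.csv(cbind(case_id = cohort$case_id, as.data.frame(rm_)),
                     file.path(out, "rater_matrix.csv"), row.names = FALSE)
    icc <- bootstrap_ci(rm_, B = cfg$bootstrap_B, seed = seeds[4])
    ba <- bland_altman(rm_)
    pcs <- per_case_sd(rm_)
    rs <- rater_summary(rm_)
    jsonlite::write_json(
      list(icc2k = icc$icc2k, ci_low = icc$ci_low, ci_high = icc$ci_high,
           n_bootstrap = icc$n_bootstrap, n = icc$n, k = icc$k,
           bland_altman = list(bias = ba$bias, loa_low = ba$loa_low,
                               loa_high = ba$loa_high),
           per_case_sd = list(mean = pcs$mean_sd, sd = pcs$sd_of_sd),
           grand_mean = rs$grand_mean,
           per_rater = rs$per_rater),
      file.path(out, "reliability.json"), auto_unbox = TRUE, digits = NA)
  })

  rules <- do.call(exclusion_rules, cfg$exclusions)
  .stage("correlation", log_con, {
    tab <- run_table(cohort, rules)
    utils::write.csv(tab, file.path(out, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(tab, "exclusion_log"),
                     file.path(out, "exclusion_log.csv"), row.names = FALSE)
    utils::write.csv(stratify(cohort, "sex", rules),
                     file.path(out, "stratified.csv"), row.names = FALSE)
    sens <- rbind(sensitivity(cohort, "fracture", rules),
                  sensitivity(cohort, "transitional", rules))
    utils::write.csv(sens, file.path(out, "sensitivity.csv"),
                     row.names = FALSE)
  })

  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(r_version = R.version.string,
         package = as.character(utils::packageVersion("kyphofat")),
         platform = R.version$platform,
         libraries = list(jsonlite = as.character(utils::packageVersion("jsonlite")))),
    file.path(out, "manifest.json"), auto_unbox = TRUE)
  invisible(out)
}
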