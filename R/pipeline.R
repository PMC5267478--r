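#' Default pipeline configuration
#'
#' Nested list mirroring the package defaults: a `model` block (reference
#' time, classification grid horizon), a `prior` block (bounds), a
#' `sampler` block (steps, burn-in, retained draws, seed, GRC likelihood
#' variant), a `data` block (synthetic design), and a `scenario` block
#' (dose grid, termination times).  A configuration may also be supplied
#' as a YAML file with the same structure.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    model = list(t_ref = 5, t_max = 600),
    prior = PRIOR_BOUNDS,
    data = list(times = c(2, 5, 10, 15, 30, 45, 60), sigma_log = 0.2,
                n_replicates = 4, seed = 1),
    sampler = list(n_steps = 2e4, burn_in = 0.5, n_keep = 500, seed = 1,
                   grc_model = "gaussian"),
    scenario = list(ku_grid = c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 4),
                    t_off_list = c(3, 12, Inf), t_report = 17),
    stages = c("synth", "fit", "ppd", "cba", "classify", "bifurcate",
               "scenarios", "report")
  )
}

#' Validate a pipeline configuration
#'
#' Checks the schema (block and field presence, value ranges) and fills
#' omitted fields from [default_config()].
#'
#' @param config nested list, or path to a YAML file.
#' @return the completed configuration, invisibly on success; errors name
#'   the offending block.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  merged <- utils::modifyList(def, config)
  if (!is.null(config$condition)) {
    if (isTRUE(config$condition$fp) && isTRUE(config$condition$fn))
      stop("config block 'condition': fp and fn must not both be TRUE")
  }
  with(merged$sampler, {
    if (n_steps < 100) stop("config block 'sampler': n_steps too small")
    if (burn_in <= 0 || burn_in >= 1)
      stop("config block 'sampler': burn_in must be in (0, 1)")
  })
  if (merged$data$sigma_log <= 0)
    stop("config block 'data': sigma_log must be > 0")
  if (!all(merged$stages %in% def$stages))
    stop("config block 'stages': unknown stage name(s) ",
         paste(setdiff(merged$stages, def$stages), collapse = ", "))
  invisible(merged)
}

#' Run the full analysis pipeline
#'
#' Executes the stages `synth` (generate the synthetic dataset), `fit`
#' (MCMC calibration), `ppd` (posterior predictive time courses), `cba`
#' (per-draw steady-state classification at rest), `classify`
#' (trajectory classification), `bifurcate` (bifurcation sweep for the
#' shipped fixtures), `scenarios` (dose response, MEK inhibition,
#' feedback removal, signal termination) and `report` (plain-text
#' summary), persisting each stage's outputs as CSV/JSON under `out_dir`.
#' Completed stages are skipped on re-run (resume semantics); a manifest
#' records seeds, package version, and output hashes.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir artifact directory, created if needed.
#' @param resume skip stages whose outputs already exist (default TRUE).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = "mapkqb_run",
                         resume = TRUE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  log_msg <- function(...) message("[mapkqb] ", ...)
  done <- function(f) resume && all(file.exists(p(f)))
  manifest <- list(package_version = as.character(utils::packageVersion("mapkqb")),
                   config = cfg, stages = list())

  if ("synth" %in% cfg$stages) {
    if (!done("data_timecourse.csv")) {
      log_msg("synth: generating dataset (seed ", cfg$data$seed, ")")
      design <- design_spec(times = cfg$data$times,
                            sigma_log = cfg$data$sigma_log,
                            n_replicates = cfg$data$n_replicates,
                            seed = cfg$data$seed)
      write_dataset_csv(generate_dataset(design), p("data"))
    } else log_msg("synth: outputs present, skipping")
  }
  data <- read_dataset_csv(p("data"), sigma_log = cfg$data$sigma_log)

  if ("fit" %in% cfg$stages) {
    if (!done("posterior.csv")) {
      log_msg("fit: MCMC (", cfg$sampler$n_steps, " steps, seed ",
              cfg$sampler$seed, ")")
      post <- mcmc_sample(data, n_steps = cfg$sampler$n_steps,
                          seed = cfg$sampler$seed,
                          init = jitter_params(design_spec()$theta_star,
                                               cfg$sampler$seed),
                          burn_in = cfg$sampler$burn_in,
                          n_keep = cfg$sampler$n_keep,
                          grc_model = cfg$sampler$grc_model)
      write_posterior_csv(post, p("posterior.csv"))
      log_msg("fit: acceptance rate ", round(post$accept_rate, 3))
    } else log_msg("fit: outputs present, skipping")
  }
  post <- if (file.exists(p("posterior.csv")))
    read_posterior_csv(p("posterior.csv")) else NULL

  if ("ppd" %in% cfg$stages && !is.null(post) && !done("ppd_ngf.csv")) {
    log_msg("ppd: posterior predictive bands")
    for (gf in c("EGF", "NGF")) {
      ppd <- posterior_predict(post, condition_for(gf),
                               t_grid = cfg$data$times,
                               sigma_log = cfg$data$sigma_log)
      df <- data.frame(time_min = rep(ppd$times, 3),
                       species = rep(ppd$species, each = length(ppd$times)),
                       mean = as.vector(ppd$mean),
                       q025 = as.vector(ppd$quantiles[, , 1]),
                       median = as.vector(ppd$quantiles[, , 2]),
                       q975 = as.vector(ppd$quantiles[, , 3]))
      utils::write.csv(df, p(paste0("ppd_", tolower(gf), ".csv")),
                       row.names = FALSE)
      if (ppd$n_failed > 0)
        log_msg("ppd ", gf, ": ", ppd$n_failed, " draws failed")
    }
  }

  if ("cba" %in% cfg$stages && !is.null(post) && !done("cba.csv")) {
    log_msg("cba: steady-state classification at rest")
    draws <- as_draws_matrix(post)
    rows <- lapply(seq_len(nrow(draws)), function(i) {
      ss <- find_steady_states(mapk_params(draws[i, ]), 0, cond_ngf())
      upper <- if (ss$classification == "bistable")
        max(ss$states[ss$stability == "stable", "x4"]) else NA_real_
      data.frame(draw_id = i, u = 0, n_steady = nrow(ss$states),
                 n_stable = ss$n_stable, class = ss$classification,
                 x4bar_upper = upper)
    })
    utils::write.csv(do.call(rbind, rows), p("cba.csv"), row.names = FALSE)
  }

  if ("classify" %in% cfg$stages && !is.null(post) &&
      !done("classification.csv")) {
    log_msg("classify: trajectory classification")
    pc <- population_classify(post)
    utils::write.csv(pc$labels, p("classification.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(pc$fractions), p("class_fractions.json"),
                         auto_unbox = TRUE, digits = NA)
    if (pc$n_failed > 0) log_msg("classify: ", pc$n_failed, " draws failed")
  }

  if ("bifurcate" %in% cfg$stages && !done("bifurcation.csv")) {
    log_msg("bifurcate: input sweeps for the shipped fixtures")
    rows <- lapply(c("bistable", "quasi_bistable"), function(nm) {
      bif <- bifurcation_sweep(mapk_fixture(nm))
      cbind(fixture = nm, bif$branches)
    })
    utils::write.csv(do.call(rbind, rows), p("bifurcation.csv"),
                     row.names = FALSE)
  }

  if ("scenarios" %in% cfg$stages && !is.null(post) &&
      !done("scenarios.json")) {
    log_msg("scenarios: validation experiments")
    dr <- dose_response(post, "NGF", ku_grid = cfg$scenario$ku_grid)
    term <- signal_termination(post, "NGF",
                               t_off_list = cfg$scenario$t_off_list,
                               t_report = cfg$scenario$t_report)
    mi <- mek_inhibition(post)
    fr <- feedback_removal(post)
    summary <- list(
      dose_bimodal = stats::setNames(as.list(dr$bimodal), dr$ku),
      termination_medians = stats::setNames(as.list(term$median),
                                            paste0("t_off_", term$t_off)),
      mek_inhibited_praf_t60_median =
        unname(mi$inhibited$quantiles[as.character(60), 2]),
      feedback_removed_pperk_t60_median =
        unname(fr$removed$quantiles[as.character(60), 2]))
    jsonlite::write_json(summary, p("scenarios.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("report" %in% cfg$stages) {
    lines <- c("mapkqb pipeline report", strrep("=", 22),
               paste("package version:", manifest$package_version))
    if (file.exists(p("class_fractions.json"))) {
      fr <- jsonlite::read_json(p("class_fractions.json"))
      lines <- c(lines, "",
                 sprintf("class fractions: bistable %.3f / quasi-bistable %.3f / monostable %.3f",
                         fr$class1_bistable, fr$class2_quasi_bistable,
                         fr$class3_monostable))
    }
    if (file.exists(p("cba.csv"))) {
      cba <- utils::read.csv(p("cba.csv"))
      lines <- c(lines, sprintf("CBA bistable at rest: %d / %d draws",
                                sum(cba$class == "bistable"), nrow(cba)))
    }
    writeLines(lines, p("report.txt"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  hashes <- tools::md5sum(files)
  manifest$outputs <- as.list(stats::setNames(hashes, basename(files)))
  manifest$seeds <- list(data = cfg$data$seed, sampler = cfg$sampler$seed)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

# deterministic small perturbation of a parameter vector, used to
# initialize chains away from (but near) a reference point
jitter_params <- function(theta, seed = 1, sd_log = 0.05) {
  with_seed(seed, {
    th <- exp(log(as.numeric(unclass(theta))) + stats::rnorm(12, 0, sd_log))
    # stay strictly inside the prior support
    th <- pmin(pmax(th, prior_lower() * (1 + 1e-9)),
               prior_upper() * (1 - 1e-9))
    mapk_params(th)
  })
}
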