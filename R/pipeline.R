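# Workflow driver: a validated run configuration plus one entry point that
# wires the modules into the fit / predict / validate / compare / analyze /
# simulate commands. Reports are machine-readable (JSON/CSV) and embed the
# configuration that produced them; logging goes to stderr.

#' Build and validate a run configuration
#'
#' Settings are taken from an optional YAML file and overridden by arguments
#' given here (arguments win). All validation failures are reported at once.
#'
#' @param ... Named settings: `t_equil` (ns, > 0 allowed 0), `se_definition`
#'   (`"rmse"`/`"dof_corrected"`), `temperature` (K), `cutoff` (A), `seed`
#'   (integer), and the per-command paths `table`, `params`, `train`,
#'   `test`, `pdb`, `out_dir`, `preset`, `ligand_resname`.
#' @param yaml_file Optional YAML file of the same settings.
#' @return A validated list of class `lie_run_config`.
#' @export
run_config <- function(..., yaml_file = NULL) {
  cfg <- list(t_equil = 5, se_definition = "rmse", temperature = 300,
              cutoff = 10, seed = 1L, out_dir = ".", preset = "minimal")
  if (!is.null(yaml_file)) {
    if (!file.exists(yaml_file))
      stop(sprintf("config file not found: %s", yaml_file), call. = FALSE)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml_file))
  }
  override <- list(...)
  if (length(override) && is.null(names(override)))
    stop("configuration overrides must be named", call. = FALSE)
  cfg <- utils::modifyList(cfg, override)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$t_equil) && length(cfg$t_equil) == 1L &&
        is.finite(cfg$t_equil) && cfg$t_equil >= 0,
      "t_equil must be a single number >= 0")
  chk(cfg$se_definition %in% c("rmse", "dof_corrected"),
      "se_definition must be 'rmse' or 'dof_corrected'")
  chk(is.numeric(cfg$temperature) && cfg$temperature > 0,
      "temperature must be > 0")
  chk(is.numeric(cfg$cutoff) && cfg$cutoff > 0, "cutoff must be > 0")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  for (p in c("table", "params", "train", "test", "pdb"))
    if (!is.null(cfg[[p]]))
      chk(file.exists(cfg[[p]]), sprintf("%s: file not found: %s", p, cfg[[p]]))
  if (length(problems))
    stop(paste(c("invalid configuration:", paste(" -", problems)),
               collapse = "\n"), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "lie_run_config"
  cfg
}

.log_msg <- function(...) message(sprintf(...))

.config_payload <- function(config) {
  unclass(config)
}

.write_report <- function(payload, config, path) {
  payload$config <- .config_payload(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a pipeline command
#'
#' Executes one of the workflow commands against a validated
#' [run_config()]:
#' \describe{
#'   \item{fit}{Fit the LIE parameters to `config$table` (complex-table
#'     CSV); writes `fit.json`.}
#'   \item{predict}{Apply parameters from `config$params` (a fit report) to
#'     `config$table`; writes `predictions.csv`.}
#'   \item{validate}{Fit on `config$train`, evaluate the frozen parameters
#'     on `config$test`; writes `validation.json`.}
#'   \item{compare}{Correlate every `dg_*` method column of `config$table`
#'     with experiment; writes `method_comparison.csv` and `.json`.}
#'   \item{analyze}{C-alpha RMSD, hydrogen bonds and non-bonded contacts
#'     for the multi-model PDB in `config$pdb`; writes `rmsd.csv` and
#'     `contacts.csv`.}
#'   \item{simulate}{Write a synthetic fixture bundle
#'     ([write_fixture_bundle()]) into `config$out_dir`.}
#' }
#' Every JSON report embeds the configuration used, and re-running with the
#' same configuration and inputs reproduces the report byte for byte.
#'
#' @param config A [run_config()].
#' @param command One of `"fit"`, `"predict"`, `"validate"`, `"compare"`,
#'   `"analyze"`, `"simulate"`.
#' @return Invisibly, a list with the computed objects and the paths of the
#'   files written (`$files`).
#' @export
run_pipeline <- function(config, command = c("fit", "predict", "validate",
                                             "compare", "analyze",
                                             "simulate")) {
  if (!inherits(config, "lie_run_config"))
    stop("'config' must come from run_config()", call. = FALSE)
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(command,
    fit = {
      if (is.null(config$table)) stop("'table' path required", call. = FALSE)
      tab <- read_complex_table(config$table, config$temperature)
      fit <- fit_lie(tab, config$se_definition, config$temperature)
      path <- file.path(config$out_dir, "fit.json")
      write_fit_json(fit, path)
      # re-write with config embedded
      payload <- jsonlite::read_json(path, simplifyVector = TRUE)
      .write_report(payload, config, path)
      .log_msg("fit: n = %d, alpha = %.4f, beta = %.4f, gamma = %.4f, R = %.3f, se = %.3f",
               fit$n, fit$params$alpha, fit$params$beta, fit$params$gamma,
               fit$r, fit$se)
      list(fit = fit, files = path)
    },
    predict = {
      if (is.null(config$table) || is.null(config$params))
        stop("'table' and 'params' paths required", call. = FALSE)
      tab <- utils::read.csv(config$table, stringsAsFactors = FALSE)
      params <- read_fit_params(config$params)
      pred <- data.frame(ligand_id = tab$ligand_id,
                         dg_lie = lie_predict(tab, params))
      path <- file.path(config$out_dir, "predictions.csv")
      utils::write.csv(pred, path, row.names = FALSE, quote = FALSE)
      .log_msg("predict: %d ligands with alpha = %.4f, beta = %.4f, gamma = %.4f",
               nrow(pred), params$alpha, params$beta, params$gamma)
      list(predictions = pred, params = params, files = path)
    },
    validate = {
      if (is.null(config$train) || is.null(config$test))
        stop("'train' and 'test' paths required", call. = FALSE)
      train <- read_complex_table(config$train, config$temperature)
      test <- read_complex_table(config$test, config$temperature)
      fit <- fit_lie(train, config$se_definition, config$temperature)
      eval_fit <- evaluate_lie(test, fit$params, config$se_definition,
                               config$temperature)
      payload <- list(
        training = list(n = fit$n, pearson_r = fit$r, standard_error = fit$se,
                        parameters = list(alpha = fit$params$alpha,
                                          beta = fit$params$beta,
                                          gamma = fit$params$gamma)),
        test = list(n = eval_fit$n, pearson_r = eval_fit$r,
                    standard_error = eval_fit$se),
        se_definition = config$se_definition)
      path <- file.path(config$out_dir, "validation.json")
      .write_report(payload, config, path)
      .log_msg("validate: train R = %.3f (se %.3f, n %d); test R = %.3f (se %.3f, n %d)",
               fit$r, fit$se, fit$n, eval_fit$r, eval_fit$se, eval_fit$n)
      list(fit = fit, evaluation = eval_fit, files = path)
    },
    compare = {
      if (is.null(config$table)) stop("'table' path required", call. = FALSE)
      tab <- read_method_table(config$table)
      cmp <- compare_methods(tab)
      csv_path <- file.path(config$out_dir, "method_comparison.csv")
      utils::write.csv(cmp, csv_path, row.names = FALSE, quote = FALSE)
      json_path <- file.path(config$out_dir, "method_comparison.json")
      .write_report(list(methods = cmp), config, json_path)
      .log_msg("compare: %s",
               paste(sprintf("%s R = %.3f", cmp$method, cmp$r),
                     collapse = "; "))
      list(comparison = cmp, files = c(csv_path, json_path))
    },
    analyze = {
      if (is.null(config$pdb)) stop("'pdb' path required", call. = FALSE)
      frames <- read_structure_pdb(config$pdb)
      rmsd <- ca_rmsd_series(frames)
      contacts <- do.call(rbind, lapply(seq_along(frames), function(k) {
        s <- frames[[k]]
        nhb <- if (any(s$atoms$element == "H"))
          nrow(detect_hbonds(s)) else NA_integer_
        data.frame(frame = k, n_hbonds = nhb, n_nbc = count_nbc(s)$n)
      }))
      rmsd_path <- file.path(config$out_dir, "rmsd.csv")
      contact_path <- file.path(config$out_dir, "contacts.csv")
      utils::write.csv(rmsd, rmsd_path, row.names = FALSE, quote = FALSE)
      utils::write.csv(contacts, contact_path, row.names = FALSE,
                       quote = FALSE)
      .log_msg("analyze: %d frame(s), mean RMSD %.3f A, mean NBC %.2f",
               nrow(rmsd), mean(rmsd$rmsd_A), mean(contacts$n_nbc))
      list(rmsd = rmsd, contacts = contacts,
           files = c(rmsd_path, contact_path))
    },
    simulate = {
      manifest <- write_fixture_bundle(config$out_dir, config$preset,
                                       config$seed)
      .log_msg("simulate: preset '%s' with %d trace(s) in %s",
               config$preset, manifest$n_traces, config$out_dir)
      list(manifest = manifest,
           files = file.path(config$out_dir, "manifest.json"))
    })
  invisible(out)
}
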