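# The LIE model: dG = alpha * dVvdW + beta * dVelec + gamma, its least-squares
# calibration, validation metrics, Ki conversion, and cross-method comparison.

#' LIE coefficients
#'
#' `alpha` scales the nonpolar (van der Waals) interaction-energy difference,
#' `beta` the polar (electrostatic) difference; `gamma` is a constant offset
#' in kcal/mol absorbing system-wide hydrophobic/desolvation effects.
#'
#' @param alpha,beta Dimensionless scaling factors.
#' @param gamma Constant offset in kcal/mol.
#' @return An object of class `lie_parameters`.
#' @export
#' @examples
#' abeta_lie_parameters()           # refit for the amyloid-beta protofibril
#' standard_lie_parameters()        # literature defaults, gamma = 0
lie_parameters <- function(alpha, beta, gamma = 0) {
  .check_scalar_number(alpha, "alpha")
  .check_scalar_number(beta, "beta")
  .check_scalar_number(gamma, "gamma")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "lie_parameters")
}

#' @export
print.lie_parameters <- function(x, ...) {
  cat(sprintf("<lie_parameters> alpha = %.4g, beta = %.4g, gamma = %.4g kcal/mol\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @describeIn lie_parameters The parameter set calibrated on amyloid-beta
#'   protofibril complexes: alpha = 0.288, beta = -0.049, gamma = -5.880.
#' @export
abeta_lie_parameters <- function() lie_parameters(0.288, -0.049, -5.880)

#' @describeIn lie_parameters The literature standard parameters
#'   (alpha = 0.18, beta = 0.5) with no offset, used as a negative control.
#' @export
standard_lie_parameters <- function() lie_parameters(0.18, 0.5, 0)

#' Averaged energies of one ligand-protofibril complex
#'
#' The four replica-averaged ligand--surroundings interaction energies that
#' enter the LIE model: van der Waals and electrostatic components in the
#' bound (complexed) and free (ligand in solvent) states.
#'
#' @param ligand_id Character ligand identifier.
#' @param vdw_bound,vdw_free,elec_bound,elec_free Averaged energies in
#'   kcal/mol, all finite.
#' @return An object of class `complex_energies`.
#' @export
complex_energies <- function(ligand_id, vdw_bound, vdw_free,
                             elec_bound, elec_free) {
  for (nm in c("vdw_bound", "vdw_free", "elec_bound", "elec_free"))
    .check_scalar_number(get(nm), nm)
  structure(list(ligand_id = as.character(ligand_id),
                 vdw_bound = vdw_bound, vdw_free = vdw_free,
                 elec_bound = elec_bound, elec_free = elec_free),
            class = "complex_energies")
}

#' @export
print.complex_energies <- function(x, ...) {
  cat(sprintf("<complex_energies> ligand %s\n", x$ligand_id))
  cat(sprintf("  vdW  bound %8.3f | free %8.3f | delta %8.3f kcal/mol\n",
              x$vdw_bound, x$vdw_free, x$vdw_bound - x$vdw_free))
  cat(sprintf("  elec bound %8.3f | free %8.3f | delta %8.3f kcal/mol\n",
              x$elec_bound, x$elec_free, x$elec_bound - x$elec_free))
  invisible(x)
}

#' Bound-minus-free interaction-energy differences
#'
#' @param ce A [complex_energies()] record.
#' @return Named numeric vector `c(d_vdw, d_elec)` in kcal/mol.
#' @export
delta_energies <- function(ce) {
  stopifnot(inherits(ce, "complex_energies"))
  c(d_vdw = ce$vdw_bound - ce$vdw_free,
    d_elec = ce$elec_bound - ce$elec_free)
}

#' Predict a binding free energy with the LIE model
#'
#' `dG = alpha * (Vvdw_bound - Vvdw_free) + beta * (Velec_bound - Velec_free)
#' + gamma`. More negative values mean stronger binding.
#'
#' @param ce A [complex_energies()] record, or a data.frame in the complex
#'   table layout (see [read_complex_table()]) for vectorised prediction.
#' @param params A [lie_parameters()] object.
#' @return Predicted binding free energy (kcal/mol); a vector for tables.
#' @export
lie_predict <- function(ce, params) {
  stopifnot(inherits(params, "lie_parameters"))
  if (inherits(ce, "complex_energies")) {
    d <- delta_energies(ce)
    return(unname(params$alpha * d[["d_vdw"]] +
                  params$beta * d[["d_elec"]] + params$gamma))
  }
  df <- .as_complex_table(ce, need_dg = FALSE)
  params$alpha * (df$vdw_bound - df$vdw_free) +
    params$beta * (df$elec_bound - df$elec_free) + params$gamma
}

# complex-table layout: ligand_id,vdw_bound,vdw_free,elec_bound,elec_free
# with dg_exp and/or ki_molar for datasets carrying experimental affinities
.as_complex_table <- function(df, need_dg = TRUE, temperature = 300) {
  if (!is.data.frame(df))
    stop("expected a data.frame in the complex-table layout", call. = FALSE)
  need <- c("ligand_id", "vdw_bound", "vdw_free", "elec_bound", "elec_free")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("complex table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$ligand_id <- as.character(df$ligand_id)
  if (anyDuplicated(df$ligand_id))
    stop("duplicated ligand_id in complex table", call. = FALSE)
  for (nm in need[-1L])
    if (!is.numeric(df[[nm]]) || any(!is.finite(df[[nm]])))
      stop(sprintf("column '%s' must be finite numeric", nm), call. = FALSE)
  if (need_dg) {
    if (is.null(df$dg_exp) && is.null(df$ki_molar))
      stop("complex table needs 'dg_exp' (kcal/mol) or 'ki_molar'",
           call. = FALSE)
    if (is.null(df$dg_exp))
      df$dg_exp <- ki_to_dg(df$ki_molar, temperature)
    if (any(!is.finite(df$dg_exp)))
      stop("column 'dg_exp' must be finite numeric", call. = FALSE)
  }
  df
}

#' Read a per-ligand complex-energy table from CSV
#'
#' Layout: `ligand_id,vdw_bound,vdw_free,elec_bound,elec_free,dg_exp`
#' (kcal/mol), optionally `ki_molar` instead of `dg_exp`; if only `ki_molar`
#' is present the experimental free energy is derived with [ki_to_dg()] at
#' `temperature`.
#'
#' @param path CSV path.
#' @param temperature Temperature in K for Ki conversion (default 300).
#' @return A validated data.frame.
#' @export
read_complex_table <- function(path, temperature = 300) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  .as_complex_table(utils::read.csv(path, stringsAsFactors = FALSE),
                    need_dg = TRUE, temperature = temperature)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return The sample correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations for a correlation", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Standard error of predictions
#'
#' Two conventions are provided because reported "standard errors" in the
#' binding free energy literature are ambiguous: `rmse` is
#' `sqrt(sum(r^2)/n)`; `dof_corrected` divides by `n - n_params` instead,
#' charging the fitted parameters their degrees of freedom.
#'
#' @param residuals Numeric vector of (predicted - experimental) residuals,
#'   kcal/mol.
#' @param n_params Number of parameters fitted on the same data (3 for a
#'   fresh LIE fit, 0 when evaluating fixed parameters).
#' @param definition `"rmse"` (default) or `"dof_corrected"`.
#' @return Standard error in kcal/mol.
#' @export
standard_error <- function(residuals, n_params = 0L,
                           definition = c("rmse", "dof_corrected")) {
  definition <- match.arg(definition)
  n <- length(residuals)
  if (n < 1L) stop("no residuals", call. = FALSE)
  if (any(!is.finite(residuals)))
    stop("residuals must be finite", call. = FALSE)
  denom <- if (definition == "rmse") n else n - n_params
  if (denom <= 0)
    stop(sprintf("need more than %d residuals for dof_corrected", n_params),
         call. = FALSE)
  sqrt(sum(residuals^2) / denom)
}

#' Convert an inhibition constant to a binding free energy
#'
#' `dG = R T ln(Ki)` at 1 M standard state, with
#' R = 1.98720425e-3 kcal/(mol K).
#'
#' @param ki Inhibition constant in molar, > 0 (vectorised).
#' @param temperature Temperature in K, > 0.
#' @return Binding free energy in kcal/mol (negative for sub-molar Ki).
#' @export
#' @examples
#' ki_to_dg(1e-6, 300)  # a 1 uM inhibitor at 300 K
ki_to_dg <- function(ki, temperature = 300) {
  .check_scalar_number(temperature, "temperature", positive = TRUE)
  if (!is.numeric(ki) || any(!is.finite(ki)) || any(ki <= 0))
    stop("'ki' must be finite and > 0 (molar)", call. = FALSE)
  lie_constants[["gas_constant"]] * temperature * log(ki)
}

.new_fit_result <- function(params, fitted, table, se_definition, n_params) {
  residuals <- fitted - table$dg_exp
  structure(
    list(params = params,
         r = pearson_r(fitted, table$dg_exp),
         se = standard_error(residuals, n_params, se_definition),
         se_definition = se_definition,
         n = nrow(table),
         ligand_id = table$ligand_id,
         predicted = fitted,
         observed = table$dg_exp,
         residuals = residuals),
    class = "lie_fit")
}

#' Fit the LIE model by ordinary least squares
#'
#' Regresses experimental binding free energies on the bound-minus-free van
#' der Waals and electrostatic energy differences, with the constant `gamma`
#' as a free intercept. The solution uses the QR decomposition via
#' [stats::lm()]; a design matrix with condition number above 1e10 is
#' rejected as collinear.
#'
#' @param table Data.frame in the complex-table layout with experimental
#'   affinities (see [read_complex_table()]); at least 4 rows.
#' @param se_definition Standard-error convention, see [standard_error()];
#'   the fit charges its 3 parameters under `"dof_corrected"`.
#' @param temperature Temperature in K for Ki conversion when `dg_exp` is
#'   absent.
#' @return An object of class `lie_fit` with elements `params`
#'   ([lie_parameters()]), `r` (Pearson correlation of predicted vs
#'   experimental), `se` (kcal/mol), `residuals` (predicted - experimental),
#'   `n`, and the per-ligand predictions.
#' @export
fit_lie <- function(table, se_definition = c("rmse", "dof_corrected"),
                    temperature = 300) {
  se_definition <- match.arg(se_definition)
  df <- .as_complex_table(table, need_dg = TRUE, temperature = temperature)
  if (nrow(df) < 4L)
    stop("need >= 4 complexes to fit 3 parameters", call. = FALSE)
  d_vdw <- df$vdw_bound - df$vdw_free
  d_elec <- df$elec_bound - df$elec_free
  X <- cbind(1, d_vdw, d_elec)
  if (kappa(X, exact = TRUE) > 1e10)
    stop("collinear energy differences: LIE design matrix is singular",
         call. = FALSE)
  fit <- stats::lm(dg_exp ~ d_vdw + d_elec,
                   data = data.frame(dg_exp = df$dg_exp,
                                     d_vdw = d_vdw, d_elec = d_elec))
  cf <- stats::coef(fit)
  params <- lie_parameters(alpha = unname(cf[["d_vdw"]]),
                           beta = unname(cf[["d_elec"]]),
                           gamma = unname(cf[["(Intercept)"]]))
  .new_fit_result(params, unname(stats::fitted(fit)), df,
                  se_definition, n_params = 3L)
}

#' Evaluate fixed LIE parameters on a dataset
#'
#' Applies [lie_predict()] with fixed parameters (no refitting) and reports
#' the Pearson correlation and standard error against the experimental
#' affinities; since no parameter was fitted on this set, the standard error
#' uses zero fitted degrees of freedom.
#'
#' @inheritParams fit_lie
#' @param params A [lie_parameters()] object.
#' @return An object of class `lie_fit` (see [fit_lie()]).
#' @export
evaluate_lie <- function(table, params,
                         se_definition = c("rmse", "dof_corrected"),
                         temperature = 300) {
  se_definition <- match.arg(se_definition)
  df <- .as_complex_table(table, need_dg = TRUE, temperature = temperature)
  if (nrow(df) < 3L)
    stop("need >= 3 complexes to evaluate", call. = FALSE)
  .new_fit_result(params, lie_predict(df, params), df,
                  se_definition, n_params = 0L)
}

#' @export
print.lie_fit <- function(x, ...) {
  cat(sprintf("<lie_fit> n = %d complexes\n", x$n))
  cat(sprintf("  alpha = %.4f, beta = %.4f, gamma = %.4f kcal/mol\n",
              x$params$alpha, x$params$beta, x$params$gamma))
  cat(sprintf("  Pearson R = %.3f, standard error (%s) = %.3f kcal/mol\n",
              x$r, x$se_definition, x$se))
  invisible(x)
}

#' Write / read a fit report as JSON
#'
#' The report holds the parameters, correlation, standard error and its
#' definition, n, and per-ligand residuals — everything needed to re-apply
#' or audit a calibration.
#'
#' @param fit An object of class `lie_fit`.
#' @param path Output (or input) JSON path.
#' @return `write_fit_json`: `path`, invisibly. `read_fit_params`: the
#'   [lie_parameters()] stored in the report.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lie_fit"))
  payload <- list(
    parameters = list(alpha = fit$params$alpha, beta = fit$params$beta,
                      gamma = fit$params$gamma),
    pearson_r = fit$r, standard_error = fit$se,
    se_definition = fit$se_definition, n = fit$n,
    ligands = data.frame(ligand_id = fit$ligand_id,
                         dg_pred = fit$predicted,
                         dg_exp = fit$observed,
                         residual = fit$residuals))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_params <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)$parameters
  lie_parameters(p$alpha, p$beta, p$gamma)
}

#' Correlate several methods' predictions with experiment
#'
#' Given a table with one experimental column and one predicted-dG column
#' per method, computes each method's Pearson correlation and RMSE against
#' experiment and ranks methods by correlation. This is how end-point
#' methods (LIE, FEP, MM/PBSA) are compared on a common ligand panel.
#'
#' @param table Data.frame with columns `ligand_id`, `dg_exp`, and one or
#'   more `dg_<method>` columns (kcal/mol), e.g. the layout
#'   `ligand_id,dg_exp,dg_lie,dg_fep,dg_mmpbsa`.
#' @param methods Optional character vector naming the method columns to
#'   use (defaults to every column starting with `dg_` other than
#'   `dg_exp`).
#' @return Data.frame `method,r,se,n`, ordered by decreasing `r`.
#' @export
compare_methods <- function(table, methods = NULL) {
  if (!is.data.frame(table))
    stop("expected a data.frame", call. = FALSE)
  if (!all(c("ligand_id", "dg_exp") %in% names(table)))
    stop("table needs 'ligand_id' and 'dg_exp' columns", call. = FALSE)
  if (is.null(methods))
    methods <- setdiff(grep("^dg_", names(table), value = TRUE), "dg_exp")
  if (length(methods) == 0L)
    stop("no method columns (dg_*) found", call. = FALSE)
  miss <- setdiff(methods, names(table))
  if (length(miss))
    stop(sprintf("missing method column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  rows <- lapply(methods, function(m) {
    keep <- is.finite(table[[m]]) & is.finite(table$dg_exp)
    if (sum(keep) < 3L)
      stop(sprintf("method '%s': need >= 3 ligands with finite values", m),
           call. = FALSE)
    pred <- table[[m]][keep]
    obs <- table$dg_exp[keep]
    data.frame(method = sub("^dg_", "", m),
               r = pearson_r(pred, obs),
               se = standard_error(pred - obs, 0L, "rmse"),
               n = sum(keep))
  })
  out <- do.call(rbind, rows)
  out[order(-out$r), , drop = FALSE]
}

#' Read a method-comparison table from CSV
#'
#' Layout: `ligand_id,dg_exp,dg_lie,dg_fep,dg_mmpbsa` (kcal/mol); any set of
#' `dg_<method>` columns is accepted.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_method_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "dg_exp") %in% names(df)))
    stop(sprintf("%s: expected 'ligand_id' and 'dg_exp' columns", path),
         call. = FALSE)
  df
}

#' Deterministic random train/test split
#'
#' @param table Data.frame (one row per ligand).
#' @param n_train Number of rows assigned to the training set,
#'   `0 < n_train < nrow(table)`.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with data.frames `train` and `test` forming a disjoint,
#'   exhaustive partition of the input rows.
#' @export
random_split <- function(table, n_train, seed = 1L) {
  if (!is.data.frame(table)) stop("expected a data.frame", call. = FALSE)
  n <- nrow(table)
  if (!is.numeric(n_train) || n_train != round(n_train) ||
      n_train <= 0 || n_train >= n)
    stop(sprintf("'n_train' must be an integer in (0, %d)", n), call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}
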