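# Interaction-energy time series: construction, GROMACS .xvg / CSV input,
# equilibration discard, and replica averaging. Internal units: ns, kcal/mol.

#' Construct an interaction-energy time series
#'
#' An `energy_trace` holds one ligand--surroundings interaction-energy
#' component (van der Waals or electrostatic) recorded along one simulation
#' replica of one state (ligand bound to the solvated protofibril, or free in
#' solvent).
#'
#' @param times Numeric vector of frame times in nanoseconds, strictly
#'   increasing.
#' @param values Numeric vector of interaction energies in kcal/mol, one per
#'   frame, all finite.
#' @param component `"vdw"` or `"elec"`.
#' @param state `"bound"` or `"free"`.
#' @param replica_id Integer replica label.
#' @param ligand_id Character ligand identifier (a PubChem CID works well).
#'
#' @return An object of class `energy_trace`.
#' @export
#' @examples
#' tr <- energy_trace(times = 1:5, values = rep(-40, 5),
#'                    component = "vdw", state = "bound",
#'                    replica_id = 1L, ligand_id = "16954")
#' trace_mean(tr)
energy_trace <- function(times, values, component, state,
                         replica_id = 1L, ligand_id = "ligand") {
  component <- .match_component(component)
  state <- .match_state(state)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(times) < 1L)
    stop("an energy trace needs at least one frame", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("all times must be finite", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("all energy values must be finite", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(
    list(times = times, values = values,
         component = component, state = state,
         replica_id = as.integer(replica_id),
         ligand_id = as.character(ligand_id)),
    class = "energy_trace"
  )
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("<energy_trace> ligand %s | %s / %s | replica %d\n",
              x$ligand_id, x$component, x$state, x$replica_id))
  cat(sprintf("  %d frames, t = %.4g .. %.4g ns, mean %.4f kcal/mol\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              mean(x$values)))
  invisible(x)
}

#' @export
length.energy_trace <- function(x) length(x$times)

#' Read a GROMACS-style .xvg energy file
#'
#' Parses the whitespace-separated numeric body of a `.xvg` file (lines
#' beginning with `#` or `@` are comments/graphing directives and are
#' skipped). Column 1 is taken as time in picoseconds and converted to
#' nanoseconds; the energy column defaults to column 2 because GROMACS
#' energy extractions can carry several terms per row.
#'
#' @param path Path to the file.
#' @inheritParams energy_trace
#' @param input_units `"kJ_per_mol"` (GROMACS default; divided by 4.184) or
#'   `"kcal_per_mol"` (taken as is).
#' @param energy_column Index of the energy column (default 2).
#'
#' @return An [energy_trace()].
#' @export
read_xvg <- function(path, component, state, replica_id = 1L,
                     ligand_id = "ligand",
                     input_units = c("kJ_per_mol", "kcal_per_mol"),
                     energy_column = 2L) {
  input_units <- match.arg(input_units)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    stop(sprintf("no data rows in %s", path), call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  ncol_min <- min(lengths(fields))
  if (ncol_min < max(2L, energy_column))
    stop(sprintf("%s: need at least %d columns, found a row with %d",
                 path, max(2L, energy_column), ncol_min), call. = FALSE)
  t_ps <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  e_raw <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", energy_column)))
  if (anyNA(t_ps) || anyNA(e_raw))
    stop(sprintf("non-numeric body line in %s", path), call. = FALSE)
  values <- if (input_units == "kJ_per_mol")
    e_raw / lie_constants[["kj_per_kcal"]] else e_raw
  energy_trace(times = t_ps / 1000, values = values,
               component = component, state = state,
               replica_id = replica_id, ligand_id = ligand_id)
}

#' Read an energy trace from CSV
#'
#' Expects the two-column layout `time_ns,energy_kcal_mol`.
#'
#' @inheritParams read_xvg
#' @return An [energy_trace()].
#' @export
read_trace_csv <- function(path, component, state, replica_id = 1L,
                           ligand_id = "ligand") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_ns", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  energy_trace(times = df$time_ns, values = df$energy_kcal_mol,
               component = component, state = state,
               replica_id = replica_id, ligand_id = ligand_id)
}

#' Write an energy trace to CSV (`time_ns,energy_kcal_mol`)
#'
#' @param trace An [energy_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "energy_trace"))
  utils::write.csv(
    data.frame(time_ns = trace$times, energy_kcal_mol = trace$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard the equilibration portion of a trace
#'
#' The systems studied here equilibrate within the first few nanoseconds;
#' frames at times less than or equal to `t_equil` are dropped before
#' averaging (the frame at exactly `t_equil` is discarded).
#'
#' @param trace An [energy_trace()].
#' @param t_equil Equilibration time in ns (default 5).
#' @return The truncated [energy_trace()], metadata preserved.
#' @export
discard_equilibration <- function(trace, t_equil = 5) {
  stopifnot(inherits(trace, "energy_trace"))
  .check_scalar_number(t_equil, "t_equil", nonneg = TRUE)
  keep <- trace$times > t_equil
  if (!any(keep))
    stop(sprintf(
      "discarding t <= %g ns leaves no frames (trace ends at %g ns)",
      t_equil, trace$times[length(trace$times)]), call. = FALSE)
  energy_trace(times = trace$times[keep], values = trace$values[keep],
               component = trace$component, state = trace$state,
               replica_id = trace$replica_id, ligand_id = trace$ligand_id)
}

#' Arithmetic mean of a trace's energies
#'
#' @param trace An [energy_trace()].
#' @return Mean interaction energy in kcal/mol.
#' @export
trace_mean <- function(trace) {
  stopifnot(inherits(trace, "energy_trace"))
  mean(trace$values)
}

#' Bundle replicas of the same ligand/component/state
#'
#' @param traces List of [energy_trace()] objects agreeing on `ligand_id`,
#'   `component` and `state`.
#' @param expected_replicas How many independent simulations the protocol
#'   calls for (default 4). A mismatch warns but does not fail.
#' @return An object of class `replica_set`.
#' @export
replica_set <- function(traces, expected_replicas = 4L) {
  if (inherits(traces, "energy_trace")) traces <- list(traces)
  if (length(traces) < 1L)
    stop("a replica set needs at least one trace", call. = FALSE)
  ok <- vapply(traces, inherits, logical(1L), what = "energy_trace")
  if (!all(ok))
    stop("all elements must be energy_trace objects", call. = FALSE)
  for (field in c("ligand_id", "component", "state")) {
    vals <- unique(vapply(traces, `[[`, character(1L), field))
    if (length(vals) != 1L)
      stop(sprintf("traces disagree on %s: %s", field,
                   paste(vals, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(traces = traces,
         ligand_id = traces[[1L]]$ligand_id,
         component = traces[[1L]]$component,
         state = traces[[1L]]$state,
         expected_replicas = as.integer(expected_replicas)),
    class = "replica_set"
  )
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf("<replica_set> ligand %s | %s / %s | %d replica(s)\n",
              x$ligand_id, x$component, x$state, length(x$traces)))
  invisible(x)
}

#' Average an energy component across replicas
#'
#' Each replica is truncated with [discard_equilibration()] and averaged;
#' replica means are then combined with equal weight. Equal weighting is the
#' symmetric choice when replicas are exchangeable; for equal-length replicas
#' it coincides with pooling all frames.
#'
#' @param rs A [replica_set()].
#' @param t_equil Equilibration time in ns passed to
#'   [discard_equilibration()].
#' @return Replica-averaged interaction energy in kcal/mol.
#' @export
replica_average <- function(rs, t_equil = 5) {
  stopifnot(inherits(rs, "replica_set"))
  n <- length(rs$traces)
  if (n != rs$expected_replicas)
    warning(sprintf("ligand %s (%s/%s): %d replica(s), expected %d",
                    rs$ligand_id, rs$component, rs$state, n,
                    rs$expected_replicas), call. = FALSE)
  means <- vapply(rs$traces,
                  function(tr) trace_mean(discard_equilibration(tr, t_equil)),
                  numeric(1L))
  mean(means)
}

#' Assemble the four averaged energies of one complex
#'
#' Packages the replica-averaged bound/free van der Waals and electrostatic
#' ligand--surroundings energies of one ligand into the record the LIE model
#' consumes.
#'
#' @param bound_vdw,bound_elec,free_vdw,free_elec [replica_set()] objects for
#'   the four component/state combinations, all sharing one `ligand_id`.
#' @param t_equil Equilibration time in ns.
#' @return A [complex_energies()] record.
#' @export
assemble_complex_energies <- function(bound_vdw, bound_elec,
                                      free_vdw, free_elec, t_equil = 5) {
  sets <- list(bound_vdw = bound_vdw, bound_elec = bound_elec,
               free_vdw = free_vdw, free_elec = free_elec)
  for (nm in names(sets))
    if (!inherits(sets[[nm]], "replica_set"))
      stop(sprintf("'%s' must be a replica_set", nm), call. = FALSE)
  ids <- unique(vapply(sets, `[[`, character(1L), "ligand_id"))
  if (length(ids) != 1L)
    stop(sprintf("ligand_id mismatch across replica sets: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  expect <- c(bound_vdw = "vdw", bound_elec = "elec",
              free_vdw = "vdw", free_elec = "elec")
  states <- c(bound_vdw = "bound", bound_elec = "bound",
              free_vdw = "free", free_elec = "free")
  for (nm in names(sets)) {
    if (sets[[nm]]$component != expect[[nm]] ||
        sets[[nm]]$state != states[[nm]])
      stop(sprintf("'%s' holds %s/%s traces", nm,
                   sets[[nm]]$component, sets[[nm]]$state), call. = FALSE)
  }
  complex_energies(
    ligand_id = ids,
    vdw_bound  = replica_average(bound_vdw, t_equil),
    vdw_free   = replica_average(free_vdw, t_equil),
    elec_bound = replica_average(bound_elec, t_equil),
    elec_free  = replica_average(free_elec, t_equil)
  )
}
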