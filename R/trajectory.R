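#' Time-energy trajectory
#'
#' The universal currency of the package: an ordered series of simulation
#' times (picoseconds) and potential energies (kcal/mol), as produced by an
#' MD engine or by the synthetic generators.  Implemented as a data frame
#' with columns `time` and `energy` plus `label`/`source` attributes, so all
#' the usual data-frame tooling applies.
#'
#' @param times numeric vector of times in ps; strictly increasing after
#'   sorting, no duplicates, length >= 2, all finite.
#' @param energies numeric vector of potential energies in kcal/mol, same
#'   length as `times`, all finite.
#' @param label free-text description (e.g. `"trpcage unfolding"`).
#' @param source provenance: a file path or `"synthetic"`.
#' @return An object of class `c("energy_trajectory", "data.frame")`, rows
#'   sorted by time.
#' @examples
#' tr <- energy_trajectory(c(0, 31.8, 5000), c(-707.6, -478.4, -350))
#' tr$energy[1]
#' @export
energy_trajectory <- function(times, energies, label = "",
                              source = "synthetic") {
  stopifnot(is.numeric(times), is.numeric(energies))
  if (length(times) != length(energies)) {
    stop("'times' and 'energies' must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a trajectory needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(energies))) {
    stop("trajectory values must all be finite", call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  energies <- energies[ord]
  if (any(diff(times) == 0)) {
    dup <- times[which(diff(times) == 0)[1L]]
    stop(sprintf("duplicated time value %g: times must be strictly increasing",
                 dup), call. = FALSE)
  }
  structure(data.frame(time = times, energy = energies),
            label = as.character(label)[1L],
            source = as.character(source)[1L],
            class = c("energy_trajectory", "data.frame"))
}

#' @export
print.energy_trajectory <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Energy trajectory: %d points, t in [%g, %g] ps, E in [%g, %g] kcal/mol\n",
              nrow(x), x$time[1L], x$time[nrow(x)],
              min(x$energy), max(x$energy)))
  if (nzchar(lab)) cat("  label:", lab, "\n")
  cat("  source:", attr(x, "source"), "\n")
  invisible(x)
}

is_energy_trajectory <- function(x) inherits(x, "energy_trajectory")

#' Read a time-energy trajectory from delimited text
#'
#' Reads a headered CSV/TSV file, pulls the named time and energy columns,
#' validates every cell as numeric (reporting the first offending line) and
#' returns a sorted, validated [energy_trajectory()].  Rows may appear in any
#' order in the file; duplicated times are rejected rather than silently
#' dropped.
#'
#' @param path file to read.
#' @param time_column,energy_column header names of the two columns.
#' @param delimiter field separator, `","` by default (use `"\t"` for TSV).
#' @param time_unit unit of the time column, `"ps"` (default) or `"ns"`;
#'   `"ns"` values are rescaled to ps on read.
#' @param label trajectory label; defaults to the file name.
#' @return An [energy_trajectory()] with `source = path`.
#' @export
read_energy_csv <- function(path, time_column = "time",
                            energy_column = "energy", delimiter = ",",
                            time_unit = c("ps", "ns"), label = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, comment.char = "")
  for (col in c(time_column, energy_column)) {
    if (!col %in% names(raw)) {
      stop(sprintf("column '%s' not found in %s (columns: %s)",
                   col, path, paste(names(raw), collapse = ", ")),
           call. = FALSE)
    }
  }
  parse_col <- function(txt, col) {
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt))
    if (length(bad)) {
      # +1 for the header line
      stop(sprintf("non-numeric value '%s' in column '%s' of %s (line %d)",
                   txt[bad[1L]], col, path, bad[1L] + 1L), call. = FALSE)
    }
    val
  }
  times <- parse_col(raw[[time_column]], time_column)
  energies <- parse_col(raw[[energy_column]], energy_column)
  if (time_unit == "ns") times <- times * 1000
  energy_trajectory(times, energies,
                    label = if (is.null(label)) basename(path) else label,
                    source = path)
}

#' Extract (time, energy) pairs from an AMBER mdout log
#'
#' Scans an AMBER-style `mdout` file line by line for `TIME(PS) =` and
#' `EPtot` key-value fields and pairs them into a trajectory.  Summary
#' blocks -- those introduced by an `A V E R A G E S` or
#' `R M S  F L U C T U A T I O N S` header -- repeat the same keys for
#' aggregate values and are skipped.  Parsing is keyword-driven, not
#' column-positional, so minor layout differences between AMBER versions are
#' tolerated.
#'
#' @param path mdout file to read.
#' @param label trajectory label; defaults to the file name.
#' @return An [energy_trajectory()] of the per-step `EPtot` values.
#' @export
read_mdout_energies <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  times <- numeric(0)
  energies <- numeric(0)
  pending_time <- NA_real_
  in_summary <- FALSE
  n_skipped <- 0L
  for (line in lines) {
    if (grepl("A V E R A G E S", line, fixed = TRUE) ||
        grepl("R M S  F L U C T U A T I O N S", line, fixed = TRUE)) {
      in_summary <- TRUE
      pending_time <- NA_real_
      next
    }
    m <- regmatches(line, regexec("TIME\\(PS\\) =\\s*([-0-9.eE+]+)", line))[[1L]]
    if (length(m) == 2L) {
      if (in_summary) n_skipped <- n_skipped + 1L else
        pending_time <- as.numeric(m[2L])
    }
    m <- regmatches(line, regexec("EPtot\\s*=\\s*([-0-9.eE+]+)", line))[[1L]]
    if (length(m) == 2L) {
      if (in_summary) {
        # summary block ends with its own energy record
        in_summary <- FALSE
      } else if (!is.na(pending_time)) {
        times <- c(times, pending_time)
        energies <- c(energies, as.numeric(m[2L]))
        pending_time <- NA_real_
      }
    }
  }
  if (length(times) == 0L) {
    stop("no (TIME(PS), EPtot) records found in ", path,
         ": is this an AMBER mdout file?", call. = FALSE)
  }
  message(sprintf("read_mdout_energies: %d step records extracted, %d summary block(s) skipped",
                  length(times), n_skipped))
  energy_trajectory(times, energies,
                    label = if (is.null(label)) basename(path) else label,
                    source = path)
}

#' Write a trajectory as CSV
#'
#' Writes `time,energy` columns with 17 significant digits, so that
#' [read_energy_csv()] round-trips the numeric values bit-exactly.  A third
#' `label` column (constant) is added only when the trajectory carries a
#' non-empty label.
#'
#' @param traj an [energy_trajectory()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_energy_csv <- function(traj, path) {
  stopifnot(is_energy_trajectory(traj))
  lab <- attr(traj, "label")
  fmt <- function(x) sprintf("%.17g", x)
  if (nzchar(lab)) {
    header <- "time,energy,label"
    rows <- paste(fmt(traj$time), fmt(traj$energy), lab, sep = ",")
  } else {
    header <- "time,energy"
    rows <- paste(fmt(traj$time), fmt(traj$energy), sep = ",")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
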