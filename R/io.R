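## Read a CSV against an exact schema (named character: column -> type).
## Header must match the schema exactly; value conversion failures report
## the offending row and column.
.read_schema <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(names(schema), names(raw))
  extra_cols <- setdiff(names(raw), names(schema))
  if (length(missing_cols) || length(extra_cols))
    stop("SchemaMismatch: missing [", paste(missing_cols, collapse = ", "),
         "], extra [", paste(extra_cols, collapse = ", "), "]")
  out <- raw[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    v <- suppressWarnings(
      if (type == "integer") as.integer(out[[col]]) else as.numeric(out[[col]]))
    bad <- which(is.na(v) & !(out[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("ParseError: column '%s', row %d: cannot parse '%s' as %s",
                   col, bad[1], out[[col]][bad[1]], type))
    if (anyNA(v))
      stop(sprintf("ParseError: column '%s', row %d: missing value",
                   col, which(is.na(v))[1]))
    out[[col]] <- v
  }
  out
}

#' Readers for the pipeline's tidy CSV tables
#'
#' Long-format UTF-8 CSVs with mandatory headers; units are encoded in the
#' column names (minutes, Gy, mm, uM). Each reader validates the header
#' against its schema (reporting missing/extra columns) and parses values
#' with row-level error messages.
#'
#' \describe{
#'   \item{readMidTable}{\code{replicate,metabolite,time_min,mass_shift,fraction}}
#'   \item{readConcentrationTable}{\code{metabolite,time_min,concentration_um}}
#'   \item{readClonogenicTable}{\code{cell_line,condition,replicate,dose_gy,cells_plated,colonies}}
#'   \item{readLdaTable}{\code{group,dose_cells,n_tested,n_positive}}
#'   \item{readGrowthTable}{\code{animal,group,day,length_mm,width_mm,height_mm}}
#' }
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readMidTable <- function(path) {
  .read_schema(path, c(replicate = "character", metabolite = "character",
                       time_min = "numeric", mass_shift = "integer",
                       fraction = "numeric"))
}

#' @rdname readMidTable
#' @export
readConcentrationTable <- function(path) {
  .read_schema(path, c(metabolite = "character", time_min = "numeric",
                       concentration_um = "numeric"))
}

#' @rdname readMidTable
#' @export
readClonogenicTable <- function(path) {
  .read_schema(path, c(cell_line = "character", condition = "character",
                       replicate = "character", dose_gy = "numeric",
                       cells_plated = "integer", colonies = "integer"))
}

#' @rdname readMidTable
#' @export
readLdaTable <- function(path) {
  .read_schema(path, c(group = "character", dose_cells = "numeric",
                       n_tested = "integer", n_positive = "integer"))
}

#' @rdname readMidTable
#' @export
readGrowthTable <- function(path) {
  .read_schema(path, c(animal = "character", group = "character",
                       day = "numeric", length_mm = "numeric",
                       width_mm = "numeric", height_mm = "numeric"))
}

#' Assemble MID time courses from a long table
#'
#' Splits a MID table (as read by \code{\link{readMidTable}} or produced by
#' \code{\link{genMidTimecourses}}) into \linkS4class{MIDTimeCourse} objects
#' nested replicate -> metabolite. Fractions at each (replicate, metabolite,
#' time) must form a complete M+0..M+n block.
#'
#' @param midTable long data.frame.
#' @return named list (replicates) of named lists (metabolites) of
#'   \linkS4class{MIDTimeCourse}.
#' @export
midTimeCourses <- function(midTable) {
  lapply(split(midTable, midTable$replicate), function(rep_df) {
    lapply(split(rep_df, rep_df$metabolite), function(met_df) {
      n <- max(met_df$mass_shift)
      times <- sort(unique(met_df$time_min))
      mids <- lapply(times, function(t) {
        blk <- met_df[met_df$time_min == t, ]
        blk <- blk[order(blk$mass_shift), ]
        if (!identical(blk$mass_shift, 0:n))
          stop("incomplete MID block for ", blk$metabolite[1], " at t = ", t)
        MID(blk$fraction, n)
      })
      MIDTimeCourse(met_df$metabolite[1], times, mids, rep_df$replicate[1])
    })
  })
}

#' Fit fluxes to a measured MID table, replicate by replicate
#'
#' The main analysis entry point: for every replicate in the table, builds
#' the model (driving function from that replicate's measured GLN course,
#' pool concentrations averaged over all time points), fits the five fluxes
#' to the glutamate/malate/aspartate/citrate courses, and averages the
#' per-replicate fits.
#'
#' @param midTable long MID data.frame (see \code{\link{readMidTable}}),
#'   containing GLN plus at least two of GLU, MAL, ASP, CIT per replicate.
#' @param concTable concentration data.frame (see
#'   \code{\link{readConcentrationTable}}), or a named numeric vector of
#'   ready steady-state concentrations.
#' @param fitConfig passed to \code{\link{fitFluxes}}.
#' @param targets metabolites fitted (default GLU, MAL, ASP, CIT; those
#'   present are used).
#' @return a \linkS4class{FluxEstimate}; per-replicate \code{fitFluxes}
#'   results are attached as \code{attr(, "replicateFits")}.
#' @export
estimateFluxes <- function(midTable, concTable, fitConfig = list(),
                           targets = c("GLU", "MAL", "ASP", "CIT")) {
  conc <- if (is.data.frame(concTable)) steadyStateConcentrations(concTable)
          else concTable
  reps <- midTimeCourses(midTable)
  fits <- lapply(reps, function(courses) {
    if (!"GLN" %in% names(courses))
      stop("InvalidDrivingFunction: replicate lacks a GLN time course")
    model <- buildFluxModel(conc, courses$GLN)
    observed <- courses[intersect(targets, names(courses))]
    fitFluxes(model, observed, fitConfig)
  })
  est <- averageReplicateFits(fits)
  attr(est, "replicateFits") <- fits
  est
}

## S4 results -> plain, JSON-ready lists with deterministic field order
.report_item <- function(x) {
  if (is(x, "FluxEstimate"))
    return(list(mean_fluxes = as.list(fluxes(x@meanFluxes)),
                gls_tca_ratio = x@meanGlsTcaRatio,
                per_replicate = lapply(x@fits, function(f) as.list(fluxes(f))),
                objectives = x@objectives))
  if (is(x, "FluxSet")) return(as.list(fluxes(x)))
  if (is(x, "LQFit"))
    return(list(alpha_per_gy = x@alpha, beta_per_gy2 = x@beta,
                se = as.list(x@se), n_points = x@nPoints))
  if (is(x, "LDAFit"))
    return(list(frequency = x@frequency, one_in = ldaFrequency(x)$oneIn,
                percent = 100 * x@frequency, ci_lower = x@lower,
                ci_upper = x@upper, deviance = x@deviance,
                df = x@dfResidual, status = x@status))
  if (is.list(x)) return(lapply(x, .report_item))
  x
}

#' Write a machine- and human-readable run report
#'
#' Serializes a named list of stage results (raw values, or package objects
#' such as \linkS4class{FluxEstimate}, \linkS4class{LQFit},
#' \linkS4class{LDAFit}, which are converted to plain structures) to
#' \code{results.json}, plus a Markdown summary \code{report.md}. Field order
#' is deterministic and no timestamps are written, so identical inputs give
#' byte-identical reports.
#'
#' @param results named list of results from one or more stages.
#' @param outDir output directory, created if missing.
#' @return invisibly, paths of the two files written.
#' @export
writeReport <- function(results, outDir) {
  if (length(results) && (is.null(names(results)) || any(names(results) == "")))
    stop("results must be a named list")
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outDir)) stop("OutputNotWritable: ", outDir)
  }
  plain <- lapply(results, .report_item)
  jp <- file.path(outDir, "results.json")
  jsonlite::write_json(plain, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  fmt <- function(x, indent = "") {
    if (is.list(x))
      return(unlist(lapply(names(x), function(nm)
        c(sprintf("%s- %s:", indent, nm), fmt(x[[nm]], paste0(indent, "  "))))))
    sprintf("%s%s", indent, paste(format(x, digits = 8), collapse = ", "))
  }
  lines <- c("# Run report", "")
  for (nm in names(plain))
    lines <- c(lines, sprintf("## %s", nm), "", fmt(plain[[nm]]), "")
  mp <- file.path(outDir, "report.md")
  writeLines(lines, mp)
  invisible(c(json = jp, markdown = mp))
}
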