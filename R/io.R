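# Plain-text readers and writers for the pipeline's exchange formats.
# Trace-matrix dialect: first row = times (s), first column = wavelengths
# (nm), cell (i, j) = delta A; UTF-8, '.' decimal.

#' Write / read a transient-absorption matrix CSV
#'
#' @param ds A [ta_dataset()].
#' @param path File path.
#' @return `write_trace_csv()`: `path` invisibly. `read_trace_csv()`:
#'   a [ta_dataset()].
#' @export
#' @rdname trace_csv
write_trace_csv <- function(ds, path) {
  stopifnot(inherits(ds, "ta_dataset"))
  header <- c("wavelength_nm", format(ds$times, digits = 15, trim = TRUE))
  body <- cbind(format(ds$wavelengths, digits = 15, trim = TRUE),
                matrix(format(ds$delta_a, digits = 15, trim = TRUE),
                       nrow(ds$delta_a)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @param n_averages Number of averaged acquisitions recorded with the
#'   dataset (not stored in the CSV).
#' @export
#' @rdname trace_csv
read_trace_csv <- function(path, n_averages = 1L) {
  raw <- read.csv(path, header = FALSE, colClasses = "character")
  times <- as.numeric(raw[1, -1])
  wl <- as.numeric(raw[-1, 1])
  da <- matrix(as.numeric(as.matrix(raw[-1, -1])), nrow = length(wl))
  ta_dataset(wl, times, da, n_averages = n_averages)
}

#' Write / read per-pH absorption spectra CSV
#'
#' First column is the wavelength (nm); one column per pH, labeled by its
#' value.
#'
#' @param spectra_by_ph List with `ph`, `wavelengths`, `spectra` (see
#'   [gen_titration_spectra()]).
#' @param path File path.
#' @return `write_spectra_csv()`: `path` invisibly. `read_spectra_csv()`:
#'   a list with `ph`, `wavelengths`, `spectra`.
#' @export
#' @rdname spectra_csv
write_spectra_csv <- function(spectra_by_ph, path) {
  df <- data.frame(wavelength_nm = spectra_by_ph$wavelengths,
                   spectra_by_ph$spectra, check.names = FALSE)
  names(df)[-1] <- format(spectra_by_ph$ph, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname spectra_csv
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ph <- as.numeric(names(df)[-1])
  ord <- order(ph)
  list(ph = ph[ord], wavelengths = df[[1]],
       spectra = as.matrix(df[, -1, drop = FALSE])[, ord, drop = FALSE])
}

#' Write / read a photocurrent trace CSV (two columns: t, I)
#'
#' @param trace A [photocurrent_trace()].
#' @param path File path.
#' @return `write_current_csv()`: `path` invisibly. `read_current_csv()`:
#'   a [photocurrent_trace()].
#' @export
#' @rdname current_csv
write_current_csv <- function(trace, path) {
  stopifnot(inherits(trace, "photocurrent_trace"))
  write.csv(data.frame(time_s = trace$times, current = trace$current),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param illumination Illumination kind of the stored trace.
#' @export
#' @rdname current_csv
read_current_csv <- function(path, illumination = "flash") {
  df <- read.csv(path)
  photocurrent_trace(df[[1]], df[[2]], illumination = illumination)
}

#' Write / read particle samples CSV (frame, species, x, y, z or frame, z)
#'
#' @param samples A [particle_samples()].
#' @param path File path.
#' @return `write_particles_csv()`: `path` invisibly.
#'   `read_particles_csv()`: a [particle_samples()].
#' @export
#' @rdname particles_csv
write_particles_csv <- function(samples, path) {
  stopifnot(inherits(samples, "particle_samples"))
  df <- as.data.frame(samples)
  df$species <- attr(samples, "species")
  cols <- intersect(c("frame", "species", "x", "y", "z"), names(df))
  write.csv(df[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param cylinder_radius Cylinder radius to attach to the samples.
#' @export
#' @rdname particles_csv
read_particles_csv <- function(path, cylinder_radius = NA) {
  df <- read.csv(path)
  species <- if ("species" %in% names(df)) df$species[1] else "water"
  df$species <- NULL
  particle_samples(df, species = species,
                   cylinder_radius = cylinder_radius)
}

#' Write a pore-radius profile as TSV (z, radius, x, y)
#'
#' @param profile A `pore_profile` from [pore_radius_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pore_profile_tsv <- function(profile, path) {
  utils::write.table(profile[, c("z", "radius", "x", "y")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PMF profile as TSV (z, g, sd, masked)
#'
#' @param pmf A `pmf_profile` from [pmf_profile()].
#' @param sd Per-bin standard deviations from [block_bootstrap_sd()]
#'   (optional; `NA` written when absent).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, sd = NULL, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(sd)) sd <- rep(NA_real_, nrow(pmf))
  stopifnot(length(sd) == nrow(pmf))
  out <- data.frame(z = pmf$z, g = pmf$g, sd = sd, masked = pmf$masked)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serializes any of the pipeline's fit results (lifetimes with standard
#' errors, sigmoid parameters, charges, assignments) as a JSON object for
#' downstream aggregation.
#'
#' @param report Named list of scalars, vectors or data frames.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
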