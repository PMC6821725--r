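# Gas constant in kcal/(mol K).
R_KCAL <- 1.9872e-3

#' Axial particle density within a cylinder
#'
#' Bins particle axial positions into contiguous slabs, averaging counts
#' over frames. Particles outside the cylinder radius are excluded (when
#' x, y are available). The bulk density is the mean per-bin count over
#' the outermost slabs on both ends of the z range, where the profile is
#' assumed unperturbed.
#'
#' @param samples A [particle_samples()].
#' @param axis Optional axis from [pore_axis()]; when supplied, positions
#'   are projected into the axis frame first, otherwise `z` (and `x`, `y`)
#'   are used as stored.
#' @param bin_width Bin width (Angstrom, > 0).
#' @param cylinder_radius Cylinder radius (Angstrom); default 36.23, the
#'   radius whose cross-section matches the protein's membrane footprint.
#' @param z_range Optional length-2 axial range; defaults to the sample
#'   range.
#' @param bulk_margin Width (Angstrom) of the bulk slabs at each end used
#'   for the bulk density (default 5).
#' @return An object of class `axial_density`: `bin_edges`, `counts`
#'   (time-averaged per bin), `n_bulk`, `cylinder_radius`, `n_frames` and
#'   `per_frame` (frames x bins count matrix, used by the block
#'   bootstrap).
#' @export
axial_density <- function(samples, axis = NULL, bin_width = 0.5,
                          cylinder_radius = 36.23, z_range = NULL,
                          bulk_margin = 5) {
  stopifnot(inherits(samples, "particle_samples"), bin_width > 0)
  n_frames <- attr(samples, "n_frames")
  if (is.null(n_frames) || n_frames < 1) stop("need at least one frame")
  df <- as.data.frame(samples)
  if (nrow(df) == 0) stop("no particles to bin")
  if (!is.null(axis) && all(c("x", "y") %in% names(df))) {
    local <- to_axis_frame(df[, c("x", "y", "z")], axis)
    df$x <- local[, 1]; df$y <- local[, 2]; df$z <- local[, 3]
  }
  if (all(c("x", "y") %in% names(df))) {
    df <- df[df$x^2 + df$y^2 <= cylinder_radius^2, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no particles inside the cylinder")
  if (is.null(z_range)) z_range <- range(df$z)
  nb <- max(1L, ceiling(diff(z_range) / bin_width))
  edges <- z_range[1] + bin_width * (0:nb)
  bin <- findInterval(df$z, edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  inside <- bin >= 1 & bin <= nb
  df <- df[inside, , drop = FALSE]; bin <- bin[inside]
  per_frame <- matrix(0, n_frames, nb)
  tab <- table(factor(df$frame, levels = seq_len(n_frames)),
               factor(bin, levels = seq_len(nb)))
  per_frame[] <- as.numeric(tab)
  counts <- colMeans(per_frame)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bulk <- centers <= z_range[1] + bulk_margin |
          centers >= z_range[2] - bulk_margin
  if (!any(bulk) || sum(counts[bulk]) == 0)
    stop("no particles in the bulk slabs; bulk density undefined")
  structure(list(bin_edges = edges, counts = counts,
                 n_bulk = mean(counts[bulk]), bulk_bins = which(bulk),
                 cylinder_radius = cylinder_radius,
                 n_frames = n_frames, per_frame = per_frame),
            class = "axial_density")
}

#' Potential of mean force by Boltzmann inversion of an axial density
#'
#' \eqn{G(z) = -RT \ln(n(z)/n_{bulk})} with R = 1.9872e-3 kcal/(mol K).
#' Empty bins are masked (not infinite) and reported as exceeding
#' \eqn{G_{cap} = RT \ln(N_{total})}, the largest barrier resolvable from
#' the sampled particle count.
#'
#' @param dens An [axial_density()].
#' @param temperature Temperature in K (default 310).
#' @param unit `"kcal"` (default) or `"kJ"`.
#' @return An object of class `pmf_profile`: data.frame with `z` (bin
#'   centers), `g`, `masked`; attributes `temperature`, `unit`, `g_cap`.
#' @export
pmf_profile <- function(dens, temperature = 310, unit = c("kcal", "kJ")) {
  stopifnot(inherits(dens, "axial_density"))
  unit <- match.arg(unit)
  if (dens$n_bulk <= 0) stop("bulk density must be positive")
  scale <- if (unit == "kcal") 1 else 4.184
  rt <- R_KCAL * temperature * scale
  centers <- (dens$bin_edges[-1] +
              dens$bin_edges[-length(dens$bin_edges)]) / 2
  masked <- dens$counts == 0
  g <- rep(NA_real_, length(centers))
  g[!masked] <- -rt * log(dens$counts[!masked] / dens$n_bulk)
  total <- sum(dens$counts) * dens$n_frames
  out <- data.frame(z = centers, g = g, masked = masked)
  structure(out, class = c("pmf_profile", "data.frame"),
            temperature = temperature, unit = unit,
            g_cap = rt * log(max(total, 2)))
}

#' Block-bootstrap standard deviation of a PMF profile
#'
#' Resamples contiguous blocks of frames with replacement, recomputes the
#' time-averaged density, bulk density and PMF for each resample, and
#' reports the per-bin standard deviation — the standard error estimate
#' appropriate for time-correlated trajectory frames.
#'
#' @param dens An [axial_density()] (carries the per-frame counts).
#' @param block_length Block length in frames (>= 1; the frame count must
#'   be at least `2 * block_length`).
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param temperature Temperature in K (default 310).
#' @return Numeric vector of per-bin standard deviations of G (same unit
#'   as [pmf_profile()], kcal/mol); bins empty in a resample are ignored
#'   for that resample.
#' @export
block_bootstrap_sd <- function(dens, block_length, n_resamples = 1000,
                               seed = NULL, temperature = 310) {
  stopifnot(inherits(dens, "axial_density"), block_length >= 1)
  Fn <- dens$n_frames
  if (Fn < 2 * block_length)
    stop("need at least 2 * block_length frames")
  nb <- ncol(dens$per_frame)
  n_blocks <- ceiling(Fn / block_length)
  starts_max <- Fn - block_length + 1
  rt <- R_KCAL * temperature
  G <- with_seed(seed, {
    out <- matrix(NA_real_, n_resamples, nb)
    for (b in seq_len(n_resamples)) {
      st <- sample.int(starts_max, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_length - 1), st, "+"))[seq_len(Fn)]
      cnt <- colMeans(dens$per_frame[idx, , drop = FALSE])
      nb_bulk <- mean(cnt[dens$bulk_bins])
      if (nb_bulk <= 0) next
      pos <- cnt > 0
      out[b, pos] <- -rt * log(cnt[pos] / nb_bulk)
    }
    out
  })
  apply(G, 2, stats::sd, na.rm = TRUE)
}

#' Ion-selectivity summary from cation and anion PMF profiles
#'
#' Reports, per named axial region, the maximum free-energy barrier of
#' each species and which species faces the lower barrier (the region is
#' selective for that species).
#'
#' @param pmf_cation,pmf_anion [pmf_profile()] objects on identical z
#'   grids.
#' @param regions Named list of length-2 z ranges; defaults to three equal
#'   thirds of the grid named `cytoplasmic`, `constriction`,
#'   `extracellular`.
#' @param min_difference Smallest barrier difference counted as selective;
#'   defaults to RT ln 2 at the profile temperature (the free energy of a
#'   twofold Boltzmann preference), so sub-thermal differences — e.g. from
#'   where exactly a region boundary cuts a barrier tail — report
#'   `"none"`.
#' @return Data frame with `region`, `barrier_cation`, `barrier_anion`,
#'   `selective_for` (`"cation"`, `"anion"` or `"none"`).
#' @export
selectivity_summary <- function(pmf_cation, pmf_anion, regions = NULL,
                                min_difference = NULL) {
  stopifnot(inherits(pmf_cation, "pmf_profile"),
            inherits(pmf_anion, "pmf_profile"))
  if (length(pmf_cation$z) != length(pmf_anion$z) ||
      any(abs(pmf_cation$z - pmf_anion$z) > 1e-9))
    stop("PMF profiles must share the same z grid")
  if (is.null(min_difference)) {
    scale <- if (identical(attr(pmf_cation, "unit"), "kJ")) 4.184 else 1
    tk <- attr(pmf_cation, "temperature")
    if (is.null(tk)) tk <- 310
    min_difference <- R_KCAL * tk * scale * log(2)
  }
  z <- pmf_cation$z
  if (is.null(regions)) {
    qs <- seq(min(z), max(z), length.out = 4)
    regions <- list(cytoplasmic = qs[1:2], constriction = qs[2:3],
                    extracellular = qs[3:4])
  }
  rows <- lapply(names(regions), function(nm) {
    rg <- regions[[nm]]
    in_rg <- z >= rg[1] & z <= rg[2]
    bc <- suppressWarnings(max(pmf_cation$g[in_rg], na.rm = TRUE))
    ba <- suppressWarnings(max(pmf_anion$g[in_rg], na.rm = TRUE))
    sel <- if (!is.finite(bc) || !is.finite(ba) ||
               abs(bc - ba) < min_difference)
      "none" else if (bc < ba) "cation" else "anion"
    data.frame(region = nm, barrier_cation = bc, barrier_anion = ba,
               selective_for = sel)
  })
  do.call(rbind, rows)
}
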