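# Bondi van der Waals radii (Angstrom) for the elements seen in protein
# crystal structures; hydrogens are ignored by the profile (none are
# modeled at typical crystallographic resolution).
bondi_radius <- function(element) {
  tbl <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  r <- tbl[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' HOLE-style pore-radius profile along an axis
#'
#' At each axial position z the pore radius is the largest sphere that fits
#' without overlapping any atom's van der Waals surface:
#' \eqn{r(z) = \max_{(x,y)} \min_i (\|p - a_i\| - r_{vdW,i})} with the
#' probe center p constrained to the plane at z. The in-plane maximization
#' uses Nelder-Mead refinement of the best candidates from a coarse
#' in-plane grid scan, plus continuation from the previous z's probe
#' center (as in HOLE); the radius is clipped at a cap.
#'
#' @param s A [structure_model()].
#' @param axis Axis from [pore_axis()].
#' @param z_range Length-2 axial range (Angstrom, relative to the axis
#'   point, i.e. the center of mass).
#' @param step Axial step (Angstrom, > 0).
#' @param cap Radius cap (default 15 Angstrom).
#' @param heavy_only Ignore hydrogens (default `TRUE`).
#' @return An object of class `pore_profile`: data.frame with `z`,
#'   `radius`, `x`, `y` (probe centers, axis-frame coordinates) and
#'   `capped` flag.
#' @export
pore_radius_profile <- function(s, axis, z_range, step = 0.5, cap = 15,
                                heavy_only = TRUE) {
  stopifnot(inherits(s, "structure_model"), step > 0,
            length(z_range) == 2, z_range[1] < z_range[2])
  sel <- if (heavy_only) s[s$element != "H", , drop = FALSE] else s
  local <- to_axis_frame(coords(sel), axis)
  vdw <- bondi_radius(sel$element)
  zs <- seq(z_range[1], z_range[2], by = step)
  res <- data.frame(z = zs, radius = NA_real_, x = NA_real_, y = NA_real_,
                    capped = FALSE)
  prev <- c(0, 0)
  for (i in seq_along(zs)) {
    z <- zs[i]
    near <- abs(local[, 3] - z) < cap + max(vdw)
    if (!any(near)) {
      res$radius[i] <- cap; res$x[i] <- prev[1]; res$y[i] <- prev[2]
      res$capped[i] <- TRUE
      next
    }
    A <- local[near, , drop = FALSE]; rv <- vdw[near]
    clearance <- function(p) {
      d <- sqrt((A[, 1] - p[1])^2 + (A[, 2] - p[2])^2 + (A[, 3] - z)^2)
      min(d - rv)
    }
    # Coarse in-plane pre-scan: the clearance landscape is multimodal
    # (every gap between atoms is a local maximum), so seed Nelder-Mead
    # from the best grid candidates as well as the continuation point.
    # Candidates stay within 5 Angstrom of the axis or the previous probe
    # center so the probe tracks the pore instead of escaping outside the
    # molecule, where clearance grows without bound.
    gx <- seq(-cap, cap, by = 1)
    grid <- as.matrix(expand.grid(x = gx, y = gx))
    near_pore <- (grid[, 1] - prev[1])^2 + (grid[, 2] - prev[2])^2 <= 25 |
                 grid[, 1]^2 + grid[, 2]^2 <= 25
    grid <- grid[near_pore, , drop = FALSE]
    gval <- apply(grid, 1, clearance)
    top <- grid[order(gval, decreasing = TRUE)[1:3], , drop = FALSE]
    seeds <- c(lapply(seq_len(nrow(top)), function(k) top[k, ]),
               list(prev, c(0, 0)))
    best <- NULL
    for (seed_pt in unique(seeds)) {
      opt <- stats::optim(seed_pt, function(p) -clearance(p),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 400))
      # tie-break by proximity to the previous probe center
      if (is.null(best) || opt$value < best$value - 1e-9 ||
          (abs(opt$value - best$value) <= 1e-9 &&
           sum((opt$par - prev)^2) < sum((best$par - prev)^2)))
        best <- opt
    }
    r <- -best$value
    res$radius[i] <- min(max(r, 0), cap)
    res$capped[i] <- r >= cap
    res$x[i] <- best$par[1]; res$y[i] <- best$par[2]
    prev <- best$par
  }
  class(res) <- c("pore_profile", "data.frame")
  res
}
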