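#' Fit the cylindrical mid-plane of an ion-channel wall
#'
#' With the pore aligned along z, every heavy atom is converted to
#' cylindrical coordinates (z, r) and a quadratic polynomial
#' `r(z) = a z^2 + b z + c` is least-squares fitted to the atom radii as
#' a function of height (plain least squares over all atoms, equivalent
#' to averaging over the angle under uniform angular sampling; a
#' binned-by-z variant is available).
#'
#' @param solute structure pre-aligned with the channel along z (apply
#'   a transform first if needed).
#' @param binned fit on 1-Angstrom z-bin means instead of raw atoms.
#' @return list of class `channel_model`: coefficients `a`, `b`, `c`,
#'   the fitted `z_range`, and the `lm` fit.
#' @export
fit_channel_midplane <- function(solute, binned = FALSE) {
  hv <- heavy_atoms(solute)
  z <- hv$z
  r <- sqrt(hv$x^2 + hv$y^2)
  if (length(unique(round(z, 6))) < 3L)
    stop("channel fit needs at least 3 distinct z values")
  if (binned) {
    bins <- floor(z)
    r <- as.numeric(tapply(r, bins, mean))
    z <- as.numeric(tapply(z, bins, mean))
    if (length(z) < 3L)
      stop("channel fit needs at least 3 distinct z bins")
  }
  fit <- stats::lm(r ~ z + I(z^2))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf[3L]), b = unname(cf[2L]),
                 c = unname(cf[1L]), z_range = range(hv$z), fit = fit),
            class = "channel_model")
}

#' @rdname fit_channel_midplane
#' @param model a `channel_model`.
#' @param z heights, Angstrom; values outside the fitted range use the
#'   nearest range endpoint.
#' @export
channel_radius <- function(model, z) {
  z <- pmin(pmax(z, model$z_range[1L]), model$z_range[2L])
  model$a * z^2 + model$b * z + model$c
}

#' @rdname fit_channel_midplane
#' @param path JSON output path for the model coefficients.
#' @export
write_channel_model <- function(model, path) {
  jsonlite::write_json(list(a = model$a, b = model$b, c = model$c,
                            z_range = model$z_range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Remove hydration sites inside the channel lumen
#'
#' A site is retained iff its cylindrical radius is at least the
#' mid-plane radius at its height (sites exactly on the mid-plane are
#' kept).
#'
#' @param sites a `hydration_sites` frame in the aligned frame.
#' @param model a `channel_model`.
#' @export
filter_channel_interior <- function(sites, model) {
  if (nrow(sites) == 0) return(sites)
  r <- sqrt(sites$x^2 + sites$y^2)
  sites[r >= channel_radius(model, sites$z), , drop = FALSE]
}

#' Remove hydration sites in the membrane-proximal zone
#'
#' Retains sites with `z <= z_cut` (default -48 Angstrom: in the
#' receptor's aligned frame, larger z approaches the lipid bilayer).
#' The cut is meaningful only in the structure's own aligned frame, so
#' it is a configuration value, not a constant.
#'
#' @param sites a `hydration_sites` frame in the aligned frame.
#' @param z_cut Angstrom; sites with z above this are removed
#'   (boundary kept).
#' @export
filter_membrane_zone <- function(sites, z_cut = -48) {
  if (nrow(sites) == 0) return(sites)
  sites[sites$z <= z_cut, , drop = FALSE]
}
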