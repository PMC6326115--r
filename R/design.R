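#' Plot design: subplot and transect geometry
#'
#' Describes the cluster-plot geometry of the national DWM inventory. A plot
#' is four subplots (one center, three satellites 36.58 m away at azimuths
#' 0, 120 and 240 degrees). Each subplot anchors coarse-woody-debris (CWD)
#' transects of 24 ft (7.32 m), fine-woody-debris (FWD) tally segments, and
#' duff/litter depth points at the transect ends.
#'
#' Two named designs are provided:
#' \describe{
#'   \item{`national_2012`}{The current protocol: 2 transects per subplot
#'     (8 x 24 ft = 192 ft = 58.5 m total), 2 duff/litter points per
#'     subplot (8 per plot).}
#'   \item{`national_2002`}{The 2002--2011 protocol: 3 transects per
#'     subplot (12 x 24 ft = 288 ft = 87.8 m total), 3 duff/litter points
#'     per subplot (12 per plot).}
#' }
#'
#' FWD is tallied on one transect per subplot: the small and medium size
#' classes on a 6 ft (1.83 m) segment (24 ft per plot) and the large class
#' on a 10 ft (3.05 m) segment (40 ft per plot), both starting 14 ft
#' (4.27 m) from subplot center.
#'
#' Transect azimuths are not part of the published protocol text; the
#' defaults ({30, 150} degrees, plus 270 for the 3-transect design) are an
#' opposing-orientation layout and are configurable, not authoritative.
#'
#' @param name `"national_2012"` (default) or `"national_2002"`.
#' @param ... Field overrides (e.g. `cwd_transect_length_ft = 58` for a
#'   regional lengthened-transect option).
#' @return An object of class `dwm_design`: a list with fields
#'   `n_subplots`, `transects_per_subplot`, `cwd_transect_length_ft`,
#'   `fwd_sm_md_length_ft`, `fwd_large_length_ft`, `fwd_offset_ft`,
#'   `dufflitter_points_per_subplot`, `subplot_offset_m`,
#'   `subplot_azimuths_deg`, `transect_azimuths_deg`.
#' @examples
#' d <- plot_design("national_2012")
#' cwd_total_length_ft(d) # 192
#' @export
plot_design <- function(name = c("national_2012", "national_2002"), ...) {
  name <- match.arg(name)
  d <- list(
    name = name,
    n_subplots = 4L,
    transects_per_subplot = if (name == "national_2012") 2L else 3L,
    cwd_transect_length_ft = 24,
    fwd_sm_md_length_ft = 6,   # per subplot, small + medium classes
    fwd_large_length_ft = 10,  # per subplot, large class
    fwd_offset_ft = 14,        # FWD segment begins 14 ft from subplot center
    dufflitter_points_per_subplot = if (name == "national_2012") 2L else 3L,
    subplot_offset_m = 36.58,
    subplot_azimuths_deg = c(0, 120, 240),
    transect_azimuths_deg = if (name == "national_2012") {
      c(30, 150)
    } else {
      c(30, 150, 270)
    }
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(d)) stop("unknown design field: ", nm, call. = FALSE)
    d[[nm]] <- over[[nm]]
  }
  if (length(d$transect_azimuths_deg) != d$transects_per_subplot) {
    stop("transect_azimuths_deg must have one azimuth per transect",
         call. = FALSE)
  }
  stopifnot(d$cwd_transect_length_ft > 0, d$n_subplots >= 1,
            d$fwd_sm_md_length_ft > 0, d$fwd_large_length_ft > 0)
  class(d) <- "dwm_design"
  d
}

#' Total CWD transect length per plot (L of the CWD estimators), in feet
#' @param design A [plot_design()] object.
#' @return Numeric scalar, e.g. 192 for the 2012 design.
#' @export
cwd_total_length_ft <- function(design) {
  design$n_subplots * design$transects_per_subplot *
    design$cwd_transect_length_ft
}

#' Total FWD transect length per plot for a size class, in feet
#' @param design A [plot_design()] object.
#' @param size_class `"small"`, `"medium"` or `"large"`.
#' @return Numeric scalar: 24 ft for small/medium, 40 ft for large under
#'   the default designs.
#' @export
fwd_total_length_ft <- function(design,
                                size_class = c("small", "medium", "large")) {
  size_class <- match.arg(size_class)
  per <- if (size_class == "large") design$fwd_large_length_ft else
    design$fwd_sm_md_length_ft
  design$n_subplots * per
}

#' Number of duff/litter depth points per plot
#' @param design A [plot_design()] object.
#' @return Integer: 8 (2012 design) or 12 (2002 design).
#' @export
dufflitter_n_points <- function(design) {
  design$n_subplots * design$dufflitter_points_per_subplot
}

#' @export
print.dwm_design <- function(x, ...) {
  cat("DWM plot design <", x$name, ">\n", sep = "")
  cat("  subplots:", x$n_subplots, "(offset", x$subplot_offset_m,
      "m at", paste(x$subplot_azimuths_deg, collapse = "/"), "deg)\n")
  cat("  CWD transects:", x$transects_per_subplot, "per subplot x",
      x$cwd_transect_length_ft, "ft =", cwd_total_length_ft(x), "ft (",
      round(cwd_total_length_ft(x) * 0.3048, 1), "m )\n")
  cat("  FWD transect: small/medium", fwd_total_length_ft(x, "small"),
      "ft, large", fwd_total_length_ft(x, "large"), "ft per plot\n")
  cat("  duff/litter points:", dufflitter_n_points(x), "per plot\n")
  invisible(x)
}
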