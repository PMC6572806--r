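# Fick's-law flux budgets and redox transition-zone detection on measured
# or simulated porewater depth profiles.

#' Diffusive flux across an interface from a concentration profile
#'
#' Estimates J = -phi * Ds * dC/dz at an interface depth, with the
#' concentration gradient taken from a least-squares line through the
#' \code{n_points} profile samples nearest the interface on one side.
#' Positive flux is directed downward (into the sediment when applied at the
#' sediment-water interface from below).
#'
#' Below-detection values (a \code{below_detection} column, or values flagged
#' NA with a detection limit) are replaced by \code{detection_limit / 2} for
#' the gradient fit and the estimate is flagged.
#'
#' @param profile data.frame with columns \code{depth_m} (strictly
#'   increasing) and \code{value} (uM); optional logical
#'   \code{below_detection}.
#' @param interface_depth interface depth, m.
#' @param porosity porosity at the interface, in (0,1).
#' @param D0 free-solution diffusivity, m^2/yr; the tortuosity correction
#'   Ds = D0/(1 - ln(phi^2)) is applied unless \code{Ds} is given directly.
#' @param n_points number of samples in the gradient window (>= 2).
#' @param side which side of the interface supplies the samples:
#'   \code{"below"} (default; deeper than the interface) or \code{"above"}.
#' @param Ds optional sediment diffusivity overriding the tortuosity rule.
#' @param detection_limit detection limit used for flagged values, uM.
#' @return object of class \code{flux_estimate}: list with \code{flux}
#'   (mmol m^-2 yr^-1, positive downward), \code{interface_depth},
#'   \code{window} (depths used), \code{gradient} (uM/m),
#'   \code{below_detection} flag.
#' @export
fick_flux <- function(profile, interface_depth, porosity, D0,
                      n_points = 3, side = c("below", "above"),
                      Ds = NULL, detection_limit = 3) {
  side <- match.arg(side)
  profile <- as.data.frame(profile)
  stopifnot(all(c("depth_m", "value") %in% names(profile)),
            porosity > 0, porosity < 1, n_points >= 2)
  if (is.unsorted(profile$depth_m, strictly = TRUE))
    stop("profile depths must be strictly increasing")
  keep <- if (side == "below") profile$depth_m >= interface_depth
          else profile$depth_m <= interface_depth
  prof <- profile[keep, , drop = FALSE]
  if (nrow(prof) < 2) stop("fewer than 2 usable points on the ", side,
                           " side of the interface")
  ord <- order(abs(prof$depth_m - interface_depth))
  prof <- prof[ord[seq_len(min(n_points, nrow(prof)))], ]
  bd <- if ("below_detection" %in% names(prof)) prof$below_detection
        else rep(FALSE, nrow(prof))
  val <- prof$value
  val[bd] <- detection_limit / 2
  grad <- unname(stats::coef(stats::lm(val ~ prof$depth_m))[2])   # uM/m
  if (is.null(Ds)) Ds <- sediment_diffusivity(D0, porosity)
  # uM * m/yr == mmol m^-2 yr^-1 (1 uM = 1 mmol m^-3)
  structure(list(flux = -porosity * Ds * grad,
                 interface_depth = interface_depth,
                 window = sort(prof$depth_m),
                 gradient = grad,
                 below_detection = all(bd)),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate> %.4g mmol m-2 yr-1 (positive down) at %.3g m; window %s%s\n",
              x$flux, x$interface_depth,
              paste(signif(x$window, 4), collapse = ", "),
              if (x$below_detection) " [all below detection]" else ""))
  invisible(x)
}

# linearly interpolated depths where a profile crosses `level`, with the
# crossing direction ("down" = decreasing with depth)
.crossings <- function(depth, value, level) {
  d <- value - level
  i <- which(d[-1] * d[-length(d)] < 0 | (d[-length(d)] != 0 & d[-1] == 0))
  if (!length(i)) return(data.frame(depth = numeric(0), direction = character(0)))
  zc <- depth[i] + (level - value[i]) * (depth[i + 1] - depth[i]) /
    (value[i + 1] - value[i])
  data.frame(depth = zc,
             direction = ifelse(value[i + 1] < value[i], "down", "up"))
}

#' Detect oxic-anoxic and anoxic-oxic transition zones in an O2 profile
#'
#' Following the oceanographic convention for deeply oxygenated sediments:
#' an OATZ is the interval over which O2 drops from \code{upper_threshold}
#' (10 uM) down to the \code{detection_limit} (3 uM); an AOTZ is the
#' interval over which O2 rises back from the detection limit to the upper
#' threshold.  Zone boundaries are linearly interpolated between bracketing
#' samples.  Zones narrower than the local sample spacing are discarded
#' (attribute \code{"discarded"} counts them).
#'
#' @param o2 data.frame with columns \code{depth_m} (strictly increasing)
#'   and \code{value} (uM).
#' @param upper_threshold upper O2 threshold, uM.
#' @param detection_limit O2 detection limit, uM.
#' @param min_width zones narrower than this (m) are discarded as noise;
#'   default (NULL) uses the median sample spacing of the profile.
#' @return data.frame with columns \code{kind} ("OATZ"/"AOTZ"), \code{top},
#'   \code{bottom} (m), in depth order; zero rows when the profile never
#'   spans the thresholds.
#' @export
detect_transition_zones <- function(o2, upper_threshold = 10,
                                    detection_limit = 3, min_width = NULL) {
  o2 <- as.data.frame(o2)
  stopifnot(all(c("depth_m", "value") %in% names(o2)),
            upper_threshold > detection_limit)
  if (is.unsorted(o2$depth_m, strictly = TRUE))
    stop("O2 profile depths must be strictly increasing")
  cu <- .crossings(o2$depth_m, o2$value, upper_threshold)
  cl <- .crossings(o2$depth_m, o2$value, detection_limit)
  zones <- list()
  # OATZ: downward crossing of upper threshold -> next downward crossing of
  # the detection limit
  for (z in cu$depth[cu$direction == "down"]) {
    lower <- cl$depth[cl$direction == "down" & cl$depth > z]
    if (length(lower))
      zones[[length(zones) + 1L]] <-
        data.frame(kind = "OATZ", top = z, bottom = min(lower))
  }
  # AOTZ: upward crossing of the detection limit -> next upward crossing of
  # the upper threshold
  for (z in cl$depth[cl$direction == "up"]) {
    upper <- cu$depth[cu$direction == "up" & cu$depth > z]
    if (length(upper))
      zones[[length(zones) + 1L]] <-
        data.frame(kind = "AOTZ", top = z, bottom = max(z, min(upper)))
  }
  if (!length(zones))
    return(structure(data.frame(kind = character(0), top = numeric(0),
                                bottom = numeric(0)), discarded = 0L))
  zz <- do.call(rbind, zones)
  # noise chatter around a threshold yields several candidate pairings per
  # zone; keep the innermost (narrowest) bracketing pair
  zz <- zz[order(zz$kind, zz$bottom, -zz$top), ]
  zz <- zz[!duplicated(zz[c("kind", "bottom")]), ]
  zz <- zz[order(zz$top), ]
  spacing <- stats::median(diff(o2$depth_m))
  wide <- (zz$bottom - zz$top) >= min_width %||% spacing
  discarded <- sum(!wide)
  if (discarded) message(discarded,
    " transition zone(s) narrower than the sample spacing discarded")
  zz <- zz[wide, ]
  rownames(zz) <- NULL
  structure(zz, discarded = discarded)
}

#' Integrated consumption within a zone from boundary fluxes
#'
#' The consumption of a species inside a zone is the difference between the
#' transport into the zone and out of it; the fraction relates that
#' consumption to a source influx (e.g. the O2 influx from the basement for
#' an AOTZ).
#'
#' @param flux_in magnitude of flux entering the zone (a
#'   \code{flux_estimate} or a number, mmol m^-2 yr^-1).
#' @param flux_out magnitude of flux leaving the zone.
#' @param source_influx magnitude of the source influx the consumption is
#'   referenced to; defaults to \code{flux_in}.
#' @return list with \code{consumption} (mmol m^-2 yr^-1), \code{fraction}
#'   (of the source influx) and \code{warning_negative} (TRUE when the
#'   apparent consumption is negative, indicating gradient-estimation
#'   noise).
#' @export
zone_consumption <- function(flux_in, flux_out, source_influx = flux_in) {
  val <- function(x) if (inherits(x, "flux_estimate")) abs(x$flux) else abs(x)
  fin <- val(flux_in); fout <- val(flux_out); src <- val(source_influx)
  consumption <- fin - fout
  list(consumption = consumption,
       fraction = if (src > 0) consumption / src else NA_real_,
       warning_negative = consumption < 0)
}

#' Partition a total efflux between the two sinks of the column
#'
#' For a species leaving the sediment both upward (into the overlying
#' seawater) and downward (into the basement aquifer), returns the percent
#' of the total efflux entering each sink.
#'
#' @param upward upward efflux magnitude (>= 0), mmol m^-2 yr^-1.
#' @param downward downward efflux magnitude (>= 0).
#' @return list with \code{percent_up} and \code{percent_down}; the two sum
#'   to exactly 100.
#' @export
efflux_partition <- function(upward, downward) {
  stopifnot(upward >= 0, downward >= 0)
  if (upward + downward == 0) stop("both effluxes are zero")
  pd <- 100 * downward / (upward + downward)
  list(percent_up = 100 - pd, percent_down = pd)
}
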