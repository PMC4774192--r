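# Synthetic generators for every external input: diurnal plasma glucose
# profiles, glucose-hormone scatter for GHT fitting, and enzyme abundance
# samples. All generators are pure functions of (specification, seed).

#' Synthetic diurnal plasma glucose profile
#'
#' Generates a smooth, strictly positive 24-h plasma glucose profile with the
#' qualitative features of a nutritional condition: the fed profile has meal
#' excursions spanning the fed set point, the fasted profile stays in the
#' low-normal range, and the diabetic profile remains persistently above
#' 14 mM. These are synthetic surrogates for measured diurnal profiles, not
#' reproductions of any particular experimental data set.
#'
#' The profile is a baseline plus smooth periodic meal pulses (wrapped
#' Gaussian bumps) plus, optionally, smooth noise interpolated from
#' independent draws at 2-h knots.
#'
#' @param condition "fed", "fasted" or "diabetic" (sets the defaults below).
#' @param baseline Baseline glucose (mM).
#' @param pulse_times,pulse_heights,pulse_widths Meal pulse centres (h),
#'   heights (mM) and Gaussian widths (h).
#' @param noise_sd Standard deviation of the smooth noise component (mM).
#' @param seed Integer seed (only used when \code{noise_sd > 0}).
#' @param dt Output resolution (h).
#' @return data.frame with \code{time_h} (0 to 24) and \code{glucose_mM}.
#' @export
#' @examples
#' prof <- gen_diurnal_glucose("fed")
#' range(prof$glucose_mM)
gen_diurnal_glucose <- function(condition = c("fed", "fasted", "diabetic"),
                                baseline = NULL, pulse_times = NULL,
                                pulse_heights = NULL, pulse_widths = NULL,
                                noise_sd = 0, seed = 1, dt = 0.25) {
  condition <- match.arg(condition)
  defaults <- switch(condition,
    fed      = list(baseline = 5.7, times = c(7, 13, 19),
                    heights = c(2.6, 1.6, 3.0), widths = c(1.5, 1.2, 1.8)),
    fasted   = list(baseline = 4.2, times = c(8, 20),
                    heights = c(0.5, 0.4), widths = c(2.5, 2.5)),
    diabetic = list(baseline = 15.5, times = c(7, 13, 19),
                    heights = c(3.0, 2.0, 3.2), widths = c(1.8, 1.5, 2.0)))
  if (is.null(baseline)) baseline <- defaults$baseline
  if (is.null(pulse_times)) pulse_times <- defaults$times
  if (is.null(pulse_heights)) pulse_heights <- defaults$heights
  if (is.null(pulse_widths)) pulse_widths <- defaults$widths
  stopifnot(length(pulse_times) == length(pulse_heights),
            length(pulse_times) == length(pulse_widths), noise_sd >= 0)

  t <- seq(0, 24, by = dt)
  g <- rep(baseline, length(t))
  for (i in seq_along(pulse_times)) {
    # wrap pulse images at +-24 h so the profile is smooth and periodic
    for (shift in c(-24, 0, 24)) {
      d <- t - (pulse_times[i] + shift)
      g <- g + pulse_heights[i] * exp(-d^2 / (2 * pulse_widths[i]^2))
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    knots <- seq(0, 24, by = 2)
    z <- stats::rnorm(length(knots) - 1, sd = noise_sd)
    z <- c(z, z[1])  # periodic
    g <- g + stats::splinefun(knots, z, method = "periodic")(t)
  }
  if (any(g <= 0)) stop("specification produced nonpositive glucose")
  if (condition == "diabetic" && min(g) <= 14)
    stop("diabetic specification must keep glucose above 14 mM")
  data.frame(time_h = t, glucose_mM = g)
}

#' Sample enzyme abundance ratios within the reported ranges
#'
#' Draws one abundance scaling factor per table enzyme: an independent uniform
#' draw within the enzyme's reported [min, max] range for the state, or the
#' fixed mean where no range is reported (the fed reference state has no
#' variation: all ratios are 1).
#'
#' @param abundance Abundance table, see [abundance_table()].
#' @param state Physiological state.
#' @param seed Optional integer seed (omit to use the current RNG stream, as
#'   [run_diurnal()] does for its ensemble).
#' @return Named numeric vector of ratios over the table enzymes.
#' @export
#' @examples
#' sample_abundance_ratios(state = "fasted", seed = 1)
sample_abundance_ratios <- function(abundance = abundance_table(),
                                    state = "fasted", seed = NULL) {
  state <- match.arg(state, physiological_states())
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(abundance)
  out <- setNames(numeric(n), abundance$enzyme)
  if (state == "fed") {
    out[] <- 1
    return(out)
  }
  mins <- abundance[[paste0(state, "_min")]]
  maxs <- abundance[[paste0(state, "_max")]]
  means <- abundance[[state]]
  if (is.null(mins)) {             # normal state: fixed means only
    out[] <- means
    return(out)
  }
  for (i in seq_len(n)) {
    out[i] <- if (is.na(mins[i])) means[i] else stats::runif(1, mins[i], maxs[i])
  }
  out
}

#' Synthetic glucose-hormone scatter data
#'
#' Points on a GHT branch with multiplicative Gaussian noise, for exercising
#' the curve fit. Zero noise returns points exactly on the curve.
#'
#' @param params GHT parameters, see [default_ght()].
#' @param hormone "insulin" or "glucagon".
#' @param n Number of points (>= 8).
#' @param glucose_range Glucose design range (mM).
#' @param rel_noise Relative noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return data.frame with \code{glucose_mM}, \code{hormone_pM},
#'   \code{hormone}.
#' @export
gen_ght_scatter <- function(params = default_ght(),
                            hormone = c("insulin", "glucagon"), n = 50,
                            glucose_range = c(2, 15), rel_noise = 0.1,
                            seed = 1) {
  hormone <- match.arg(hormone)
  stopifnot(n >= 8, rel_noise >= 0, glucose_range[1] > 0)
  set.seed(seed)
  g <- seq(glucose_range[1], glucose_range[2], length.out = n)
  y <- ght(g, "normal", params)[[hormone]]
  if (rel_noise > 0) y <- y * (1 + stats::rnorm(n, sd = rel_noise))
  y <- pmax(y, 0)
  data.frame(glucose_mM = g, hormone_pM = y, hormone = hormone,
             stringsAsFactors = FALSE)
}
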