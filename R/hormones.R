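# Glucose-hormone transfer (GHT) functions and the phosphorylation signal
# function gamma.

#' Default glucose-hormone transfer parameters
#'
#' Hill-type transfer curves mapping plasma glucose (mM) to portal insulin and
#' glucagon levels (pM). Insulin rises with glucose, glucagon falls. The
#' diabetic variant scales the whole insulin curve to 10 % and the whole
#' glucagon curve to 200 % of normal, reflecting impaired beta-cell secretion
#' and alpha-cell disinhibition.
#'
#' @return A list of class \code{ght_params} with elements \code{insulin}
#'   (basal, amp, K, h), \code{glucagon} (basal, amp, K, h) and
#'   \code{diabetic} (insulin_scale, glucagon_scale).
#' @export
default_ght <- function() {
  structure(list(
    insulin  = list(basal = 20,  amp = 1200, K = 9, h = 4),
    glucagon = list(basal = 30,  amp = 170,  K = 6, h = 4),
    diabetic = list(insulin_scale = 0.10, glucagon_scale = 2.0)
  ), class = "ght_params")
}

#' Plasma hormone levels from plasma glucose (GHT function)
#'
#' @param glucose Plasma glucose (mM), > 0; vectorized.
#' @param variant "normal" or "diabetic".
#' @param params GHT parameters, see [default_ght()].
#' @return A list with numeric elements \code{insulin} and \code{glucagon}
#'   (pM), each the length of \code{glucose}.
#' @export
#' @examples
#' ght(7.5)
#' ght(7.5, variant = "diabetic")
ght <- function(glucose, variant = c("normal", "diabetic"),
                params = default_ght()) {
  variant <- match.arg(variant)
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be positive")
  pi_ <- params$insulin; pg <- params$glucagon
  ins <- pi_$basal + pi_$amp * glucose^pi_$h / (pi_$K^pi_$h + glucose^pi_$h)
  glu <- pg$basal + pg$amp * pg$K^pg$h / (pg$K^pg$h + glucose^pg$h)
  if (variant == "diabetic") {
    ins <- ins * params$diabetic$insulin_scale
    glu <- glu * params$diabetic$glucagon_scale
  }
  list(insulin = ins, glucagon = glu)
}

#' Fit a Hill-type GHT branch to glucose-hormone scatter data
#'
#' Least-squares fit of \code{basal + amp * g^h / (K^h + g^h)} (rising,
#' insulin) or \code{basal + amp * K^h / (K^h + g^h)} (falling, glucagon) by
#' Levenberg-Marquardt minimization with five deterministic starting points;
#' ties are broken by lowest residual sum of squares, then lowest Hill
#' exponent.
#'
#' @param data data.frame with columns \code{glucose_mM} and \code{hormone_pM}.
#' @param hormone "insulin" (rising) or "glucagon" (falling).
#' @return List with the fitted \code{basal}, \code{amp}, \code{K}, \code{h},
#'   the residual sum of squares \code{rss} and \code{hormone}.
#' @export
fit_ght <- function(data, hormone = c("insulin", "glucagon")) {
  hormone <- match.arg(hormone)
  g <- data$glucose_mM; y <- data$hormone_pM
  if (length(g) < 4) stop("need at least 4 data points")
  if (any(g <= 0)) stop("glucose values must be positive")
  if (diff(range(g)) < sqrt(.Machine$double.eps))
    stop("degenerate data: all glucose values identical")
  rising <- hormone == "insulin"
  model <- function(p, g) {
    hill <- g^p[4] / (p[3]^p[4] + g^p[4])
    if (rising) p[1] + p[2] * hill else p[1] + p[2] * (1 - hill)
  }
  resid_fn <- function(p) model(p, g) - y
  span <- max(diff(range(y)), 1e-8)
  base <- if (rising) min(y) else min(y)
  starts <- list(
    c(base, span, stats::median(g), 2),
    c(base, span, stats::median(g), 4),
    c(base, span, mean(range(g)), 1),
    c(base, 2 * span, stats::quantile(g, 0.75, names = FALSE), 3),
    c(max(base, 1e-3), span, stats::quantile(g, 0.25, names = FALSE), 6)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(0, 0, 1e-3, 0.2), upper = c(Inf, Inf, 100, 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && fit$par[4] < best$par[4]))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("GHT fit failed from all starting points")
  list(basal = best$par[1], amp = best$par[2], K = best$par[3],
       h = best$par[4], rss = best$rss, hormone = hormone)
}

#' Default parameters of the phosphorylation signal function
#'
#' gamma(insulin, glucagon) is the fraction of an interconvertible enzyme in
#' the phosphorylated form: a product of a glucagon-activating branch with
#' basal level \code{basal} (the kinase/phosphatase balance in the absence of
#' hormones) and an insulin-suppressing branch. Both branches saturate; at
#' saturating glucagon (1e5 pM, basal insulin) gamma tends to 1, at
#' saturating insulin gamma tends to 0. The glucagon half-saturation constant
#' is calibrated so that gamma = 0.32 at the hormone levels of the
#' normal-state glucose set point.
#'
#' @return List of class \code{gamma_params}: \code{basal}, \code{Kg},
#'   \code{hg} (glucagon branch), \code{Ki}, \code{hi} (insulin branch),
#'   \code{saturating} (pM).
#' @export
default_gamma <- function() {
  structure(list(basal = 0.7, Kg = 53.8, hg = 2.5, Ki = 300, hi = 2,
                 saturating = 1e5),
            class = "gamma_params")
}

#' Phosphorylated enzyme fraction from hormone levels
#'
#' @param insulin Insulin (pM), >= 0; vectorized.
#' @param glucagon Glucagon (pM), >= 0; vectorized.
#' @param params See [default_gamma()].
#' @return gamma in [0, 1].
#' @export
#' @examples
#' gamma_fraction(insulin = 20, glucagon = 1e5)   # ~1
#' gamma_fraction(insulin = 1e5, glucagon = 30)   # ~0
gamma_fraction <- function(insulin, glucagon, params = default_gamma()) {
  if (any(insulin < 0) || any(glucagon < 0))
    stop("hormone levels must be >= 0")
  xg <- (glucagon / params$Kg)^params$hg
  G <- (params$basal + xg) / (1 + xg)
  I <- insulin^params$hi / (params$Ki^params$hi + insulin^params$hi)
  pmin(pmax(G * (1 - I), 0), 1)
}

# gamma at a clamped plasma glucose level through the GHT coupling.
gamma_at_glucose <- function(glucose, variant = "normal",
                             ght_params = default_ght(),
                             gamma_params = default_gamma()) {
  h <- ght(glucose, variant, ght_params)
  gamma_fraction(h$insulin, h$glucagon, gamma_params)
}
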