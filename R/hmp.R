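# Harmonic mean p-value combination. The raw HMP of L p-values is
# 1 / sum(w_i / p_i); its null distribution is heavy-tailed (the reciprocal
# of an equal-weight HMP of L uniform p-values asymptotically follows a
# Landau distribution, location log(L) + 0.874367..., scale pi/2), which
# yields the asymptotically exact multiplicity-adjusted p-value. The Landau
# tail is evaluated by direct numerical integration of the classic integral
# representation of its density.

# classic Landau density: f(x) = (1/pi) Int_0^inf exp(-t log t - x t) sin(pi t) dt
.dlandau <- function(x) {
    vapply(x, function(xi)
        stats::integrate(function(t) {
            v <- exp(-t * log(t) - xi * t) * sin(pi * t) / pi
            v[t == 0] <- 0
            v
        }, 0, Inf, rel.tol = 1e-12, abs.tol = 0,
        stop.on.error = FALSE)$value, numeric(1L))
}

# upper tail of the classic Landau; far tail handled by the 1/x^2 density
# asymptote beyond 100x the evaluation point
.plandauUpper <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi))
            return(if (xi > 0) 0 else 1)
        if (xi > 50) {
            body <- stats::integrate(.dlandau, xi, 100 * xi, rel.tol = 1e-9,
                                     subdivisions = 1000L,
                                     stop.on.error = FALSE)$value
            min(1, body + 1 / (100 * xi))
        } else {
            min(1, stats::integrate(.dlandau, xi, Inf, rel.tol = 1e-9,
                                    subdivisions = 1000L,
                                    stop.on.error = FALSE)$value)
        }
    }, numeric(1L))
}

#' Combine p-values by the harmonic mean p-value (HMP)
#'
#' The raw HMP is `1 / sum(w_i / p_i)` with weights summing to one (equal by
#' default). For `L >= 2` the asymptotically exact multiplicity adjustment is
#' also computed: the reciprocal of the raw HMP is referred to a Landau
#' distribution with location `log(L) + 0.8743670...` and scale `pi/2`, whose
#' upper tail gives a p-value valid for arbitrarily dependent tests. For
#' `L = 1`, or when `adjust = FALSE`, the adjusted value equals the raw one.
#'
#' @param ps Numeric vector of p-values in `(0, 1]`. Zeros are clamped to the
#'   smallest positive double with a warning.
#' @param weights Optional weights summing to 1; default equal.
#' @param adjust Compute the asymptotically exact adjusted p-value
#'   (default `TRUE`).
#' @return A list with `raw` (the harmonic mean), `adjusted`, and `L`.
#' @examples
#' harmonicMeanP(c(0.01, 0.04))$raw  # 2/125 = 0.016
#' harmonicMeanP(rep(0.2, 5))$raw    # 0.2
#' @export
harmonicMeanP <- function(ps, weights = NULL, adjust = TRUE) {
    if (length(ps) == 0L)
        stop("'ps' must contain at least one p-value")
    if (anyNA(ps) || any(ps < 0) || any(ps > 1))
        stop("p-values must lie in (0, 1]")
    if (any(ps == 0)) {
        warning("p-value(s) of 0 clamped to the smallest positive double")
        ps[ps == 0] <- .Machine$double.xmin
    }
    L <- length(ps)
    if (is.null(weights))
        weights <- rep(1 / L, L)
    if (length(weights) != L || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-8)
        stop("'weights' must be non-negative, match length(ps), and sum to 1")
    raw <- 1 / sum(weights / ps)
    adjusted <- raw
    if (adjust && L >= 2L) {
        # scale pi/2 cancels against the classic-form parametrisation
        # (classic density = Landau with location log(pi/2), scale pi/2)
        z <- 1 / raw - log(L) - 0.874367040387922 + log(pi / 2)
        adjusted <- .plandauUpper(z)
    }
    list(raw = raw, adjusted = adjusted, L = L)
}
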