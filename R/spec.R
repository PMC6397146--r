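#' Fundamental and harmonic seasonal frequencies
#'
#' Builds the frequency set \eqn{\omega_i = 2\pi i / p} for
#' \eqn{i = 1, \dots, R_s}, where \eqn{p} is the fundamental period in years.
#' With the default annual period, harmonic 1 is the annual cycle and
#' harmonic 2 the semi-annual cycle.
#'
#' @param fundamental_period Fundamental period in years (> 0).
#' @param n_harmonics Number of harmonics \eqn{R_s} (positive integer,
#'   at most 6).
#' @return An object of class `"harmonic_set"` with fields
#'   `fundamental_period`, `n_harmonics` and `omega` (radians per year).
#' @export
#' @examples
#' make_harmonics(1, 2)$omega / pi   # 2, 4
make_harmonics <- function(fundamental_period = 1, n_harmonics = 2) {
  if (!is.numeric(fundamental_period) || length(fundamental_period) != 1L ||
      !is.finite(fundamental_period) || fundamental_period <= 0)
    stop("invalid specification: `fundamental_period` must be a positive number")
  n_harmonics <- as.integer(n_harmonics)
  if (is.na(n_harmonics) || n_harmonics < 1L)
    stop("invalid specification: `n_harmonics` must be a positive integer")
  if (n_harmonics > 6L)
    stop("invalid specification: at most 6 harmonics are supported")
  structure(list(fundamental_period = fundamental_period,
                 n_harmonics = n_harmonics,
                 omega = 2 * pi * seq_len(n_harmonics) / fundamental_period),
            class = "harmonic_set")
}

#' Time-varying-parameter evolution model
#'
#' Describes how one regression coefficient (or the trend) evolves:
#' a random walk (`"rw"`) or an integrated random walk (`"irw"`, which adds
#' a latent slope state and yields smoother paths). The noise variance
#' ratio (NVR) is the ratio of the parameter's process-noise variance per
#' unit time to the observation-noise variance; `nvr = 0` makes the
#' parameter constant over time.
#'
#' @param kind `"rw"`/`"random_walk"` or `"irw"`/`"integrated_random_walk"`.
#' @param nvr Noise variance ratio, `>= 0`, or `NA` to be estimated.
#' @return An object of class `"tvp_model"`.
#' @export
tvp_model <- function(kind = c("rw", "irw", "random_walk", "integrated_random_walk"),
                      nvr = NA_real_) {
  kind <- match.arg(kind)
  kind <- switch(kind, random_walk = "rw", integrated_random_walk = "irw", kind)
  nvr <- as.numeric(nvr)[1L]
  if (!is.na(nvr) && (!is.finite(nvr) || nvr < 0))
    stop("invalid specification: `nvr` must be >= 0 (or NA to estimate)")
  structure(list(kind = kind, nvr = nvr), class = "tvp_model")
}

#' Unobserved-components model specification
#'
#' Defines the additive decomposition `y_t = T_t + S_t + e_t` (a cycle
#' component is accepted as a flag for interface completeness but not
#' estimated): a trend with its own TVP law, and a seasonal component
#' `S_t = sum_i a_{i,t} cos(omega_i t) + b_{i,t} sin(omega_i t)` whose
#' coefficients share a TVP law (or take one per harmonic).
#'
#' @param trend A [tvp_model()] for the trend, or `"none"` for a model
#'   without a trend block. Character shorthand `"rw"`/`"irw"` is accepted.
#' @param seasonal A [tvp_model()] shared by all harmonic coefficients, a
#'   list of one per harmonic, or `NULL`/`"none"` together with
#'   `harmonics = NULL` for a trend-only model. Character shorthand accepted.
#' @param harmonics A [make_harmonics()] set, or `NULL` for trend-only.
#' @param include_cycle Must be `FALSE`; kept as a configuration stub.
#' @param sigma2 Observation-noise variance \eqn{\sigma^2_e}, or `NULL` to
#'   estimate it.
#' @return An object of class `"uc_spec"`.
#' @export
uc_spec <- function(trend = tvp_model("irw"),
                    seasonal = tvp_model("rw"),
                    harmonics = make_harmonics(1, 2),
                    include_cycle = FALSE,
                    sigma2 = NULL) {
  if (isTRUE(include_cycle))
    stop("invalid specification: the cycle component is a stub and cannot be estimated")
  if (is.character(trend))
    trend <- if (identical(trend, "none")) NULL else tvp_model(trend)
  if (is.character(seasonal))
    seasonal <- if (identical(seasonal, "none")) NULL else tvp_model(seasonal)
  if (!is.null(trend) && !inherits(trend, "tvp_model"))
    stop("invalid specification: `trend` must be a tvp_model, \"none\" or NULL")
  if (is.null(harmonics)) seasonal <- NULL
  if (!is.null(harmonics) && !inherits(harmonics, "harmonic_set"))
    stop("invalid specification: `harmonics` must come from make_harmonics()")
  if (!is.null(harmonics)) {
    if (inherits(seasonal, "tvp_model")) {
      seasonal <- rep(list(seasonal), harmonics$n_harmonics)
    } else if (is.list(seasonal)) {
      if (length(seasonal) != harmonics$n_harmonics ||
          !all(vapply(seasonal, inherits, logical(1), "tvp_model")))
        stop("invalid specification: `seasonal` must be one tvp_model or one per harmonic")
    } else stop("invalid specification: `seasonal` missing for a model with harmonics")
  }
  if (is.null(trend) && is.null(harmonics))
    stop("invalid specification: model needs a trend and/or harmonics")
  if (!is.null(sigma2)) {
    sigma2 <- as.numeric(sigma2)[1L]
    if (!is.finite(sigma2) || sigma2 < 0)
      stop("invalid specification: `sigma2` must be >= 0")
  }
  structure(list(trend = trend, seasonal = seasonal, harmonics = harmonics,
                 include_cycle = FALSE, sigma2 = sigma2),
            class = "uc_spec")
}

#' @export
print.uc_spec <- function(x, ...) {
  lay <- state_layout(x)
  cat("Unobserved-components model specification\n")
  cat("  trend   :", if (is.null(x$trend)) "none" else x$trend$kind, "\n")
  if (!is.null(x$harmonics))
    cat(sprintf("  seasonal: %d harmonic(s), period %.4g yr, TVP %s\n",
                x$harmonics$n_harmonics, x$harmonics$fundamental_period,
                paste(unique(vapply(x$seasonal, `[[`, "", "kind")), collapse = "/")))
  else cat("  seasonal: none\n")
  cat("  state dimension:", lay$m, "\n")
  invisible(x)
}

# Internal: flatten the spec into per-unit state blocks.
# Each unit is one TVP (trend level, or one harmonic coefficient a_i / b_i);
# a random walk occupies 1 state, an integrated random walk 2 (level, slope).
# The observation row loads the unit's first (level) state with a factor:
# 1 for the trend, cos(omega_i t) for a_i, sin(omega_i t) for b_i.
state_layout <- function(spec) {
  stopifnot(inherits(spec, "uc_spec"))
  units <- list()
  if (!is.null(spec$trend))
    units[[length(units) + 1L]] <- list(role = "trend", kind = spec$trend$kind,
                                        omega = NA_real_, group = "trend")
  if (!is.null(spec$harmonics)) {
    for (i in seq_len(spec$harmonics$n_harmonics)) {
      w <- spec$harmonics$omega[i]
      kind <- spec$seasonal[[i]]$kind
      units[[length(units) + 1L]] <- list(role = "a", kind = kind, omega = w,
                                          group = "seasonal", harmonic = i)
      units[[length(units) + 1L]] <- list(role = "b", kind = kind, omega = w,
                                          group = "seasonal", harmonic = i)
    }
  }
  sizes <- vapply(units, function(u) if (u$kind == "irw") 2L else 1L, integer(1))
  first <- cumsum(c(1L, sizes))[seq_along(sizes)]
  for (k in seq_along(units)) {
    units[[k]]$idx <- seq.int(first[k], length.out = sizes[k])
    units[[k]]$level <- first[k]
  }
  trend_level <- if (!is.null(spec$trend)) units[[1L]]$level else NA_integer_
  list(units = units, m = sum(sizes), trend_level = trend_level,
       seasonal_levels = vapply(Filter(function(u) u$group == "seasonal", units),
                                `[[`, integer(1), "level"))
}

# Internal: expand user-facing NVRs (named "trend"/"seasonal", a scalar, or a
# full per-unit vector) into one value per state unit.
expand_nvrs <- function(spec, nvrs) {
  lay <- state_layout(spec)
  nunits <- length(lay$units)
  if (length(nvrs) == nunits && is.null(names(nvrs))) return(as.numeric(nvrs))
  if (length(nvrs) == 1L && is.null(names(nvrs)))
    return(rep(as.numeric(nvrs), nunits))
  out <- numeric(nunits)
  nm <- names(nvrs)
  if (is.null(nm)) stop("`nvrs` must be named (trend/seasonal), a scalar, or per-unit")
  for (k in seq_len(nunits)) {
    g <- lay$units[[k]]$group
    if (!g %in% nm) stop("`nvrs` missing value for group '", g, "'")
    out[k] <- as.numeric(nvrs[[g]])
  }
  if (any(!is.finite(out)) || any(out < 0)) stop("NVRs must be finite and >= 0")
  out
}

#' Observation (regression) row at an instant
#'
#' Returns the row `h_t` such that `h_t %*% state = T_t + S_t`: trend
#' entries first (`1` for a random-walk trend, `1, 0` for an integrated
#' random walk), then `cos(omega_i t), sin(omega_i t)` loadings for each
#' harmonic (with zeros on any latent slope states).
#'
#' @param t Scalar instant in decimal years.
#' @param spec A [uc_spec()].
#' @param seasonal_only Zero out the trend loading (used for seasonal bands).
#' @return Numeric vector of length equal to the state dimension.
#' @export
#' @examples
#' observation_vector(0, uc_spec(trend = "rw", harmonics = make_harmonics(1, 1)))
observation_vector <- function(t, spec, seasonal_only = FALSE) {
  lay <- state_layout(spec)
  h <- numeric(lay$m)
  for (u in lay$units) {
    f <- switch(u$role,
                trend = if (seasonal_only) 0 else 1,
                a = cos(u$omega * t),
                b = sin(u$omega * t))
    h[u$level] <- f
  }
  h
}

#' State transition over an irregular sampling gap
#'
#' Block-diagonal transition matrix and process covariance for a gap of
#' `delta_t` years. Random-walk blocks are the identity with variance
#' `nvr * sigma2_e * delta_t` (process variance accumulates linearly with
#' elapsed time — the irregular-sampling mechanism); integrated-random-walk
#' blocks use `[[1, dt], [0, 1]]` with the exact continuous-time
#' discretization covariance
#' `nvr * sigma2_e * [[dt^3/3, dt^2/2], [dt^2/2, dt]]`.
#'
#' @param delta_t Elapsed time in years (> 0).
#' @param spec A [uc_spec()].
#' @param nvrs NVRs: named `c(trend = , seasonal = )`, a scalar, or one per
#'   state unit.
#' @param sigma2_e Observation-noise variance scaling the process noise.
#' @return List with `A` (transition matrix) and `Q` (process covariance).
#' @export
transition_system <- function(delta_t, spec, nvrs, sigma2_e = 1) {
  if (!is.numeric(delta_t) || length(delta_t) != 1L || !is.finite(delta_t) ||
      delta_t <= 0)
    stop("observation ordering error: `delta_t` must be a positive gap")
  lay <- state_layout(spec)
  nv <- expand_nvrs(spec, nvrs)
  A <- diag(1, lay$m)
  Q <- matrix(0, lay$m, lay$m)
  for (k in seq_along(lay$units)) {
    u <- lay$units[[k]]
    q <- nv[k] * sigma2_e
    if (u$kind == "rw") {
      Q[u$idx, u$idx] <- q * delta_t
    } else {
      A[u$idx, u$idx] <- matrix(c(1, 0, delta_t, 1), 2, 2)
      Q[u$idx, u$idx] <- q * matrix(c(delta_t^3 / 3, delta_t^2 / 2,
                                      delta_t^2 / 2, delta_t), 2, 2)
    }
  }
  list(A = A, Q = Q)
}
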