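# symmetrize a covariance to suppress drift from floating-point asymmetry
sym <- function(P) (P + t(P)) / 2

# Internal: precompute everything about a filter run that does not depend on
# the hyperparameters — observation rows, gap-dependent transition matrices,
# and per-unit process-covariance blocks scaled later by nvr * sigma2.
filter_context <- function(series, spec) {
  lay <- state_layout(spec)
  tt <- series$times
  y <- series$values
  n <- length(tt)
  m <- lay$m
  H <- t(vapply(tt, observation_vector, numeric(m), spec = spec))
  if (m == 1L) H <- matrix(H, n, 1L)
  obs <- !is.na(y)
  s2y <- stats::var(y[obs])
  if (!is.finite(s2y) || s2y <= 0) s2y <- max(mean(y[obs]^2), 1)
  Alist <- vector("list", n)
  Qb <- vector("list", n)  # per step: list of per-unit covariance blocks (nvr*sigma2 = 1)
  for (k in seq_len(n)[-1]) {
    dt <- tt[k] - tt[k - 1L]
    A <- diag(1, m)
    blocks <- vector("list", length(lay$units))
    for (j in seq_along(lay$units)) {
      u <- lay$units[[j]]
      if (u$kind == "rw") {
        blocks[[j]] <- matrix(dt, 1, 1)
      } else {
        A[u$idx, u$idx] <- matrix(c(1, 0, dt, 1), 2, 2)
        blocks[[j]] <- matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
      }
    }
    Alist[[k]] <- A
    Qb[[k]] <- blocks
  }
  list(lay = lay, times = tt, y = y, obs = obs, n = n, m = m, H = H,
       Alist = Alist, Qb = Qb, s2y = s2y, spec = spec)
}

# Internal: filter recursion on a prepared context. `nvu` is one NVR per
# state unit. lite = TRUE returns only innovations and the log-likelihood
# (used inside the likelihood search).
kf_core <- function(ctx, nvu, sigma2, P0_scale = 1e7, lite = FALSE) {
  n <- ctx$n
  m <- ctx$m
  lay <- ctx$lay
  y <- ctx$y
  obs <- ctx$obs
  Ffloor <- 1e-12 * ctx$s2y
  x <- numeric(m)
  if (!is.na(lay$trend_level)) x[lay$trend_level] <- y[which(obs)[1L]]
  P <- diag(P0_scale * ctx$s2y, m)
  v <- Fv <- rep(NA_real_, n)
  loglik <- 0
  if (!lite) {
    xp <- xf <- matrix(0, n, m)
    Pp <- Pf <- array(0, c(m, m, n))
  }
  for (k in seq_len(n)) {
    if (k > 1L) {
      A <- ctx$Alist[[k]]
      x <- drop(A %*% x)
      P <- A %*% P %*% t(A)
      qb <- ctx$Qb[[k]]
      for (j in seq_along(lay$units)) {
        if (nvu[j] > 0) {
          idx <- lay$units[[j]]$idx
          P[idx, idx] <- P[idx, idx] + nvu[j] * sigma2 * qb[[j]]
        }
      }
      P <- sym(P)
    }
    if (!lite) {
      xp[k, ] <- x
      Pp[, , k] <- P
    }
    if (obs[k]) {
      h <- ctx$H[k, ]
      Ph <- drop(P %*% h)
      Fk <- sum(h * Ph) + sigma2
      if (!is.finite(Fk) || Fk <= 0)
        stop(sprintf("numerical conditioning failure: singular innovation variance at t = %.6g",
                     ctx$times[k]))
      Fk <- max(Fk, Ffloor)
      vk <- y[k] - sum(h * x)
      K <- Ph / Fk
      x <- x + K * vk
      P <- sym(P - tcrossprod(K) * Fk)
      v[k] <- vk
      Fv[k] <- Fk
      loglik <- loglik - 0.5 * (log(2 * pi) + log(Fk) + vk^2 / Fk)
    }
    if (!lite) {
      xf[k, ] <- x
      Pf[, , k] <- P
    }
  }
  if (lite) return(list(v = v, F = Fv, loglik = loglik))
  list(v = v, F = Fv, loglik = loglik, xp = xp, Pp = Pp, xf = xf, Pf = Pf)
}

#' Kalman filter for irregularly sampled series
#'
#' Runs the standard predict/update recursion where each prediction step
#' uses the gap-dependent transition of [transition_system()], so arbitrary
#' inter-sample spacing is handled exactly. Initialization is an
#' approximately diffuse prior: covariance `P0_scale * var(y)` times the
#' identity; state mean zero except the trend level, which starts at the
#' first observation. The log-likelihood comes from the prediction-error
#' decomposition. `NA` values are treated as unobserved instants
#' (prediction only, no update), which supports interpolation grids.
#'
#' @param series An [irregular_series()] (or coercible); `NA` values mark
#'   instants where the state is propagated but not updated.
#' @param spec A [uc_spec()].
#' @param nvrs NVRs, as in [transition_system()].
#' @param sigma2_e Observation-noise variance (> 0).
#' @param P0_scale Diffuse-prior variance multiplier (default `1e7`).
#' @return Object of class `"seasdhr_kf"`: times, observations, observation
#'   rows `H`, predicted/filtered state means (`xp`, `xf`; n x m) and
#'   covariance arrays (`Pp`, `Pf`; m x m x n), innovations `v` and their
#'   variances `F`, `loglik`, transition list `Alist`, and the inputs.
#' @export
kalman_filter <- function(series, spec, nvrs, sigma2_e, P0_scale = 1e7) {
  series <- as_irregular_series_allow_na(series)
  stopifnot(inherits(spec, "uc_spec"))
  if (!is.numeric(sigma2_e) || length(sigma2_e) != 1L || !is.finite(sigma2_e) ||
      sigma2_e < 0)
    stop("`sigma2_e` must be a non-negative variance")
  ctx <- filter_context(series, spec)
  if (sum(ctx$obs) < 1L) stop("series contains no observed values")
  if (sum(ctx$obs) < ctx$m)
    warning(sprintf("only %d observations for a %d-dimensional state", sum(ctx$obs), ctx$m))
  nvu <- expand_nvrs(spec, nvrs)
  out <- kf_core(ctx, nvu, sigma2_e, P0_scale = P0_scale)
  structure(list(times = ctx$times, y = ctx$y, obs = ctx$obs, H = ctx$H,
                 xp = out$xp, Pp = out$Pp, xf = out$xf, Pf = out$Pf,
                 v = out$v, F = out$F, loglik = out$loglik, Alist = ctx$Alist,
                 spec = spec, nvrs = nvrs, sigma2_e = sigma2_e,
                 P0 = P0_scale * ctx$s2y, s2y = ctx$s2y),
            class = "seasdhr_kf")
}

# internal coercion that tolerates NA values (unobserved instants)
as_irregular_series_allow_na <- function(x) {
  if (inherits(x, "irregular_series")) return(x)
  if (is.list(x) && !is.null(x$times) && !is.null(x$values)) {
    if (is.unsorted(x$times, strictly = TRUE))
      stop("`times` must be strictly increasing")
    return(structure(list(times = as.numeric(x$times),
                          values = as.numeric(x$values),
                          label = if (is.null(x$label)) "" else x$label),
                     class = "irregular_series"))
  }
  as_irregular_series(x)
}

#' Fixed-interval smoother
#'
#' Backward `r`/`N` recursion (the disturbance-smoothing form of
#' fixed-interval smoothing) over the output of [kalman_filter()],
#' producing state estimates conditional on the whole series. This form
#' never inverts the predicted covariance, so it stays accurate under the
#' near-diffuse initialization. At the final instant smoothed equals
#' filtered, and smoothed variances never exceed filtered variances.
#'
#' @param kf A `"seasdhr_kf"` object.
#' @return Object of class `"seasdhr_smooth"`: the filter fields plus `xs`
#'   (n x m smoothed means) and `Ps` (m x m x n smoothed covariances).
#' @export
fixed_interval_smooth <- function(kf) {
  stopifnot(inherits(kf, "seasdhr_kf"))
  n <- length(kf$times)
  m <- ncol(kf$xf)
  xs <- kf$xf
  Ps <- kf$Pf
  r <- numeric(m)
  N <- matrix(0, m, m)
  for (k in seq(n, 1L)) {
    Ppk <- matrix(kf$Pp[, , k], m, m)
    if (kf$obs[k]) {
      h <- kf$H[k, ]
      Fk <- kf$F[k]
      K <- drop(Ppk %*% h) / Fk          # filter gain
      # L' r with L = (I - K h'): r - h (K' r), done without forming L
      r <- h * (kf$v[k] / Fk) + (r - h * sum(K * r))
      IKh <- diag(1, m) - tcrossprod(K, h)
      N <- tcrossprod(h) / Fk + t(IKh) %*% N %*% IKh
    }
    xs[k, ] <- kf$xp[k, ] + drop(Ppk %*% r)
    Ps[, , k] <- sym(Ppk - Ppk %*% N %*% Ppk)
    if (k > 1L) {
      A <- kf$Alist[[k]]
      r <- drop(t(A) %*% r)
      N <- t(A) %*% N %*% A
    }
  }
  out <- kf
  out$xs <- xs
  out$Ps <- Ps
  class(out) <- c("seasdhr_smooth", "seasdhr_kf")
  out
}

# Internal: exact diffuse initialization by regression augmentation
# (de Jong-style diffuse Kalman filter). The initial state delta is treated
# as an unknown fixed vector: y_k = X_k delta + h_k' x~_k + e_k with
# X_k = h_k' Phi(1 -> k) and x~ the zero-initial-state process (P0 = 0).
# A single filter pass on the columns [y, X] yields the innovations of all
# inputs; delta is estimated by GLS on the innovations, and smoothed states
# and covariances are the base results plus the delta correction:
#   xs_k = S_k(y) + W_k delta_hat,  W_k = Phi_k - S_k(X)
#   Ps_k = Ps_base_k + W_k A^{-1} W_k'
# where A = sum vX vX'/F is the GLS information. All arithmetic stays at
# data scale, so the NVR = 0 limit reproduces OLS exactly and smoothed
# covariances are accurate at every instant. The reported log-likelihood is
# the diffuse (marginal) likelihood
#   -0.5 [ (n-q) log 2pi + sum log F + log|A| + (S_yy - b'A^{-1}b) ].
diffuse_fit <- function(ctx, nvu, sigma2, lite = FALSE) {
  n <- ctx$n
  m <- ctx$m
  cc <- m + 1L
  lay <- ctx$lay
  obs <- ctx$obs
  no <- sum(obs)
  if (no <= m)
    stop(sprintf("need more than %d observations to identify a %d-dimensional initial state",
                 m, m))
  Phi <- diag(1, m)
  x <- matrix(0, m, cc)
  P <- matrix(0, m, m)
  V <- matrix(NA_real_, n, cc)
  Fv <- rep(NA_real_, n)
  if (!lite) {
    xp_all <- array(0, c(n, m, cc))
    Pp <- array(0, c(m, m, n))
    Phis <- array(0, c(m, m, n))
  }
  for (k in seq_len(n)) {
    if (k > 1L) {
      A <- ctx$Alist[[k]]
      x <- A %*% x
      P <- A %*% P %*% t(A)
      qb <- ctx$Qb[[k]]
      for (j in seq_along(lay$units)) {
        if (nvu[j] > 0) {
          idx <- lay$units[[j]]$idx
          P[idx, idx] <- P[idx, idx] + nvu[j] * sigma2 * qb[[j]]
        }
      }
      P <- sym(P)
      Phi <- A %*% Phi
    }
    if (!lite) {
      xp_all[k, , ] <- x
      Pp[, , k] <- P
      Phis[, , k] <- Phi
    }
    if (obs[k]) {
      h <- ctx$H[k, ]
      Ph <- drop(P %*% h)
      Fk <- sum(h * Ph) + sigma2
      if (!is.finite(Fk) || Fk <= 0)
        stop(sprintf("numerical conditioning failure: singular innovation variance at t = %.6g",
                     ctx$times[k]))
      vk <- c(ctx$y[k], drop(h %*% Phi)) - drop(h %*% x)
      K <- Ph / Fk
      x <- x + K %o% vk
      P <- sym(P - tcrossprod(K) * Fk)
      V[k, ] <- vk
      Fv[k] <- Fk
    }
  }
  Fo <- Fv[obs]
  vy <- V[obs, 1L]
  VX <- V[obs, -1L, drop = FALSE]
  A_gls <- crossprod(VX, VX / Fo)
  b <- drop(crossprod(VX, vy / Fo))
  delta <- tryCatch(solve(A_gls, b), error = function(e)
    stop("initial state not identifiable from the observation design"))
  Syy <- sum(vy^2 / Fo)
  quad <- Syy - sum(b * delta)
  ldA <- as.numeric(determinant(A_gls, logarithm = TRUE)$modulus)
  loglik <- -0.5 * ((no - m) * log(2 * pi) + sum(log(Fo)) + ldA + quad)
  if (lite)
    return(list(loglik = loglik, quad = quad, no = no, q = m,
                sum_logF = sum(log(Fo)), ldA = ldA, F = Fv, V = V))

  r <- matrix(0, m, cc)
  N <- matrix(0, m, m)
  xs <- matrix(0, n, m)
  Ps <- array(0, c(m, m, n))
  Ainv <- solve(A_gls)
  for (k in seq(n, 1L)) {
    Ppk <- matrix(Pp[, , k], m, m)
    if (obs[k]) {
      h <- ctx$H[k, ]
      Fk <- Fv[k]
      K <- drop(Ppk %*% h) / Fk
      r <- h %o% (V[k, ] / Fk) + (r - h %o% drop(crossprod(K, r)))
      IKh <- diag(1, m) - tcrossprod(K, h)
      N <- tcrossprod(h) / Fk + t(IKh) %*% N %*% IKh
    }
    xs_all_k <- xp_all[k, , ] + Ppk %*% r
    W <- Phis[, , k] - xs_all_k[, -1L, drop = FALSE]
    xs[k, ] <- xs_all_k[, 1L] + drop(W %*% delta)
    Ps[, , k] <- sym(Ppk - Ppk %*% N %*% Ppk + W %*% Ainv %*% t(W))
    if (k > 1L) {
      Ak <- ctx$Alist[[k]]
      r <- t(Ak) %*% r
      N <- t(Ak) %*% N %*% Ak
    }
  }
  structure(list(times = ctx$times, y = ctx$y, obs = obs, H = ctx$H,
                 xs = xs, Ps = Ps, loglik = loglik, delta = delta,
                 A_gls = A_gls, quad = quad, no = no, q = m,
                 v = V[, 1L], F = Fv, spec = ctx$spec, nvrs = nvu,
                 sigma2_e = sigma2),
            class = "seasdhr_diffuse")
}

# Internal: effective dof of the diffuse-limit smoother influence map:
# rank of the diffuse regression design plus sum lambda/(lambda + sigma2)
# over the eigenvalues of the base (P0 = 0) signal covariance projected
# orthogonally to that design.
effective_dof_diffuse <- function(ctx, nvu, sigma2) {
  n <- ctx$n
  m <- ctx$m
  lay <- ctx$lay
  # base unconditional state covariances (P0 = 0) and diffuse design X
  Pu <- vector("list", n)
  P <- matrix(0, m, m)
  Phi <- diag(1, m)
  X <- matrix(0, n, m)
  X[1L, ] <- ctx$H[1L, ]
  Pu[[1L]] <- P
  if (n > 1L) for (k in 2:n) {
    A <- ctx$Alist[[k]]
    P <- A %*% P %*% t(A)
    qb <- ctx$Qb[[k]]
    for (j in seq_along(lay$units)) {
      if (nvu[j] > 0) {
        idx <- lay$units[[j]]$idx
        P[idx, idx] <- P[idx, idx] + nvu[j] * sigma2 * qb[[j]]
      }
    }
    P <- sym(P)
    Pu[[k]] <- P
    Phi <- A %*% Phi
    X[k, ] <- drop(ctx$H[k, ] %*% Phi)
  }
  oidx <- which(ctx$obs)
  no <- length(oidx)
  S <- matrix(0, no, no)
  for (ji in seq_len(no)) {
    j <- oidx[ji]
    Mcur <- Pu[[j]]
    S[ji, ji] <- drop(ctx$H[j, ] %*% Mcur %*% ctx$H[j, ])
    if (j < n) {
      for (k in (j + 1L):n) {
        Mcur <- Mcur %*% t(ctx$Alist[[k]])
        ki <- match(k, oidx)
        if (!is.na(ki)) {
          val <- drop(ctx$H[j, ] %*% Mcur %*% ctx$H[k, ])
          S[ji, ki] <- val
          S[ki, ji] <- val
        }
      }
    }
  }
  qx <- qr(X[oidx, , drop = FALSE])
  qrank <- qx$rank
  Qm <- qr.Q(qx)[, seq_len(qrank), drop = FALSE]
  B <- S - Qm %*% crossprod(Qm, S)
  B <- B - (B %*% Qm) %*% t(Qm)
  ev <- pmax(eigen(sym(B), symmetric = TRUE, only.values = TRUE)$values, 0)
  qrank + sum(ev / (ev + sigma2))
}

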