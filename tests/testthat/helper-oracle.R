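# Independent oracles, written directly from the model definition rather than
# through the package's recursions.

# Brute-force joint-Gaussian oracle: builds the implied covariance of all
# observations for a trend + random-walk-harmonic state model and conditions
# on it directly. Supports trend in {"irw", "rw", "none"}; harmonic
# coefficients evolve as random walks.
oracle_joint <- function(times, y, period = 1, n_harm = 1,
                         trend = c("irw", "rw", "none"),
                         nvr_trend = 0, nvr_seas = 0, sigma2,
                         P0_abs = NULL, P0_scale = 1e7) {
  trend <- match.arg(trend)
  n <- length(times)
  om <- if (n_harm > 0) 2 * pi * seq_len(n_harm) / period else numeric(0)
  tsize <- switch(trend, irw = 2L, rw = 1L, none = 0L)
  m <- tsize + 2L * n_harm
  Hrow <- function(t) {
    h <- numeric(m)
    if (tsize >= 1L) h[1] <- 1
    for (i in seq_len(n_harm)) {
      h[tsize + 2L * i - 1L] <- cos(om[i] * t)
      h[tsize + 2L * i] <- sin(om[i] * t)
    }
    h
  }
  Amat <- function(dt) {
    A <- diag(1, m)
    if (tsize == 2L) A[1, 2] <- dt
    A
  }
  Qmat <- function(dt) {
    Q <- matrix(0, m, m)
    if (tsize == 2L)
      Q[1:2, 1:2] <- nvr_trend * sigma2 *
        matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
    if (tsize == 1L) Q[1, 1] <- nvr_trend * sigma2 * dt
    if (n_harm > 0) {
      idx <- (tsize + 1L):m
      diag(Q)[idx] <- diag(Q)[idx] + nvr_seas * sigma2 * dt
    }
    Q
  }
  if (is.null(P0_abs)) {
    s2y <- stats::var(y)
    if (!is.finite(s2y) || s2y <= 0) s2y <- max(mean(y^2), 1)
    P0_abs <- P0_scale * s2y
  }
  x0 <- numeric(m)
  if (tsize >= 1L) x0[1] <- y[1]

  Phis <- vector("list", n)
  Pu <- vector("list", n)
  Pu[[1]] <- diag(P0_abs, m)
  if (n > 1) for (k in 2:n) {
    dt <- times[k] - times[k - 1]
    Phis[[k]] <- Amat(dt)
    Pu[[k]] <- Phis[[k]] %*% Pu[[k - 1]] %*% t(Phis[[k]]) + Qmat(dt)
  }
  covjk <- function(j, k) {  # Cov(x_j, x_k), j <= k
    M <- Pu[[j]]
    if (k > j) for (l in (j + 1):k) M <- M %*% t(Phis[[l]])
    M
  }
  H <- t(vapply(times, Hrow, numeric(m)))
  if (m == 1L) H <- matrix(H, n, 1L)
  Sy <- matrix(0, n, n)
  for (j in 1:n) for (k in j:n) {
    v <- drop(H[j, ] %*% covjk(j, k) %*% H[k, ])
    Sy[j, k] <- v
    Sy[k, j] <- v
  }
  Sy <- Sy + diag(sigma2, n)
  mu <- as.numeric(H %*% x0)   # transition keeps the prior mean constant
  L <- chol((Sy + t(Sy)) / 2)
  z <- backsolve(L, y - mu, transpose = TRUE)
  loglik <- -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
  w <- backsolve(L, z)  # Sy^{-1} (y - mu)

  xs <- vs <- matrix(0, n, m)
  fitted <- fitvar <- numeric(n)
  Pcs <- vector("list", n)
  for (k in 1:n) {
    Cxy <- matrix(0, m, n)
    for (j in 1:n) {
      M <- if (j <= k) t(covjk(j, k)) else covjk(k, j)  # Cov(x_k, x_j)
      Cxy[, j] <- M %*% H[j, ]
    }
    xs[k, ] <- x0 + drop(Cxy %*% w)
    Pc <- Pu[[k]] - Cxy %*% solve(Sy, t(Cxy))
    Pcs[[k]] <- Pc
    vs[k, ] <- diag(Pc)
    fitted[k] <- drop(H[k, ] %*% xs[k, ])
    fitvar[k] <- drop(H[k, ] %*% Pc %*% H[k, ])
  }
  list(loglik = loglik, xs = xs, vs = vs, fitted = fitted, fitvar = fitvar,
       Pcs = Pcs, H = H)
}

# Ordinary least-squares harmonic regression oracle (the constant-parameter
# limit of the dynamic model), via stats::lm.
ols_harmonic <- function(times, y, period = 1, n_harm = 2,
                         trend = c("irw", "rw")) {
  trend <- match.arg(trend)
  X <- data.frame(y = y)
  for (i in seq_len(n_harm)) {
    X[[paste0("c", i)]] <- cos(2 * pi * i * times / period)
    X[[paste0("s", i)]] <- sin(2 * pi * i * times / period)
  }
  fo <- if (trend == "irw") {
    X$tt <- times
    stats::as.formula(paste("y ~ tt +", paste(
      c(outer(c("c", "s"), seq_len(n_harm), paste0)), collapse = " + ")))
  } else {
    stats::as.formula(paste("y ~", paste(
      c(outer(c("c", "s"), seq_len(n_harm), paste0)), collapse = " + ")))
  }
  lmfit <- stats::lm(fo, data = X)
  sm <- summary(lmfit)
  list(fitted = unname(stats::fitted(lmfit)),
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic["value"]),
       numdf = unname(sm$fstatistic["numdf"]),
       dendf = unname(sm$fstatistic["dendf"]),
       p = ncol(stats::model.matrix(lmfit)))
}

rel_err <- function(a, b, floor = 1e-12) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# small irregular time grid used across tests
make_times <- function(n, seed, span = 4, start = 2011) {
  set.seed(seed)
  sort(start + runif(n, 0, span))
}
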