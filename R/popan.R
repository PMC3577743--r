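# POPAN (Schwarz-Arnason) parameterization of the Jolly-Seber open-population
# model: superpopulation size N_m, entry proportions pent, survival phi and
# detection p. Fitting is by maximum likelihood on link scales (sin for phi
# and p, multinomial-logit for pent, log for N_m - D), with multi-start
# quasi-Newton optimization and delta-method standard errors.

#' Specify a POPAN model structure
#'
#' Structures mirror the usual mark-recapture notation: `phi(.)p(t)pent(.)N`
#' means constant survival, time-varying detection, constant entry.
#'
#' @param phi,p,pent `"constant"` or `"time"`.
#' @return A `popan_model` with a `label` and a `K(T)` function giving the
#'   parameter count for `T` occasions.
#' @export
popan_model <- function(phi = c("constant", "time"),
                        p = c("constant", "time"),
                        pent = c("constant", "time")) {
  phi <- match.arg(phi); p <- match.arg(p); pent <- match.arg(pent)
  lab <- function(s) if (s == "time") "t" else "."
  structure(list(phi = phi, p = p, pent = pent,
                 label = sprintf("phi(%s)p(%s)pent(%s)N",
                                 lab(phi), lab(p), lab(pent))),
            class = "popan_model")
}

#' Parse POPAN model labels
#'
#' Accepts comma-separated labels such as
#' `"phi(.)p(t)pent(.)N, phi(t)p(t)pent(t)N"`.
#'
#' @param x character scalar or vector of labels.
#' @return List of [popan_model()] objects.
#' @export
parse_popan_models <- function(x) {
  labs <- trimws(unlist(strsplit(x, ",")))
  lapply(labs, function(l) {
    m <- regmatches(l, regexec("phi\\((.)\\)p\\((.)\\)pent\\((.)\\)N?", l))[[1]]
    if (length(m) != 4L) stop("cannot parse model label: ", l)
    conv <- function(s) if (s == "t") "time" else "constant"
    popan_model(conv(m[2]), conv(m[3]), conv(m[4]))
  })
}

popan_K <- function(model, T) {
  (if (model$phi == "time") T - 1L else 1L) +
    (if (model$p == "time") T else 1L) +
    (if (model$pent == "time") T - 1L else 1L) + 1L
}

check_histories <- function(histories) {
  ch <- as.matrix(histories)
  storage.mode(ch) <- "integer"
  if (!all(ch %in% c(0L, 1L))) stop("capture histories must be 0/1")
  if (any(rowSums(ch) < 1L)) stop("every history must have at least one detection")
  if (ncol(ch) < 2L) stop("need at least 2 occasions")
  ch
}

# collapse to unique histories with counts
collapse_histories <- function(ch) {
  key <- apply(ch, 1, paste, collapse = "")
  tab <- table(key)
  uniq <- do.call(rbind, lapply(names(tab), function(k)
    as.integer(strsplit(k, "")[[1]])))
  list(ch = uniq, n = as.vector(tab))
}

#' POPAN log-likelihood
#'
#' Full superpopulation likelihood: the multinomial over observed capture
#' histories plus the binomial term for the `N_m - D` superpopulation
#' members never detected. An individual enters at occasion `b` with
#' probability `pent_b`, survives occasion-to-occasion with probability
#' `phi_t`, and is detected while alive with probability `p_t`.
#'
#' @param histories binary matrix (individuals x occasions) or data frame;
#'   every row must contain a detection.
#' @param phi survival probabilities, length 1 or `T - 1`.
#' @param p detection probabilities, length 1 or `T`.
#' @param pent entry proportions over occasions, length `T`, summing to 1.
#' @param N_m marked superpopulation size (`>= ` number of observed
#'   individuals; `-Inf` is returned below it).
#' @return Scalar log-likelihood.
#' @export
popan_loglik <- function(histories, phi, p, pent, N_m) {
  ch <- check_histories(histories)
  T <- ncol(ch); D <- nrow(ch)
  phi <- rep_len(phi, T - 1L); p <- rep_len(p, T)
  if (length(pent) != T) stop("pent must have one entry proportion per occasion")
  if (abs(sum(pent) - 1) > 1e-8) stop("pent must sum to 1")
  if (any(c(phi, p) < 0 | c(phi, p) > 1) || any(pent < 0)) return(-Inf)
  if (N_m < D) return(-Inf)
  u <- collapse_histories(ch)
  never <- if (N_m > D) (N_m - D) * log(prob_never_detected(phi, p, pent)) else 0
  sum(u$n * log(history_probs(u$ch, phi, p, pent))) +
    lgamma(N_m + 1) - lgamma(N_m - D + 1) - sum(lgamma(u$n + 1)) +
    never
}

# P(omega) for each row of a unique-history matrix, via the psi/chi recursions:
#   psi_t = P(alive and not yet detected just before occasion t's detection)
#   chi_t = P(never detected after occasion t | alive at t)
history_probs <- function(ch, phi, p, pent) {
  T <- ncol(ch)
  psi <- numeric(T)
  psi[1] <- pent[1]
  for (t in seq_len(T - 1L)) psi[t + 1L] <- psi[t] * (1 - p[t]) * phi[t] + pent[t + 1L]
  chi <- numeric(T)
  chi[T] <- 1
  for (t in rev(seq_len(T - 1L)))
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1L]) * chi[t + 1L]
  apply(ch, 1, function(w) {
    f <- which(w == 1L)[1L]; l <- max(which(w == 1L))
    pr <- psi[f]
    for (t in f:l) pr <- pr * (if (w[t] == 1L) p[t] else (1 - p[t]))
    if (l > f) pr <- pr * prod(phi[f:(l - 1L)])
    pr * chi[l]
  })
}

prob_never_detected <- function(phi, p, pent) {
  T <- length(p)
  xi <- numeric(T)
  xi[T] <- 1 - p[T]
  for (t in rev(seq_len(T - 1L)))
    xi[t] <- (1 - p[t]) * ((1 - phi[t]) + phi[t] * xi[t + 1L])
  sum(pent * xi)
}

## ---- link functions ------------------------------------------------------

sin_link <- function(theta) (sin(theta) + 1) / 2         # real -> (0, 1)
sin_link_inv <- function(prob) asin(2 * pmin(pmax(prob, 1e-6), 1 - 1e-6) - 1)

# natural-scale parameters from the link-scale vector for a model structure
popan_unpack <- function(theta, model, T, D) {
  n_phi <- if (model$phi == "time") T - 1L else 1L
  n_p <- if (model$p == "time") T else 1L
  n_pent <- if (model$pent == "time") T - 1L else 1L
  i <- 0L
  phi <- rep_len(sin_link(theta[i + seq_len(n_phi)]), T - 1L); i <- i + n_phi
  p <- rep_len(sin_link(theta[i + seq_len(n_p)]), T); i <- i + n_p
  a <- theta[i + seq_len(n_pent)]; i <- i + n_pent
  w <- if (model$pent == "time") c(1, exp(a)) else c(1, rep(exp(a), T - 1L))
  pent <- w / sum(w)
  N_m <- D + exp(theta[i + 1L])
  list(phi = phi, p = p, pent = pent, N_m = N_m)
}

#' Fit a POPAN model by maximum likelihood
#'
#' Maximizes [popan_loglik()] on link scales (sin for survival and
#' detection, multinomial-logit for entry proportions, log for the
#' never-seen count `N_m - D`) with multi-start BFGS. Standard errors come
#' from the inverse numerical Hessian on the link scale, moved to the
#' natural scale by the delta method; the CI for `N_m` is log-normal on
#' `N_m - D`, mirroring the usual mark-recapture convention.
#'
#' @param histories binary capture-history matrix, every row with `>= 1`
#'   detection.
#' @param model a [popan_model()] (default: constant phi and pent,
#'   time-varying p — the usual choice for photo-id series with varying
#'   effort).
#' @param n_starts number of optimizer starts (first from empirical
#'   heuristics, the rest dispersed).
#' @param seed optional integer seed for the dispersed starts.
#' @return A `popan_fit`: parameter estimates with SEs and CIs, `loglik`,
#'   `K`, `ess` (number of individuals), convergence diagnostics, and
#'   `notes` flagging confounded terminal parameters in the fully
#'   time-dependent model.
#' @export
fit_popan <- function(histories, model = popan_model("constant", "time", "constant"),
                      n_starts = 10L, seed = NULL) {
  ch <- check_histories(histories)
  ch <- ch[do.call(order, as.data.frame(ch)), , drop = FALSE]  # row-order invariance
  T <- ncol(ch); D <- nrow(ch)
  if (T < 3L && (model$phi == "time" || model$pent == "time"))
    stop("time-varying structures need at least 3 occasions")
  if (!is.null(seed)) set.seed(seed)
  u <- collapse_histories(ch)
  negll <- function(theta) {
    par <- popan_unpack(theta, model, T, D)
    pr <- history_probs(u$ch, par$phi, par$p, par$pent)
    p0 <- prob_never_detected(par$phi, par$p, par$pent)
    if (any(pr <= 0) || p0 <= 0 || p0 >= 1) return(1e10)
    ll <- sum(u$n * log(pr)) +
      lgamma(par$N_m + 1) - lgamma(par$N_m - D + 1) - sum(lgamma(u$n + 1)) +
      (par$N_m - D) * log(p0)
    if (!is.finite(ll)) 1e10 else -ll
  }
  n_phi <- if (model$phi == "time") T - 1L else 1L
  n_p <- if (model$p == "time") T else 1L
  n_pent <- if (model$pent == "time") T - 1L else 1L
  K <- n_phi + n_p + n_pent + 1L
  p_emp <- min(max(mean(colSums(ch) / D), 0.05), 0.95)
  base_start <- c(rep(sin_link_inv(0.85), n_phi),
                  rep(sin_link_inv(p_emp), n_p),
                  rep(log(0.05 / 0.75), n_pent),   # modest entry after occ. 1
                  log(max(0.25 * D, 1)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1L) base_start else
      base_start + runif(K, -1, 1) * c(rep(0.5, n_phi + n_p), rep(1, n_pent), 0.7)
    fit <- tryCatch(
      optim(start, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("POPAN optimization failed from every start")
  converged <- best$convergence == 0 && best$value < 1e9
  theta <- best$par
  par <- popan_unpack(theta, model, T, D)

  # delta-method SEs: cov on link scale, Jacobian of the natural parameters
  vcov_link <- tryCatch({
    H <- optimHess(theta, negll)
    solve(H)
  }, error = function(e) matrix(NA_real_, K, K))
  nat <- function(th) {
    pp <- popan_unpack(th, model, T, D)
    c(pp$phi[1:(if (model$phi == "time") T - 1 else 1)][seq_len(n_phi)],
      pp$p[seq_len(n_p)], pp$pent, pp$N_m)
  }
  J <- tryCatch(numeric_jacobian(nat, theta), error = function(e) NULL)
  nat_se <- if (!is.null(J) && all(is.finite(vcov_link)))
    sqrt(pmax(diag(J %*% vcov_link %*% t(J)), 0)) else rep(NA_real_, n_phi + n_p + T + 1L)

  idx_N <- n_phi + n_p + T + 1L
  N_hat <- par$N_m
  se_N <- nat_se[idx_N]
  f0 <- N_hat - D
  ci_N <- if (is.finite(se_N) && f0 > 0) {
    cv0 <- se_N / f0
    C <- exp(1.96 * sqrt(log(1 + cv0^2)))
    c(D + f0 / C, D + f0 * C)
  } else c(NA_real_, NA_real_)

  notes <- character(0)
  if (model$phi == "time" && model$p == "time")
    notes <- c(notes, paste("fully time-dependent structure: terminal phi and p",
                            "are confounded; only their product is identifiable"))
  structure(list(
    model = model, label = model$label,
    phi = par$phi, p = par$p, pent = par$pent, N_m = N_hat,
    se = list(phi = nat_se[seq_len(n_phi)],
              p = nat_se[n_phi + seq_len(n_p)],
              pent = nat_se[n_phi + n_p + seq_len(T)],
              N_m = se_N),
    N_m_ci = ci_N,
    loglik = -best$value, K = K, ess = D, n_occasions = T,
    converged = converged, notes = notes, theta = theta),
    class = "popan_fit")
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    J[, k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

#' @export
print.popan_fit <- function(x, ...) {
  cat(sprintf("POPAN fit %s: loglik = %.3f, K = %d, N_m = %.1f (95%% CI %.1f-%.1f)\n",
              x$label, x$loglik, x$K, x$N_m, x$N_m_ci[1], x$N_m_ci[2]))
  cat(sprintf("  phi = %s;  p = %s;  pent = %s\n",
              paste(sprintf("%.3f", unique(x$phi)), collapse = ", "),
              paste(sprintf("%.3f", x$p), collapse = ", "),
              paste(sprintf("%.3f", x$pent), collapse = ", ")))
  if (length(x$notes)) cat("  note:", x$notes, sep = "\n  ")
  invisible(x)
}

#' Quasi-likelihood AICc
#'
#' `QAICc = -2 loglik / chat + 2K + 2K(K + 1)/(ess - K - 1)`; reduces to
#' AICc at `chat = 1`. Models are ranked by ascending QAICc.
#'
#' @param loglik maximized log-likelihood.
#' @param K parameter count (including the overdispersion parameter's cost
#'   is left to the caller, as in standard usage).
#' @param chat variance-inflation factor, `>= 1`.
#' @param ess effective sample size (number of individuals by default
#'   elsewhere in the package).
#' @return Scalar QAICc.
#' @export
qaicc <- function(loglik, K, chat = 1, ess) {
  if (chat < 1) stop("chat must be >= 1")
  if (ess <= K + 1) stop("effective sample size must exceed K + 1")
  -2 * loglik / chat + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

#' Overdispersion factor by parametric bootstrap
#'
#' Simulates capture histories from the fitted model, refits, and returns
#' `chat = observed deviance / mean simulated deviance`, floored at 1. The
#' deviance is against the saturated multinomial over observed histories.
#'
#' @param histories the observed capture-history matrix.
#' @param fit a converged [fit_popan()] result.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @return `chat` (scalar, `>= 1`) with attribute `boot_deviances`.
#' @export
estimate_chat <- function(histories, fit, n_boot = 100L, seed = NULL) {
  ch <- check_histories(histories)
  if (!fit$converged) stop("chat requires a converged global fit")
  if (!is.null(seed)) set.seed(seed)
  dev_obs <- popan_deviance(ch, fit)
  T <- ncol(ch)
  devs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- simulate_popan_histories(round(fit$N_m), fit$phi, fit$p, fit$pent)
    if (nrow(sim) < 5L) next
    refit <- tryCatch(fit_popan(sim, fit$model, n_starts = 3L),
                      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) next
    devs[b] <- popan_deviance(sim, refit)
  }
  ok <- is.finite(devs)
  if (mean(ok) < 0.8) stop("more than 20% of bootstrap refits failed")
  chat <- max(1, dev_obs / mean(devs[ok]))
  attr(chat, "boot_deviances") <- devs[ok]
  chat
}

# deviance vs the saturated model (empirical multinomial over observed
# histories with N = D, so the never-seen term vanishes)
popan_deviance <- function(ch, fit) {
  u <- collapse_histories(ch)
  D <- nrow(ch)
  ll_fit <- popan_loglik(ch, fit$phi, fit$p, fit$pent, fit$N_m)
  ll_sat <- sum(u$n * log(u$n / D)) +
    lgamma(D + 1) - sum(lgamma(u$n + 1))
  -2 * (ll_fit - ll_sat)
}

# forward simulation used by estimate_chat and the synthetic-data module
simulate_popan_histories <- function(N, phi, p, pent) {
  T <- length(pent)
  p <- rep_len(p, T)
  phi <- rep_len(phi, T - 1L)
  entry <- sample.int(T, N, replace = TRUE, prob = pent)
  ch <- matrix(0L, N, T)
  alive <- matrix(FALSE, N, T)
  for (t in seq_len(T)) {
    newly <- entry == t
    alive[, t] <- newly | (if (t > 1L) alive[, t - 1L] & (runif(N) < phi[t - 1L]) else FALSE)
    ch[, t] <- as.integer(alive[, t] & (runif(N) < p[t]))
  }
  ch[rowSums(ch) > 0L, , drop = FALSE]
}

#' Rank a set of POPAN models by QAICc
#'
#' @param histories capture-history matrix.
#' @param models list of [popan_model()] objects (or a label string for
#'   [parse_popan_models()]).
#' @param chat overdispersion factor: a number, or `"auto"` to estimate it
#'   from the most general model in the set via [estimate_chat()].
#' @param n_boot bootstrap replicates when `chat = "auto"`.
#' @param seed optional integer seed.
#' @return A `popan_model_set`: list with `table` (label, QAICc, K, loglik,
#'   N_m, SE, CI, converged; sorted by QAICc), `fits`, `chat`.
#' @export
rank_popan_models <- function(histories, models, chat = 1, n_boot = 100L,
                              seed = NULL) {
  if (is.character(models) && !is.list(models)) models <- parse_popan_models(models)
  ch <- check_histories(histories)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(models, function(m)
    fit_popan(ch, m, seed = if (is.null(seed)) NULL else sample.int(2^31 - 1, 1)))
  if (identical(chat, "auto")) {
    Ks <- vapply(fits, `[[`, numeric(1), "K")
    glob <- fits[[which.max(Ks)]]
    chat <- as.numeric(estimate_chat(ch, glob, n_boot = n_boot,
                                     seed = if (is.null(seed)) NULL else sample.int(2^31 - 1, 1)))
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$label,
               qaicc = qaicc(f$loglik, f$K, chat, f$ess),
               K = f$K, loglik = f$loglik,
               N_m = f$N_m, se_N_m = f$se$N_m,
               N_m_lo = f$N_m_ci[1], N_m_hi = f$N_m_ci[2],
               converged = f$converged)
  }))
  ord <- order(tab$qaicc)
  structure(list(table = tab[ord, ], fits = fits[ord], chat = chat),
            class = "popan_model_set")
}

#' Total abundance from a marked-population estimate and the mark ratio
#'
#' `N = N_m / theta`, with the mark-ratio variance
#' `Var(N) = N^2 (Var(N_m)/N_m^2 + (1 - theta)/(n theta))`, where `n` is
#' the number of animals from which `theta` was estimated. The CI is
#' log-normal.
#'
#' @param N_m marked population estimate.
#' @param se_N_m its standard error.
#' @param theta proportion of marked individuals, in (0, 1].
#' @param n number of animals from which `theta` was estimated.
#' @return An `abundance_estimate`: list with `N` (unrounded), `N_rounded`,
#'   `se`, `cv`, `ci`, `theta`, `n`.
#' @export
total_abundance <- function(N_m, se_N_m, theta, n) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  if (n < 1) stop("n must be >= 1")
  N <- N_m / theta
  v <- N^2 * (se_N_m^2 / N_m^2 + (1 - theta) / (n * theta))
  se <- sqrt(v)
  cv <- se / N
  C <- exp(1.96 * sqrt(log(1 + cv^2)))
  structure(list(N = N, N_rounded = round(N), se = se, cv = cv,
                 ci = c(N / C, N * C), theta = theta, n = n),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Total abundance: N = %d (%.2f), SE = %.2f, CV = %.3f, 95%% CI %.0f-%.0f (theta = %.2f, n = %d)\n",
              x$N_rounded, x$N, x$se, x$cv, x$ci[1], x$ci[2], x$theta, x$n))
  invisible(x)
}
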