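#' @name disprop
#' @title Disproportionality statistics: ROR and MGPS EBGM
#' @description
#' Two complementary signal statistics over drug-event report counts.
#'
#' **Reporting odds ratio.** From the 2x2 table, `ROR = (a*d)/(b*c)` with the
#' Woolf log-variance `se = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `CI = exp(log(ROR) +/- z * se)`. The interval is symmetric on the log
#' scale, so `sqrt(ci_low * ci_high)` recovers the point estimate. A zero in
#' any cell makes the estimate undefined; the result is flagged invalid
#' rather than continuity-corrected, because the positivity rule below
#' already requires at least `min_count` co-reports.
#'
#' **MGPS / EBGM.** DuMouchel's Multi-item Gamma Poisson Shrinker models the
#' observed count of a drug-event cell as `N ~ Poisson(lambda * E)` with a
#' two-component gamma prior on the relative reporting rate,
#' `lambda ~ P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2)`
#' (shape/rate). Marginally `N` is a mixture of negative binomials; the five
#' hyperparameters are estimated by maximizing the marginal likelihood over
#' all cells. The posterior for a cell is again a two-component gamma mixture
#' with updated parameters `(alpha_j + N, beta_j + E)` and weight `Q`; EBGM is
#' the posterior geometric mean `exp(E[log lambda])` (digamma closed form) and
#' EBGM05/EBGM95 are the posterior 5th/95th percentiles found by bracketed
#' root finding on the mixture CDF.
#'
#' **Positivity.** A cell is ROR-positive when `a >= 3` and the 95% CI lower
#' bound exceeds 1; EBGM-positive when EBGM05 exceeds 2. Both flags are
#' reported side by side.
NULL

#' Reporting odds ratio with Woolf confidence interval
#'
#' Vectorized over cells. Any zero cell yields `valid = FALSE` with `NA`
#' estimates (no continuity correction unless `haldane = TRUE`, which adds
#' 0.5 to every cell of invalid tables).
#'
#' @param a,b,c,d non-negative cell counts, or a `contingency_table` passed
#'   as `a`.
#' @param conf_level confidence level (default 0.95).
#' @param haldane apply the 0.5 continuity correction to zero-cell tables.
#' @return tibble with columns `a`, `ror`, `ci_low`, `ci_high`, `log_se`,
#'   `valid`.
#' @export
#' @examples
#' ror(5, 95, 100, 9900)
ror <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95,
                haldane = FALSE) {
  if (inherits(a, "contingency_table")) {
    tb <- a
    a <- tb$a; b <- tb$b; c <- tb$c; d <- tb$d
  }
  counts <- cbind(a, b, c, d)
  if (any(counts < 0)) stop("negative cell count", call. = FALSE)
  valid <- rowSums(counts == 0) == 0
  aa <- a; bb <- b; cc <- c; dd <- d
  if (haldane) {
    adj <- !valid
    aa <- a + 0.5 * adj; bb <- b + 0.5 * adj
    cc <- c + 0.5 * adj; dd <- d + 0.5 * adj
    use <- rep(TRUE, length(a))
  } else {
    use <- valid
  }
  z <- stats::qnorm((1 + conf_level) / 2)
  est <- log_se <- lo <- hi <- rep(NA_real_, length(a))
  est[use] <- (aa[use] * dd[use]) / (bb[use] * cc[use])
  log_se[use] <- sqrt(1 / aa[use] + 1 / bb[use] + 1 / cc[use] + 1 / dd[use])
  lo[use] <- exp(log(est[use]) - z * log_se[use])
  hi[use] <- exp(log(est[use]) + z * log_se[use])
  tibble::tibble(a = as.numeric(a), ror = est, ci_low = lo, ci_high = hi,
                 log_se = log_se, valid = valid)
}

# marginal log-likelihood of the negative-binomial mixture at one theta
# theta = c(alpha1, beta1, alpha2, beta2, P); N, E vectors; w multiplicity
nbmix_loglik <- function(theta, N, E, w = NULL) {
  a1 <- theta[1]; b1 <- theta[2]; a2 <- theta[3]; b2 <- theta[4]; P <- theta[5]
  l1 <- stats::dnbinom(N, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(N, size = a2, prob = b2 / (b2 + E), log = TRUE)
  ll <- logsumexp2(log(P) + l1, log1p(-P) + l2)
  if (is.null(w)) sum(ll) else sum(w * ll)
}

#' Fit the MGPS gamma-mixture hyperprior by marginal maximum likelihood
#'
#' Maximizes the negative-binomial mixture likelihood over
#' `theta = (alpha1, beta1, alpha2, beta2, P)` with L-BFGS-B on
#' log-transformed (logit for `P`) parameters. Multi-start: DuMouchel's
#' classic initialization `(0.2, 0.1, 2, 4, 1/3)` plus deterministically
#' jittered variants, because the mixture likelihood is multimodal. With
#' `squash = TRUE`, identical `(N, binned E)` cells are aggregated with
#' multiplicity weights before optimization (same likelihood, fewer terms).
#'
#' @param N,E observed and expected counts per cell (equal-length vectors,
#'   all `E > 0`), or a `cell_counts` tibble passed as `N`.
#' @param starts number of optimizer starts (>= 1; first is the classic
#'   initialization).
#' @param squash aggregate duplicated cells before optimizing.
#' @param control passed to [stats::optim()] (factr/pgtol already tightened).
#' @return an `ebgm_prior`: list with `alpha1`, `beta1`, `alpha2`, `beta2`,
#'   `P`, `loglik`, `converged`, `n_cells`.
#' @export
fit_mgps_prior <- function(N, E = NULL, starts = 5, squash = FALSE,
                           control = list()) {
  if (is.data.frame(N)) {
    E <- N$E
    N <- N$N
  }
  if (length(N) != length(E)) stop("N and E lengths differ", call. = FALSE)
  if (any(E <= 0)) stop("all expected counts must be positive", call. = FALSE)

  w <- NULL
  if (squash) {
    key <- paste(N, signif(E, 3))
    agg <- tapply(seq_along(N), key, identity)
    idx <- vapply(agg, `[`, integer(1), 1L)
    w <- vapply(agg, length, integer(1))
    N <- N[idx]
    E <- vapply(agg, function(i) mean(.subset(E, i)), numeric(1))
  }

  to_theta <- function(p) c(exp(p[1:4]), stats::plogis(p[5]))
  negll <- function(p) {
    th <- to_theta(p)
    if (any(!is.finite(th))) return(1e12)
    val <- -nbmix_loglik(th, N, E, w)
    if (!is.finite(val)) 1e12 else val
  }

  classic <- c(0.2, 0.1, 2.0, 4.0, 1 / 3)
  jitter_factors <- list(
    c(1, 1, 1, 1, 1),
    c(2, 2, 0.5, 0.5, 1.5),
    c(0.5, 0.5, 2, 2, 0.6),
    c(3, 1, 1, 3, 1),
    c(1, 3, 3, 1, 0.8)
  )
  starts <- max(1L, as.integer(starts))
  inits <- lapply(seq_len(starts), function(i) {
    f <- jitter_factors[[(i - 1L) %% length(jitter_factors) + 1L]]
    th <- classic * f
    th[5] <- min(max(th[5], 0.02), 0.98)
    c(log(th[1:4]), stats::qlogis(th[5]))
  })

  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  best <- NULL
  any_conv <- FALSE
  for (p0 in inits) {
    fit <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B",
                   lower = rep(c(-12, -20), c(4, 1)),
                   upper = rep(c(12, 20), c(4, 1)),
                   control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # degenerate input (e.g. a single cell): report a diffuse prior, flagged
    th <- classic
    ll <- nbmix_loglik(th, N, E, w)
    any_conv <- FALSE
  } else {
    th <- to_theta(best$par)
    ll <- -best$value
  }
  structure(list(alpha1 = th[1], beta1 = th[2], alpha2 = th[3], beta2 = th[4],
                 P = th[5], loglik = ll,
                 converged = any_conv && length(N) > 1,
                 n_cells = length(N)),
            class = "ebgm_prior")
}

#' @export
print.ebgm_prior <- function(x, ...) {
  cat(sprintf(paste0("<ebgm_prior> alpha1=%.4g beta1=%.4g alpha2=%.4g ",
                     "beta2=%.4g P=%.4g\n  loglik=%.4f over %d cells",
                     " (converged: %s)\n"),
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$P, x$loglik,
              x$n_cells, x$converged))
  invisible(x)
}

check_prior <- function(prior) {
  ok <- inherits(prior, "ebgm_prior") &&
    all(vapply(prior[c("alpha1", "beta1", "alpha2", "beta2")],
               function(v) is.finite(v) && v > 0, logical(1))) &&
    prior$P > 0 && prior$P < 1
  if (!ok) stop("invalid EBGM prior", call. = FALSE)
  invisible(prior)
}

# posterior mixture weight Q for each cell, in a numerically safe way
posterior_q <- function(N, E, prior) {
  l1 <- log(prior$P) +
    stats::dnbinom(N, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E),
                   log = TRUE)
  l2 <- log1p(-prior$P) +
    stats::dnbinom(N, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E),
                   log = TRUE)
  exp(l1 - logsumexp2(l1, l2))
}

# p-quantile of Q*Gamma(s1, r1) + (1-Q)*Gamma(s2, r2). The root is bracketed
# by the component quantiles and found on the log scale, because with a tiny
# posterior shape the quantile can be many orders of magnitude below 1 and an
# absolute x tolerance would lose all relative precision there.
mixture_gamma_quantile <- function(p, Q, s1, r1, s2, r2, tol = 1e-10) {
  q1 <- stats::qgamma(p, shape = s1, rate = r1)
  q2 <- stats::qgamma(p, shape = s2, rate = r2)
  if (Q >= 1 - 1e-12) return(q1)
  if (Q <= 1e-12) return(q2)
  lo <- max(min(q1, q2), 1e-300)
  hi <- max(q1, q2)
  if (hi - lo <= .Machine$double.eps * hi) return(hi)
  g <- function(t) {
    x <- exp(t)
    Q * stats::pgamma(x, shape = s1, rate = r1) +
      (1 - Q) * stats::pgamma(x, shape = s2, rate = r2) - p
  }
  exp(stats::uniroot(g, lower = log(lo), upper = log(hi), extendInt = "upX",
                     tol = tol)$root)
}

#' Posterior EBGM summaries for drug-event cells
#'
#' Given the fitted hyperprior, the posterior relative reporting rate of a
#' cell is `Q * Gamma(alpha1 + N, beta1 + E) + (1 - Q) * Gamma(alpha2 + N,
#' beta2 + E)`. EBGM is the posterior geometric mean,
#' `exp(Q * (digamma(alpha1 + N) - log(beta1 + E)) + (1 - Q) * (...))`;
#' EBGM05/EBGM95 solve the mixture CDF at 0.05/0.95 by bracketed root
#' finding.
#'
#' @param N,E observed/expected counts (vectors; `E > 0`, `N >= 0`), or a
#'   `cell_counts` tibble passed as `N`.
#' @param prior an `ebgm_prior` from [fit_mgps_prior()].
#' @return tibble with columns `N`, `E`, `Q`, `ebgm`, `ebgm05`, `ebgm95`.
#' @export
ebgm_cell <- function(N, E = NULL, prior) {
  if (is.data.frame(N)) {
    E <- N$E
    N <- N$N
  }
  check_prior(prior)
  if (any(E <= 0) || any(N < 0)) {
    stop("ebgm_cell requires E > 0 and N >= 0", call. = FALSE)
  }
  Q <- posterior_q(N, E, prior)
  s1 <- prior$alpha1 + N; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + N; r2 <- prior$beta2 + E
  ebgm <- exp(Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2)))
  q05 <- q95 <- numeric(length(N))
  for (i in seq_along(N)) {
    q05[i] <- mixture_gamma_quantile(0.05, Q[i], s1[i], r1[i], s2[i], r2[i])
    q95[i] <- mixture_gamma_quantile(0.95, Q[i], s1[i], r1[i], s2[i], r2[i])
  }
  tibble::tibble(N = N, E = E, Q = Q, ebgm = ebgm, ebgm05 = q05, ebgm95 = q95)
}

#' Classify signals with the dual ROR / EBGM positivity criteria
#'
#' `ror_positive` requires at least `min_count` co-reports (strictly more
#' when `strict = TRUE`) and a 95% CI lower bound above 1; `ebgm_positive`
#' requires EBGM05 above `ebgm05_threshold`. The two flags are independent
#' and both are reported.
#'
#' @param a report counts.
#' @param ror_result tibble from [ror()] (same length).
#' @param ebgm_result tibble from [ebgm_cell()] (same length), or `NULL`
#'   when only ROR is assessed.
#' @param min_count minimum co-report count for ROR positivity (default 3).
#' @param strict require `a > min_count` instead of `a >= min_count`.
#' @param ebgm05_threshold EBGM05 cutoff (default 2).
#' @return tibble with logical columns `ror_positive`, `ebgm_positive`.
#' @export
classify_signals <- function(a, ror_result, ebgm_result = NULL,
                             min_count = 3, strict = FALSE,
                             ebgm05_threshold = 2) {
  count_ok <- if (strict) a > min_count else a >= min_count
  ror_pos <- count_ok & !is.na(ror_result$ci_low) & ror_result$ci_low > 1
  ebgm_pos <- if (is.null(ebgm_result)) {
    rep(NA, length(a))
  } else {
    !is.na(ebgm_result$ebgm05) & ebgm_result$ebgm05 > ebgm05_threshold
  }
  tibble::tibble(ror_positive = ror_pos, ebgm_positive = ebgm_pos)
}
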