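# Shared fixtures built in code. Reused across test files; everything is
# seeded so reruns are identical.

# a small hand-written faers_data object with known structure
make_mini_faers <- function() {
  demo <- tibble::tibble(
    primaryid = c("1001", "1002", "1003", "1004"),
    caseid = c("C1", "C2", "C3", "C4"),
    caseversion = 1L,
    fda_dt = c("20190101", "20190201", "20190301", "20190401"),
    sex = c("F", "M", NA, "F"),
    age = c(70, 45, NA, 88),
    age_cod = c("YR", "YR", NA, "YR"),
    occp_cod = c("MD", "CN", NA, "PH")
  )
  drug <- tibble::tibble(
    primaryid = c("1001", "1002", "1002", "1003", "1004"),
    drug_seq = c(1L, 1L, 2L, 1L, 1L),
    role_cod = c("PS", "PS", "SS", "PS", "PS"),
    drugname = c("LIPITOR", "AGENT001", "ZOCOR", "ZOCOR", "AGENT002"),
    prod_ai = c("ATORVASTATIN", "AGENT001", "SIMVASTATIN", "SIMVASTATIN",
                "AGENT002")
  )
  reac <- tibble::tibble(
    primaryid = c("1001", "1001", "1002", "1003", "1004"),
    pt = c("HEPATITIS", "NAUSEA", "HEADACHE", "CHOLESTASIS", "HEPATITIS")
  )
  outc <- tibble::tibble(
    primaryid = c("1001", "1003", "1004"),
    outc_cod = c("DE", "HO", "OT")
  )
  assemble_cases(demo, drug, reac, outc)
}

# default small simulation used by several files (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cases = 1500, duplicate_rate = 0.1, seed = 101)
      cache <<- simulate_faers(cfg)
    }
    cache
  }
})

# quadrature oracle for the EBGM posterior: integrates the unnormalized
# posterior density prior(lambda) * Poisson(N | lambda * E) directly, so it
# never touches the package's negative-binomial / digamma / root-finding code
quad_posterior <- function(N, E, prior, what = c("log_mean", "cdf"), q = NULL) {
  what <- match.arg(what)
  # work on t = log(lambda): the transformed density is smooth and decays
  # exponentially in both tails even when a gamma shape is below 1
  lse <- function(a, b) {
    m <- pmax(a, b)
    out <- m + log(exp(a - m) + exp(b - m))
    out[is.infinite(m) & m < 0] <- -Inf
    out
  }
  log_g <- function(t) {
    l <- exp(t)
    lp <- lse(log(prior$P) + dgamma(l, prior$alpha1, rate = prior$beta1,
                                    log = TRUE),
              log1p(-prior$P) + dgamma(l, prior$alpha2, rate = prior$beta2,
                                       log = TRUE))
    lp + dpois(N, l * E, log = TRUE) + t   # + t is the Jacobian
  }
  cand <- log(c((N + 0.5) / E, 1, prior$alpha1 / prior$beta1,
                prior$alpha2 / prior$beta2))
  M <- max(log_g(cand), na.rm = TRUE)
  g <- function(t) {
    v <- exp(log_g(t) - M)
    v[!is.finite(v)] <- 0
    v
  }
  Z <- integrate(g, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  if (what == "log_mean") {
    num <- integrate(function(t) t * g(t), -Inf, Inf,
                     rel.tol = 1e-10, abs.tol = 0)$value
    num / Z
  } else {
    integrate(g, -Inf, log(q), rel.tol = 1e-10, abs.tol = 0)$value / Z
  }
}

# oracle posterior quantile: root-find on the quadrature CDF (log-q scale);
# the posterior component quantiles only seed the search bracket
quad_quantile <- function(N, E, prior, p = 0.05) {
  q1 <- qgamma(p, shape = prior$alpha1 + N, rate = prior$beta1 + E)
  q2 <- qgamma(p, shape = prior$alpha2 + N, rate = prior$beta2 + E)
  lo <- log(max(min(q1, q2), 1e-300)) - 1
  hi <- log(max(q1, q2)) + 1
  f <- function(t) quad_posterior(N, E, prior, "cdf", q = exp(t)) - p
  exp(uniroot(f, lower = lo, upper = hi, extendInt = "upX",
              tol = 1e-9)$root)
}
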