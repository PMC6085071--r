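#' Log-likelihood of a per-individual prevalence given pooled assays
#'
#' A pool of `n` individuals tests positive unless every member is
#' uninfected, so `P(positive) = 1 - (1 - p)^n`. With independent pools the
#' log-likelihood is
#' `sum over positive pools of log(1 - (1 - p)^n_i) +
#'  sum over negative pools of n_i * log(1 - p)`.
#' Assay sensitivity and specificity are taken as 1 (a single successful
#' amplification marks a pool positive).
#'
#' @param p Prevalence in `[0, 1]`.
#' @param pool_sizes Integer vector of pool sizes (>= 1).
#' @param positive Logical vector of pool outcomes, same length.
#' @return The log-likelihood; `-Inf` at `p = 0` with a positive pool or at
#'   `p = 1` with a negative pool.
#' @export
pool_log_likelihood <- function(p, pool_sizes, positive) {
  check_survey(pool_sizes, positive)
  stopifnot_prob(p, "p")
  q <- 1 - p
  lp <- 0
  if (any(positive)) {
    pr <- 1 - q^pool_sizes[positive]
    lp <- lp + sum(ifelse(pr > 0, log(pr), -Inf))
  }
  if (any(!positive)) {
    lp <- lp + if (q > 0) sum(pool_sizes[!positive]) * log(q) else -Inf
  }
  lp
}

check_survey <- function(pool_sizes, positive) {
  if (length(pool_sizes) == 0L) {
    stop("survey must contain at least one pool", call. = FALSE)
  }
  if (length(pool_sizes) != length(positive)) {
    stop("`pool_sizes` and `positive` must have equal length", call. = FALSE)
  }
  if (any(pool_sizes < 1 | pool_sizes != floor(pool_sizes))) {
    stop("pool sizes must be integers >= 1", call. = FALSE)
  }
}

#' Maximum-likelihood prevalence from a pooled survey
#'
#' Maximises [pool_log_likelihood()] over `[0, 1]` and reports the
#' 2-log-likelihood support interval, the set of `p` whose log-likelihood is
#' within 2 natural-log units of the maximum (asymptotically close to a 95%
#' confidence interval). All-negative surveys give `p_hat = 0` (lower bound
#' 0); all-positive surveys give `p_hat = 1` (upper bound 1). Interval
#' endpoints are found by bisection to 1e-9.
#'
#' @param survey A tibble/data frame with columns `pool_size` and `positive`
#'   (logical or 0/1).
#' @return An object of class `prevalence_fit` with elements `p_hat`,
#'   `lower`, `upper`, `loglik_max`, `n_pools`, `n_individuals`, `survey`.
#'   Use [tidy()] / [glance()] to extract tibbles.
#' @export
estimate_prevalence <- function(survey) {
  ps <- survey$pool_size
  y <- as.logical(survey$positive)
  check_survey(ps, y)
  ll <- function(p) pool_log_likelihood(p, ps, y)
  if (!any(y)) {
    p_hat <- 0
  } else if (all(y)) {
    p_hat <- 1
  } else {
    opt <- stats::optimize(Vectorize(ll), c(0, 1), maximum = TRUE,
                           tol = 1e-9)
    p_hat <- opt$maximum
  }
  llmax <- ll(p_hat)
  thr <- llmax - 2
  bisect <- function(lo, hi, increasing) {
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      above <- ll(mid) >= thr
      if (above == increasing) hi <- mid else lo <- mid
      if (hi - lo < 1e-9) break
    }
    (lo + hi) / 2
  }
  lower <- if (!any(y)) 0 else bisect(0, p_hat, increasing = TRUE)
  upper <- if (all(y)) 1 else bisect(p_hat, 1, increasing = FALSE)
  structure(
    list(p_hat = p_hat, lower = max(0, lower), upper = min(1, upper),
         loglik_max = llmax, n_pools = length(ps),
         n_individuals = sum(ps),
         survey = tibble::tibble(pool_size = ps, positive = y)),
    class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat(sprintf(
    "Pooled prevalence MLE: %.4f (2-LL interval %.4f-%.4f)\n",
    x$p_hat, x$lower, x$upper))
  cat(sprintf("  %d pools, %d individuals, %d positive\n", x$n_pools,
              x$n_individuals, sum(x$survey$positive)))
  invisible(x)
}

#' @rdname estimate_prevalence
#' @param x A `prevalence_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.prevalence_fit <- function(x, ...) {
  tibble::tibble(term = "prevalence", estimate = x$p_hat,
                 lower = x$lower, upper = x$upper)
}

#' @rdname estimate_prevalence
#' @exportS3Method generics::glance
glance.prevalence_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik_max, n_pools = x$n_pools,
                 n_individuals = x$n_individuals,
                 n_positive = sum(x$survey$positive))
}

#' Prevalence at which a survey design looks ubiquitous
#'
#' The minimal prevalence `p` at which every pool of the design tests
#' positive with probability at least `alpha`, i.e. the smallest `p` with
#' `prod(1 - (1 - p)^n_i) >= alpha`. Above this prevalence a virus is
#' indistinguishable from fixed/ubiquitous with probability `alpha`. The
#' product is strictly increasing in `p`, so the root is found by bisection.
#'
#' @param pool_sizes Integer vector of pool sizes.
#' @param alpha Required probability that all pools are positive.
#' @param tol Bisection tolerance.
#' @return The threshold prevalence.
#' @export
ubiquity_threshold <- function(pool_sizes, alpha = 0.95, tol = 1e-9) {
  if (length(pool_sizes) == 0L) {
    stop("`pool_sizes` must be non-empty", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  all_pos <- function(p) prod(1 - (1 - p)^pool_sizes)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (all_pos(mid) >= alpha) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate a pooled presence/absence survey
#'
#' Each pool is positive independently with probability
#' `1 - (1 - p)^n_i`.
#'
#' @param p True per-individual prevalence.
#' @param pool_sizes Integer vector of pool sizes.
#' @param seed Integer seed.
#' @return A tibble with `pool_size` and `positive`.
#' @export
sim_pool_survey <- function(p, pool_sizes, seed) {
  stopifnot_prob(p, "p")
  withr::with_seed(seed, {
    pos <- stats::runif(length(pool_sizes)) < 1 - (1 - p)^pool_sizes
    tibble::tibble(pool_size = as.integer(pool_sizes), positive = pos)
  })
}
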