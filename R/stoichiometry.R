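#' Binomial probability of detecting k of n subunits
#'
#' `p_k = [n! / k!(n-k)!] p^k (1-p)^(n-k)`: the probability that exactly k
#' of the n subunits of a complex are detected when each is detected
#' independently with probability p.
#'
#' @param n Subunit copy number (integer >= 1).
#' @param k Number detected, `0 <= k <= n` (vectorized).
#' @param p Per-subunit detection probability in `[0, 1]`.
#' @export
binomial_pmf <- function(n, k, p) {
  if (any(k < 0) || any(k > n) || p < 0 || p > 1 || n < 1) {
    stop("binomial_pmf: need 0 <= k <= n and 0 <= p <= 1")
  }
  dbinom(k, n, p)
}

# Observed frequencies prepared for fitting a copy-number-n model: classes
# beyond n (overcounting tail) are pooled into class n; classes beyond the
# largest observed k are implicitly pooled into the top class on the
# expected side.
pool_observed <- function(xk, n) {
  xk <- as.numeric(xk)
  if (length(xk) > n) {
    xk[n] <- sum(xk[n:length(xk)])
    xk <- xk[seq_len(n)]
  }
  xk
}

# Expected class frequencies for classes 1..kmax under (N, p): the top
# class absorbs the tail P(K >= kmax) so frequencies over k >= 1 sum to
# N * (1 - (1-p)^n).
expected_classes <- function(N, n, p, kmax) {
  pk <- dbinom(seq_len(kmax), n, p)
  pk[kmax] <- pk[kmax] + pbinom(kmax, n, p, lower.tail = FALSE)
  N * pk
}

chi2_value <- function(xk, Xk) {
  if (any(Xk <= 0)) return(Inf)
  sum((xk - Xk)^2 / Xk)
}

#' Chi-square goodness of fit between observed and expected frequencies
#'
#' `chi2 = sum_k ((x_k - X_k) / sqrt(X_k))^2`, assuming Poisson errors
#' `sqrt(X_k)` on the expected class counts. A fit is considered
#' consistent with the data when chi2 lies within `F +/- sqrt(2F)` of the
#' degrees of freedom F (the mean +/- SD of a chi-square distribution with
#' F degrees of freedom). Classes with near-zero expectation are pooled
#' with their upper neighbour before summing.
#'
#' @param observed,expected Frequency vectors over the same classes.
#' @param n_fitted_params Number of fitted parameters (2 for a free
#'   `(N, p)` fit, 1 when only N was fitted).
#' @param min_expected Pooling threshold for expected counts.
#' @return list `chi2`, `dof`, `within_band`, `n_classes`, `pooled`.
#' @export
chi_square_gof <- function(observed, expected, n_fitted_params = 2L,
                           min_expected = 1e-6) {
  stopifnot(length(observed) == length(expected))
  xk <- as.numeric(observed)
  Xk <- as.numeric(expected)
  pooled <- FALSE
  i <- 1L
  while (i <= length(Xk)) {
    if (Xk[i] < min_expected && length(Xk) > 1L) {
      j <- if (i < length(Xk)) i + 1L else i - 1L
      Xk[j] <- Xk[j] + Xk[i]
      xk[j] <- xk[j] + xk[i]
      Xk <- Xk[-i]; xk <- xk[-i]
      pooled <- TRUE
    } else i <- i + 1L
  }
  if (any(Xk <= 0)) stop("expected frequencies must be positive after pooling")
  chi2 <- sum((xk - Xk)^2 / Xk)
  dof <- length(Xk) - n_fitted_params
  within <- if (dof > 0) abs(chi2 - dof) <= sqrt(2 * dof) else NA
  list(chi2 = chi2, dof = dof, within_band = within,
       n_classes = length(Xk), pooled = pooled)
}

#' Fit the zero-truncated binomial burst-count model with free (N, p_det)
#'
#' The burst-count histogram of clusters with k >= 1 bursts is fitted by
#' weighted least squares against `X_k = N p_k(n, p_det)`, minimizing the
#' chi-square `sum_k ((x_k - X_k)^2 / X_k)` over the total number of
#' complexes N (including the unseen zero-burst class) and the detection
#' probability p_det. The zero-burst class is never fitted; it is reported
#' as `X_0 = N (1 - p_det)^n` (the missed events). Observed classes beyond
#' n are pooled into class n; expected mass beyond the largest compared
#' class is pooled into it.
#'
#' @param histogram A `burst_histogram` (or plain frequency vector).
#' @param n Candidate subunit copy number.
#' @param p_bounds Plausibility bounds on p_det (see
#'   [plausibility_gate()]).
#' @return Object of class `binomial_fit`: `n`, `p_det`, `N`, `X_k`
#'   (expected frequencies for k = 0..kmax, the zero class first), `chi2`,
#'   `dof`, `within_band`, `accepted`, `reliable`, `observed`.
#' @export
fit_binomial_free <- function(histogram, n, p_bounds = c(0.35, 0.75)) {
  xk_raw <- if (inherits(histogram, "burst_histogram")) histogram$counts
            else as.numeric(histogram)
  xk <- pool_observed(xk_raw, n)
  if (sum(xk > 0) < 2L) {
    stop("need at least two non-zero burst classes to fit (N, p_det)")
  }
  kmax <- length(xk)
  nobs <- sum(xk)
  # profile chi2 over a p grid (N optimized per p), then polish in 2D
  best <- NULL
  for (p in seq(0.02, 0.98, by = 0.02)) {
    oN <- optimize(function(N) chi2_value(xk, expected_classes(N, n, p, kmax)),
                   interval = c(nobs / 2, nobs * 50))
    if (is.null(best) || oN$objective < best$val) {
      best <- list(p = p, N = oN$minimum, val = oN$objective)
    }
  }
  obj <- function(par) {
    chi2_value(xk, expected_classes(exp(par[1L]), n, plogis(par[2L]), kmax))
  }
  fit <- optim(c(log(best$N), qlogis(best$p)), obj)
  fit <- optim(fit$par, obj) # Nelder-Mead restart to polish
  N <- exp(fit$par[1L])
  p <- plogis(fit$par[2L])
  Xk <- expected_classes(N, n, p, kmax)
  gof <- chi_square_gof(xk, Xk, n_fitted_params = 2L)
  reliable <- p > 0.01 && p < 0.99 && is.finite(fit$value)
  out <- structure(list(
    n = as.integer(n), p_det = p, N = N,
    X_k = c(`0` = N * (1 - p)^n, setNames(Xk, seq_len(kmax))),
    chi2 = gof$chi2, dof = gof$dof, within_band = gof$within_band,
    reliable = reliable, observed = setNames(xk, seq_len(kmax)),
    p_bounds = p_bounds
  ), class = "binomial_fit")
  out$accepted <- isTRUE(gof$within_band) && plausibility_gate(out, p_bounds)$accepted
  out
}

#' Compare candidate copy numbers at a fixed detection probability
#'
#' For each candidate copy number n, fits only the total complex number N
#' (p_det held fixed at its calibrated value) and ranks the candidates by
#' the residual chi-square. This is the model-comparison step that decides
#' e.g. between two and three tagged copies per heteromeric complex, or
#' between a trimer and a hexamer.
#'
#' @param histogram A `burst_histogram` (or plain frequency vector).
#' @param p_det The fixed, independently calibrated detection probability.
#' @param candidate_ns Integer vector of candidate copy numbers.
#' @param p_bounds Plausibility bounds (applied to `p_det` itself here).
#' @return Object of class `stoich_comparison`: data.frame `ranking`
#'   (`n`, `N`, `chi2`, `dof`, `within_band`, `accepted`) sorted by
#'   ascending chi2, plus the per-candidate `fits`.
#' @export
fit_binomial_fixed_p <- function(histogram, p_det, candidate_ns,
                                 p_bounds = c(0.35, 0.75)) {
  stopifnot(length(candidate_ns) >= 1L, p_det > 0, p_det <= 1)
  xk_raw <- if (inherits(histogram, "burst_histogram")) histogram$counts
            else as.numeric(histogram)
  fits <- lapply(as.integer(candidate_ns), function(n) {
    xk <- pool_observed(xk_raw, n)
    kmax <- length(xk)
    nobs <- sum(xk)
    oN <- optimize(function(N) chi2_value(xk, expected_classes(N, n, p_det, kmax)),
                   interval = c(nobs / 2, nobs * 50), tol = 1e-8)
    N <- oN$minimum
    Xk <- expected_classes(N, n, p_det, kmax)
    gof <- chi_square_gof(xk, Xk, n_fitted_params = 1L)
    structure(list(
      n = n, p_det = p_det, N = N,
      X_k = c(`0` = N * (1 - p_det)^n, setNames(Xk, seq_len(kmax))),
      chi2 = gof$chi2, dof = gof$dof, within_band = gof$within_band,
      reliable = TRUE, observed = setNames(xk, seq_len(kmax)),
      p_bounds = p_bounds,
      accepted = isTRUE(gof$within_band) &&
        p_det >= p_bounds[1L] && p_det <= p_bounds[2L]
    ), class = "binomial_fit")
  })
  ranking <- data.frame(
    n = vapply(fits, `[[`, integer(1), "n"),
    N = vapply(fits, `[[`, numeric(1), "N"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    dof = vapply(fits, `[[`, numeric(1), "dof"),
    within_band = vapply(fits, function(f) isTRUE(f$within_band), logical(1)),
    accepted = vapply(fits, `[[`, logical(1), "accepted")
  )
  # a candidate whose pooled histogram leaves no residual degrees of freedom
  # (e.g. n = 1 collapses everything into one class) is unidentifiable and
  # cannot win on chi2 alone: rank it after all identifiable candidates
  ranking$identifiable <- ranking$dof >= 1L
  ranking$accepted <- ranking$accepted & ranking$identifiable
  o <- order(!ranking$identifiable, ranking$chi2)
  structure(list(ranking = ranking[o, , drop = FALSE], fits = fits[o]),
            class = "stoich_comparison")
}

#' Plausibility gate on the fitted detection probability
#'
#' A model whose chi-square is acceptable can still be rejected when its
#' fitted p_det is implausible: fitting a hexamer to trimer data halves
#' p_det (6 p' must match 3 p to preserve the mean), pushing it below any
#' calibrated value for the fluorophore. Default bounds bracket typical
#' calibrations of photoconvertible tags (0.42--0.52).
#'
#' @param fit A `binomial_fit`.
#' @param p_bounds Lower/upper plausible p_det.
#' @return list `accepted` (logical), `reason` (character).
#' @export
plausibility_gate <- function(fit, p_bounds = c(0.35, 0.75)) {
  p <- fit$p_det
  if (p < p_bounds[1L]) {
    list(accepted = FALSE,
         reason = sprintf("p_det = %.3f below plausible range [%.2f, %.2f]",
                          p, p_bounds[1L], p_bounds[2L]))
  } else if (p > p_bounds[2L]) {
    list(accepted = FALSE,
         reason = sprintf("p_det = %.3f above plausible range [%.2f, %.2f]",
                          p, p_bounds[1L], p_bounds[2L]))
  } else {
    list(accepted = TRUE, reason = "")
  }
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat(sprintf("<binomial_fit> n = %d: p_det = %.3f, N = %.1f, chi2 = %.2f (dof %d)%s\n",
              x$n, x$p_det, x$N, x$chi2, x$dof,
              if (isTRUE(x$accepted)) ", accepted" else ""))
  invisible(x)
}

#' @export
print.stoich_comparison <- function(x, ...) {
  cat("<stoich_comparison> candidates ranked by residual chi2:\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
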