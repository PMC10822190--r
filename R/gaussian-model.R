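#' Fit a per-gene Gaussian for one stage
#'
#' The stage model of each gene is a single Gaussian: `mu` is the arithmetic
#' mean and `sigma` the sample standard deviation (denominator n - 1) of the
#' gene's expression over the stage's samples. `sigma` is floored at
#' `sigma_floor` so that constant genes stay usable downstream.
#'
#' @param values numeric vector of n >= 3 finite, nonnegative expression
#'   values.
#' @param sigma_floor lower bound on `sigma` (default `1e-8`).
#' @return list with `mu`, `sigma` and `mean_expression` (the upper
#'   integration limit of the truncated probabilities; equal to `mu`).
#' @export
fit_gene_gaussian <- function(values, sigma_floor = 1e-8) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 samples to fit a Gaussian")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be nonnegative")
  mu <- mean(values)
  sigma <- max(stats::sd(values), sigma_floor)
  list(mu = mu, sigma = sigma, mean_expression = mu)
}

#' Normality goodness-of-fit for one gene's stage values
#'
#' Because the Gaussian parameters are estimated from the same sample, a
#' plain Kolmogorov-Smirnov test would be anticonservative; the
#' Lilliefors-corrected KS test is used instead (Shapiro-Wilk for n < 5,
#' where the Lilliefors tables do not apply). A constant vector gets
#' p-value 0 by convention.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return list with `pvalue` and `pass` (`pvalue >= alpha`).
#' @export
goodness_of_fit <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 samples")
  if (stats::sd(values) == 0) {
    return(list(pvalue = 0, pass = FALSE))
  }
  p <- if (length(values) >= 5L) {
    nortest::lillie.test(values)$p.value
  } else {
    stats::shapiro.test(values)$p.value
  }
  list(pvalue = p, pass = p >= alpha)
}

#' Zero-truncated cumulative probability
#'
#' Integral of the fitted Gaussian density from 0 to `x`:
#' `P(x) = Phi((x - mu)/sigma) - Phi(-mu/sigma)`. The lower limit is 0, not
#' -Inf, so the value lies in `[0, 1)` and `P(0) = 0`.
#'
#' @param fit a fit from [fit_gene_gaussian()] (or any list with `mu`,
#'   `sigma`).
#' @param x nonnegative numeric vector of evaluation points.
#' @return probabilities in `[0, 1)`, same length as `x`.
#' @export
truncated_cdf <- function(fit, x) {
  if (any(x < 0)) stop("truncated_cdf is defined for x >= 0 only")
  pmax(stats::pnorm((x - fit$mu) / fit$sigma) -
         stats::pnorm(-fit$mu / fit$sigma), 0)
}

#' Within-stage Pearson correlation of a gene pair
#'
#' Computed on the raw (untransformed) stage sample vectors and clipped to
#' `[-rho_max, rho_max]` to keep the bivariate normal CDF well-conditioned.
#' A constant vector yields 0 (with a warning) rather than an error.
#'
#' @param values_i,values_j equal-length numeric vectors, n >= 3.
#' @param rho_max clip bound (default 0.999).
#' @return the clipped correlation.
#' @export
pair_correlation <- function(values_i, values_j, rho_max = 0.999) {
  if (length(values_i) != length(values_j)) stop("vectors differ in length")
  if (length(values_i) < 3L) stop("need at least 3 samples")
  if (stats::sd(values_i) == 0 || stats::sd(values_j) == 0) {
    warning("constant vector in pair_correlation; returning rho = 0")
    return(0)
  }
  r <- stats::cor(values_i, values_j)
  max(min(r, rho_max), -rho_max)
}

#' Joint truncated probability of a gene pair
#'
#' Probability that a bivariate normal with means `(mu_i, mu_j)`, SDs
#' `(sigma_i, sigma_j)` and correlation `rho` falls in the rectangle
#' `[0, g_i] x [0, g_j]`, where the upper limits are the two stage means.
#' Evaluated with `mvtnorm::pmvnorm`, i.e. the inclusion-exclusion of
#' bivariate normal CDFs.
#'
#' @param fit_i,fit_j fits from [fit_gene_gaussian()] for the two genes in
#'   the same stage.
#' @param rho correlation from [pair_correlation()], `|rho| <= 0.999`.
#' @return probability in `[0, 1]`.
#' @export
joint_probability <- function(fit_i, fit_j, rho) {
  if (abs(rho) > 0.999 + 1e-12) stop("|rho| must be <= 0.999")
  upper <- c(fit_i$mean_expression, fit_j$mean_expression)
  if (any(upper <= 0)) return(0)
  corr <- matrix(c(1, rho, rho, 1), 2L, 2L)
  q <- mvtnorm::pmvnorm(lower = c(0, 0), upper = upper,
                        mean = c(fit_i$mu, fit_j$mu),
                        sigma = corr * tcrossprod(c(fit_i$sigma, fit_j$sigma)))
  q <- as.numeric(q)
  if (q < -1e-12 || q > 1 + 1e-12) {
    stop("bivariate normal integrator returned a value outside [0, 1]")
  }
  min(max(q, 0), 1)
}

# Fit all genes of one stage view; returns a list of per-gene fits plus a
# goodness-of-fit summary. Rows of `view` are genes.
.fit_stage <- function(view, sigma_floor = 1e-8, gof_alpha = 0.05,
                       run_gof = TRUE) {
  genes <- rownames(view)
  fits <- vector("list", length(genes))
  names(fits) <- genes
  gof_p <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    v <- view[i, ]
    f <- fit_gene_gaussian(v, sigma_floor = sigma_floor)
    if (run_gof) {
      g <- goodness_of_fit(v, alpha = gof_alpha)
      f$gof_pvalue <- g$pvalue
      f$gof_pass <- g$pass
      gof_p[i] <- g$pvalue
    }
    fits[[i]] <- f
  }
  attr(fits, "gof_failures") <- if (run_gof) sum(gof_p < gof_alpha) else NA_integer_
  fits
}
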