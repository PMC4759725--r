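#' Mixture-component variances under the Pareto principle
#'
#' For the two-component normal mixture prior on marker effects, a fraction
#' `pi` of markers (the "large" component) carries a fraction `1 - pi` of
#' the genetic variance, and vice versa:
#' `sigma1^2 = (1 - pi) Vg / (pi Nm)` and
#' `sigma2^2 = pi Vg / ((1 - pi) Nm)`,
#' which satisfy `Nm (pi sigma1^2 + (1 - pi) sigma2^2) = Vg`.
#'
#' @param pi Prior probability of the large-variance component, in (0, 1).
#' @param var_g Total genetic variance.
#' @param n_markers Number of markers `Nm`.
#' @return List with `sigma1_2` and `sigma2_2`.
#' @export
#' @examples
#' mixp_variances(0.01, 1, 4600)
mixp_variances <- function(pi, var_g, n_markers) {
  if (!is.finite(pi) || pi <= 0 || pi >= 1)
    stop("pi must lie in (0, 1)", call. = FALSE)
  stopifnot(var_g > 0, n_markers >= 1)
  list(sigma1_2 = (1 - pi) * var_g / (pi * n_markers),
       sigma2_2 = pi * var_g / ((1 - pi) * n_markers))
}

new_fit_result <- function(method, mu, b, w = NULL, iterations = 1L,
                           delta = 0, converged = TRUE) {
  structure(list(method = method, mu = mu, b = b, w = w,
                 iterations = iterations, delta = delta,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): %d markers, mu = %.4f, %d iteration(s)%s\n",
              x$method, length(x$b), x$mu, x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' SNP-BLUP (ridge regression) marker-effect estimation
#'
#' Fits `y = mu + X b + e` with a common normal prior `b_j ~ N(0,
#' sigma_b^2)`, i.e. ridge regression with penalty `lambda = sigma_e^2 /
#' sigma_b^2` and an unpenalized mean.  Solved exactly through the dual
#' (n x n) system when markers outnumber records, and through the primal
#' normal equations otherwise.
#'
#' @param y Phenotypes (length n).
#' @param X Standardized genotype matrix (n x markers).
#' @param sigma_b2 Prior variance per marker effect, typically
#'   `var_g / n_markers`.
#' @param sigma_e2 Environmental (residual) variance.
#' @return A `fit_result` with fields `mu` and `b`.
#' @export
fit_snp_blup <- function(y, X, sigma_b2, sigma_e2) {
  stopifnot(length(y) == nrow(X), sigma_b2 > 0, sigma_e2 > 0)
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("non-finite values in y or X", call. = FALSE)
  lambda <- sigma_e2 / sigma_b2
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  yc <- y - mean(y)
  n <- nrow(X); m <- ncol(X)
  if (n <= m) {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    b <- drop(crossprod(Xc, solve(K, yc)))
  } else {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    b <- drop(solve(A, crossprod(Xc, yc)))
  }
  new_fit_result("snp_blup", mu = mean(y) - sum(xm * b), b = b)
}

#' MixP marker-effect estimation by iterative conditional expectation
#'
#' Fits `y = mu + X b + e` where each marker effect follows a two-component
#' normal mixture, `b_j ~ pi N(0, sigma1^2) + (1 - pi) N(0, sigma2^2)`.
#' The ICE algorithm sweeps markers in fixed position order; for each
#' marker it computes the conditional posterior mean of the effect under
#' each mixture component, weights them by the posterior component
#' probability, and sets the effect to that expectation (no sampling).
#' The residual is updated incrementally, so one sweep costs O(n x m).
#' Sweeps stop when the largest effect change falls below
#' `tol_rel * sd(y)` or after `max_iter` sweeps (the result is then flagged
#' unconverged, with a warning).
#'
#' @inheritParams fit_snp_blup
#' @param pi Prior probability of the large-variance component.
#' @param sigma1_2,sigma2_2 Component variances, e.g. from
#'   [mixp_variances()].
#' @param max_iter Maximum number of sweeps (default 1000).
#' @param tol_rel Convergence tolerance relative to `sd(y)` (default 1e-8).
#' @return A `fit_result` with fields `mu`, `b`, the posterior large-
#'   component probabilities `w`, `iterations` and `converged`.
#' @export
fit_mixp_ice <- function(y, X, pi, sigma1_2, sigma2_2, sigma_e2,
                         max_iter = 1000L, tol_rel = 1e-8) {
  stopifnot(length(y) == nrow(X))
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop("non-finite values in y or X", call. = FALSE)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) {
    # zero-variance response: nothing to fit
    return(new_fit_result("mixp", mu = mean(y), b = numeric(ncol(X)),
                          w = rep(pi, ncol(X))))
  }
  res <- cpp_mixp_ice(X, y, pi, sigma1_2, sigma2_2, sigma_e2,
                      as.integer(max_iter), tol_rel * sdy)
  if (!res$converged)
    warning(sprintf(
      "MixP ICE did not converge in %d sweeps (last max change %.3g)",
      res$iterations, res$delta), call. = FALSE)
  new_fit_result("mixp", mu = res$mu, b = res$b, w = res$w,
                 iterations = res$iterations, delta = res$delta,
                 converged = res$converged)
}

#' Genomic estimated breeding values
#'
#' `ghat_i = sum_j X_ij bhat_j` over the validation individuals' genotypes,
#' standardized with the reference frequencies.  The fitted mean is not
#' added: GEBV are deviations, invariant to shifting the phenotypes.
#'
#' @param X_validation Standardized validation genotype matrix.
#' @param fit A `fit_result`.
#' @return Numeric vector of GEBV.
#' @export
predict_gebv <- function(X_validation, fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (ncol(X_validation) != length(fit$b))
    stop("validation markers do not match the fitted markers", call. = FALSE)
  drop(X_validation %*% fit$b)
}

#' Accuracy of genomic prediction
#'
#' Pearson correlation between true and predicted genetic values in the
#' validation set.  If the predictions have zero variance (e.g. all marker
#' effects are zero), the accuracy is reported as 0 with a warning rather
#' than NaN.
#'
#' @param g_true True genetic values.
#' @param g_hat Predicted genetic values (GEBV).
#' @return A correlation in `[-1, 1]`.
#' @export
prediction_accuracy <- function(g_true, g_hat) {
  if (length(g_true) != length(g_hat) || length(g_true) < 2L)
    stop("g_true and g_hat must have equal length >= 2", call. = FALSE)
  if (sd(g_hat) == 0 || sd(g_true) == 0) {
    warning("zero-variance predictions; accuracy reported as 0",
            call. = FALSE)
    return(0)
  }
  cor(g_true, g_hat)
}
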