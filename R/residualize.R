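# Step 1 of the pipeline: remove main effects from the phenotype with a
# penalized regression, then split individuals into low/high groups by the
# empirical quantiles of the residual (or of the raw phenotype).

# Run code with a throwaway RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Fit the penalized main-effect model and extract residuals
#'
#' Regresses the phenotype on all gene columns (main effects only, no
#' interaction terms) with the elastic net, the penalty parameter lambda
#' chosen by K-fold cross-validation minimizing mean squared prediction
#' error. The residual vector is the phenotype minus the fitted main-effect
#' contribution; using it in place of the raw phenotype makes the downstream
#' group truncation independent of strong main effects.
#'
#' The elastic-net penalty is parameterized as
#' \eqn{\lambda[(1-\alpha)/2\,\lVert\beta\rVert_2^2 + \alpha\lVert\beta\rVert_1]}
#' with mixing \eqn{\alpha} = \code{mixing} (default 1/3). The intercept is
#' always fitted and unpenalized. Cross-validation fold assignment is drawn
#' from the explicit seed, so the selected lambda (and hence the fit) is
#' reproducible.
#'
#' @param x Standardized expression matrix (see [standardize_expression()]).
#' @param y Numeric phenotype vector, one value per row of \code{x}.
#' @param mixing Elastic-net mixing parameter in [0, 1]; 1 is the LASSO.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @param penalty Optional fixed lambda; skips cross-validation when given.
#' @return Object of class \code{"residual_fit"}: list with elements
#'   \code{intercept}, \code{coefficients} (length p, named), \code{residuals}
#'   (length n), \code{fitted}, \code{penalty} (selected lambda),
#'   \code{mixing}, \code{cv_folds}, \code{seed}.
#' @examples
#' set.seed(1)
#' x <- standardize_expression(matrix(rnorm(200 * 10), 200, 10))
#' y <- 2 * x[, 3] + rnorm(200, sd = 0.5)
#' fit <- fit_main_effects(x, y, seed = 7)
#' round(fit$coefficients[3], 2)
#' @export
fit_main_effects <- function(x, y, mixing = 1/3, cv_folds = 10L, seed = 1L,
                             penalty = NULL) {
  x <- as_expression_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("phenotype length ", length(y), " != ", n, " rows")
  if (any(!is.finite(y))) stop("phenotype has non-finite values")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  if (is.null(penalty)) {
    cv_folds <- as.integer(cv_folds)
    if (cv_folds < 2L) stop("cv_folds must be >= 2")
    if (n < cv_folds) stop("fewer samples than cv_folds")
  }

  if (stats::var(y) == 0) {
    # degenerate constant response: the null model is exact
    beta <- stats::setNames(numeric(ncol(x)), colnames(x))
    return(structure(list(intercept = mean(y), coefficients = beta,
                          residuals = y - mean(y), fitted = rep(mean(y), n),
                          penalty = Inf, mixing = mixing,
                          cv_folds = cv_folds, seed = seed),
                     class = "residual_fit"))
  }

  if (!is.null(penalty)) {
    fit <- glmnet::glmnet(x, y, alpha = mixing, lambda = penalty,
                          standardize = FALSE)
    lambda <- penalty
    cf <- as.numeric(stats::coef(fit, s = penalty))
  } else {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    cv <- glmnet::cv.glmnet(x, y, alpha = mixing, foldid = foldid,
                            standardize = FALSE)
    lambda <- cv$lambda.min
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  }
  intercept <- cf[1L]
  beta <- stats::setNames(cf[-1L], colnames(x))
  fitted <- as.numeric(intercept + x %*% beta)
  structure(list(intercept = intercept, coefficients = beta,
                 residuals = y - fitted, fitted = fitted,
                 penalty = lambda, mixing = mixing,
                 cv_folds = if (is.null(penalty)) cv_folds else NA_integer_,
                 seed = seed),
            class = "residual_fit")
}

#' @export
print.residual_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("Penalized main-effect fit (elastic net, mixing =",
      format(x$mixing, digits = 4), ")\n")
  cat("  lambda:", format(x$penalty, digits = 4),
      " nonzero coefficients:", nz, "/", length(x$coefficients), "\n")
  cat("  residual SD:", format(stats::sd(x$residuals), digits = 4), "\n")
  invisible(x)
}

#' Split individuals into low and high groups at a truncation point
#'
#' Given per-individual values (raw phenotype or main-effect residuals) and a
#' truncation point \code{a} in ]0, 0.5], the low group contains individuals
#' with value at or below the empirical a-quantile and the high group those at
#' or above the (1 - a)-quantile; individuals in between are left unassigned.
#' At a = 0.5 the sample is rank-split into two halves forming a partition:
#' with odd n the median individual goes to the low group, and exact ties are
#' broken deterministically by sample index. Quantiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param values Numeric vector, one value per individual.
#' @param a Truncation point in ]0, 0.5].
#' @param basis Label recording what the values are
#'   (\code{"phenotype"} or \code{"residual"}); informational only.
#' @return Object of class \code{"group_assignment"}: list with logical masks
#'   \code{low} and \code{high}, the truncation point \code{a}, and
#'   \code{basis}.
#' @examples
#' g <- assign_groups(1:10, a = 0.2)
#' which(g$low); which(g$high)
#' @export
assign_groups <- function(values, a = 0.5, basis = c("phenotype", "residual")) {
  basis <- match.arg(basis)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!(a > 0 && a <= 0.5)) stop("a must be in ]0, 0.5]")
  if (max(values) == min(values)) stop("all values identical: no truncation possible")

  if (a == 0.5) {
    ord <- order(values, seq_len(n))  # stable index tie-break
    n_low <- ceiling(n / 2)           # odd n: median sample to the low group
    low <- high <- logical(n)
    low[ord[seq_len(n_low)]] <- TRUE
    high[ord[(n_low + 1L):n]] <- TRUE
  } else {
    q_low <- stats::quantile(values, probs = a, type = 7, names = FALSE)
    q_high <- stats::quantile(values, probs = 1 - a, type = 7, names = FALSE)
    low <- values <= q_low
    high <- values >= q_high
    if (any(low & high)) stop("degenerate truncation: groups overlap (too many ties)")
  }
  if (!any(low) || !any(high)) stop("empty group at a = ", a)
  structure(list(low = low, high = high, a = a, basis = basis),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment (a =", x$a, ", basis =", x$basis, "):",
      sum(x$low), "low,", sum(x$high), "high,",
      length(x$low) - sum(x$low) - sum(x$high), "unassigned\n")
  invisible(x)
}
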