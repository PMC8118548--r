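# Group-wise dependency matrices: plain truncated correlation networks and
# the truncated part-correlation metric, plus the zero-decision rule used by
# the sign adjustment.

#' @keywords internal
new_group_network <- function(values, metric, group, a = NA_real_) {
  structure(values, metric = metric, group = group, a = a,
            class = c("group_network", class(values)))
}

#' Pearson correlation network within one phenotype group
#'
#' Computes the Pearson correlation matrix over the masked rows only
#' (re-centering within the group: truncation shifts column means by design),
#' with the diagonal set to 0.
#'
#' @param x Expression matrix (standardized on the full sample).
#' @param mask Logical vector selecting the group's rows; at least 4.
#' @param group Label, \code{"low"} or \code{"high"}.
#' @param a Truncation point, recorded on the result.
#' @return A \code{"group_network"} matrix (p x p, symmetric, diagonal 0) with
#'   attributes \code{metric = "correlation"}, \code{group}, \code{a}.
#' @export
group_correlation <- function(x, mask, group = c("low", "high"), a = NA_real_) {
  group <- match.arg(group)
  x <- as_expression_matrix(x)
  mask <- check_mask(mask, nrow(x))
  xm <- x[mask, , drop = FALSE]
  sds <- apply(xm, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) within group: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(xm)
  diag(r) <- 0
  new_group_network(r, metric = "correlation", group = group, a = a)
}

#' @keywords internal
check_mask <- function(mask, n) {
  if (is.numeric(mask)) {
    m <- logical(n); m[mask] <- TRUE; mask <- m
  }
  if (!is.logical(mask) || length(mask) != n) stop("mask must be logical of length ", n)
  if (sum(mask) < 4L) stop("group must contain at least 4 samples, has ", sum(mask))
  mask
}

#' Full-sample pairwise regression residuals
#'
#' For every ordered gene pair (j, k) fits the simple regression of X_j on
#' X_k, with intercept, over ALL n individuals (the non-truncated data). The
#' residual \eqn{\epsilon_{j|k}} carries whatever part of X_j is not linearly
#' explained by X_k before any phenotypic truncation. Slopes and intercepts
#' are stored in closed form (p x p matrices); residual vectors are
#' materialized lazily through the \code{residual} accessor, so memory stays
#' O(p^2) rather than O(n p^2).
#'
#' @param x Expression matrix standardized on the full sample.
#' @return Object of class \code{"part_residuals"}: list with \code{slopes}
#'   (slopes[j, k] = slope of X_j on X_k), \code{intercepts},
#'   \code{means}, \code{vars} (full-sample column moments), \code{cov}
#'   (full-sample covariance matrix), and function
#'   \code{residual(j, k)} returning the length-n residual vector.
#' @export
part_residuals <- function(x) {
  x <- as_expression_matrix(x)
  if (!is_standardized(x)) {
    # tolerated, but the propositions condition on zero-mean unit-SD columns
    warning("expression matrix is not flagged as standardized")
  }
  n <- nrow(x)
  mu <- colMeans(x)
  S <- stats::cov(x)
  v <- diag(S)
  if (any(v == 0)) stop("constant column(s): ",
                        paste(colnames(x)[v == 0], collapse = ", "))
  # slope of X_j on X_k: cov(j,k)/var(k); columns index the predictor k
  slopes <- sweep(S, 2L, v, "/")
  diag(slopes) <- 1
  intercepts <- matrix(mu, nrow(S), ncol(S)) - sweep(slopes, 2L, mu, "*")
  diag(intercepts) <- 0
  res_fun <- function(j, k) {
    x[, j] - intercepts[j, k] - slopes[j, k] * x[, k]
  }
  structure(list(slopes = slopes, intercepts = intercepts, means = mu,
                 vars = v, cov = S, n = n, gene_names = colnames(x),
                 residual = res_fun),
            class = "part_residuals")
}

#' Truncated part-correlation network within one phenotype group
#'
#' Entry (j, k) is the Pearson correlation, computed within the masked group,
#' between gene k and the full-sample regression residual
#' \eqn{\epsilon_{j|k}} of gene j on gene k. Removing the full-sample linear
#' relationship first makes the two variables uncorrelated before truncation,
#' so any dependency re-emerging inside a phenotype group is attributable to
#' the phenotype conditioning — the property the differential-network sign
#' rules rely on. The resulting matrix is asymmetric (orientation j|k versus
#' k|j); see [orient_networks()] for the pairwise symmetrization applied
#' before differencing.
#'
#' Entries whose within-group residual variance vanishes are set to 0 with a
#' warning.
#'
#' All within-group correlations are evaluated in closed form from the group
#' covariance matrix and the full-sample slopes, so the computation is
#' O(p^2) in memory for any n.
#'
#' @inheritParams group_correlation
#' @param residuals A [part_residuals()] object computed on the full sample.
#' @return A \code{"group_network"} matrix (p x p, diagonal 0) with attribute
#'   \code{metric = "part_correlation"}.
#' @export
part_correlation <- function(x, mask, residuals, group = c("low", "high"),
                             a = NA_real_) {
  group <- match.arg(group)
  x <- as_expression_matrix(x)
  mask <- check_mask(mask, nrow(x))
  if (!inherits(residuals, "part_residuals")) stop("residuals must come from part_residuals()")
  if (residuals$n != nrow(x)) stop("residuals were fitted on a different sample size")

  xm <- x[mask, , drop = FALSE]
  Cg <- stats::cov(xm)           # group covariance
  vg <- diag(Cg)
  if (any(vg == 0)) {
    stop("constant column(s) within group: ",
         paste(colnames(x)[vg == 0], collapse = ", "))
  }
  B <- residuals$slopes          # B[j, k] = full-sample slope of X_j on X_k
  p <- ncol(x)
  # within-group moments of eps_{j|k} = X_j - a_{jk} - b_{jk} X_k:
  #   cov_g(X_k, eps_{j|k}) = Cg[k,j] - b_{jk} Cg[k,k]
  #   var_g(eps_{j|k})      = Cg[j,j] - 2 b_{jk} Cg[j,k] + b_{jk}^2 Cg[k,k]
  vk <- matrix(vg, p, p, byrow = TRUE)   # [j,k] -> var_g(X_k)
  vj <- matrix(vg, p, p)                 # [j,k] -> var_g(X_j)
  cov_ke <- t(Cg) - B * vk
  var_e <- vj - 2 * B * Cg + B^2 * vk
  denom2 <- var_e * vk
  phi <- matrix(0, p, p, dimnames = dimnames(Cg))
  ok <- denom2 > .Machine$double.eps
  phi[ok] <- cov_ke[ok] / sqrt(denom2[ok])
  degenerate <- !ok
  diag(degenerate) <- FALSE
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) with zero within-group residual variance; ",
            "part-correlation set to 0")
  }
  phi[phi > 1] <- 1; phi[phi < -1] <- -1
  diag(phi) <- 0
  new_group_network(phi, metric = "part_correlation", group = group, a = a)
}

#' Symmetrize a pair of oriented part-correlation networks
#'
#' The part-correlation matrix is asymmetric: entry (j, k) uses the residual
#' of j on k and entry (k, j) the residual of k on j. For the differential
#' network the two group matrices must carry a mutually consistent
#' orientation per unordered pair. With \code{method = "max_diff"} the
#' orientation maximizing |high - low| is selected pair by pair and its two
#' group values placed symmetrically in both matrices (maximizes detection
#' sensitivity while preserving the sign pattern the interaction rules rely
#' on); \code{"average"} averages the two orientations instead.
#'
#' @param high,low Asymmetric \code{"group_network"} matrices from
#'   [part_correlation()].
#' @param method Orientation rule, \code{"max_diff"} (default) or
#'   \code{"average"}.
#' @return List with symmetric matrices \code{high} and \code{low}.
#' @export
orient_networks <- function(high, low, method = c("max_diff", "average")) {
  method <- match.arg(method)
  if (!identical(dim(high), dim(low))) stop("shape mismatch")
  h <- unclass(high); l <- unclass(low)
  if (method == "average") {
    hs <- (h + t(h)) / 2
    ls <- (l + t(l)) / 2
  } else {
    d1 <- abs(h - l)        # orientation (j|k) stored at [j,k]
    d2 <- t(d1)             # orientation (k|j) seen from [j,k]
    use_t <- d2 > d1        # strict: ties keep the lower-triangle orientation
    hs <- ifelse(use_t, t(h), h)
    ls <- ifelse(use_t, t(l), l)
    # enforce one orientation per unordered pair from the lower triangle
    hs[upper.tri(hs)] <- t(hs)[upper.tri(hs)]
    ls[upper.tri(ls)] <- t(ls)[upper.tri(ls)]
  }
  diag(hs) <- 0; diag(ls) <- 0
  list(high = new_group_network(hs, metric = attr(high, "metric"),
                                group = "high", a = attr(high, "a")),
       low = new_group_network(ls, metric = attr(low, "metric"),
                               group = "low", a = attr(low, "a")))
}

#' Zero-decision rule for network entries
#'
#' Constructs the rule used to decide whether a group dependency is "zero"
#' before sign adjustment: either hard thresholding (|value| < r is zero;
#' default r = 0.1) or a Bonferroni-corrected two-sided correlation t-test.
#'
#' @param method \code{"hard_threshold"} or \code{"bonferroni"}.
#' @param r Hard threshold (> 0).
#' @param alpha_level Test level for the Bonferroni rule.
#' @param n_tests Number of tests for the Bonferroni correction; defaults to
#'   p(p - 1) (both orientations) when used inside [diffnet()].
#' @return Object of class \code{"zero_rule"}.
#' @export
zero_rule <- function(method = c("hard_threshold", "bonferroni"), r = 0.1,
                      alpha_level = 0.05, n_tests = 1L) {
  method <- match.arg(method)
  if (r <= 0) stop("r must be positive")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in ]0, 1[")
  if (n_tests < 1) stop("n_tests must be >= 1")
  structure(list(method = method, r = r, alpha_level = alpha_level,
                 n_tests = as.integer(n_tests)),
            class = "zero_rule")
}

#' Apply the zero-decision rule to dependency values
#'
#' Hard threshold: zero iff |value| < r. Bonferroni: zero iff the two-sided
#' p-value of \eqn{t = value\sqrt{n-2}/\sqrt{1-value^2}} on n - 2 degrees of
#' freedom exceeds alpha_level / n_tests.
#'
#' @param value Numeric vector or matrix of dependency values in [-1, 1].
#' @param rule A [zero_rule()].
#' @param n_group Group sample size (needed for the Bonferroni rule; >= 3).
#' @return Logical of the same shape: TRUE where the value is deemed zero.
#' @export
is_zero <- function(value, rule = zero_rule(), n_group = NULL) {
  if (!inherits(rule, "zero_rule")) stop("rule must come from zero_rule()")
  if (any(abs(value) > 1 + 1e-12, na.rm = TRUE)) stop("|value| must be <= 1")
  if (rule$method == "hard_threshold") {
    out <- abs(value) < rule$r
  } else {
    if (is.null(n_group)) stop("n_group required for the bonferroni rule")
    if (n_group < 3L) stop("bonferroni rule needs n_group >= 3")
    v <- pmin(pmax(value, -1), 1)
    tstat <- v * sqrt(n_group - 2) / sqrt(pmax(1 - v^2, .Machine$double.eps))
    pval <- 2 * stats::pt(abs(tstat), df = n_group - 2, lower.tail = FALSE)
    out <- pval > rule$alpha_level / rule$n_tests
  }
  if (is.matrix(value)) dim(out) <- dim(value)
  out
}
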