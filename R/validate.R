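# Parametric and survival follow-up of detected interactions: the Aiken-West
# moderation test, quantile-based risk classification, Kaplan-Meier curves
# and the two-group log-rank test.

#' Aiken-West interaction (moderation) test for one gene pair
#'
#' Ordinary least squares of the response on both genes and their product,
#' with intercept: \eqn{Y = \mu + X_k\beta_k + X_l\beta_l + X_kX_l\beta_{kl}}.
#' Two-sided t-test p-values are reported for all three slopes. The
#' interaction is deemed relevant when its p-value is below the test level
#' AND below both main-effect p-values. Censored observations must be removed
#' upstream when the response is a survival time.
#'
#' @param xk,xl Numeric expression vectors.
#' @param y Numeric response.
#' @param alpha_level Test level (default 0.05).
#' @return Object of class \code{"aiken_west"}: list with
#'   \code{beta_k}, \code{beta_l}, \code{beta_kl}, \code{p_k}, \code{p_l},
#'   \code{p_kl}, \code{relevant}, \code{alpha_level}, \code{n}.
#' @export
aiken_west <- function(xk, xl, y, alpha_level = 0.05) {
  n <- length(y)
  if (length(xk) != n || length(xl) != n) stop("length mismatch")
  if (n < 5L) stop("need at least 5 observations")
  fit <- stats::lm(y ~ xk + xl + I(xk * xl))
  if (anyNA(stats::coef(fit))) stop("collinear design: coefficients not estimable")
  sm <- summary(fit)$coefficients
  out <- list(beta_k = sm["xk", 1L], beta_l = sm["xl", 1L],
              beta_kl = sm["I(xk * xl)", 1L],
              p_k = sm["xk", 4L], p_l = sm["xl", 4L],
              p_kl = sm["I(xk * xl)", 4L],
              alpha_level = alpha_level, n = n)
  out$relevant <- out$p_kl < out$p_k && out$p_kl < out$p_l &&
    out$p_kl < alpha_level
  structure(out, class = "aiken_west")
}

#' @export
print.aiken_west <- function(x, ...) {
  cat("Aiken-West interaction test (n =", x$n, ")\n")
  cat(sprintf("  beta_k  = %8.4f  p = %.3g\n", x$beta_k, x$p_k))
  cat(sprintf("  beta_l  = %8.4f  p = %.3g\n", x$beta_l, x$p_l))
  cat(sprintf("  beta_kl = %8.4f  p = %.3g\n", x$beta_kl, x$p_kl))
  cat("  relevant:", x$relevant, "(level", x$alpha_level, ")\n")
  invisible(x)
}

#' Quantile-based risk classification from an interaction term
#'
#' Classifies individuals into low/high risk from the per-individual value of
#' an interaction term (the elementwise product of the two standardized
#' expression columns). With a positive interaction effect, values below the
#' empirical q-quantile are low risk; with a negative effect the rule is
#' mirrored (values above the (1 - q)-quantile are low risk). The default
#' q = 2/3 emphasizes the high-risk profile. Quantiles are type 7; values
#' exactly at the threshold fall to high risk.
#'
#' @param interaction_values Numeric vector (e.g. \code{xk * xl}).
#' @param effect_sign +1 or -1, the sign of the interaction effect.
#' @param q Classification quantile in ]0, 1[.
#' @return Object of class \code{"risk_groups"}: list with factor
#'   \code{assignment} (levels low_risk, high_risk, excluded), \code{q},
#'   \code{direction}.
#' @export
risk_classify <- function(interaction_values, effect_sign = 1, q = 2/3) {
  v <- as.numeric(interaction_values)
  if (any(!is.finite(v))) stop("values must be finite")
  if (!(q > 0 && q < 1)) stop("q must be in ]0, 1[")
  if (max(v) == min(v)) stop("constant interaction values")
  s <- sign(effect_sign)
  if (s == 0) stop("effect_sign must be nonzero")
  if (s > 0) {
    thr <- stats::quantile(v, probs = q, type = 7, names = FALSE)
    low <- v < thr
  } else {
    thr <- stats::quantile(v, probs = 1 - q, type = 7, names = FALSE)
    low <- v > thr
  }
  assignment <- factor(ifelse(low, "low_risk", "high_risk"),
                       levels = c("low_risk", "high_risk", "excluded"))
  structure(list(assignment = assignment, q = q, direction = s),
            class = "risk_groups")
}

#' Combine two risk classifiers by intersection
#'
#' Individuals low risk under both classifiers form the combined low-risk
#' group, high risk under both the combined high-risk group; everyone else is
#' excluded.
#'
#' @param g1,g2 \code{"risk_groups"} objects over the same cohort.
#' @return A \code{"risk_groups"} object.
#' @export
combine_risk <- function(g1, g2) {
  stopifnot(inherits(g1, "risk_groups"), inherits(g2, "risk_groups"))
  a1 <- as.character(g1$assignment); a2 <- as.character(g2$assignment)
  if (length(a1) != length(a2)) stop("cohort size mismatch")
  comb <- rep("excluded", length(a1))
  comb[a1 == "low_risk" & a2 == "low_risk"] <- "low_risk"
  comb[a1 == "high_risk" & a2 == "high_risk"] <- "high_risk"
  structure(list(assignment = factor(comb, levels = c("low_risk", "high_risk",
                                                      "excluded")),
                 q = g1$q, direction = NA_integer_),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  print(table(x$assignment))
  invisible(x)
}

#' @keywords internal
risk_factor <- function(groups, n) {
  if (inherits(groups, "risk_groups")) groups <- groups$assignment
  g <- factor(as.character(groups))
  if (length(g) != n) stop("group length mismatch")
  keep <- !is.na(g) & g != "excluded"
  list(keep = keep, g = droplevels(g[keep]))
}

#' Kaplan-Meier survival estimate per risk group
#'
#' Product-limit estimator per group (excluded individuals dropped), with the
#' median survival time defined as the first time at which the estimated
#' survival probability drops to 0.5 or below (NA when never reached).
#'
#' @param time Nonnegative survival/censoring times.
#' @param event 1 = death observed, 0 = right-censored.
#' @param groups A [risk_classify()] result, or a factor/character vector.
#' @return List with \code{fit} (a [survival::survfit] object),
#'   \code{median} (named vector of per-group medians), and \code{table}
#'   (data frame: group, time, n_risk, n_event, surv).
#' @export
kaplan_meier <- function(time, event, groups) {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(event) != length(time)) stop("length mismatch")
  if (any(time < 0)) stop("negative times")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  rf <- risk_factor(groups, length(time))
  g <- rf$g; keep <- rf$keep
  if (nlevels(g) < 1L || any(table(g) == 0L)) stop("empty group")
  ev <- tapply(event[keep], g, sum)
  if (any(ev == 0L)) warning("group(s) without events: ",
                             paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(time[keep], event[keep]) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1L], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  tab <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE)
  med <- vapply(levels(g), function(lv) {
    tt <- tab[tab$group == lv, ]
    hit <- tt$time[tt$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1L))
  list(fit = fit, median = med, table = tab)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic comparing the survival distributions of two
#' risk groups, with the p-value from the chi-square distribution on one
#' degree of freedom. Excluded individuals are dropped.
#'
#' @inheritParams kaplan_meier
#' @return List with \code{chi_square}, \code{p}, \code{n}.
#' @export
log_rank_test <- function(time, event, groups) {
  time <- as.numeric(time); event <- as.integer(event)
  rf <- risk_factor(groups, length(time))
  g <- rf$g; keep <- rf$keep
  if (nlevels(g) != 2L) stop("log-rank test needs exactly 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(time[keep], event[keep]) ~ g)
  chi <- sd_$chisq
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = sum(keep))
}
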