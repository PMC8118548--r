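# Steps 2-3: differential networks, the sign-adjustment operator Pi, the
# interaction-type labels, and the end-to-end diffnet() fit.

#' Elementwise absolute differential network
#'
#' @param high,low \code{"group_network"} matrices of the same metric/shape.
#' @return Symmetric matrix |high - low|.
#' @export
differential_matrix <- function(high, low) {
  if (!identical(attr(high, "metric"), attr(low, "metric"))) {
    stop("metric mismatch: ", attr(high, "metric"), " vs ", attr(low, "metric"))
  }
  if (!identical(dim(high), dim(low))) stop("shape mismatch")
  abs(unclass(high) - unclass(low))
}

#' Sign-adjustment operator for a pair of group dependencies
#'
#' Encodes the interaction evidence carried by the low/high dependency pair,
#' after applying the zero rule to each side:
#' \itemize{
#'   \item +1 — both nonzero with opposite signs (the pattern produced by a
#'     product-term, type I, interaction);
#'   \item -1 — exactly one side nonzero (a one-group-only dependency, the
#'     type II activation/deactivation pattern);
#'   \item 0 — both zero (no interaction evidence).
#' }
#' The both-nonzero-same-sign pattern is not covered by the defining cases; it
#' indicates a phenotype-independent association between the genes and is
#' mapped to 0 by default (\code{same_sign = "zero"});
#' \code{same_sign = "keep_positive"} maps it to +1 for sensitivity analysis.
#'
#' @param phi_high,phi_low Dependency values (scalars, vectors or matrices of
#'   equal shape) from the high and low groups.
#' @param rule A [zero_rule()].
#' @param n_high,n_low Group sizes (used by the Bonferroni rule).
#' @param same_sign Handling of the both-nonzero-same-sign cell.
#' @return Integer(s) in {-1, 0, +1}, same shape as the inputs.
#' @examples
#' pi_value(0.5, -0.5)   # type I pattern
#' pi_value(0.5, 0.02)   # type II pattern
#' pi_value(0.05, 0.02)  # no evidence
#' @export
pi_value <- function(phi_high, phi_low, rule = zero_rule(),
                     n_high = NULL, n_low = NULL,
                     same_sign = c("zero", "keep_positive")) {
  same_sign <- match.arg(same_sign)
  if (!identical(dim(phi_high), dim(phi_low)) ||
      length(phi_high) != length(phi_low)) stop("shape mismatch")
  zh <- is_zero(phi_high, rule, n_high)
  zl <- is_zero(phi_low, rule, n_low)
  out <- integer(length(phi_high))
  opposite <- !zh & !zl & (sign(phi_high) == -sign(phi_low))
  same <- !zh & !zl & (sign(phi_high) == sign(phi_low))
  one_sided <- xor(zh, zl)
  out[opposite] <- 1L
  out[one_sided] <- -1L
  if (same_sign == "keep_positive") out[same] <- 1L
  if (is.matrix(phi_high)) dim(out) <- dim(phi_high)
  out
}

#' Sign-adjusted differential network from two group networks
#'
#' Computes the differential network q = |high - low|, its sign-adjusted
#' version q_signed = q * Pi(high, low), and the per-edge interaction labels:
#' q_signed > 0 is evidence for a nonzero product-term (type I) effect,
#' q_signed < 0 for a nonzero activation/deactivation (type II) effect, and
#' q_signed = 0 for neither.
#'
#' @inheritParams differential_matrix
#' @param rule A [zero_rule()].
#' @param n_high,n_low Group sizes (Bonferroni rule only).
#' @param same_sign Passed to [pi_value()].
#' @return Object of class \code{"diffnet"} (without pipeline metadata): list
#'   with matrices \code{q}, \code{q_signed}, character matrix \code{labels}
#'   ("type_I"/"type_II"/"none"), the inputs \code{high}, \code{low}, the
#'   \code{rule}, and \code{metric}.
#' @export
sign_adjust <- function(high, low, rule = zero_rule(),
                        n_high = NULL, n_low = NULL,
                        same_sign = c("zero", "keep_positive")) {
  same_sign <- match.arg(same_sign)
  q <- differential_matrix(high, low)
  pim <- pi_value(unclass(high), unclass(low), rule, n_high, n_low, same_sign)
  q_signed <- q * pim
  labels <- matrix("none", nrow(q), ncol(q), dimnames = dimnames(q))
  labels[q_signed > 0] <- "type_I"
  labels[q_signed < 0] <- "type_II"
  diag(labels) <- "none"
  diag(q) <- 0; diag(q_signed) <- 0
  metric <- if (identical(attr(high, "metric"), "part_correlation")) "dPCCN" else "dCCN"
  structure(list(q = q, q_signed = q_signed, labels = labels,
                 high = high, low = low, rule = rule, metric = metric),
            class = "diffnet")
}

#' Trait-specific differential co-expression network
#'
#' Fits the full three-step model-guided differential network pipeline to an
#' expression matrix and a quantitative phenotype:
#' \enumerate{
#'   \item (optional, \code{residual_adjust = TRUE}) regress the phenotype on
#'     all gene main effects with the elastic net and keep the residuals, so
#'     the truncation below is independent of strong main effects;
#'   \item split individuals into low/high groups at the truncation point
#'     \code{a} of the (residualized) phenotype and estimate one dependency
#'     network per group — truncated part-correlations (\code{metric =
#'     "dpccn"}, the default) or plain truncated Pearson correlations
#'     (\code{"dccn"});
#'   \item form the sign-adjusted differential network: edges with opposite
#'     group signs are labeled type I (product-term interactions), one-sided
#'     dependencies type II (activation/deactivation interactions).
#' }
#' Columns of \code{x} are standardized on the full sample before anything
#' else (never re-standardized within groups).
#'
#' @param x Numeric expression matrix, individuals x genes.
#' @param y Numeric phenotype vector (one value per individual).
#' @param a Truncation point in ]0, 0.5]; the default 0.5 uses every sample.
#' @param metric \code{"dpccn"} (truncated part-correlation) or
#'   \code{"dccn"} (truncated correlation).
#' @param residual_adjust Replace the phenotype with elastic-net main-effect
#'   residuals before truncation (default TRUE).
#' @param rule [zero_rule()] deciding when a group dependency counts as zero.
#'   For the Bonferroni rule \code{n_tests} defaults to p(p - 1).
#' @param mixing,cv_folds Elastic-net parameters for the residual step.
#' @param seed Integer seed (cross-validation folds).
#' @param orientation Symmetrization rule for the part-correlation matrices;
#'   see [orient_networks()].
#' @param same_sign Passed to [pi_value()].
#' @return Object of class \code{"diffnet"}: matrices \code{q},
#'   \code{q_signed}, \code{labels}, the group networks \code{high} and
#'   \code{low}, the \code{groups} assignment, the residual \code{fit} (or
#'   NULL), and the call parameters. Use [top_edges()] to extract an edge
#'   list and [write_edge_list()] to serialize it.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(400 * 6), 400, 6)
#' y <- x[, 1] * x[, 2] + rnorm(400)
#' fit <- diffnet(x, y, residual_adjust = FALSE, seed = 1)
#' fit$labels[1, 2]
#' @export
diffnet <- function(x, y, a = 0.5, metric = c("dpccn", "dccn"),
                    residual_adjust = TRUE, rule = NULL, mixing = 1/3,
                    cv_folds = 10L, seed = 1L,
                    orientation = c("max_diff", "average"),
                    same_sign = c("zero", "keep_positive")) {
  metric <- match.arg(metric)
  orientation <- match.arg(orientation)
  same_sign <- match.arg(same_sign)
  cl <- match.call()
  x <- as_expression_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("phenotype length != number of individuals")
  if (any(!is.finite(y))) stop("phenotype has non-finite values")
  if (!(a > 0 && a <= 0.5)) stop("a must be in ]0, 0.5]")
  p <- ncol(x)
  if (is.null(rule)) rule <- zero_rule()
  if (rule$method == "bonferroni" && rule$n_tests == 1L) {
    rule$n_tests <- p * (p - 1L)
  }

  xs <- if (is_standardized(x)) x else standardize_expression(x)

  fit <- NULL
  basis_values <- y
  basis <- "phenotype"
  if (residual_adjust) {
    fit <- fit_main_effects(xs, y, mixing = mixing, cv_folds = cv_folds,
                            seed = seed)
    basis_values <- fit$residuals
    basis <- "residual"
  }
  groups <- assign_groups(basis_values, a = a, basis = basis)
  n_low <- sum(groups$low); n_high <- sum(groups$high)

  if (metric == "dpccn") {
    pres <- part_residuals(xs)
    high <- part_correlation(xs, groups$high, pres, group = "high", a = a)
    low <- part_correlation(xs, groups$low, pres, group = "low", a = a)
    oriented <- orient_networks(high, low, method = orientation)
    high <- oriented$high; low <- oriented$low
  } else {
    high <- group_correlation(xs, groups$high, group = "high", a = a)
    low <- group_correlation(xs, groups$low, group = "low", a = a)
  }

  out <- sign_adjust(high, low, rule = rule, n_high = n_high, n_low = n_low,
                     same_sign = same_sign)
  out$groups <- groups
  out$fit <- fit
  out$a <- a
  out$residual_adjusted <- residual_adjust
  out$orientation <- if (metric == "dpccn") orientation else NA_character_
  out$same_sign <- same_sign
  out$seed <- seed
  out$call <- cl
  out
}

#' Extract the strongest edges of a differential network
#'
#' Keeps, per interaction type, the edges with largest |q_signed| up to the
#' cap, with deterministic tie-breaking by gene-name pair. Edges with label
#' "none" are dropped.
#'
#' @param net A \code{"diffnet"} object.
#' @param max_per_type Maximum edges retained per interaction type
#'   (default 70, a display-oriented sparsification).
#' @return Data frame with columns \code{gene_a}, \code{gene_b} (gene_a
#'   before gene_b in column order), \code{q}, \code{q_signed}, \code{type},
#'   ordered by descending |q_signed|.
#' @export
top_edges <- function(net, max_per_type = 70L) {
  stopifnot(inherits(net, "diffnet"))
  if (max_per_type < 1L) stop("max_per_type must be >= 1")
  p <- ncol(net$q)
  nm <- colnames(net$q)
  if (is.null(nm)) nm <- paste0("g", seq_len(p))
  idx <- which(upper.tri(net$q), arr.ind = TRUE)
  df <- data.frame(gene_a = nm[idx[, 1L]], gene_b = nm[idx[, 2L]],
                   q = net$q[idx], q_signed = net$q_signed[idx],
                   type = net$labels[idx], stringsAsFactors = FALSE)
  df <- df[df$type != "none", , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df <- df[order(-abs(df$q_signed), df$gene_a, df$gene_b), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$type), function(i) {
    i[seq_len(min(length(i), max_per_type))]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  df <- df[order(-abs(df$q_signed), df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Edge ranking scores for benchmarking
#'
#' Returns |q_signed| for every unordered gene pair (0 where the sign
#' adjustment found no interaction evidence), the score used when sweeping a
#' decision threshold for ROC evaluation.
#'
#' @param net A \code{"diffnet"} object.
#' @return Named numeric vector over pairs "j:k" (column indices, j < k).
#' @export
edge_scores <- function(net) {
  stopifnot(inherits(net, "diffnet"))
  idx <- which(upper.tri(net$q_signed), arr.ind = TRUE)
  stats::setNames(abs(net$q_signed[idx]), paste0(idx[, 1L], ":", idx[, 2L]))
}

#' @export
print.diffnet <- function(x, ...) {
  p <- ncol(x$q)
  tab <- table(factor(x$labels[upper.tri(x$labels)],
                      levels = c("type_I", "type_II", "none")))
  cat("Trait-specific differential co-expression network (", x$metric, ")\n",
      sep = "")
  cat("  genes:", p, " truncation a:", x$a,
      " residual-adjusted:", isTRUE(x$residual_adjusted), "\n")
  cat("  groups: ", sum(x$groups$low), " low / ", sum(x$groups$high),
      " high\n", sep = "")
  cat("  zero rule: ", x$rule$method,
      if (x$rule$method == "hard_threshold") paste0(" (r = ", x$rule$r, ")")
      else paste0(" (alpha = ", x$rule$alpha_level, ", m = ", x$rule$n_tests, ")"),
      "\n", sep = "")
  cat("  edges: ", tab[["type_I"]], " type I, ", tab[["type_II"]],
      " type II, ", tab[["none"]], " none\n", sep = "")
  invisible(x)
}

#' @export
summary.diffnet <- function(object, max_per_type = 10L, ...) {
  print(object)
  ed <- top_edges(object, max_per_type = max_per_type)
  if (nrow(ed)) {
    cat("\nTop edges (|q_signed|, up to", max_per_type, "per type):\n")
    print(ed, digits = 3)
  } else cat("\nNo labeled edges.\n")
  invisible(ed)
}

#' Plot method: image of the signed differential network
#'
#' Draws the q_signed matrix as a heat image (blue = type II / negative,
#' red = type I / positive).
#'
#' @param x A \code{"diffnet"} object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.diffnet <- function(x, ...) {
  m <- x$q_signed
  lim <- max(abs(m), 1e-12)
  pal <- grDevices::colorRampPalette(c("steelblue", "white", "firebrick"))(65)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  zlim = c(-lim, lim), col = pal, xlab = "gene", ylab = "gene",
                  main = paste0("Sign-adjusted ", x$metric), ...)
  invisible(x)
}

#' @export
residuals.diffnet <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("no residual step: fitted with residual_adjust = FALSE")
  }
  object$fit$residuals
}
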