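# ROC / partial-AUC evaluation and the reference methods needed for the
# benchmark comparison: sign-adjusted dCCN and the exhaustive LASSO
# interaction search.

#' ROC curve over gene-pair scores
#'
#' Sweeps a decision threshold over the distinct score values (ties grouped)
#' and accumulates true/false positive rates against a set of ground-truth
#' positive pairs. FPR is false positives over the number of negative pairs.
#' The curve always starts at (0,0) and ends at (1,1); the AUC is the
#' trapezoidal area, which equals the concordance probability
#' P(score_pos > score_neg) + P(tie)/2.
#'
#' @param scores Named nonnegative numeric vector over all gene pairs (names
#'   "j:k" as produced by [edge_scores()]), or unnamed with \code{truth}
#'   given as a logical/0-1 vector of the same length.
#' @param truth Character vector of positive pair keys (matched against
#'   \code{names(scores)}), or a logical/0-1 vector aligned with
#'   \code{scores}.
#' @return Object of class \code{"roc_result"}: list with nondecreasing
#'   \code{fpr}, \code{tpr} (including the (0,0) and (1,1) endpoints),
#'   \code{auc}, \code{n_pos}, \code{n_neg}.
#' @export
roc_curve <- function(scores, truth) {
  scores <- as.numeric0(scores)
  if (is.character(truth)) {
    if (is.null(names(scores))) stop("character truth requires named scores")
    pos <- names(scores) %in% truth
  } else {
    if (length(truth) != length(scores)) stop("truth length mismatch")
    pos <- as.logical(truth)
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 1L) stop("no positive pairs in truth")
  if (n_neg < 1L) stop("no negative pairs")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- pos[ord]
  # group tied scores: cumulative counts at the end of each tie block
  last_of_block <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(lab)[last_of_block]
  fp <- cumsum(!lab)[last_of_block]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @keywords internal
as.numeric0 <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  if (any(!is.finite(x))) stop("scores must be finite")
  if (any(x < 0)) stop("scores must be nonnegative")
  x
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", x$n_pos, "positive /", x$n_neg, "negative pairs: AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Standardized partial AUC up to an FPR bound
#'
#' Area under the ROC curve restricted to FPR in [0, bound], standardized
#' (McClish) so that a perfect classifier scores 1 and the chance diagonal
#' 0.5 regardless of the bound:
#' \deqn{0.5\,[1 + (A - A_{min}) / (A_{max} - A_{min})]}
#' with \eqn{A} the raw truncated area, \eqn{A_{min} = bound^2/2} (diagonal)
#' and \eqn{A_{max} = bound}. At bound = 1 this reduces to the ordinary AUC.
#' The curve is linearly interpolated at the bound.
#'
#' @param roc A [roc_curve()] result.
#' @param bound Upper FPR bound in ]0, 1].
#' @return Standardized partial AUC in [0, 1].
#' @export
partial_auc <- function(roc, bound = 0.2) {
  stopifnot(inherits(roc, "roc_result"))
  if (!(bound > 0 && bound <= 1)) stop("bound must be in ]0, 1]")
  fpr <- roc$fpr; tpr <- roc$tpr
  keep <- fpr <= bound
  f <- fpr[keep]; t <- tpr[keep]
  if (max(f) < bound) {
    # interpolate the curve at the bound
    i <- which(fpr > bound)[1L]
    t_at <- tpr[i - 1L] +
      (tpr[i] - tpr[i - 1L]) * (bound - fpr[i - 1L]) / (fpr[i] - fpr[i - 1L])
    f <- c(f, bound); t <- c(t, t_at)
  }
  area <- sum(diff(f) * (t[-1L] + t[-length(t)]) / 2)
  a_min <- bound^2 / 2
  0.5 * (1 + (area - a_min) / (bound - a_min))
}

#' Exhaustive LASSO interaction search
#'
#' The classic parametric reference: regress the phenotype on all p main
#' effects plus all p(p-1)/2 standardized pairwise product columns with an
#' L1 penalty (lambda by cross-validation), and score each pair by the
#' absolute coefficient of its product term.
#'
#' @param x Standardized expression matrix.
#' @param y Phenotype vector.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed (fold assignment).
#' @param max_pairs Guard: refuse more than this many product columns
#'   (default 50000) to bound memory.
#' @return Named numeric vector of pair scores ("j:k", j < k).
#' @export
exhaustive_lasso <- function(x, y, cv_folds = 10L, seed = 1L,
                             max_pairs = 50000L) {
  x <- as_expression_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("phenotype length mismatch")
  n_pairs <- p * (p - 1L) / 2L
  if (n_pairs > max_pairs) {
    stop(n_pairs, " product columns exceed max_pairs = ", max_pairs)
  }
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  prod_cols <- x[, idx[, 1L], drop = FALSE] * x[, idx[, 2L], drop = FALSE]
  psd <- apply(prod_cols, 2L, stats::sd)
  psd[psd == 0] <- 1
  prod_cols <- scale(prod_cols, center = TRUE, scale = psd)
  design <- cbind(x, prod_cols)
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv <- glmnet::cv.glmnet(design, y, alpha = 1, foldid = foldid,
                          standardize = FALSE)
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  stats::setNames(abs(cf[(p + 1L):(p + n_pairs)]),
                  paste0(idx[, 1L], ":", idx[, 2L]))
}

#' Median rank of the true pairs under a scoring
#'
#' Ranks all pairs by decreasing score (average rank for ties) and returns
#' the median rank of the ground-truth positive pairs; lower is better.
#'
#' @param scores Named pair scores.
#' @param truth Character vector of positive pair keys.
#' @return Median rank (numeric).
#' @export
true_pair_ranks <- function(scores, truth) {
  rk <- rank(-scores, ties.method = "average")
  stats::median(rk[names(scores) %in% truth])
}

#' Benchmark the differential-network methods on simulated phenotypes
#'
#' Runs the Table-style simulation comparison: a fixed expression backbone,
#' \code{replicates} fresh phenotype simulations from Model A (interaction
#' effects only) or Model B (plus strong main effects), each analyzed by the
#' requested methods, scored against the 14 ground-truth pairs with full and
#' truncated (FPR <= 0.2, mean-TPR-normalized) AUCs, and averaged over
#' replicates. Following the original design, Model A is analyzed with groups
#' on the raw phenotype (no residual adjustment) and Model B with residual
#' adjustment.
#'
#' @param methods Subset of \code{c("sign_dpccn", "sign_dccn",
#'   "exhaustive_lasso")}.
#' @param backbone Expression matrix to reuse across replicates, or NULL to
#'   generate one via [generate_backbone()] with \code{n}, \code{p}.
#' @param model \code{"A"} or \code{"B"}.
#' @param replicates Number of phenotype replicates (default 10).
#' @param seed Integer seed; replicate r uses seed + r.
#' @param n,p Backbone dimensions when \code{backbone} is NULL.
#' @param a Truncation point.
#' @param r Hard threshold of the zero rule.
#' @param progress Print per-replicate progress.
#' @return Data frame with one row per method: \code{method},
#'   \code{model}, \code{auc} (mean full AUC), \code{pauc} (mean truncated
#'   AUC at FPR 0.2), \code{replicates}. Per-replicate values attached as
#'   attribute \code{"per_replicate"}.
#' @export
run_benchmark <- function(methods = c("sign_dpccn", "sign_dccn",
                                      "exhaustive_lasso"),
                          backbone = NULL, model = c("A", "B"),
                          replicates = 10L, seed = 1L,
                          n = 191L, p = 231L, a = 0.5, r = 0.1,
                          progress = FALSE) {
  model <- match.arg(model)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(backbone)) {
    backbone <- generate_backbone(n = n, p = p, seed = seed)
  } else {
    backbone <- as_expression_matrix(backbone)
    if (!is_standardized(backbone)) backbone <- standardize_expression(backbone)
  }
  rule <- zero_rule(r = r)
  per <- expand.grid(method = methods, replicate = seq_len(replicates),
                     stringsAsFactors = FALSE)
  per$auc <- NA_real_; per$pauc <- NA_real_
  for (rep_i in seq_len(replicates)) {
    rep_seed <- seed + rep_i
    sim <- if (model == "A") {
      simulate_model_a(backbone, seed = rep_seed)
    } else {
      simulate_model_b(backbone, seed = rep_seed)
    }
    truth <- truth_pairs(sim$truth)
    adjust <- model == "B"
    for (m in methods) {
      scores <- switch(
        m,
        sign_dpccn = edge_scores(diffnet(sim$x, sim$y, a = a, metric = "dpccn",
                                         residual_adjust = adjust, rule = rule,
                                         seed = rep_seed)),
        sign_dccn = edge_scores(diffnet(sim$x, sim$y, a = a, metric = "dccn",
                                        residual_adjust = adjust, rule = rule,
                                        seed = rep_seed)),
        exhaustive_lasso = exhaustive_lasso(standardize_expression(sim$x),
                                            sim$y, seed = rep_seed)
      )
      rc <- roc_curve(scores, truth)
      row <- per$method == m & per$replicate == rep_i
      per$auc[row] <- rc$auc
      per$pauc[row] <- partial_auc(rc, 0.2)
    }
    if (progress) {
      message("replicate ", rep_i, "/", replicates, " done")
    }
  }
  out <- do.call(rbind, lapply(methods, function(m) {
    rows <- per[per$method == m, ]
    data.frame(method = m, model = model, auc = mean(rows$auc),
               pauc = mean(rows$pauc), replicates = replicates,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_replicate") <- per
  out
}
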