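# Synthetic-data engine: expression backbones with standard-normal marginals
# and phenotype models with known interaction ground truth (six product-term
# interactions, two ReLU activation terms, six disrupted co-expression pairs,
# optional strong main effects).

#' Generate an expression backbone
#'
#' Simulates an individuals x genes matrix with standard-normal marginals,
#' either fully independent columns or a block-correlation structure realized
#' by a closed-form one-factor construction per block
#' (\eqn{X = \sqrt{\rho} Z_{block} + \sqrt{1-\rho}\,E}). The default
#' dimensions n = 191, p = 231 mirror a typical proteomic cohort (191 AML
#' patients x 231 proteins). Columns are z-scored on the way out.
#'
#' @param n Number of individuals (>= 8).
#' @param p Number of genes (>= 2).
#' @param structure \code{"independent"} or \code{"block"}.
#' @param block_size Genes per correlated block (structure = "block").
#' @param rho Within-block correlation in [0, 1[.
#' @param seed Integer seed.
#' @return Standardized expression matrix with gene names g1..gp.
#' @export
generate_backbone <- function(n = 191L, p = 231L,
                              structure = c("independent", "block"),
                              block_size = 10L, rho = 0.6, seed = 1L) {
  structure <- match.arg(structure)
  n <- as.integer(n); p <- as.integer(p)
  if (n < 8L) stop("n must be >= 8")
  if (p < 2L) stop("p must be >= 2")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1[")
  x <- with_seed(seed, {
    e <- matrix(stats::rnorm(n * p), n, p)
    if (structure == "independent") {
      e
    } else {
      block <- ((seq_len(p) - 1L) %/% block_size) + 1L
      z <- matrix(stats::rnorm(n * max(block)), n, max(block))
      sqrt(rho) * z[, block, drop = FALSE] + sqrt(1 - rho) * e
    }
  })
  colnames(x) <- paste0("g", seq_len(p))
  standardize_expression(x)
}

#' Rectified product activation term
#'
#' Elementwise product of two gene columns, thresholded at its own empirical
#' median: values at or above the median are kept, the rest set to 0. This is
#' the activation/deactivation (type II) term used by the simulation models.
#'
#' @param xj,xk Numeric vectors of equal length.
#' @return Numeric vector of the same length.
#' @examples
#' relu_term(c(1, 1, 1, 1), c(1, 2, 3, 4))  # median 2.5 -> c(0, 0, 3, 4)
#' @export
relu_term <- function(xj, xk) {
  if (length(xj) != length(xk)) stop("length mismatch")
  prod <- xj * xk
  med <- stats::median(prod)
  ifelse(prod >= med, prod, 0)
}

#' Induce collinearity between gene pairs before truncation
#'
#' For each (target, source) pair the target column is overwritten, on all
#' rows, as source + N(0, noise_sd^2). With unit-variance sources and the
#' default noise_sd = 0.25 the induced correlation is
#' \eqn{(1 + 0.0625)^{-1/2} \approx 0.97}, mimicking the strong collinearities
#' between interacting genes that break plain differential-correlation
#' detection.
#'
#' @param x Expression matrix.
#' @param pairs List of integer pairs \code{c(target, source)}.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return The modified matrix (no longer flagged standardized).
#' @export
apply_collinearity <- function(x, pairs, noise_sd = 0.25, seed = 1L) {
  x <- as_expression_matrix(x)
  targets <- vapply(pairs, `[`, integer(1L), 1L)
  sources <- vapply(pairs, `[`, integer(1L), 2L)
  if (any(targets == sources)) stop("pair members must be distinct")
  if (anyDuplicated(targets)) stop("overlapping target columns")
  if (any(c(targets, sources) > ncol(x)) || any(c(targets, sources) < 1L)) {
    stop("pair index out of range")
  }
  with_seed(seed, {
    for (i in seq_along(pairs)) {
      x[, targets[i]] <- x[, sources[i]] + stats::rnorm(nrow(x), sd = noise_sd)
    }
  })
  attr(x, "standardized") <- FALSE
  x
}

#' Induce phenotype-conditional disrupted co-expression
#'
#' For individuals whose phenotype value is at or above the empirical
#' \code{cut_quantile} of y, the SECOND member of each pair is overwritten as
#' +/- (first member) + N(0, noise_sd^2); all other rows are untouched and y
#' itself is never recomputed. This creates a strong correlation present only
#' among high-phenotype individuals — the disrupted-pathway (type II)
#' interaction pattern.
#'
#' @param x Expression matrix.
#' @param y Phenotype vector used only to select rows.
#' @param pairs_with_sign List of \code{list(pair = c(j, k), sign = +1/-1)}.
#' @param cut_quantile Quantile of y above which rows are modified
#'   (default 4/5).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return The modified matrix.
#' @export
apply_disruption <- function(x, y, pairs_with_sign, cut_quantile = 4/5,
                             noise_sd = 0.25, seed = 1L) {
  x <- as_expression_matrix(x)
  if (length(y) != nrow(x)) stop("y length mismatch")
  if (any(!is.finite(y))) stop("y must be finite")
  if (cut_quantile <= 0) stop("cut_quantile must be in ]0, 1]")
  if (cut_quantile >= 1) return(x)  # degenerate: nothing to modify
  cut <- stats::quantile(y, probs = cut_quantile, type = 7, names = FALSE)
  rows <- y >= cut
  with_seed(seed, {
    for (ps in pairs_with_sign) {
      j <- ps$pair[1L]; k <- ps$pair[2L]
      if (max(j, k) > ncol(x) || min(j, k) < 1L) stop("pair index out of range")
      x[rows, k] <- ps$sign * x[rows, j] +
        stats::rnorm(sum(rows), sd = noise_sd)
    }
  })
  attr(x, "standardized") <- FALSE
  x
}

#' Interaction layout for the simulation models
#'
#' Returns the index sets defining which gene pairs carry which interaction
#' type. For p >= 231 these are the reference layout on a 231-protein panel:
#' six product-term (type I) pairs (75,150), (100,200), (125,215), (25,52),
#' (33,66), (88,144); two ReLU pairs (12,183), (109,54); six disrupted pairs
#' C-(2,170), C-(50,115), C-(44,99), C+(12,180), C+(60,125), C+(211,222);
#' collinear overwrites 125 <- 215 and 75 <- 150 (inside two of the type I
#' pairs); main-effect genes {10, 30, 50, 70, 90, 100} with coefficient 2.
#' For 32 <= p < 231 a scaled layout with the same architecture is used:
#' type I pairs (1,2)...(11,12), ReLU (13,14), (15,16), disrupted
#' C-(17,18), C-(19,20), C-(21,22), C+(23,24), C+(25,26), C+(27,28),
#' collinear overwrites 1 <- 2 and 5 <- 6, main effects {3, 17, 29, 30, 31,
#' 32} (two of which sit on interacting genes, as in the reference layout).
#'
#' @param p Number of genes.
#' @return List with \code{type1_pairs}, \code{relu_pairs},
#'   \code{disrupted} (list of pair + sign), \code{collinear_pairs}
#'   (target, source), \code{main_idx}, \code{main_beta}.
#' @export
interaction_config <- function(p) {
  if (p >= 231L) {
    list(
      type1_pairs = list(c(75L, 150L), c(100L, 200L), c(125L, 215L),
                         c(25L, 52L), c(33L, 66L), c(88L, 144L)),
      relu_pairs = list(c(12L, 183L), c(109L, 54L)),
      disrupted = list(list(pair = c(2L, 170L), sign = -1),
                       list(pair = c(50L, 115L), sign = -1),
                       list(pair = c(44L, 99L), sign = -1),
                       list(pair = c(12L, 180L), sign = 1),
                       list(pair = c(60L, 125L), sign = 1),
                       list(pair = c(211L, 222L), sign = 1)),
      collinear_pairs = list(c(125L, 215L), c(75L, 150L)),
      main_idx = c(10L, 30L, 50L, 70L, 90L, 100L),
      main_beta = 2
    )
  } else if (p >= 32L) {
    list(
      type1_pairs = list(c(1L, 2L), c(3L, 4L), c(5L, 6L),
                         c(7L, 8L), c(9L, 10L), c(11L, 12L)),
      relu_pairs = list(c(13L, 14L), c(15L, 16L)),
      disrupted = list(list(pair = c(17L, 18L), sign = -1),
                       list(pair = c(19L, 20L), sign = -1),
                       list(pair = c(21L, 22L), sign = -1),
                       list(pair = c(23L, 24L), sign = 1),
                       list(pair = c(25L, 26L), sign = 1),
                       list(pair = c(27L, 28L), sign = 1)),
      collinear_pairs = list(c(1L, 2L), c(5L, 6L)),
      main_idx = c(3L, 17L, 29L, 30L, 31L, 32L),
      main_beta = 2
    )
  } else {
    stop("need p >= 32 for the scaled interaction layout (got ", p, ")")
  }
}

#' All ground-truth positive pairs of a simulation truth object
#'
#' @param truth A truth list from [simulate_model_a()] / [simulate_model_b()].
#' @return Character vector of canonical pair keys "j:k" with j < k.
#' @export
truth_pairs <- function(truth) {
  pairs <- c(truth$type1_pairs, truth$relu_pairs,
             lapply(truth$disrupted, `[[`, "pair"))
  unique(vapply(pairs, function(pr) {
    paste0(min(pr), ":", max(pr))
  }, character(1L)))
}

#' Simulate a phenotype with interaction effects only (Model A)
#'
#' Builds a phenotype from six product-term (type I) interactions, two ReLU
#' activation (type II) terms, and Gaussian noise, then induces six disrupted
#' co-expression (type II) pairs conditional on the upper phenotype tail.
#' Order of operations: (1) collinearity overwrites inside two type I pairs
#' (before the phenotype is computed, so the products use the collinear
#' values); (2) phenotype = sum of six products + two ReLU terms +
#' N(0, noise_sd^2), intercept 0; (3) tail-conditional disruption of the six
#' designated pairs (y is not recomputed).
#'
#' @param x Expression backbone (p >= 32; p >= 231 for the reference layout).
#' @param seed Integer seed.
#' @param noise_sd Residual standard deviation (default 1.75).
#' @param config Interaction layout; defaults to
#'   \code{interaction_config(ncol(x))}.
#' @param cut_quantile Disruption cut (default 4/5).
#' @param disruption_noise_sd,collinearity_noise_sd Overwrite noise SDs.
#' @param collinearity Apply the collinearity overwrites (default TRUE).
#' @return List with \code{y} (phenotype vector), \code{truth} (ground-truth
#'   layout incl. \code{noise_sd} and, via [truth_pairs()], the 14 positive
#'   pairs), and \code{x} (the modified expression matrix).
#' @export
simulate_model_a <- function(x, seed = 1L, noise_sd = 1.75, config = NULL,
                             cut_quantile = 4/5, disruption_noise_sd = 0.25,
                             collinearity_noise_sd = 0.25,
                             collinearity = TRUE) {
  x <- as_expression_matrix(x)
  p <- ncol(x); n <- nrow(x)
  if (is.null(config)) config <- interaction_config(p)
  all_idx <- c(unlist(config$type1_pairs), unlist(config$relu_pairs),
               unlist(lapply(config$disrupted, `[[`, "pair")),
               unlist(config$collinear_pairs))
  if (any(all_idx > p) || any(all_idx < 1L)) stop("config index out of range")

  if (collinearity && length(config$collinear_pairs)) {
    x <- apply_collinearity(x, config$collinear_pairs,
                            noise_sd = collinearity_noise_sd,
                            seed = seed + 1L)
  }
  y <- with_seed(seed + 2L, {
    yy <- stats::rnorm(n, sd = noise_sd)
    for (pr in config$type1_pairs) yy <- yy + x[, pr[1L]] * x[, pr[2L]]
    for (pr in config$relu_pairs) yy <- yy + relu_term(x[, pr[1L]], x[, pr[2L]])
    yy
  })
  x <- apply_disruption(x, y, config$disrupted, cut_quantile = cut_quantile,
                        noise_sd = disruption_noise_sd, seed = seed + 3L)
  truth <- list(type1_pairs = config$type1_pairs,
                relu_pairs = config$relu_pairs,
                disrupted = config$disrupted,
                collinear_pairs = if (collinearity) config$collinear_pairs else list(),
                main_effects = stats::setNames(numeric(0), character(0)),
                noise_sd = noise_sd,
                disruption_quantile = cut_quantile,
                disruption_noise_sd = disruption_noise_sd)
  list(y = y, truth = truth, x = x)
}

#' Simulate a phenotype with interaction and strong main effects (Model B)
#'
#' The Model A phenotype plus six strong main effects (coefficient 2) and an
#' additional independent noise term of the same SD. The main effects make
#' the raw-phenotype truncation uninformative for interactions, which is what
#' the residual-adjustment step of [diffnet()] is designed to undo.
#'
#' @inheritParams simulate_model_a
#' @param extra_noise Add the second independent noise term (default TRUE,
#'   the additive reading of the model definition).
#' @return As [simulate_model_a()]; \code{truth$main_effects} maps the six
#'   gene indices to their coefficient.
#' @export
simulate_model_b <- function(x, seed = 1L, noise_sd = 1.75, config = NULL,
                             cut_quantile = 4/5, disruption_noise_sd = 0.25,
                             collinearity_noise_sd = 0.25,
                             collinearity = TRUE, extra_noise = TRUE) {
  if (is.null(config)) config <- interaction_config(ncol(as.matrix(x)))
  sim <- simulate_model_a(x, seed = seed, noise_sd = noise_sd, config = config,
                          cut_quantile = cut_quantile,
                          disruption_noise_sd = disruption_noise_sd,
                          collinearity_noise_sd = collinearity_noise_sd,
                          collinearity = collinearity)
  xb <- sim$x
  y <- sim$y + as.numeric(xb[, config$main_idx, drop = FALSE] %*%
                            rep(config$main_beta, length(config$main_idx)))
  if (extra_noise) {
    y <- y + with_seed(seed + 4L, stats::rnorm(nrow(xb), sd = noise_sd))
  }
  truth <- sim$truth
  truth$main_effects <- stats::setNames(rep(config$main_beta,
                                            length(config$main_idx)),
                                        config$main_idx)
  list(y = y, truth = truth, x = xb)
}

#' Write a simulated replicate to disk
#'
#' Writes the expression matrix and phenotype as TSV plus the ground truth as
#' a JSON sidecar.
#'
#' @param sim A list from [simulate_model_a()] or [simulate_model_b()].
#' @param prefix Output path prefix; writes \code{<prefix>_X.tsv},
#'   \code{<prefix>_y.tsv}, \code{<prefix>_truth.json}.
#' @return Invisibly, the three file paths.
#' @export
write_simulation <- function(sim, prefix) {
  px <- paste0(prefix, "_X.tsv")
  py <- paste0(prefix, "_y.tsv")
  pt <- paste0(prefix, "_truth.json")
  utils::write.table(format(sim$x, digits = 12, trim = TRUE), px, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(y = format(sim$y, digits = 12, trim = TRUE)),
                     py, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, pt, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(deparse(sim$truth), pt)
  }
  invisible(c(px, py, pt))
}
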