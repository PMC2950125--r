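#' Relative abundance profile
#'
#' Expression of a gene in each tissue as a fraction of its summed expression
#' across tissues. Scaling the input by any positive constant leaves the
#' profile unchanged. An all-zero input yields an undefined profile (all NA,
#' with attribute `undefined = TRUE`).
#'
#' @param x Non-negative intensity vector (optionally named by tissue).
#' @return Numeric vector summing to 1, or all-NA when undefined.
#' @examples
#' relative_abundance(c(liver = 1, brain = 1, testis = 2))
#' @export
relative_abundance <- function(x) {
  if (any(x < 0)) stop("intensities must be non-negative")
  tot <- sum(x)
  if (tot == 0) {
    out <- rep(NA_real_, length(x)); names(out) <- names(x)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- x / tot
  attr(out, "undefined") <- FALSE
  out
}

#' Relative abundance by row of an intensity matrix
#' @param m Non-negative genes x tissues matrix.
#' @return Matrix of row-wise profiles (all-zero rows become NA).
#' @export
ra_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("intensities must be non-negative")
  tot <- rowSums(m)
  out <- m / tot
  out[tot == 0, ] <- NA_real_
  out
}

#' Between-species expression divergence
#'
#' Divergence between two relative-abundance profiles on the same tissue
#' axis, computed as the sum over tissues of the squared RA difference (the
#' square of the Euclidean distance; bounded by 2 for probability vectors).
#'
#' @param a,b Relative-abundance vectors with matching tissue names/order.
#' @return Non-negative divergence score.
#' @examples
#' expression_divergence(c(1, 0), c(0, 1))   # 2, maximally disjoint
#' @export
expression_divergence <- function(a, b) {
  if (length(a) != length(b))
    stop("axis mismatch: profiles have different lengths")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("axis mismatch: tissue names differ or are ordered differently")
  sum((a - b)^2)
}

#' Compare divergence scores between gene groups
#'
#' Pairwise Wilcoxon rank-sum tests of divergence scores across groups (e.g.
#' age class x chromosome class), reporting the two-sided p and the one-sided
#' p that the first group's scores are larger.
#'
#' @param scores Numeric divergence scores.
#' @param groups Factor/character of group labels, same length.
#' @return data.frame: group1, group2, n1, n2, p_two, p_greater.
#' @export
group_divergence_compare <- function(scores, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least two non-empty groups")
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    x <- scores[groups == pr[1]]; y <- scores[groups == pr[2]]
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
               p_two = wilcoxon_rank_sum(x, y, "two")$p_value,
               p_greater = wilcoxon_rank_sum(x, y, "one_greater")$p_value)
  })
  do.call(rbind, out)
}

#' Exponential decay curve of the male-biased proportion
#'
#' `f(t) = N * (exp(r * t) * (1 - d) + d)` with gene age `t <= 0` in myr:
#' `N` is the male-biased proportion among brand-new genes (f(0) = N), `r`
#' the decay rate per myr, and `d` the asymptotic fraction of `N` retained by
#' the oldest genes (deep-time plateau `N * d`).
#'
#' @param t Ages in myr (non-positive).
#' @param N,r,d Model parameters (N > 0, r >= 0, 0 <= d <= 1).
#' @return f(t).
#' @export
decay_curve <- function(t, N, r, d) N * (exp(r * t) * (1 - d) + d)

decay_objective <- function(par, t, p, w)
  sum(w * (p - decay_curve(t, par[1], par[2], par[3]))^2)

#' Fit the male-bias decay model
#'
#' Fits `f(t) = N (e^{rt}(1-d) + d)` to per-branch male-biased proportions by
#' weighted nonlinear least squares (weights = genes per branch; Gaussian
#' maximum likelihood with variance proportional to 1/weight), under the
#' constraints N > 0, r >= 0, 0 <= d <= 1. Optimisation is multi-start:
#' a data-driven start (N from the youngest branch, d from the oldest/
#' youngest ratio, r on a coarse grid) plus jittered restarts from a fixed
#' internal seed, with box-constrained quasi-Newton refinement and a final
#' simplex polish.
#'
#' @param ages Branch midpoint ages in myr (all <= 0), at least 4 values.
#' @param proportions Observed male-biased proportions in \[0, 1\].
#' @param counts Genes per branch (weights); defaults to equal weights.
#' @param n_starts Number of jittered restarts (default 20).
#' @return An object of class `"decay_fit"` supporting `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' t <- c(-300, -150, -75, -30, -10, -3)
#' fit <- fit_decay(t, decay_curve(t, 0.9, 0.008, 0.22))
#' coef(fit)
#' @export
fit_decay <- function(ages, proportions, counts = NULL, n_starts = 20) {
  if (length(ages) < 4) stop("need at least 4 points to fit 3 parameters")
  if (length(proportions) != length(ages))
    stop("ages and proportions differ in length")
  if (any(ages > 0)) stop("ages must be <= 0 (myr before present)")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (is.null(counts)) counts <- rep(1, length(ages))
  if (length(counts) != length(ages) || any(counts <= 0))
    stop("counts must be positive, one per branch")
  lower <- c(1e-6, 0, 0); upper <- c(2, 2, 1)

  N0 <- max(proportions[which.max(ages)], 0.05)
  d0 <- min(max(proportions[which.min(ages)] / N0, 0.01), 0.99)
  starts <- lapply(c(0.002, 0.005, 0.01, 0.02, 0.05, 0.08, 0.15, 0.3),
                   function(r0) c(N0, r0, d0))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(20101005L)
  for (i in seq_len(max(0, n_starts - length(starts)))) {
    st <- c(N0, 0.05, d0) * exp(stats::runif(3, -0.7, 0.7))
    st <- pmin(pmax(st, lower + 1e-6), upper - c(0, 0, 1e-6))
    starts[[length(starts) + 1]] <- st
  }
  if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old_seed, envir = globalenv())

  obj <- function(par) decay_objective(par, ages, proportions, counts)
  best <- NULL
  trace_obj <- numeric(0)
  for (st in starts) {
    o <- try(stats::optim(st, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = 1e1, maxit = 1000,
                                         parscale = c(0.5, 0.02, 0.5))),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    trace_obj <- c(trace_obj, o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("decay fit failed to converge from every start")
  polish <- try(stats::optim(best$par, obj,
                             method = "L-BFGS-B", lower = lower, upper = upper,
                             control = list(factr = 1, maxit = 2000,
                                            parscale = pmax(abs(best$par), 1e-3))),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value)
    best <- polish
  nm <- try(stats::optim(best$par, function(q)
    obj(pmin(pmax(q, lower), upper)),
    method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 5000)), silent = TRUE)
  if (!inherits(nm, "try-error") && nm$value < best$value) {
    best$par <- pmin(pmax(nm$par, lower), upper)
    best$value <- nm$value
    best$convergence <- nm$convergence
  }
  par <- stats::setNames(best$par, c("N", "r", "d"))
  structure(list(coefficients = par, objective = best$value,
                 converged = best$convergence == 0,
                 n_starts = length(starts), start_objectives = trace_obj,
                 data = data.frame(age = ages, proportion = proportions,
                                   count = counts),
                 call = match.call()),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
fitted.decay_fit <- function(object, ...) {
  p <- object$coefficients
  decay_curve(object$data$age, p["N"], p["r"], p["d"])
}

#' @export
residuals.decay_fit <- function(object, ...)
  object$data$proportion - fitted(object)

#' @rdname fit_decay
#' @param object,x A `decay_fit`.
#' @param newdata Optional numeric ages (myr <= 0) at which to predict.
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$age else
    if (is.data.frame(newdata)) newdata$age else newdata
  p <- object$coefficients
  decay_curve(t, p["N"], p["r"], p["d"])
}

#' @export
print.decay_fit <- function(x, ...) {
  p <- x$coefficients
  cat("Exponential decay fit  f(t) = N (exp(rt)(1-d) + d)\n")
  cat(sprintf("  N = %.4g  r = %.4g /myr  d = %.4g\n", p["N"], p["r"], p["d"]))
  cat(sprintf("  initial proportion f(0) = %.3g, deep-time plateau N*d = %.3g\n",
              p["N"], p["N"] * p["d"]))
  cat(sprintf("  weighted RSS = %.4g over %d points (%sconverged)\n",
              x$objective, nrow(x$data), if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              plateau = unname(object$coefficients["N"] *
                               object$coefficients["d"]),
              objective = object$objective, converged = object$converged,
              residuals = residuals(object), n = nrow(object$data))
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("decay fit:", x$n, "points, weighted RSS", format(x$objective, digits = 4),
      "\n")
  print(x$coefficients)
  cat("plateau N*d =", format(x$plateau, digits = 4), "\n")
  cat("residual range:", format(range(x$residuals), digits = 3), "\n")
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$age, d$proportion, xlab = "branch midpoint age (myr)",
                 ylab = "male-biased proportion",
                 pch = 19, cex = 0.3 + sqrt(d$count / max(d$count)), ...)
  tt <- seq(min(d$age), 0, length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @rdname fit_decay
#' @param nsim Number of simulated proportion sets.
#' @param seed Optional integer seed.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- round(object$data$count)
  out <- replicate(nsim, stats::rbinom(length(mu), n, mu) / n)
  as.data.frame(out)
}
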