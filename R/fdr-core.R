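#' Rank merged PSMs by score
#'
#' Merged modified and unmodified PSMs are sorted in ascending order of their
#' score (hyperscore-like, higher = better). The worst PSM receives rank 1
#' and the best receives rank N. Ties keep the stable input order. Each
#' record is labelled by its target/decoy and modified/unmodified status,
#' giving the four subsets the group-specific FDR is built from.
#'
#' @param merged data.frame of canonical PSM records (see
#'   [read_psm_table()]); must contain `score`, `is_decoy`, `is_modified`.
#' @return a `ranked_psms` object: the input records with added `rank` and
#'   `label` columns. `label` is one of `target-unmodified`,
#'   `target-modified`, `decoy-unmodified`, `decoy-modified`.
#' @export
rank_psms <- function(merged) {
  merged <- data.table::as.data.table(merged)
  n <- nrow(merged)
  if (n == 0L) stop("cannot rank an empty PSM set", call. = FALSE)
  if (any(!is.finite(merged$score))) {
    stop("non-finite score at record(s): ",
         paste(utils::head(which(!is.finite(merged$score)), 5L),
               collapse = ", "), call. = FALSE)
  }
  ord <- order(merged$score)          # stable: ties keep input order
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  merged$rank <- rnk
  merged$label <- paste0(ifelse(merged$is_decoy, "decoy-", "target-"),
                         ifelse(merged$is_modified, "modified", "unmodified"))
  data.table::setattr(merged, "class",
                      c("ranked_psms", class(merged)))
  merged
}

#' Threshold grid over ranks
#'
#' Counts only change at ranks held by decoy PSMs, so the default grid is
#' the set of decoy ranks plus both range ends. `"all"` evaluates at every
#' rank; a numeric vector gives an explicit grid.
#'
#' @param ranked a [rank_psms()] result.
#' @param grid `"decoy"`, `"all"`, or an increasing numeric vector of ranks.
#' @return sorted integer vector of threshold ranks within 1..N.
#' @export
threshold_grid <- function(ranked, grid = "decoy") {
  n <- nrow(ranked)
  if (is.numeric(grid)) {
    g <- sort(unique(as.integer(grid)))
    if (length(g) == 0L || g[1] < 1L || g[length(g)] > n) {
      stop("numeric grid must lie within 1..N", call. = FALSE)
    }
    return(g)
  }
  grid <- match.arg(grid, c("decoy", "all"))
  if (grid == "all") return(seq_len(n))
  sort(unique(c(1L, ranked$rank[ranked$is_decoy], n)))
}

#' Cumulative count curves over score thresholds
#'
#' For each threshold rank r the curves count PSMs with rank >= r (scores at
#' or above the threshold): `N` target-unmodified, `N_k` target-modified,
#' `D` all decoys, `D_k` modified decoys, `T` all targets, and the global
#' FDR `D(r)/T(r)` over all PSMs. The global FDR is 0 where both counts are
#' zero and `NA` (flagged undefined) where targets vanish while decoys
#' remain.
#'
#' @param ranked a [rank_psms()] result.
#' @param grid threshold grid, see [threshold_grid()].
#' @param plus_one use the (D+1)/T decoy correction for the global FDR.
#' @return a `count_curves` data.table with columns `threshold`, `N`,
#'   `N_k`, `D`, `D_k`, `T`, `fdr`.
#' @export
count_curves <- function(ranked, grid = "decoy", plus_one = FALSE) {
  g <- threshold_grid(ranked, grid)
  n <- nrow(ranked)
  tail_count <- function(which_rows) {
    ind <- integer(n)
    ind[ranked$rank[which_rows]] <- 1L
    tc <- rev(cumsum(rev(ind)))
    tc[g]
  }
  N   <- tail_count(!ranked$is_decoy & !ranked$is_modified)
  N_k <- tail_count(!ranked$is_decoy &  ranked$is_modified)
  D   <- tail_count( ranked$is_decoy)
  D_k <- tail_count( ranked$is_decoy &  ranked$is_modified)
  Tt  <- N + N_k
  num <- if (plus_one) D + 1L else D
  fdr <- ifelse(Tt > 0L, num / Tt, ifelse(D > 0L, NA_real_, 0))
  out <- data.table::data.table(threshold = g, N = N, N_k = N_k,
                                D = D, D_k = D_k, T = Tt, fdr = fdr)
  data.table::setattr(out, "n_total", n)
  data.table::setattr(out, "class", c("count_curves", class(out)))
  out
}

#' Poisson error propagation for the gamma ratio
#'
#' Standard error of the ratio x/y of two Poisson counts, where x is the
#' number of modified false identifications and y the number of all false
#' identifications above a threshold:
#' \deqn{\sigma(x/y) = (x/y)\sqrt{1/x + 1/y}.}
#' Undefined (returned as `NA`) when either count is below 1, signalling
#' insufficient decoys at that threshold.
#'
#' @param x modified decoy count(s), x <= y.
#' @param y total decoy count(s).
#' @return numeric vector of propagated standard errors.
#' @export
error_propagation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (any(ok & (x > y))) stop("x must not exceed y", call. = FALSE)
  out <- rep(NA_real_, length(x))
  def <- ok & x >= 1 & y >= 1
  out[def] <- (x[def] / y[def]) * sqrt(1 / x[def] + 1 / y[def])
  out
}

#' Empirical gamma curve with stability mask
#'
#' The gamma parameter is the proportion of k-modified PSMs among all false
#' identifications. Its decoy-based estimate at each threshold is
#' `D_k(r)/D(r)`. As decoys thin out at high ranks the ratio becomes
#' unstable; thresholds whose Poisson error propagation exceeds
#' `sigma_cutoff` are masked out before regression.
#'
#' @param curves a [count_curves()] result.
#' @param sigma_cutoff maximum admissible error propagation (default 0.01).
#' @return a `gamma_curve` data.table with `threshold`, `D`, `D_k`,
#'   `gamma_hat`, `sigma`, `stable`.
#' @export
estimate_gamma_curve <- function(curves, sigma_cutoff = 0.01) {
  gamma_hat <- ifelse(curves$D > 0L, curves$D_k / curves$D, NA_real_)
  sigma <- error_propagation(curves$D_k, curves$D)
  stable <- !is.na(sigma) & sigma <= sigma_cutoff & curves$D > 0L
  if (!any(stable)) {
    stop("no threshold passes the error-propagation cutoff; ",
         "add decoys (e.g. more random proteins) or raise sigma_cutoff",
         call. = FALSE)
  }
  out <- data.table::data.table(threshold = curves$threshold,
                                D = curves$D, D_k = curves$D_k,
                                gamma_hat = gamma_hat, sigma = sigma,
                                stable = stable)
  data.table::setattr(out, "sigma_cutoff", sigma_cutoff)
  data.table::setattr(out, "class", c("gamma_curve", class(out)))
  out
}

#' Decoy/target ratio curve
#'
#' The ratio of the number of decoy PSMs to the number of target PSMs above
#' each threshold, used to locate the inflection point that anchors one
#' spline knot.
#'
#' @param curves a [count_curves()] result.
#' @return data.table with `threshold` and `rho = D/T`, restricted to
#'   thresholds with at least one target.
#' @export
decoy_target_ratio <- function(curves) {
  keep <- curves$T > 0L
  data.table::data.table(threshold = curves$threshold[keep],
                         rho = curves$D[keep] / curves$T[keep])
}

.gaussian_smooth <- function(v, spacing, sigma) {
  if (sigma <= 0) return(v)
  h <- as.integer(ceiling(4 * sigma / spacing))
  if (h < 1L) return(v)
  w <- stats::dnorm(seq(-h, h) * spacing, sd = sigma)
  w <- w / sum(w)
  n <- length(v)
  # reflect padding at both boundaries
  pad <- c(v[pmin(h + 1L, n):2L], v, v[(n - 1L):pmax(n - h, 1L)])
  if (h >= n) {  # very wide kernel relative to the series
    idx <- seq_len(n) + h
    return(vapply(idx, function(i) {
      lo <- i - h; hi <- i + h
      sel <- pmax(pmin(seq(lo, hi), length(pad)), 1L)
      sum(pad[sel] * w)
    }, 0))
  }
  as.numeric(stats::filter(pad, w, sides = 2))[seq_len(n) + h]
}

#' Inflection rank of the decoy/target ratio
#'
#' Takes the first derivative of the ratio curve by central finite
#' differences, smooths it with a Gaussian kernel (reflect padding at the
#' boundaries), and returns the grid rank attaining the global minimum of
#' the smoothed derivative — the steepest descent of the decoy/target ratio.
#' Ties resolve to the smallest rank.
#'
#' @param ratio a [decoy_target_ratio()] result (or any data.frame with
#'   `threshold` and `rho`).
#' @param smoothing_sigma Gaussian kernel width in rank units; default 2%
#'   of the grid span.
#' @return the anchor rank (a grid threshold value).
#' @export
find_inflection_rank <- function(ratio, smoothing_sigma = NULL) {
  ok <- is.finite(ratio$rho)
  x <- as.numeric(ratio$threshold[ok])
  y <- ratio$rho[ok]
  m <- length(x)
  if (m < 5L) stop("inflection undefined: ratio curve has fewer than 5 points",
                   call. = FALSE)
  if (is.unsorted(x)) { o <- order(x); x <- x[o]; y <- y[o] }
  if (is.null(smoothing_sigma)) smoothing_sigma <- 0.02 * (x[m] - x[1])
  d <- numeric(m)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[m] <- (y[m] - y[m - 1]) / (x[m] - x[m - 1])
  if (m > 2L) d[2:(m - 1)] <- (y[3:m] - y[1:(m - 2)]) / (x[3:m] - x[1:(m - 2)])
  spacing <- stats::median(diff(x))
  ds <- .gaussian_smooth(d, spacing, smoothing_sigma)
  x[which.min(ds)]
}

#' @rdname fit_spline_linear_gamma
#' @export
fit_linear_gamma <- function(curve) {
  pts <- curve[curve$stable & !is.na(curve$gamma_hat), ]
  if (nrow(pts) < 2L) {
    stop("linear gamma fit needs at least 2 stable thresholds", call. = FALSE)
  }
  fit <- stats::lm(gamma_hat ~ threshold, data = pts)
  cf <- stats::coef(fit)
  .new_spline_model(nodes = range(pts$threshold),
                    a = unname(cf[1]), b = unname(cf[2]),
                    anchor = NA_real_, anchored = FALSE,
                    fitted = stats::fitted(fit), observed = pts$gamma_hat,
                    n_points = nrow(pts), method = "linear")
}

.new_spline_model <- function(nodes, a, b, anchor, anchored, fitted, observed,
                              n_points, method, dropped_knots = numeric()) {
  res <- observed - fitted
  sstot <- sum((observed - mean(observed))^2)
  ssres <- sum(res^2)
  structure(list(nodes = nodes, a = a, b = b, anchor = anchor,
                 anchored = anchored,
                 r2 = if (sstot > 0) 1 - ssres / sstot else NA_real_,
                 rmse = sqrt(mean(res^2)), n_points = n_points,
                 method = method, dropped_knots = dropped_knots),
            class = "spline_linear_model")
}

#' @export
print.spline_linear_model <- function(x, ...) {
  cat(sprintf("%s gamma model: %d segment(s), fitted on %d thresholds\n",
              x$method, length(x$a), x$n_points))
  cat("  nodes:", paste(signif(x$nodes, 6), collapse = ", "), "\n")
  if (isTRUE(x$anchored)) cat("  anchor node:", x$anchor, "\n")
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g\n", x$r2, x$rmse))
  invisible(x)
}

#' Spline-linear regression of the gamma curve
#'
#' Fits the modified-decoy proportion gamma as a continuous piecewise-linear
#' function of rank over the stable thresholds,
#' \deqn{\gamma(x) = a_i + b_i x, \quad x_{i-1} \le x \le x_i,}
#' by least squares on a hinge (truncated power) basis. The boundary nodes
#' sit at the ends of the stable range; `n_interior_knots` interior knots
#' are equally spaced, with the knot nearest `anchor` replaced by the anchor
#' rank (the inflection point of the decoy/target ratio) so that exactly one
#' node is rooted there. An anchor outside the stable range falls back to
#' the spaced knots and flags the model; a segment left with fewer than two
#' stable points drops its knot with a warning.
#'
#' `fit_linear_gamma()` is the single-segment special case (ordinary least
#' squares of gamma on rank), retained for comparison with the original
#' linear transferred-FDR formulation.
#'
#' @param curve an [estimate_gamma_curve()] result.
#' @param anchor anchor rank from [find_inflection_rank()].
#' @param n_interior_knots number of interior knots including the anchor
#'   (default 3).
#' @return a `spline_linear_model`: nodes `x_0 < ... < x_n`, per-segment
#'   coefficients `a`, `b`, the anchor, and fit diagnostics `r2`, `rmse`
#'   computed on the stable thresholds.
#' @export
fit_spline_linear_gamma <- function(curve, anchor, n_interior_knots = 3L) {
  pts <- curve[curve$stable & !is.na(curve$gamma_hat), ]
  if (nrow(pts) < n_interior_knots + 2L) {
    stop(sprintf("spline fit needs at least %d stable thresholds, have %d",
                 n_interior_knots + 2L, nrow(pts)), call. = FALSE)
  }
  x <- pts$threshold; y <- pts$gamma_hat
  x0 <- min(x); xn <- max(x)
  if (n_interior_knots == 0L) {
    m <- fit_linear_gamma(curve)
    m$method <- "spline-linear"
    return(m)
  }
  spaced <- seq(x0, xn, length.out = n_interior_knots + 2L)
  knots <- spaced[-c(1L, length(spaced))]
  anchored <- !is.na(anchor) && anchor > x0 && anchor < xn
  if (anchored) {
    knots[which.min(abs(knots - anchor))] <- anchor
  } else {
    warning("anchor rank outside the stable range; using spaced knots only",
            call. = FALSE)
  }
  knots <- sort(unique(knots))
  dropped <- numeric()
  repeat {
    nodes <- c(x0, knots, xn)
    seg_n <- vapply(seq_len(length(nodes) - 1L), function(i) {
      sum(x >= nodes[i] & x <= nodes[i + 1L])
    }, 0L)
    if (all(seg_n >= 2L) || length(knots) == 0L) break
    thin <- which.min(seg_n)
    # drop a knot bounding the thinnest segment, sparing the anchor if we can
    cand <- unique(c(thin - 1L, thin))
    cand <- cand[cand >= 1L & cand <= length(knots)]
    not_anchor <- cand[!anchored | knots[cand] != anchor]
    drop_i <- if (length(not_anchor)) not_anchor[1L] else cand[1L]
    warning(sprintf("segment with <2 stable points: dropping knot at rank %s",
                    format(knots[drop_i])), call. = FALSE)
    dropped <- c(dropped, knots[drop_i])
    knots <- knots[-drop_i]
  }
  if (length(knots) == 0L) {
    m <- fit_linear_gamma(curve)
    m$method <- "spline-linear"
    m$dropped_knots <- dropped
    return(m)
  }
  hinges <- vapply(knots, function(k) pmax(x - k, 0), numeric(length(x)))
  X <- cbind(1, x, hinges)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  if (anyNA(cf)) {  # collinear hinge (e.g. knot at a data gap): drop and refit
    bad <- which(is.na(cf)) - 2L
    bad <- bad[bad >= 1L]
    dropped <- c(dropped, knots[bad])
    knots <- knots[-bad]
    hinges <- vapply(knots, function(k) pmax(x - k, 0), numeric(length(x)))
    X <- cbind(1, x, hinges)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
  }
  nseg <- length(knots) + 1L
  d <- if (length(knots)) cf[-(1:2)] else numeric()
  b <- cf[2] + c(0, cumsum(d))
  a <- cf[1] + c(0, cumsum(-d * knots))
  .new_spline_model(nodes = c(x0, knots, xn), a = unname(a), b = unname(b),
                    anchor = if (anchored) anchor else NA_real_,
                    anchored = anchored,
                    fitted = as.numeric(X %*% cf), observed = y,
                    n_points = length(x), method = "spline-linear",
                    dropped_knots = dropped)
}

#' Evaluate a gamma model at given ranks
#'
#' Piecewise evaluation of a fitted spline-linear (or linear) gamma model.
#' Ranks beyond the last node are extrapolated with the last segment's
#' coefficients; ranks before the first node use the first segment. Since
#' gamma is a proportion, results are clipped to \[0, 1\].
#'
#' @param model a [fit_spline_linear_gamma()] or [fit_linear_gamma()] result.
#' @param r numeric vector of ranks.
#' @param clip clip the result into \[0,1\] (default `TRUE`).
#' @return numeric vector of gamma values.
#' @export
evaluate_gamma <- function(model, r, clip = TRUE) {
  nseg <- length(model$a)
  idx <- findInterval(r, model$nodes)
  idx <- pmin(pmax(idx, 1L), nseg)
  g <- model$a[idx] + model$b[idx] * r
  if (clip) g <- pmin(pmax(g, 0), 1)
  g
}

#' @export
predict.spline_linear_model <- function(object, r, ...) {
  evaluate_gamma(object, r)
}

#' Transferred FDR curve for the modified group
#'
#' The group-specific (transferred) FDR at threshold rank r rescales the
#' global FDR by the unmodified/modified target ratio and the modelled
#' modified fraction of false identifications:
#' \deqn{\widehat{FDR}_k(r) = \frac{N(r)}{N_k(r)} \gamma_k(r) \, FDR(r).}
#' Thresholds with no modified targets above them are skipped. Values are
#' not truncated; monotonization happens in [qvalues_and_threshold()].
#'
#' By the source formulation `N(r)` counts target identifications *without*
#' the modification; `n_definition = "all_targets"` switches the numerator
#' to all targets `T(r)` instead.
#'
#' @param curves a [count_curves()] result.
#' @param model a fitted gamma model.
#' @param n_definition `"unmodified"` (default) or `"all_targets"`.
#' @return data.table with `threshold` and `fdr_k`.
#' @export
transferred_fdr_curve <- function(curves, model,
                                  n_definition = c("unmodified",
                                                   "all_targets")) {
  n_definition <- match.arg(n_definition)
  keep <- curves$N_k > 0L & !is.na(curves$fdr)
  num <- if (n_definition == "unmodified") curves$N else curves$T
  g <- evaluate_gamma(model, curves$threshold)
  data.table::data.table(
    threshold = curves$threshold[keep],
    fdr_k = (num[keep] / curves$N_k[keep]) * g[keep] * curves$fdr[keep])
}

#' Separate (subset-only) FDR for the modified group
#'
#' Classical target-decoy estimation restricted to the modified subset:
#' `FDR_sep(r) = D_k(r) / T_k(r)` over thresholds within the subset, with
#' q-values by running minimum over more permissive thresholds. Unstable
#' when modified decoys are scarce; with no modified decoys at all the
#' q-values are identically 0 and the result is flagged as a low-confidence
#' estimate (attribute `low_confidence`).
#'
#' @param ranked a [rank_psms()] result.
#' @return data.table with `threshold`, `fdr_sep`, `q` over the modified
#'   subset's threshold grid (empty when the subset has no targets).
#' @export
separate_fdr_curve <- function(ranked) {
  sub <- ranked[ranked$is_modified, ]
  if (sum(!sub$is_decoy) == 0L) {
    out <- data.table::data.table(threshold = integer(),
                                  fdr_sep = numeric(), q = numeric())
    data.table::setattr(out, "low_confidence", TRUE)
    return(out)
  }
  g <- sort(unique(c(min(sub$rank), sub$rank[sub$is_decoy], max(sub$rank))))
  D_k <- vapply(g, function(r) sum(sub$is_decoy & sub$rank >= r), 0L)
  T_k <- vapply(g, function(r) sum(!sub$is_decoy & sub$rank >= r), 0L)
  fdr <- ifelse(T_k > 0L, D_k / T_k, NA_real_)
  keep <- !is.na(fdr)
  out <- data.table::data.table(threshold = g[keep], fdr_sep = fdr[keep])
  out$q <- cummin(out$fdr_sep)
  data.table::setattr(out, "low_confidence", all(D_k == 0L))
  out
}

#' q-values, acceptance and the rank threshold
#'
#' Monotonizes an FDR curve into q-values — the minimal FDR level at which
#' the acceptance set containing a given threshold would be accepted,
#' computed as the running minimum over more permissive (lower-rank)
#' thresholds — and determines the minimal accepting rank at level `alpha`.
#' When `ranked` is supplied, each modified target PSM is annotated with its
#' transferred FDR, q-value and accept flag (a PSM is accepted iff its rank
#' is at or above the rank threshold, equivalently iff its q-value is at or
#' below `alpha`).
#'
#' @param fdr_curve data.table with `threshold` and an FDR value column
#'   (`fdr_k` or `fdr_sep`).
#' @param alpha acceptance level (default 0.01).
#' @param ranked optional [rank_psms()] result for per-PSM annotation.
#' @return list with `curve` (threshold, fdr, q, accepted), `threshold_rank`
#'   (`NA` when no rank achieves q <= alpha), `alpha`, and `annotations`
#'   (per modified target PSM, or `NULL`).
#' @export
qvalues_and_threshold <- function(fdr_curve, alpha = 0.01, ranked = NULL) {
  if (nrow(fdr_curve) == 0L) {
    return(list(curve = data.table::data.table(threshold = integer(),
                                               fdr = numeric(), q = numeric(),
                                               accepted = logical()),
                threshold_rank = NA_integer_, alpha = alpha,
                annotations = NULL))
  }
  valcol <- intersect(c("fdr_k", "fdr_sep", "fdr"), names(fdr_curve))[1]
  o <- order(fdr_curve$threshold)
  cur <- data.table::data.table(threshold = fdr_curve$threshold[o],
                                fdr = fdr_curve[[valcol]][o])
  cur$q <- cummin(cur$fdr)
  cur$accepted <- cur$q <= alpha
  thr <- if (any(cur$accepted)) min(cur$threshold[cur$accepted])
         else NA_integer_
  ann <- NULL
  if (!is.null(ranked)) {
    mt <- ranked[!ranked$is_decoy & ranked$is_modified, ]
    if (nrow(mt)) {
      pos <- findInterval(mt$rank, cur$threshold)
      qv <- ifelse(pos >= 1L, cur$q[pmax(pos, 1L)], NA_real_)
      fv <- ifelse(pos >= 1L, cur$fdr[pmax(pos, 1L)], NA_real_)
      ann <- data.table::data.table(
        file = mt$file, scan = mt$scan, charge = mt$charge,
        peptide = mt$peptide, modifications = mt$modifications,
        proteins = mt$proteins, score = mt$score, rank = mt$rank,
        transferred_fdr = fv, q_value = qv,
        accepted = !is.na(thr) & mt$rank >= thr)
      if ("is_correct" %in% names(mt)) ann$is_correct <- mt$is_correct
    }
  }
  list(curve = cur, threshold_rank = thr, alpha = alpha, annotations = ann)
}

#' @export
plot.gamma_curve <- function(x, model = NULL, ...) {
  graphics::plot(x$threshold, x$gamma_hat,
                 col = ifelse(x$stable, "steelblue", "grey70"), pch = 16,
                 cex = 0.5, xlab = "rank threshold",
                 ylab = expression(hat(gamma)), ...)
  if (!is.null(model)) {
    r <- seq(min(x$threshold), max(x$threshold), length.out = 400)
    graphics::lines(r, evaluate_gamma(model, r), col = "firebrick", lwd = 2)
    graphics::abline(v = model$nodes, lty = 3, col = "grey50")
  }
  invisible(x)
}
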