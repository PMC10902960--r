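#' Fit a segmented log-linear (joinpoint) model with fixed breakpoints
#'
#' Least-squares fit of `ln y` on the continuous hinge design
#' `{1, t, (t - T_1)_+, ..., (t - T_k)_+}`: the fitted log-curve is
#' piecewise linear and continuous at every breakpoint. The slope of
#' segment `s` is the first-segment slope plus the slope changes at all
#' earlier breakpoints.
#'
#' @param times Observation times (years), strictly increasing.
#' @param values Positive series (the model is linear in `ln y`).
#' @param breakpoints Breakpoint times, strictly increasing and strictly
#'   inside `range(times)`; may be empty (ordinary log-linear regression).
#' @param min_segment Minimum number of observations strictly between
#'   consecutive breakpoints (and between a breakpoint and either end).
#' @return Object of class `joinpoint_fit`: coefficients, `vcov`,
#'   `breakpoints`, per-segment `slopes` with `slope_se`, residual `df`,
#'   `sse`, fitted values and residuals on the log scale, and the input
#'   series.
#' @export
fit_segments <- function(times, values, breakpoints = numeric(0),
                         min_segment = 2) {
  n <- length(times)
  if (length(values) != n) stop("times/values length mismatch", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values <= 0))
    stop("log-linear model requires positive series", call. = FALSE)
  breakpoints <- sort(breakpoints)
  if (length(breakpoints)) {
    if (any(breakpoints <= min(times)) || any(breakpoints >= max(times)))
      stop("breakpoints must lie strictly inside the time range",
           call. = FALSE)
    bounds <- c(-Inf, breakpoints, Inf)
    for (s in seq_len(length(bounds) - 1)) {
      inner <- sum(times > bounds[s] & times < bounds[s + 1])
      if (inner < min_segment)
        stop("degenerate segment: fewer than ", min_segment,
             " observations strictly between ",
             if (is.finite(bounds[s])) bounds[s] else "start", " and ",
             if (is.finite(bounds[s + 1])) bounds[s + 1] else "end",
             call. = FALSE)
    }
  }
  X <- joinpoint_design(times, breakpoints)
  fit <- stats::lm.fit(X, log(values))
  p <- ncol(X)
  df <- n - p
  sse <- sum(fit$residuals^2)
  sigma2 <- sse / df
  XtXinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  vcov <- sigma2 * XtXinv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  k <- length(breakpoints)
  # slope of segment s = beta_1 + sum of the first (s-1) slope changes
  L <- cbind(0, 1, if (k) outer(seq_len(k + 1), seq_len(k), `>`) * 1)
  slopes <- as.vector(L %*% fit$coefficients)
  slope_se <- sqrt(diag(L %*% vcov %*% t(L)))
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                colnames(X)),
                 vcov = vcov, breakpoints = breakpoints,
                 slopes = slopes, slope_se = slope_se, slope_contrast = L,
                 df = df, sse = sse, sigma2 = sigma2,
                 fitted = as.vector(X %*% fit$coefficients),
                 residuals = as.vector(fit$residuals),
                 times = times, values = values),
            class = "joinpoint_fit")
}

joinpoint_design <- function(times, breakpoints) {
  X <- cbind(`(Intercept)` = 1, t = times)
  for (b in breakpoints) X <- cbind(X, pmax(times - b, 0))
  if (length(breakpoints))
    colnames(X)[-(1:2)] <- paste0("hinge_", breakpoints)
  X
}

#' @export
print.joinpoint_fit <- function(x, ...) {
  k <- length(x$breakpoints)
  cat(sprintf("<joinpoint_fit> %d joinpoint%s%s, %d segment%s\n",
              k, if (k == 1) "" else "s",
              if (k) paste0(" (", paste(x$breakpoints, collapse = ", "), ")")
              else "",
              k + 1, if (k) "s" else ""))
  print(apc(x))
  invisible(x)
}

#' Select the number of joinpoints
#'
#' Exhaustive grid search over breakpoint placements at the observed time
#' points (respecting the minimum-segment rule), keeping the best
#' least-squares fit for each number of joinpoints `k = 0..max_joinpoints`,
#' then choosing `k` by an information criterion. Plain BIC is
#' `n ln(SSE/n) + p ln(n)` with `p = 2(k+1)` effective parameters (each
#' joinpoint contributes a slope change and an estimated location). The
#' default weighted BIC adds one further penalty unit per joinpoint
#' (`p = 3k + 2`), weighting breakpoints more heavily on short series to
#' guard against overfitting. Deterministic given inputs.
#'
#' @inheritParams fit_segments
#' @param max_joinpoints Largest number of joinpoints to consider.
#' @param criterion `"weighted_bic"` (default) or `"bic"`.
#' @return The selected `joinpoint_fit`, with attributes `criterion` (the
#'   name) and `criterion_table` (a tibble of `k`, best `sse`, criterion
#'   value).
#' @export
select_model <- function(times, values, max_joinpoints = 3,
                         criterion = c("weighted_bic", "bic"),
                         min_segment = 2) {
  criterion <- match.arg(criterion)
  n <- length(times)
  if (any(values <= 0))
    stop("log-linear model requires positive series", call. = FALSE)
  # candidate break indices: >= min_segment obs strictly on each side
  lo <- min_segment + 1
  hi <- n - min_segment
  feasible_k <- if (hi < lo) 0 else
    min(max_joinpoints, floor((hi - lo) / (min_segment + 1)) + 1)
  if (feasible_k < max_joinpoints)
    stop("series of length ", n, " supports at most ", feasible_k,
         " joinpoint(s) with min_segment = ", min_segment, call. = FALSE)
  logy <- log(values)
  best <- vector("list", max_joinpoints + 1)
  rows <- list()
  for (k in 0:max_joinpoints) {
    combos <- if (k == 0) list(integer(0)) else
      spaced_combinations(lo:hi, k, gap = min_segment + 1)
    sse_best <- Inf; idx_best <- NULL
    for (idx in combos) {
      X <- joinpoint_design(times, times[idx])
      r <- stats::.lm.fit(X, logy)$residuals
      sse <- sum(r^2)
      if (sse < sse_best) { sse_best <- sse; idx_best <- idx }
    }
    p_eff <- 2 * (k + 1)
    # floor the SSE so (numerically) perfect fits are ranked by penalty alone
    sse_best <- max(sse_best, n * .Machine$double.eps^0.75)
    crit <- n * log(sse_best / n) +
      switch(criterion,
             bic = p_eff * log(n),
             weighted_bic = (p_eff + k) * log(n))
    best[[k + 1]] <- list(k = k, idx = idx_best, sse = sse_best, crit = crit)
    rows[[k + 1]] <- tibble::tibble(k = k, sse = sse_best, criterion = crit)
  }
  tab <- do.call(rbind, rows)
  pick <- best[[which.min(tab$criterion)]]
  fit <- fit_segments(times, values, breakpoints = times[pick$idx],
                      min_segment = min_segment)
  attr(fit, "criterion") <- criterion
  attr(fit, "criterion_table") <- tab
  fit
}

# all k-subsets of positions with consecutive elements >= gap apart
spaced_combinations <- function(positions, k, gap) {
  out <- list()
  m <- length(positions)
  recurse <- function(start, chosen) {
    if (length(chosen) == k) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    if (start > m) return()
    for (i in start:m) {
      if (length(chosen) && positions[i] - chosen[length(chosen)] < gap) next
      recurse(i + 1, c(chosen, positions[i]))
    }
  }
  if ((k - 1) * gap + 1 <= m) recurse(1, integer(0))
  out
}

#' Annual percentage change per segment
#'
#' On the log scale each segment has constant slope `b`, so the fitted
#' series changes by a constant `APC = (exp(b) - 1) * 100` percent per
#' year within the segment. Confidence intervals exponentiate the
#' t-interval of the slope; the p-value tests the slope against zero.
#'
#' @param fit A `joinpoint_fit`.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with one row per segment: `segment`, `start`, `end`,
#'   `slope`, `apc`, `lo`, `hi`, `p_value`.
#' @export
apc <- function(fit, conf = 0.95) {
  edges <- c(min(fit$times), fit$breakpoints, max(fit$times))
  tq <- stats::qt(1 - (1 - conf) / 2, fit$df)
  b <- fit$slopes; se <- fit$slope_se
  tibble::tibble(
    segment = seq_along(b),
    start = edges[-length(edges)],
    end = edges[-1],
    slope = b,
    apc = (exp(b) - 1) * 100,
    lo = (exp(b - tq * se) - 1) * 100,
    hi = (exp(b + tq * se) - 1) * 100,
    p_value = 2 * stats::pt(abs(b / se), fit$df, lower.tail = FALSE))
}

#' Average annual percentage change
#'
#' The segment-length-weighted geometric summary across segments:
#' `AAPC = (exp(sum(w_i b_i) / sum(w_i)) - 1) * 100`, where `b_i` is the
#' log-scale slope of segment `i` and `w_i` the number of years it spans.
#' With a single segment, AAPC equals that segment's APC.
#'
#' `aapc()` is generic: applied to a `joinpoint_fit` it derives slopes,
#' weights and a delta-method confidence interval from the fitted
#' covariance; applied to a numeric vector of per-segment APCs (percent)
#' it needs the segment-length weights explicitly and returns the point
#' summary (with a CI only if slope standard errors are supplied).
#'
#' @param x A `joinpoint_fit` or numeric vector of per-segment APCs.
#' @param ... Passed on to methods.
#' @return Tibble with `aapc`, `lo`, `hi`, `p_value` (CI columns `NA` when
#'   no uncertainty information is available).
#' @export
#' @examples
#' aapc(c(1.09, 0.43, 1.01, 0.51), weights = c(7, 8, 4, 11))
aapc <- function(x, ...) UseMethod("aapc")

#' @rdname aapc
#' @param weights Years per segment (positive, same length as the APCs).
#' @param ses Optional standard errors of the log-scale segment slopes.
#' @param df Residual degrees of freedom for the t-interval.
#' @param conf Confidence level.
#' @export
aapc.default <- function(x, weights, ses = NULL, df = Inf, conf = 0.95, ...) {
  if (length(x) != length(weights))
    stop("APCs and weights must have equal length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(x <= -100))
    stop("APC <= -100% has no log-scale slope", call. = FALSE)
  b <- log(1 + x / 100)
  wb <- sum(weights * b) / sum(weights)
  est <- (exp(wb) - 1) * 100
  if (is.null(ses))
    return(tibble::tibble(aapc = est, lo = NA_real_, hi = NA_real_,
                          p_value = NA_real_))
  se <- sqrt(sum((weights / sum(weights))^2 * ses^2))
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  tibble::tibble(aapc = est,
                 lo = (exp(wb - tq * se) - 1) * 100,
                 hi = (exp(wb + tq * se) - 1) * 100,
                 p_value = 2 * stats::pt(abs(wb / se), df,
                                         lower.tail = FALSE))
}

#' @rdname aapc
#' @export
aapc.joinpoint_fit <- function(x, conf = 0.95, ...) {
  edges <- c(min(x$times), x$breakpoints, max(x$times))
  w <- diff(edges)
  # weighted mean slope is a linear combination of the coefficients
  a <- as.vector(t(w / sum(w)) %*% x$slope_contrast)
  wb <- sum(a * x$coefficients)
  se <- sqrt(as.vector(t(a) %*% x$vcov %*% a))
  tq <- stats::qt(1 - (1 - conf) / 2, x$df)
  tibble::tibble(aapc = (exp(wb) - 1) * 100,
                 lo = (exp(wb - tq * se) - 1) * 100,
                 hi = (exp(wb + tq * se) - 1) * 100,
                 p_value = 2 * stats::pt(abs(wb / se), x$df,
                                         lower.tail = FALSE))
}
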