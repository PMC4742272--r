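# Cohort statistics layer: two-sample comparisons, 2x2 outcome tables,
# ROC/AUC, interobserver ICC. Standard tests are delegated to stats::
# (t.test, chisq.test, fisher.test, wilcox.test); the exact Mann-Whitney
# path is enumerated here because the stock exact path refuses tied data,
# and ICC(2,1) is coded from its ANOVA decomposition (no ICC package in the
# dependency set).

#' Compare two continuous samples
#'
#' Student's t (pooled variance) or the Mann-Whitney U test, two-sided. The
#' U test enumerates the full permutation distribution of U (midranks, so
#' ties are handled exactly) whenever the number of group assignments is
#' small enough (`choose(n1 + n2, n1) <= 2e5`, which covers samples up to
#' ~10 per arm); larger samples use the normal approximation with tie
#' correction.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param method `"t"` or `"mann_whitney"`.
#' @return A list with `method`, `statistic` (t or U), `p` (two-sided),
#'   and `exact` (logical, U test only).
#' @export
compare_continuous <- function(x, y, method = c("t", "mann_whitney")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (method == "t") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stop("degenerate samples: zero variance in both groups")
    ht <- stats::t.test(x, y, var.equal = TRUE)
    return(list(method = "t", statistic = unname(ht$statistic),
                p = ht$p.value, exact = NA))
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= 2e5) {
    u_all <- mann_whitney_enumerate(r, n1)
    p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    return(list(method = "mann_whitney", statistic = u_obs, p = p, exact = TRUE))
  }
  hw <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(method = "mann_whitney", statistic = u_obs, p = hw$p.value, exact = FALSE)
}

# all attainable U statistics over group-label permutations (midranks)
mann_whitney_enumerate <- function(r, n1) {
  idx <- utils::combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Event-rate comparison on a 2x2 outcome table
#'
#' Rows are groups, columns are (event, no event). Reports per-group event
#' percentages rounded half-up to integers (the presentation convention of
#' clinical outcome tables) and a two-sided test: chi-square without
#' continuity correction (df = 1) or Fisher's exact test. With
#' `method = "auto"` Fisher is chosen when any expected count is below 5.
#'
#' @param tbl 2x2 numeric matrix of non-negative integer counts
#'   `rbind(group1 = c(events, no_events), group2 = ...)`.
#' @param method `"auto"`, `"chi_square"` or `"fisher"`.
#' @return A list with `rates` (exact percentages), `rates_rounded`
#'   (half-up integers), `method`, `statistic` (chi-square only), `p`.
#' @export
event_rate_test <- function(tbl, method = c("auto", "chi_square", "fisher")) {
  method <- match.arg(method)
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == 2L)) stop("tbl must be 2x2")
  if (any(tbl < 0) || any(tbl != round(tbl))) stop("counts must be non-negative integers")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    stop("zero-margin table: a row or column has no observations")
  rates <- 100 * tbl[, 1] / rowSums(tbl)
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  if (method == "auto") method <- if (any(expected < 5)) "fisher" else "chi_square"
  if (method == "chi_square") {
    ht <- stats::chisq.test(tbl, correct = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- stats::fisher.test(tbl)
    stat <- NA_real_; p <- ht$p.value
  }
  list(rates = unname(rates), rates_rounded = floor(unname(rates) + 0.5),
       method = method, statistic = stat, p = p)
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the all-pairs concordance probability, computed by the
#' midrank (Mann-Whitney) identity with ties counted 1/2. Orientation is
#' explicit and never auto-flipped: `"low"` means low scores predict events
#' (the direction of both chromatin scores, whose low ranges hold the event
#' patients), `"high"` the opposite. The 95% CI is DeLong's.
#'
#' @param scores numeric per-patient scores.
#' @param events logical (or 0/1) outcome vector; both classes must occur.
#' @param orientation `"low"` or `"high"`.
#' @return A `roc_result` with `auc`, `ci_lo`, `ci_hi`, `orientation`, and
#'   `curve`, a data frame of (fpr, tpr) from (0,0) to (1,1), monotone in
#'   both coordinates.
#' @export
roc_auc <- function(scores, events, orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  events <- as.logical(events)
  if (anyNA(scores) || anyNA(events)) stop("scores and events must not contain NA")
  n1 <- sum(events); n0 <- sum(!events)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)
  auc_high <- (sum(r[events]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  auc <- if (orientation == "high") auc_high else 1 - auc_high
  ci <- tryCatch({
    ro <- pROC::roc(response = events, predictor = scores,
                    direction = if (orientation == "low") ">" else "<",
                    levels = c(FALSE, TRUE), quiet = TRUE)
    suppressWarnings(as.numeric(pROC::ci.auc(ro, method = "delong"))[c(1, 3)])
  }, error = function(e) c(NA_real_, NA_real_))
  # threshold sweep: positive call = score on the event side of t
  s <- if (orientation == "low") -scores else scores
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(events[ord]); fp <- cumsum(!events[ord])
  keep <- c(diff(s[ord]) != 0, TRUE)   # collapse tied thresholds
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  structure(list(auc = auc, ci_lo = min(ci[1], auc), ci_hi = max(ci[2], auc),
                 orientation = orientation, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result AUC %.3f (95%% CI %.3f-%.3f), orientation: %s scores predict events>\n",
              x$auc, x$ci_lo, x$ci_hi, x$orientation))
  invisible(x)
}

#' Interobserver agreement: ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures — the
#' standard interobserver form. Computed from the two-way ANOVA
#' decomposition of an n subjects x k raters grid, with the F-based 95%
#' confidence interval (McGraw & Wong) and the F test against ICC = 0.
#'
#' @param ratings numeric matrix, n subjects (rows) x k raters (columns),
#'   complete, n >= 3 and k >= 2.
#' @param conf_level confidence level (default 0.95).
#' @return A list with `icc`, `ci_lo`, `ci_hi`, `p`, `n`, `k`.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need n >= 3 subjects and k >= 2 raters")
  if (anyNA(ratings)) stop("incomplete rating grid")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse > 0) {
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
    p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {  # perfect agreement: zero residual variance
    lo <- hi <- icc
    p <- 0
  }
  list(icc = icc, ci_lo = lo, ci_hi = hi, p = p, n = n, k = k)
}
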