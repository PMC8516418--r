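#' Base-10 log transform
#'
#' Applied to right-skewed positive measurements (fission-pore durations)
#' before Student's t-tests so the transformed values are approximately
#' normal.
#'
#' @param values positive numeric vector.
#' @return `log10(values)`.
#' @export
log_transform <- function(values) {
  if (any(values <= 0, na.rm = TRUE))
    stop("log transform requires strictly positive values")
  log10(values)
}

#' Two-tailed Student's t-tests
#'
#' Thin wrappers around [stats::t.test()] returning the trio (t, p, df).
#' The unpaired version is the classical equal-variance Student test.
#'
#' @param a,b numeric vectors (for the paired test, aligned pairs).
#' @return list with `t`, `p`, `df`.
#' @export
ttest_unpaired <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  r <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(r$statistic), p = r$p.value, df = unname(r$parameter))
}

#' @rdname ttest_unpaired
#' @export
ttest_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  r <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(r$statistic), p = r$p.value, df = unname(r$parameter))
}

#' One-way ANOVA with Student-Newman-Keuls post hoc comparisons
#'
#' Omnibus one-way ANOVA followed by the stepwise SNK procedure on the
#' ordered group means: each pair spanning `r` ordered means is compared
#' with the studentized range distribution with `r` means, and a pair is
#' declared significant only when every pair containing it is also
#' significant (the SNK non-contradiction rule). Unequal group sizes use
#' the Tukey-Kramer standard error.
#'
#' @param values numeric measurements.
#' @param groups group labels (>= 3 levels, each with n >= 2).
#' @param alpha post hoc significance level.
#' @return list with `F`, `p` (omnibus), `df`, and `posthoc` -- a data.frame
#'   with one row per pair: `group1`, `group2`, `q`, `span`, `p_snk`,
#'   `significant`.
#' @export
anova_oneway_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 3)
    stop("fewer than 3 groups: use a t-test instead")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  df_err <- an[["Df"]][2]
  mse <- an[["Mean Sq"]][2]
  means <- tapply(values, groups, mean)
  ord <- order(means)
  means <- means[ord]
  ns <- ns[ord]
  lev <- names(means)
  pairs <- list()
  pmat <- matrix(NA_real_, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    span <- j - i + 1
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- (means[j] - means[i]) / se
    pmat[i, j] <- stats::ptukey(q, nmeans = span, df = df_err,
                                lower.tail = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      group1 = lev[i], group2 = lev[j], q = unname(q), span = span,
      p_snk = pmat[i, j])
  }
  # stepwise rule: (i,j) significant iff all containing pairs significant
  sigmat <- matrix(NA, k, k)
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      # immediate containing pairs are (i-1, j) and (i, j+1)
      ok <- TRUE
      if (span < k) {
        if (i > 1 && !isTRUE(sigmat[i - 1, j])) ok <- FALSE
        if (j < k && !isTRUE(sigmat[i, j + 1])) ok <- FALSE
      }
      sigmat[i, j] <- ok && (pmat[i, j] < alpha)
    }
  }
  posthoc <- do.call(rbind, pairs)
  posthoc$significant <- mapply(function(g1, g2) {
    i <- match(g1, lev); j <- match(g2, lev)
    isTRUE(sigmat[i, j])
  }, posthoc$group1, posthoc$group2)
  rownames(posthoc) <- NULL
  list(F = Fv, p = p, df = c(k - 1, df_err), posthoc = posthoc)
}

#' Group summary table: mean +/- SEM with n
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @return data.frame with `group`, `n`, `mean`, `sem` (`NA` with a warning
#'   for singleton groups).
#' @export
summarize_groups <- function(values, groups) {
  groups <- factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    n <- length(v)
    if (n < 2) warning("group ", g, " has a single value; SEM undefined")
    data.frame(group = g, n = n, mean = mean(v),
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
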