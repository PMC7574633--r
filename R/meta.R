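#' Per-study log odds ratio and standard error
#'
#' Woolf effect for one 2x2 table: `log OR = log(ad/bc)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; zero cells receive the
#' Haldane--Anscombe 0.5 correction on all four cells.
#'
#' @inheritParams pearson_chi2
#' @return List with `log_or` and `se`.
#' @export
study_effect <- function(a, b, c, d) {
  w <- odds_ratio_woolf(a, b, c, d)
  list(log_or = w$log_or, se = w$se)
}

#' Cochran Q, I-squared and DerSimonian-Laird tau-squared
#'
#' Inverse-variance heterogeneity statistics for k study effects:
#' `Q = sum w_i (theta_i - theta_FE)^2` with `w_i = 1/SE_i^2`,
#' `I2 = max(0, (Q - df)/Q) * 100`, and the DerSimonian--Laird moment
#' estimator `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))`.
#'
#' @param log_or Numeric vector of study effects (log odds ratios).
#' @param se Matching standard errors.
#' @return List with `Q`, `df`, `I2` (percent), `tau2`, `p_Q`.
#' @export
meta_heterogeneity <- function(log_or, se) {
  k <- length(log_or)
  if (k < 2) stop("heterogeneity requires at least 2 studies")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  theta_fe <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - theta_fe)^2)
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, I2 = I2, tau2 = tau2,
       p_Q = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Pool study effects under a fixed- or random-effects model
#'
#' Fixed effect: inverse-variance weights `1/SE^2`. Random effects:
#' weights `1/(SE^2 + tau2)` with the DerSimonian--Laird `tau2`. The
#' pooled CI is `exp(theta +/- z / sqrt(sum w))` and the p-value is the
#' two-sided normal tail of `theta * sqrt(sum w)`.
#'
#' @inheritParams meta_heterogeneity
#' @param model `"fixed"` or `"random"`.
#' @param tau2 Between-study variance for the random model (computed via
#'   [meta_heterogeneity()] when `NULL`).
#' @param conf_level Confidence level.
#' @return List with `log_or`, `se`, `or`, `ci_low`, `ci_high`, `z`, `p`,
#'   `weights` (normalised to percent), `model`, `tau2`.
#' @export
meta_pool <- function(log_or, se, model = c("fixed", "random"),
                      tau2 = NULL, conf_level = 0.95) {
  model <- match.arg(model)
  k <- length(log_or)
  if (k < 2) stop("pooling requires at least 2 studies")
  if (model == "random" && is.null(tau2))
    tau2 <- meta_heterogeneity(log_or, se)$tau2
  w <- if (model == "random") 1 / (se^2 + tau2) else 1 / se^2
  theta <- sum(w * log_or) / sum(w)
  se_pool <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- theta / se_pool
  list(log_or = theta, se = se_pool, or = exp(theta),
       ci_low = exp(theta - z * se_pool),
       ci_high = exp(theta + z * se_pool),
       z = stat, p = 2 * stats::pnorm(-abs(stat)),
       weights = 100 * w / sum(w), model = model,
       tau2 = if (model == "random") tau2 else 0)
}

#' Meta-analysis of per-study blood-type 2x2 tables
#'
#' For each contrast (blood type X vs non-X), computes Woolf per-study
#' effects, Cochran Q / I-squared / DerSimonian--Laird tau-squared, picks
#' the pooling model by the severe-heterogeneity rule (random effects iff
#' `I2 > i2_threshold`, default 50%), and pools. Contrasts with fewer than
#' two studies are skipped with a warning.
#'
#' @param studies Data frame in long format with columns `study`,
#'   `contrast` (e.g. `"A"`, `"B"`, `"O"`, `"AB"`), `case_item`,
#'   `case_nonitem`, `ctrl_item`, `ctrl_nonitem` (see
#'   [abo_longevity_studies()] for the bundled example).
#' @param model `"auto"` (I-squared rule, default), or force `"fixed"` /
#'   `"random"` for every contrast.
#' @param i2_threshold Percent I-squared above which the random-effects
#'   model is selected (strict inequality).
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `abo_meta`: a list with one element per
#'   contrast, each holding `studies` (per-study data frame with `or`,
#'   `ci_low`, `ci_high`, `weight`), `Q`, `df`, `I2`, `tau2`, `p_Q`,
#'   `model`, and the pooled `or`, `ci_low`, `ci_high`, `p`.
#' @examples
#' fit <- abo_meta(abo_longevity_studies())
#' fit
#' @export
abo_meta <- function(studies, model = c("auto", "fixed", "random"),
                     i2_threshold = 50, conf_level = 0.95) {
  model <- match.arg(model)
  req <- c("study", "contrast", "case_item", "case_nonitem",
           "ctrl_item", "ctrl_nonitem")
  if (!all(req %in% names(studies)))
    stop("`studies` must have columns: ", paste(req, collapse = ", "))
  contrasts <- unique(studies$contrast)
  out <- list()
  for (ct in contrasts) {
    s <- studies[studies$contrast == ct, , drop = FALSE]
    if (nrow(s) < 2) {
      warning("contrast ", ct, " has fewer than 2 studies; skipped")
      next
    }
    eff <- study_effect(s$case_item, s$case_nonitem,
                        s$ctrl_item, s$ctrl_nonitem)
    het <- meta_heterogeneity(eff$log_or, eff$se)
    use <- if (model == "auto") {
      if (het$I2 > i2_threshold) "random" else "fixed"
    } else model
    pool <- meta_pool(eff$log_or, eff$se, use, tau2 = het$tau2,
                      conf_level = conf_level)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    per <- data.frame(
      study = s$study,
      case_item = s$case_item, case_nonitem = s$case_nonitem,
      ctrl_item = s$ctrl_item, ctrl_nonitem = s$ctrl_nonitem,
      log_or = eff$log_or, se = eff$se,
      or = exp(eff$log_or),
      ci_low = exp(eff$log_or - z * eff$se),
      ci_high = exp(eff$log_or + z * eff$se),
      weight = pool$weights,
      stringsAsFactors = FALSE)
    out[[ct]] <- list(contrast = ct, k = nrow(s), studies = per,
                      Q = het$Q, df = het$df, I2 = het$I2,
                      tau2 = het$tau2, p_Q = het$p_Q, model = use,
                      or = pool$or, ci_low = pool$ci_low,
                      ci_high = pool$ci_high, p = pool$p)
  }
  structure(out, i2_threshold = i2_threshold, conf_level = conf_level,
            class = "abo_meta")
}

#' @export
print.abo_meta <- function(x, ...) {
  cat("Meta-analysis of blood-type case-control tables\n")
  for (m in x) {
    cat(sprintf(
      "  %s/non-%s: k=%d, Q=%.2f (df=%d), I2=%.1f%%, model=%s, OR=%.2f (%.2f-%.2f), p=%.2f\n",
      m$contrast, m$contrast, m$k, m$Q, m$df, m$I2, m$model,
      m$or, m$ci_low, m$ci_high, m$p))
  }
  invisible(x)
}

#' @export
summary.abo_meta <- function(object, ...) {
  do.call(rbind, lapply(object, function(m) {
    data.frame(contrast = m$contrast, k = m$k, Q = m$Q, df = m$df,
               I2 = m$I2, tau2 = m$tau2, model = m$model, or = m$or,
               ci_low = m$ci_low, ci_high = m$ci_high, p = m$p,
               stringsAsFactors = FALSE)
  }))
}

#' Forest plot for a fitted meta-analysis
#'
#' Base-graphics forest plot: per-study squares sized by weight with CI
#' whiskers, a pooled diamond, and the null line at OR = 1, on a log
#' x-axis; one panel per contrast (use `contrast` to plot a single one).
#'
#' @param x An `abo_meta` object.
#' @param contrast Optional contrast label to plot alone.
#' @param ... Unused.
#' @export
plot.abo_meta <- function(x, contrast = NULL, ...) {
  items <- if (is.null(contrast)) x else x[contrast]
  old <- graphics::par(mfrow = c(length(items), 1),
                       mar = c(4, 9, 2, 6))
  on.exit(graphics::par(old))
  for (m in items) {
    s <- m$studies
    k <- nrow(s)
    ys <- rev(seq_len(k)) + 1.5
    xlim <- range(c(s$ci_low, s$ci_high, m$ci_low, m$ci_high, 1))
    graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 2), log = "x",
                   yaxt = "n", xlab = "Odds ratio (log scale)", ylab = "",
                   main = sprintf("%s vs non-%s (%s effects, I2 = %.1f%%)",
                                  m$contrast, m$contrast, m$model, m$I2))
    graphics::abline(v = 1, lty = 2, col = "grey40")
    graphics::segments(s$ci_low, ys, s$ci_high, ys)
    graphics::points(s$or, ys, pch = 15,
                     cex = 0.6 + 1.6 * s$weight / max(s$weight))
    graphics::axis(2, at = ys, labels = s$study, las = 1, cex.axis = 0.8)
    graphics::axis(4, at = ys, las = 1, cex.axis = 0.7,
                   labels = sprintf("%.2f (%.2f-%.2f) %.1f%%",
                                    s$or, s$ci_low, s$ci_high, s$weight))
    # pooled diamond
    yd <- 0.9
    graphics::polygon(c(m$ci_low, m$or, m$ci_high, m$or),
                      c(yd, yd + 0.35, yd, yd - 0.35), col = "grey30")
    graphics::axis(2, at = yd, labels = "Pooled", las = 1, cex.axis = 0.8)
    graphics::axis(4, at = yd, las = 1, cex.axis = 0.7,
                   labels = sprintf("%.2f (%.2f-%.2f)",
                                    m$or, m$ci_low, m$ci_high))
  }
  invisible(x)
}

#' Forest-plot table for export
#'
#' Flattens an `abo_meta` fit into one data frame: per-study rows (OR, CI,
#' weight percent) followed by a pooled row per contrast carrying Q, I2
#' and the selected model.
#'
#' @param x An `abo_meta` object.
#' @return Data frame with columns `contrast`, `row`, `study`, `or`,
#'   `ci_low`, `ci_high`, `weight`, `Q`, `I2`, `model`.
#' @export
forest_table <- function(x) {
  stopifnot(inherits(x, "abo_meta"))
  do.call(rbind, lapply(x, function(m) {
    rbind(
      data.frame(contrast = m$contrast, row = "study",
                 study = m$studies$study, or = m$studies$or,
                 ci_low = m$studies$ci_low, ci_high = m$studies$ci_high,
                 weight = m$studies$weight, Q = NA_real_, I2 = NA_real_,
                 model = NA_character_, stringsAsFactors = FALSE),
      data.frame(contrast = m$contrast, row = "pooled", study = "Pooled",
                 or = m$or, ci_low = m$ci_low, ci_high = m$ci_high,
                 weight = 100, Q = m$Q, I2 = m$I2, model = m$model,
                 stringsAsFactors = FALSE))
  }))
}
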