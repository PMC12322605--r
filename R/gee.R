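# Marginal (GEE-type) mixed-design model, post-hoc trial comparisons and
# Hedges g effect sizes.
#
# Model: Gaussian identity-link marginal regression of one metric on
# group (reference: older), hand (reference: right) and trial dummies
# (reference: trial 1), optionally with group x hand and group x trial
# interactions, clustered by participant under a working correlation
# structure (exchangeable by default), with robust (sandwich) standard
# errors. Estimation is iterative generalized least squares: beta given the
# working correlation, then moment re-estimation of the scale and of the
# correlation parameter from standardized residuals, to convergence.

# Core Gaussian GEE solver. y: response; X: design; id: cluster factor.
.gee_gaussian <- function(y, X, id, corstr = c("exchangeable", "independence",
                                               "ar1"),
                          se_type = c("bias-corrected", "robust"),
                          maxit = 100L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  se_type <- match.arg(se_type)
  id <- as.character(id)
  cl <- split(seq_along(y), id)
  p <- ncol(X)
  N <- length(y)
  if (qr(X)$rank < p)
    stop("model-spec error: design matrix is rank deficient ",
         "(a factor level is missing from the data)")
  beta <- qr.solve(X, y)
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    phi <- sum(r^2) / (N - p)
    if (phi <= 1e-10 * (mean(y^2) + 1)) {
      # exact fit: residuals are rounding noise, the working correlation is
      # unidentifiable; fall back to independence and stop
      alpha <- 0
      break
    }
    alpha_new <- if (corstr == "independence") 0 else {
      num <- 0; den <- 0
      for (ix in cl) {
        ri <- r[ix] / sqrt(phi)
        ni <- length(ri)
        if (ni < 2L) next
        if (corstr == "exchangeable") {
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          den <- den + ni * (ni - 1) / 2
        } else { # ar1: lag-1 products in cluster order
          num <- num + sum(ri[-1] * ri[-ni])
          den <- den + (ni - 1)
        }
      }
      nmax <- max(lengths(cl))
      max(min(num / (den - p), 0.99), -1 / (nmax - 1) + 1e-3)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in cl) {
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      Ri_inv <- .wcorr_inverse(length(ix), alpha_new, corstr)
      W <- crossprod(Xi, Ri_inv)
      A <- A + W %*% Xi
      b <- b + drop(W %*% yi)
    }
    beta_new <- solve(A, b)
    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta))) &&
      abs(alpha_new - alpha) < 1e-8
    beta <- beta_new
    alpha <- alpha_new
    if (done) break
    if (it == maxit)
      stop("convergence error: GEE did not converge in ", maxit,
           " iterations (last alpha = ", signif(alpha, 4), ")")
  }
  # robust sandwich covariance; the bias-corrected form (default) inflates
  # each cluster's residual by (I - H_i)^-1 (Mancl-DeRouen), which removes
  # the downward bias of the uncorrected sandwich at moderate cluster
  # counts and keeps the group test near its nominal level.
  r <- y - drop(X %*% beta)
  A <- matrix(0, p, p)
  Ws <- vector("list", length(cl))
  for (j in seq_along(cl)) {
    ix <- cl[[j]]
    Xi <- X[ix, , drop = FALSE]
    Ri_inv <- .wcorr_inverse(length(ix), alpha, corstr)
    Ws[[j]] <- crossprod(Xi, Ri_inv)
    A <- A + Ws[[j]] %*% Xi
  }
  Ainv <- solve(A)
  M <- matrix(0, p, p)
  for (j in seq_along(cl)) {
    ix <- cl[[j]]
    ri <- r[ix]
    if (se_type == "bias-corrected") {
      Xi <- X[ix, , drop = FALSE]
      Hi <- Xi %*% Ainv %*% Ws[[j]]       # cluster leverage
      ri <- solve(diag(length(ix)) - Hi, ri)
    }
    u <- drop(Ws[[j]] %*% ri)
    M <- M + tcrossprod(u)
  }
  V <- Ainv %*% M %*% Ainv
  list(beta = beta, vcov = V, alpha = alpha, phi = phi,
       n_clusters = length(cl), n_obs = N, iterations = it)
}

# Inverse working correlation matrix (scale-free; the dispersion cancels in
# the estimating equations).
.wcorr_inverse <- function(n, alpha, corstr) {
  if (n == 1L || corstr == "independence" || alpha == 0) return(diag(n))
  if (corstr == "exchangeable") {
    # R = (1-a) I + a J  =>  R^-1 = (I - a/(1+(n-1)a) J) / (1-a)
    a <- alpha
    (diag(n) - matrix(a / (1 + (n - 1) * a), n, n)) / (1 - a)
  } else {
    solve(alpha^abs(outer(seq_len(n), seq_len(n), "-")))
  }
}

#' Fit the marginal mixed-design model for one metric
#'
#' @param data long-format cohort dataset (one row per participant x hand x
#'   trial) with columns `participant_id`, `group`, `hand`, `trial` and the
#'   metric columns.
#' @param metric name of the metric column to model.
#' @param include_interactions add `group:hand` and `group:trial` terms.
#' @param corstr working correlation: `"exchangeable"` (default),
#'   `"independence"` or `"ar1"` (cells ordered by hand then trial).
#' @param se_type `"bias-corrected"` (default; Mancl-DeRouen small-sample
#'   sandwich, calibrated at cohort-scale cluster counts) or `"robust"`
#'   (uncorrected sandwich).
#' @return An object of class `hr_gee`: coefficient table (`term`, `B`,
#'   `SE`, `z`, `p`; `young`, `left`, `trial2/3` vs the older / right /
#'   trial-1 references), the estimated working correlation, scale, and fit
#'   metadata.
#' @export
fit_marginal_model <- function(data, metric,
                               include_interactions = FALSE,
                               corstr = "exchangeable",
                               se_type = c("bias-corrected", "robust")) {
  se_type <- match.arg(se_type)
  data <- as.data.frame(data)
  need <- c("participant_id", "group", "hand", "trial", metric)
  if (!all(need %in% names(data)))
    stop("schema error: dataset lacks column(s) ",
         paste(setdiff(need, names(data)), collapse = ", "))
  if (length(unique(data$group)) < 2L)
    stop("analysis error: need both age groups in the data")
  if (min(table(unique(data[c("participant_id", "group")])$group)) < 2L)
    stop("analysis error: need at least 2 participants per group")
  df <- data.frame(
    y = data[[metric]],
    group = factor(data$group, levels = c("older", "young")),
    hand = factor(data$hand, levels = c("right", "left")),
    trial = factor(data$trial, levels = c(1, 2, 3)),
    id = data$participant_id)
  if (anyNA(df$y)) stop("analysis error: missing values in metric ", metric)
  form <- if (include_interactions)
    y ~ group + hand + trial + group:hand + group:trial
  else y ~ group + hand + trial
  X <- stats::model.matrix(form, df)
  # order within cluster by hand then trial (matters only for ar1)
  ord <- order(df$id, df$hand, df$trial)
  fit <- .gee_gaussian(df$y[ord], X[ord, , drop = FALSE], df$id[ord],
                       corstr = corstr, se_type = se_type)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  # an exactly-fit metric (zero residual variance) has no usable SE
  z <- ifelse(se > 0, fit$beta / se, NA_real_)
  coef_tab <- data.frame(term = colnames(X), B = unname(fit$beta),
                         SE = unname(se), z = unname(z),
                         p = unname(2 * stats::pnorm(-abs(z))))
  rownames(coef_tab) <- NULL
  structure(list(metric = metric, coefficients = coef_tab,
                 corstr = corstr, se_type = se_type,
                 alpha = fit$alpha, phi = fit$phi,
                 n_participants = fit$n_clusters, n_cells = fit$n_obs,
                 iterations = fit$iterations,
                 reference_levels = c(group = "older", hand = "right",
                                      trial = "1")),
            class = "hr_gee")
}

#' @export
print.hr_gee <- function(x, ...) {
  cat(sprintf("Marginal model (%s working correlation) for %s\n",
              x$corstr, x$metric))
  cat(sprintf("  %d participants, %d cells; est. correlation %.3f\n",
              x$n_participants, x$n_cells, x$alpha))
  tab <- x$coefficients
  tab$B <- signif(tab$B, 4); tab$SE <- signif(tab$SE, 4)
  tab$z <- round(tab$z, 2); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hedges g for two paired conditions
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` using the
#' two-condition pooled SD (average of the two variances, equal n), times
#' the small-sample bias correction `J = 1 - 3 / (4 (2n - 2) - 1)`.
#'
#' @param x,y equal-length numeric vectors (condition 1, condition 2).
#' @return Hedges g (signed: negative when `x` below `y`).
#' @export
hedges_g <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must be paired with n >= 2")
  sp <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (sp == 0) stop("undefined effect size: zero pooled SD")
  J <- 1 - 3 / (4 * (2 * n - 2) - 1)
  (mean(x) - mean(y)) / sp * J
}

#' Post-hoc pairwise trial comparisons
#'
#' Collapses hands by averaging (one value per participant per trial; only
#' participants with all three trials are kept, dropped ones are recorded in
#' the `dropped` attribute), then runs paired t-tests for trial pairs (1,2),
#' (1,3), (2,3) with Bonferroni correction over the three comparisons and
#' Hedges g per pair. Differences are taken earlier-minus-later, so
#' improvement on later trials yields negative t and g.
#'
#' @param data long-format cohort dataset.
#' @param metric metric column name.
#' @return Data frame: `trial_i`, `trial_j`, `n`, `t`, `df`, `p`,
#'   `p_bonferroni` (`min(1, 3p)`), `hedges_g`.
#' @export
posthoc_trials <- function(data, metric) {
  data <- as.data.frame(data)
  if (!metric %in% names(data)) stop("no metric column ", metric)
  agg <- stats::aggregate(data[[metric]],
                          by = list(participant_id = data$participant_id,
                                    trial = data$trial), FUN = mean)
  wide <- stats::reshape(agg, idvar = "participant_id", timevar = "trial",
                         direction = "wide")
  trial_cols <- paste0("x.", 1:3)
  if (!all(trial_cols %in% names(wide)))
    stop("analysis error: some trials absent from the data")
  complete <- stats::complete.cases(wide[, trial_cols])
  dropped <- wide$participant_id[!complete]
  wide <- wide[complete, ]
  if (nrow(wide) < 2L) stop("analysis error: fewer than 2 complete participants")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    xi <- wide[[paste0("x.", pr[1])]]
    xj <- wide[[paste0("x.", pr[2])]]
    if (all(xi == xj)) {          # degenerate: no change on any participant
      tstat <- 0; dfree <- length(xi) - 1L; pval <- 1; g <- 0
    } else {
      tt <- stats::t.test(xi, xj, paired = TRUE)
      tstat <- unname(tt$statistic); dfree <- unname(tt$parameter)
      pval <- tt$p.value; g <- hedges_g(xi, xj)
    }
    data.frame(trial_i = pr[1], trial_j = pr[2], n = length(xi),
               t = tstat, df = dfree, p = pval,
               p_bonferroni = min(1, 3 * pval), hedges_g = g)
  }))
  structure(out, dropped = dropped)
}

#' Full analysis report over all seven metrics
#'
#' For every metric: group means and SDs, the marginal model with the
#' group x hand interaction (the headline group / hand / interaction
#' p-values), trial main effects from the main-effects model, post-hoc trial
#' comparisons when a trial effect is significant at `alpha`, and a
#' learning-plateau flag when trial 1 differs from trials 2 and 3 but trials
#' 2 and 3 do not differ (Bonferroni-adjusted).
#'
#' @param data long-format cohort dataset.
#' @param alpha significance level (default 0.05).
#' @param corstr working correlation structure.
#' @return An object of class `hr_report` (a named list, one entry per
#'   metric, plus `alpha` and `n_participants`), serializable with
#'   [report_json()].
#' @export
analysis_report <- function(data, alpha = 0.05, corstr = "exchangeable") {
  data <- as.data.frame(data)
  metrics <- intersect(METRIC_NAMES, names(data))
  if (!length(metrics)) stop("schema error: no metric columns in dataset")
  per_metric <- lapply(metrics, function(m) {
    fit_main <- fit_marginal_model(data, m, corstr = corstr)
    fit_int <- fit_marginal_model(data, m, include_interactions = TRUE,
                                  corstr = corstr)
    ct_main <- fit_main$coefficients
    ct_int <- fit_int$coefficients
    pick <- function(tab, term) tab[tab$term == term, , drop = FALSE]
    gm <- do.call(rbind, lapply(c("young", "older"), function(g) {
      v <- data[[m]][data$group == g]
      data.frame(group = g, mean = mean(v), sd = stats::sd(v))
    }))
    trial_p <- c(pick(ct_main, "trial2")$p, pick(ct_main, "trial3")$p)
    res <- list(
      metric = m, group_stats = gm,
      p_group = pick(ct_int, "groupyoung")$p,
      p_hand = pick(ct_int, "handleft")$p,
      p_group_x_hand = pick(ct_int, "groupyoung:handleft")$p,
      coefficients = ct_main,
      coefficients_interaction = ct_int,
      trial_significant = isTRUE(any(trial_p < alpha)))
    if (res$trial_significant) {
      ph <- posthoc_trials(data, m)
      res$posthoc <- ph
      sig <- ph$p_bonferroni < alpha
      res$learning_plateau <- isTRUE(sig[1] && sig[2] && !sig[3])
    } else {
      res$posthoc <- NULL
      res$learning_plateau <- FALSE
    }
    res
  })
  names(per_metric) <- metrics
  structure(list(metrics = per_metric, alpha = alpha, corstr = corstr,
                 n_participants = length(unique(data$participant_id))),
            class = "hr_report")
}

#' @export
print.hr_report <- function(x, ...) {
  cat(sprintf("Mixed-design analysis report (alpha = %g, %s correlation, %d participants)\n\n",
              x$alpha, x$corstr, x$n_participants))
  for (m in x$metrics) {
    flag <- function(p) if (p < x$alpha) "*" else " "
    cat(sprintf("%-26s group P=%.3g%s hand P=%.3g%s group:hand P=%.3g%s\n",
                m$metric, m$p_group, flag(m$p_group), m$p_hand,
                flag(m$p_hand), m$p_group_x_hand, flag(m$p_group_x_hand)))
    if (!is.null(m$posthoc)) {
      ph <- m$posthoc
      for (i in seq_len(nrow(ph)))
        cat(sprintf("    trial %d vs %d: t(%d)=%.2f, adj P=%.4g, g=%.2f\n",
                    ph$trial_i[i], ph$trial_j[i], ph$df[i], ph$t[i],
                    ph$p_bonferroni[i], ph$hedges_g[i]))
      if (isTRUE(m$learning_plateau))
        cat("    learning plateau: trial 1 differs from trials 2 and 3;",
            "trials 2 and 3 do not differ\n")
    }
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#' @param report an `hr_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "hr_report"))
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
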