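#' Build the value-probe regression design for transfer trials
#'
#' For each transfer trial the two regressors are the unsigned difference
#' in absolute values and the unsigned difference in relative values of the
#' presented pair, both normalized to `[0, 1]`:
#'
#' * absolute value of an option = its expected value, min-max normalized
#'   across all task options;
#' * relative value of an option = its within-context rank value
#'   ([relative_order()]: 0, 0.5 or 1).
#'
#' The default absolute-value definition is design-EV based; both mappings
#' are configurable by supplying `abs_values` / `rel_values`.
#'
#' @param trials Trials tibble; transfer trials are used, in row order
#'   (activation matrices must share this row order).
#' @param task The task.
#' @param abs_values,rel_values Optional named numeric vectors
#'   (`option_id` -> value in `[0, 1]`) overriding the defaults.
#' @return A `probe_design` tibble: `session_id` (if present), `trial`,
#'   `dabs`, `drel`.
#' @export
probe_design <- function(trials, task, abs_values = NULL, rel_values = NULL) {
  task <- load_task_spec(task)
  evs <- ev_lookup(task)
  abs_values <- abs_values %||% ((evs - min(evs)) / (max(evs) - min(evs)))
  ord <- relative_order(task)
  rel_values <- rel_values %||% setNames(ord$rank_value, ord$option_id)
  tr <- filter(trials, .data$phase == "transfer")
  out <- tibble(
    trial = tr$trial,
    dabs = abs(abs_values[tr$option_1] - abs_values[tr$option_2]),
    drel = abs(rel_values[tr$option_1] - rel_values[tr$option_2]))
  if ("session_id" %in% names(tr)) out <- mutate(out, session_id = tr$session_id, .before = 1)
  class(out) <- c("probe_design", class(out))
  out
}

#' Per-unit linear regressions of activations on value differences
#'
#' Fits, for every hidden unit separately, the ordinary least squares model
#' `activation ~ intercept + dabs + drel` across transfer trials, and
#' returns both partial coefficients with two-sided t-test p-values. This
#' asks which units carry trial-to-trial information about absolute and/or
#' relative value differences of the presented pair.
#'
#' @param activations Numeric matrix, trials x units (row order matching
#'   `design`).
#' @param design A [probe_design()] tibble (or data frame with `dabs`,
#'   `drel`).
#' @param alpha Per-test significance level before correction.
#' @return An `rvb_probe`: `units` tibble (`unit`, `coef_abs`, `coef_rel`,
#'   `p_abs`, `p_rel`, `sig_abs`, `sig_rel`), significance `counts`
#'   (`abs_only`, `rel_only`, `both`; each unit in at most one bucket),
#'   `correction = "none"`, `alpha`, `n_trials`.
#' @export
unit_regressions <- function(activations, design, alpha = 0.05) {
  activations <- as.matrix(activations)
  n <- nrow(activations)
  stopifnot(n == nrow(design))
  if (n < 4) abort("need at least 4 trials for the two-regressor probe")
  X <- cbind(intercept = 1, dabs = design$dabs, drel = design$drel)
  sv <- svd(X)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > 1e10)
    abort(sprintf("collinear probe design (condition number %.3g)", kappa),
          class = "relbandit_collinear")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, activations)            # 3 x units
  res <- activations - X %*% B
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtX_inv), sigma2))              # 3 x units
  tval <- B / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  units <- tibble(
    unit = colnames(activations) %||% paste0("u", seq_len(ncol(activations))),
    coef_abs = B[2, ], coef_rel = B[3, ],
    p_abs = pval[2, ], p_rel = pval[3, ],
    sig_abs = pval[2, ] < alpha, sig_rel = pval[3, ] < alpha)
  new_probe(units, correction = "none", alpha = alpha, n_trials = n,
            family_size = NA_integer_)
}

new_probe <- function(units, correction, alpha, n_trials, family_size) {
  counts <- c(abs_only = sum(units$sig_abs & !units$sig_rel),
              rel_only = sum(units$sig_rel & !units$sig_abs),
              both = sum(units$sig_abs & units$sig_rel))
  structure(list(units = units, counts = counts, correction = correction,
                 alpha = alpha, n_trials = n_trials, family_size = family_size),
            class = "rvb_probe")
}

#' Multiple-comparison correction for probe results
#'
#' Recomputes significance flags and bucket counts under a correction over
#' the family of units x regressors tests. The default is Bonferroni at
#' family-wise `alpha` over `2 * n_units` tests (a deliberately
#' conservative rule); any [stats::p.adjust()] method is accepted. A family
#' size of 1 reduces to the uncorrected result.
#'
#' @param probe An `rvb_probe` from [unit_regressions()].
#' @param method A [stats::p.adjust()] method name (default
#'   `"bonferroni"`).
#' @param family_size Family size for the Bonferroni rule; defaults to
#'   `2 * n_units`. Ignored by other methods, which operate on the pooled
#'   p-value vector.
#' @param alpha Family-wise level.
#' @return A corrected `rvb_probe`.
#' @export
apply_correction <- function(probe, method = "bonferroni", family_size = NULL,
                             alpha = probe$alpha) {
  stopifnot(inherits(probe, "rvb_probe"))
  if (!method %in% p.adjust.methods)
    abort(paste0("unknown correction method '", method, "'"))
  u <- probe$units
  if (method == "bonferroni") {
    fam <- family_size %||% (2L * nrow(u))
    u$sig_abs <- pmin(1, u$p_abs * fam) < alpha
    u$sig_rel <- pmin(1, u$p_rel * fam) < alpha
  } else {
    fam <- 2L * nrow(u)
    adj <- p.adjust(c(u$p_abs, u$p_rel), method = method)
    u$sig_abs <- adj[seq_len(nrow(u))] < alpha
    u$sig_rel <- adj[nrow(u) + seq_len(nrow(u))] < alpha
  }
  new_probe(u, correction = method, alpha = alpha, n_trials = probe$n_trials,
            family_size = fam)
}

#' @export
print.rvb_probe <- function(x, ...) {
  cat(sprintf("<rvb_probe> %d units, %d trials, correction = %s (alpha = %g)\n",
              nrow(x$units), x$n_trials, x$correction, x$alpha))
  print(x$counts)
  invisible(x)
}

#' @describeIn unit_regressions One row per unit.
#' @param x An `rvb_probe`.
#' @param ... Unused.
#' @export
tidy.rvb_probe <- function(x, ...) x$units

#' @describeIn unit_regressions One-row summary with bucket counts.
#' @export
glance.rvb_probe <- function(x, ...) {
  tibble(n_units = nrow(x$units), n_trials = x$n_trials,
         correction = x$correction, alpha = x$alpha,
         abs_only = x$counts[["abs_only"]], rel_only = x$counts[["rel_only"]],
         both = x$counts[["both"]])
}

#' Contrast of mean unsigned probe coefficients
#'
#' Compares the average magnitude of the absolute-value and relative-value
#' partial coefficients across units, with a paired t-test. A larger
#' unsigned relative-value coefficient indicates the activations track
#' relative more than absolute value.
#'
#' @param probe An `rvb_probe` (>= 2 units).
#' @return A list with `summary` (per-regressor mean |coef| and its
#'   standard error across units) and `test` (paired t statistic, df,
#'   p-value, mean difference rel - abs).
#' @export
coefficient_contrast <- function(probe) {
  u <- probe$units
  if (nrow(u) < 2) abort("coefficient_contrast needs at least 2 units")
  a <- abs(u$coef_abs); r <- abs(u$coef_rel)
  tt <- t.test(r, a, paired = TRUE)
  list(summary = tibble(regressor = c("abs", "rel"),
                        mean_abs_coef = c(mean(a), mean(r)),
                        se = c(sd(a), sd(r)) / sqrt(nrow(u))),
       test = tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value, mean_diff = unname(tt$estimate)))
}

#' Synthesize activation matrices with planted value signals
#'
#' Generates a trials x units activation matrix as
#' `intercept + loading_abs * dabs + loading_rel * drel + noise`, with
#' independent Gaussian noise. Used to exercise the probe pipeline with a
#' known ground truth in place of transformer hidden states.
#'
#' @param design A [probe_design()] tibble.
#' @param loadings Numeric matrix, units x 2 (columns: abs, rel loadings).
#' @param noise_sd Noise standard deviation (0 gives exact recovery).
#' @param intercepts Per-unit intercepts (recycled).
#' @param seed Integer seed.
#' @return Numeric matrix, trials x units.
#' @export
synth_activations <- function(design, loadings, noise_sd = 1, intercepts = 0,
                              seed = 1) {
  loadings <- as.matrix(loadings)
  stopifnot(ncol(loadings) == 2)
  n <- nrow(design); m <- nrow(loadings)
  X <- cbind(design$dabs, design$drel)
  with_session_seed(seed, {
    A <- X %*% t(loadings) + matrix(rnorm(n * m, 0, noise_sd), n, m)
    sweep(A, 2, rep_len(intercepts, m), "+")
  })
}
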