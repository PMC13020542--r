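#' @importFrom stats as.formula model.matrix pnorm qnorm vcov setNames
NULL

# ---- internal: estimated marginal means from a fixed-effect fit ------------

# Reference-grid contrast vectors: for each level of `factor`, average the
# fixed-effect design rows over the levels of the other factors (equal
# weights), then estimate L beta with Wald intervals. Works for lmer, glmer
# and lm fits sharing the fixed-effect formula.
fixef_of <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
}
vcov_of <- function(fit) as.matrix(vcov(fit))

emm_contrasts <- function(fit, data, factor, rhs) {
  vars <- all.vars(rhs)
  grid <- expand.grid(lapply(setNames(vars, vars), function(v) {
    if (is.factor(data[[v]])) factor(levels(data[[v]]), levels = levels(data[[v]]))
    else sort(unique(data[[v]]))
  }), stringsAsFactors = FALSE)
  mm <- model.matrix(rhs, grid)
  levs <- levels(data[[factor]])
  L <- t(vapply(levs, function(lv) {
    colMeans(mm[grid[[factor]] == lv, , drop = FALSE])
  }, numeric(ncol(mm))))
  rownames(L) <- levs
  L
}

wald_rows <- function(L, beta, V, conf = 0.95, exp_scale = FALSE) {
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- 2 * pnorm(-abs(est / se))
  out <- data.frame(estimate = est, se = se,
                    lwr = est - z * se, upr = est + z * se, p_value = p)
  if (exp_scale) {
    out$estimate <- exp(out$estimate)
    out$lwr <- exp(out$lwr)
    out$upr <- exp(out$upr)
  }
  out
}

pairwise_L <- function(L) {
  levs <- rownames(L)
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  D <- t(vapply(pairs, function(pr) L[pr[1L], ] - L[pr[2L], ],
                numeric(ncol(L))))
  rownames(D) <- vapply(pairs, paste, "", collapse = " - ")
  attr(D, "pairs") <- pairs
  D
}

prep_cohort <- function(cohort) {
  d <- as.data.frame(cohort)
  d$condition <- factor(d$condition,
                        levels = intersect(nn_conditions(), unique(d$condition)))
  d$period <- factor(d$period)
  d$participant <- factor(d$participant)
  d
}

new_effect_table <- function(means, differences, metadata) {
  structure(list(means = means, differences = differences,
                 metadata = metadata),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat("<effect_table>", x$metadata$model, "on", x$metadata$outcome, "\n")
  cat("Condition estimates:\n")
  print(x$means, row.names = FALSE, digits = 4)
  if (!is.null(x$differences) && nrow(x$differences)) {
    cat("Pairwise comparisons:\n")
    print(x$differences, row.names = FALSE, digits = 4)
  }
  if (isTRUE(x$metadata$singular)) cat("note: singular random-effect fit\n")
  invisible(x)
}

fit_lmm_engine <- function(data, outcome, rhs_terms) {
  fml <- as.formula(paste(outcome, "~", rhs_terms, "+ (1 | participant)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings({
      f <- lme4::lmer(fml, data = data,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
      as.matrix(vcov(f))  # zero-variance fits can break vcov; probe it here
      f
    })),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate data (e.g. zero variance) can defeat lmer; fall back to the
    # fixed-effect model and flag it
    fit <- stats::lm(as.formula(paste(outcome, "~", rhs_terms)), data = data)
    attr(fit, "nn_fallback") <- TRUE
  }
  fit
}

is_singular_fit <- function(fit) {
  if (inherits(fit, "merMod")) suppressWarnings(lme4::isSingular(fit)) else TRUE
}

#' Crossover linear mixed model: condition means and pairwise differences
#'
#' Fits `outcome ~ condition + period + (1 | participant)` (period dropped
#' when constant) and reports model-based estimated marginal means per
#' condition and all pairwise differences, with large-sample Wald 95%
#' intervals and P-values. No multiplicity adjustment is applied.
#'
#' @param cohort A `crossover_cohort` data frame (columns `participant`,
#'   `period`, `condition` and the outcome).
#' @param outcome_name Name of the outcome column (e.g. `"fmd_pct"`).
#' @param conf Confidence level (default 0.95).
#' @return An `effect_table`: list with `means` (condition, estimate, se,
#'   lwr, upr), `differences` (pairwise contrasts with P-values) and
#'   `metadata` (model, CI method, singularity flag).
#' @examples
#' coh <- simulate_cohort(make_design(20, seed = 1), seed = 1)
#' fit_lmm(coh, "fmd_pct")
#' @export
fit_lmm <- function(cohort, outcome_name, conf = 0.95) {
  d <- prep_cohort(cohort)
  if (!outcome_name %in% names(d)) {
    stop("unknown outcome column: ", outcome_name, call. = FALSE)
  }
  if (nlevels(d$condition) < 2L) stop("need >= 2 conditions", call. = FALSE)
  if (nlevels(d$participant) < 2L) stop("need >= 2 participants", call. = FALSE)
  use_period <- nlevels(d$period) > 1L
  rhs_terms <- if (use_period) "condition + period" else "condition"
  fit <- fit_lmm_engine(d, outcome_name, rhs_terms)
  rhs <- as.formula(paste("~", rhs_terms))
  L <- emm_contrasts(fit, d, "condition", rhs)
  beta <- fixef_of(fit); V <- vcov_of(fit)
  means <- cbind(condition = rownames(L),
                 wald_rows(L, beta, V, conf)[, c("estimate", "se", "lwr", "upr")])
  D <- pairwise_L(L)
  diffs <- cbind(contrast = rownames(D), wald_rows(D, beta, V, conf))
  rownames(means) <- rownames(diffs) <- NULL
  new_effect_table(means, diffs, list(
    model = "linear mixed model (random participant intercept)",
    outcome = outcome_name,
    fixed_effects = rhs_terms,
    ci_method = "Wald, large-sample normal",
    multiplicity_adjustment = "none",
    singular = is_singular_fit(fit),
    n_obs = nrow(d)
  ))
}

#' Random-intercept logistic model for heart-rate-peak occurrence
#'
#' Fits `hr_peak_occurred ~ condition + period + (1 | participant)` with a
#' logit link and reports odds ratios for all condition pairs, overall
#' ("all" rows, period-adjusted) and within each period (per-period subset
#' fits with `condition + (1 | participant)`), with Wald 95% intervals.
#'
#' @param response_dataset Data frame with `participant`, `period`,
#'   `condition` and a binary `hr_peak_occurred` column (excluded records
#'   already removed).
#' @param conf Confidence level.
#' @param per_period If `FALSE`, skip the per-period subset fits and report
#'   only the overall ("all") odds ratios (faster for replicate studies).
#' @return An `effect_table` whose `differences` component holds one row per
#'   condition pair x period ("1", "2", "3", "all"): `odds_ratio`, `lwr`,
#'   `upr`, `p_value`. `means` holds per-condition marginal response
#'   probabilities from the overall model.
#' @export
fit_glmm_occurrence <- function(response_dataset, conf = 0.95,
                                per_period = TRUE) {
  d <- prep_cohort(response_dataset)
  y <- d$hr_peak_occurred
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  d <- d[!is.na(y), ]
  use_period <- nlevels(droplevels(d$period)) > 1L
  rhs_terms <- if (use_period) "condition + period" else "condition"
  fml <- as.formula(paste("hr_peak_occurred ~", rhs_terms, "+ (1 | participant)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = d, family = stats::binomial())
  ))
  beta <- fixef_of(fit); V <- vcov_of(fit)
  separation <- any(abs(beta) > 15)
  rhs <- as.formula(paste("~", rhs_terms))
  L <- emm_contrasts(fit, d, "condition", rhs)
  means <- cbind(condition = rownames(L), wald_rows(L, beta, V, conf))
  means$estimate <- stats::plogis(drop(L %*% beta))
  means <- means[, c("condition", "estimate")]
  names(means) <- c("condition", "marginal_probability")

  or_rows <- function(fit2, d2, rhs_terms2, period_label) {
    b <- fixef_of(fit2); V2 <- vcov_of(fit2)
    L2 <- emm_contrasts(fit2, d2, "condition", as.formula(paste("~", rhs_terms2)))
    D <- pairwise_L(L2)
    w <- wald_rows(D, b, V2, conf, exp_scale = TRUE)
    data.frame(contrast = gsub(" - ", " / ", rownames(D)),
               period = period_label,
               odds_ratio = w$estimate, lwr = w$lwr, upr = w$upr,
               p_value = w$p_value)
  }
  rows <- list()
  if (use_period && per_period) {
    for (per in levels(droplevels(d$period))) {
      dp <- droplevels(d[d$period == per, ])
      if (nlevels(dp$condition) < 2L) next
      fp <- suppressMessages(suppressWarnings(
        lme4::glmer(hr_peak_occurred ~ condition + (1 | participant),
                    data = dp, family = stats::binomial())
      ))
      rows[[length(rows) + 1L]] <- or_rows(fp, dp, "condition", per)
    }
  }
  rows[[length(rows) + 1L]] <- or_rows(fit, d, rhs_terms, "all")
  diffs <- do.call(rbind, rows)
  rownames(diffs) <- NULL
  new_effect_table(means, diffs, list(
    model = "logistic GLMM (random participant intercept)",
    outcome = "hr_peak_occurred",
    fixed_effects = rhs_terms,
    ci_method = "Wald, large-sample normal",
    complete_separation = separation,
    singular = is_singular_fit(fit),
    n_obs = nrow(d)
  ))
}

#' Mixed model for heart-rate change after noise peaks
#'
#' Fits `delta ~ condition + period + (1 | participant)` to before/after
#' heart-rate deltas and reports per-exposure means (per period from subset
#' fits and overall from the period-adjusted model) plus pairwise exposure
#' differences.
#'
#' @param response_dataset Data frame with `participant`, `period`,
#'   `condition`, `delta` (bpm; excluded records already removed).
#' @param conf Confidence level.
#' @return An `effect_table`: `means` has one row per exposure x period
#'   ("1", "2", "3", "all") with estimate, SE and CI; `differences` holds
#'   the pairwise exposure contrasts from the overall model.
#' @export
fit_before_after <- function(response_dataset, conf = 0.95) {
  d <- prep_cohort(response_dataset)
  if (!"delta" %in% names(d)) stop("`delta` column required", call. = FALSE)
  d <- d[!is.na(d$delta), ]
  use_period <- nlevels(droplevels(d$period)) > 1L
  rhs_terms <- if (use_period) "condition + period" else "condition"
  fit <- fit_lmm_engine(d, "delta", rhs_terms)
  beta <- fixef_of(fit); V <- vcov_of(fit)

  mean_rows <- function(fit2, d2, rhs_terms2, period_label) {
    b <- fixef_of(fit2); V2 <- vcov_of(fit2)
    L2 <- emm_contrasts(fit2, d2, "condition", as.formula(paste("~", rhs_terms2)))
    w <- wald_rows(L2, b, V2, conf)
    data.frame(condition = rownames(L2), period = period_label,
               estimate = w$estimate, se = w$se, lwr = w$lwr, upr = w$upr)
  }
  rows <- list()
  if (use_period) {
    for (per in levels(droplevels(d$period))) {
      dp <- droplevels(d[d$period == per, ])
      fp <- fit_lmm_engine(dp, "delta", "condition")
      rows[[length(rows) + 1L]] <- mean_rows(fp, dp, "condition", per)
    }
  }
  rows[[length(rows) + 1L]] <- mean_rows(fit, d, rhs_terms, "all")
  means <- do.call(rbind, rows)
  rownames(means) <- NULL

  rhs <- as.formula(paste("~", rhs_terms))
  D <- pairwise_L(emm_contrasts(fit, d, "condition", rhs))
  diffs <- cbind(contrast = rownames(D), wald_rows(D, beta, V, conf))
  rownames(diffs) <- NULL
  new_effect_table(means, diffs, list(
    model = "linear mixed model on before/after heart-rate delta",
    outcome = "delta",
    fixed_effects = rhs_terms,
    ci_method = "Wald, large-sample normal",
    singular = is_singular_fit(fit),
    n_obs = nrow(d)
  ))
}

#' Vitamin-C contrast on the post-intervention FMD change
#'
#' Per-condition intervention-vs-none differences come from the interaction
#' model `fmd_change_pct ~ condition * vitc + (1 | participant)`; the pooled
#' contrast from the main-effects model `~ condition + vitc`.
#'
#' @param cohort A `crossover_cohort` with `fmd_change_pct` and `vitc`
#'   (0/1) columns.
#' @param conf Confidence level.
#' @return An `effect_table`: `differences` holds the vitamin-C contrast per
#'   condition plus a pooled row; `means` the per-condition x group model
#'   means.
#' @export
fit_vitc_contrast <- function(cohort, conf = 0.95) {
  d <- prep_cohort(cohort)
  if (length(unique(d$vitc)) < 2L) {
    stop("both intervention groups must be present", call. = FALSE)
  }
  d$vitc <- as.numeric(d$vitc)
  fit_int <- fit_lmm_engine(d, "fmd_change_pct", "condition * vitc")
  beta <- fixef_of(fit_int); V <- vcov_of(fit_int)

  # per condition: design-row difference (vitc=1) - (vitc=0)
  levs <- levels(d$condition)
  rhs <- ~ condition * vitc
  grid1 <- data.frame(condition = factor(levs, levels = levs), vitc = 1)
  grid0 <- data.frame(condition = factor(levs, levels = levs), vitc = 0)
  Ld <- model.matrix(rhs, grid1) - model.matrix(rhs, grid0)
  rownames(Ld) <- levs
  per_cond <- cbind(condition = levs, wald_rows(Ld, beta, V, conf))

  fit_main <- fit_lmm_engine(d, "fmd_change_pct", "condition + vitc")
  bm <- fixef_of(fit_main); Vm <- vcov_of(fit_main)
  Lp <- matrix(0, 1L, length(bm), dimnames = list("pooled", names(bm)))
  Lp[1L, "vitc"] <- 1
  pooled <- cbind(condition = "all", wald_rows(Lp, bm, Vm, conf))
  diffs <- rbind(per_cond, pooled)
  rownames(diffs) <- NULL

  Lg <- rbind(cbind(model.matrix(rhs, grid0)), cbind(model.matrix(rhs, grid1)))
  gm <- data.frame(
    condition = rep(levs, 2L),
    vitc = rep(c(0, 1), each = length(levs)),
    estimate = drop(Lg %*% beta)
  )
  new_effect_table(gm, diffs, list(
    model = "linear mixed model, exposure + intervention fixed effects",
    outcome = "fmd_change_pct",
    fixed_effects = "condition * vitc (per-condition), condition + vitc (pooled)",
    ci_method = "Wald, large-sample normal",
    singular = is_singular_fit(fit_int),
    n_obs = nrow(d)
  ))
}
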