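BEHAVIOUR_COLS <- c("p_sit", "p_raised", "p_stand", "p_off_nest", "p_off_ledge")

#' Boldness scoring by principal component analysis
#'
#' Collapses the five behaviour-state proportions of the novel-object test
#' into a single score, the first principal component of the centred,
#' unscaled (covariance) PCA. Because the five proportions sum to one,
#' the compositional constraint forces a zero-variance fifth component
#' whose loadings are all `1/sqrt(5)` in absolute value; the leading
#' components therefore capture all behavioural variation by component
#' four. PC1 is sign-oriented so that the sitting proportion loads
#' positively: high scores mean the bird stayed seated through the test
#' (bold), low scores that it left (shy).
#'
#' @param tests data frame with the five proportion columns `p_sit`,
#'   `p_raised`, `p_stand`, `p_off_nest`, `p_off_ledge` (each row one
#'   test, rows summing to 1).
#' @return list with `loadings` (5 x 5 orthonormal matrix),
#'   `variance_explained` (per-component proportions),
#'   `cumulative_variance`, `scores` (per-test PC1) and the full score
#'   matrix `all_scores`.
#' @export
pca_boldness <- function(tests) {
  X <- as.matrix(tests[, BEHAVIOUR_COLS])
  if (nrow(X) < 6)
    abort_fmt("need at least 6 tests for a 5-variable PCA (got %d)", nrow(X))
  if (any(abs(rowSums(X) - 1) > 1e-6))
    abort_fmt("behaviour proportions must sum to 1 per test")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  if (load["p_sit", 1] < 0) {
    load[, 1] <- -load[, 1]
    scores[, 1] <- -scores[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    loadings = load,
    variance_explained = ve,
    cumulative_variance = cumsum(ve),
    scores = scores[, 1],
    all_scores = scores
  )
}

#' Adjusted repeatability of a trait
#'
#' Estimates repeatability (intraclass correlation) as the between-
#' individual share of variance from a linear mixed model with a random
#' intercept per individual,
#' `R = sigma2_id / (sigma2_id + sigma2_residual)`, adjusted for the
#' supplied fixed covariates. Confidence intervals come from a seeded
#' parametric bootstrap (simulate from the fitted model, refit, recompute
#' R); the p value is a likelihood-ratio test of the random effect
#' against the 50:50 chi-square(0)/chi-square(1) mixture appropriate for
#' a variance component on the boundary.
#'
#' The default interval is the basic (reflected) bootstrap,
#' `2*R - quantile(R*, 1 - a)`, clamped to `[0, 1]`: the variance-ratio
#' estimator is biased toward zero in small samples and the percentile
#' interval inherits that bias twice, while the basic interval cancels
#' it. Percentile intervals remain available via `ci_type`.
#'
#' @param values numeric response (e.g. per-test PC1 scores).
#' @param ids individual identifiers, same length.
#' @param covariates optional data frame of fixed covariates.
#' @param n_boot parametric bootstrap replicates (default 1000).
#' @param ci_levels confidence levels for bootstrap intervals.
#' @param ci_type `"basic"` (default) or `"perc"`.
#' @param seed RNG seed for the bootstrap.
#' @return list with `R`, `ci` (matrix, one row per level), `p`,
#'   `var_id`, `var_residual`, `n_boot`.
#' @export
adjusted_repeatability <- function(values, ids, covariates = NULL,
                                   n_boot = 1000, ci_levels = 0.95,
                                   ci_type = c("basic", "perc"),
                                   seed = 1) {
  ci_type <- match.arg(ci_type)
  df <- data.frame(.value = values, .id = factor(ids))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (!any(table(df$.id) >= 2))
    abort_fmt("repeatability undefined: no individual has repeated measures")
  rhs <- if (is.null(covariates)) "1" else
    paste(colnames(covariates), collapse = " + ")
  form <- stats::as.formula(paste(".value ~", rhs, "+ (1 | .id)"))

  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # numerically exact repetition within birds defeats the mixed-model
    # solver; the variance decomposition is then degenerate with R = 1
    within_var <- mean(tapply(df$.value, df$.id, stats::var), na.rm = TRUE)
    total_var <- stats::var(df$.value)
    if (is.finite(within_var) && within_var <= 1e-10 * max(total_var, 1)) {
      ci <- matrix(1, length(ci_levels), 2,
                   dimnames = list(paste0(ci_levels * 100, "%"),
                                   c("lower", "upper")))
      return(list(R = 1, ci = ci, p = 0,
                  var_id = total_var, var_residual = within_var,
                  n_boot = n_boot))
    }
    stop(fit)
  }
  rep_from_fit <- function(m) {
    vc <- lme4::VarCorr(m)
    vb <- as.numeric(vc$.id)
    ve <- attr(vc, "sc")^2
    if (vb + ve <= 0) return(0)
    vb / (vb + ve)
  }
  R <- rep_from_fit(fit)
  vc <- lme4::VarCorr(fit)
  vb <- as.numeric(vc$.id)
  ve <- attr(vc, "sc")^2

  ci <- matrix(NA_real_, length(ci_levels), 2,
               dimnames = list(paste0(ci_levels * 100, "%"), c("lower", "upper")))
  if (n_boot > 0) {
    if (ve < 1e-10 * max(vb, 1)) {
      # degenerate: no residual variance, R pinned at 1
      ci[] <- 1
    } else {
      bs <- suppressMessages(suppressWarnings(
        lme4::bootMer(fit, rep_from_fit, nsim = n_boot, seed = seed,
                      type = "parametric")
      ))
      for (k in seq_along(ci_levels)) {
        q <- quantile_ci(bs$t[, 1], ci_levels[k])
        ci[k, ] <- if (ci_type == "basic")
          pmin(pmax(c(2 * R - q[2], 2 * R - q[1]), 0), 1) else q
      }
    }
  }

  # LRT of the random effect (ML fits), boundary-corrected mixture p value
  fit_ml <- lme4::refitML(fit)
  form0 <- stats::as.formula(paste(".value ~", rhs))
  fit0 <- stats::lm(form0, data = df)
  D <- 2 * (as.numeric(stats::logLik(fit_ml)) - as.numeric(stats::logLik(fit0)))
  p <- if (D <= 0) 1 else 0.5 * stats::pchisq(D, df = 1, lower.tail = FALSE)

  list(R = R, ci = ci, p = p, var_id = vb, var_residual = ve, n_boot = n_boot)
}

#' One boldness estimate per individual
#'
#' Fits ordinary least squares with individual identity as a factor
#' without a global intercept, plus the supplied covariates (numeric
#' covariates are centred first so per-bird coefficients are estimates at
#' mean covariate values). The coefficient on each individual's factor
#' level is its boldness; birds tested once still receive an estimate.
#' Covariates aliased with the design (rank deficiency) are dropped with
#' a warning.
#'
#' @param scores per-test PC1 scores.
#' @param ids individual identifiers, same length.
#' @param covariates optional data frame of fixed covariates.
#' @return data frame with `bird_id`, `boldness`, `n_tests`.
#' @export
individual_boldness <- function(scores, ids, covariates = NULL) {
  df <- data.frame(.score = scores, .id = factor(ids))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    for (nm in names(cv)) {
      if (inherits(cv[[nm]], "Date")) cv[[nm]] <- as.numeric(cv[[nm]])
      if (is.numeric(cv[[nm]])) cv[[nm]] <- cv[[nm]] - mean(cv[[nm]])
    }
    df <- cbind(df, cv)
    cov_names <- names(cv)
  }
  repeat {
    rhs <- paste(c("0", ".id", cov_names), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste(".score ~", rhs)), data = df)
    co <- stats::coef(fit)
    bad <- names(co)[is.na(co)]
    bad_cov <- unique(unlist(lapply(cov_names, function(nm)
      if (any(startsWith(bad, nm))) nm else NULL)))
    if (length(bad_cov) == 0) break
    warning("dropping aliased covariate(s): ", paste(bad_cov, collapse = ", "),
            call. = FALSE)
    cov_names <- setdiff(cov_names, bad_cov)
  }
  lev <- levels(df$.id)
  est <- stats::coef(fit)[paste0(".id", lev)]
  data.frame(
    bird_id = lev,
    boldness = as.numeric(est),
    n_tests = as.integer(table(df$.id)[lev]),
    stringsAsFactors = FALSE
  )
}

#' Median split into bold and shy groups
#'
#' Birds strictly above the median boldness score are bold; birds at or
#' below the median are shy (the tie at the median goes to shy, an
#' explicit rule the split needs to be reproducible). With distinct
#' scores the groups differ in size by at most one.
#'
#' @param scores data frame from [individual_boldness()] (columns
#'   `bird_id`, `boldness`), or a named numeric vector.
#' @return the input with a `group` column (`"bold"`/`"shy"`).
#' @export
classify_bold_shy <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(bird_id = names(scores), boldness = as.numeric(scores))
  if (nrow(scores) < 2) abort_fmt("need at least 2 birds for a median split")
  med <- stats::median(scores$boldness)
  scores$group <- ifelse(scores$boldness > med, "bold", "shy")
  if (all(scores$group == "shy"))
    warning("all scores equal: every bird classified shy", call. = FALSE)
  scores
}
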