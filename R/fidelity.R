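check_sites <- function(sites) {
  need <- c("site_id", "bird_id", "trip_id", "lat_c", "lon_c")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    abort_fmt("sites must be a data frame with columns %s",
              paste(need, collapse = ", "))
  if (is.null(sites$colony_id)) sites$colony_id <- "colony1"
  if (is.null(sites$t_mid)) sites$t_mid <- as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
  sites
}

# bird ids with sites on >= 2 distinct trips
eligible_focal_birds <- function(sites) {
  tab <- tapply(sites$trip_id, sites$bird_id, function(x) length(unique(x)))
  names(tab)[tab >= 2]
}

#' Draw the random pairing for one focal site
#'
#' Pairs a focal foraging site with (a) one site used by the same bird on
#' a different trip (the within-individual pair) and (b) one site from
#' each other bird of the focal bird's colony (the between-individual
#' pairs), all drawn uniformly. Single-trip birds cannot be focal but are
#' retained as between-individual donors.
#'
#' @param sites site table (`site_id`, `bird_id`, `trip_id`, `colony_id`,
#'   `lat_c`, `lon_c`, `t_mid`).
#' @param focal_site_id the focal site's `site_id`.
#' @return list with `focal_site_id`, `within_site_id` and
#'   `between_site_ids` (named by donor bird).
#' @export
draw_pairs <- function(sites, focal_site_id) {
  sites <- check_sites(sites)
  f <- sites[sites$site_id == focal_site_id, ]
  if (nrow(f) != 1) abort_fmt("focal site '%s' not found", focal_site_id)
  own <- sites[sites$bird_id == f$bird_id & sites$trip_id != f$trip_id, ]
  if (nrow(own) == 0)
    abort_fmt("bird '%s' has no sites on another trip; single-trip birds cannot be focal",
              f$bird_id)
  colony <- sites[sites$colony_id == f$colony_id, ]
  others <- unique(colony$bird_id[colony$bird_id != f$bird_id])
  if (length(others) == 0)
    abort_fmt("colony '%s' has fewer than 2 birds with sites", f$colony_id)
  within <- own$site_id[sample.int(nrow(own), 1)]
  between <- vapply(others, function(b) {
    cand <- colony$site_id[colony$bird_id == b]
    cand[sample.int(length(cand), 1)]
  }, character(1))
  list(focal_site_id = focal_site_id, within_site_id = within,
       between_site_ids = between)
}

#' Bernoulli similarity outcomes for one pairing
#'
#' For each between-individual paired site, the outcome is 1 when the
#' focal bird's own within-individual paired site is closer to the focal
#' site than the other bird's site (the inverted similarity index, so 1
#' accumulates toward high fidelity). Equal distances score 0. Also
#' returns the absolute time difference in days between the focal and
#' within-individual sites, the pairing's temporal-proximity covariate.
#'
#' @param pair a pairing from [draw_pairs()].
#' @param sites the site table.
#' @return list with `outcomes` (0/1 vector named by donor bird) and
#'   `timediff_days`.
#' @export
similarity_outcomes <- function(pair, sites) {
  sites <- check_sites(sites)
  idx <- match(c(pair$focal_site_id, pair$within_site_id, pair$between_site_ids),
               sites$site_id)
  f <- sites[idx[1], ]
  w <- sites[idx[2], ]
  b <- sites[idx[-(1:2)], ]
  d_w <- haversine_m(c(f$lat_c, f$lon_c), c(w$lat_c, w$lon_c))
  d_b <- haversine_m(matrix(c(f$lat_c, f$lon_c), 1),
                     cbind(b$lat_c, b$lon_c))
  outcomes <- as.integer(d_w < d_b)
  names(outcomes) <- names(pair$between_site_ids)
  list(outcomes = outcomes,
       timediff_days = abs(as.numeric(difftime(f$t_mid, w$t_mid, units = "days"))))
}

# Precompute everything an iteration reuses: per-colony distance matrices,
# per-site within-trip candidates, per-bird donor site indices.
fidelity_randomization_prep <- function(sites) {
  sites <- check_sites(sites)
  focal_birds <- eligible_focal_birds(sites)
  if (length(focal_birds) == 0)
    abort_fmt("no bird has sites on more than one trip")
  n <- nrow(sites)
  D <- matrix(NA_real_, n, n)
  for (cid in unique(sites$colony_id)) {
    idx <- which(sites$colony_id == cid)
    if (length(unique(sites$bird_id[idx])) < 2)
      abort_fmt("colony '%s' has fewer than 2 birds with sites", cid)
    p <- cbind(sites$lat_c[idx], sites$lon_c[idx])
    for (k in seq_along(idx))
      D[idx[k], idx] <- haversine_m(p[rep(k, length(idx)), , drop = FALSE], p)
  }
  tdays <- as.numeric(sites$t_mid) / 86400
  focal <- which(sites$bird_id %in% focal_birds)
  within_cand <- lapply(focal, function(f)
    which(sites$bird_id == sites$bird_id[f] & sites$trip_id != sites$trip_id[f]))
  donors <- lapply(focal, function(f) {
    others <- setdiff(unique(sites$bird_id[sites$colony_id == sites$colony_id[f]]),
                      sites$bird_id[f])
    lapply(others, function(b) which(sites$bird_id == b))
  })
  list(sites = sites, focal_birds = focal_birds, focal = focal,
       within_cand = within_cand, donors = donors, D = D, tdays = tdays,
       focal_bird_of_site = sites$bird_id[focal])
}

#' One randomization iteration of the site-fidelity index
#'
#' Runs the pairing for every site of every eligible focal bird (birds
#' with sites on at least two trips), pools the Bernoulli outcomes and
#' fits a binomial GLM with bird identity as a factor (no global
#' intercept) plus the centred within-pair time difference. Each bird's
#' fidelity estimate is the inverse logit of its coefficient (i.e. at the
#' mean time difference); the standard error is propagated by the delta
#' method. Birds in complete separation (all outcomes equal) are clamped
#' to `[1/(2m), 1 - 1/(2m)]` for m outcomes and flagged.
#'
#' @param sites site table for one breeding stage.
#' @param include_timediff include the time-difference covariate?
#' @param prep internal precomputation (reused across iterations).
#' @return data frame with one row per eligible bird: `bird_id`,
#'   `fidelity`, `se`, `n_outcomes`, `separated`.
#' @export
fidelity_iteration <- function(sites, include_timediff = TRUE, prep = NULL) {
  if (is.null(prep)) prep <- fidelity_randomization_prep(sites)
  focal_birds <- prep$focal_birds
  nf <- length(prep$focal)
  bird_v <- outcome_v <- td_v <- vector("list", nf)
  for (k in seq_len(nf)) {
    f <- prep$focal[k]
    wc <- prep$within_cand[[k]]
    w <- wc[sample.int(length(wc), 1)]
    dons <- prep$donors[[k]]
    bsel <- vapply(dons, function(ix) ix[sample.int(length(ix), 1)], integer(1))
    d_w <- prep$D[f, w]
    outcome_v[[k]] <- as.integer(d_w < prep$D[f, bsel])
    bird_v[[k]] <- rep(prep$focal_bird_of_site[k], length(bsel))
    td_v[[k]] <- rep(abs(prep$tdays[f] - prep$tdays[w]), length(bsel))
  }
  bird <- factor(unlist(bird_v), levels = focal_birds)
  outcome <- unlist(outcome_v)
  td_c <- unlist(td_v)
  td_c <- td_c - mean(td_c)

  means <- tapply(outcome, bird, mean)
  m <- tapply(outcome, bird, length)
  separated <- means <= 0 | means >= 1
  out <- data.frame(
    bird_id = focal_birds,
    fidelity = NA_real_, se = NA_real_,
    n_outcomes = as.integer(m), separated = as.logical(separated),
    stringsAsFactors = FALSE
  )
  out$fidelity[separated] <- pmin(pmax(means[separated], 1 / (2 * m[separated])),
                                  1 - 1 / (2 * m[separated]))
  out$se[separated] <- sqrt(out$fidelity[separated] * (1 - out$fidelity[separated]) /
                              m[separated])
  keep_birds <- focal_birds[!separated]
  if (length(keep_birds)) {
    rows <- bird %in% keep_birds
    X <- outer(as.character(bird[rows]), keep_birds, "==") + 0
    colnames(X) <- keep_birds
    use_td <- include_timediff && stats::sd(td_c[rows]) > 0
    if (use_td) X <- cbind(X, td_c = td_c[rows])
    fit <- suppressWarnings(stats::glm.fit(X, outcome[rows],
                                           family = stats::binomial()))
    eta <- fit$coefficients[keep_birds]
    W <- fit$weights
    cov <- tryCatch(solve(crossprod(X * sqrt(W))), error = function(e) NULL)
    se_eta <- if (is.null(cov)) rep(NA_real_, length(keep_birds)) else
      sqrt(diag(cov))[seq_along(keep_birds)]
    p <- stats::plogis(eta)
    i <- match(keep_birds, out$bird_id)
    out$fidelity[i] <- p
    out$se[i] <- se_eta * p * (1 - p)
  }
  out
}

#' Run the full site-fidelity randomization
#'
#' Repeats [fidelity_iteration()] `n_iter` times (default 1,000) under a
#' single seeded RNG stream, so each focal site is randomly paired
#' `n_iter` times; two runs with the same seed are identical.
#'
#' @inheritParams fidelity_iteration
#' @param n_iter number of randomization iterations.
#' @param seed RNG seed.
#' @return data frame of per-bird, per-iteration estimates (`bird_id`,
#'   `iteration`, `fidelity`, `se`, `separated`), with a per-bird summary
#'   (mean and sd over iterations) in attribute `summary`.
#' @export
run_fidelity_randomization <- function(sites, n_iter = 1000, seed = 1,
                                       include_timediff = TRUE) {
  prep <- fidelity_randomization_prep(sites)
  set.seed(seed)
  its <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    est <- fidelity_iteration(sites, include_timediff = include_timediff,
                              prep = prep)
    est$iteration <- i
    its[[i]] <- est
  }
  out <- do.call(rbind, its)
  smry <- do.call(rbind, lapply(split(out, out$bird_id), function(d) data.frame(
    bird_id = d$bird_id[1],
    fidelity_mean = mean(d$fidelity),
    fidelity_sd = stats::sd(d$fidelity),
    stringsAsFactors = FALSE
  )))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}

# terms of the fidelity / spatial models that actually vary in the data
usable_terms <- function(birds, candidates) {
  ok <- vapply(candidates, function(tm) {
    v <- birds[[tm]]
    !is.null(v) && length(unique(v)) >= 2
  }, logical(1))
  candidates[ok]
}

#' Model site fidelity against boldness across randomization iterations
#'
#' For each randomization iteration's per-bird fidelity estimates, fits
#' the linear model `fidelity ~ boldness + sex + colony + date` (terms
#' that do not vary in the data are omitted). The two-way interactions
#' boldness:sex and boldness:colony are screened first on the
#' iteration-mean estimates by F-test model comparison and kept only if
#' significant. Per-term F statistics and p values are averaged across
#' iterations; coefficients are reported as the across-iteration mean
#' with 2.5%/97.5% iteration quantiles (the spread induced by the random
#' pairing) and as a confidence interval combining the mean estimate with
#' the mean model standard error (the interval used for inference).
#'
#' @param estimates output of [run_fidelity_randomization()].
#' @param birds per-bird covariate table: `bird_id`, `boldness` and
#'   optionally `sex`, `colony_id`, `date`.
#' @param alpha significance threshold for keeping interactions.
#' @return list with `coefficients` (data frame: term, mean, iter_lower,
#'   iter_upper, mean_se, ci_lower, ci_upper), `terms` (term, mean_F,
#'   mean_p), `dropped_interactions`, `n_iter`, `formula`.
#' @export
boldness_fidelity_model <- function(estimates, birds, alpha = 0.05) {
  if (is.null(birds$boldness)) abort_fmt("`birds` must contain a boldness column")
  if (!is.null(birds$date) && inherits(birds$date, "Date"))
    birds$date <- as.numeric(birds$date)
  main <- c("boldness", usable_terms(birds, c("sex", "colony_id", "date")))
  cand_int <- intersect(c("sex", "colony_id"), main)
  cand_int <- if (length(cand_int)) paste0("boldness:", cand_int) else character(0)

  merge_iter <- function(est) merge(est, birds, by = "bird_id")
  mean_est <- stats::aggregate(fidelity ~ bird_id, data = estimates, FUN = mean)
  dmean <- merge_iter(mean_est)
  if (any(is.na(dmean$boldness)))
    abort_fmt("every estimated bird needs covariates (missing boldness for %s)",
              paste(dmean$bird_id[is.na(dmean$boldness)], collapse = ", "))

  base_form <- stats::as.formula(paste("fidelity ~", paste(main, collapse = " + ")))
  # screen interactions on the iteration-mean estimates
  dropped <- character(0)
  kept_int <- character(0)
  for (it in cand_int) {
    f_full <- stats::update(base_form, paste(". ~ . +", it))
    fit_full <- stats::lm(f_full, data = dmean)
    if (any(is.na(stats::coef(fit_full)))) { dropped <- c(dropped, it); next }
    fit_red <- stats::lm(base_form, data = dmean)
    a <- stats::anova(fit_red, fit_full)
    pv <- a$`Pr(>F)`[2]
    if (is.na(pv) || pv > alpha) dropped <- c(dropped, it) else kept_int <- c(kept_int, it)
  }
  form <- if (length(kept_int))
    stats::update(base_form, paste(". ~ . +", paste(kept_int, collapse = " + ")))
  else base_form

  fit0 <- stats::lm(form, data = dmean)
  if (any(is.na(stats::coef(fit0)))) {
    al <- stats::alias(fit0)
    abort_fmt("aliased covariates in fidelity model: %s",
              paste(rownames(al$Complete), collapse = ", "))
  }

  iters <- sort(unique(estimates$iteration))
  coef_names <- names(stats::coef(fit0))
  coefs <- matrix(NA_real_, length(iters), length(coef_names),
                  dimnames = list(NULL, coef_names))
  ses <- coefs
  term_labels <- attr(stats::terms(fit0), "term.labels")
  Fs <- matrix(NA_real_, length(iters), length(term_labels),
               dimnames = list(NULL, term_labels))
  Ps <- Fs
  dfs <- NULL
  for (k in seq_along(iters)) {
    d <- merge_iter(estimates[estimates$iteration == iters[k], ])
    fit <- stats::lm(form, data = d)
    sm <- stats::coef(summary(fit))
    coefs[k, ] <- sm[coef_names, "Estimate"]
    ses[k, ] <- sm[coef_names, "Std. Error"]
    dr <- stats::drop1(fit, test = "F")
    Fs[k, ] <- dr[term_labels, "F value"]
    Ps[k, ] <- dr[term_labels, "Pr(>F)"]
    if (is.null(dfs)) dfs <- stats::df.residual(fit)
  }
  qs <- apply(coefs, 2, quantile_ci, level = 0.95)
  mean_coef <- colMeans(coefs)
  mean_se <- colMeans(ses)
  list(
    coefficients = data.frame(
      term = coef_names,
      mean = mean_coef,
      iter_lower = qs[1, ], iter_upper = qs[2, ],
      mean_se = mean_se,
      ci_lower = mean_coef - stats::qnorm(0.975) * mean_se,
      ci_upper = mean_coef + stats::qnorm(0.975) * mean_se,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    terms = data.frame(
      term = term_labels,
      mean_F = colMeans(Fs), mean_p = colMeans(Ps),
      df_residual = dfs,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    dropped_interactions = dropped,
    n_iter = length(iters),
    formula = form
  )
}
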