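#' Pipeline configuration
#'
#' Defaults reflect the emulated study design: a 300 m colony buffer,
#' 1 hr minimum trip duration, interpolation to 10 min during incubation
#' and 2 min during chick rearing, a 3-state HMM, 1,000 randomization
#' iterations and 1,000 bootstrap replicates.
#'
#' @param buffer_m colony buffer radius (m).
#' @param min_trip_hr minimum trip duration (hr).
#' @param interp_min named fix-interval minutes per stage.
#' @param n_states HMM states.
#' @param n_restarts HMM fit restarts.
#' @param hmm_start optional [movement_hmm()] starting values.
#' @param fidelity_n_iter randomization iterations.
#' @param n_boot bootstrap replicates for repeatability intervals.
#' @param seed RNG seed; every stochastic stage derives from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(buffer_m = 300, min_trip_hr = 1,
                            interp_min = c(incubation = 10, chick_rearing = 2),
                            n_states = 3, n_restarts = 5, hmm_start = NULL,
                            fidelity_n_iter = 1000, n_boot = 1000, seed = 1) {
  stopifnot(buffer_m > 0, min_trip_hr > 0, all(interp_min > 0),
            n_states >= 1, n_restarts >= 1, fidelity_n_iter >= 1, n_boot >= 0,
            is.numeric(seed))
  structure(list(buffer_m = buffer_m, min_trip_hr = min_trip_hr,
                 interp_min = interp_min, n_states = n_states,
                 n_restarts = n_restarts, hmm_start = hmm_start,
                 fidelity_n_iter = fidelity_n_iter, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read pipeline input files
#'
#' @param dir directory containing `fixes.csv`, `colonies.csv` and
#'   optionally `personality.csv`.
#' @return list with `fixes` (POSIXct timestamps), `colonies`, `tests`.
#' @export
read_pipeline_inputs <- function(dir) {
  fp <- file.path(dir, "fixes.csv")
  cp <- file.path(dir, "colonies.csv")
  if (!file.exists(fp)) abort_fmt("input error [missing_fixes]: %s not found", fp)
  if (!file.exists(cp)) abort_fmt("input error [missing_colonies]: %s not found", cp)
  fixes <- utils::read.csv(fp, stringsAsFactors = FALSE)
  need <- c("bird_id", "colony_id", "stage", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(fixes))
  if (length(miss))
    abort_fmt("input error [schema]: fixes.csv lacks columns %s", paste(miss, collapse = ", "))
  fixes$t <- as.POSIXct(fixes$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(is.na(fixes$t)))
    abort_fmt("input error [schema]: unparseable ISO-8601 timestamps in rows %s",
              paste(utils::head(which(is.na(fixes$t)), 5), collapse = ", "))
  fixes <- fixes[order(fixes$bird_id, fixes$t), ]
  colonies <- utils::read.csv(cp, stringsAsFactors = FALSE)
  if (!all(c("colony_id", "lat", "lon") %in% names(colonies)))
    abort_fmt("input error [schema]: colonies.csv needs colony_id, lat, lon")
  pp <- file.path(dir, "personality.csv")
  tests <- if (file.exists(pp)) utils::read.csv(pp, stringsAsFactors = FALSE) else NULL
  list(fixes = fixes, colonies = colonies, tests = tests)
}

#' Run the full analysis pipeline
#'
#' Orchestrates segmentation, interpolation, HMM fitting and decoding
#' (one model per breeding stage, or per stage x region when the colony
#' table carries a `region` column), area-restricted-search screening,
#' foraging-site extraction, trip metrics, boldness scoring, the
#' site-fidelity randomization, group repeatability and the spatial
#' models. Every stochastic stage derives its seed from `config$seed`,
#' so identical inputs and config reproduce the report exactly.
#'
#' @param fixes fix table (`bird_id`, `colony_id`, `stage`, `t` POSIXct,
#'   `lat`, `lon`).
#' @param colonies colony coordinates (`colony_id`, `lat`, `lon`,
#'   optional `region`).
#' @param tests optional personality-test table (see
#'   [simulate_personality()] for columns).
#' @param bird_meta optional per-bird covariates (`bird_id`, `sex`).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for delimited-text outputs
#'   (`trips.csv`, `states.csv`, `sites.csv`, `boldness.csv`,
#'   `fidelity_estimates.csv`, `repeatability.csv`, `report.json`).
#' @return the report: a list with per-stage bookkeeping (`counts`),
#'   fitted models, site/trip tables and all estimates.
#' @export
run_pipeline <- function(fixes, colonies, tests = NULL, bird_meta = NULL,
                         config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(colonies$region)) colonies$region <- "all"
  colony_lookup <- function(id) {
    i <- match(id, colonies$colony_id)
    if (any(is.na(i)))
      abort_fmt("input error [missing_colony]: no coordinates for colony %s",
                paste(unique(id[is.na(i)]), collapse = ", "))
    i
  }

  # --- segmentation + interpolation ------------------------------------
  report_counts <- list()
  trips <- list()
  dropped_short <- 0L
  for (b in unique(fixes$bird_id)) {
    fb <- fixes[fixes$bird_id == b, ]
    ci <- colony_lookup(fb$colony_id[1])
    colony <- c(colonies$lat[ci], colonies$lon[ci])
    runs_all <- segment_trips(fb, colony, buffer_m = config$buffer_m,
                              min_duration_hr = 0)
    kept <- segment_trips(fb, colony, buffer_m = config$buffer_m,
                          min_duration_hr = config$min_trip_hr)
    dropped_short <- dropped_short + (length(runs_all) - length(kept))
    for (tr in kept) {
      iv <- config$interp_min[[tr$stage[1]]]
      if (is.null(iv)) iv <- config$interp_min[[1]]
      tr_i <- interpolate_trip(tr, iv)
      tr_i$region <- colonies$region[ci]
      tr_i$colony_lat <- colony[1]
      tr_i$colony_lon <- colony[2]
      trips[[tr_i$trip_id[1]]] <- tr_i
    }
  }
  if (length(trips) == 0) abort_fmt("input error [no_trips]: no foraging trips found")

  # --- HMM per stage x region group ------------------------------------
  groups <- vapply(trips, function(tr) paste(tr$stage[1], tr$region[1], sep = "|"),
                   character(1))
  hmm_fits <- list()
  states <- list()
  for (g in unique(groups)) {
    g_trips <- trips[groups == g]
    obs <- do.call(rbind, lapply(g_trips, steps_and_angles))
    set.seed(config$seed + 10L)
    fit <- fit_hmm(obs, n_states = config$n_states, start = config$hmm_start,
                   n_restarts = config$n_restarts)
    labels <- label_states(fit)
    path <- viterbi(fit, obs)
    obs$state <- path
    obs$label <- labels[path]
    hmm_fits[[g]] <- list(model = fit, labels = labels)
    states[[g]] <- obs
  }
  states <- do.call(rbind, states)

  # --- ARS screening + sites -------------------------------------------
  sites <- list()
  dropped_no_ars <- 0L
  kept_trips <- list()
  for (id in names(trips)) {
    tr <- trips[[id]]
    g <- paste(tr$stage[1], tr$region[1], sep = "|")
    path <- states$state[states$trip_id == id]
    s <- extract_sites(tr, path, hmm_fits[[g]]$labels)
    if (nrow(s) == 0) {
      dropped_no_ars <- dropped_no_ars + 1L
      next
    }
    s$stage <- tr$stage[1]
    s$colony_id <- tr$colony_id[1]
    sites[[id]] <- s
    kept_trips[[id]] <- tr
  }
  sites <- if (length(sites)) do.call(rbind, sites) else NULL

  # --- trip metrics -----------------------------------------------------
  metrics <- do.call(rbind, lapply(kept_trips, function(tr)
    cbind(trip_metrics(tr, c(tr$colony_lat[1], tr$colony_lon[1])),
          stage = tr$stage[1])))
  if (!is.null(metrics)) rownames(metrics) <- NULL

  report <- list(
    counts = list(
      n_fixes = nrow(fixes),
      n_birds = length(unique(fixes$bird_id)),
      trips_in = length(trips) + dropped_short,
      trips_kept = length(kept_trips),
      dropped_below_min_duration = dropped_short,
      dropped_no_ars = dropped_no_ars,
      n_sites = if (is.null(sites)) 0L else nrow(sites)
    ),
    hmm = lapply(hmm_fits, function(h) list(
      labels = h$labels,
      loglik = attr(h$model, "loglik"),
      AIC = attr(h$model, "AIC"),
      step_mean = h$model$step_mean, step_sd = h$model$step_sd,
      angle_mu = h$model$angle_mu, angle_kappa = h$model$angle_kappa,
      Gamma = h$model$Gamma, delta = h$model$delta
    )),
    trip_metrics = metrics,
    sites = sites
  )

  # --- personality ------------------------------------------------------
  boldness <- NULL
  if (!is.null(tests) && nrow(tests) >= 6) {
    pca <- pca_boldness(tests)
    covs <- data.frame(
      date = as.numeric(as.Date(tests$date)),
      stage = factor(tests$stage),
      observer = factor(tests$observer),
      test_number = tests$test_number
    )
    covs <- covs[, vapply(covs, function(x) length(unique(x)) >= 2, logical(1)),
                 drop = FALSE]
    rpt <- if (any(table(tests$bird_id) >= 2)) {
      adjusted_repeatability(pca$scores, tests$bird_id,
                             covariates = if (ncol(covs)) covs else NULL,
                             n_boot = config$n_boot, seed = config$seed + 20L)
    } else NULL
    ib <- individual_boldness(pca$scores, tests$bird_id,
                              covariates = if (ncol(covs)) covs else NULL)
    boldness <- classify_bold_shy(ib)
    report$personality <- list(
      loadings = pca$loadings,
      variance_explained = pca$variance_explained,
      repeatability = rpt,
      n_bold = sum(boldness$group == "bold"),
      n_shy = sum(boldness$group == "shy")
    )
    report$boldness <- boldness
  }

  # --- per-stage analyses ----------------------------------------------
  if (!is.null(sites) && !is.null(boldness)) {
    bird_covars <- boldness[, c("bird_id", "boldness")]
    if (!is.null(bird_meta)) bird_covars <- merge(bird_covars, bird_meta, by = "bird_id",
                                                  all.x = TRUE)
    cmap <- unique(sites[, c("bird_id", "colony_id")])
    bird_covars <- merge(bird_covars, cmap, by = "bird_id", all.x = TRUE)
    dmap <- stats::aggregate(as.numeric(sites$t_mid), list(bird_id = sites$bird_id), mean)
    names(dmap)[2] <- "date"
    # centred days, not epoch seconds, to keep model matrices well scaled
    dmap$date <- (dmap$date - mean(dmap$date)) / 86400
    bird_covars <- merge(bird_covars, dmap, by = "bird_id", all.x = TRUE)

    report$fidelity <- list()
    report$spatial <- list()
    report$repeatability <- list()
    for (st in unique(sites$stage)) {
      s_st <- sites[sites$stage == st, ]
      fid <- try(run_fidelity_randomization(
        s_st, n_iter = config$fidelity_n_iter, seed = config$seed + 30L), silent = TRUE)
      if (!inherits(fid, "try-error")) {
        mod <- try(boldness_fidelity_model(fid, bird_covars), silent = TRUE)
        report$fidelity[[st]] <- list(
          summary = attr(fid, "summary"),
          model = if (inherits(mod, "try-error")) attr(mod, "condition")$message else mod,
          estimates = fid
        )
      } else {
        report$fidelity[[st]] <- attr(fid, "condition")$message
      }
      sp <- try(spatial_partition_models(s_st, bird_covars), silent = TRUE)
      report$spatial[[st]] <- if (inherits(sp, "try-error"))
        attr(sp, "condition")$message else sp
      m_st <- metrics[metrics$stage == st, ]
      gr <- try(group_repeatability(m_st, boldness, n_boot = config$n_boot,
                                    seed = config$seed + 40L), silent = TRUE)
      report$repeatability[[st]] <- if (inherits(gr, "try-error"))
        attr(gr, "condition")$message else gr
    }
  }

  if (!is.null(output_dir)) write_pipeline_outputs(report, states, output_dir)
  report
}

write_pipeline_outputs <- function(report, states, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x) && is.data.frame(x))
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(report$trip_metrics, "trips.csv")
  w(report$sites, "sites.csv")
  w(states[, c("trip_id", "index", "state", "label")], "states.csv")
  w(report$boldness, "boldness.csv")
  for (st in names(report$fidelity)) {
    fi <- report$fidelity[[st]]
    if (is.list(fi)) {
      w(fi$estimates, sprintf("fidelity_estimates_%s.csv", st))
      w(fi$summary, sprintf("fidelity_summary_%s.csv", st))
    }
  }
  for (st in names(report$repeatability))
    if (is.data.frame(report$repeatability[[st]]))
      w(report$repeatability[[st]], sprintf("repeatability_%s.csv", st))
  slim <- report
  slim$sites <- NULL
  slim$trip_metrics <- NULL
  for (st in names(slim$fidelity))
    if (is.list(slim$fidelity[[st]])) slim$fidelity[[st]]$estimates <- NULL
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns", POSIXt = "ISO8601")
  invisible(dir)
}
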