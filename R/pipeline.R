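#' Default pipeline configuration
#'
#' The full configuration list accepted by [validate_config()] and
#' [run_pipeline()], with the study defaults: synthetic input mode, a
#' 15-variety x 2-N x 15-replicate design imaged on 12 days, the
#' default segmentation parameters, variety-mean growth fitting, and
#' the standard nitrogen inputs per pot.
#'
#' @return A nested configuration list.
#' @export
default_run_config <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    paths = list(manifest = NULL, trait_csv = NULL, harvest_csv = NULL),
    synthetic = list(n_varieties = 15L, n_replicates = 15L,
                     imaging_days = seq(25, 80, by = 5)),
    segmentation = list(grey_threshold = 0.95,
                        plant_hue_window = c(60, 180),
                        cage_hue_window = c(200, 260),
                        saturation_min = 0.25,
                        min_component_area = 4L,
                        morphology_radius = 0L),
    growth = list(per_pot = FALSE, grid_res = 0.1),
    n_inputs = as.list(n_input_defaults),
    report = list(rank_trait = "dw_g", top_k = 3L)
  )
}

.config_keys <- list(
  top = c("mode", "seed", "paths", "synthetic", "segmentation", "growth",
          "n_inputs", "report"),
  paths = c("manifest", "trait_csv", "harvest_csv"),
  synthetic = c("n_varieties", "n_replicates", "imaging_days"),
  segmentation = c("roi", "grey_threshold", "plant_hue_window",
                   "cage_hue_window", "saturation_min",
                   "min_component_area", "morphology_radius"),
  growth = c("per_pot", "grid_res"),
  report = c("rank_trait", "top_k"))

#' Validate a pipeline configuration
#'
#' Reads a configuration from a YAML file (or takes a list), fills in
#' defaults, and checks it against a strict schema: unknown keys are
#' errors, exactly one input mode may be active, referenced paths must
#' exist, and numeric parameters must be in range. All violations are
#' collected and reported together.
#'
#' @param config path to a YAML file, or a configuration list.
#' @param stop_on_error raise an error listing every violation
#'   (default); if `FALSE`, return the character vector of errors
#'   (empty when valid) instead of the config.
#' @return The validated configuration (class `run_config`), or the
#'   error vector when `stop_on_error = FALSE`.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_bad_arg("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_bad_arg("`config` must be a list or a YAML path")
  errors <- character(0)
  err <- function(...) errors <<- c(errors, paste0(...))

  unknown <- setdiff(names(config), .config_keys$top)
  if (length(unknown)) err("unknown key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("paths", "synthetic", "segmentation", "growth", "report")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), .config_keys[[sec]])
      if (length(bad))
        err(sec, ": unknown key(s): ", paste(bad, collapse = ", "))
    }
  }

  full <- utils::modifyList(default_run_config(),
                            config[intersect(names(config), .config_keys$top)])

  if (!is.character(full$mode) || length(full$mode) != 1L ||
      !full$mode %in% c("synthetic", "image_manifest", "trait_csv"))
    err("mode: must be one of synthetic, image_manifest, trait_csv")
  if (!is.numeric(full$seed) || length(full$seed) != 1L ||
      full$seed != round(full$seed))
    err("seed: must be a single integer")

  active_paths <- c(manifest = !is.null(full$paths$manifest),
                    trait_csv = !is.null(full$paths$trait_csv))
  if (sum(active_paths) > 1L)
    err("paths: manifest and trait_csv are both set; exactly one input mode may be active")
  if (identical(full$mode, "image_manifest") && !active_paths[["manifest"]])
    err("paths.manifest: required in image_manifest mode")
  if (identical(full$mode, "trait_csv") && !active_paths[["trait_csv"]])
    err("paths.trait_csv: required in trait_csv mode")
  if (identical(full$mode, "synthetic") && any(active_paths))
    err("paths: no input paths may be set in synthetic mode")
  for (p in c("manifest", "trait_csv", "harvest_csv")) {
    v <- full$paths[[p]]
    if (!is.null(v) && !file.exists(v))
      err("paths.", p, ": file not found: ", v)
  }

  syn <- full$synthetic
  if (!is.numeric(syn$n_varieties) || syn$n_varieties < 2)
    err("synthetic.n_varieties: must be an integer >= 2")
  if (!is.numeric(syn$n_replicates) || syn$n_replicates < 1)
    err("synthetic.n_replicates: must be an integer >= 1")
  if (!is.numeric(syn$imaging_days) || length(syn$imaging_days) < 5L ||
      any(diff(syn$imaging_days) <= 0))
    err("synthetic.imaging_days: must be >= 5 strictly increasing days")

  seg <- tryCatch(do.call(segmentation_config, full$segmentation),
                  error = function(e) e)
  if (inherits(seg, "error"))
    err("segmentation: ", conditionMessage(seg))

  if (!is.logical(full$growth$per_pot) || length(full$growth$per_pot) != 1L)
    err("growth.per_pot: must be TRUE or FALSE")
  if (!is.numeric(full$growth$grid_res) || full$growth$grid_res <= 0)
    err("growth.grid_res: must be a positive number of days")

  if (!is.numeric(unlist(full$n_inputs)) || any(unlist(full$n_inputs) <= 0))
    err("n_inputs: all N inputs must be positive grams")
  if (!is.numeric(full$report$top_k) || full$report$top_k < 0)
    err("report.top_k: must be a non-negative integer")

  if (!stop_on_error) return(errors)
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  full$seed <- as.integer(full$seed)
  structure(full, class = c("run_config", "list"))
}

#' Simulate a full screening study
#'
#' Generates a coherent synthetic study at the platform's scale: per
#' variety x nitrogen level a one-breakpoint piecewise-linear mean EB
#' trajectory (a mix of commencement- and completion-type series, with
#' later commencement and steeper slopes at optimum N), per-pot series
#' with multiplicative pot vigour and additive observation noise, and
#' a per-pot harvest table derived from the final EB so that harvest
#' biomass and grain yield correlate with the image traits.
#'
#' @param n_varieties,n_replicates design size.
#' @param imaging_days DAS of imaging (>= 5, strictly increasing).
#' @param seed integer seed.
#' @return List with `trait_series` (pot x day EB/TVA records),
#'   `harvest` (per-pot harvest and vegetative traits) and `truth`
#'   (the variety-level generating parameters).
#' @export
simulate_study <- function(n_varieties = 15L, n_replicates = 15L,
                           imaging_days = seq(25, 80, by = 5), seed = 1L) {
  with_seed(seed, {
    varieties <- sprintf("Var%02d", seq_len(n_varieties))
    n_levels <- c("low", "optimum")
    d1 <- imaging_days[1L]; dn <- imaging_days[length(imaging_days)]
    truth <- list(); series <- list(); harvest <- list()
    pot <- 0L
    for (nl in n_levels) {
      for (v in varieties) {
        vig <- exp(stats::rnorm(1, 0, 0.15))
        commence <- stats::runif(1) < if (nl == "low") 0.35 else 0.9
        if (nl == "low") {
          if (commence) {
            bp <- stats::runif(1, d1 + 10, min(52, dn - 5))
            s1 <- stats::runif(1, 5, 8) * vig
            s2 <- s1 * stats::runif(1, 1.6, 2.4)
          } else {
            bp <- stats::runif(1, max(60, d1 + 10), dn - 5)
            s1 <- stats::runif(1, 6, 14) * vig
            s2 <- s1 * stats::runif(1, 0.35, 0.65)
          }
          start_eb <- stats::runif(1, 10, 30)
        } else {
          if (commence) {
            bp <- stats::runif(1, d1 + 8, min(55, dn - 5))
            s1 <- stats::runif(1, 15, 30) * vig
            s2 <- s1 * stats::runif(1, 1.5, 2.3)
          } else {
            bp <- stats::runif(1, max(58, d1 + 10), dn - 5)
            s1 <- stats::runif(1, 20, 30) * vig
            s2 <- s1 * stats::runif(1, 0.5, 0.8)
          }
          start_eb <- stats::runif(1, 20, 60)
        }
        gspec <- growth_spec(lag_slope = s1, linear_slope = s2,
                             breakpoints = bp, observation_days = imaging_days,
                             start_eb = start_eb, noise_sd = 0, seed = seed)
        mu <- growth_mean(gspec, imaging_days)
        truth[[paste(v, nl)]] <- data.frame(
          variety = v, n_level = nl, breakpoint_x = bp, slope1 = s1,
          slope2 = s2, phase_true = if (commence) "commencement" else "completion")
        for (r in seq_len(n_replicates)) {
          pot <- pot + 1L
          pid <- sprintf("P%04d", pot)
          pvig <- exp(stats::rnorm(1, 0, 0.08))
          eb <- pmax(mu * pvig + stats::rnorm(length(mu), 0, 6), 0)
          tva <- pmax(0.22 * eb + stats::rnorm(length(eb), 0, 3), 0)
          series[[pid]] <- data.frame(pot_id = pid, variety = v, n_level = nl,
                                      das = imaging_days, eb_kpix = eb,
                                      tva_kpix = tva)
          eb_final <- eb[length(eb)]
          mid_idx <- which.min(abs(imaging_days - 49))
          eb_veg <- eb[mid_idx]
          dw <- max(0.046 * eb_final * (if (nl == "low") 1 else 1.05) +
                      stats::rnorm(1, 0, 1.2), 0.5)
          hi <- stats::runif(1, 0.40, 0.55)
          gy <- hi * dw
          mb <- max(0.030 * eb_veg + stats::rnorm(1, 0, 0.5), 0.2)
          la <- max(26 * mb + stats::rnorm(1, 0, 12), 5)
          opt <- nl == "optimum"
          harvest[[pid]] <- data.frame(
            pot_id = pid, variety = v, n_level = nl,
            eb_kpix = eb_veg, tva_kpix = tva[mid_idx], mb_g = mb, la_cm2 = la,
            dw_g = dw, gy_g = gy,
            sn = max(stats::rnorm(1, if (opt) 15.4 else 4.2, 1.2), 1),
            gn = max(stats::rnorm(1, if (opt) 37.9 else 34.8, 3.5), 5),
            gw1000_g = max(stats::rnorm(1, if (opt) 44.3 else 41.4, 2.5), 20),
            shoot_n_pct = max(stats::rnorm(1, if (opt) 0.64 else 0.35, 0.05), 0.05),
            grain_n_pct = max(stats::rnorm(1, if (opt) 2.7 else 2.1, 0.12) -
                                0.02 * (gy - mean(c(5.9, 24)[1 + opt])), 0.5),
            wsc_pct = max(stats::rnorm(1, if (opt) 8.6 else 5.0, 1.2), 0.5))
        }
      }
    }
    list(trait_series = do.call(rbind, c(series, make.row.names = FALSE)),
         harvest = do.call(rbind, c(harvest, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

write_pipeline_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Orchestrates the method end to end from one validated
#' configuration: input (simulated study, image manifest, or trait
#' CSV) -> trait table -> broken-stick fits -> phase classification and
#' common linear-phase windows -> recommended screening day -> NUE and
#' harvest statistics -> correlation and ranked reports -> figures and
#' a machine-readable run manifest. Identical configuration and seed
#' give identical numeric outputs. A stage failure halts the run with
#' the stage named in the error and a `_FAILED` marker file in the
#' output directory; artifacts already written are retained.
#'
#' @param config a [validate_config()] result, a configuration list,
#'   or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the output directory, the artifact
#'   paths and the main in-memory results.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)), file.path(out_dir, "_FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  trait_series <- NULL; harvest <- NULL; prefit <- NULL
  stage("ingest", {
    if (config$mode == "synthetic") {
      sim <- simulate_study(config$synthetic$n_varieties,
                            config$synthetic$n_replicates,
                            config$synthetic$imaging_days, config$seed)
      trait_series <- sim$trait_series
      harvest <- sim$harvest
    } else if (config$mode == "image_manifest") {
      manifest <- utils::read.csv(config$paths$manifest, stringsAsFactors = FALSE)
      seg <- do.call(segmentation_config, config$segmentation)
      trait_series <- extract_trait_table(manifest, seg)
    } else {
      tab <- utils::read.csv(config$paths$trait_csv, stringsAsFactors = FALSE)
      if (all(c("breakpoint_x", "slope1", "slope2") %in% names(tab))) {
        prefit <- tab
      } else {
        check_columns(tab, c("variety", "n_level", "das", "eb_kpix"), "trait_csv")
        trait_series <- tab
      }
    }
    if (is.null(harvest) && !is.null(config$paths$harvest_csv))
      harvest <- utils::read.csv(config$paths$harvest_csv, stringsAsFactors = FALSE)
    if (!is.null(trait_series))
      artifacts <- c(artifacts,
                     write_pipeline_csv(trait_series, out_dir, "trait_table.csv"))
    if (!is.null(harvest))
      artifacts <- c(artifacts,
                     write_pipeline_csv(harvest, out_dir, "harvest_table.csv"))
  })

  fits <- stage("fit", {
    if (!is.null(prefit)) {
      prefit$phase <- classify_phase(prefit$slope1, prefit$slope2)
      prefit
    } else {
      fit_growth_table(trait_series, per_pot = config$growth$per_pot,
                       grid_res = config$growth$grid_res)
    }
  })
  artifacts <- c(artifacts, write_pipeline_csv(fits, out_dir, "growth_fits.csv"))

  windows <- stage("window", {
    lv <- unique(fits$n_level)
    das_range <- if (!is.null(trait_series)) range(trait_series$das) else NULL
    ws <- lapply(lv, function(l)
      common_linear_window(fits[fits$n_level == l, , drop = FALSE],
                           n_level = l, das_range = das_range))
    names(ws) <- lv
    summary <- do.call(rbind, lapply(ws, function(w) data.frame(
      n_level = w$n_level, start_das = w$start_das, end_das = w$end_das,
      empty = w$empty,
      recommended_das = if (!w$empty && !is.null(trait_series))
        recommend_screening_das(w, unique(trait_series$das)) else NA_real_)))
    artifacts <- c(artifacts,
                   write_pipeline_csv(summary, out_dir, "window_summary.csv"))
    ws
  })

  stats_out <- stage("stats", {
    out <- list()
    if (!is.null(harvest)) {
      nrep <- nue_report(harvest, unlist(config$n_inputs))
      artifacts <- c(artifacts, write_pipeline_csv(nrep, out_dir, "nue_report.csv"))
      out$nue <- nrep
      anova_rows <- list()
      for (resp in intersect(c("dw_g", "gy_g", "nue_b"), names(nrep))) {
        a <- two_way_anova(nrep, resp)
        tab <- cbind(response = resp, a$table, cv_pct = a$cv_pct)
        anova_rows[[resp]] <- tab
      }
      artifacts <- c(artifacts, write_pipeline_csv(
        do.call(rbind, c(anova_rows, make.row.names = FALSE)),
        out_dir, "anova_summary.csv"))
      traits <- intersect(c("eb_kpix", "tva_kpix", "mb_g", "la_cm2",
                            "dw_g", "gy_g"), names(harvest))
      if (length(traits) >= 2L) {
        cors <- lapply(unique(harvest$n_level), function(l) {
          cr <- correlation_matrix(harvest[harvest$n_level == l, , drop = FALSE],
                                   traits)
          pairs <- which(upper.tri(cr$r), arr.ind = TRUE)
          data.frame(n_level = l,
                     trait_a = traits[pairs[, 1L]], trait_b = traits[pairs[, 2L]],
                     r = cr$r[pairs], p = cr$p[pairs], n = cr$n[pairs],
                     stars = cr$stars[pairs])
        })
        artifacts <- c(artifacts, write_pipeline_csv(
          do.call(rbind, cors), out_dir, "correlation_validation.csv"))
      }
      if (!is.null(trait_series)) {
        tc <- timecourse_correlation(trait_series, harvest)
        artifacts <- c(artifacts,
                       write_pipeline_csv(tc, out_dir, "timecourse_correlation.csv"))
        out$timecourse <- tc
      }
      ref_level <- if ("low" %in% nrep$n_level) "low" else nrep$n_level[1L]
      rk <- rank_report(nrep, config$report$rank_trait,
                        n_level = ref_level, k = config$report$top_k)
      artifacts <- c(artifacts, write_pipeline_csv(rk, out_dir, "rank_report.csv"))
      out$rank <- rk
    }
    out
  })

  stage("figures", {
    if (!is.null(trait_series) && !config$growth$per_pot) {
      grDevices::png(file.path(out_dir, "growth_fits.png"),
                     width = 900, height = 500)
      fit_objs <- attr(fits, "fits")
      graphics::par(mfrow = c(1, length(windows)))
      for (l in names(windows)) {
        sub <- fits[fits$n_level == l, ]
        graphics::plot(NA, xlim = range(trait_series$das),
                       ylim = c(0, max(trait_series$eb_kpix)),
                       xlab = "DAS", ylab = "EB (kPix)",
                       main = paste(l, "N"))
        for (g in names(fit_objs)) {
          f <- fit_objs[[g]]
          if (!grepl(paste0("\r", l, "$"), g)) next
          graphics::lines(f$das, f$fitted, col = "grey40")
          graphics::points(f$breakpoint_x, f$breakpoint_y, pch = 19,
                           col = if (f$phase == "commencement") "forestgreen" else "firebrick")
        }
        graphics::abline(v = c(windows[[l]]$start_das, windows[[l]]$end_das),
                         lty = 2, col = "steelblue")
      }
      grDevices::dev.off()
    }
    if (!is.null(stats_out$nue)) {
      grDevices::png(file.path(out_dir, "nue_boxplot.png"),
                     width = 900, height = 500)
      graphics::boxplot(nue_b ~ n_level, data = stats_out$nue,
                        ylab = "NUE_b (g biomass / g N)", xlab = "N level")
      grDevices::dev.off()
    }
  })

  stage("manifest", {
    manifest <- list(
      package = "nuephen",
      version = as.character(utils::packageVersion("nuephen")),
      r_version = R.version.string,
      seed = config$seed,
      mode = config$mode,
      config = unclass(config),
      created = format(Sys.time(), tz = "UTC"),
      artifacts = lapply(stats::setNames(nm = basename(artifacts)), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  })

  invisible(list(out_dir = out_dir, artifacts = artifacts, fits = fits,
                 windows = windows, stats = stats_out))
}
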