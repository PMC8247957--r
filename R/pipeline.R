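#' Run the full community-thermal-adjustment analysis
#'
#' Orchestrates every stage behind one call: read (or simulate) the input
#' tables, aggregate winter temperatures, apply the inclusion filters,
#' compute community indices, fit the trend models (temperature, CTI,
#' CTI_SD, and optionally the Poisson dwelling-count model), derive
#' latitudinal gradients, displacement velocities, climatic debt and scenario
#' labels, and optionally run the moving-window grid and the
#' species-resampling robustness stage. Outputs are written to a run
#' directory together with a machine-readable manifest (config echo, seed,
#' filter report, md5 checksums of every artifact) and a human-readable
#' summary. Any stage failure aborts with the stage name; outputs already
#' written stay on disk along with the manifest.
#'
#' @param config list. Either \code{fixture} (a [make_fixture()] name) or
#'   the paths \code{species,sites,surveys,temperature}. Options (defaults in
#'   parentheses): \code{out_dir} (required), \code{study_start} (1993),
#'   \code{study_end} (2017), \code{alpha} (0.05), \code{horizon}
#'   (study-window length), \code{spatial} ("exp"), \code{weighted} (FALSE),
#'   \code{dwelling_model} (TRUE), \code{grid} (list(cell_size = 5, step = 1,
#'   min_sites = 15) or NULL to skip), \code{resampling}
#'   (list(fraction = 0.2, iterations = 200) or NULL to skip), \code{seed}
#'   (1).
#' @return invisibly, a list with the in-memory stage results and the run
#'   directory.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(config = cfg)
  # artifact names accumulate in an environment: stage expressions are
  # promises evaluated in this frame, where `<<-` would skip the frame and
  # leak to the global environment
  art <- new.env(parent = emptyenv())
  art$written <- character(0)
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest(cfg, results, art$written, failed_stage = name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs ----------------------------------------------------------
  results$tables <- stage("load", {
    if (!is.null(cfg$fixture)) {
      sim <- make_fixture(cfg$fixture)
      log_line("load", paste0("fixture '", cfg$fixture, "': ",
                              nrow(sim$sites), " sites, ",
                              nrow(sim$species), " species"))
      list(species = sim$species, sites = sim$sites, surveys = sim$surveys,
           temperature = sim$temperature)
    } else {
      tb <- read_tables(cfg$species, cfg$sites, cfg$surveys)
      tb$temperature <- read_temperature(cfg$temperature)
      tb
    }
  })

  results$winter <- stage("winter_temperature", {
    tmp <- results$tables$temperature
    if (isTRUE(attr(tmp, "aggregated")) || "winter_temp_c" %in% names(tmp)) {
      tmp[, c("site_id", "year", "winter_temp_c")]
    } else {
      winter_temperature(tmp)
    }
  })

  results$filter <- stage("filter", {
    fl <- filter_sites_and_surveys(results$tables$surveys, cfg$study_start,
                                   cfg$study_end)
    log_line("filter", sprintf("%d/%d sites kept, %d/%d surveys kept",
                               fl$report$n_sites_kept, fl$report$n_sites_in,
                               fl$report$n_surveys_kept,
                               fl$report$n_surveys_in))
    fl
  })
  surveys <- results$filter$surveys

  results$indices <- stage("indices", {
    idx <- build_indices(surveys, results$tables$species,
                         weighted = cfg$weighted)
    utils::write.csv(idx, file.path(cfg$out_dir, "indices.csv"),
                     row.names = FALSE)
    art$written <- c(art$written, "indices.csv")
    log_line("indices", paste(nrow(idx), "count events indexed"))
    idx
  })

  site_cols <- results$tables$sites[, c("site_id", "lon", "lat", "protected")]
  model_data <- merge(results$indices, site_cols, by = "site_id")
  temp_data <- merge(results$winter, site_cols, by = "site_id")
  temp_data <- temp_data[temp_data$year >= cfg$study_start &
                           temp_data$year <= cfg$study_end &
                           temp_data$site_id %in% unique(surveys$site_id), ]

  results$fits <- stage("trends", {
    fits <- list(
      temperature = fit_trend_model(
        temp_data, trend_spec("winter_temp_c", spatial = cfg$spatial)),
      cti = fit_trend_model(
        model_data, trend_spec("cti", spatial = cfg$spatial)),
      cti_sd = fit_trend_model(
        model_data, trend_spec("cti_sd", spatial = cfg$spatial))
    )
    if (isTRUE(cfg$dwelling_model)) {
      dl <- merge(dwelling_long(results$indices), site_cols, by = "site_id")
      fits$dwelling <- fit_trend_model(
        dl, trend_spec("n_species", family = "poisson", dwelling = TRUE,
                       spatial = cfg$spatial))
    }
    trend_table(fits, file.path(cfg$out_dir, "trends.csv"))
    art$written <- c(art$written, "trends.csv")
    for (nm in names(fits))
      log_line("trends", paste0(nm, ": converged = ", fits[[nm]]$converged))
    fits
  })

  results$debt <- stage("velocity_debt", {
    grad_temp <- fit_latitudinal_gradient(temp_data, "winter_temp_c")
    grad_cti <- fit_latitudinal_gradient(model_data, "cti")
    st_cti <- stratum_trends(results$fits$cti)
    st_sd <- stratum_trends(results$fits$cti_sd)
    st_tmp <- stratum_trends(results$fits$temperature)
    temp_trend <- contrast(results$fits$temperature, c(year_c = 1,
      stats::setNames(0.5, grep("year_c:protected|protected:year_c",
                                results$fits$temperature$coefficients$term,
                                value = TRUE))))
    v_temp <- trend_to_velocity(temp_trend$estimate, grad_temp$slope,
                                cfg$horizon, "temperature")
    v_in <- trend_to_velocity(st_cti$estimate[st_cti$stratum == "inside"],
                              grad_cti$slope, cfg$horizon, "cti")
    v_out <- trend_to_velocity(st_cti$estimate[st_cti$stratum == "outside"],
                               grad_cti$slope, cfg$horizon, "cti")
    scen <- list(
      inside = classify_scenario(
        list(estimate = st_cti$estimate[st_cti$stratum == "inside"],
             p = st_cti$p[st_cti$stratum == "inside"]),
        list(estimate = st_sd$estimate[st_sd$stratum == "inside"],
             p = st_sd$p[st_sd$stratum == "inside"]), cfg$alpha),
      outside = classify_scenario(
        list(estimate = st_cti$estimate[st_cti$stratum == "outside"],
             p = st_cti$p[st_cti$stratum == "outside"]),
        list(estimate = st_sd$estimate[st_sd$stratum == "outside"],
             p = st_sd$p[st_sd$stratum == "outside"]), cfg$alpha))
    dt <- debt_table(v_temp$velocity,
                     c(inside = v_in$velocity, outside = v_out$velocity),
                     scen, cfg$horizon)
    utils::write.csv(dt, file.path(cfg$out_dir, "debt.csv"),
                     row.names = FALSE)
    art$written <- c(art$written, "debt.csv")
    log_line("velocity_debt",
             sprintf("v_temp %.2f km/yr; debt inside %.2f, outside %.2f",
                     v_temp$velocity, dt$debt_km_yr[1], dt$debt_km_yr[2]))
    list(grad_temp = grad_temp, grad_cti = grad_cti, v_temp = v_temp,
         stratum_trends = list(cti = st_cti, cti_sd = st_sd,
                               temperature = st_tmp),
         scenarios = scen, table = dt)
  })

  if (!is.null(cfg$grid)) {
    results$grid <- stage("grid", {
      cells <- build_cells(results$tables$sites,
                           cell_size = cfg$grid$cell_size,
                           step = cfg$grid$step,
                           min_sites = cfg$grid$min_sites)
      cells <- fit_cell_trends(cells, results$tables$sites, results$indices,
                               results$winter,
                               grad_temp = results$debt$grad_temp$slope,
                               grad_cti = results$debt$grad_cti$slope)
      cells_csv(cells, file.path(cfg$out_dir, "cells.csv"))
      art$written <- c(art$written, "cells.csv")
      regs <- list(
        cti_shift = regress_on_pa(cells, "cti_shift"),
        debt = regress_on_pa(cells, "debt"),
        cti_sd_trend = regress_on_pa(cells, "cti_sd_trend"))
      loc <- pa_vs_location(cells)
      writeLines(jsonlite::toJSON(
        list(regressions = lapply(regs, function(r)
          list(response = r$response, n_cells = r$n_cells,
               delta_zero_pa = r$delta_zero_pa,
               coefficients = r$coefficients)),
          pa_vs_location = loc),
        auto_unbox = TRUE, digits = NA, dataframe = "columns"),
        file.path(cfg$out_dir, "cell_regressions.json"))
      art$written <- c(art$written, "cell_regressions.json")
      log_line("grid", paste(nrow(cells), "cells retained"))
      list(cells = cells, regressions = regs, pa_vs_location = loc)
    })
  }

  if (!is.null(cfg$resampling)) {
    results$resampling <- stage("resampling", {
      rs <- resample_trends(surveys, results$tables$species,
                            results$tables$sites,
                            fraction = cfg$resampling$fraction,
                            iterations = cfg$resampling$iterations,
                            seed = cfg$seed + 7L, weighted = cfg$weighted,
                            spatial = "none")
      utils::write.csv(rs$per_iteration,
                       file.path(cfg$out_dir, "resampling.csv"),
                       row.names = FALSE)
      art$written <- c(art$written, "resampling.csv")
      log_line("resampling", paste(rs$iterations, "iterations"))
      rs
    })
  }

  stage("report", {
    write_manifest(cfg, results, art$written)
    write_summary(cfg, results)
  })
  invisible(c(results, list(out_dir = cfg$out_dir)))
}

validate_run_config <- function(config) {
  cfg <- config
  if (is.null(cfg$out_dir)) stop("run config needs out_dir", call. = FALSE)
  if (is.null(cfg$fixture)) {
    for (p in c("species", "sites", "surveys", "temperature")) {
      if (is.null(cfg[[p]]))
        stop("run config needs path '", p, "' (or a fixture name)",
             call. = FALSE)
      if (!file.exists(cfg[[p]]))
        stop("run config: path for '", p, "' does not exist: ", cfg[[p]],
             call. = FALSE)
    }
  }
  defaults <- list(study_start = 1993, study_end = 2017, alpha = 0.05,
                   spatial = "exp", weighted = FALSE, dwelling_model = TRUE,
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$study_start >= cfg$study_end)
    stop("run config: study_start must precede study_end", call. = FALSE)
  if (is.null(cfg$horizon))
    cfg$horizon <- cfg$study_end - cfg$study_start
  if (!is.null(cfg$grid)) {
    gd <- list(cell_size = 5, step = 1, min_sites = 15)
    for (nm in names(gd))
      if (is.null(cfg$grid[[nm]])) cfg$grid[[nm]] <- gd[[nm]]
  }
  if (!is.null(cfg$resampling)) {
    rd <- list(fraction = 0.2, iterations = 200)
    for (nm in names(rd))
      if (is.null(cfg$resampling[[nm]])) cfg$resampling[[nm]] <- rd[[nm]]
  }
  cfg
}

write_manifest <- function(cfg, results, written, failed_stage = NULL) {
  files <- file.path(cfg$out_dir, written)
  sums <- if (length(files) > 0) as.list(tools::md5sum(files)) else list()
  names(sums) <- written
  manifest <- list(
    package = "ctidebt",
    version = as.character(utils::packageVersion("ctidebt")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    filter_report = if (!is.null(results$filter))
      unclass(results$filter$report),
    checksums = sums,
    failed_stage = failed_stage
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(cfg$out_dir, "manifest.json"))
}

write_summary <- function(cfg, results) {
  path <- file.path(cfg$out_dir, "summary.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("Community thermal adjustment run (", cfg$study_start, "-",
    cfg$study_end, ")")
  rp <- results$filter$report
  w("Sites kept: ", rp$n_sites_kept, "/", rp$n_sites_in,
    "; surveys kept: ", rp$n_surveys_kept, "/", rp$n_surveys_in)
  st <- results$debt$stratum_trends$cti
  w("CTI trend (degC/yr): inside ",
    format(st$estimate[st$stratum == "inside"], digits = 3), ", outside ",
    format(st$estimate[st$stratum == "outside"], digits = 3))
  dt <- results$debt$table
  for (i in seq_len(nrow(dt))) {
    w(dt$stratum[i], ": v_cti ", round(dt$v_cti_km_yr[i], 1),
      " km/yr, debt ", round(dt$debt_km_yr[i], 1), " km/yr (",
      round(dt$cumulative_km[i]), " km over ", dt$horizon_yr[i],
      " yr), scenario ", dt$scenario[i])
  }
}

#' Recompute the published velocity/debt arithmetic
#'
#' Recomputes every worked-example quantity from the bundled published
#' inputs (stratum CTI trends, latitudinal gradients, the published
#' temperature velocity, and the study horizon) and compares with the
#' published values. Velocities are reported to one decimal; debts,
#' cumulative distances and relative differences are derived from the
#' reported (one-decimal) velocities, matching the publication's own
#' reporting convention. Comparisons: exact after one-decimal rounding for
#' velocities and debts, +/- 0.5 km for cumulative distances (printed as
#' whole km), exact after integer rounding for percentages.
#'
#' @param inputs optional named numeric vector overriding the bundled
#'   inputs (useful for sensitivity checks); names as in
#'   \code{worked_example_inputs()}.
#' @return data frame of class \code{worked_examples}: quantity, computed,
#'   published, tolerance, pass.
#' @export
verify_worked_examples <- function(inputs = NULL) {
  ins <- worked_example_inputs()
  if (!is.null(inputs)) ins[names(inputs)] <- inputs
  horizon <- ins[["horizon_yr"]]

  v_in <- trend_to_velocity(ins[["cti_trend_inside_c_per_yr"]],
                            ins[["cti_lat_gradient_c_per_deg"]],
                            horizon)$velocity
  v_out <- trend_to_velocity(ins[["cti_trend_outside_c_per_yr"]],
                             ins[["cti_lat_gradient_c_per_deg"]],
                             horizon)$velocity
  v_temp <- ins[["temp_velocity_km_per_yr"]]
  r_in <- round(v_in, 1)
  r_out <- round(v_out, 1)
  debt_in <- climatic_debt(v_temp, r_in, horizon, "inside")
  debt_out <- climatic_debt(v_temp, r_out, horizon, "outside")
  pct_shift <- relative_difference(r_in, r_out, "share-of-larger")
  pct_debt <- relative_difference(debt_in$debt, debt_out$debt,
                                  "relative-to-reference")

  rows <- rbind(
    wx_row("cti_velocity_inside_km_yr", v_in, 3.5, "round1"),
    wx_row("cti_velocity_outside_km_yr", v_out, 2.0, "round1"),
    wx_row("debt_inside_km_yr", debt_in$debt, 7.9, "round1"),
    wx_row("debt_outside_km_yr", debt_out$debt, 9.4, "round1"),
    wx_row("temp_shift_cumulative_km", v_temp * horizon, 285, "km"),
    wx_row("cti_shift_cumulative_inside_km", r_in * horizon, 87, "km"),
    wx_row("cti_shift_cumulative_outside_km", r_out * horizon, 50, "km"),
    wx_row("debt_cumulative_inside_km", debt_in$cumulative_km, 198, "km"),
    wx_row("debt_cumulative_outside_km", debt_out$cumulative_km, 235, "km"),
    wx_row("cti_shift_excess_inside_pct", pct_shift, 43, "pct"),
    wx_row("debt_reduction_inside_pct", pct_debt, 16, "pct")
  )
  class(rows) <- c("worked_examples", class(rows))
  rows
}

wx_row <- function(quantity, computed, published, rule) {
  pass <- switch(rule,
                 round1 = round(computed, 1) == published,
                 km = abs(computed - published) <= 0.5,
                 pct = round(computed) == published)
  data.frame(quantity = quantity, computed = computed,
             published = published, rule = rule, pass = pass,
             stringsAsFactors = FALSE)
}

#' Published inputs for the worked examples
#'
#' The stratum CTI temporal trends, latitudinal gradients, published
#' temperature velocity and study horizon, read from the CSV bundled with
#' the package.
#'
#' @return named numeric vector.
#' @export
worked_example_inputs <- function() {
  path <- system.file("extdata", "published_inputs.csv",
                      package = "ctidebt")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' @export
print.worked_examples <- function(x, ...) {
  cat("Worked velocity/debt examples: ", sum(x$pass), "/", nrow(x),
      " match the published values\n", sep = "")
  print(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}
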