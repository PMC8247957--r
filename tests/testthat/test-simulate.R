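test_that("sim_config validates its arguments and applies presets", {
  expect_error(sim_config(tau = 0), "tau")
  expect_error(sim_config(m_col = 0.5), "m_col")
  expect_error(sim_config(m_ext = 2), "m_ext")
  expect_error(sim_config(scenario = "5"), "scenario")
  expect_equal(sim_config(scenario = "1", warming = 0.1)$warming, 0)
  expect_equal(sim_config(scenario = "4")$warming, 0.04)
})

test_that("identical configs give byte-identical simulations", {
  a <- simulate_communities(sim_config(n_sites = 30, n_species = 12,
                                       year_end = 2000, seed = 7))
  b <- simulate_communities(sim_config(n_sites = 30, n_species = 12,
                                       year_end = 2000, seed = 7))
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$temperature, b$temperature)
  c <- simulate_communities(sim_config(n_sites = 30, n_species = 12,
                                       year_end = 2000, seed = 8))
  expect_false(identical(a$surveys, c$surveys))
})

test_that("the temperature field carries the configured gradient and trend", {
  cfg <- sim_config(n_sites = 300, year_start = 1993, year_end = 2017,
                    sigma_t = 0.5, seed = 30)
  sim <- simulate_communities(cfg, abundance = FALSE)
  wt <- merge(sim$ground_truth$winter_temp, sim$sites[, c("site_id", "lat")],
              by = "site_id")
  m <- lm(winter_temp_c ~ lat + I(year - 1993), data = wt)
  expect_lt(abs(unname(coef(m)["lat"]) - cfg$gradient), 0.01)
  expect_lt(abs(unname(coef(m)[3]) - cfg$warming), 0.005)
  # monthly values average back to the winter value exactly
  win <- winter_temperature(sim$temperature)
  mrg <- merge(win, sim$ground_truth$winter_temp, by = c("site_id", "year"))
  expect_equal(mrg$winter_temp_c.x, mrg$winter_temp_c.y, tolerance = 1e-12)
})

test_that("the STI pool has the configured spread under both distributions", {
  cfg_u <- sim_config(n_species = 4000, seed = 31)
  sp_u <- simulate_communities(cfg_u, abundance = FALSE)$species
  expect_equal(mean(sp_u$sti_c), cfg_u$sti_mean, tolerance = 0.3)
  expect_equal(sd(sp_u$sti_c), cfg_u$sti_sd, tolerance = 0.3)
  half <- cfg_u$sti_sd * sqrt(3)
  expect_true(all(abs(sp_u$sti_c - cfg_u$sti_mean) <= half + 1e-3))

  cfg_n <- sim_config(n_species = 4000, sti_dist = "normal", seed = 31)
  sp_n <- simulate_communities(cfg_n, abundance = FALSE)$species
  expect_equal(sd(sp_n$sti_c), cfg_n$sti_sd, tolerance = 0.3)
  expect_gt(max(abs(sp_n$sti_c - cfg_n$sti_mean)), half)
})

test_that("surveys mirror the ground-truth occupancy matrices", {
  sim <- tiny_sim()
  yrs <- sim$ground_truth$years
  k <- which(yrs == 1997)
  occ <- sim$ground_truth$occupancy[[k]]
  sv <- sim$surveys[sim$surveys$year == 1997, ]
  got <- paste(sv$site_id, sv$species_id)
  idx <- which(occ, arr.ind = TRUE)
  want <- paste(sim$sites$site_id[idx[, 2]], sim$species$species_id[idx[, 1]])
  expect_setequal(got, want)
  # abundances are positive integers
  expect_true(all(sim$surveys$count >= 1))
  expect_true(all(sim$surveys$count == round(sim$surveys$count)))
})

test_that("presets freeze the corresponding process inside the window", {
  for (sc in c("2", "3")) {
    cfg <- sim_config(n_sites = 40, n_species = 20, year_end = 2005,
                      scenario = sc, seed = 33)
    sim <- simulate_communities(cfg, abundance = FALSE)
    occ <- sim$ground_truth$occupancy
    gains <- losses <- 0
    for (k in 2:length(occ)) {
      gains <- gains + sum(!occ[[k - 1]] & occ[[k]])
      losses <- losses + sum(occ[[k - 1]] & !occ[[k]])
    }
    if (sc == "2") {
      expect_equal(gains, 0)
      expect_gt(losses, 0)
    } else {
      expect_equal(losses, 0)
      expect_gt(gains, 0)
    }
  }
})

test_that("transition counts match the declared probabilities with multipliers", {
  cfg <- sim_config(n_sites = 400, n_species = 40, year_end = 2017,
                    m_col = 2, m_ext = 0.5, burn_in = 5, seed = 34)
  sim <- simulate_communities(cfg, abundance = FALSE)
  occ <- sim$ground_truth$occupancy
  wt <- sim$ground_truth$winter_temp
  yrs <- sim$ground_truth$years
  sti <- sim$species$sti_c
  mcol <- ifelse(sim$sites$protected == 1, cfg$m_col, 1)
  mext <- ifelse(sim$sites$protected == 1, cfg$m_ext, 1)

  # expected vs observed transition counts per protection stratum, summing
  # the exact Bernoulli probabilities the generator declares
  obs_gain <- exp_gain <- obs_loss <- exp_loss <- c(`0` = 0, `1` = 0)
  var_gain <- var_loss <- c(`0` = 0, `1` = 0)
  for (k in 2:length(occ)) {
    tk <- wt$winter_temp_c[wt$year == yrs[k]][
      match(sim$sites$site_id, wt$site_id[wt$year == yrs[k]])]
    p <- exp(-outer(sti, tk, `-`)^2 / (2 * cfg$tau^2))
    p_col <- pmin(sweep(cfg$c0 * p, 2, mcol, `*`), 1)
    p_ext <- pmin(sweep(cfg$e0 * (1 - p), 2, mext, `*`), 1)
    for (s in c(0, 1)) {
      cols <- sim$sites$protected == s
      key <- as.character(s)
      empty <- !occ[[k - 1]][, cols]
      full <- occ[[k - 1]][, cols]
      obs_gain[key] <- obs_gain[key] + sum(empty & occ[[k]][, cols])
      exp_gain[key] <- exp_gain[key] + sum(p_col[, cols][empty])
      var_gain[key] <- var_gain[key] +
        sum((p_col * (1 - p_col))[, cols][empty])
      obs_loss[key] <- obs_loss[key] + sum(full & !occ[[k]][, cols])
      exp_loss[key] <- exp_loss[key] + sum(p_ext[, cols][full])
      var_loss[key] <- var_loss[key] +
        sum((p_ext * (1 - p_ext))[, cols][full])
    }
  }
  # if the generator dropped the protection multipliers, the expected
  # counts (which include them) would miss by far more than 5 sigma
  expect_true(all(abs(obs_gain - exp_gain) < 5 * sqrt(var_gain)))
  expect_true(all(abs(obs_loss - exp_loss) < 5 * sqrt(var_loss)))
})

test_that("fixtures are registered, deterministic and warn-free at tiny scale", {
  expect_error(fixture_config("nope"), "unknown fixture")
  cfg <- fixture_config("tiny")
  expect_equal(cfg$n_sites, 20)
  a <- make_fixture("tiny", abundance = FALSE)
  b <- make_fixture("tiny", abundance = FALSE)
  expect_identical(a$surveys, b$surveys)
  expect_equal(a$ground_truth$n_clipped, 0)
})

test_that("write_sim writes the four tables plus ground truth", {
  dir <- withr_like_tempdir()
  paths <- write_sim(tiny_sim(), dir)
  expect_true(all(file.exists(paths)))
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$config$seed, 101)
  expect_null(gt$occupancy)
})

test_that("simulate_trend_data matches its declared moments and truth", {
  d <- simulate_trend_data(n_sites = 150, n_years = 20, rho = 0,
                           sigma_site = 0.4, sigma_resid = 0.2, seed = 35)
  truth <- attr(d, "truth")
  expect_equal(nrow(d), 150 * 20)
  m <- lm(y ~ I(year - 1993) * protected, data = d)
  expect_lt(abs(unname(coef(m)[2]) - truth[["beta_year"]]), 0.005)
  # site-effect variance shows up between sites
  site_means <- tapply(residuals(lm(y ~ I(year - 1993) * protected, data = d)),
                       d$site_id, mean)
  expect_equal(sd(site_means), 0.4, tolerance = 0.1)

  # residual mode: correlation between nearby sites within years
  ds <- simulate_trend_data(n_sites = 100, n_years = 30, rho = 3,
                            spatial_mode = "residual", sigma_site = 0,
                            sigma_resid = 1, seed = 36)
  wide <- matrix(ds$y, 100, 30)
  wide <- wide - rowMeans(wide)
  xy <- unique(ds[, c("site_id", "lon", "lat")])
  D <- as.matrix(dist(xy[, c("lon", "lat")]))
  C <- cor(t(wide))
  near <- D > 0 & D < 1; far <- D > 15
  expect_gt(mean(C[near]), mean(C[far]) + 0.2)
})
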