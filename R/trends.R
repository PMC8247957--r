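#' Specify a community trend model
#'
#' Describes the mixed model for a response observed per (site, year):
#' fixed effects of (centered) year, protection status and their interaction
#' (optionally crossed with the cold/warm dwelling category for count
#' responses), an iid site random intercept, and an optional exponential
#' spatial correlation term. The spatial term is a site-level Gaussian random
#' field with correlation \code{exp(-d / rho)} at inter-site distance
#' \code{d}, the form glmmTMB uses for exponential spatial structures;
#' distances are Euclidean in decimal-degree space by default, mirroring the
#' coordinate-based convention of the source analyses (great-circle distances
#' would require a different correlation kernel and are deliberately not
#' silently substituted).
#'
#' @param response name of the response column in the data.
#' @param family \code{"gaussian"} (fit by REML) or \code{"poisson"}
#'   (log link, Laplace-approximated marginal likelihood).
#' @param spatial \code{"exp"} or \code{"none"}.
#' @param protection include protection status and its interaction with year.
#' @param dwelling include the dwelling category (Poisson count model only),
#'   crossed with year and protection up to the 3-way interaction.
#' @param site_effect include the iid site random intercept.
#' @param center_year year mapped to 0; default: window start (makes the
#'   protection main effect interpretable at a real year and stabilizes the
#'   optimizer).
#' @param rho_fixed fix the spatial range at this value instead of
#'   estimating it (NULL = estimate). Useful when the range is known (e.g.
#'   simulation studies) or held across many related fits.
#' @param spatial_max_sites refuse the exponential spatial term beyond this
#'   many unique locations (dense covariance; no silent approximation).
#' @return object of class \code{trend_spec}.
#' @export
trend_spec <- function(response, family = c("gaussian", "poisson"),
                       spatial = c("exp", "none"), protection = TRUE,
                       dwelling = FALSE, site_effect = TRUE,
                       center_year = NULL, rho_fixed = NULL,
                       spatial_max_sites = 1000) {
  family <- match.arg(family)
  spatial <- match.arg(spatial)
  if (dwelling && family != "poisson")
    stop("dwelling-category terms are for the Poisson count model",
         call. = FALSE)
  if (!is.null(rho_fixed) && (!is.finite(rho_fixed) || rho_fixed <= 0))
    stop("rho_fixed must be a positive number", call. = FALSE)
  structure(list(response = response, family = family, spatial = spatial,
                 protection = protection, dwelling = dwelling,
                 site_effect = site_effect, center_year = center_year,
                 rho_fixed = rho_fixed,
                 spatial_max_sites = spatial_max_sites),
            class = "trend_spec")
}

#' Fit a community trend model
#'
#' Fits the model described by a [trend_spec()] with glmmTMB. Gaussian
#' responses use restricted maximum likelihood; Poisson responses the Laplace
#' approximation. Wald tests use residual degrees of freedom
#' \code{n_obs - n_fixed}.
#'
#' @param data data frame with the response column plus \code{year},
#'   \code{site_id}, \code{lon}, \code{lat}, and (as required)
#'   \code{protected} and \code{dwelling}.
#' @param spec a \code{trend_spec}.
#' @return object of class \code{trend_fit}: coefficient table (estimate, se,
#'   t, p), variance components (\code{var_site}, \code{sigma2},
#'   \code{spatial_sd}, \code{rho}), log-likelihood, convergence and boundary
#'   flags, and the underlying glmmTMB fit.
#' @export
fit_trend_model <- function(data, spec) {
  stopifnot(inherits(spec, "trend_spec"))
  need <- c(spec$response, "year", "site_id")
  if (spec$protection) need <- c(need, "protected")
  if (spec$dwelling) need <- c(need, "dwelling")
  if (spec$spatial == "exp") need <- c(need, "lon", "lat")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("trend model data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(data$site_id)) < 2 || length(unique(data$year)) < 2)
    stop("trend model needs >=2 sites and >=2 distinct years", call. = FALSE)

  center <- if (is.null(spec$center_year)) min(data$year) else spec$center_year
  d <- data
  d$.y <- d[[spec$response]]
  d$year_c <- d$year - center
  d$site_id <- factor(d$site_id)

  rhs <- "year_c"
  if (spec$protection && spec$dwelling) {
    rhs <- "year_c * protected * dwelling"
  } else if (spec$protection) {
    rhs <- "year_c * protected"
  } else if (spec$dwelling) {
    rhs <- "year_c * dwelling"
  }
  if (spec$site_effect) rhs <- paste(rhs, "+ (1 | site_id)")
  if (spec$spatial == "exp") {
    loc <- unique(d[, c("lon", "lat")])
    if (nrow(loc) > spec$spatial_max_sites)
      stop("exponential spatial correlation refused for ", nrow(loc),
           " unique locations (> spatial_max_sites = ",
           spec$spatial_max_sites,
           "); use spatial = \"none\" or down-sample sites", call. = FALSE)
    d$.pos <- glmmTMB::numFactor(d$lon, d$lat)
    d$.spgrp <- factor(1)
    rhs <- paste(rhs, "+ exp(0 + .pos | .spgrp)")
  }
  form <- stats::as.formula(paste(".y ~", rhs))

  # gaussian fits without the spatial term are delegated to lme4 (same REML
  # model, much faster); spatial and Poisson fits use glmmTMB, which carries
  # the exponential spatial covariance and the Laplace approximation.
  use_lmer <- spec$family == "gaussian" && spec$spatial == "none" &&
    spec$site_effect
  if (use_lmer) {
    m <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
    beta <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
  } else {
    fam <- if (spec$family == "gaussian") stats::gaussian() else
      stats::poisson()
    args <- list(form, data = d, family = fam,
                 REML = spec$family == "gaussian")
    if (spec$spatial == "exp" && !is.null(spec$rho_fixed)) {
      # theta layout: site us block (1), then exp block (log sd, log range);
      # fixing the range removes the hardest optimizer dimension
      n_th <- 2L + as.integer(spec$site_effect)
      map_th <- factor(c(seq_len(n_th - 1L), NA))
      start_th <- c(rep(0, n_th - 1L), log(spec$rho_fixed))
      args$map <- list(theta = map_th)
      args$start <- list(theta = start_th)
    }
    m <- do.call(glmmTMB::glmmTMB, args)
    beta <- glmmTMB::fixef(m)$cond
    V <- stats::vcov(m)$cond
  }
  se <- sqrt(diag(V))
  n_obs <- nrow(d)
  df_resid <- n_obs - length(beta)
  tval <- beta / se
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta),
                      se = as.numeric(se), t = as.numeric(tval),
                      p = 2 * stats::pt(-abs(tval), df_resid),
                      stringsAsFactors = FALSE)

  if (use_lmer) {
    vc <- lme4::VarCorr(m)
    var_site <- as.numeric(attr(vc[["site_id"]], "stddev")[1])^2
    sigma2 <- stats::sigma(m)^2
    sp <- list(sd = NA_real_, rho = NA_real_)
    converged <- length(m@optinfo$conv$lme4$messages) == 0 ||
      all(grepl("singular", unlist(m@optinfo$conv$lme4$messages)))
  } else {
    vc <- glmmTMB::VarCorr(m)$cond
    var_site <- if (spec$site_effect)
      as.numeric(attr(vc[["site_id"]], "stddev")[1])^2 else 0
    sigma2 <- if (spec$family == "gaussian") glmmTMB::sigma(m)^2 else
      NA_real_
    sp <- extract_spatial(vc)
    converged <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
  }
  structure(list(
    coefficients = coefs, vcov = as.matrix(V), var_site = var_site,
    sigma2 = sigma2, spatial_sd = sp$sd, rho = sp$rho,
    logLik = as.numeric(stats::logLik(m)), n_obs = n_obs,
    df_resid = df_resid, converged = converged,
    boundary = spec$site_effect && var_site < 1e-8,
    family = spec$family, spatial = spec$spatial,
    center_year = center, spec = spec, model = m
  ), class = "trend_fit")
}

# recover the exponential range parameter from the fitted correlation
# structure: corr(d) = exp(-d / rho) inverted on a well-conditioned pair of
# fitted locations (robust to the internal parameterization).
extract_spatial <- function(vc) {
  i <- which(vapply(vc, function(b) {
    identical(unname(attr(b, "blockCode")), 5)
  }, logical(1)))
  if (length(i) == 0) return(list(sd = NA_real_, rho = NA_real_))
  b <- vc[[i[1]]]
  sdv <- as.numeric(attr(b, "stddev")[1])
  C <- attr(b, "correlation")
  nm <- rownames(C)
  xy <- t(vapply(nm, function(s) {
    as.numeric(strsplit(gsub("^pos\\(|\\)$", "", sub("^[^(]*", "pos", s)),
                        ",")[[1]])
  }, numeric(2)))
  rho <- NA_real_
  if (nrow(C) >= 2) {
    off <- C[lower.tri(C)]
    ij <- which(lower.tri(C), arr.ind = TRUE)
    ok <- which(off > 1e-6 & off < 1 - 1e-6)
    if (length(ok) > 0) {
      dd <- sqrt(rowSums((xy[ij[ok, 1], , drop = FALSE] -
                            xy[ij[ok, 2], , drop = FALSE])^2))
      # corr = exp(-d/rho): least squares of log corr on distance, through 0
      rho <- -sum(dd * dd) / sum(dd * log(off[ok]))
    }
  }
  list(sd = sdv, rho = rho)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Community trend model (", x$family,
      if (x$spatial == "exp") ", exponential spatial correlation" else "",
      ")\n", sep = "")
  cat("  n =", x$n_obs, " residual df =", x$df_resid,
      " logLik =", format(x$logLik, digits = 6), "\n")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat("  var(site) =", format(x$var_site, digits = 4))
  if (x$family == "gaussian")
    cat("  var(resid) =", format(x$sigma2, digits = 4))
  if (!is.na(x$spatial_sd))
    cat("  spatial sd =", format(x$spatial_sd, digits = 4),
        " range rho =", format(x$rho, digits = 4))
  cat("\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  if (x$boundary) cat("  note: site variance at boundary (~0)\n")
  invisible(x)
}

#' Wald test of a linear combination of coefficients
#'
#' @param fit a \code{trend_fit}.
#' @param weights numeric vector over the coefficient vector; either
#'   unnamed (full length) or named with a subset of coefficient names
#'   (others zero).
#' @return data frame \code{estimate, se, t, p, df}.
#' @export
contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "trend_fit"))
  terms <- fit$coefficients$term
  if (!is.null(names(weights))) {
    bad <- setdiff(names(weights), terms)
    if (length(bad) > 0)
      stop("contrast names not among coefficients: ",
           paste(bad, collapse = ", "), call. = FALSE)
    w <- stats::setNames(numeric(length(terms)), terms)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(terms))
      stop("contrast weights must have length ", length(terms), call. = FALSE)
    w <- as.numeric(weights)
  }
  est <- sum(w * fit$coefficients$estimate)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  tval <- est / se
  data.frame(estimate = est, se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), fit$df_resid), df = fit$df_resid)
}

#' Per-stratum temporal trends from a fitted model
#'
#' With protection coded 0/1 and year centered, the outside-PA trend is the
#' year coefficient, the inside-PA trend adds the interaction, and the
#' inside-minus-outside difference is the interaction itself (the "post hoc"
#' comparison).
#'
#' @param fit a \code{trend_fit} from a model with protection terms.
#' @param per report trends per this many years (e.g. 100 to avoid decimals).
#' @return data frame with rows outside, inside, difference.
#' @export
stratum_trends <- function(fit, per = 1) {
  terms <- fit$coefficients$term
  int <- grep("year_c:protected|protected:year_c", terms, value = TRUE)
  if (length(int) != 1)
    stop("fit lacks a year x protection interaction", call. = FALSE)
  rows <- rbind(
    cbind(stratum = "outside", contrast(fit, c(year_c = 1))),
    cbind(stratum = "inside",
          contrast(fit, stats::setNames(c(1, 1), c("year_c", int)))),
    cbind(stratum = "difference", contrast(fit, stats::setNames(1, int)))
  )
  rows$estimate <- rows$estimate * per
  rows$se <- rows$se * per
  rows
}

#' Annual means with year as a categorical effect
#'
#' Refits the trend model with year as a factor to check visually that a
#' linear year effect is appropriate: one estimate with a 95% Wald interval
#' per (year, protection) cell. Cells without observations are dropped with a
#' warning (no interpolation).
#'
#' @param data as for [fit_trend_model()].
#' @param response response column name.
#' @param spatial \code{"none"} (default) or \code{"exp"}.
#' @return data frame \code{year, protected, estimate, se, lwr, upr}.
#' @export
annual_means <- function(data, response, spatial = c("none", "exp")) {
  spatial <- match.arg(spatial)
  d <- data
  d$.y <- d[[response]]
  d$site_id <- factor(d$site_id)
  all_cells <- expand.grid(year = sort(unique(d$year)),
                           protected = sort(unique(d$protected)))
  have <- unique(d[, c("year", "protected")])
  missing <- nrow(all_cells) - nrow(have)
  if (missing > 0)
    warning(missing, " empty (year, protection) cells dropped", call. = FALSE)
  d$.cell <- factor(paste(d$year, d$protected, sep = "_"))
  rhs <- ".cell + (1 | site_id)"
  if (spatial == "exp") {
    d$.pos <- glmmTMB::numFactor(d$lon, d$lat)
    d$.spgrp <- factor(1)
    rhs <- paste(rhs, "+ exp(0 + .pos | .spgrp)")
  }
  m <- glmmTMB::glmmTMB(stats::as.formula(paste(".y ~ 0 +", rhs)),
                        data = d, REML = TRUE)
  beta <- glmmTMB::fixef(m)$cond
  se <- sqrt(diag(as.matrix(stats::vcov(m)$cond)))
  keep <- grepl("^\\.cell", names(beta))
  lev <- sub("^\\.cell", "", names(beta)[keep])
  parts <- strsplit(lev, "_", fixed = TRUE)
  out <- data.frame(
    year = as.integer(vapply(parts, `[`, character(1), 1)),
    protected = as.numeric(vapply(parts, `[`, character(1), 2)),
    estimate = as.numeric(beta[keep]), se = as.numeric(se[keep])
  )
  z <- stats::qnorm(0.975)
  out$lwr <- out$estimate - z * out$se
  out$upr <- out$estimate + z * out$se
  out[order(out$protected, out$year), ]
}

#' Write a tidy trend table
#'
#' One row per (response, term) with estimates, Wald tests and variance
#' components, in the style of a main-results table; temporal trends can be
#' rescaled (e.g. per 100 years) at the reporting layer without touching the
#' fit.
#'
#' @param fits named list of \code{trend_fit} objects (names = responses).
#' @param path optional CSV path.
#' @return data frame, invisibly when written.
#' @export
trend_table <- function(fits, path = NULL) {
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cbind(response = nm, f$coefficients,
          var_site = f$var_site, sigma2 = f$sigma2,
          spatial_sd = f$spatial_sd, rho = f$rho,
          n_obs = f$n_obs, converged = f$converged)
  }))
  if (!is.null(path)) {
    utils::write.csv(rows, path, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
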