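#' Community temperature index for one count event
#'
#' CTI is the mean species temperature index (STI) of the species present in
#' a survey; CTI_SD is the sample (n - 1) standard deviation of those STIs.
#' Occurrence (presence--absence) weighting: every species counts once.
#' Communities are treated as samples of assemblages, hence the sample
#' denominator; with the >=2-species inclusion rule it is always defined.
#'
#' @param species_ids character vector of species present in the survey.
#' @param species species table (\code{species_id,sti_c}).
#' @param missing_sti \code{"drop"} (default; species without an STI are
#'   dropped with a warning) or \code{"error"}.
#' @return list \code{cti}, \code{cti_sd}, \code{richness}.
#' @export
compute_cti <- function(species_ids, species, missing_sti = c("drop", "error")) {
  missing_sti <- match.arg(missing_sti)
  sti <- species$sti_c[match(species_ids, species$species_id)]
  if (anyNA(sti)) {
    offenders <- species_ids[is.na(sti)]
    if (missing_sti == "error")
      stop("species without STI: ", paste(offenders, collapse = ", "),
           call. = FALSE)
    warning("dropping species without STI: ",
            paste(offenders, collapse = ", "), call. = FALSE)
    sti <- sti[!is.na(sti)]
  }
  if (length(sti) < 2)
    stop("community index undefined: fewer than 2 species with known STI",
         call. = FALSE)
  list(cti = mean(sti), cti_sd = stats::sd(sti), richness = length(sti))
}

#' Abundance-weighted community temperature index
#'
#' Weighted mean and weighted standard deviation of STIs with raw counts as
#' weights. The weighted SD uses the frequency interpretation: it equals the
#' sample SD of the STI multiset in which each species is repeated
#' \code{count} times. With equal counts the weighted mean coincides with the
#' unweighted CTI; the weighted SD coincides only when every count is 1
#' (larger equal counts enlarge the implied multiset, shrinking the sample
#' correction).
#'
#' @param species_ids species present in the survey.
#' @param counts positive integer abundances, parallel to \code{species_ids}.
#' @param species species table.
#' @param log_counts if TRUE, weights are \code{log1p(count)} rather than raw
#'   counts (dampens dominance of very abundant species).
#' @return list \code{cti}, \code{cti_sd}, \code{richness}.
#' @export
compute_cti_weighted <- function(species_ids, counts, species,
                                 log_counts = FALSE) {
  if (length(counts) != length(species_ids) || anyNA(counts))
    stop("abundance missing for species: ",
         paste(species_ids[is.na(counts)], collapse = ", "), call. = FALSE)
  sti <- species$sti_c[match(species_ids, species$species_id)]
  if (anyNA(sti))
    stop("species without STI: ",
         paste(species_ids[is.na(sti)], collapse = ", "), call. = FALSE)
  if (length(sti) < 2)
    stop("community index undefined: fewer than 2 species", call. = FALSE)
  w <- if (log_counts) log1p(counts) else as.numeric(counts)
  m <- sum(w * sti) / sum(w)
  v <- sum(w * (sti - m)^2) / (sum(w) - 1)
  list(cti = m, cti_sd = sqrt(v), richness = length(sti))
}

#' Classify a species as cold- or warm-dwelling at a site
#'
#' A species is warm-dwelling at a site when its STI exceeds the mean CTI of
#' the site's whole retained time series, cold-dwelling otherwise. Exact ties
#' go to cold: a deterministic, documented rule (ties have measure ~0 on real
#' STI values).
#'
#' @param sti species temperature index, deg C.
#' @param site_mean_cti mean of the site's per-survey CTIs.
#' @return \code{"warm"} or \code{"cold"} (vectorized).
#' @export
classify_dwelling <- function(sti, site_mean_cti) {
  ifelse(sti > site_mean_cti, "warm", "cold")
}

#' Cold/warm dwelling counts for one survey
#'
#' @param species_ids species present.
#' @param species species table.
#' @param site_mean_cti site-level mean CTI over the retained series.
#' @return list \code{n_cold}, \code{n_warm}; their sum is the richness.
#' @export
dwelling_counts <- function(species_ids, species, site_mean_cti) {
  sti <- species$sti_c[match(species_ids, species$species_id)]
  sti <- sti[!is.na(sti)]
  cls <- classify_dwelling(sti, site_mean_cti)
  list(n_cold = sum(cls == "cold"), n_warm = sum(cls == "warm"))
}

#' Per-survey community index table
#'
#' Computes CTI, CTI_SD, richness and cold/warm dwelling counts for every
#' count event in a (filtered) survey table. The site-level mean CTI used for
#' the dwelling classification is computed from the retained surveys only.
#'
#' @param surveys long-format survey table.
#' @param species species table.
#' @param weighted FALSE (occurrence weighting, default) or TRUE (abundance).
#' @param log_counts passed to [compute_cti_weighted()].
#' @return data frame
#'   \code{site_id,year,cti,cti_sd,richness,n_cold,n_warm,weighted}.
#' @export
build_indices <- function(surveys, species, weighted = FALSE,
                          log_counts = FALSE) {
  sti <- species$sti_c[match(surveys$species_id, species$species_id)]
  known <- !is.na(sti)
  if (!all(known)) {
    warning("dropping ", sum(!known),
            " survey rows for species without STI", call. = FALSE)
    surveys <- surveys[known, , drop = FALSE]
    sti <- sti[known]
  }
  key <- factor(paste(surveys$site_id, surveys$year, sep = "\r"))
  ki <- as.integer(key)
  ones <- rep(1, length(ki))
  if (weighted) {
    if (anyNA(surveys$count))
      stop("abundance weighting requested but counts are missing",
           call. = FALSE)
    w <- surveys$count
    sw <- drop(rowsum(w, ki))
    mean_sti <- drop(rowsum(w * sti, ki)) / sw
    var_sti <- drop(rowsum(w * (sti - mean_sti[ki])^2, ki)) / (sw - 1)
  } else {
    n <- drop(rowsum(ones, ki))
    mean_sti <- drop(rowsum(sti, ki)) / n
    var_sti <- drop(rowsum((sti - mean_sti[ki])^2, ki)) / (n - 1)
  }
  richness <- drop(rowsum(ones, ki))
  keys <- levels(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  idx <- data.frame(
    site_id = vapply(parts, `[`, character(1), 1),
    year = as.integer(vapply(parts, `[`, character(1), 2)),
    cti = as.numeric(mean_sti),
    cti_sd = sqrt(as.numeric(var_sti)),
    richness = as.integer(richness),
    stringsAsFactors = FALSE
  )
  if (any(idx$richness < 2))
    stop("community index undefined for ", sum(idx$richness < 2),
         " surveys with <2 species; apply filter_sites_and_surveys() first",
         call. = FALSE)

  site_mean <- tapply(idx$cti, idx$site_id, mean)
  warm <- sti > site_mean[surveys$site_id]
  idx$n_warm <- as.integer(drop(rowsum(as.numeric(warm), ki)))
  idx$n_cold <- idx$richness - idx$n_warm
  idx$weighted <- weighted
  idx <- idx[order(idx$site_id, idx$year),
             c("site_id", "year", "cti", "cti_sd", "richness",
               "n_cold", "n_warm", "weighted")]
  rownames(idx) <- NULL
  idx
}

#' Site-level mean CTI
#'
#' @param indices output of [build_indices()].
#' @return named numeric vector, one mean CTI per site.
#' @export
site_mean_cti <- function(indices) {
  tapply(indices$cti, indices$site_id, mean)
}

#' Long dwelling-count table for the Poisson trend model
#'
#' Reshapes a community index table to one row per (site, year, dwelling
#' category) with the species count as response.
#'
#' @param indices output of [build_indices()].
#' @return data frame \code{site_id,year,dwelling,n_species}.
#' @export
dwelling_long <- function(indices) {
  out <- rbind(
    data.frame(site_id = indices$site_id, year = indices$year,
               dwelling = "cold", n_species = indices$n_cold,
               stringsAsFactors = FALSE),
    data.frame(site_id = indices$site_id, year = indices$year,
               dwelling = "warm", n_species = indices$n_warm,
               stringsAsFactors = FALSE)
  )
  out$dwelling <- factor(out$dwelling, levels = c("cold", "warm"))
  out
}
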