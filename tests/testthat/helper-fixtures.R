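# Shared test helpers: small deterministic tables built in memory.

# fresh empty directory under tempdir(); cleaned up with the R session
withr_like_tempdir <- function() {
  d <- tempfile("ctidebt-test-")
  dir.create(d)
  d
}

toy_species <- function() {
  data.frame(species_id = c("a", "b", "c", "d"),
             sti_c = c(2, 4, 6, 10),
             stringsAsFactors = FALSE)
}

toy_sites <- function() {
  data.frame(site_id = c("s1", "s2"),
             lon = c(0, 1), lat = c(40, 45),
             protected = c(1L, 0L),
             pa_area_km2 = c(12.5, 0),
             stringsAsFactors = FALSE)
}

toy_surveys <- function() {
  data.frame(
    site_id = rep(c("s1", "s2"), each = 3),
    year = rep(2000L, 6),
    species_id = c("a", "b", "c", "b", "c", "d"),
    count = c(3, 1, 2, 5, 1, 1),
    stringsAsFactors = FALSE
  )
}

# a survey table where both sites qualify under the default inclusion rules
qualifying_surveys <- function() {
  years <- c(1993L, 1995L, 2001L, 2011L, 2015L)
  do.call(rbind, lapply(c("s1", "s2"), function(s) {
    do.call(rbind, lapply(years, function(y) {
      data.frame(site_id = s, year = y,
                 species_id = c("a", "b", "c"),
                 count = c(2, 3, 4), stringsAsFactors = FALSE)
    }))
  }))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("tiny")
    cache
  }
})
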