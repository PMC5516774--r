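#' Packaged impact-experiment observations
#'
#' Longitudinal mean +/- SD observations from the bovine osteochondral
#' explant drop-tower experiments, on the fraction-of-control scale
#' (printed percentages divided by 100; the viability series was already
#' rescaled by its 89% pre-impact baseline so that control reads 1.0 —
#' see [normalize_viability()] for applying that rescaling to raw data).
#' GAG sampling days are converted to hours (7 d = 168 h, 14 d = 336 h).
#'
#' The 7 J/cm^2 set has 9 viability, 2 ATP and 2 GAG records; the
#' 14 J/cm^2 set has 9 viability records (no ATP or GAG was collected at
#' the higher energy).
#'
#' @param impact `"7J"` or `"14J"`.
#' @return A tibble with columns `stream` (`"viability"`, `"atp"`, `"gag"`),
#'   `time_h`, `mean`, `sd`, carrying the impact label in attribute
#'   `impact`.
#' @examples
#' impact_observations("7J")
#' @export
impact_observations <- function(impact = c("7J", "14J")) {
  if (!is.character(impact) || !impact[1] %in% c("7J", "14J")) {
    abort(sprintf("unknown impact label `%s` (use \"7J\" or \"14J\")",
                  as.character(impact[1])))
  }
  impact <- match.arg(impact)
  path <- system.file("extdata", paste0("observations_", impact, ".csv"),
                      package = "cartox", mustWork = TRUE)
  obs <- read_observations(path)
  attr(obs, "impact") <- impact
  obs
}

#' Read and write observation tables
#'
#' CSV dialect: comma-separated, header `stream,time_h,mean,sd`, UTF-8,
#' `.` decimal. Values are on the fraction-of-control scale.
#'
#' @param path File path.
#' @return `read_observations()` returns a validated observation tibble;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stream = readr::col_character(),
                           time_h = readr::col_double(),
                           mean = readr::col_double(),
                           sd = readr::col_double()))
  validate_observations(obs)
}

#' @rdname read_observations
#' @param observations An observation tibble (columns `stream`, `time_h`,
#'   `mean`, `sd`).
#' @export
write_observations <- function(observations, path) {
  observations <- validate_observations(observations)
  readr::write_csv(observations, path)
  invisible(path)
}

#' Validate an observation table
#'
#' Checks the observation-set contract: known streams, times >= 0, means in
#' \[0, 1.5\] (fraction-of-control scale), SDs >= 0, and no duplicated
#' `(stream, time)` pairs.
#'
#' @param observations A data frame with columns `stream`, `time_h`, `mean`,
#'   `sd` (`sd` may be absent for fitting-only use; it is then filled with
#'   `NA`).
#' @return The validated tibble (invisibly coerced to `tibble`).
#' @export
validate_observations <- function(observations) {
  need <- c("stream", "time_h", "mean")
  if (!all(need %in% names(observations))) {
    abort(sprintf("observations need columns %s", paste(need, collapse = ", ")))
  }
  obs <- as_tibble(observations)
  if (!"sd" %in% names(obs)) obs$sd <- NA_real_
  obs <- obs[, c("stream", "time_h", "mean", "sd")]
  bad <- setdiff(unique(obs$stream), c("viability", "atp", "gag"))
  if (length(bad)) {
    abort(sprintf("unknown stream(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(obs$time_h < 0)) abort("observation times must be >= 0")
  if (any(obs$mean < 0 | obs$mean > 1.5)) {
    abort("observation means must lie in [0, 1.5] (fraction-of-control scale)")
  }
  if (any(!is.na(obs$sd) & obs$sd < 0)) abort("observation sds must be >= 0")
  if (anyDuplicated(obs[, c("stream", "time_h")])) {
    abort("duplicate (stream, time) observation")
  }
  obs
}

#' Rescale raw viability percentages to the fraction-of-control scale
#'
#' In the source experiments all explants, controls included, averaged 89%
#' initial viability; taking that as the healthy baseline, raw percentages
#' are divided by the baseline so that normal cartilage reads 1.0.
#'
#' @param raw_percent Raw viability value(s) in percent.
#' @param baseline_percent Baseline viability in percent (> 0), default 89.
#' @return Fraction-of-control value(s).
#' @examples
#' normalize_viability(89)  # 1.0
#' normalize_viability(44.5)  # 0.5
#' @export
normalize_viability <- function(raw_percent, baseline_percent = 89) {
  if (!is.numeric(baseline_percent) || length(baseline_percent) != 1L ||
      !is.finite(baseline_percent) || baseline_percent <= 0) {
    abort("`baseline_percent` must be a single number > 0")
  }
  raw_percent / baseline_percent
}
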