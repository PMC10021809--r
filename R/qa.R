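# Quality assurance: capacity correlations and urban/rural summaries.
#
# Discharge capacity grows with population served, so the Pearson
# correlation between log10 permitted discharge capacity and log10
# estimated population (and density and area) is a boundary sanity check.
# Correlations are computed overall and per construction-method stratum on
# both the log10 and raw scales; strata with fewer than three usable
# records are reported as not estimable rather than dropped.

#' Base-10 log transform with explicit exclusions
#'
#' Non-positive values cannot be log-transformed; they are excluded and
#' their indices reported, never silently coerced.
#'
#' @param values numeric vector.
#' @return list with `transformed` (log10 of the positive values) and
#'   `excluded` (integer indices of non-positive or non-finite values).
#' @export
log10Series <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) == length(values))
    emptyInputError("log10Series: no positive values to transform")
  list(transformed = log10(values[setdiff(seq_along(values), bad)]),
       excluded = bad)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the two-sided p-value from the t statistic on
#' n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite, non-degenerate).
#' @return list with `r`, `p` and `n`.
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y)) domainError("x and y must have equal length")
  if (length(x) < 3L) domainError("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    domainError("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .err("sewersheds_degenerate_error", "zero variance in a correlation input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Assemble QA records from estimates and plants
#'
#' Joins the per-sewershed population estimates to the plant table.
#'
#' @param estimates data.frame from [estimateAll()].
#' @param plants a `PlantSet` (or its `featureData` data.frame).
#' @return data.frame with `shed_id`, `plant_id`, `capacity`, `pop`,
#'   `density`, `area`, `method`, `county_id`.
#' @export
qaRecords <- function(estimates, plants) {
  pd <- if (is(plants, "PlantSet")) featureData(plants) else plants
  idx <- match(estimates$plant_id, pd$plant_id)
  if (anyNA(idx))
    referenceError(paste("estimates refer to unknown plant(s):",
                         paste(unique(estimates$plant_id[is.na(idx)]),
                               collapse = ", ")))
  data.frame(shed_id = estimates$shed_id,
             plant_id = estimates$plant_id,
             capacity = pd$capacity[idx],
             pop = estimates$pop2020,
             density = estimates$density,
             area = estimates$area,
             method = estimates$method,
             county_id = if ("county_id" %in% names(pd)) pd$county_id[idx]
                         else NA_character_,
             stringsAsFactors = FALSE)
}

.corRow <- function(stratum, scale, pair, x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  res <- tryCatch(pearsonWithP(x, y),
                  sewersheds_error = function(e) NULL)
  data.frame(stratum = stratum, scale = scale, pair = pair,
             n = length(x),
             r = if (is.null(res)) NA_real_ else res$r,
             p = if (is.null(res)) NA_real_ else res$p,
             estimable = !is.null(res),
             stringsAsFactors = FALSE)
}

#' Capacity-correlation report, overall and per construction method
#'
#' For each stratum with at least three records: Pearson r and p for
#' discharge capacity against population, population density and area, on
#' the log10 scale (non-positive values excluded per [log10Series()]) and
#' on the raw scale.  Degenerate strata (too few records or zero variance)
#' appear with `estimable = FALSE`; one bad stratum never suppresses the
#' others.
#'
#' @param records data.frame from [qaRecords()].
#' @param exclude_stratum optional method label (or county id) whose
#'   records are dropped before computing the report.
#' @return data.frame of class `QAReport`: one row per stratum x scale x
#'   variable pair with columns `stratum`, `scale`, `pair`, `n`, `r`, `p`,
#'   `estimable`.
#' @export
qaReport <- function(records, exclude_stratum = NULL) {
  if (nrow(records) < 3L) domainError("qaReport: need at least 3 records")
  if (!is.null(exclude_stratum))
    records <- records[!(records$method %in% exclude_stratum) &
                       !(records$county_id %in% exclude_stratum), , drop = FALSE]
  strata <- c("overall", sort(unique(records$method)))
  pairs <- c(pop = "pop", density = "density", area = "area")
  rows <- list()
  for (st in strata) {
    rec <- if (st == "overall") records else records[records$method == st, , drop = FALSE]
    for (pv in names(pairs)) {
      y <- rec[[pairs[[pv]]]]
      x <- rec$capacity
      # log10 scale: exclude non-positives from both series pairwise
      okl <- is.finite(x) & is.finite(y) & x > 0 & y > 0
      rows[[length(rows) + 1L]] <-
        .corRow(st, "log10", paste0("capacity_vs_", pv),
                log10(x[okl]), log10(y[okl]))
      rows[[length(rows) + 1L]] <-
        .corRow(st, "raw", paste0("capacity_vs_", pv), x, y)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("QAReport", "data.frame")
  out
}

#' @export
print.QAReport <- function(x, ...) {
  cat("QA correlation report (Pearson r of discharge capacity vs variable)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Urban/rural summary table
#'
#' Medians by county class: sewershed count, sewered population, density,
#' area, discharge capacity, and the median per-county proportion of
#' population on sewer.
#'
#' @param records data.frame from [qaRecords()] (county ids required).
#' @param county_table data.frame with `county_id`, `urban` (logical) and
#'   `pop` (total county population).
#' @return data.frame with one row per class (`urban`, `rural`); classes
#'   with no counties appear with `n_sheds = 0` and NA medians.
#' @export
urbanRuralSummary <- function(records, county_table) {
  need <- c("county_id", "urban", "pop")
  if (!all(need %in% names(county_table)))
    schemaError("county_table must have county_id, urban, pop")
  idx <- match(records$county_id, county_table$county_id)
  if (anyNA(idx))
    referenceError(paste("unresolvable county id(s):",
                         paste(unique(records$county_id[is.na(idx)]),
                               collapse = ", ")))
  records$urban <- county_table$urban[idx]
  perCounty <- do.call(rbind, lapply(split(records, records$county_id), function(d) {
    tot <- county_table$pop[match(d$county_id[1L], county_table$county_id)]
    data.frame(county_id = d$county_id[1L], urban = d$urban[1L],
               n_sheds = nrow(d), sewered = sum(d$pop),
               prop_sewer = if (tot > 0) min(sum(d$pop) / tot, 1) else NA_real_)
  }))
  out <- do.call(rbind, lapply(c(TRUE, FALSE), function(u) {
    rec <- records[records$urban == u, , drop = FALSE]
    pc <- perCounty[perCounty$urban == u, , drop = FALSE]
    data.frame(class = if (u) "urban" else "rural",
               n_counties = nrow(pc),
               n_sheds = nrow(rec),
               med_sheds_per_county = stats::median(pc$n_sheds),
               med_pop = stats::median(rec$pop),
               med_density = stats::median(rec$density),
               med_area = stats::median(rec$area),
               med_capacity = stats::median(rec$capacity),
               med_prop_sewer = stats::median(pc$prop_sewer),
               stringsAsFactors = FALSE)
  }))
  out$flag <- ifelse(out$n_sheds == 0L, "empty_class", "")
  out
}
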