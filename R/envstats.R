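#' 8-day composite calendar
#'
#' The satellite ocean-color convention: composite periods are 8 days long,
#' start on January 1, and restart each January 1, so the last period of a
#' year has 5 days (6 in leap years). Returns all periods overlapping
#' `[start_date, end_date]`.
#'
#' @param start_date,end_date Calendar dates.
#' @return A tibble: `composite_start`, `composite_end` (inclusive),
#'   `n_days`.
#' @export
composite_calendar <- function(start_date, end_date) {
  start_date <- as_date(start_date); end_date <- as_date(end_date)
  if (end_date < start_date) abort("end_date must be >= start_date")
  years <- seq(year(start_date), year(end_date))
  starts <- as_date(unlist(lapply(years, function(y) {
    jan1 <- ymd(sprintf("%d-01-01", y))
    dec31 <- ymd(sprintf("%d-12-31", y))
    s <- seq(jan1, dec31, by = "8 days")
    s
  })))
  ends <- c(starts[-1] - 1, ymd(sprintf("%d-12-31", max(years))))
  # last composite of each year is clipped at Dec 31
  ends <- pmin(ends, ymd(sprintf("%d-12-31", year(starts))))
  keep <- ends >= start_date & starts <= end_date
  tibble(
    composite_start = starts[keep],
    composite_end = ends[keep],
    n_days = as.integer(ends[keep] - starts[keep]) + 1L
  )
}

#' Average a gridded field over a box around a point
#'
#' Unweighted mean of the non-missing grid cells whose centers fall inside a
#' square box (default 20 x 20 km) centered on a location — the spatial
#' support used to attach a satellite field to a mooring.
#'
#' @param field Tibble with columns `latitude`, `longitude`, `value`.
#' @param latitude,longitude Box center, decimal degrees.
#' @param box_side_km Box side, km (default 20).
#' @return The mean of observed cells in the box; `NA` if all are missing.
#' @export
box_average <- function(field, latitude, longitude, box_side_km = 20) {
  half <- box_side_km / 2
  km_per_deg_lat <- 111.32
  km_per_deg_lon <- 111.32 * cos(latitude * pi / 180)
  dy <- abs(field$latitude - latitude) * km_per_deg_lat
  dx <- abs(field$longitude - longitude) * km_per_deg_lon
  inside <- dy <= half & dx <= half
  if (!any(inside)) abort("box does not cover any grid cell")
  v <- field$value[inside]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' 8-day call-hour proportions from an occurrence grid
#'
#' Aggregates an hourly occurrence grid to the proportion of effort-hours
#' with presence per 8-day composite period, aligned to the satellite
#' composite calendar so acoustic and environmental series share dates.
#' Partial edge windows (deployment starting or ending mid-composite) use
#' the covered days and are flagged.
#'
#' @param grid An `occurrence_grid` (single class, or one row group per
#'   class).
#' @return A tibble per class and composite: `composite_start`, `class`,
#'   `proportion`, `presence_hours`, `effort_hours`, `n_days_covered`,
#'   `partial` (fewer days covered than the composite holds). Composites
#'   with zero effort have `NA` proportion.
#' @export
composite_8day <- function(grid) {
  cal <- composite_calendar(min(grid$date), max(grid$date))
  idx <- findInterval(as.numeric(grid$date), as.numeric(cal$composite_start))
  grid |>
    mutate(composite_start = cal$composite_start[idx]) |>
    group_by(.data$composite_start, .data$class) |>
    summarise(
      presence_hours = sum(.data$presence * .data$effort),
      effort_hours = sum(.data$effort),
      n_days_covered = dplyr::n_distinct(.data$date),
      .groups = "drop"
    ) |>
    left_join(cal, by = "composite_start") |>
    mutate(
      proportion = ifelse(.data$effort_hours > 0,
                          .data$presence_hours / .data$effort_hours, NA_real_),
      partial = .data$n_days_covered < .data$n_days
    ) |>
    select("composite_start", "class", "proportion", "presence_hours",
           "effort_hours", "n_days_covered", "partial")
}

#' Median-impute missing chlorophyll-a values
#'
#' Replaces each missing value with the median of the observed values of the
#' same series (per site), flagging imputed entries. Observed values are
#' never altered.
#'
#' @param x Numeric series with `NA`s; at least one observed value.
#' @return A tibble: `value` (imputed series), `imputed` (logical flags).
#' @export
impute_chla <- function(x) {
  if (all(is.na(x))) abort("all values missing; nothing to impute from")
  med <- median(x, na.rm = TRUE)
  tibble(value = ifelse(is.na(x), med, x), imputed = is.na(x))
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin tidy wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-squared p-value on k-1 degrees of freedom).
#'
#' @param groups A list of numeric vectors, each non-empty.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
kruskal_wallis <- function(groups) {
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty")
  if (sum(lengths(groups)) < 3L) abort("need total N >= 3")
  if (length(unique(unlist(groups))) == 1L) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  n = sum(lengths(groups))))
  }
  kt <- kruskal.test(groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = sum(lengths(groups)))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise Z tests following a Kruskal-Wallis test:
#' `Z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups of the pooled sample; two-sided
#' p-values from the standard normal, adjusted for multiplicity.
#'
#' @param groups A named list of numeric vectors (names become group
#'   labels), each non-empty.
#' @param adjustment `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`
#'   (mean-rank of `group1` minus `group2`, standardized), `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(groups, adjustment = c("holm", "bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty")
  k <- length(groups)
  if (k < 2L) abort("need >= 2 groups")
  labels <- names(groups) %||% as.character(seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_len(k), lengths(groups))
  r <- rank(pooled)
  n_tot <- length(pooled)
  mean_ranks <- tapply(r, grp, mean)
  n_i <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_base <- n_tot * (n_tot + 1) / 12 -
    if (n_tot > 1) tie_term / (12 * (n_tot - 1)) else 0
  pairs <- utils::combn(k, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_base * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se > 0) (mean_ranks[i] - mean_ranks[j]) / se else 0
    tibble(group1 = labels[i], group2 = labels[j], z = unname(z),
           p_raw = 2 * stats::pnorm(-abs(z)))
  })
  out$p_adjusted <- p.adjust(out$p_raw, method = adjustment)
  out
}

#' Model-ready table of composites and covariates
#'
#' Joins per-site 8-day call-hour proportions to the site's environmental
#' series and returns the long-format table an external occupancy model
#' (e.g. a quasi-binomial GAMM) would consume, plus a descriptive Spearman
#' rank-correlation summary of proportion against each covariate per site.
#'
#' @param composites Named list (by site code) of [composite_8day()] outputs
#'   filtered to one class each.
#' @param env Named list (by site code) of environmental tibbles
#'   (`composite_start`, `sst_c`, `chla_mg_m3`), e.g. from [sim_env()];
#'   chl-a is median-imputed per site before joining.
#' @return A list with `table` (site, composite_start, proportion, sst_c,
#'   chla_mg_m3, chla_imputed) and `spearman` (site, covariate, rho,
#'   p_value, n).
#' @export
build_model_table <- function(composites, env) {
  sites <- names(composites)
  if (is.null(sites) || length(sites) == 0L) abort("need >= 1 named site")
  tab <- purrr::map_dfr(sites, function(s) {
    e <- env[[s]]
    imp <- impute_chla(e$chla_mg_m3)
    composites[[s]] |>
      select("composite_start", "proportion") |>
      inner_join(
        tibble(composite_start = e$composite_start, sst_c = e$sst_c,
               chla_mg_m3 = imp$value, chla_imputed = imp$imputed),
        by = "composite_start"
      ) |>
      mutate(site = s, .before = 1)
  })
  spearman <- purrr::map_dfr(sites, function(s) {
    d <- tab |> filter(.data$site == s)
    purrr::map_dfr(c(sst_c = "sst_c", chla_mg_m3 = "chla_mg_m3"), function(v) {
      ok <- complete.cases(d$proportion, d[[v]])
      if (sum(ok) < 4) {
        return(tibble(covariate = v, rho = NA_real_, p_value = NA_real_,
                      n = sum(ok)))
      }
      ct <- suppressWarnings(
        cor.test(d$proportion[ok], d[[v]][ok], method = "spearman")
      )
      tibble(covariate = v, rho = unname(ct$estimate),
             p_value = ct$p.value, n = sum(ok))
    }) |> mutate(site = s, .before = 1)
  })
  list(table = tab, spearman = spearman)
}
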