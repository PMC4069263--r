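# Life tables, instantaneous hazard, log-rank, lifespan summaries and
# detection of mortality separation / post-switch convergence.

#' Build a daily life table from event records
#'
#' Days are integers starting at 1. Censoring on day `d` removes flies after
#' that day's deaths are recorded (censored flies were alive when sampled),
#' so `n_at_risk(d + 1) = n_at_risk(d) - deaths(d) - censored(d)`.
#'
#' @param events data.frame with columns `day` (positive integers) and
#'   `status` ("death" or "censored"); typically one cohort's rows from
#'   [simulate_cohorts()].
#' @param cohort optional label stored on the table.
#' @return a `life_table`: data.frame `day`, `n_at_risk`, `deaths`,
#'   `censored`, from day 1 through the last event day.
#' @export
build_life_table <- function(events, cohort = NULL) {
  if (!all(events$status %in% c("death", "censored"))) {
    bad <- unique(setdiff(events$status, c("death", "censored")))
    stop("unknown status: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  day <- as.integer(events$day)
  if (any(day < 1) || any(day != events$day)) {
    stop("event days must be positive integers", call. = FALSE)
  }
  last <- max(day)
  days <- seq_len(last)
  deaths <- tabulate(day[events$status == "death"], nbins = last)
  censored <- tabulate(day[events$status == "censored"], nbins = last)
  n0 <- nrow(events)
  n_at_risk <- n0 - c(0L, cumsum(deaths + censored)[-last])
  lt <- data.frame(day = days, n_at_risk = n_at_risk, deaths = deaths,
                   censored = censored)
  attr(lt, "cohort") <- cohort
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Instantaneous hazard from a life table
#'
#' Discrete-time estimator: with deaths `D(d)` and at-risk `N(d)` summed
#' over a centered window of `window` days (truncated at the ends of the
#' table), the hazard is `-log(1 - D/N)`, the continuous-time rate implied
#' by the daily death probability. Days with `N = 0` or `D = N` give `NaN`.
#'
#' @param life_table a [build_life_table()] result.
#' @param window odd-preferred pooling window in days (1 = no pooling).
#' @return a `hazard_series`: data.frame `day`, `hazard`, with the window
#'   stored as an attribute.
#' @export
hazard <- function(life_table, window = 1) {
  stopifnot(window >= 1)
  half <- (window - 1) / 2
  nd <- nrow(life_table)
  D <- numeric(nd)
  N <- numeric(nd)
  for (i in seq_len(nd)) {
    lo <- max(1, ceiling(i - half))
    hi <- min(nd, floor(i + half))
    D[i] <- sum(life_table$deaths[lo:hi])
    N[i] <- sum(life_table$n_at_risk[lo:hi])
  }
  h <- ifelse(N == 0 | D == N, NaN, -log(1 - D / N))
  out <- data.frame(day = life_table$day, hazard = h)
  attr(out, "window") <- window
  attr(out, "cohort") <- attr(life_table, "cohort")
  class(out) <- c("hazard_series", "data.frame")
  out
}

#' Log-rank test between two event lists
#'
#' Two-group log-rank comparison (chi-square with 1 df, two-sided p);
#' censored observations contribute to the risk sets only. Computed with
#' the survival package.
#'
#' @param events_a,events_b data.frames with `day` and `status` columns.
#' @return list with `statistic` and `p`.
#' @export
log_rank <- function(events_a, events_b) {
  if (!nrow(events_a) || !nrow(events_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ev <- rbind(
    data.frame(day = events_a$day, dead = events_a$status == "death", grp = "A"),
    data.frame(day = events_b$day, dead = events_b$status == "death", grp = "B"))
  if (!any(ev$dead)) stop("no deaths in either group; log-rank undefined",
                          call. = FALSE)
  fit <- survival::survdiff(survival::Surv(day, dead) ~ grp, data = ev)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(fit$chisq), p = p)
}

#' Maximum lifespan: mean lifespan of the longest-surviving 10 percent
#'
#' Censored flies are excluded from the ranking; the top
#' `ceiling(top_fraction * n_deaths)` death days are averaged.
#'
#' @param events data.frame with `day` and `status`.
#' @param top_fraction fraction of deaths counted as "longest surviving".
#' @return mean death day of the top fraction.
#' @export
max_lifespan <- function(events, top_fraction = 0.10) {
  dd <- sort(events$day[events$status == "death"], decreasing = TRUE)
  if (!length(dd)) stop("no deaths: maximum lifespan undefined", call. = FALSE)
  k <- ceiling(top_fraction * length(dd))
  mean(dd[seq_len(k)])
}

#' Detect sustained hazard separation between two cohorts
#'
#' First day `d` at which `hA / hB >= fold` holds on `k` consecutive days
#' with both hazards defined. Directional: the caller puts the
#' higher-mortality cohort in `a`.
#'
#' @param a,b `hazard_series` for the two cohorts.
#' @param fold required hazard ratio (> 1).
#' @param k consecutive days required.
#' @return the day, or `NA` if never.
#' @export
detect_separation <- function(a, b, fold = 1.5, k = 3) {
  stopifnot(fold > 1, k >= 1)
  days <- intersect(a$day, b$day)
  ha <- a$hazard[match(days, a$day)]
  hb <- b$hazard[match(days, b$day)]
  ok <- is.finite(ha) & is.finite(hb) & hb > 0 & (ha / hb >= fold)
  first_run_start(days, ok, k)
}

#' Detect post-switch convergence of the switched cohort onto the RF hazard
#'
#' Smallest lag `L >= 0` such that `|log(hSF / hRF)| <= log(1 + tol)` on
#' days `switch_day + L, ..., switch_day + L + k - 1` (all with both hazards
#' defined and positive).
#'
#' @param h_sf,h_rf `hazard_series` for the switched and restricted cohorts.
#' @param switch_day day of the diet switch.
#' @param tol ratio tolerance (0.25 = within 25 percent).
#' @param k consecutive days required.
#' @return lag in days post-switch, or `NA` if never.
#' @export
detect_convergence <- function(h_sf, h_rf, switch_day, tol = 0.25, k = 2) {
  stopifnot(tol > 0, k >= 1)
  days <- intersect(h_sf$day, h_rf$day)
  days <- days[days >= switch_day]
  if (!length(days)) return(NA_integer_)
  hs <- h_sf$hazard[match(days, h_sf$day)]
  hr <- h_rf$hazard[match(days, h_rf$day)]
  valid <- is.finite(hs) & is.finite(hr) & hs > 0 & hr > 0
  ok <- valid
  ok[valid] <- abs(log(hs[valid] / hr[valid])) <= log(1 + tol)
  d <- first_run_start(days, ok, k)
  if (is.na(d)) NA_integer_ else as.integer(d - switch_day)
}

# first element of `days` starting a run of >= k consecutive-day successes
first_run_start <- function(days, ok, k) {
  n <- length(ok)
  if (n < k) return(NA_integer_)
  for (i in seq_len(n - k + 1)) {
    idx <- i:(i + k - 1)
    if (all(ok[idx]) && all(diff(days[idx]) == 1)) return(days[i])
  }
  NA_integer_
}

#' Write a life table with its hazard series to TSV
#' @param life_table a [build_life_table()] result.
#' @param path output path.
#' @param window hazard pooling window.
#' @export
write_life_table <- function(life_table, path, window = 1) {
  h <- hazard(life_table, window)
  out <- cbind(life_table, hazard = h$hazard)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
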