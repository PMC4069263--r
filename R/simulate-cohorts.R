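# Gompertz survival cohorts with a diet switch and scheduled censoring.

#' Configuration for the cohort simulator
#'
#' Defines three cohorts of flies followed daily under Gompertz mortality:
#' CF (control food) with hazard `a * exp(b * day)`, RF (restricted food)
#' with hazard `dr_hazard_fold * a * exp(b * day)`, and SF which follows the
#' CF hazard until `switch_day` and then moves to the RF hazard linearly (in
#' hazard) over `convergence_lag` days.
#'
#' @param n_flies flies per cohort at day 1.
#' @param gompertz_a baseline hazard per day at day 0 (> 0).
#' @param gompertz_b exponential age-acceleration rate per day.
#' @param dr_hazard_fold multiplicative hazard reduction under restricted
#'   food, in (0, 1]; 0.5 halves age-specific mortality.
#' @param switch_day day of the CF-to-RF switch for the SF cohort.
#' @param convergence_lag days over which the SF hazard interpolates from
#'   the CF to the RF level (0 = instantaneous).
#' @param max_day last simulated day; survivors at `max_day` are censored
#'   administratively.
#' @param censor_schedule optional named list per cohort of data.frames with
#'   columns `day`, `count`: live flies removed (censored) on those days,
#'   e.g. sampling decrements. NULL = no scheduled censoring.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_flies = 3000,
                              gompertz_a = 0.001,
                              gompertz_b = 0.09,
                              dr_hazard_fold = 0.5,
                              switch_day = 40,
                              convergence_lag = 3,
                              max_day = 120,
                              censor_schedule = NULL,
                              seed = 1L) {
  if (gompertz_a <= 0) stop("gompertz_a must be > 0", call. = FALSE)
  if (dr_hazard_fold <= 0 || dr_hazard_fold > 1) {
    stop("dr_hazard_fold must lie in (0, 1]", call. = FALSE)
  }
  if (switch_day < 1) stop("switch_day must be >= 1", call. = FALSE)
  if (convergence_lag < 0) stop("convergence_lag must be >= 0", call. = FALSE)
  if (!is.null(censor_schedule)) {
    bad <- setdiff(names(censor_schedule), c("CF", "RF", "SF"))
    if (length(bad)) stop("censor_schedule cohorts must be CF/RF/SF", call. = FALSE)
  }
  structure(list(n_flies = as.integer(n_flies), gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, dr_hazard_fold = dr_hazard_fold,
                 switch_day = as.integer(switch_day),
                 convergence_lag = convergence_lag,
                 max_day = as.integer(max_day),
                 censor_schedule = censor_schedule, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' True daily hazard of a simulated cohort
#'
#' @param config a [cohort_sim_config()].
#' @param cohort "CF", "RF" or "SF".
#' @param days integer days at which to evaluate.
#' @return numeric hazard per day.
#' @export
true_hazard <- function(config, cohort, days) {
  a <- config$gompertz_a
  b <- config$gompertz_b
  h_cf <- a * exp(b * days)
  h_rf <- config$dr_hazard_fold * h_cf
  switch(cohort,
    CF = h_cf,
    RF = h_rf,
    SF = {
      lag <- config$convergence_lag
      w <- if (lag > 0) pmin(pmax((days - config$switch_day) / lag, 0), 1)
           else as.numeric(days >= config$switch_day)
      (1 - w) * h_cf + w * h_rf
    },
    stop("unknown cohort: ", cohort, call. = FALSE))
}

#' Simulate event records for the three cohorts
#'
#' Each day, every fly still alive dies with probability
#' `1 - exp(-h(day))`; scheduled censoring then removes live flies (a
#' schedule that asks for more flies than remain alive is an error naming
#' the day). Survivors at `max_day` are censored on that day.
#'
#' @param config a [cohort_sim_config()].
#' @return list with
#'   \describe{
#'     \item{events}{data.frame `fly_id`, `cohort`, `day`, `status`
#'       ("death" or "censored"); one row per fly.}
#'     \item{truth}{the config itself plus per-cohort hazard closures
#'       (`truth$hazard(cohort, days)`).}
#'   }
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  cohorts <- c("CF", "RF", "SF")
  all_events <- vector("list", length(cohorts))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    n <- config$n_flies
    day_of <- integer(n)
    status <- character(n)
    alive <- seq_len(n)
    sched <- config$censor_schedule[[co]]
    for (d in seq_len(config$max_day)) {
      if (!length(alive)) break
      p <- 1 - exp(-true_hazard(config, co, d))
      dies <- stats::runif(length(alive)) < p
      day_of[alive[dies]] <- d
      status[alive[dies]] <- "death"
      alive <- alive[!dies]
      if (!is.null(sched)) {
        k <- sum(sched$count[sched$day == d])
        if (k > 0) {
          if (k > length(alive)) {
            stop(sprintf("censor schedule for %s on day %d asks for %d flies but only %d remain alive",
                         co, d, k, length(alive)), call. = FALSE)
          }
          taken <- alive[seq_len(k)]
          day_of[taken] <- d
          status[taken] <- "censored"
          alive <- alive[-seq_len(k)]
        }
      }
    }
    if (length(alive)) {
      day_of[alive] <- config$max_day
      status[alive] <- "censored"
    }
    all_events[[ci]] <- data.frame(
      fly_id = sprintf("%s_%05d", co, seq_len(n)),
      cohort = co, day = day_of, status = status, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  truth <- list(config = config,
                hazard = function(cohort, days) true_hazard(config, cohort, days))
  list(events = events, truth = truth)
}

#' Sampling-style censor schedule
#'
#' Emulates the removal of live flies for expression profiling: `per_sample`
#' flies are censored from each cohort on the day of each post-switch
#' sampling hour (hour h falls on day `switch_day + ceiling(h / 24)`).
#'
#' @param switch_day day of the diet switch.
#' @param hours post-switch sampling hours.
#' @param per_sample flies removed per sampling time per cohort.
#' @param cohorts cohorts sampled.
#' @return named list suitable for `censor_schedule` in [cohort_sim_config()].
#' @export
sampling_censor_schedule <- function(switch_day = 40,
                                     hours = c(2, 4, 6, 8, 12, 18, 24, 32, 40, 48, 56, 72),
                                     per_sample = 75,
                                     cohorts = c("CF", "RF", "SF")) {
  days <- switch_day + ceiling(hours / 24)
  tab <- as.data.frame(table(days), stringsAsFactors = FALSE)
  sched <- data.frame(day = as.integer(tab$days),
                      count = as.integer(tab$Freq) * per_sample)
  stats::setNames(rep(list(sched), length(cohorts)), cohorts)
}

#' Write event records to TSV
#' @param events data.frame from [simulate_cohorts()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(events)
}

#' Read event records from TSV
#' @param path path to a TSV with columns `fly_id`, `cohort`, `day`, `status`.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort", "day", "status")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ev
}
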