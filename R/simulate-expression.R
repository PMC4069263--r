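# Synthetic three-cohort expression time courses with known per-gene truth.

#' Configuration for the expression simulator
#'
#' Builds and validates the parameter set for [simulate_expression()]. The
#' simulator emulates an already-normalized log2 expression matrix for three
#' cohorts -- CF (control food), RF (restricted food) and SF (switched from
#' CF to RF at the switch time) -- sampled over a post-switch time grid.
#'
#' Each gene is drawn from one of seven archetypes:
#' \describe{
#'   \item{null}{no diet effect anywhere.}
#'   \item{switch_up / switch_down}{diet-dependent (RF differs from CF by
#'     `+delta` / `-delta`); the SF cohort moves from the CF level to the RF
#'     level along a fast logistic in time.}
#'   \item{refractory}{diet-dependent, but SF stays at the CF level.}
#'   \item{responsive}{diet-dependent; SF settles at an intermediate level
#'     (`responsive_level` of the CF-to-RF gap), matching neither cohort.}
#'   \item{deviating}{diet-independent (RF equals CF) but SF departs from
#'     both by `delta` (sign chosen per gene).}
#'   \item{slow_switch}{diet-dependent; SF follows a slow logistic
#'     (`slow_t0`, `slow_tau`) that has not completed by the last sampled
#'     hour.}
#' }
#'
#' @param n_genes number of genes (rows).
#' @param archetype_mix named numeric vector of proportions over the seven
#'   archetypes; must sum to 1.
#' @param delta log2 effect size: the RF-minus-CF mean difference for every
#'   diet-dependent gene (and the SF offset of deviating genes).
#' @param t0 midpoint (hours) of the fast switching logistic.
#' @param tau time constant (hours) of the fast switching logistic.
#' @param slow_t0,slow_tau midpoint and time constant of the slow logistic
#'   used by the `slow_switch` archetype.
#' @param responsive_level position of the responsive plateau along the
#'   CF-to-RF gap, strictly between 0 and 1.
#' @param sigma residual noise SD in log2 units (per sample).
#' @param timepoints strictly increasing post-switch sampling hours.
#' @param replicates_per_point biological replicates per cohort x time point.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   output.
#'
#' @return an object of class `expr_sim_config` (a validated list).
#' @seealso [simulate_expression()]
#' @export
expr_sim_config <- function(n_genes = 2000,
                            archetype_mix = c(null = 0.40, switch_up = 0.10,
                                              switch_down = 0.10, refractory = 0.15,
                                              responsive = 0.10, deviating = 0.05,
                                              slow_switch = 0.10),
                            delta = 2,
                            t0 = 2,
                            tau = 1,
                            slow_t0 = 36,
                            slow_tau = 24,
                            responsive_level = 0.5,
                            sigma = 0.25,
                            timepoints = c(2, 4, 6, 8, 12, 18, 24, 32, 40, 48, 56, 72),
                            replicates_per_point = 3,
                            seed = 1L) {
  archetypes <- c("null", "switch_up", "switch_down", "refractory",
                  "responsive", "deviating", "slow_switch")
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% archetypes)) {
    stop("archetype_mix must be named with archetypes among: ",
         paste(archetypes, collapse = ", "), call. = FALSE)
  }
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9) {
    stop("archetype_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing with length >= 2", call. = FALSE)
  }
  if (replicates_per_point < 1) stop("replicates_per_point must be >= 1", call. = FALSE)
  if (responsive_level <= 0 || responsive_level >= 1) {
    stop("responsive_level must lie strictly between 0 and 1", call. = FALSE)
  }
  mix <- stats::setNames(numeric(length(archetypes)), archetypes)
  mix[names(archetype_mix)] <- archetype_mix
  cfg <- list(n_genes = as.integer(n_genes), archetype_mix = mix,
              delta = delta, t0 = t0, tau = tau,
              slow_t0 = slow_t0, slow_tau = slow_tau,
              responsive_level = responsive_level, sigma = sigma,
              timepoints = timepoints,
              replicates_per_point = as.integer(replicates_per_point),
              seed = as.integer(seed))
  class(cfg) <- "expr_sim_config"
  cfg
}

# Largest-remainder allocation of n genes to archetype proportions, so the
# realized mix matches the requested one exactly (up to integer rounding).
allocate_archetypes <- function(n, mix) {
  raw <- n * mix
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(mix), times = counts)
}

# Fractional progress of the SF cohort toward the RF level, per archetype.
# Returns a vector over `t` in [0, 1] (responsive/deviating use a constant
# plateau; deviating is handled by the caller since its RF offset is zero).
sf_fraction <- function(archetype, t, cfg) {
  switch(archetype,
    null        = rep(0, length(t)),
    refractory  = rep(0, length(t)),
    switch_up   = stats::plogis((t - cfg$t0) / cfg$tau),
    switch_down = stats::plogis((t - cfg$t0) / cfg$tau),
    responsive  = rep(cfg$responsive_level, length(t)),
    deviating   = rep(1, length(t)),
    slow_switch = stats::plogis((t - cfg$slow_t0) / cfg$slow_tau),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

#' Simulate a three-cohort expression matrix with known truth
#'
#' Draws per-gene baselines uniformly on \[4, 12\] log2 units (the typical
#' microarray score range), applies the archetype-specific RF offset and SF
#' time profile, and adds i.i.d. Gaussian noise with SD `sigma` to every
#' sample. The SF cohort is only sampled post-switch, so all columns sit on
#' the post-switch time grid.
#'
#' @param config an [expr_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{expr}{an `expression_matrix` (see [expression_matrix()]):
#'       genes x (3 cohorts x timepoints x replicates) log2 values plus
#'       sample metadata.}
#'     \item{truth}{data.frame `gene_id`, `archetype`, `direction`
#'       (sign of the planted diet/deviation effect: "up", "down" or
#'       "none").}
#'   }
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  tp <- cfg$timepoints
  reps <- cfg$replicates_per_point
  cohorts <- c("CF", "RF", "SF")

  archetype <- allocate_archetypes(n, cfg$archetype_mix)
  gene_id <- sprintf("g%04d", seq_len(n))
  mu <- stats::runif(n, 4, 12)
  # signed effect per gene: switching genes carry their stated direction;
  # the other diet-dependent archetypes (and deviators) go either way
  sign_g <- ifelse(archetype == "switch_down", -1, 1)
  free_sign <- archetype %in% c("deviating", "refractory", "responsive", "slow_switch")
  sign_g[free_sign] <- sample(c(-1, 1), sum(free_sign), replace = TRUE)
  dev <- archetype == "deviating"
  delta_g <- cfg$delta * sign_g
  delta_g[archetype == "null"] <- 0

  meta <- expand.grid(replicate = seq_len(reps), time_h = tp, cohort = cohorts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("cohort", "time_h", "replicate")]
  meta$sample_id <- sprintf("%s_t%02d_r%d", meta$cohort, meta$time_h, meta$replicate)

  m <- matrix(0, nrow = n, ncol = nrow(meta),
              dimnames = list(gene_id, meta$sample_id))
  # cohort mean surfaces: CF = mu; RF = mu + delta (0 for deviating/null);
  # SF = mu + offset * f(t)
  rf_delta <- delta_g
  rf_delta[dev] <- 0
  frac <- t(vapply(archetype, sf_fraction, numeric(length(tp)),
                   t = tp, cfg = cfg))        # genes x timepoints
  for (j in seq_len(nrow(meta))) {
    co <- meta$cohort[j]
    ti <- match(meta$time_h[j], tp)
    mean_j <- switch(co,
      CF = mu,
      RF = mu + rf_delta,
      SF = mu + delta_g * frac[, ti])
    m[, j] <- mean_j
  }
  if (cfg$sigma > 0) {
    m <- m + matrix(stats::rnorm(length(m), sd = cfg$sigma), nrow = n)
  }

  truth <- data.frame(
    gene_id = gene_id,
    archetype = archetype,
    direction = ifelse(delta_g > 0, "up", ifelse(delta_g < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
  list(expr = expression_matrix(m, meta[, c("sample_id", "cohort", "time_h", "replicate")]),
       truth = truth)
}
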