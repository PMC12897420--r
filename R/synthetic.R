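#' Synthetic daily rainfall with persistent wet spells
#'
#' Generates an intermittent daily rainfall series from a two-state Markov
#' occurrence chain (wet/dry, with persistence) and gamma-distributed
#' wet-day amounts. The gamma scale is chosen so that the *unconditional*
#' mean depth equals `target_mean_mm`: with stationary wet-day probability
#' `pi = p_wet_after_dry / (1 + p_wet_after_dry - p_wet_after_wet)`, the
#' wet-day mean is `target_mean_mm / pi`. Defaults emulate a wet tropical
#' alpine (paramo) regime: frequent light rain (mean about 3.1 mm/day) with
#' rare daily maxima around 40 mm.
#'
#' @param n_days Number of days to generate.
#' @param p_wet_after_dry Probability a dry day is followed by a wet day.
#' @param p_wet_after_wet Probability a wet day is followed by a wet day.
#' @param amount_shape Gamma shape for wet-day amounts.
#' @param target_mean_mm Target unconditional mean depth, mm/day.
#' @param start_date First calendar day of the series.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `date`, `precip_mm`.
#' @examples
#' r <- gen_rainfall(365, seed = 1)
#' mean(r$precip_mm)
#' @export
gen_rainfall <- function(n_days,
                         p_wet_after_dry = 0.5,
                         p_wet_after_wet = 0.7,
                         amount_shape = 1,
                         target_mean_mm = 3.1,
                         start_date = as.Date("2008-01-01"),
                         seed = NULL) {
  stopifnot(n_days >= 1,
            p_wet_after_dry >= 0, p_wet_after_dry <= 1,
            p_wet_after_wet >= 0, p_wet_after_wet <= 1,
            amount_shape > 0, target_mean_mm > 0)
  if (!is.null(seed)) set.seed(seed)
  wet <- logical(n_days)
  pi_wet <- if (p_wet_after_dry == 0 && p_wet_after_wet == 0) 0 else
    p_wet_after_dry / (1 + p_wet_after_dry - p_wet_after_wet)
  wet[1] <- stats::runif(1) < pi_wet
  for (t in seq_len(n_days)[-1]) {
    pw <- if (wet[t - 1]) p_wet_after_wet else p_wet_after_dry
    wet[t] <- stats::runif(1) < pw
  }
  p <- numeric(n_days)
  nw <- sum(wet)
  if (nw > 0 && pi_wet > 0) {
    scale <- target_mean_mm / (pi_wet * amount_shape)
    p[wet] <- stats::rgamma(nw, shape = amount_shape, scale = scale)
  }
  data.frame(date = as.Date(start_date) + seq_len(n_days) - 1, precip_mm = p)
}

#' Synthetic sampling design with antecedent warm-up
#'
#' Draws `n_events` strictly increasing sampling dates within a discharge
#' span, each at least `warmup_days` after the series start (so every
#' antecedent window is fully observed) and at least `min_gap_days` apart.
#'
#' @param start,end First and last day of the available discharge series.
#' @param n_events Number of sampling events.
#' @param min_gap_days Minimum spacing between events, days.
#' @param warmup_days Days of history required before the first event
#'   (at least the largest antecedent window; default 9).
#' @param seed Optional integer seed.
#' @return Vector of `Date`s, strictly increasing.
#' @export
gen_sampling_design <- function(start, end, n_events, min_gap_days = 14,
                                warmup_days = 9, seed = NULL) {
  stopifnot(n_events >= 1, min_gap_days >= 1, warmup_days >= 0)
  if (!is.null(seed)) set.seed(seed)
  start <- as.Date(start); end <- as.Date(end)
  first_ok <- start + warmup_days
  span <- as.integer(end - first_ok) + 1L
  reduced <- span - (n_events - 1L) * (min_gap_days - 1L)
  if (span < 1L || reduced < n_events) {
    stop("span too short for ", n_events, " events with a minimum gap of ",
         min_gap_days, " days")
  }
  pos <- sort(sample.int(reduced, n_events))
  offsets <- pos + (seq_len(n_events) - 1L) * (min_gap_days - 1L)
  first_ok + offsets - 1L
}

#' Synthetic fuzzy trait matrix
#'
#' Random family-by-category affinity matrix under a trait schema. Within
#' each trait block one category receives the maximal score 3 (so every
#' family scores every trait and per-trait normalisation is defined) and
#' the remaining categories receive small scores drawn from \{0, 1, 2\}
#' with decreasing probability.
#'
#' @param n_families Number of families.
#' @param schema Trait schema data frame.
#' @param seed Optional integer seed.
#' @return Integer matrix, families x categories, scores in \[0, 3\], with
#'   row names `fam01`, ... and column names `trait|category`.
#' @export
gen_trait_matrix <- function(n_families, schema = default_trait_schema(),
                             seed = NULL) {
  stopifnot(n_families >= 1)
  validate_trait_schema(schema)
  if (!is.null(seed)) set.seed(seed)
  traits <- unique(as.character(schema$trait))
  tm <- matrix(0L, n_families, nrow(schema),
               dimnames = list(sprintf("fam%02d", seq_len(n_families)),
                               schema_labels(schema)))
  for (tr in traits) {
    cols <- which(as.character(schema$trait) == tr)
    for (i in seq_len(n_families)) {
      sc <- sample(0:2, length(cols), replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
      sc[sample.int(length(cols), 1)] <- 3L
      tm[i, cols] <- sc
    }
  }
  tm
}

#' Synthetic-community scenario
#'
#' Parameters of the planted flow-diversity dependence used by
#' [gen_communities()]: communities become more even (higher Shannon
#' diversity and evenness) as a chosen antecedent-flow descriptor at a
#' known "true" window increases.
#'
#' @param true_window Antecedent window (days) carrying the planted signal.
#' @param driver Descriptor name carrying the signal; one of `"q_mean"`,
#'   `"rb"`, `"n_rise"`, `"sum_rise"`, `"sum_fall"`, `"sum_abs"`.
#' @param n_events Number of sampling events.
#' @param n_families Number of families.
#' @param a0 Intercept of the log Dirichlet concentration.
#' @param a1 Slope of the log Dirichlet concentration on the standardised
#'   driver (effect size; 0 plants no signal).
#' @param count_mean Expected number of specimens per event (Poisson).
#' @return A list of class `"memory_scenario"`.
#' @export
memory_scenario <- function(true_window = 9, driver = "sum_fall",
                            n_events = 20, n_families = 15,
                            a0 = 0.5, a1 = 0.8, count_mean = 200) {
  driver <- match.arg(driver, c("q_mean", "rb", "n_rise", "sum_rise",
                                "sum_fall", "sum_abs"))
  stopifnot(n_events >= 5, n_families >= 3, count_mean > 0, true_window >= 2)
  structure(list(true_window = true_window, driver = driver,
                 n_events = n_events, n_families = n_families,
                 a0 = a0, a1 = a1, count_mean = count_mean),
            class = "memory_scenario")
}

#' Synthetic communities with a planted evenness response to flow
#'
#' For each event the scenario's driver descriptor (at the true window) is
#' standardised across events to `z`; the community's symmetric Dirichlet
#' concentration is `theta = exp(a0 + a1 * z)`; relative abundances are
#' drawn from Dirichlet(theta, ..., theta); the total count is Poisson with
#' mean `count_mean` (forced to at least 1); and counts are multinomial.
#' Larger driver values therefore yield stochastically more even
#' communities, hence higher expected Shannon diversity and evenness; with
#' `a1 = 0` community structure is independent of flow.
#'
#' @param scenario A [memory_scenario()].
#' @param driver_values Driver descriptor value for each event, at the
#'   scenario's true window (length `n_events`).
#' @param seed Optional integer seed.
#' @return Integer counts matrix, families x events.
#' @export
gen_communities <- function(scenario, driver_values, seed = NULL) {
  stopifnot(inherits(scenario, "memory_scenario"))
  if (length(driver_values) != scenario$n_events) {
    stop("need one driver value per event (", scenario$n_events, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- driver_values - mean(driver_values)
  sdz <- stats::sd(driver_values)
  z <- if (sdz > 0) z / sdz else z * 0
  theta <- exp(scenario$a0 + scenario$a1 * z)
  nf <- scenario$n_families
  counts <- matrix(0L, nf, scenario$n_events,
                   dimnames = list(sprintf("fam%02d", seq_len(nf)),
                                   sprintf("ev%02d", seq_len(scenario$n_events))))
  for (e in seq_len(scenario$n_events)) {
    g <- stats::rgamma(nf, shape = theta[e], rate = 1)
    if (all(g == 0)) g[sample.int(nf, 1)] <- 1  # guard against underflow
    p <- g / sum(g)
    total <- max(1L, stats::rpois(1, scenario$count_mean))
    counts[, e] <- stats::rmultinom(1, total, p)[, 1]
  }
  counts
}

#' One complete synthetic ecohydrological study
#'
#' Convenience generator running the whole synthetic chain: rainfall,
#' discharge simulation, sampling design, antecedent descriptors, trait
#' matrix, planted communities and per-event diversity. All randomness is
#' controlled by `seed` (sub-seeds are derived for each stage).
#'
#' @param scenario A [memory_scenario()].
#' @param n_years Length of the rainfall record in (365-day) years.
#' @param catchment A [catchment_config()].
#' @param windows Antecedent windows to tabulate.
#' @param seed Integer seed.
#' @return A list with elements `rainfall`, `discharge`, `event_dates`,
#'   `descriptors`, `traits`, `abundance`, `diversity`, `scenario`.
#' @examples
#' \donttest{
#' study <- synth_memory_study(memory_scenario(n_events = 12), seed = 1)
#' head(study$diversity)
#' }
#' @export
synth_memory_study <- function(scenario = memory_scenario(),
                               n_years = 10,
                               catchment = catchment_config(),
                               windows = c(3, 6, 9),
                               seed = 1) {
  stopifnot(scenario$true_window %in% windows)
  sub <- derive_seeds(seed, 4L)
  rain <- gen_rainfall(n_years * 365L, seed = sub[1])
  q <- simulate_discharge(rain, catchment)
  events <- gen_sampling_design(min(rain$date), max(rain$date),
                                scenario$n_events,
                                min_gap_days = max(3L, (n_years * 365L) %/%
                                                     (4L * scenario$n_events)),
                                warmup_days = max(windows), seed = sub[2])
  desc <- descriptor_table(q, events, windows)
  truth <- desc[desc$window == scenario$true_window, ]
  truth <- truth[match(events, truth$event_date), ]
  tm <- gen_trait_matrix(scenario$n_families, seed = sub[3])
  ab <- gen_communities(scenario, truth[[scenario$driver]], seed = sub[4])
  colnames(ab) <- format(events)
  div <- diversity_table(ab, tm)
  list(rainfall = rain, discharge = q, event_dates = events,
       descriptors = desc, traits = tm, abundance = ab, diversity = div,
       scenario = scenario)
}

# Deterministic stream of sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
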