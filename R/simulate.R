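# Synthetic multiannual community + environment generator emulating the two
# sampling designs the pipeline targets: monthly open-ocean (BATS-like) and
# weekly coastal (WEC-like) grids, with antagonistic summer/winter ASV
# guilds, annual sinusoidal temperature, winter-peaking nutrients, a spring
# chlorophyll bloom, stochastic wind/river forcing, and a per-year
# environment -> community coupling strength.

ar1_series <- function(n, rho, sd) {
  e <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive")) +
    stats::rnorm(1, sd = sd) * rho^(seq_len(n))
}

#' Simulation configuration
#'
#' Defaults describe a WEC-like weekly coastal series: 7 years, 10% missed
#' weeks, 8 summer- and 8 winter-peaking ASVs against 14 aperiodic ASVs
#' (6 of them non-SAR11), seasonal amplitude 1.2 on the log scale
#' (~11-fold summer:winter swing for a seasonal ASV), Dirichlet
#' concentration 200 for realistic amplicon overdispersion, and log-normal
#' library sizes around 20,000 reads.
#'
#' @param n_years simulated span in years.
#' @param cadence `"weekly"` or `"monthly"`.
#' @param missing_fraction fraction of interior sampling dates dropped.
#' @param n_summer_asvs,n_winter_asvs,n_aperiodic_asvs guild sizes.
#' @param seasonal_amplitude amplitude of the annual log-affinity cosine.
#' @param dispersion Dirichlet concentration (larger = less overdispersion).
#' @param library_size_meanlog,library_size_sdlog log-normal read-depth
#'   parameters.
#' @param coupling_strength per-year weight in \[0,1\]: 1 = expected
#'   proportions track the same-week environment, 0 = they follow an 8-week
#'   moving average of the seasonal signal (decoupled).
#' @param storminess per-year wind/river forcing level in \[0,1\].
#' @param env_response weight of the shared week-scale environmental anomaly
#'   in seasonal ASVs' log affinity.
#' @param site `"wec"` or `"bats"` (controls winter ecotype labels).
#' @param start_date first sampling date (a Monday by default).
#' @param seed master RNG seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_years = 7, cadence = c("weekly", "monthly"),
                       missing_fraction = 0.1,
                       n_summer_asvs = 8, n_winter_asvs = 8,
                       n_aperiodic_asvs = 14,
                       seasonal_amplitude = 1.2, dispersion = 200,
                       library_size_meanlog = log(2e4),
                       library_size_sdlog = 0.35,
                       coupling_strength = rep(1, n_years),
                       storminess = rep(0.3, n_years),
                       env_response = 0.5,
                       site = c("wec", "bats"),
                       start_date = "2015-01-05", seed = 1) {
  cadence <- match.arg(cadence)
  site <- match.arg(site)
  cfg <- list(n_years = n_years, cadence = cadence,
              missing_fraction = missing_fraction,
              n_summer_asvs = n_summer_asvs, n_winter_asvs = n_winter_asvs,
              n_aperiodic_asvs = n_aperiodic_asvs,
              seasonal_amplitude = seasonal_amplitude,
              dispersion = dispersion,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              coupling_strength = rep_len(coupling_strength, n_years),
              storminess = rep_len(storminess, n_years),
              env_response = env_response, site = site,
              start_date = as.character(start_date), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Named preset configurations
#'
#' `bats_like`: monthly, 3 years, no gaps. `wec_like`: weekly, 7 years, 10%
#' missed weeks. `coupled_year`: weekly, 2 years, full same-week coupling,
#' calm weather. `decoupled_year`: weekly, 2 years, zero coupling, stormy
#' weather (the record-wet-winter contrast).
#'
#' @param seed master seed forwarded to every preset.
#' @return named list of `sim_config` objects.
#' @export
presets <- function(seed = 1) {
  list(
    bats_like = sim_config(n_years = 3, cadence = "monthly",
                           missing_fraction = 0, site = "bats", seed = seed),
    wec_like = sim_config(n_years = 7, cadence = "weekly",
                          missing_fraction = 0.1, site = "wec", seed = seed),
    coupled_year = sim_config(n_years = 2, cadence = "weekly",
                              missing_fraction = 0,
                              coupling_strength = c(1, 1),
                              storminess = c(0.15, 0.15), seed = seed),
    decoupled_year = sim_config(n_years = 2, cadence = "weekly",
                                missing_fraction = 0,
                                coupling_strength = c(0, 0),
                                storminess = c(0.8, 0.8), seed = seed)
  )
}

# Annual phase in [0, 365): days since 1 Jan of the start year, mod 365
# (365-day simulation year; calendar drift over a few years is negligible).
sim_phase_day <- function(dates, start_date) {
  origin <- as.Date(paste0(format(as.Date(start_date), "%Y"), "-01-01"))
  as.numeric(as.Date(dates) - origin) %% 365
}

#' Generate a synthetic environmental table
#'
#' 17 variables on the configured sampling grid: an annual temperature
#' sinusoid (trough mid-February) with AR(1) anomalies, winter-peaking
#' nutrients floored at zero, a spring chlorophyll bloom, log-normal AR(1)
#' wind and river forcing whose level scales with per-year storminess, and
#' correlated nuisance variables (oxygen, air temperature, PAR, ...).
#'
#' @param cfg a [sim_config()].
#' @return data frame (`date` + 17 variables) with `missing_fraction` of the
#'   interior dates dropped. Attribute `"drivers"` carries the full grid and
#'   the shared anomaly used by [generate_community()].
#' @export
generate_environment <- function(cfg) {
  start <- as.Date(cfg$start_date)
  full_dates <- if (cfg$cadence == "weekly") {
    seq(start, by = 7, length.out = floor(cfg$n_years * 365.25 / 7))
  } else {
    seq(start, by = "month", length.out = cfg$n_years * 12)
  }
  n <- length(full_dates)
  d <- sim_phase_day(full_dates, cfg$start_date)
  year_idx <- pmin(1L + floor(as.numeric(full_dates - start) / 365.25),
                   cfg$n_years)
  storm <- cfg$storminess[year_idx]
  env <- with_seed(cfg$seed, {
    # delta: shared weather/mixing state. A windy week stirs the surface
    # layer, so one common AR(1) signal loads onto most variables at once
    # (cooling, nutrient injection, turbidity, river input, oxygenation);
    # it is also the anomaly a coupled community responds to. Its variance
    # is modulated by a storm envelope — windier in winter, with multi-week
    # stormy/calm regimes — so week-scale change in environment and (when
    # coupled) community co-oscillates at the envelope's period.
    # storm regimes wax and wane over multi-week spells; the year-level
    # storm load is configured, not random, so the log-envelope is centred
    # per realization.
    regime <- ar1_series(n, 0.9, 1)
    regime <- regime - mean(regime)
    envelope <- exp(0.5 * regime)
    # mixing state: a quasi-periodic ~8-week storm cycle (damped AR(2)
    # oscillator — the weekly-cadence signature of recurrent mid-latitude
    # weather regimes) over rougher week-to-week weather
    p0 <- if (cfg$cadence == "weekly") 8 else 2
    damp <- 0.93
    osc <- as.numeric(stats::arima.sim(
      list(ar = c(2 * damp * cos(2 * pi / p0), -damp^2)), n))
    core <- 0.85 * osc / stats::sd(osc) + 0.53 * ar1_series(n, 0.7, 1)
    delta <- envelope * core / stats::sd(core)
    # week-scale change in coastal surface water is weather-coherent: the
    # mixing state moves wind, river input, clouds, heat flux, turbidity,
    # nutrients and oxygenation together; idiosyncratic noise is secondary.
    temp_anom <- -0.6 * delta + ar1_series(n, 0.8, 0.25)
    temperature <- 13.4 + 5.8 * cos(2 * pi * (d - 227) / 365) + temp_anom
    wind_max <- exp(log(8 * (1 + 1.5 * storm)) +
                      0.45 * delta + ar1_series(n, 0.5, 0.12))
    wind_mean <- 0.65 * wind_max * exp(stats::rnorm(n, sd = 0.06))
    river_flow <- exp(log(10 * (1 + 2 * storm)) +
                        0.45 * delta + ar1_series(n, 0.7, 0.15))
    winter <- function(base, amp, mix, sd)
      pmax(0, base + amp * cos(2 * pi * (d - 15) / 365) + mix * delta +
             stats::rnorm(n, sd = sd))
    spring_dist <- pmin(abs(d - 110), 365 - abs(d - 110))
    chlorophyll <- (0.8 + 2.8 * exp(-0.5 * (spring_dist / 18)^2)) *
      exp(0.25 * delta + stats::rnorm(n, sd = 0.1))
    vars <- data.frame(
      date = full_dates,
      temperature = temperature,
      salinity = 35.2 - 0.004 * river_flow - 0.06 * delta +
        stats::rnorm(n, sd = 0.02),
      oxygen = 280 - 4 * (temperature - 13.4) + 5 * delta +
        stats::rnorm(n, sd = 2),
      nitrate = winter(5, 5, 1.5, 0.3),
      nitrite = winter(0.3, 0.25, 0.08, 0.03),
      silicate = winter(4, 3, 1.0, 0.25),
      phosphate = winter(0.4, 0.3, 0.1, 0.025),
      ammonium = pmax(0, 0.5 + 0.12 * delta + stats::rnorm(n, sd = 0.06)),
      chlorophyll = chlorophyll,
      par = pmax(0, 30 + 25 * cos(2 * pi * (d - 172) / 365) - 6 * delta +
                   stats::rnorm(n, sd = 2.5)),
      net_heat_flux = 60 * cos(2 * pi * (d - 190) / 365) - 25 * delta +
        ar1_series(n, 0.5, 10),
      air_temperature = temperature + stats::rnorm(n, sd = 0.8),
      wind_max = wind_max,
      wind_mean = wind_mean,
      river_flow = river_flow,
      turbidity = pmax(0, 0.8 + 0.06 * river_flow + 0.3 * delta +
                         stats::rnorm(n, sd = 0.1)),
      humidity = 80 + 4 * cos(2 * pi * (d - 30) / 365) + 3 * delta +
        stats::rnorm(n, sd = 1.5))
    n_drop <- floor(cfg$missing_fraction * n)
    keep <- seq_len(n)
    if (n_drop > 0) {
      interior <- 2:(n - 1)
      keep <- sort(setdiff(seq_len(n), sample(interior, n_drop)))
    }
    list(vars = vars, delta = delta, envelope = envelope, keep = keep)
  })
  out <- env$vars[env$keep, ]
  rownames(out) <- NULL
  attr(out, "drivers") <- list(full_dates = full_dates, phase_day = d,
                               year_idx = year_idx, delta = env$delta,
                               envelope = env$envelope, keep = env$keep)
  out
}

ecotype_labels_for <- function(cfg) {
  summer_pool <- c(rep("Ia.3", max(1, cfg$n_summer_asvs - 2)), "IV", "Ib.2")
  winter_pool <- if (cfg$site == "wec")
    c("Ia.1", "Ia.1", "IIa.B", "IIa.B", "Ib", "IIb", "II", "Ia.1")
  else c("Ib", "Ib", "IIa.A", "IIa.A", "Ia.4", "IV", "I", "IIa")
  n_other <- min(6, cfg$n_aperiodic_asvs)
  aper_pool <- c(rep("other", n_other),
                 rep(c("II", "IIIa", "I", "IIa"),
                     length.out = max(0, cfg$n_aperiodic_asvs - n_other)))
  list(summer = rep_len(summer_pool, cfg$n_summer_asvs),
       winter = rep_len(winter_pool, cfg$n_winter_asvs),
       aperiodic = aper_pool[seq_len(cfg$n_aperiodic_asvs)])
}

#' Generate a synthetic ASV community tracking the environment
#'
#' Each seasonal ASV i carries an annual log affinity
#' A*cos(2*pi*(d - peak_i)/365) plus `env_response` times the shared
#' week-scale environmental anomaly (positive for summer ASVs, negative for
#' winter ones). Under per-year coupling c the effective log affinity is
#' c * signal + (1 - c) * (8-week moving average of the signal): full
#' coupling makes expected proportions respond to the same-week environment,
#' zero coupling removes week-scale response while preserving the annual
#' cycle. Proportions are drawn Dirichlet(concentration * expected), counts
#' multinomial at log-normal library sizes.
#'
#' @param cfg a [sim_config()].
#' @param env output of [generate_environment()] under the same `cfg`.
#' @return list: `counts` (a [count_matrix()]), `taxonomy` (named vector),
#'   `truth` (per-ASV classes/peaks, per-year coupling labels, driver
#'   parameters).
#' @export
generate_community <- function(cfg, env) {
  drv <- attr(env, "drivers")
  if (is.null(drv)) stop("env must come from generate_environment()")
  if (!all(as.Date(env$date) %in% drv$full_dates))
    stop("env dates inconsistent with its simulation grid")
  n_full <- length(drv$full_dates)
  guilds <- ecotype_labels_for(cfg)
  n_s <- cfg$n_summer_asvs; n_w <- cfg$n_winter_asvs; n_a <- cfg$n_aperiodic_asvs
  n_asv <- n_s + n_w + n_a
  asv_ids <- sprintf("ASV%03d", seq_len(n_asv))
  classes <- c(rep("summer", n_s), rep("winter", n_w), rep("aperiodic", n_a))
  labels <- c(guilds$summer, guilds$winter, guilds$aperiodic)
  # winter guild mirrors the summer guild exactly (peak + half year, paired
  # base shares below): antagonism keeps the seasonal mass semiannual, so
  # compositional closure leaks no annual signal into the aperiodic ASVs.
  summer_peaks <- round(seq(185, 230, length.out = n_s))
  winter_peaks <- round(rep_len(summer_peaks, n_w) + 182.5) %% 365
  peaks <- c(summer_peaks, winter_peaks, rep(NA_integer_, n_a))
  res <- with_seed(cfg$seed + 1000000L, {
    # guild base shares fixed (other 40%, aperiodic SAR11 24%, 18% each guild)
    # so the two seasonal guilds are balanced and closure leakage into the
    # aperiodic ASVs stays small.
    raw <- stats::rlnorm(n_asv, 0, 0.8)
    share <- numeric(n_asv)
    is_other <- labels == "other"
    grp <- list(summer = classes == "summer", winter = classes == "winter",
                ap_sar = classes == "aperiodic" & !is_other, other = is_other)
    tgt <- c(summer = 0.22, winter = 0.22, ap_sar = 0.11, other = 0.45)
    for (g in names(grp)) {
      idx <- grp[[g]]
      if (any(idx)) share[idx] <- tgt[[g]] * raw[idx] / sum(raw[idx])
    }
    # pair winter shares with their mirrored summer partners
    if (n_w > 0 && n_s > 0) {
      s_share <- share[classes == "summer"]
      share[classes == "winter"] <-
        tgt[["winter"]] * rep_len(s_share, n_w) / sum(rep_len(s_share, n_w))
    }
    A <- cfg$seasonal_amplitude
    d <- drv$phase_day
    # the anomaly response saturates (tanh, cap 1.5 on the log scale): a
    # 4-sigma storm cannot peg the community to one guild. It is also
    # mean-neutral: the expected multiplicative response, integrated over
    # the week's anomaly distribution, is divided out, so the softmax
    # denominator is not rectified upward in stormy regimes and the
    # aperiodic ASVs see no systematic leakage from the seasonal guilds.
    k <- cfg$env_response
    tau <- 3
    resp <- tau * tanh(drv$delta / tau)
    z <- seq(-5, 5, by = 0.1)
    wz <- stats::dnorm(z) * 0.1
    comp <- log(colSums(
      exp(k * tau * tanh(outer(z, drv$envelope) / tau)) * wz))
    logaff <- matrix(rep(log(share), each = n_full), nrow = n_full)
    for (i in which(classes != "aperiodic")) {
      r <- if (classes[i] == "summer") 1 else -1
      logaff[, i] <- logaff[, i] + A * cos(2 * pi * (d - peaks[i]) / 365) +
        k * r * resp - comp
    }
    cw <- cfg$coupling_strength[drv$year_idx]
    for (i in which(classes != "aperiodic")) {
      sm <- moving_average(logaff[, i], 8)
      logaff[, i] <- cw * logaff[, i] + (1 - cw) * sm
    }
    expected <- exp(logaff - apply(logaff, 1, max))
    expected <- expected / rowSums(expected)
    libs <- pmax(100, round(stats::rlnorm(n_full, cfg$library_size_meanlog,
                                          cfg$library_size_sdlog)))
    counts <- matrix(0L, nrow = n_full, ncol = n_asv)
    for (w in seq_len(n_full)) {
      gam <- stats::rgamma(n_asv, shape = cfg$dispersion * expected[w, ])
      if (sum(gam) == 0) gam <- expected[w, ]
      counts[w, ] <- stats::rmultinom(1, libs[w], gam / sum(gam))[, 1]
    }
    list(counts = counts, share = share, expected = expected)
  })
  keep <- drv$keep
  cm <- count_matrix(res$counts[keep, , drop = FALSE],
                     drv$full_dates[keep],
                     sample_ids = paste0("S", format(drv$full_dates[keep])),
                     asv_ids = asv_ids)
  truth <- list(
    asv = data.frame(asv_id = asv_ids, class = classes, ecotype = labels,
                     peak_day = peaks, base_share = res$share,
                     stringsAsFactors = FALSE),
    years = data.frame(year = seq_len(cfg$n_years),
                       coupling_strength = cfg$coupling_strength,
                       storminess = cfg$storminess,
                       label = ifelse(cfg$coupling_strength >= 0.5,
                                      "coupled", "uncoupled"),
                       stringsAsFactors = FALSE),
    params = list(seasonal_amplitude = cfg$seasonal_amplitude,
                  env_response = cfg$env_response,
                  dispersion = cfg$dispersion, seed = cfg$seed),
    expected = res$expected[keep, , drop = FALSE])
  list(counts = cm, taxonomy = stats::setNames(labels, asv_ids), truth = truth)
}

#' Simulate a full dataset (environment + community + ground truth)
#'
#' @param cfg a [sim_config()] or the name of a [presets()] entry.
#' @param seed optional seed override.
#' @return list: `counts`, `taxonomy`, `env`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- presets(seed = seed %||% 1)[[cfg]]
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  env <- generate_environment(cfg)
  com <- generate_community(cfg, env)
  list(counts = com$counts, taxonomy = com$taxonomy, env = env,
       truth = com$truth, config = cfg)
}
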