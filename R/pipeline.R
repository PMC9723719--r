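#' Build a validated pipeline configuration
#'
#' Either `simulate` (a [presets()] name) or `input` (paths to counts,
#' taxonomy and env tables) must be given. Unknown keys are rejected.
#'
#' @param simulate preset name, or `NULL` to read files.
#' @param input list with `counts`, `taxonomy`, `env` paths and optionally
#'   `format` (see [read_count_table()]).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param alpha significance level used throughout.
#' @param p_adjust multiplicity correction across ASVs.
#' @param rarefaction list: `depth` (NULL = minimum retained total), `floor`.
#' @param spline list: `df`, `period` (days).
#' @param wavelet list: `omega0`, `dj`, `n_sim`, `alpha`, `window`,
#'   `threshold`.
#' @param clustering list: `k`, `linkage`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL, out_dir = "results",
                            seed = 1, alpha = 0.05, p_adjust = "BH",
                            rarefaction = list(), spline = list(),
                            wavelet = list(), clustering = list()) {
  merge_defaults <- function(user, defaults, what) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0)
      stop("unknown ", what, " option(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  if (is.null(simulate) && is.null(input))
    stop("either `simulate` or `input` must be given")
  cfg <- list(
    simulate = simulate, input = input, out_dir = out_dir,
    seed = as.integer(seed), alpha = alpha, p_adjust = p_adjust,
    rarefaction = merge_defaults(rarefaction,
                                 list(depth = NULL, floor = 1000),
                                 "rarefaction"),
    spline = merge_defaults(spline, list(df = 4, period = 366), "spline"),
    wavelet = merge_defaults(wavelet,
                             list(omega0 = 6, dj = 1 / 20, time_smooth = 2,
                                  n_sim = 100, alpha = 0.05, window = 12,
                                  threshold = 0.2),
                             "wavelet"),
    clustering = merge_defaults(clustering,
                                list(k = 2, linkage = "average"),
                                "clustering"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Per-variable linear interpolation of missing env values in time.
impute_env <- function(env) {
  t <- as.numeric(as.Date(env$date))
  for (v in setdiff(colnames(env), "date")) {
    if (anyNA(env[[v]])) {
      ok <- !is.na(env[[v]])
      env[[v]] <- stats::approx(t[ok], env[[v]][ok], xout = t, rule = 2)$y
    }
  }
  env
}

#' Run the full analysis pipeline
#'
#' Sequences community preparation (ecotype collapse, rarefaction),
#' Bray-Curtis time-decay with periodic spline fit, per-ASV seasonality
#' screening, constrained ordination + PERMANOVA + warm/cold clustering,
#' and (for weekly cadences) the environmental-coupling wavelet analysis.
#' All artifacts land under `cfg$out_dir`; a manifest with input hashes,
#' seed and versions makes reruns verifiable.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest (invisibly written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)

  dat <- stage("load", {
    if (!is.null(cfg$simulate)) {
      simulate_dataset(cfg$simulate, seed = cfg$seed)
    } else {
      cm <- read_count_table(cfg$input$counts,
                             format = cfg$input$format %||% "tsv")
      list(counts = cm, taxonomy = read_taxonomy(cfg$input$taxonomy),
           env = read_env_table(cfg$input$env), truth = NULL)
    }
  })
  cadence <- if (median(diff(as.numeric(dat$counts$dates))) <= 10)
    "weekly" else "monthly"

  stage("community", {
    eco <- collapse_by_ecotype(dat$counts, dat$taxonomy)
    ra_eco <- relative_abundance(eco)
    utils::write.csv(data.frame(sample_id = eco$sample_ids,
                                date = as.character(eco$dates),
                                ra_eco$values, check.names = FALSE),
                     out("ecotype_relative_abundance.csv"), row.names = FALSE)
    emit(out("ecotype_relative_abundance.csv"))
    frac <- sar11_fraction(dat$counts, dat$taxonomy)
    utils::write.csv(data.frame(sample_id = names(frac),
                                date = as.character(dat$counts$dates),
                                sar11_fraction = frac),
                     out("sar11_fraction.csv"), row.names = FALSE)
    emit(out("sar11_fraction.csv"))
  })

  sar11 <- subset_count_matrix(
    dat$counts, asvs = dat$taxonomy[dat$counts$asv_ids] != "other")
  rar <- stage("rarefaction",
               rarefy(sar11, depth = cfg$rarefaction$depth, seed = cfg$seed,
                      floor = cfg$rarefaction$floor))
  bc <- pairwise_distance(rar$counts, "bray_curtis")

  decay <- stage("time_decay", {
    curve <- fit_periodic_spline(time_decay(bc, rar$dates),
                                 df = cfg$spline$df,
                                 period = cfg$spline$period)
    utils::write.csv(as.data.frame(curve), out("time_decay.csv"),
                     row.names = FALSE)
    emit(out("time_decay.csv"))
    curve
  })
  peak <- first_peak_lag(decay)

  seas <- stage("seasonality", {
    tab <- seasonality_screen(relative_abundance(dat$counts), cadence,
                              alpha = cfg$alpha, method = cfg$p_adjust)
    utils::write.csv(tab, out("seasonality.csv"), row.names = FALSE)
    emit(out("seasonality.csv"))
    tab
  })

  ord <- stage("ordination", {
    env_i <- impute_env(dat$env[as.Date(dat$env$date) %in% rar$dates, ])
    idx <- match(as.Date(env_i$date), rar$dates)
    bc_o <- bc[idx, idx]
    capres <- cap(bc_o, env_i, seed = cfg$seed)
    cl <- hierarchical_clusters(bc_o, rar$dates[idx],
                                k = cfg$clustering$k,
                                linkage = cfg$clustering$linkage)
    prm <- permanova(bc_o, cl$season, seed = cfg$seed)
    utils::write.csv(data.frame(sample_id = rownames(capres$site_scores),
                                capres$site_scores,
                                cluster = cl$cluster, season = cl$season),
                     out("ordination_scores.csv"), row.names = FALSE)
    emit(out("ordination_scores.csv"))
    utils::write.csv(data.frame(variable = rownames(capres$biplot_scores),
                                capres$biplot_scores),
                     out("ordination_biplot.csv"), row.names = FALSE)
    emit(out("ordination_biplot.csv"))
    writeLines(cl$newick, out("dendrogram.nwk"))
    emit(out("dendrogram.nwk"))
    list(cap = capres, clusters = cl, permanova = prm)
  })

  coupling <- NULL
  if (cadence == "weekly") {
    coupling <- stage("env_coupling", {
      ra <- relative_abundance(sar11)
      wg_com <- to_weekly_grid(ra$dates, ra$values)
      envv <- impute_env(dat$env)
      keep_vars <- vapply(envv[-1], function(v)
        max(v, na.rm = TRUE) > min(v, na.rm = TRUE), logical(1))
      if (!all(keep_vars))
        warning("dropping degenerate env variable(s): ",
                paste(names(keep_vars)[!keep_vars], collapse = ", "))
      std <- vapply(envv[-1][keep_vars], minmax_standardize,
                    numeric(nrow(envv)))
      wg_env <- to_weekly_grid(envv$date, std)
      span <- as.numeric(intersect(wg_com$monday_dates, wg_env$monday_dates))
      ci <- match(span, as.numeric(wg_com$monday_dates))
      ei <- match(span, as.numeric(wg_env$monday_dates))
      bc_w <- consecutive_distances(wg_com$values[ci, , drop = FALSE],
                                    "bray_curtis")
      eu_w <- consecutive_distances(wg_env$values[ei, , drop = FALSE],
                                    "euclidean")
      cmap <- wavelet_coherence(bc_w, eu_w, dt = 1,
                                omega0 = cfg$wavelet$omega0,
                                dj = cfg$wavelet$dj,
                                time_smooth = cfg$wavelet$time_smooth,
                                n_sim = cfg$wavelet$n_sim,
                                alpha = cfg$wavelet$alpha, seed = cfg$seed)
      seg <- segment_phases(cmap, window = cfg$wavelet$window,
                            threshold = cfg$wavelet$threshold)
      # transition w -> w+1 is paired with the environment of week w+1
      env_after <- wg_env$values[ei, , drop = FALSE][-1, , drop = FALSE]
      phases <- if (any(seg$coupled) && any(!seg$coupled)) {
        compare_phases(env_after, seg$coupled)
      } else {
        message("phase comparison skipped: only one phase present")
        data.frame(variable = character(0), statistic = numeric(0),
                   p = numeric(0), q = numeric(0),
                   median_coupled = numeric(0),
                   median_uncoupled = numeric(0))
      }
      utils::write.csv(data.frame(week = utils::head(as.Date(span, origin = "1970-01-01"), -1),
                                  bray_curtis = bc_w, euclidean = eu_w,
                                  coupling_score = seg$score,
                                  coupled = seg$coupled),
                       out("weekly_distances.csv"), row.names = FALSE)
      emit(out("weekly_distances.csv"))
      utils::write.csv(phases, out("phase_comparison.csv"), row.names = FALSE)
      emit(out("phase_comparison.csv"))
      jsonlite::write_json(
        list(periods = cmap$periods, times = cmap$times, alpha = cmap$alpha,
             n_sim = cmap$n_sim, seed = cfg$seed,
             intervals = seg$intervals),
        out("coherence_summary.json"), auto_unbox = TRUE, digits = NA)
      emit(out("coherence_summary.json"))
      list(map = cmap, segmentation = seg, phases = phases)
    })
  } else {
    message("env_coupling skipped: cadence is ", cadence,
            " (weekly grid required)")
  }

  if (!is.null(dat$truth)) {
    jsonlite::write_json(dat$truth[c("asv", "years", "params")],
                         out("groundtruth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    emit(out("groundtruth.json"))
  }

  manifest <- list(
    seed = cfg$seed,
    cadence = cadence,
    package_version = as.character(utils::packageVersion("ecocycle")),
    first_peak_lag_days = peak,
    permanova = list(pseudo_F = ord$permanova$pseudo_F, p = ord$permanova$p),
    cap = list(constrained_proportion = ord$cap$constrained_proportion,
               adjusted_R2 = ord$cap$adjusted_R2),
    n_seasonal_asvs = sum(seas$class != "nonseasonal"),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
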