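#' Default pipeline configuration
#'
#' A fully serializable configuration for an end-to-end synthetic study run.
#' A single top-level seed fans out deterministically to per-stage child
#' seeds so each stage is independently reproducible.
#'
#' @param seed Top-level integer seed.
#' @param n_participants Cohort size (default 74).
#' @param out_dir Output directory.
#' @param trace,cohort,proteome Optional named lists overriding
#'   [trace_params()], [cohort_params()], [proteome_params()] defaults.
#' @param detection Optional overrides for [peak_config()].
#' @param npx_subjects Subjects drawn into the proteomics set (default 40).
#' @param split_n Responder group size (default 20).
#' @param p_threshold Retention threshold for the proteomics t-tests.
#' @param edges Optional interaction edge-list TSV path.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 74L,
                            out_dir = tempfile("noisenight_run_"),
                            trace = list(), cohort = list(),
                            proteome = list(), detection = list(),
                            npx_subjects = 40L, split_n = 20L,
                            p_threshold = 0.05, edges = NULL) {
  structure(list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    out_dir = out_dir,
    trace = trace, cohort = cohort, proteome = proteome,
    detection = detection,
    npx_subjects = as.integer(npx_subjects),
    split_n = as.integer(split_n),
    p_threshold = p_threshold,
    edges = edges
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' @param path A `.yaml`/`.yml` or `.json` configuration file whose keys
#'   mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

# deterministic fan-out of one seed into per-stage child seeds (< 2^31)
child_seed <- function(seed, stage) {
  offsets <- c(design = 11L, nights = 23L, cohort = 37L, npx = 53L,
               edges = 71L)
  ((as.double(seed) * 48271 + offsets[[stage]] * 104729) %% 2147483647) |>
    as.integer()
}

#' Generate a synthetic interaction edge list
#'
#' A stand-in for a precomputed protein-interaction edge list: random
#' protein pairs with uniform confidence scores. Purely synthetic; carries
#' no biological information.
#'
#' @param proteins Protein ids.
#' @param n_edges Number of random edges.
#' @param seed Optional integer seed.
#' @return Data frame `node_a`, `node_b`, `score`.
#' @export
synthetic_edges <- function(proteins, n_edges = 400L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- sample(proteins, n_edges, replace = TRUE)
  b <- sample(proteins, n_edges, replace = TRUE)
  keep <- a != b
  data.frame(node_a = a[keep], node_b = b[keep],
             score = round(stats::runif(sum(keep)), 3))
}

#' Run the complete synthetic study pipeline
#'
#' Simulates the crossover design, every participant-night trace, runs peak
#' detection and response pairing on each night, fits the crossover models
#' (FMD linear mixed model, occurrence GLMM, before/after deltas, vitamin-C
#' contrast) and the proteomics workflow, and writes all outputs plus a
#' manifest (file hashes, package version, echoed config) to
#' `config$out_dir`.
#'
#' @param config A `pipeline_config`.
#' @return The output bundle (list), invisibly carrying `out_dir`.
#' @export
run_full_study <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- stage("design",
    make_design(config$n_participants, seed = child_seed(config$seed, "design")))
  tparams <- stage("trace_params", do.call(trace_params, config$trace))
  cparams <- stage("cohort_params", do.call(cohort_params, config$cohort))
  pparams <- stage("proteome_params", do.call(proteome_params, config$proteome))
  det_noise <- stage("detection",
    do.call(peak_config, utils::modifyList(list(channel_mode = "raw"),
                                           config$detection)))
  det_hr <- stage("detection",
    do.call(peak_config, utils::modifyList(list(channel_mode = "detrended"),
                                           config$detection)))

  cohort <- stage("cohort",
    simulate_cohort(design, cparams, seed = child_seed(config$seed, "cohort")))

  # per-night simulation + detection
  night_seed0 <- child_seed(config$seed, "nights")
  schedules <- lapply(stats::setNames(nm = nn_conditions()), make_schedule)
  night_summaries <- list()
  occ_rows <- list()
  delta_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(design))) {
    for (per in 1:3) {
      k <- k + 1L
      cond <- design[[paste0("period", per)]][i]
      night <- simulate_night(schedules[[cond]], tparams,
                              seed = (night_seed0 + k) %% 2147483647L)
      res <- analyse_night(night, det_noise, det_hr)
      night_summaries[[k]] <- data.frame(
        participant = design$participant[i], period = per, condition = cond,
        n_noise_peaks = nrow(res$noise_peaks),
        n_hr_peaks = nrow(res$hr_peaks),
        n_true_events = length(night$truth$event_onsets),
        n_true_surges = length(night$truth$surge_onsets)
      )
      occ <- res$occurrence
      occ <- occ[!occ$excluded, , drop = FALSE]
      if (nrow(occ)) {
        occ_rows[[k]] <- cbind(participant = design$participant[i],
                               period = per, condition = cond, occ)
      }
      ba <- res$before_after
      ba <- ba[!ba$excluded, , drop = FALSE]
      if (nrow(ba)) {
        delta_rows[[k]] <- cbind(participant = design$participant[i],
                                 period = per, condition = cond, ba)
      }
    }
  }
  nights <- do.call(rbind, night_summaries)
  occurrence <- do.call(rbind, occ_rows)
  deltas <- do.call(rbind, delta_rows)

  effects <- list(
    fmd = stage("fit_lmm", fit_lmm(cohort, "fmd_pct")),
    occurrence = stage("fit_glmm", fit_glmm_occurrence(occurrence)),
    before_after = stage("fit_before_after", fit_before_after(deltas)),
    vitc = stage("fit_vitc", fit_vitc_contrast(cohort))
  )

  # proteomics on a subset with noise-induced FMD change = noise60 - control
  prot <- stage("proteomics", {
    wide <- merge(
      cohort[cohort$condition == "noise60", c("participant", "fmd_pct")],
      cohort[cohort$condition == "control", c("participant", "fmd_pct")],
      by = "participant", suffixes = c("_n60", "_ctl")
    )
    wide$fmd_change <- wide$fmd_pct_n60 - wide$fmd_pct_ctl
    n_sub <- min(config$npx_subjects, nrow(wide))
    set.seed(child_seed(config$seed, "npx"))
    pick <- wide[sample(nrow(wide), n_sub), ]
    fmd_changes <- stats::setNames(pick$fmd_change,
                                   sprintf("S%03d", pick$participant))
    pparams$n_subjects <- n_sub
    npx <- simulate_npx(pparams, fmd_changes,
                        seed = child_seed(config$seed, "npx"))
    edges <- if (is.null(config$edges)) {
      synthetic_edges(rownames(npx$npx), seed = child_seed(config$seed, "edges"))
    } else config$edges
    run_proteomics(npx, split_n = min(config$split_n, n_sub %/% 2L),
                   p_threshold = config$p_threshold, edges = edges)
  })

  bundle <- list(config = config, design = design, cohort = cohort,
                 nights = nights, occurrence = occurrence, deltas = deltas,
                 effects = effects, proteomics = prot, out_dir = config$out_dir)
  write_bundle(bundle)
  invisible(bundle)
}

effect_table_df <- function(et) {
  list(means = et$means, differences = et$differences)
}

write_bundle <- function(bundle) {
  out <- bundle$out_dir
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  }
  wcsv(bundle$design, "design.csv")
  wcsv(bundle$cohort, "cohort.csv")
  wcsv(bundle$nights, "nights.csv")
  wcsv(bundle$occurrence, "occurrence.csv")
  wcsv(bundle$deltas, "deltas.csv")
  for (nm in names(bundle$effects)) {
    et <- bundle$effects[[nm]]
    wcsv(et$means, paste0("effects_", nm, "_means.csv"))
    wcsv(et$differences, paste0("effects_", nm, "_differences.csv"))
  }
  pr <- bundle$proteomics
  wcsv(pr$de, "proteomics_de.csv")
  jsonlite::write_json(list(strong = pr$split$strong, weak = pr$split$weak),
                       file.path(out, "proteomics_split.json"))
  if (!is.null(pr$cluster)) {
    wcsv(data.frame(protein = pr$cluster$order), "proteomics_cluster_order.csv")
  }
  wcsv(data.frame(subject = rownames(pr$pca$scores), pr$pca$scores),
       "proteomics_pca_scores.csv")
  if (!is.null(pr$network)) {
    utils::write.table(pr$network$edges, file.path(out, "proteomics_subgraph.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1))]
  yaml::write_yaml(cfg_list, file.path(out, "config.yaml"))
  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(
    package = "noisenight",
    version = as.character(utils::packageVersion("noisenight")),
    seed = cfg$seed,
    files = as.list(tools::md5sum(file.path(out, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Human-readable study report
#'
#' Formats the fitted condition means, pairwise FMD differences, the
#' odds-ratio table (condition pair x period) and the before/after
#' heart-rate table from a pipeline bundle. With a partial bundle the
#' available sections are printed and missing artifacts listed as warnings.
#'
#' @param bundle A bundle returned by [run_full_study()] (or a partial list
#'   with some of its components).
#' @return Character vector of report lines, invisibly; also printed.
#' @export
report <- function(bundle) {
  lines <- c("== noisenight study report ==")
  missing <- character(0)
  fmt <- function(x, d = 2) formatC(x, digits = d, format = "f")
  if (!is.null(bundle$nights)) {
    lines <- c(lines, sprintf("Nights simulated: %d (%d participants x 3)",
                              nrow(bundle$nights),
                              length(unique(bundle$nights$participant))))
  } else missing <- c(missing, "nights")
  if (!is.null(bundle$effects$fmd)) {
    m <- bundle$effects$fmd$means
    d <- bundle$effects$fmd$differences
    lines <- c(lines, "-- FMD (%) by condition [95% CI] --",
               sprintf("  %-8s %s [%s, %s]", m$condition, fmt(m$estimate),
                       fmt(m$lwr), fmt(m$upr)),
               "-- Pairwise FMD differences --",
               sprintf("  %-20s %s [%s, %s]  P=%s", d$contrast,
                       fmt(d$estimate), fmt(d$lwr), fmt(d$upr),
                       fmt(d$p_value, 4)))
  } else missing <- c(missing, "effects$fmd")
  if (!is.null(bundle$effects$occurrence)) {
    o <- bundle$effects$occurrence$differences
    lines <- c(lines, "-- Heart-rate peak occurrence odds ratios --",
               sprintf("  %-20s period %-3s OR %s [%s, %s]  P=%s",
                       o$contrast, o$period, fmt(o$odds_ratio),
                       fmt(o$lwr), fmt(o$upr), fmt(o$p_value, 4)))
  } else missing <- c(missing, "effects$occurrence")
  if (!is.null(bundle$effects$before_after)) {
    b <- bundle$effects$before_after$means
    lines <- c(lines, "-- Heart-rate change after noise peaks (bpm) --",
               sprintf("  %-8s period %-3s %s (SE %s) [%s, %s]",
                       b$condition, b$period, fmt(b$estimate), fmt(b$se),
                       fmt(b$lwr), fmt(b$upr)))
  } else missing <- c(missing, "effects$before_after")
  if (!is.null(bundle$effects$vitc)) {
    v <- bundle$effects$vitc$differences
    lines <- c(lines, "-- Vitamin-C contrast on FMD change (%) --",
               sprintf("  %-8s %s [%s, %s]  P=%s", v$condition,
                       fmt(v$estimate), fmt(v$lwr), fmt(v$upr),
                       fmt(v$p_value, 4)))
  } else missing <- c(missing, "effects$vitc")
  if (!is.null(bundle$proteomics)) {
    lines <- c(lines, sprintf("-- Proteomics: %d/%d proteins retained at P<%g --",
                              sum(bundle$proteomics$de$retained),
                              nrow(bundle$proteomics$de),
                              bundle$config$p_threshold %||% 0.05))
  } else missing <- c(missing, "proteomics")
  if (length(missing)) {
    for (m in missing) warning("report: missing bundle artifact '", m, "'",
                               call. = FALSE)
    lines <- c(lines, paste("MISSING:", paste(missing, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
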