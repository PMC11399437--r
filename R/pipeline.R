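# End-to-end orchestration: generate (or load) a cohort, preprocess the
# inspection logs, fit the prospect-theory model per attitude group, fit
# the supporting regressions, and write a machine-readable report bundle
# with a manifest of config hash, seeds, and file checksums.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] for synthetic data, or a directory
#'   path containing `participants.csv`, `ratings.csv`, `events.csv`,
#'   `decisions.csv` (see [read_cohort_dir()]).
#' @param pt_config [sampler_config()] for the choice model.
#' @param assoc_config [sampler_config()] for the regressions.
#' @param fit_groups Attitude groups to fit the choice model to
#'   (`"anti"`, `"neutral"`, `"pro"`), or `character(0)` to skip.
#' @param pt_max_participants Optional cap on participants per fitted
#'   group (first n kept) to bound run time.
#' @param schema_map Column mapping for `cohort` directories, see
#'   [read_cohort_dir()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            pt_config = sampler_config(),
                            assoc_config = assoc_sampler_config(),
                            fit_groups = c("anti", "neutral", "pro"),
                            pt_max_participants = NULL,
                            schema_map = NULL,
                            seed = 1) {
  stopifnot(inherits(cohort, "cohort_config") ||
              (is.character(cohort) && length(cohort) == 1))
  if (is.character(cohort) && !dir.exists(cohort)) {
    stop("cohort directory does not exist: ", cohort)
  }
  structure(list(cohort = cohort, pt_config = pt_config,
                 assoc_config = assoc_config, fit_groups = fit_groups,
                 pt_max_participants = pt_max_participants,
                 schema_map = schema_map,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a cohort from CSV files
#'
#' Loads `participants.csv`, `ratings.csv`, `events.csv`, `decisions.csv`
#' from a directory into a cohort bundle. `schema_map` adapts externally
#' produced files: a named list per table mapping this package's column
#' names to the file's column names, e.g.
#' `list(events = c(participant_id = "subj", duration_ms = "dur"))`.
#'
#' @param dir Directory with the four CSV files.
#' @param schema_map Optional per-table column mappings.
#' @return A `cohort` bundle (without ground truth).
#' @export
read_cohort_dir <- function(dir, schema_map = NULL) {
  read_one <- function(name, required) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    map <- schema_map[[name]]
    if (!is.null(map)) {
      for (ours in names(map)) {
        theirs <- map[[ours]]
        if (!theirs %in% names(df)) {
          stop("schema_map for ", name, ": column '", theirs, "' not found")
        }
        names(df)[names(df) == theirs] <- ours
      }
    }
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      stop(name, ".csv is missing column(s): ", paste(miss, collapse = ", "))
    }
    df
  }
  structure(list(
    participants = read_one("participants", c("participant_id", "attitude")),
    ratings = read_one("ratings", c("participant_id", "outcome_label", "rating")),
    events = read_one("events", c("participant_id", "trial_index", "vaccine",
                                  "box_id", "onset_ms", "duration_ms")),
    decisions = read_one("decisions", c("participant_id", "trial_index",
                                        "vaccine", "decision")),
    truth = NULL,
    evidence = load_evidence_table()
  ), class = "cohort")
}

# derive a stage seed from the master seed (kept well below 2^31)
.stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + offset
}

#' Run the full analysis pipeline
#'
#' Stages (in order): `generate` (or load), `preprocess`, `fit-pt`,
#' `fit-assoc`, `report`. Each stage's outputs are written before the next
#' starts; a `manifest.json` records the config hash, the seeds used, and
#' an MD5 checksum per written file.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Subset of stages to run (later stages reuse in-memory
#'   results of earlier ones, so partial runs must include their
#'   prerequisites).
#' @return The report bundle (list), invisibly writes all artifacts.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("generate", "preprocess", "fit-pt",
                                    "fit-assoc", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("generate", "preprocess", "fit-pt",
                                "fit-assoc", "report"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t_start <- Sys.time()
  log_stage <- function(...) {
    message(sprintf("[vaxcog %s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...)))
  }
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  bundle <- list(config = config)

  # -- generate / load -------------------------------------------------------
  if ("generate" %in% stages) {
    data_dir <- file.path(out_dir, "data")
    if (is.character(config$cohort)) {
      log_stage("generate: loading cohort from ", config$cohort)
      cohort <- read_cohort_dir(config$cohort, config$schema_map)
    } else {
      log_stage("generate: synthetic cohort (seed ",
                .stage_seed(config$seed, 1L), ")")
      cohort <- generate_cohort(config$cohort, .stage_seed(config$seed, 1L),
                                out_dir = data_dir)
      for (f in list.files(data_dir, full.names = TRUE)) note(f)
    }
    bundle$cohort <- cohort
  }

  # -- preprocess ------------------------------------------------------------
  if ("preprocess" %in% stages) {
    if (is.null(bundle$cohort)) stop("stage preprocess: no cohort available")
    log_stage("preprocess: filtering events and classifying ignorance")
    cohort <- bundle$cohort
    summ <- summarize_trials(cohort$events,
                             cohort$decisions[, c("participant_id",
                                                  "trial_index", "vaccine")],
                             cohort$evidence)
    descr <- summarize_ignorance(summ$trials, cohort$participants)
    utils::write.csv(summ$trials,
                     note(file.path(out_dir, "ignorance_summaries.csv")),
                     row.names = FALSE)
    jsonlite::write_json(descr,
                         note(file.path(out_dir, "group_descriptives.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    bundle$trial_summaries <- summ
    bundle$descriptives <- descr
  }

  # -- fit-pt ----------------------------------------------------------------
  if ("fit-pt" %in% stages && length(config$fit_groups) > 0) {
    if (is.null(bundle$trial_summaries)) stop("stage fit-pt: run preprocess first")
    cohort <- bundle$cohort
    fits <- list()
    for (gi in seq_along(config$fit_groups)) {
      g <- config$fit_groups[gi]
      ids <- cohort$participants$participant_id[cohort$participants$attitude == g]
      if (length(ids) == 0) stop("stage fit-pt: no participants in group ", g)
      if (!is.null(config$pt_max_participants)) {
        ids <- utils::head(ids, config$pt_max_participants)
      }
      log_stage("fit-pt: group ", g, " (", length(ids), " participants)")
      dec <- cohort$decisions[cohort$decisions$participant_id %in% ids, ]
      flags <- bundle$trial_summaries$outcomes
      flags <- flags[flags$participant_id %in% ids, ]
      pdat <- build_pt_data(dec, cohort$ratings, flags, cohort$evidence)
      cfg <- config$pt_config
      cfg$seed <- .stage_seed(config$seed, 10L + gi)
      fit <- fit_pt_model(pdat, cfg)
      post <- pt_group_posterior(fit)
      acc_in <- posterior_predictive_accuracy(fit, method = "in_sample")
      acc_loo <- posterior_predictive_accuracy(fit, method = "loo")
      group_pars <- names(post)
      draws_long <- do.call(rbind, lapply(group_pars, function(p) {
        data.frame(parameter = p, draw = seq_along(post[[p]]),
                   value = post[[p]], stringsAsFactors = FALSE)
      }))
      utils::write.csv(draws_long,
                       note(file.path(out_dir, paste0("pt_draws_", g, ".csv"))),
                       row.names = FALSE)
      diag <- list(group = g, n_participants = length(ids),
                   n_draws = fit$n_draws,
                   max_rhat = max(fit$rhat),
                   rhat_below_1_01 = all(fit$rhat < 1.01),
                   divergences = sum(fit$diagnostics$divergences),
                   balanced_accuracy_in_sample = acc_in$balanced_accuracy,
                   balanced_accuracy_loo = acc_loo$balanced_accuracy,
                   config = unclass(cfg))
      jsonlite::write_json(diag,
                           note(file.path(out_dir,
                                          paste0("pt_diagnostics_", g, ".json"))),
                           auto_unbox = TRUE, digits = NA)
      fits[[g]] <- list(fit = fit, posterior = post, diagnostics = diag)
    }
    bundle$pt_fits <- fits
  }

  # -- fit-assoc -------------------------------------------------------------
  if ("fit-assoc" %in% stages) {
    if (is.null(bundle$trial_summaries)) stop("stage fit-assoc: run preprocess first")
    cohort <- bundle$cohort
    log_stage("fit-assoc: acceptance ~ attitude + vaccine (logistic)")
    adat <- merge(cohort$decisions[, c("participant_id", "trial_index",
                                       "vaccine", "decision")],
                  cohort$participants[, c("participant_id", "attitude")],
                  by = "participant_id")
    adat$accept <- as.integer(adat$decision == "accept")
    cfgA <- config$assoc_config
    cfgA$seed <- .stage_seed(config$seed, 20L)
    fitA <- fit_hierarchical_logistic(
      adat, regression_spec("accept", "bernoulli",
                            predictors = c("attitude", "vaccine")), cfgA)
    log_stage("fit-assoc: ignorance level ~ attitude (ordered logit)")
    odat <- merge(bundle$trial_summaries$trials,
                  cohort$participants[, c("participant_id", "attitude")],
                  by = "participant_id")
    odat$ignorance <- factor(odat$ignorance_level,
                             levels = c("none", "partial", "full"),
                             ordered = TRUE)
    cfgO <- config$assoc_config
    cfgO$seed <- .stage_seed(config$seed, 21L)
    fitO <- fit_ordered_logit(
      odat, regression_spec("ignorance", "ordered", predictors = "attitude"),
      cfgO)
    effects <- list(
      acceptance = list(
        odds_ratios = coefficient_odds_ratios(fitA),
        predicted_by_attitude = predicted_levels(fitA, "attitude"),
        predicted_by_vaccine = predicted_levels(fitA, "vaccine"),
        max_rhat = max(fitA$rhat)
      ),
      ignorance = list(
        predicted_by_attitude = predicted_levels(fitO, "attitude"),
        max_rhat = max(fitO$rhat)
      )
    )
    jsonlite::write_json(effects, note(file.path(out_dir, "effects.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    bundle$assoc <- list(acceptance = fitA, ignorance = fitO,
                         effects = effects)
  }

  # -- report ----------------------------------------------------------------
  if ("report" %in% stages) {
    log_stage("report: writing summary")
    report <- write_report(bundle, out_dir)
    for (f in report$files) note(f)
    bundle$report <- report
  }

  # manifest
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(.config_echo(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = as.list(tools::md5sum(unique(written)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

# serializable echo of a pipeline config (drops environments/closures)
.config_echo <- function(config) {
  list(seed = config$seed,
       fit_groups = config$fit_groups,
       pt_max_participants = config$pt_max_participants,
       cohort = if (is.character(config$cohort)) config$cohort else "synthetic",
       pt_config = unclass(config$pt_config),
       assoc_config = unclass(config$assoc_config))
}

#' Write the human-readable report
#'
#' Tables of ignorance/neglect descriptives, group-level posterior
#' summaries of the choice-model parameters (the loss-aversion multiplier
#' is computed per draw, then summarized), and regression effect
#' summaries, as markdown plus JSON.
#'
#' @param bundle A pipeline bundle from [run_pipeline()].
#' @param out_dir Output directory.
#' @return List with `json` (report content) and `files` (paths written).
#' @export
write_report <- function(bundle, out_dir) {
  missing_parts <- setdiff(c("cohort", "descriptives"), names(bundle))
  if (length(missing_parts) > 0) {
    stop("incomplete bundle; missing: ", paste(missing_parts, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rep <- list(descriptives = bundle$descriptives)

  # refusal patterns per group
  dec <- merge(bundle$cohort$decisions,
               bundle$cohort$participants[, c("participant_id", "attitude")],
               by = "participant_id")
  by_part <- stats::aggregate(list(n_accept = dec$decision == "accept"),
                              by = list(participant_id = dec$participant_id,
                                        attitude = dec$attitude), FUN = sum)
  rep$decisions <- do.call(rbind, lapply(split(by_part, by_part$attitude),
    function(g) data.frame(attitude = g$attitude[1],
                           n_participants = nrow(g),
                           prop_refused_all = mean(g$n_accept == 0),
                           mean_accepted = mean(g$n_accept))))
  rownames(rep$decisions) <- NULL

  if (!is.null(bundle$pt_fits)) {
    rep$pt_parameters <- lapply(bundle$pt_fits, function(gf) {
      post <- gf$posterior
      summ <- function(v) {
        h <- hdi(v)
        c(median = stats::median(v), hdi_lower = h[1], hdi_upper = h[2])
      }
      pars <- c("beta", "Lambda", "gamma", "alpha", "phi")
      tab <- t(vapply(pars, function(p) summ(post[[p]]), numeric(3)))
      list(table = data.frame(parameter = pars, tab),
           diagnostics = gf$diagnostics)
    })
  }
  if (!is.null(bundle$assoc)) rep$association = bundle$assoc$effects

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  md <- c("# Vaccination decision analysis report", "",
          "## Ignorance and neglect descriptives", "",
          .md_table(bundle$descriptives), "",
          "## Decision patterns", "", .md_table(rep$decisions))
  if (!is.null(rep$pt_parameters)) {
    for (g in names(rep$pt_parameters)) {
      md <- c(md, "", paste0("## Choice-model posterior: ", g, " group"), "",
              .md_table(rep$pt_parameters[[g]]$table),
              "",
              sprintf("max R-hat %.4f; balanced accuracy in-sample %.3f, loo %.3f",
                      rep$pt_parameters[[g]]$diagnostics$max_rhat,
                      rep$pt_parameters[[g]]$diagnostics$balanced_accuracy_in_sample,
                      rep$pt_parameters[[g]]$diagnostics$balanced_accuracy_loo))
    }
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  list(json = rep, files = c(json_path, md_path))
}

# minimal markdown table renderer
.md_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
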