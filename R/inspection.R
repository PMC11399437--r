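# Preprocessing of Mouselab hover-event logs into trial-level
# deliberate-ignorance levels and probability-neglect indices.
#
# Hover events shorter than 200 ms are treated as incidental and removed;
# all downstream indices are based on inspection counts, not durations.
# A trial shows full deliberate ignorance when no evidence box was
# inspected, none when every box was inspected at least once, and partial
# otherwise. Probability neglect (the strict, preregistered definition) is
# inspecting an outcome but never its probability; outcomes without a
# displayed probability are excluded from the neglect indices.

.MIN_INSPECTION_MS <- 200

#' Remove incidental hover events
#'
#' Retains exactly the events with `duration_ms >= 200`; sub-200 ms hovers
#' are treated as incidental cursor passes.
#'
#' @param events Data frame with columns `participant_id`, `trial_index`,
#'   `vaccine`, `box_id`, `onset_ms`, `duration_ms`.
#' @return A `cleaned_log`: the retained events plus per
#'   participant x trial x box inspection counts (`counts` attribute).
#' @export
filter_incidental <- function(events) {
  req <- c("participant_id", "trial_index", "vaccine", "box_id",
           "onset_ms", "duration_ms")
  stopifnot(all(req %in% names(events)))
  if (nrow(events) > 0 && any(events$duration_ms < 0)) {
    stop("negative event duration")
  }
  kept <- events[events$duration_ms >= .MIN_INSPECTION_MS, , drop = FALSE]
  rownames(kept) <- NULL
  counts <- if (nrow(kept) > 0) {
    stats::aggregate(list(n_inspections = kept$box_id),
                     by = list(participant_id = kept$participant_id,
                               trial_index = kept$trial_index,
                               vaccine = kept$vaccine,
                               box_id = kept$box_id),
                     FUN = length)
  } else {
    data.frame(participant_id = character(0), trial_index = integer(0),
               vaccine = character(0), box_id = character(0),
               n_inspections = integer(0), stringsAsFactors = FALSE)
  }
  structure(kept, class = c("cleaned_log", "data.frame"), counts = counts)
}

#' Deliberate-ignorance level of one trial
#'
#' @param counts Named integer vector of inspection counts per box id
#'   (boxes absent from the vector count as 0).
#' @param layout Box layout from [evidence_layout()] for the trial's vaccine.
#' @return `"full"`, `"partial"`, or `"none"`.
#' @export
classify_ignorance_level <- function(counts, layout) {
  stopifnot(is.data.frame(layout), "box_id" %in% names(layout))
  extra <- setdiff(names(counts), layout$box_id)
  if (length(extra) > 0) {
    stop("counts reference box(es) outside the layout: ",
         paste(extra, collapse = ", "))
  }
  full_counts <- stats::setNames(rep(0L, nrow(layout)), layout$box_id)
  full_counts[names(counts)] <- counts
  if (all(full_counts == 0L)) return("full")
  if (all(full_counts >= 1L)) return("none")
  "partial"
}

#' Probability-neglect flags of one trial
#'
#' For each category (side effects overall, mild, severe, extreme,
#' benefits) the flag is `TRUE` iff some outcome of that category has its
#' outcome box inspected but its paired probability box never inspected.
#' Outcomes without a probability box are excluded; inspecting a probability
#' without its outcome is not neglect (the definition is one-directional).
#'
#' @inheritParams classify_ignorance_level
#' @return Named logical vector: `side_effects`, `mild`, `severe`,
#'   `extreme`, `benefits`.
#' @export
detect_probability_neglect <- function(counts, layout) {
  full_counts <- stats::setNames(rep(0L, nrow(layout)), layout$box_id)
  ok <- intersect(names(counts), layout$box_id)
  full_counts[ok] <- counts[ok]
  out_boxes <- layout[layout$role == "outcome", , drop = FALSE]
  flags <- c(side_effects = FALSE, mild = FALSE, severe = FALSE,
             extreme = FALSE, benefits = FALSE)
  for (i in seq_len(nrow(out_boxes))) {
    prob_id <- sub("_outcome$", "_prob", out_boxes$box_id[i])
    if (!prob_id %in% layout$box_id) next  # no probability displayed
    neglected <- full_counts[out_boxes$box_id[i]] > 0L &&
      full_counts[prob_id] == 0L
    if (!neglected) next
    if (out_boxes$kind[i] == "benefit") {
      flags["benefits"] <- TRUE
    } else {
      flags["side_effects"] <- TRUE
      flags[out_boxes$severity[i]] <- TRUE
    }
  }
  flags
}

#' Per-trial ignorance summaries and per-outcome inspection flags
#'
#' Applies the duration filter, then classifies every participant x trial
#' into an ignorance level and computes all neglect flags, together with
#' the per-outcome inspected/probability-inspected flags the choice model
#' consumes.
#'
#' @param events Raw hover-event data frame (see [filter_incidental()]), or
#'   a `cleaned_log`.
#' @param decisions Data frame with `participant_id`, `trial_index`,
#'   `vaccine` defining the full set of trials (so that trials without any
#'   retained event are classified as full ignorance).
#' @param evidence An `evidence_table`.
#' @return List with `trials` (one row per trial: `ignorance_level`,
#'   `neglect_side_effects`, `neglect_mild`, `neglect_severe`,
#'   `neglect_extreme`, `neglect_benefits`) and `outcomes` (one row per
#'   trial x outcome: `outcome_inspected`, `probability_inspected`).
#' @export
summarize_trials <- function(events, decisions, evidence) {
  stopifnot(inherits(evidence, "evidence_table"))
  log_ <- if (inherits(events, "cleaned_log")) events else filter_incidental(events)
  counts <- attr(log_, "counts")
  layouts <- lapply(attr(evidence, "vaccines"),
                    function(v) evidence_layout(evidence, v))
  names(layouts) <- attr(evidence, "vaccines")
  specs <- lapply(attr(evidence, "vaccines"),
                  function(v) vaccine_spec(evidence, v))
  names(specs) <- attr(evidence, "vaccines")

  ckey <- paste(counts$participant_id, counts$trial_index, counts$box_id)
  cmap <- stats::setNames(counts$n_inspections, ckey)

  n_tr <- nrow(decisions)
  lev <- character(n_tr)
  neglect <- matrix(FALSE, n_tr, 5,
                    dimnames = list(NULL, c("side_effects", "mild", "severe",
                                            "extreme", "benefits")))
  out_rows <- vector("list", n_tr)
  for (t in seq_len(n_tr)) {
    v <- decisions$vaccine[t]
    layout <- layouts[[v]]
    keys <- paste(decisions$participant_id[t], decisions$trial_index[t],
                  layout$box_id)
    cnt <- cmap[keys]
    cnt[is.na(cnt)] <- 0L
    names(cnt) <- layout$box_id
    lev[t] <- classify_ignorance_level(cnt, layout)
    neglect[t, ] <- detect_probability_neglect(cnt, layout)
    spec <- specs[[v]]
    kind_tag <- ifelse(spec$outcome_kind == "side_effect", "se", "b")
    knum <- ifelse(spec$outcome_kind == "side_effect", seq_len(6L), seq_len(6L) - 3L)
    out_id <- paste0(kind_tag, knum, "_outcome")
    prob_id <- paste0(kind_tag, knum, "_prob")
    has_prob <- prob_id %in% layout$box_id
    pi_ <- rep(FALSE, 6L)
    pi_[has_prob] <- cnt[prob_id[has_prob]] > 0L
    out_rows[[t]] <- data.frame(
      participant_id = decisions$participant_id[t],
      trial_index = decisions$trial_index[t],
      vaccine = v,
      outcome_index = seq_len(6L),
      outcome_inspected = unname(cnt[out_id] > 0L),
      probability_inspected = pi_,
      stringsAsFactors = FALSE
    )
  }
  trials <- data.frame(participant_id = decisions$participant_id,
                       trial_index = decisions$trial_index,
                       vaccine = decisions$vaccine,
                       ignorance_level = lev,
                       stringsAsFactors = FALSE)
  trials$neglect_side_effects <- neglect[, "side_effects"]
  trials$neglect_mild <- neglect[, "mild"]
  trials$neglect_severe <- neglect[, "severe"]
  trials$neglect_extreme <- neglect[, "extreme"]
  trials$neglect_benefits <- neglect[, "benefits"]
  list(trials = trials, outcomes = do.call(rbind, out_rows))
}

#' Group-level ignorance and neglect descriptives
#'
#' @param trial_summaries The `trials` data frame from [summarize_trials()].
#' @param groups Data frame mapping `participant_id` to `attitude`.
#' @return Data frame with one row per group: proportions of trials at each
#'   ignorance level, proportions of trials with each neglect flag, and the
#'   proportion of participants with at least one neglect trial (side
#'   effects and benefits).
#' @export
summarize_ignorance <- function(trial_summaries, groups) {
  stopifnot(all(c("participant_id", "attitude") %in% names(groups)))
  att <- groups$attitude[match(trial_summaries$participant_id,
                               groups$participant_id)]
  if (any(is.na(att))) stop("trial(s) with unknown participant group label")
  res <- lapply(split(seq_len(nrow(trial_summaries)), att), function(idx) {
    tr <- trial_summaries[idx, , drop = FALSE]
    by_part_se <- tapply(tr$neglect_side_effects, tr$participant_id, any)
    by_part_b <- tapply(tr$neglect_benefits, tr$participant_id, any)
    data.frame(
      n_trials = nrow(tr),
      prop_full = mean(tr$ignorance_level == "full"),
      prop_partial = mean(tr$ignorance_level == "partial"),
      prop_none = mean(tr$ignorance_level == "none"),
      prop_neglect_side_effects = mean(tr$neglect_side_effects),
      prop_neglect_mild = mean(tr$neglect_mild),
      prop_neglect_severe = mean(tr$neglect_severe),
      prop_neglect_extreme = mean(tr$neglect_extreme),
      prop_neglect_benefits = mean(tr$neglect_benefits),
      prop_participants_neglect_se = mean(by_part_se),
      prop_participants_neglect_benefits = mean(by_part_b)
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(attitude = rownames(out), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
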