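# Vaccine-evidence table: typed access to the 8-vaccine evidence grid
# (3 side effects + 3 benefits per vaccine, probabilities shown per million
# or as effectiveness percentages), severity classes, and the per-trial
# Mouselab box layout.

# canonical severity classes for the 15 side-effect labels
.severity_classes <- c("mild", "severe", "extreme")

.default_severity_map <- c(
  "fever"                        = "mild",
  "tiredness"                    = "mild",
  "headache"                     = "mild",
  "muscle pain"                  = "mild",
  "severe general discomfort"    = "severe",
  "severe drowsiness"            = "severe",
  "severe tiredness"             = "severe",
  "severe headache"              = "severe",
  "severe muscle pain"           = "severe",
  "blood clots"                  = "extreme",
  "immune system attacks nerves" = "extreme",
  "immune system attacks blood"  = "extreme",
  "facial paralysis"             = "extreme",
  "heart muscle inflammation"    = "extreme",
  "heart membrane inflammation"  = "extreme"
)

#' Canonical normalization of an outcome label
#'
#' Lowercases, collapses runs of whitespace, and strips parenthetical
#' qualifiers (e.g. a trailing clinical synonym) so that severity lookup is
#' robust to cosmetic variation in label spelling.
#'
#' @param label Character vector of outcome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_label <- function(label) {
  x <- tolower(trimws(label))
  x <- gsub("\\s*\\([^)]*\\)", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Severity class of a side-effect label
#'
#' Maps each of the 15 known side-effect labels to its severity class:
#' 4 mild (fever, tiredness, headache, muscle pain), 5 severe (the
#' "severe ..." labels), and 6 extreme (blood clots, immune system attacking
#' nerves or blood, facial paralysis, heart muscle/membrane inflammation).
#'
#' @param label Character vector of side-effect labels (normalized
#'   internally, see [normalize_label()]).
#' @param severity_map Named character vector mapping normalized labels to
#'   severity classes; defaults to the packaged 15-label map.
#' @return Character vector with values in `c("mild","severe","extreme")`.
#' @export
severity_of <- function(label, severity_map = .default_severity_map) {
  key <- normalize_label(label)
  unknown <- setdiff(unique(key), names(severity_map))
  if (length(unknown) > 0L) {
    stop("unknown side-effect label(s): ", paste(unknown, collapse = ", "),
         "; known labels: ", paste(names(severity_map), collapse = ", "))
  }
  unname(severity_map[key])
}

#' Convert a displayed probability to a fraction
#'
#' Side-effect frequencies are displayed as cases per 1,000,000 people and
#' vaccine effectiveness as percentages; both are converted to fractions in
#' \[0, 1\] for modelling.
#'
#' @param raw Numeric vector of displayed values (NA allowed, passed
#'   through).
#' @param format `"per_million"` or `"percent"` (recycled).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
convert_probability <- function(raw, format) {
  format <- match.arg(format, c("per_million", "percent"), several.ok = TRUE)
  if (length(format) == 1L) format <- rep(format, length(raw))
  stopifnot(length(format) == length(raw))
  ok <- is.na(raw) |
    (raw >= 0 & ((format == "per_million" & raw <= 1e6) |
                   (format == "percent" & raw <= 100)))
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("probability value out of range: ", raw[bad], " (", format[bad], ")")
  }
  ifelse(format == "per_million", raw / 1e6, raw / 100)
}

#' Load the vaccine-evidence table
#'
#' Reads the evidence CSV (by default the packaged transcription of the
#' eight-vaccine evidence grid), validates its structure, and converts all
#' displayed probabilities to fractions.
#'
#' The validated invariants are: exactly 8 vaccines; 3 side effects and 3
#' benefits per vaccine; 15 distinct side-effect labels overall, partitioned
#' 4 mild / 5 severe / 6 extreme; probabilities in range for their display
#' format; missing probabilities only for benefits (three vaccines do not
#' display a probability for protection against death).
#'
#' @param source Path to an evidence CSV with columns `vaccine`,
#'   `country_category`, `technology_category`, `outcome_kind`,
#'   `outcome_label`, `severity`, `probability_raw`, `probability_format`.
#'   Defaults to the packaged table.
#' @return An object of class `evidence_table`: a data frame (one row per
#'   vaccine x outcome) with an additional `probability` column in
#'   fractions, plus attributes `severity_map` and `vaccines`.
#' @export
load_evidence_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "vaccine_evidence.csv", package = "vaxcog")
  }
  if (!file.exists(source)) stop("evidence file not found: ", source)
  ev <- utils::read.csv(source, stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("vaccine", "country_category", "technology_category",
                "outcome_kind", "outcome_label", "severity",
                "probability_raw", "probability_format")
  missing_cols <- setdiff(required, names(ev))
  if (length(missing_cols) > 0L) {
    stop("evidence table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_evidence(ev)
  ev$probability <- convert_probability(ev$probability_raw, ev$probability_format)
  structure(ev,
            class = c("evidence_table", "data.frame"),
            severity_map = .default_severity_map,
            vaccines = unique(ev$vaccine))
}

# structural validation of the raw evidence data frame (fractions not yet
# computed); stops with the offending row/vaccine on violation
validate_evidence <- function(ev) {
  bad_kind <- !ev$outcome_kind %in% c("side_effect", "benefit")
  if (any(bad_kind)) {
    stop("row ", which(bad_kind)[1L], ": unknown outcome_kind '",
         ev$outcome_kind[which(bad_kind)[1L]], "'")
  }
  vac <- unique(ev$vaccine)
  if (length(vac) != 8L) {
    stop("expected exactly 8 vaccines, found ", length(vac))
  }
  for (v in vac) {
    rows <- ev[ev$vaccine == v, ]
    n_se <- sum(rows$outcome_kind == "side_effect")
    n_b <- sum(rows$outcome_kind == "benefit")
    if (n_se != 3L || n_b != 3L) {
      stop("vaccine '", v, "': expected 3 side effects and 3 benefits, found ",
           n_se, " and ", n_b)
    }
  }
  se <- ev[ev$outcome_kind == "side_effect", ]
  b <- ev[ev$outcome_kind == "benefit", ]
  if (any(is.na(se$probability_raw))) {
    stop("side-effect probability missing for vaccine '",
         se$vaccine[which(is.na(se$probability_raw))[1L]], "'")
  }
  # severity: benefits not_applicable, side effects consistent with the map
  if (any(b$severity != "not_applicable")) {
    stop("benefit rows must have severity 'not_applicable' (vaccine '",
         b$vaccine[which(b$severity != "not_applicable")[1L]], "')")
  }
  labs <- unique(normalize_label(se$outcome_label))
  if (length(labs) != 15L) {
    stop("expected 15 distinct side-effect labels, found ", length(labs))
  }
  declared <- severity_of(se$outcome_label)
  if (any(declared != se$severity)) {
    i <- which(declared != se$severity)[1L]
    stop("row for '", se$outcome_label[i], "' declares severity '",
         se$severity[i], "' but the canonical class is '", declared[i], "'")
  }
  counts <- table(severity_of(labs))
  if (!identical(as.integer(counts[.severity_classes]), c(4L, 5L, 6L))) {
    stop("side-effect labels must partition 4 mild / 5 severe / 6 extreme; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  invisible(TRUE)
}

#' Write an evidence table back to CSV
#'
#' Inverse of [load_evidence_table()]; writing and reloading yields an
#' identical structure (round-trip property).
#'
#' @param ev An `evidence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(ev, path) {
  stopifnot(inherits(ev, "evidence_table"))
  cols <- c("vaccine", "country_category", "technology_category",
            "outcome_kind", "outcome_label", "severity",
            "probability_raw", "probability_format")
  utils::write.csv(as.data.frame(ev)[, cols], path, row.names = FALSE,
                   quote = TRUE, na = "NA")
  invisible(path)
}

#' Rows of the evidence table for one vaccine
#'
#' @param ev An `evidence_table`.
#' @param vaccine Vaccine brand name.
#' @return Data frame of the vaccine's 6 outcomes (side effects first).
#' @export
vaccine_spec <- function(ev, vaccine) {
  stopifnot(inherits(ev, "evidence_table"))
  rows <- ev[ev$vaccine == vaccine, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown vaccine '", vaccine, "'; known: ",
         paste(attr(ev, "vaccines"), collapse = ", "))
  }
  rows <- rows[order(rows$outcome_kind, decreasing = TRUE), ]  # side_effect first
  as.data.frame(rows)
}

#' Mouselab box layout for one vaccine's trial
#'
#' Derives the ordered set of hideable evidence boxes for a trial: one
#' outcome box per side effect and per benefit, plus one probability box for
#' each outcome whose probability is displayed. Brand, country, and
#' technology are always visible and are not boxes. Benefits without a
#' displayed probability (the three death-protection cells left blank)
#' contribute an outcome box but no probability box.
#'
#' @param ev An `evidence_table`.
#' @param vaccine Vaccine brand name.
#' @return Data frame with columns `box_id`, `outcome_index` (1-6, side
#'   effects first), `role` (`"outcome"`/`"probability"`), `kind`,
#'   `label`, `severity`, `probability` (NA for outcome boxes).
#' @export
evidence_layout <- function(ev, vaccine) {
  rows <- vaccine_spec(ev, vaccine)
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    kind_tag <- if (rows$outcome_kind[i] == "side_effect") "se" else "b"
    k <- if (kind_tag == "se") i else i - 3L
    base <- paste0(kind_tag, k)
    boxes <- data.frame(
      box_id = paste0(base, "_outcome"),
      outcome_index = i,
      role = "outcome",
      kind = rows$outcome_kind[i],
      label = rows$outcome_label[i],
      severity = rows$severity[i],
      probability = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.na(rows$probability[i])) {
      boxes <- rbind(boxes, data.frame(
        box_id = paste0(base, "_prob"),
        outcome_index = i,
        role = "probability",
        kind = rows$outcome_kind[i],
        label = rows$outcome_label[i],
        severity = rows$severity[i],
        probability = rows$probability[i],
        stringsAsFactors = FALSE
      ))
    }
    out[[i]] <- boxes
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
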