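# Derivation of the 13 cognitive summary scores from raw task measures.
#
# The score schedule is configuration, not code: each entry names an output
# score, one operator from a small fixed set, and the raw-measure keys it
# consumes.  The default schedule implements the battery summary used
# throughout the package: span average, fluency contrast, three accuracies,
# two reversed reaction-time contrasts, two efficiency scores, three semantic
# contrasts of condition-wise efficiencies, and one generation-task score.

#' Efficiency score (reversed rate-corrected speed)
#'
#' Reaction time divided by accuracy, sign-reversed so that higher values mean
#' better performance: `-(rt / acc)`.
#'
#' @param rt Reaction time in seconds (> 0).
#' @param acc Accuracy as a proportion (> 0).
#' @return `-(rt / acc)`; vectorized.
#' @examples
#' efficiency_score(1.2, 0.8) # -1.5
#' @export
efficiency_score <- function(rt, acc) {
  if (any(!is.finite(rt)) || any(!is.finite(acc))) {
    stop("`rt` and `acc` must be finite")
  }
  if (any(acc <= 0)) stop("efficiency is undefined for accuracy <= 0")
  if (any(rt <= 0)) stop("reaction times must be positive")
  -(rt / acc)
}

#' Condition contrast
#'
#' Plain difference `a - b`, used for fluency (category - letter), strength
#' (strong - weak), modality (picture - word) and specificity
#' (specific - general) contrasts.
#'
#' @param a,b Finite numeric vectors.
#' @return `a - b`.
#' @export
contrast_score <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("inputs must be finite")
  a - b
}

#' Default 13-score schedule
#'
#' Returns the ordered schedule mapping raw measures to the 13 cognitive
#' scores. Entries with `keep = FALSE` are intermediates (condition-wise
#' efficiency scores feeding the semantic contrasts). Operators:
#' \describe{
#'   \item{mean}{row mean of the named measures}
#'   \item{contrast}{first minus second input}
#'   \item{efficiency}{[efficiency_score()] of a reaction-time and an
#'     accuracy measure}
#'   \item{accuracy}{identity pass-through of a single measure}
#'   \item{negate}{sign reversal (used for the switch and inhibition costs,
#'     where smaller raw costs mean better performance)}
#' }
#' Raw measures taken per condition use keys of the form
#' `"reaction_time.<condition>"` / `"accuracy.<condition>"`.
#'
#' The composition of the battery summary into exactly 13 scores is one
#' consistent reading of the task set; the schedule is data, so alternative
#' readings can be supplied to [assemble_scores()].
#'
#' @return A list of schedule entries.
#' @export
default_score_schedule <- function() {
  eff <- function(cond) {
    list(name = paste0(".eff_", cond), op = "efficiency",
         inputs = c(paste0("reaction_time.", cond), paste0("accuracy.", cond)),
         keep = FALSE)
  }
  list(
    list(name = "digit_span", op = "mean",
         inputs = c("digit_span_forward", "digit_span_backward")),
    list(name = "verbal_fluency_contrast", op = "contrast",
         inputs = c("fluency_category", "fluency_letter")),
    list(name = "picture_naming", op = "accuracy", inputs = "naming_accuracy"),
    list(name = "four_mountains", op = "accuracy",
         inputs = "four_mountains_accuracy"),
    list(name = "rapm", op = "accuracy", inputs = "rapm_accuracy"),
    list(name = "flexibility", op = "negate", inputs = "switch_cost"),
    list(name = "inhibition", op = "negate", inputs = "inhibition_cost"),
    list(name = "feature_matching_eff", op = "efficiency",
         inputs = c("reaction_time.feature_matching",
                    "accuracy.feature_matching")),
    list(name = "paired_associate_eff", op = "efficiency",
         inputs = c("reaction_time.paired_associate",
                    "accuracy.paired_associate")),
    eff("strong"), eff("weak"), eff("picture"), eff("word"),
    eff("specific"), eff("general"),
    list(name = "strength_contrast", op = "contrast",
         inputs = c(".eff_strong", ".eff_weak")),
    list(name = "modality_contrast", op = "contrast",
         inputs = c(".eff_picture", ".eff_word")),
    list(name = "specificity_contrast", op = "contrast",
         inputs = c(".eff_specific", ".eff_general")),
    list(name = "unusual_uses", op = "accuracy", inputs = "unusual_uses")
  )
}

# measure key for a long-table row: "<measure>" or "<measure>.<condition>"
measure_key <- function(measure, condition) {
  ifelse(is.na(condition) | condition == "", measure,
         paste(measure, condition, sep = "."))
}

#' Assemble cognitive scores from a long raw-measure table
#'
#' Pivots a long table of raw task measures to subjects-by-measures, applies
#' the score schedule, and (by default) standardizes each score column to mean
#' 0 and sample standard deviation 1 across the cohort.
#'
#' @param raw Data frame with columns `subject`, `measure`, `condition`
#'   (`NA` or `""` for condition-free measures) and `value`.
#' @param schedule Score schedule, see [default_score_schedule()].
#' @param standardize Standardize score columns across subjects
#'   (default `TRUE`).
#' @return Numeric matrix, subjects in rows (in first-appearance order), one
#'   column per kept schedule entry (13 for the default schedule).
#' @export
assemble_scores <- function(raw, schedule = default_score_schedule(),
                            standardize = TRUE) {
  need <- c("subject", "measure", "value")
  if (!is.data.frame(raw) || !all(need %in% names(raw))) {
    stop("`raw` must be a data frame with columns subject, measure, ",
         "condition (optional), value")
  }
  condition <- if ("condition" %in% names(raw)) raw$condition else NA
  key <- measure_key(as.character(raw$measure), as.character(condition))
  subj <- factor(raw$subject, levels = unique(raw$subject))
  wide <- tapply(raw$value, list(subj, factor(key, levels = unique(key))),
                 mean)
  env <- new.env(parent = emptyenv())
  for (k in colnames(wide)) assign(k, wide[, k], envir = env)

  fetch <- function(keys, score) {
    vals <- lapply(keys, function(k) {
      if (!exists(k, envir = env, inherits = FALSE)) {
        stop("score '", score, "' needs measure '", k,
             "', which is missing from the raw table", call. = FALSE)
      }
      v <- get(k, envir = env, inherits = FALSE)
      if (anyNA(v)) {
        stop("score '", score, "': measure '", k,
             "' is missing for some subjects", call. = FALSE)
      }
      v
    })
    vals
  }

  out <- list()
  for (entry in schedule) {
    vals <- fetch(entry$inputs, entry$name)
    value <- switch(entry$op,
      mean = rowMeans(do.call(cbind, vals)),
      contrast = contrast_score(vals[[1]], vals[[2]]),
      efficiency = efficiency_score(vals[[1]], vals[[2]]),
      accuracy = vals[[1]],
      negate = -vals[[1]],
      stop("unknown schedule operator '", entry$op, "'")
    )
    assign(entry$name, value, envir = env)
    if (entry$keep %||% TRUE) out[[entry$name]] <- value
  }
  scores <- do.call(cbind, out)
  rownames(scores) <- rownames(wide)
  if (standardize) scores <- standardize_columns(scores)
  scores
}
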