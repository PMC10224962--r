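# Contextual valence: attribution from call type, MANOVA of PC scores on
# valence with call type as a control fixed factor, and the eight
# per-parameter linear models.

#' Assign contextual valence from call type
#'
#' Deterministic mapping from the production-context interpretation of each
#' call type: partner interactions (clucking) are positive; predator and
#' human-handling contexts (terror, handling) are negative; nest-defence
#' exchanges with other birds (low trill, short, short-trill) are likely
#' negative; single and classic calls occur in too many contexts and stay
#' unknown. Only positive/negative calls enter the inferential dataset.
#'
#' @param call_type Character vector of [call_types()] labels.
#' @param context Optional free-text production context (recorded, not used
#'   by the mapping).
#' @return Factor with levels `positive`, `negative`, `likely_negative`,
#'   `unknown`.
#' @export
assign_valence <- function(call_type, context = NULL) {
  map <- c(single = "unknown", clucking = "positive", classic = "unknown",
           terror = "negative", handling = "negative",
           low_trill = "likely_negative", short = "likely_negative",
           short_trill = "likely_negative")
  bad <- setdiff(unique(as.character(call_type)), names(map))
  if (length(bad)) stop("unknown call_type label(s): ",
                        paste(bad, collapse = ", "))
  factor(unname(map[as.character(call_type)]),
         levels = c("positive", "negative", "likely_negative", "unknown"))
}

#' Restrict a feature table to calls of clear valence
#'
#' Adds a `valence` column if missing (via [assign_valence()]) and keeps
#' only positive/negative calls; with the balanced 30-calls-per-type design
#' this keeps clucking + terror + handling = 90 calls.
#'
#' @param features Feature table with `call_type`.
#' @return The positive/negative rows, `valence` as a two-level factor with
#'   `negative` as the reference level.
#' @export
valence_subset <- function(features) {
  if (!"valence" %in% names(features))
    features$valence <- assign_valence(features$call_type)
  keep <- features$valence %in% c("positive", "negative")
  out <- features[keep, , drop = FALSE]
  if (!nrow(out)) stop("no calls of positive or negative valence")
  out$valence <- stats::relevel(factor(as.character(out$valence),
                                       levels = c("negative", "positive")),
                                ref = "negative")
  if (nlevels(droplevels(out$valence)) < 2)
    warning("only one valence level present")
  rownames(out) <- NULL
  out
}

#' MANOVA of PC scores on valence, controlling for call type
#'
#' Multivariate linear model of the first PCs on valence plus call type,
#' sequential (type-I) sums of squares with valence entered first, Pillai's
#' trace with its F approximation. Call type is nested within valence by
#' design (each type carries exactly one valence), so the call-type factor
#' is partially aliased with valence; the aliasing is reported rather than
#' hidden.
#'
#' @param pc_scores Numeric matrix of PC scores (rows = calls; the reference
#'   analysis uses the first five components).
#' @param valence Two-level factor (`negative` reference).
#' @param call_type Factor of call types, used as a control fixed factor.
#' @param test Multivariate statistic (default `"Pillai"`).
#' @return List: `statistic` (Pillai's trace for valence), `F`, `df`,
#'   `p_value`, `aliased` (whether call type lost columns to aliasing),
#'   `table` (the full summary table).
#' @export
manova_on_pcs <- function(pc_scores, valence, call_type, test = "Pillai") {
  pc_scores <- as.matrix(pc_scores)
  stopifnot(nrow(pc_scores) == length(valence),
            length(valence) == length(call_type))
  valence <- droplevels(factor(valence))
  call_type <- droplevels(factor(call_type))
  if (nlevels(valence) < 2) stop("need >= 2 valence levels")
  if (any(apply(pc_scores, 2, stats::sd) == 0))
    stop("degenerate responses: constant PC score column")
  dat <- data.frame(valence = valence, call_type = call_type)
  fit <- stats::manova(pc_scores ~ valence + call_type, data = dat)
  sm <- summary(fit, test = test)
  tab <- sm$stats
  row <- grep("^valence", rownames(tab))[1]
  aliased <- any(is.na(stats::coef(fit)))
  list(statistic = unname(tab[row, test]),
       F = unname(tab[row, "approx F"]),
       df = unname(tab[row, c("num Df", "den Df")]),
       p_value = unname(tab[row, "Pr(>F)"]),
       aliased = aliased, table = tab)
}

#' The eight valence linear models
#'
#' For each selected acoustic parameter, ordinary least squares of the raw
#' parameter on valence (negative = reference, so the intercept is the
#' negative-valence mean and the effect the positive-minus-negative
#' difference), with Wald t-based 95% confidence intervals, R-squared and
#' adjusted R-squared.
#'
#' @param features Feature table already restricted by [valence_subset()]
#'   (it is applied automatically if a `valence` column is absent or still
#'   carries other levels).
#' @param parameters Parameters to model; default the eight selected
#'   frequency and duration variables.
#' @param conf_level Confidence level for the intervals.
#' @return `auk_valence_models` data frame, one row per parameter:
#'   intercept/effect estimates, CI bounds, effect p-value, `r2`, `r2_adj`,
#'   `n_obs`.
#' @export
fit_valence_models <- function(features,
                               parameters = c("f0_max", "f0_mean", "f0_range",
                                              "q50", "f0_abs_slope", "f0_var",
                                              "f0_end", "duration"),
                               conf_level = 0.95) {
  if (!"valence" %in% names(features) ||
      !all(features$valence %in% c("positive", "negative")))
    features <- valence_subset(features)
  if (nlevels(droplevels(factor(features$valence))) < 2)
    stop("both valence levels are required")
  missing_p <- setdiff(parameters, names(features))
  if (length(missing_p)) stop("parameters absent from the table: ",
                              paste(missing_p, collapse = ", "))
  rows <- lapply(parameters, function(p) {
    d <- data.frame(y = features[[p]], valence = features$valence)
    fit <- stats::lm(y ~ valence, data = d)
    sm <- summary(fit)
    if (sm$sigma == 0)
      warning("zero residual variance for ", p, ": CIs undefined")
    ci <- suppressWarnings(stats::confint(fit, level = conf_level))
    co <- stats::coef(fit)
    data.frame(parameter = p,
               intercept_estimate = unname(co[1]),
               intercept_lo = ci[1, 1], intercept_hi = ci[1, 2],
               effect_estimate = unname(co[2]),
               effect_lo = ci[2, 1], effect_hi = ci[2, 2],
               effect_p = sm$coefficients[2, 4],
               r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
               n_obs = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("auk_valence_models", "data.frame")
  out
}
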