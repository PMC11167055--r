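# Association between per-domain skill scores and binary 3-month continence
# recovery: univariable logistic odds ratios with Wald intervals, a
# multivariable model adjusting for age, BMI, PSA and prostate volume, and
# the ROC/AUC of its predicted values. "Rate ratio" in the output headers is
# the exponentiated logistic coefficient (an odds ratio); the historical
# table-header wording is kept.

waldRow <- function(fit, term, label) {
  b <- stats::coef(fit)[term]
  se <- sqrt(diag(stats::vcov(fit)))[term]
  z <- b / se
  data.frame(domain = label, rate_ratio = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             separation = !fit$converged ||
               any(fit$fitted.values > 1 - 1e-8) &&
               any(fit$fitted.values < 1e-8),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariable logistic association of one skill score with the outcome
#'
#' Maximum-likelihood logistic regression of the binary outcome on a single
#' score; the effect is reported as the exponentiated coefficient with a
#' Wald 95 percent interval and two-sided Wald p-value. Complete or
#' quasi-complete separation is flagged in the \code{separation} column
#' rather than failing silently.
#'
#' @param scores numeric skill scores (one domain).
#' @param outcome binary outcome vector; both classes required, n >= 10.
#' @param label domain code used in the output row.
#' @return one-row data.frame: \code{domain}, \code{rate_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{separation}.
#' @export
fitUnivariable <- function(scores, outcome, label = "score") {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class", call. = FALSE)
  if (length(outcome) < 10L)
    stop("need at least 10 cases", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(outcome ~ scores, family = stats::binomial()))
  waldRow(fit, "scores", label)
}

#' Multivariable logistic model: six skill domains plus patient covariates
#'
#' Joint logistic fit of the outcome on all six domain scores and the four
#' patient covariates (age, BMI, PSA, prostate volume) with an intercept.
#'
#' @param skill n x 6 matrix of domain scores (columns
#'   \code{subSkillCodes()}).
#' @param covariates data.frame with columns \code{age}, \code{bmi},
#'   \code{psa}, \code{prostate_volume}.
#' @param outcome binary outcome vector.
#' @return list: \code{fit} (the glm), \code{rows} (per-term
#'   \code{\link{fitUnivariable}}-style data.frame for the six skill terms),
#'   \code{predicted} (fitted probabilities in [0, 1]).
#' @export
fitMultivariable <- function(skill, covariates, outcome) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class", call. = FALSE)
  skill <- as.matrix(skill)
  colnames(skill) <- subSkillCodes()
  X <- cbind(skill, as.matrix(covariates[, c("age", "bmi", "psa",
                                             "prostate_volume")]))
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1L), keep)
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(c("(Intercept)", colnames(X))[dropped], collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(outcome = outcome, X)
  fit <- suppressWarnings(
    stats::glm(outcome ~ ., family = stats::binomial(), data = d))
  rows <- do.call(rbind, lapply(subSkillCodes(),
                                function(k) waldRow(fit, k, k)))
  list(fit = fit, rows = rows, predicted = stats::fitted(fit))
}

#' ROC curve and AUC from predicted values
#'
#' Thresholds every observed prediction; the curve is monotone
#' nondecreasing in both coordinates and the AUC is the shared midrank
#' implementation (\code{\link{computeAUC}}).
#'
#' @param predicted numeric predictions (e.g. fitted probabilities).
#' @param outcome binary outcomes; both classes required.
#' @return list: \code{curve} (data.frame \code{fpr}, \code{tpr}),
#'   \code{auc}.
#' @export
rocFromPredictions <- function(predicted, outcome) {
  outcome <- as.integer(outcome)
  auc <- computeAUC(predicted, outcome)   # errors on one-class input
  ord <- order(predicted, decreasing = TRUE)
  tp <- cumsum(outcome[ord] == 1L)
  fp <- cumsum(outcome[ord] == 0L)
  curve <- data.frame(fpr = c(0, fp / sum(outcome == 0L)),
                      tpr = c(0, tp / sum(outcome == 1L)))
  list(curve = curve, auc = auc)
}

#' Attach per-surgeon skill scores to an outcome table
#'
#' Aggregates stitch-level predicted ideal-skill probabilities (or labels)
#' to one score per surgeon and domain, then joins them onto the outcome
#' table by surgeon id.
#'
#' @param outcome_table data.frame with a \code{surgeon_id} column.
#' @param cohort the \code{SutureCohort} the predictions refer to.
#' @param prob n x 6 stitch-level matrix (columns \code{subSkillCodes()}).
#' @param fun aggregator over a surgeon's stitches (default \code{mean};
#'   \code{median} available).
#' @return the outcome table with six added \code{score_<code>} columns.
#' @export
attachSkillScores <- function(outcome_table, cohort, prob, fun = mean) {
  sid <- stitchTable(cohort)$surgeon_id
  for (k in subSkillCodes()) {
    agg <- tapply(prob[, k], sid, fun)
    outcome_table[[paste0("score_", k)]] <-
      as.numeric(agg[as.character(outcome_table$surgeon_id)])
  }
  outcome_table
}
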