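# Multivariable Cox proportional-hazards association of clinical covariates
# and signature scores with overall survival under three time origins.

SURVIVAL_ORIGINS <- c("primary_dx", "any_met_dx", "brm_dx")

#' Build a survival table under a chosen time origin
#'
#' Time-to-event is measured from the primary diagnosis, from the first
#' diagnosis of any metastasis, or from the diagnosis of brain metastasis.
#' Patients lacking the origin date are excluded (their count is reported
#' via a message and an attribute).
#'
#' @param clinical Validated clinical data.frame (see [read_clinical()]).
#' @param origin One of `"primary_dx"`, `"any_met_dx"`, `"brm_dx"`.
#' @param scores Optional named numeric vector patient id -> signature
#'   score, entered as the `signature_score` covariate.
#' @return data.frame `patient_id`, `time` (days), `event`,
#'   `age_at_primary_dx`, `stage` (ordinal 1-4), `race`, and optionally
#'   `signature_score`; attribute `n_excluded` counts patients without the
#'   origin date.
#' @export
build_survival_table <- function(clinical, origin = SURVIVAL_ORIGINS,
                                 scores = NULL) {
  origin <- match.arg(origin)
  origin_col <- switch(origin, primary_dx = "t_primary_dx",
                       any_met_dx = "t_met_dx", brm_dx = "t_brm_dx")
  has_origin <- !is.na(clinical[[origin_col]]) & !is.na(clinical$t_event)
  n_excluded <- sum(!has_origin)
  if (n_excluded > 0) {
    message(n_excluded, " patient(s) excluded: no ", origin, " date")
  }
  kept <- clinical[has_origin, , drop = FALSE]
  time <- kept$t_event - kept[[origin_col]]
  if (any(time < 0)) {
    stop("negative follow-up time for patient ",
         kept$patient_id[which(time < 0)[1L]])
  }
  out <- data.frame(
    patient_id = kept$patient_id,
    time = as.numeric(time),
    event = as.logical(kept$event),
    age_at_primary_dx = kept$age_at_primary_dx,
    stage = match(kept$stage, c("I", "II", "III", "IV")),
    race = kept$race,
    stringsAsFactors = FALSE
  )
  if (!is.null(scores)) {
    out$signature_score <- unname(scores[out$patient_id])
  }
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded, origin = origin)
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron approximation for tied event times
#' (day-resolution data routinely produces ties). Stage enters
#' ordinal-linear by default (`stage_coding = "categorical"` switches to
#' factor contrasts); race enters one-hot with the largest group as the
#' reference. Per covariate the hazard ratio, Wald 95% confidence interval
#' and p-value are returned; non-convergence or separation is flagged on
#' the result, never silently dropped.
#'
#' @param rows Output of [build_survival_table()].
#' @param covariates Covariate column names to include (default: the
#'   clinical base model plus `signature_score` when present).
#' @param stage_coding `"ordinal"` (linear in stage 1-4) or
#'   `"categorical"`.
#' @return data.frame `covariate`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p`; attributes `converged` (logical) and `n_events`.
#' @export
fit_cox <- function(rows, covariates = NULL,
                    stage_coding = c("ordinal", "categorical")) {
  stage_coding <- match.arg(stage_coding)
  if (is.null(covariates)) {
    covariates <- intersect(c("stage", "age_at_primary_dx", "race",
                              "signature_score"), names(rows))
  }
  if (sum(rows$event) < 2L) stop("fewer than 2 observed events")
  dat <- rows
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (anyNA(v)) stop("missing values in covariate ", cv)
    if (length(unique(v)) < 2L) {
      stop("covariate constant across patients: ", cv)
    }
  }
  if ("race" %in% covariates) {
    tab <- sort(table(dat$race), decreasing = TRUE)
    dat$race <- stats::relevel(factor(dat$race), ref = names(tab)[1L])
  }
  if ("stage" %in% covariates && stage_coding == "categorical") {
    dat$stage <- factor(dat$stage)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    }
  )
  sm <- summary(fit)
  coefs <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(
    covariate = rownames(coefs),
    hazard_ratio = unname(coefs[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(coefs[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  converged <- is.null(attr(fit, "fit_warning")) &&
    all(is.finite(out$hazard_ratio)) && all(is.finite(out$ci_high))
  structure(out,
            converged = converged,
            warning = attr(fit, "fit_warning"),
            n_events = sum(rows$event),
            log_likelihood = as.numeric(fit$loglik[2L]),
            iterations = fit$iter)
}

#' Per-signature survival association (forest-table rows)
#'
#' Each signature score is entered one at a time alongside the clinical
#' base model (stage, age at primary diagnosis, race), and the signature
#' coefficient row is collected into a forest-plot-ready table.
#'
#' @param clinical Validated clinical data.frame.
#' @param score_table Signatures x patients matrix of metagene scores.
#' @param origin Time origin, see [build_survival_table()].
#' @return data.frame `signature`, `origin`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p`, `converged`.
#' @export
signature_survival_scan <- function(clinical, score_table,
                                    origin = SURVIVAL_ORIGINS) {
  origin <- match.arg(origin)
  res <- lapply(rownames(score_table), function(sig) {
    scores <- score_table[sig, ]
    rows <- suppressMessages(
      build_survival_table(clinical, origin, scores = scores))
    rows <- rows[!is.na(rows$signature_score), , drop = FALSE]
    fit <- tryCatch(fit_cox(rows), error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(signature = sig, origin = origin,
                        hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    row <- fit[fit$covariate == "signature_score", , drop = FALSE]
    data.frame(signature = sig, origin = origin,
               hazard_ratio = row$hazard_ratio, ci_low = row$ci_low,
               ci_high = row$ci_high, p = row$p,
               converged = isTRUE(attr(fit, "converged")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
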