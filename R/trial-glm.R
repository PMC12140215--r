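#' Circularly linearized predictor table for trial-wise models
#'
#' Phases enter logistic models as sine/cosine pairs, so that a cosine
#' modulation of detection probability of any preferred phase is a linear
#' combination of the pair. Adds `sin_fm`, `cos_fm`, `sin_tacs`, `cos_tacs`,
#' a `depth` factor (from `condition`) and a `participant` factor.
#'
#' @param table Trial table with populated `fm_phase`, `tacs_phase`,
#'   `accuracy` (active-stimulation rows; NA phases are an error).
#' @return Data frame ready for [fit_candidates()].
#' @export
build_design <- function(table) {
  stopifnot(is.data.frame(table))
  if (any(is.na(table$fm_phase)) || any(is.na(table$tacs_phase)))
    stop("build_design: NA phases; filter to rows with both phases populated")
  data.frame(accuracy = table$accuracy,
             sin_fm = sin(table$fm_phase), cos_fm = cos(table$fm_phase),
             sin_tacs = sin(table$tacs_phase),
             cos_tacs = cos(table$tacs_phase),
             depth = factor(table$condition),
             participant = factor(table$participant))
}

#' Default candidate predictor sets
#'
#' Five families combining FM phase, tACS phase, modulation depth and the
#' phase-by-depth interactions. Each value is the fixed-effects right-hand
#' side of a logistic model formula.
#'
#' @return Named character vector of model right-hand sides.
#' @export
candidate_models <- function() {
  c(fm         = "sin_fm + cos_fm",
    tacs       = "sin_tacs + cos_tacs",
    fm_depth   = "(sin_fm + cos_fm) * depth",
    tacs_depth = "(sin_tacs + cos_tacs) * depth",
    full       = "(sin_fm + cos_fm) * depth + (sin_tacs + cos_tacs) * depth")
}

.fit_one <- function(rhs, design, mixed = TRUE, nAGQ = 1L) {
  if (mixed) {
    f <- stats::as.formula(paste("accuracy ~", rhs, "+ (1 | participant)"))
    fit <- tryCatch(
      suppressMessages(lme4::glmer(f, data = design, family = stats::binomial,
                                   nAGQ = nAGQ)),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, mixed = TRUE))
  }
  f <- stats::as.formula(paste("accuracy ~", rhs))
  list(fit = stats::glm(f, data = design, family = stats::binomial),
       mixed = FALSE)
}

#' Fit candidate logistic models and select by AIC
#'
#' Each candidate is fit as a mixed-effects logistic regression with a
#' participant random intercept (Laplace approximation; `nAGQ = 0` selects
#' the faster PIRLS approximation for large simulation studies). A
#' candidate whose mixed fit fails falls back to a fixed-effects logistic
#' fit with a logged downgrade. The winner has the lowest AIC; exact ties
#' go to the candidate with fewer parameters.
#'
#' @param design Output of [build_design()].
#' @param candidates Named character vector of model right-hand sides
#'   (default [candidate_models()]; >= 2 required).
#' @param mixed Fit random-intercept models (default TRUE).
#' @param nAGQ Integration setting passed to [lme4::glmer()].
#' @return A `model_comparison`: `table` (data frame sorted by AIC with
#'   `model`, `aic`, `delta_aic`, `n_par`, `mixed`), `winner` (name),
#'   `winner_fit`, `delta_aic` (winner to runner-up).
#' @export
fit_candidates <- function(design, candidates = candidate_models(),
                           mixed = TRUE, nAGQ = 1L) {
  if (length(candidates) < 2) stop("fit_candidates: need >= 2 candidates")
  if (!all(design$accuracy %in% c(0, 1)))
    stop("fit_candidates: accuracy must be binary")
  fits <- lapply(candidates, .fit_one, design = design, mixed = mixed,
                 nAGQ = nAGQ)
  aic <- vapply(fits, function(f) stats::AIC(f$fit), numeric(1))
  npar <- vapply(fits, function(f) attr(stats::logLik(f$fit), "df"), numeric(1))
  if (any(!is.finite(aic))) stop("fit_candidates: non-finite AIC")
  ord <- order(aic, npar)
  tab <- data.frame(model = names(candidates)[ord], aic = aic[ord],
                    delta_aic = aic[ord] - aic[ord][1], n_par = npar[ord],
                    mixed = vapply(fits, `[[`, logical(1), "mixed")[ord],
                    row.names = NULL)
  structure(list(table = tab, winner = tab$model[1],
                 winner_rhs = candidates[[tab$model[1]]],
                 winner_fit = fits[[tab$model[1]]]$fit,
                 delta_aic = if (nrow(tab) > 1) tab$aic[2] - tab$aic[1] else NA,
                 mixed_downgraded = names(candidates)[
                   mixed & !vapply(fits, `[[`, logical(1), "mixed")]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (lowest AIC wins):\n")
  print(x$table, row.names = FALSE)
  if (length(x$mixed_downgraded) > 0)
    cat("downgraded to fixed-effects:",
        paste(x$mixed_downgraded, collapse = ", "), "\n")
  invisible(x)
}

# in-sample AUC of a fitted binary model (conditional predictions)
.model_auc <- function(fit, response) {
  pred <- stats::fitted(fit)
  as.numeric(pROC::auc(pROC::roc(response, pred, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Surrogate-AUC significance of the winning model
#'
#' Computes the in-sample AUC of the winning model, then refits the same
#' model on `n_perm` surrogate datasets in which accuracy values are
#' shuffled within participant (all condition labels fixed) and records the
#' surrogate AUCs. The one-sided p-value is the fraction of surrogate AUCs
#' at least as large as the observed one.
#'
#' @param design Output of [build_design()].
#' @param winner_rhs Right-hand side of the winning model (fixed effects).
#' @param n_perm Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @param mixed,nAGQ Passed to the refits.
#' @return List with `auc`, `null_auc` (vector), `p_value`.
#' @export
surrogate_auc <- function(design, winner_rhs, n_perm = 1000, seed = 1,
                          mixed = TRUE, nAGQ = 1L) {
  if (length(unique(design$accuracy)) < 2)
    stop("surrogate_auc: degenerate outcome vector")
  obs_fit <- .fit_one(winner_rhs, design, mixed, nAGQ)
  obs <- .model_auc(obs_fit$fit, design$accuracy)
  set.seed(as.integer(seed))
  null_auc <- vapply(seq_len(n_perm), function(i) {
    d <- design
    d$accuracy <- stats::ave(d$accuracy, d$participant,
                             FUN = function(a) a[sample.int(length(a))])
    .model_auc(.fit_one(winner_rhs, d, mixed, nAGQ)$fit, d$accuracy)
  }, numeric(1))
  list(auc = obs, null_auc = null_auc,
       p_value = (sum(null_auc >= obs) + 1) / (n_perm + 1))
}
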