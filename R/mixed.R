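#' Build the two mixed-effects regression designs
#'
#' Constructs the behavioral (binomial, responses) and neural (linear, firing
#' rates) regression designs used to dissociate Bayesian from anti-Bayesian
#' prior use while accounting for all experimental variables. Both share the
#' seven fixed-effect terms: prior, saccade-driven noise, image noise,
#' displacement, and the image-by-saccade, image-by-prior and
#' saccade-by-prior interactions. Random intercepts and slopes are grouped
#' by session for the behavioral model and by neuron for the neural model.
#'
#' Numeric coding: `prior_high` is 0/1 (low/high cued prior), `saccade` is
#' 0/1, and `image` is the noise level 1/2/3 (low/medium/high). Because
#' image noise varies only on saccade trials and the lone no-saccade cell
#' sits at low image noise, the image-by-saccade product is an exact linear
#' combination of the intercept, saccade and image columns for any numeric
#' coding: that term is structurally unidentifiable in this design. It is
#' kept in the printed formula, flagged in the returned `aliased` field, and
#' dropped by the mixed-model machinery at fit time; both prior interactions
#' (the terms the dissociation rests on) are unaffected. Any other rank
#' deficiency (for example a single-condition table) raises an error naming
#' the aliased columns.
#'
#' @param data Joined trial/rate table with columns `response`, `rate`,
#'   `prior` (cued level), `saccade`, `image_noise`, `displacement`,
#'   `session_id`, `neuron_id`.
#' @param slopes `"main"` (random slopes for the four main effects,
#'   uncorrelated; the default, which keeps the estimation well-posed at
#'   cohort sizes) or `"full"` (slopes for all seven predictors).
#' @return List of class `mixed_designs` with elements `behavioral` and
#'   `neural`, each carrying `formula`, `data`, `family` and `group`;
#'   plus `fixed_terms`. A rank-deficient fixed-effects matrix raises an
#'   error naming the aliased columns.
#' @export
build_mixed_designs <- function(data, slopes = c("main", "full")) {
  slopes <- match.arg(slopes)
  need <- c("response", "rate", "prior", "saccade", "image_noise",
            "displacement", "session_id", "neuron_id")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("design table is missing columns: ", paste(missing, collapse = ", "))
  }
  # the regressions contrast the two cued extremes; neutral 0.5-prior
  # trials (present for model fitting) are not part of the contrast
  pr <- sort(unique(data$prior))
  if (length(pr) > 2) {
    data <- data[data$prior %in% range(pr), , drop = FALSE]
  }
  df <- data.frame(
    response = as.integer(data$response),
    rate = as.numeric(data$rate),
    prior_high = as.integer(data$prior == max(data$prior)),
    saccade = as.integer(data$saccade),
    image = match(data$image_noise, c("low", "medium", "high")),
    displacement = abs(as.numeric(data$displacement)),
    session_id = factor(data$session_id),
    neuron_id = factor(data$neuron_id)
  )
  fixed_terms <- c("prior_high", "saccade", "image", "displacement",
                   "image:saccade", "image:prior_high", "saccade:prior_high")
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), df)
  qr_x <- qr(X)
  aliased <- character(0)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    if (!setequal(aliased, "saccade:image")) {
      stop("rank-deficient fixed-effects design; aliased terms: ",
           paste(aliased, collapse = ", "))
    }
  }
  slope_terms <- if (slopes == "full") fixed_terms
                 else c("prior_high", "saccade", "image", "displacement")
  re <- function(group) {
    paste0("(1 + ", paste(slope_terms, collapse = " + "), " || ", group, ")")
  }
  mk <- function(outcome, group, family) {
    list(formula = stats::as.formula(
           paste(outcome, "~", fixed_rhs, "+", re(group))),
         data = df, family = family, group = group)
  }
  structure(list(
    behavioral = mk("response", "session_id", "binomial"),
    neural = mk("rate", "neuron_id", "gaussian"),
    fixed_terms = fixed_terms, aliased = aliased
  ), class = "mixed_designs")
}

#' Fit the behavioral and neural mixed-effects models
#'
#' Fits the binomial generalized linear mixed model for the binary responses
#' (grouped by session) and the linear mixed model for the firing rates
#' (grouped by neuron) and returns fixed-effect coefficient tables. The
#' binomial model uses the fast adaptive-Gauss-Hermite-free approximation
#' (`nAGQ = 0`); linear-model p-values use the Wald normal approximation on
#' the t statistic.
#'
#' @param designs A [build_mixed_designs()] object.
#' @return List of class `mixed_fits` with `behavioral` and `neural`
#'   coefficient data frames (`term`, `estimate`, `se`, `z`, `p`,
#'   `converged`) and the fitted `lme4` models in `models`.
#' @export
fit_mixed_models <- function(designs) {
  stopifnot(inherits(designs, "mixed_designs"))
  coef_table <- function(model, converged) {
    sm <- summary(model)$coefficients
    z <- sm[, "Estimate"] / sm[, "Std. Error"]
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               se = sm[, "Std. Error"], z = z,
               p = 2 * stats::pnorm(-abs(z)),
               converged = converged, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  fit_one <- function(d) {
    if (d$family == "binomial") {
      m <- lme4::glmer(d$formula, data = d$data, family = stats::binomial(),
                       nAGQ = 0,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa", calc.derivs = FALSE))
    } else {
      m <- lme4::lmer(d$formula, data = d$data,
                      control = lme4::lmerControl(
                        optimizer = "bobyqa", calc.derivs = FALSE))
    }
    # optimizer return code; singular (boundary) fits are not failures
    conv <- isTRUE(m@optinfo$conv$opt == 0)
    list(model = m, table = coef_table(m, conv))
  }
  beh <- fit_one(designs$behavioral)
  neu <- fit_one(designs$neural)
  structure(list(behavioral = beh$table, neural = neu$table,
                 models = list(behavioral = beh$model, neural = neu$model)),
            class = "mixed_fits")
}
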