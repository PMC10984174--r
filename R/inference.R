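# Home-range size modelling: gamma GLMs with a log link, small-sample AICc,
# all-subsets candidate sets fitted in two stages (intrinsic then
# extrinsic), Delta-AICc retention backed by 85% Wald intervals, and full
# (zero-substitution) model averaging with unconditional standard errors.

#' Fit a gamma GLM with log link
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`); the gamma shape parameter is then profiled by ML so the
#' log-likelihood used for AICc is coherent. Coefficient standard errors
#' use the Pearson-based dispersion (the `summary.glm` convention): the ML
#' shape estimate is biased upward in small samples and would understate
#' the Wald intervals that the retention rule depends on.
#'
#' @param formula model formula; the response must be strictly positive
#'   (areas in hectares).
#' @param data model frame.
#' @return object of class `roam_gamma_glm`: `coefficients` (matrix with
#'   estimates and SEs), `loglik`, `shape`, `k` (parameter count including
#'   intercept and shape), `n`, `fit` (the underlying glm). Fits that have
#'   not converged after 1000 IRLS iterations raise an error.
#' @export
fit_gamma_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y <= 0)) stop("gamma GLM response must be strictly positive")
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- stats::glm(formula, data = data, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(maxit = 1000,
                                                 epsilon = 1e-10))
  if (!fit$converged) stop("IRLS failed to converge in 1000 iterations")
  mu <- stats::fitted(fit)
  # profile ML of the shape given the IRLS mean fit; bounded search keeps
  # the degenerate zero-deviance case (shape -> Inf) finite
  prof <- function(ls) sum(stats::dgamma(y, shape = exp(ls),
                                         rate = exp(ls) / mu, log = TRUE))
  shape <- exp(stats::optimize(prof, c(log(1e-3), log(1e8)),
                               maximum = TRUE, tol = 1e-10)$maximum)
  ll <- sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(list(coefficients = cf, loglik = ll, shape = shape,
                 k = nrow(cf) + 1L, n = length(y), fit = fit,
                 formula = formula),
            class = "roam_gamma_glm")
}

#' @export
print.roam_gamma_glm <- function(x, ...) {
  cat(sprintf("<gamma GLM (log link), n = %d, shape = %.3f, logLik = %.3f>\n",
              x$n, x$shape, x$loglik))
  print(round(x$coefficients[, 1:2, drop = FALSE], 4))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k parameter count (intercept + slopes + shape).
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Wald confidence interval for one coefficient
#'
#' @param model a `roam_gamma_glm`.
#' @param term coefficient name.
#' @param level confidence level (0.85 uses z = 1.4395).
#' @return named vector `estimate, lower, upper`.
#' @export
wald_ci <- function(model, term, level = 0.85) {
  cf <- model$coefficients
  if (!term %in% rownames(cf)) stop("no such term: ", term)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- cf[term, 1]; se <- cf[term, 2]
  c(estimate = est, lower = est - z * se, upper = est + z * se)
}

.model_label <- function(preds) {
  if (!length(preds)) "Null" else paste(preds, collapse = " + ")
}

#' Fit all predictor subsets of one selection stage
#'
#' Fits the `2^p` subset models over `stage_predictors` (each also carrying
#' `carried` predictors from the previous stage), ranks them by AICc and
#' attaches Delta-AICc and Akaike weights over the full candidate set.
#' Animals with missing values in any used column are dropped with a
#' message.
#'
#' @param data covariate table with the response column.
#' @param response response column name (e.g. `"mcp_area_ha"`).
#' @param stage_predictors character vector of predictors to combine.
#' @param carried predictors forced into every candidate.
#' @return object of class `roam_modelset`: `table` (data.frame: model, df,
#'   AICc, delta_aicc, weight), `models` (list of `roam_gamma_glm`),
#'   `predictors` (list per model), `n`.
#' @export
all_subsets <- function(data, response, stage_predictors, carried = character()) {
  used_cols <- c(response, stage_predictors, carried)
  cc <- stats::complete.cases(data[, used_cols, drop = FALSE])
  if (any(!cc))
    message(sum(!cc), " animal(s) dropped for missing covariates; n = ",
            sum(cc))
  data <- data[cc, , drop = FALSE]
  subsets <- list(character(0))
  for (p in stage_predictors)
    subsets <- c(subsets, lapply(subsets, c, p))
  models <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    preds <- c(carried, subsets[[i]])
    rhs <- if (length(preds)) paste(preds, collapse = " + ") else "1"
    f <- stats::as.formula(paste(response, "~", rhs))
    m <- fit_gamma_glm(f, data)
    models[[i]] <- m
    rows[[i]] <- data.frame(model = .model_label(preds), df = m$k,
                            AICc = aicc(m$loglik, m$k, m$n),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta_aicc / 2)
  tab$weight <- tab$weight / sum(tab$weight)
  ord <- order(tab$AICc)
  structure(list(table = tab[ord, ], models = models[ord],
                 predictors = lapply(subsets, c)[ord],
                 carried = carried, n = nrow(data)),
            class = "roam_modelset")
}

#' @export
print.roam_modelset <- function(x, ...) {
  cat(sprintf("<roam_modelset: %d candidate models, n = %d>\n",
              nrow(x$table), x$n))
  tab <- x$table
  tab$AICc <- round(tab$AICc, 4)
  tab$delta_aicc <- round(tab$delta_aicc, 4)
  tab$weight <- round(tab$weight, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predictors retained by the Delta-AICc + confidence-interval rule
#'
#' A predictor is retained when it appears in at least one model within
#' `delta_cut` of the best AICc AND its Wald CI (at `ci_level`, in the best
#' model containing it) excludes zero. Factor predictors count as retained
#' when any of their dummy coefficients passes the CI rule.
#'
#' @param modelset a `roam_modelset`.
#' @param delta_cut Delta-AICc threshold (default 2).
#' @param ci_level confidence level (default 0.85).
#' @return character vector of retained predictor names (possibly empty).
#' @export
retain_predictors <- function(modelset, delta_cut = 2, ci_level = 0.85) {
  tab <- modelset$table
  carried <- modelset$carried
  stage_preds <- unique(unlist(lapply(modelset$predictors, setdiff,
                                      carried)))
  retained <- character(0)
  for (p in stage_preds) {
    in_model <- vapply(modelset$predictors,
                       function(pr) p %in% pr, logical(1))
    top <- in_model & tab$delta_aicc < delta_cut
    if (!any(top)) next
    best <- which(in_model)[1]   # models are AICc-ordered
    m <- modelset$models[[best]]
    terms <- grep(paste0("^", p), rownames(m$coefficients), value = TRUE)
    excl <- vapply(terms, function(tm) {
      ci <- wald_ci(m, tm, ci_level)
      ci["lower"] > 0 || ci["upper"] < 0
    }, logical(1))
    if (any(excl)) retained <- c(retained, p)
  }
  retained
}

#' Full (zero-substitution) model averaging
#'
#' Averages coefficients over the models within `delta_cut`, weights
#' renormalised; a coefficient absent from a model contributes zero there.
#' Unconditional standard errors follow the standard weight-combined
#' formula `sum_m w_m sqrt(se_m^2 + (b_m - b_bar)^2)`.
#'
#' @param modelset a `roam_modelset`.
#' @param delta_cut Delta-AICc threshold.
#' @param ci_level level for the averaged Wald CIs (default 0.85).
#' @return data.frame `(term, coefficient, se, lower, upper)`.
#' @export
model_average <- function(modelset, delta_cut = 2, ci_level = 0.85) {
  keep <- which(modelset$table$delta_aicc < delta_cut)
  if (!length(keep)) stop("no model within the Delta-AICc cut")
  w <- modelset$table$weight[keep]
  w <- w / sum(w)
  terms <- unique(unlist(lapply(modelset$models[keep], function(m)
    rownames(m$coefficients))))
  out <- lapply(terms, function(tm) {
    b <- se <- numeric(length(keep))
    for (j in seq_along(keep)) {
      cf <- modelset$models[[keep[j]]]$coefficients
      if (tm %in% rownames(cf)) {
        b[j] <- cf[tm, 1]; se[j] <- cf[tm, 2]
      }                                   # else zero-substitution
    }
    bbar <- sum(w * b)
    use <- sum(w * sqrt(se^2 + (b - bbar)^2))
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    data.frame(term = tm, coefficient = bbar, se = use,
               lower = bbar - z * use, upper = bbar + z * use,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-stage all-subsets selection of home-range predictors
#'
#' Stage 1 fits all subsets of the intrinsic predictors (sex, age,
#' neuroticism); predictors passing the Delta-AICc + CI retention rule are
#' carried into stage 2, which fits all subsets of the extrinsic predictors
#' (road density, major road, ordinal start date) on the full-information
#' animal set for that stage. Model-averaged coefficients are computed over
#' the stage-2 models within the Delta-AICc cut.
#'
#' @param covariates covariate table from [build_covariates()] (or
#'   equivalent columns).
#' @param response response column name.
#' @param config a [roam_config()] (CI level, Delta-AICc cut).
#' @param intrinsic,extrinsic predictor name vectors.
#' @return list `intrinsic` (modelset), `extrinsic` (modelset),
#'   `carried` (stage-1 survivors), `retained` (stage-2 survivors),
#'   `averaged` (data.frame from [model_average()]).
#' @export
two_stage_selection <- function(covariates, response = "mcp_area_ha",
                                config = roam_config(),
                                intrinsic = c("sex", "age", "neuroticism"),
                                extrinsic = c("road_density", "major_road",
                                              "start_ordinal_date")) {
  s1 <- all_subsets(covariates, response, intrinsic)
  carried <- retain_predictors(s1, config$delta_aicc_cut, config$ci_level_glm)
  s2 <- all_subsets(covariates, response, extrinsic, carried = carried)
  retained <- retain_predictors(s2, config$delta_aicc_cut,
                                config$ci_level_glm)
  avg <- model_average(s2, config$delta_aicc_cut, config$ci_level_glm)
  list(intrinsic = s1, extrinsic = s2, carried = carried,
       retained = retained, averaged = avg)
}
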