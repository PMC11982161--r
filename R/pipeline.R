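# Dyad-level statistical stage: assemble the long measures table, designate
# within-dyad roles and dyad types, fit the random-intercept mixed models and
# per-item appraisal GLMs, and apply Benjamini-Hochberg correction.
#
# Estimation is delegated to lme4/lmerTest (maximum likelihood, Satterthwaite
# degrees of freedom) and stats::lm; what is fixed here is the design:
# task as a categorical predictor with introduction as baseline, traits of
# the higher-scoring partner (role A) and lower-scoring partner (role B),
# standardized betas via z-scored refit, and the reporting contract
# (B, beta, SE, t, df, p, adjusted p, ICC, marginal/conditional R2, AIC).

#' Designate within-dyad roles from trait scores
#'
#' The partner with the higher score is role "A", the other "B"; on a tie the
#' first-listed partner is "A".
#'
#' @param score_1,score_2 finite trait scores of the two partners, in listed
#'   order.
#' @return Character vector `c(role_of_1, role_of_2)`.
#' @export
assign_roles <- function(score_1, score_2) {
  stopifnot(is.finite(score_1), is.finite(score_2))
  if (score_1 >= score_2) c("A", "B") else c("B", "A")
}

#' Standardize a numeric vector
#'
#' Centered by the mean and scaled by the sample standard deviation.
#'
#' @param values numeric vector of length at least 2 with nonzero variance.
#' @return Vector with mean 0 and sample standard deviation 1.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a zero-variance vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Classify a dyad by its partners' standardized trait scores
#'
#' Members at or above `+threshold` SD are "high", at or below `-threshold`
#' are "low"; a dyad with any mid-range member is labeled `"mid"`. Intended
#' for descriptive plotting only.
#'
#' @param z_a,z_b standardized trait scores of the two partners.
#' @param threshold high/low cutoff in SD units (default 0.5).
#' @return One of `"++"`, `"--"`, `"+-"`, `"mid"`.
#' @export
classify_dyad <- function(z_a, z_b, threshold = 0.5) {
  lvl <- function(z) if (z >= threshold) "high" else if (z <= -threshold) "low" else "mid"
  la <- lvl(z_a); lb <- lvl(z_b)
  if (la == "mid" || lb == "mid") return("mid")
  if (la == "high" && lb == "high") return("++")
  if (la == "low" && lb == "low") return("--")
  "+-"
}

#' Assemble the long dyad-task measures table
#'
#' One row per dyad and task, carrying the coordination measures, the chosen
#' trait standardized across all participants and split into the
#' higher-scoring (A) and lower-scoring (B) partner, and the descriptive
#' dyad-type label. Task is coded as a factor with introduction as the
#' baseline level.
#'
#' @param measures a `data.frame` of [dyad_measures()] rows (e.g.
#'   `simulate_study()$measures`).
#' @param traits `data.frame` with columns `participant_id`, `dyad_id`, and
#'   the trait column.
#' @param trait name of the trait column to attach (default
#'   `"extraversion"`).
#' @return A `data.frame` with `n_dyads * n_tasks` rows and columns
#'   `dyad_id`, `task`, the measure columns, `trait_a`, `trait_b`,
#'   `dyad_type`.
#' @export
assemble_measures_table <- function(measures, traits,
                                    trait = "extraversion") {
  stopifnot(is.data.frame(measures), is.data.frame(traits),
            trait %in% names(traits))
  tasks <- c("introduction", "self_disclosure", "argumentative")
  dyads <- unique(measures$dyad_id)
  grid <- expand.grid(dyad_id = dyads, task = tasks,
                      stringsAsFactors = FALSE)
  key <- paste(measures$dyad_id, measures$task)
  if (anyDuplicated(key)) {
    stop("duplicated (dyad_id, task) rows in measures", call. = FALSE)
  }
  missing <- setdiff(paste(grid$dyad_id, grid$task), key)
  if (length(missing) > 0) {
    stop("incomplete dyad-task grid; missing: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  traits <- traits[order(traits$dyad_id, traits$participant_id), ]
  z <- standardize(traits[[trait]])
  per_dyad <- lapply(split(seq_len(nrow(traits)), traits$dyad_id), function(ix) {
    stopifnot(length(ix) == 2)
    roles <- assign_roles(traits[[trait]][ix[1]], traits[[trait]][ix[2]])
    za <- z[ix[roles == "A"]]
    zb <- z[ix[roles == "B"]]
    data.frame(dyad_id = traits$dyad_id[ix[1]], trait_a = za, trait_b = zb,
               dyad_type = classify_dyad(za, zb), stringsAsFactors = FALSE)
  })
  per_dyad <- do.call(rbind, per_dyad)
  out <- merge(as.data.frame(measures), per_dyad, by = "dyad_id")
  out$task <- factor(out$task, levels = tasks)
  out <- out[order(out$dyad_id, out$task), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values with validation of the
#' input range.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# Standardized-beta refit: z-score the response and every continuous,
# non-constant predictor column; factor (task) dummies stay binary.
std_data <- function(data, response) {
  for (nm in names(data)) {
    v <- data[[nm]]
    if (is.numeric(v) && stats::sd(v) > 0) {
      data[[nm]] <- (v - mean(v)) / stats::sd(v)
    }
  }
  data
}

#' Fit a dyad random-intercept mixed model for one coordination measure
#'
#' Maximum-likelihood linear mixed model with a random intercept per dyad,
#' Satterthwaite degrees of freedom, and task coded with introduction as the
#' baseline. Standardized betas come from refitting after z-scoring the
#' response and the continuous predictors (task dummies are left binary).
#'
#' @param table an [assemble_measures_table()] result.
#' @param response name of the response column (e.g. `"rr_global"`).
#' @param fixed_terms character vector of fixed-effect terms combined with
#'   `+` (e.g. `"task"` or `"trait_a * trait_b * task"`).
#' @param bh_family `"model"` (default) adjusts all non-intercept p-values of
#'   this model together; `"none"` leaves `p_adjusted = p`.
#' @return An object of class `model_fit`: `response_name`, `coefficients`
#'   (term, B, beta, SE, t, df, p, p_adjusted), `icc`, `marginal_r2`,
#'   `conditional_r2`, `aic`, `n_groups`, `n_obs`, `singular`, and the
#'   underlying `fit`.
#' @export
fit_mixed_model <- function(table, response, fixed_terms = "task",
                            bh_family = c("model", "none")) {
  bh_family <- match.arg(bh_family)
  if (!response %in% names(table)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  vars <- all.vars(stats::reformulate(fixed_terms))
  unknown <- setdiff(vars, names(table))
  if (length(unknown) > 0) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(table$dyad_id)) < 2) {
    stop("need at least 2 dyads", call. = FALSE)
  }
  rhs <- paste(c(fixed_terms, "(1 | dyad_id)"), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  # lmerTest supplies Satterthwaite df; degenerate fits (e.g. zero residual
  # variance) can break its post-processing, in which case we keep the lme4
  # fit and fall back to residual df
  fit <- tryCatch(lmerTest::lmer(form, data = table, REML = FALSE),
                  error = function(e) lme4::lmer(form, data = table,
                                                 REML = FALSE))
  singular <- lme4::isSingular(fit)
  coefs <- tryCatch({
    if (inherits(fit, "lmerModLmerTest")) {
      co <- as.data.frame(stats::coef(summary(fit)))
      names(co) <- c("B", "SE", "df", "t", "p")
    } else {
      co <- as.data.frame(stats::coef(summary(fit)))
      names(co) <- c("B", "SE", "t")
      co$df <- nrow(table) - nrow(co)
      co$p <- 2 * stats::pt(abs(co$t), co$df, lower.tail = FALSE)
    }
    co
  }, error = function(e) {
    # a deviance surface too flat for a curvature-based vcov (e.g. an exact
    # linear response): report point estimates, leave inference NA
    fe <- lme4::fixef(fit)
    data.frame(B = unname(fe), SE = NA_real_, df = NA_real_, t = NA_real_,
               p = NA_real_, row.names = names(fe))
  })
  # standardized betas (point estimates only: plain lme4 refit suffices)
  sdata <- std_data(table, response)
  sfit <- lme4::lmer(form, data = sdata, REML = FALSE)
  beta <- lme4::fixef(sfit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- vc$vcov[vc$grp == "dyad_id"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  icc <- var_re / (var_re + var_res)
  var_fix <- stats::var(stats::predict(fit, re.form = NA))
  tot <- var_fix + var_re + var_res
  out <- data.frame(
    term = rownames(coefs), B = coefs$B, beta = unname(beta[rownames(coefs)]),
    SE = coefs$SE, t = coefs$t, df = coefs$df, p = coefs$p,
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- out$p
  if (bh_family == "model") {
    nz <- out$term != "(Intercept)"
    if (!anyNA(out$p[nz])) out$p_adjusted[nz] <- bh_adjust(out$p[nz])
  }
  rownames(out) <- NULL
  structure(
    list(response_name = response, coefficients = out, icc = icc,
         marginal_r2 = var_fix / tot,
         conditional_r2 = (var_fix + var_re) / tot,
         aic = stats::AIC(fit),
         n_groups = length(unique(table$dyad_id)), n_obs = nrow(table),
         singular = singular, fit = fit),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<model_fit> %s (%d obs, %d groups)\n", x$response_name,
              x$n_obs, x$n_groups))
  print(format(x$coefficients, digits = digits), ...)
  cat(sprintf("ICC = %.2f, marginal/conditional R2 = %.3f/%.3f, AIC = %.1f%s\n",
              x$icc, x$marginal_r2, x$conditional_r2, x$aic,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  invisible(x)
}

#' Fit a per-item appraisal general linear model
#'
#' Ordinary linear model of one 1-5 appraisal item on standardized
#' coordination and trait predictors. Raw p-values are reported; adjust them
#' across the item family with [adjust_model_family()].
#'
#' @param data `data.frame` with the item scores and predictor columns, one
#'   row per participant.
#' @param item_name response column (scores in `[1, 5]`).
#' @param predictors character vector of terms combined with `+`, e.g.
#'   `c("trait_a * trait_b * rr_los")`.
#' @return A `model_fit` (with `icc` and the R2 components `NA` except
#'   `marginal_r2`, the model R2).
#' @export
fit_appraisal_model <- function(data, item_name, predictors) {
  if (!item_name %in% names(data)) {
    stop("item column not found: ", item_name, call. = FALSE)
  }
  y <- data[[item_name]]
  if (any(y < 1 | y > 5)) {
    stop("item scores must lie in [1, 5]", call. = FALSE)
  }
  vars <- all.vars(stats::reformulate(predictors))
  unknown <- setdiff(vars, names(data))
  if (length(unknown) > 0) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) {
    if (is.numeric(data[[v]]) && stats::sd(data[[v]]) == 0) {
      stop("zero-variance predictor: ", v, call. = FALSE)
    }
  }
  form <- stats::as.formula(paste(item_name, "~",
                                  paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sfit <- stats::lm(form, data = std_data(data, item_name))
  coefs <- as.data.frame(stats::coef(summary(fit)))
  names(coefs) <- c("B", "SE", "t", "p")
  out <- data.frame(
    term = rownames(coefs), B = coefs$B,
    beta = unname(stats::coef(sfit)[rownames(coefs)]),
    SE = coefs$SE, t = coefs$t, df = fit$df.residual, p = coefs$p,
    p_adjusted = coefs$p, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(
    list(response_name = item_name, coefficients = out, icc = NA_real_,
         marginal_r2 = summary(fit)$r.squared, conditional_r2 = NA_real_,
         aic = stats::AIC(fit), n_groups = NA_integer_, n_obs = nrow(data),
         singular = FALSE, fit = fit),
    class = "model_fit"
  )
}

#' Assemble the per-participant appraisal modeling table
#'
#' One row per participant for one appraisal item, joining the item score
#' with the dyad's standardized role-based trait scores (`trait_a`,
#' `trait_b`) and the dyad's task-mean coordination predictors (`rr_los`,
#' `q_dcrp`, `lam_ard`), standardized across dyads.
#'
#' @param study a [simulate_study()] result (or a list with compatible
#'   `traits`, `measures`, `appraisals` elements).
#' @param item which appraisal item to attach.
#' @param trait trait column used for the role-based dyad scores.
#' @return A `data.frame` ready for [fit_appraisal_model()].
#' @export
assemble_appraisal_table <- function(study, item, trait = "extraversion") {
  app <- study$appraisals[study$appraisals$item == item, ]
  if (nrow(app) == 0) stop("unknown appraisal item: ", item, call. = FALSE)
  tab <- assemble_measures_table(study$measures, study$traits, trait = trait)
  agg <- stats::aggregate(tab[, c("rr_los", "q_dcrp", "lam_ard")],
                          by = list(dyad_id = tab$dyad_id), FUN = mean)
  for (v in c("rr_los", "q_dcrp", "lam_ard")) {
    agg[[v]] <- standardize(agg[[v]])
  }
  dyads <- tab[!duplicated(tab$dyad_id),
               c("dyad_id", "trait_a", "trait_b", "dyad_type")]
  out <- merge(merge(app, dyads, by = "dyad_id"), agg, by = "dyad_id")
  names(out)[names(out) == "score"] <- item
  out
}

#' Benjamini-Hochberg adjustment across a family of fitted models
#'
#' Pools the non-intercept p-values of several [fit_appraisal_model()] or
#' [fit_mixed_model()] results, adjusts them as one family, and writes the
#' adjusted values back into each model's coefficient table.
#'
#' @param fits list of `model_fit` objects.
#' @return The list with updated `p_adjusted` columns.
#' @export
adjust_model_family <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "model_fit")))
  take <- lapply(fits, function(f) f$coefficients$term != "(Intercept)")
  pooled <- unlist(Map(function(f, nz) f$coefficients$p[nz], fits, take))
  adj <- bh_adjust(pooled)
  pos <- 0L
  for (i in seq_along(fits)) {
    k <- sum(take[[i]])
    fits[[i]]$coefficients$p_adjusted[take[[i]]] <- adj[pos + seq_len(k)]
    pos <- pos + k
  }
  fits
}
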