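#' Model specification for one response variable
#'
#' Binds each response to its error family and link exactly as in the
#' analysis design: herbivore richness to Poisson/log with an offset of
#' log(total assemblage herbivore richness); mean Jaccard and Simpson
#' dissimilarity to binomial/logit (proportion data, prior weights equal
#' to the number of pairwise terms averaged); mean d' to Gaussian/identity.
#' Fixed effects are phylogenetic isolation (PI, z-scored by default),
#' plant origin (PO, coded native = 1 so positive coefficients mean higher
#' values on natives) and optionally their interaction; the random effect
#' is an intercept per assemblage.
#'
#' @param response one of `"richness"`, `"mean_jaccard"`, `"mean_simpson"`,
#'   `"mean_dprime"`.
#' @param interaction include the PI x PO interaction term.
#' @param standardize_pi z-score PI before fitting (raw-scale coefficients
#'   are reported alongside either way).
#' @param weighted for the binomial responses, use
#'   `n_native_comparators` as prior weights (default) or weight 1.
#' @return object of class `herb_model_spec`.
#' @export
model_spec <- function(response = c("richness", "mean_jaccard",
                                    "mean_simpson", "mean_dprime"),
                       interaction = FALSE, standardize_pi = TRUE,
                       weighted = TRUE) {
  response <- match.arg(response)
  family_link <- switch(response,
                        richness = "poisson_log",
                        mean_jaccard = ,
                        mean_simpson = "binomial_logit",
                        mean_dprime = "gaussian_identity")
  structure(list(response = response, family_link = family_link,
                 interaction = interaction, standardize_pi = standardize_pi,
                 weighted = weighted,
                 offset = response == "richness"),
            class = "herb_model_spec")
}

prepare_model_frame <- function(data, spec) {
  need <- c("assemblage_id", "origin", "phylo_isolation", spec$response)
  if (spec$offset) need <- c(need, "total_richness")
  if (spec$family_link == "binomial_logit") need <- c(need, "n_native_comparators")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  if (nrow(df) == 0L) stop("no complete observations", call. = FALSE)
  df$PO <- as.numeric(df$origin == "native")
  if (length(unique(df$PO)) < 2L) {
    stop("rank-deficient design: all plants share one origin", call. = FALSE)
  }
  pi_center <- if (spec$standardize_pi) mean(df$phylo_isolation) else 0
  pi_scale <- if (spec$standardize_pi) sd(df$phylo_isolation) else 1
  if (!is.finite(pi_scale) || pi_scale == 0) {
    stop("rank-deficient design: phylogenetic isolation is constant",
         call. = FALSE)
  }
  df$PI <- (df$phylo_isolation - pi_center) / pi_scale
  df$y <- df[[spec$response]]
  df$assemblage_id <- factor(df$assemblage_id)
  df$.off <- if (spec$offset) log(df$total_richness) else 0
  df$.w <- if (spec$family_link == "binomial_logit" && spec$weighted) {
    df$n_native_comparators
  } else 1
  attr(df, "pi_center") <- pi_center
  attr(df, "pi_scale") <- pi_scale
  df
}

model_formula <- function(spec, random = TRUE) {
  fx <- if (spec$interaction) "PI * PO" else "PI + PO"
  rhs <- paste0(fx,
                if (random) " + (1 | assemblage_id)" else "",
                if (spec$offset) " + offset(.off)" else "")
  as.formula(paste("y ~", rhs))
}

# glmer warns about non-integer successes when a weighted proportion is
# supplied; that is exactly our (documented) binomial encoding, so the
# warning is muffled -- all other warnings pass through.
quiet_nonint <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

fit_engine <- function(df, spec, random = TRUE) {
  fml <- model_formula(spec, random = random)
  if (spec$family_link == "gaussian_identity") {
    if (random) {
      lme4::lmer(fml, data = df, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      stats::lm(fml, data = df)
    }
  } else {
    fam <- if (spec$family_link == "poisson_log") stats::poisson("log") else
      stats::binomial("logit")
    if (random) {
      quiet_nonint(lme4::glmer(
        fml, data = df, family = fam, weights = .w,
        control = lme4::glmerControl(check.conv.singular = "ignore")))
    } else {
      quiet_nonint(stats::glm(fml, data = df, family = fam, weights = .w))
    }
  }
}

#' Fit one mixed model of the analysis
#'
#' Maximum-likelihood (Laplace) fit of the GLMM given by `spec` on a
#' per-plant metrics table (as from [build_plant_metrics()], rows stacked
#' over assemblages). Rows with missing values in the used columns are
#' dropped.
#'
#' @param data per-plant metrics data.frame.
#' @param spec a [model_spec()].
#' @return object of class `herb_fit`: coefficient table (with raw-PI-scale
#'   estimates alongside the fitted scale), random-intercept variance,
#'   log-likelihood, group/observation counts and the underlying lme4 fit.
#' @export
fit_model <- function(data, spec) {
  df <- prepare_model_frame(data, spec)
  if (nlevels(df$assemblage_id) < 2L) {
    stop("need >= 2 assemblages for a random intercept", call. = FALSE)
  }
  fit <- fit_engine(df, spec, random = TRUE)
  # a nonzero optimizer status is a genuine failure; gradient-check
  # messages are advisory and already surfaced as warnings by lme4
  opt <- fit@optinfo$conv$opt
  if (!is.null(opt) && length(opt) == 1L && is.numeric(opt) && opt != 0) {
    stop("mixed-model optimizer failed (status ", opt, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  }
  as_herb_fit(fit, df, spec, fallback_used = FALSE)
}

coef_table <- function(fit, pi_scale) {
  sm <- summary(fit)$coefficients
  stat_col <- intersect(c("z value", "t value"), colnames(sm))[1]
  out <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], statistic = sm[, stat_col],
                    stringsAsFactors = FALSE, row.names = NULL)
  p_col <- grep("^Pr\\(", colnames(sm), value = TRUE)
  out$p_value <- if (length(p_col)) sm[, p_col[1]] else
    2 * stats::pnorm(-abs(out$statistic))  # Wald normal for lmer t values
  # back-transform PI terms to the raw Myr scale
  out$estimate_raw <- out$estimate
  sel <- grepl("PI", out$term)
  out$estimate_raw[sel] <- out$estimate[sel] / pi_scale
  out
}

as_herb_fit <- function(fit, df, spec, fallback_used) {
  mixed <- inherits(fit, "merMod")
  re_var <- if (mixed) {
    as.numeric(lme4::VarCorr(fit)$assemblage_id)
  } else NA_real_
  structure(list(
    fit = fit, spec = spec,
    coefficients = coef_table(fit, attr(df, "pi_scale")),
    re_variance = re_var,
    re_sd = if (mixed) sqrt(re_var) else NA_real_,
    logLik = as.numeric(logLik(fit)),
    n_obs = nrow(df), n_groups = nlevels(df$assemblage_id),
    fallback_used = fallback_used, data = df,
    pi_center = attr(df, "pi_center"), pi_scale = attr(df, "pi_scale")),
    class = "herb_fit")
}

#' @export
print.herb_fit <- function(x, ...) {
  cat("<herb_fit> ", x$spec$response, " ~ PI ",
      if (x$spec$interaction) "* " else "+ ", "PO, ",
      x$spec$family_link, if (x$fallback_used) " (fixed-effects fallback)",
      "\n  n = ", x$n_obs, " plants in ", x$n_groups, " assemblages",
      if (!x$fallback_used) paste0("; RE variance = ", signif(x$re_variance, 4)),
      "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test for the PI x PO interaction
#'
#' Fits the model with and without the interaction term, compares them
#' with a 1-df chi-square LRT, and keeps the interaction only when the
#' test is significant at `alpha`.
#'
#' @param data per-plant metrics data.frame.
#' @param spec a [model_spec()]; its `interaction` flag is ignored.
#' @param alpha significance threshold for keeping the interaction.
#' @return list: `lrt` (data.frame `chi_squared`, `df`, `p_value`,
#'   `keep_interaction`) and `fit` (the chosen `herb_fit`).
#' @export
lrt_interaction <- function(data, spec, alpha = 0.05) {
  spec_red <- spec
  spec_red$interaction <- FALSE
  spec_full <- spec
  spec_full$interaction <- TRUE
  fit_red <- fit_model(data, spec_red)
  fit_full <- fit_model(data, spec_full)
  chi2 <- 2 * (fit_full$logLik - fit_red$logLik)
  if (chi2 < -1e-4) {
    stop("full-model log-likelihood below reduced model (",
         signif(chi2, 3), "); optimizer failure", call. = FALSE)
  }
  chi2 <- max(chi2, 0)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  keep <- p < alpha
  list(lrt = data.frame(chi_squared = chi2, df = 1L, p_value = p,
                        keep_interaction = keep),
       fit = if (keep) fit_full else fit_red)
}

#' Refit without the random effect when its variance vanishes
#'
#' When the fitted random-intercept variance is below `threshold` the
#' model is refitted as a fixed-effects-only GLM and goodness of fit is
#' reported as McFadden's pseudo-R2 (`1 - ll_model / ll_null`, the null
#' model keeping only the intercept and any offset).
#'
#' @param fit a `herb_fit` from [fit_model()].
#' @param threshold variance threshold triggering the fallback.
#' @return a `herb_fit`; either `fit` unchanged or the fixed-effects refit
#'   with `fallback_used = TRUE` and `mcfadden` set.
#' @export
fallback_if_singular <- function(fit, threshold = 1e-8) {
  if (fit$fallback_used || is.na(fit$re_variance) ||
      fit$re_variance >= threshold) {
    return(fit)
  }
  df <- fit$data
  spec <- fit$spec
  refit <- fit_engine(df, spec, random = FALSE)
  out <- as_herb_fit(refit, df, spec, fallback_used = TRUE)
  out$mcfadden <- mcfadden_r2(refit, df, spec)
  out
}

mcfadden_r2 <- function(fit, df, spec) {
  null_fml <- as.formula(paste("y ~ 1",
                               if (spec$offset) "+ offset(.off)" else ""))
  null_fit <- if (spec$family_link == "gaussian_identity") {
    stats::lm(null_fml, data = df)
  } else {
    fam <- if (spec$family_link == "poisson_log") stats::poisson("log") else
      stats::binomial("logit")
    quiet_nonint(stats::glm(null_fml, data = df, family = fam, weights = .w))
  }
  1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit))
}

#' Marginal and conditional R2 for a mixed fit
#'
#' Variance-partition R2 in the Nakagawa-Schielzeth sense: marginal
#' `var_f / (var_f + var_r + var_d)` and conditional
#' `(var_f + var_r) / (same)`, where `var_f` is the variance of the fixed
#' linear predictor (offset excluded), `var_r` the random-intercept
#' variance and `var_d` the family-specific distribution variance on the
#' link scale (Gaussian: residual variance; logit: pi^2/3; log-Poisson:
#' `ln(1 + 1/lambda0)` with `lambda0 = exp(beta0 + mean(offset))`, the
#' lognormal approximation).
#'
#' @param fit a mixed `herb_fit` (not a fallback fit).
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  if (fit$fallback_used) {
    stop("fixed-effects-only fit: use McFadden's pseudo-R2", call. = FALSE)
  }
  mod <- fit$fit
  X <- lme4::getME(mod, "X")
  beta <- lme4::fixef(mod)
  var_f <- var(as.vector(X %*% beta))
  var_r <- fit$re_variance
  var_d <- switch(fit$spec$family_link,
                  gaussian_identity = stats::sigma(mod)^2,
                  binomial_logit = pi^2 / 3,
                  poisson_log = {
                    lambda0 <- exp(unname(beta[1]) + mean(fit$data$.off))
                    log(1 + 1 / lambda0)
                  })
  denom <- var_f + var_r + var_d
  c(marginal = var_f / denom, conditional = (var_f + var_r) / denom)
}

#' Run the full model stage over guild scopes and responses
#'
#' For each requested guild scope (`all`, `endophage`, `exophage`) the
#' eligible assemblages are (re-)built at that scope, per-plant metrics
#' are stacked, and each of the four response models is fitted with the
#' interaction LRT and the singular-fit fallback applied.
#'
#' @param dataset list of filtered [assemblage()] objects.
#' @param tt a [tax_tree()] covering all plants.
#' @param scopes character subset of `c("all", "endophage", "exophage")`.
#' @param alpha LRT significance threshold.
#' @param exclude_self passed to metric construction.
#' @param require_eligible_subassemblages drop guild sub-assemblages that
#'   fail the eligibility criteria after splitting (default keeps them,
#'   flagged, mirroring the ambiguity in the screening design).
#' @return list with data.frames `models`, `lrt`, `r2`, and `metrics`
#'   (the stacked per-plant tables with a `guild_scope` column).
#' @export
run_full_analysis <- function(dataset, tt,
                              scopes = c("all", "endophage", "exophage"),
                              alpha = 0.05, exclude_self = TRUE,
                              require_eligible_subassemblages = FALSE) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  dm <- patristic_matrix(tt)
  responses <- c("richness", "mean_jaccard", "mean_simpson", "mean_dprime")
  models <- list()
  lrts <- list()
  r2s <- list()
  metrics <- list()
  for (scope in scopes) {
    dat <- scope_dataset(dataset, scope, require_eligible_subassemblages)
    if (length(dat) == 0L) {
      warning("no usable assemblages in scope '", scope, "'", call. = FALSE)
      next
    }
    met <- do.call(rbind, lapply(dat, function(a) {
      build_plant_metrics(a, tt, exclude_self = exclude_self, dist_matrix = dm)
    }))
    met$guild_scope <- scope
    metrics[[scope]] <- met
    for (resp in responses) {
      res <- tryCatch({
        spec <- model_spec(resp)
        ans <- lrt_interaction(met, spec, alpha = alpha)
        fit <- fallback_if_singular(ans$fit)
        list(ans = ans, fit = fit)
      }, error = function(e) {
        warning("model for '", resp, "' in scope '", scope, "' failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      fit <- res$fit
      co <- fit$coefficients
      co$scope <- scope
      co$response <- resp
      co$re_variance <- fit$re_variance
      co$re_sd <- fit$re_sd
      models[[paste(scope, resp)]] <- co
      lr <- res$ans$lrt
      lr$scope <- scope
      lr$response <- resp
      lrts[[paste(scope, resp)]] <- lr
      r2row <- data.frame(scope = scope, response = resp,
                          r2_marginal = NA_real_, r2_conditional = NA_real_,
                          mcfadden = NA_real_,
                          fallback_used = fit$fallback_used)
      if (fit$fallback_used) {
        r2row$mcfadden <- fit$mcfadden
      } else {
        r2 <- r2_nakagawa(fit)
        r2row$r2_marginal <- r2[["marginal"]]
        r2row$r2_conditional <- r2[["conditional"]]
      }
      r2s[[paste(scope, resp)]] <- r2row
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(models = bind(models), lrt = bind(lrts), r2 = bind(r2s),
       metrics = bind(metrics))
}

scope_dataset <- function(dataset, scope, require_eligible) {
  if (scope == "all") {
    return(Filter(function(a) check_eligibility(a)$passed, dataset))
  }
  subs <- lapply(dataset, function(a) split_by_guild(a)[[scope]])
  subs <- Filter(function(a) n_plants(a) > 0 && n_herbivores(a) > 0, subs)
  if (require_eligible) {
    subs <- Filter(function(a) isTRUE(attr(a, "eligible_after_split")), subs)
  }
  # modeling still needs >= 2 origins and >= 1 native comparator per plant;
  # degenerate sub-assemblages surface as NA rows downstream
  subs
}
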