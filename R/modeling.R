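# Association modelling: covariate residualization, exhaustive-subset
# cross-validated variable selection over the 12 Near/Far connectivity
# variables, and the final OLS association, moderation, variance-partition
# and likelihood-ratio analyses. Ordinary model machinery (lm, Type-II
# partial sums of squares via car::Anova, log-likelihoods) is delegated to
# base R and car; the selection procedure itself is implemented here.

#' Partial eta-squared from sums of squares
#'
#' `SS_effect / (SS_effect + SS_residual)`: the variance-explained effect
#' size reported per predictor.
#'
#' @param ss_effect,ss_residual Sums of squares.
#' @return Partial eta-squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(9.67, 76.05)  # ~0.11
#' @export
partial_eta_sq <- function(ss_effect, ss_residual) {
  abort_if(any(ss_effect < 0) || any(ss_residual < 0), "sums of squares must be >= 0")
  ss_effect / (ss_effect + ss_residual)
}

#' Regress covariates out of a set of variables
#'
#' Each variable is replaced by the residuals of its OLS regression on the
#' covariates (plus intercept).
#'
#' @param table Modelling table.
#' @param vars Variables to residualize.
#' @param covariates Covariate columns. Default `sex`, `age_5mo`,
#'   `likelihood`.
#' @return The table with the named variables residualized.
#' @export
residualize <- function(table, vars,
                        covariates = c("sex", "age_5mo", "likelihood")) {
  abort_if(!all(covariates %in% names(table)), "missing covariate column(s): ",
           paste(setdiff(covariates, names(table)), collapse = ", "))
  abort_if(!all(vars %in% names(table)), "missing variable column(s): ",
           paste(setdiff(vars, names(table)), collapse = ", "))
  X <- stats::model.matrix(~ ., data = table[, covariates, drop = FALSE])
  abort_if(anyNA(X) || anyNA(as.matrix(table[, vars])),
           "missing values in variables or covariates; subset to complete cases first")
  abort_if(qr(X)$rank < ncol(X), "rank-deficient covariate matrix")
  for (v in vars) {
    table[[v]] <- unname(stats::lm.fit(X, table[[v]])$residuals)
  }
  table
}

# All 2^p subsets of seq_len(p) as index vectors (bit order: subset id - 1).
enumerate_subsets <- function(p) {
  lapply(0:(2^p - 1), function(m) which(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) > 0))
}

# Fold assignment for one repeat: stratified round-robin after shuffling.
make_folds <- function(n, folds, strata = NULL) {
  fold_id <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  pos <- 0L
  for (s in split(seq_len(n), strata)) {
    s <- s[sample.int(length(s))]
    fold_id[s] <- ((pos + seq_along(s) - 1L) %% folds) + 1L
    pos <- pos + length(s)
  }
  fold_id
}

#' Exhaustive-subset variable selection by repeated k-fold cross-validation
#'
#' All `2^p` subsets of the candidate variables (including the empty and full
#' sets) are fitted as OLS regressions of the outcome and scored by repeated
#' k-fold cross-validated R-squared. The 100 best-scoring subsets are kept,
#' the frequency of each variable among them is tallied, and the most
#' frequent `top_vars` variables are selected.
#'
#' @param table Modelling table (complete cases are taken over the columns
#'   used).
#' @param outcome Outcome column. Default `"ados_css_total"`.
#' @param candidates Candidate variable names (default: the 12 Near/Far
#'   variables present in `table`).
#' @param folds,repeats CV configuration. Defaults 10 and 10; each repeat
#'   uses a different random fold split.
#' @param top_models Number of best subsets tallied. Default 100.
#' @param top_vars Number of variables selected. Default 5.
#' @param seed RNG seed for the fold splits.
#' @param stratify_by Optional column used to stratify fold assignment
#'   (default `"group"` when present; small-n stability).
#' @param cv_method `"pooled"` (default: out-of-fold residuals pooled within
#'   a repeat, R2 = 1 - SSE/SST over all held-out predictions) or
#'   `"per_fold"` (per-fold R2 against the held-out fold mean, averaged).
#' @return A `selection_result`: `n_subsets`, `mean_cv_r2` (per subset),
#'   `top_models` (data frame of the best subsets), `variable_frequency`,
#'   `selected`, and the CV configuration.
#' @export
cv_subset_selection <- function(table, outcome = "ados_css_total",
                                candidates = intersect(modeling_variable_names(),
                                                       names(table)),
                                folds = 10L, repeats = 10L,
                                top_models = 100L, top_vars = 5L, seed = 1L,
                                stratify_by = if ("group" %in% names(table)) "group" else NULL,
                                cv_method = c("pooled", "per_fold")) {
  cv_method <- match.arg(cv_method)
  abort_if(length(candidates) == 0L, "empty candidate list")
  abort_if(!outcome %in% names(table), "outcome column '", outcome, "' not found")
  cols <- c(outcome, candidates, stratify_by)
  use <- stats::complete.cases(table[, cols, drop = FALSE])
  tab <- table[use, , drop = FALSE]
  n <- nrow(tab)
  abort_if(n < folds, "need at least `folds` (= ", folds, ") complete cases, have ", n)
  y <- tab[[outcome]]
  X <- as.matrix(tab[, candidates, drop = FALSE])
  p <- length(candidates)
  subsets <- enumerate_subsets(p)
  n_subsets <- length(subsets)
  strata <- if (!is.null(stratify_by)) tab[[stratify_by]] else NULL
  sst_all <- sum((y - mean(y))^2)
  r2 <- matrix(0, n_subsets, repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- make_folds(n, folds, strata)
      sse <- numeric(n_subsets)
      r2f <- numeric(n_subsets)
      for (f in seq_len(folds)) {
        te <- fold_id == f
        Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        ytr <- y[!te]; yte <- y[te]
        sst_f <- sum((yte - mean(yte))^2)
        for (s in seq_len(n_subsets)) {
          js <- subsets[[s]]
          A <- cbind(1, Xtr[, js, drop = FALSE])
          beta <- stats::lm.fit(A, ytr)$coefficients
          beta[is.na(beta)] <- 0
          pred <- drop(cbind(1, Xte[, js, drop = FALSE]) %*% beta)
          e2 <- sum((yte - pred)^2)
          sse[s] <- sse[s] + e2
          if (cv_method == "per_fold")
            r2f[s] <- r2f[s] + (1 - e2 / sst_f)
        }
      }
      r2[, r] <- if (cv_method == "pooled") 1 - sse / sst_all else r2f / folds
    }
  })
  mean_r2 <- rowMeans(r2)
  ord <- order(-mean_r2, seq_len(n_subsets))  # deterministic tie-break
  top_idx <- ord[seq_len(min(top_models, n_subsets))]
  top_df <- data.frame(
    subset_id = top_idx,
    variables = vapply(top_idx, function(i)
      paste(candidates[subsets[[i]]], collapse = "+"), character(1)),
    n_vars = vapply(top_idx, function(i) length(subsets[[i]]), integer(1)),
    mean_cv_r2 = mean_r2[top_idx],
    stringsAsFactors = FALSE
  )
  freq <- vapply(seq_len(p), function(j)
    sum(vapply(top_idx, function(i) j %in% subsets[[i]], logical(1))), integer(1))
  names(freq) <- candidates
  # tie-break: mean CV R2 of the top subsets containing the variable, then name
  tie_r2 <- vapply(seq_len(p), function(j) {
    has <- vapply(top_idx, function(i) j %in% subsets[[i]], logical(1))
    if (any(has)) mean(mean_r2[top_idx[has]]) else -Inf
  }, numeric(1))
  sel_ord <- order(-freq, -tie_r2, candidates)
  selected <- candidates[sel_ord[seq_len(min(top_vars, p))]]
  structure(list(n_subsets = n_subsets, mean_cv_r2 = mean_r2,
                 top_models = top_df, variable_frequency = freq,
                 selected = selected, n = n,
                 config = list(outcome = outcome, folds = folds,
                               repeats = repeats, top_models = top_models,
                               top_vars = top_vars, seed = seed,
                               cv_method = cv_method,
                               stratify_by = stratify_by)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Subset selection: %d subsets, %d-fold CV x %d repeats (n = %d)\n",
              x$n_subsets, x$config$folds, x$config$repeats, x$n))
  cat("Variable frequency among top", nrow(x$top_models), "models:\n")
  print(sort(x$variable_frequency, decreasing = TRUE))
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# Fit an OLS model and package coefficients, Type-II partial SS, partial
# eta^2, p-values, R^2 and log-likelihood.
fit_ols <- function(table, rhs_terms, outcome, kappa_warn = 1e3) {
  cols <- unique(c(outcome, unlist(strsplit(rhs_terms, ":", fixed = TRUE))))
  use <- stats::complete.cases(table[, cols, drop = FALSE])
  tab <- table[use, , drop = FALSE]
  fml <- stats::reformulate(rhs_terms, response = outcome)
  fit <- stats::lm(fml, data = tab)
  X <- stats::model.matrix(fit)
  sv <- svd(scale(X[, -1, drop = FALSE]))$d
  cond <- if (length(sv) && min(sv) > 0) max(sv) / min(sv) else Inf
  if (cond > kappa_warn)
    warning("ill-conditioned design (condition number ", signif(cond, 3), ")")
  abort_if(fit$df.residual < 1,
           "saturated model: no residual degrees of freedom (n = ", nrow(tab),
           ", parameters = ", length(stats::coef(fit)), ")")
  an <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    # degenerate case (zero residual SS): partial SS via term deletion
    d1 <- suppressWarnings(stats::drop1(fit))
    data.frame(`Sum Sq` = c(d1[["Sum of Sq"]][-1], stats::deviance(fit)),
               Df = c(d1$Df[-1], fit$df.residual),
               `Pr(>F)` = NA_real_, check.names = FALSE,
               row.names = c(rownames(d1)[-1], "Residuals"))
  })
  ss <- pmax(an[["Sum Sq"]], 0)  # guard tiny negative SS from exact fits
  names(ss) <- rownames(an)
  ss_res <- ss[["Residuals"]]
  terms <- setdiff(rownames(an), "Residuals")
  eta2 <- partial_eta_sq(ss[terms], ss_res)
  sm <- summary(fit)
  anova_tab <- data.frame(term = rownames(an), sum_sq = an[["Sum Sq"]],
                          df = an[["Df"]], p = an[["Pr(>F)"]],
                          stringsAsFactors = FALSE)
  structure(list(model = fit, outcome = outcome, terms = terms,
                 coefficients = stats::coef(fit),
                 p_values = sm$coefficients[, "Pr(>|t|)"],
                 partial_eta2 = eta2,
                 anova = anova_tab,
                 r_squared = sm$r.squared,
                 ss_residual = ss_res,
                 df_residual = fit$df.residual,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(tab), condition_number = cond),
            class = "fit_result")
}

#' Fit the main-effect association model
#'
#' OLS of the outcome on the selected connectivity predictors plus
#' covariates, reporting per-predictor beta, two-sided t p-values, Type-II
#' partial sums of squares and partial eta-squared, model R-squared and
#' log-likelihood.
#'
#' @param table Modelling table.
#' @param predictors Selected connectivity variables.
#' @param covariates Covariates entering the fit. Default `likelihood`,
#'   `sex`, `age_5mo`; use `character(0)` for none.
#' @param outcome Outcome column. Default `"ados_css_total"`.
#' @return A `fit_result`.
#' @export
fit_main_model <- function(table, predictors,
                           covariates = c("likelihood", "sex", "age_5mo"),
                           outcome = "ados_css_total") {
  abort_if(length(predictors) == 0L, "no predictors")
  fit_ols(table, c(covariates, predictors), outcome)
}

#' Fit the moderation model (predictor x moderator interactions)
#'
#' Expands the main-effect model with interaction terms between each
#' connectivity predictor and a binary moderator (autism likelihood status by
#' default).
#'
#' @inheritParams fit_main_model
#' @param moderator Binary moderator column. Default `"likelihood"`.
#' @return A `fit_result` including the interaction terms.
#' @export
fit_moderation_model <- function(table, predictors,
                                 covariates = c("likelihood", "sex", "age_5mo"),
                                 moderator = "likelihood",
                                 outcome = "ados_css_total") {
  abort_if(!moderator %in% names(table), "moderator column not found")
  mv <- stats::na.omit(table[[moderator]])
  abort_if(length(unique(mv)) < 2L, "moderator is constant")
  abort_if(length(unique(mv)) > 2L, "moderator must be binary")
  rhs <- c(union(covariates, moderator), predictors,
           paste0(predictors, ":", moderator))
  fit_ols(table, rhs, outcome)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("OLS fit: %s ~ %s (n = %d, R2 = %.3f)\n", x$outcome,
              paste(x$terms, collapse = " + "), x$n, x$r_squared))
  tab <- data.frame(beta = round(x$coefficients[-1], 3),
                    p = signif(x$p_values[-1], 3))
  eta <- x$partial_eta2[match(rownames(tab), names(x$partial_eta2))]
  tab$partial_eta2 <- round(eta, 3)
  print(tab)
  invisible(x)
}

#' Side-by-side ANOVA comparison of nested models
#'
#' Lays out per-predictor Type-II sums of squares and p-values of a model
#' before and after adding extra predictor(s), plus the residual SS and
#' degrees of freedom, so shifts in variance attribution can be read off
#' directly.
#'
#' @param fit_without,fit_with Nested `fit_result`s on the same rows.
#' @return Data frame with columns `term`, `ss_without`, `p_without`,
#'   `ss_with`, `p_with` (Residuals and df as final rows).
#' @export
compare_models_anova <- function(fit_without, fit_with) {
  abort_if(!inherits(fit_without, "fit_result") || !inherits(fit_with, "fit_result"),
           "inputs must be fit_results")
  abort_if(fit_without$n != fit_with$n, "models were fitted on different rows")
  abort_if(!all(fit_without$terms %in% fit_with$terms),
           "models are not nested: '",
           paste(setdiff(fit_without$terms, fit_with$terms), collapse = ", "),
           "' absent from the larger model")
  a0 <- fit_without$anova; a1 <- fit_with$anova
  terms <- setdiff(a1$term, "Residuals")
  out <- data.frame(
    term = c(terms, "Residuals", "df"),
    ss_without = c(a0$sum_sq[match(terms, a0$term)], fit_without$ss_residual,
                   fit_without$df_residual),
    p_without = c(a0$p[match(terms, a0$term)], NA, NA),
    ss_with = c(a1$sum_sq[match(terms, a1$term)], fit_with$ss_residual,
                fit_with$df_residual),
    p_with = c(a1$p[match(terms, a1$term)], NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Nested likelihood-ratio test of two OLS fits
#'
#' `2 * (loglik_full - loglik_reduced)` referred to a chi-squared
#' distribution with df equal to the parameter difference.
#'
#' @param reduced,full Nested `fit_result`s on the same rows.
#' @return List with `chi2`, `df`, `p`.
#' @export
lr_test <- function(reduced, full) {
  abort_if(reduced$n != full$n, "models were fitted on different rows")
  abort_if(!all(reduced$terms %in% full$terms), "models are not nested")
  df <- reduced$df_residual - full$df_residual
  abort_if(df < 0, "the 'full' model has fewer parameters than the 'reduced' one")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  abort_if(chi2 < -1e-6, "full model has lower likelihood; fits are not nested")
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Variable selection and association model for the motion-laterality outcome
#'
#' Runs the same exhaustive-subset CV selection with the Global Motion
#' Laterality Score as the outcome and then fits the final OLS on the
#' selected connectivity predictors with no covariates (the covariates are
#' expected to have been regressed out of all variables beforehand with
#' [residualize()]).
#'
#' @param table Modelling table with a `gmls` column (pre-residualized).
#' @param candidates Candidate connectivity variables.
#' @param ... Passed to [cv_subset_selection()].
#' @return List with `selection` (a `selection_result`) and `fit` (a
#'   `fit_result`).
#' @export
gmls_association <- function(table,
                             candidates = intersect(modeling_variable_names(),
                                                    names(table)), ...) {
  abort_if(!"gmls" %in% names(table), "`table` lacks a gmls column")
  sel <- cv_subset_selection(table, outcome = "gmls", candidates = candidates, ...)
  fit <- fit_main_model(table, predictors = sel$selected,
                        covariates = character(0), outcome = "gmls")
  list(selection = sel, fit = fit)
}
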