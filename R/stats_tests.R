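# Permutation tests of topographic group and stimulus differences,
# Kruskal-Wallis and Wilcoxon rank tests, and Benjamini-Hochberg FDR
# correction. Permutation p-values use the add-one estimator
# p = (1 + #{|perm| >= |obs|}) / (n_perm + 1), which can never be exactly 0,
# and the reported effect size d is the observed mean difference divided by
# the standard deviation of the permutation distribution.

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values (monotone, `>=` the raw p-values).
#' @export
fdr_bh <- function(pvals) {
  abort_if(!is.numeric(pvals) || any(!is.finite(pvals)) ||
             any(pvals < 0 | pvals > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Shared tail computation for permutation tests.
perm_summary <- function(obs, perm, n_perm, seed, comparison) {
  d_sd <- apply(perm, 1, stats::sd)
  p <- vapply(seq_along(obs), function(i)
    (1 + sum(abs(perm[i, ]) >= abs(obs[i]) - 1e-12)) / (n_perm + 1), numeric(1))
  res <- data.frame(aoi = names(obs), obs_diff = unname(obs),
                    d = unname(obs) / ifelse(d_sd > 0, d_sd, NA_real_),
                    p = p, q = fdr_bh(p), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(comparison = comparison, table = res, n_perm = n_perm,
                 seed = seed, perm_sd = d_sd),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test:", x$comparison, sprintf("(B = %d, seed = %s)\n",
                                                 x$n_perm, format(x$seed)))
  print(transform(x$table, obs_diff = round(obs_diff, 4), d = round(d, 2),
                  p = signif(p, 3), q = signif(q, 3)))
  invisible(x)
}

#' Permutation test of a pairwise group difference in topographic patterns
#'
#' The full three-group labelling is shuffled `n_perm` times; for each shuffle
#' the per-AoI difference in mean (normalized, flipped) scores between the
#' requested pair of relabelled groups is recorded, and the observed
#' difference is referred to the empirical permutation distribution
#' (two-sided). q-values are BH-adjusted across the AoIs of this comparison.
#'
#' @param values Numeric participant x AoI matrix (columns in canonical AoI
#'   order) of normalized-flipped topography scores.
#' @param labels Group label per participant (3 groups).
#' @param pair Character vector of length 2: the two groups to compare
#'   (difference is `mean(pair[1]) - mean(pair[2])`).
#' @param n_perm Number of label shuffles. Default 10000.
#' @param seed RNG seed for the shuffles.
#' @return A `permutation_result` with per-AoI `obs_diff`, `d`, `p`, `q`.
#' @export
permutation_group_test <- function(values, labels, pair, n_perm = 10000L,
                                   seed = 1L) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  abort_if(nrow(values) != length(labels), "one label per row of `values` required")
  abort_if(length(pair) != 2L || !all(pair %in% labels),
           "`pair` must name two non-empty groups")
  abort_if(min(table(labels)[pair]) < 2L, "need >= 2 participants per group")
  if (is.null(colnames(values))) colnames(values) <- aoi_levels(ncol(values) %/% 2)
  wA <- (labels == pair[1]) / sum(labels == pair[1])
  wB <- (labels == pair[2]) / sum(labels == pair[2])
  obs <- drop(crossprod(values, wA - wB))
  W <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      lp <- sample(labels)
      (lp == pair[1]) / sum(lp == pair[1]) - (lp == pair[2]) / sum(lp == pair[2])
    }, numeric(length(labels)))
  })
  perm <- crossprod(values, W)  # AoI x n_perm
  perm_summary(obs, perm, n_perm, seed,
               comparison = paste(pair[1], "vs", pair[2]))
}

#' Paired permutation test of a stimulus difference in topographic patterns
#'
#' Within-participant condition labels (social vs non-social) are randomly
#' swapped; the observed per-AoI mean (social - nonsocial) difference is
#' referred to the resulting sign-flip distribution.
#'
#' @param social,nonsocial Participant x AoI matrices with matching rows
#'   (same participants, same order).
#' @param n_perm Number of label swaps. Default 10000.
#' @param seed RNG seed.
#' @return A `permutation_result`.
#' @export
permutation_stimulus_test <- function(social, nonsocial, n_perm = 10000L,
                                      seed = 1L) {
  social <- as.matrix(social); nonsocial <- as.matrix(nonsocial)
  abort_if(!identical(dim(social), dim(nonsocial)),
           "`social` and `nonsocial` must be matched participant x AoI matrices")
  if (!is.null(rownames(social)) && !is.null(rownames(nonsocial)))
    abort_if(!identical(rownames(social), rownames(nonsocial)),
             "participants of the two conditions do not match")
  n <- nrow(social)
  abort_if(n < 2L, "need >= 2 participants")
  D <- social - nonsocial
  if (is.null(colnames(D))) colnames(D) <- aoi_levels(ncol(D) %/% 2)
  obs <- colMeans(D)
  S <- with_seed(seed, matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n))
  perm <- crossprod(D, S) / n
  perm_summary(obs, perm, n_perm, seed, comparison = "social vs nonsocial")
}

#' Kruskal-Wallis test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-squared
#' p with k-1 df). Degenerate all-identical input returns H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  abort_if(nlevels(droplevels(groups)) < 2L, "need >= 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Wilcoxon rank-sum tests of group differences in connectivity asymmetry
#'
#' For each band x stimulus condition, right-minus-left asymmetry scores are
#' compared between every pair of groups with a Wilcoxon rank-sum test;
#' q-values are BH-adjusted within each band x stimulus family (the family
#' definition is configurable). The effect size `d` is the standardized mean
#' difference (pooled SD).
#'
#' @param scores Data frame with columns `participant`, `group`, `value` and
#'   optionally `band`, `stimulus`.
#' @param family `"condition"` (default: BH within each band x stimulus) or
#'   `"global"` (across all comparisons).
#' @return Data frame of pairwise comparisons: condition columns, `group1`,
#'   `group2`, `n1`, `n2`, `median_diff`, `d`, `W`, `p`, `q`.
#' @export
wilcoxon_asymmetry <- function(scores, family = c("condition", "global")) {
  family <- match.arg(family)
  abort_if(!all(c("group", "value") %in% names(scores)),
           "`scores` needs columns group, value")
  abort_if(any(!is.finite(scores$value)), "asymmetry scores must be finite")
  cond_cols <- intersect(c("band", "stimulus"), names(scores))
  key <- if (length(cond_cols)) interaction(scores[cond_cols], drop = TRUE)
         else factor(rep("all", nrow(scores)))
  res <- lapply(split(scores, key), function(d) {
    gs <- sort(unique(as.character(d$group)))
    abort_if(any(table(d$group) == 0), "empty group")
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      x <- d$value[d$group == pr[1]]; y <- d$value[d$group == pr[2]]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                   (length(x) + length(y) - 2))
      out <- data.frame(group1 = pr[1], group2 = pr[2],
                        n1 = length(x), n2 = length(y),
                        median_diff = stats::median(x) - stats::median(y),
                        d = if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_,
                        W = unname(wt$statistic), p = wt$p.value,
                        stringsAsFactors = FALSE)
      for (cc in rev(cond_cols)) out <- cbind(stats::setNames(d[1, cc, drop = FALSE], cc), out)
      out
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (family == "condition" && length(cond_cols)) {
    key2 <- interaction(out[cond_cols], drop = TRUE)
    out$q <- stats::ave(out$p, key2, FUN = fdr_bh)
  } else {
    out$q <- fdr_bh(out$p)
  }
  out
}

#' Write permutation results as TSV and JSON
#'
#' @param results List of `permutation_result` objects.
#' @param path_tsv,path_json Optional output paths.
#' @return The combined data frame, invisibly when written.
#' @export
write_permutation_results <- function(results, path_tsv = NULL, path_json = NULL) {
  rows <- lapply(results, function(r)
    cbind(comparison = r$comparison, r$table, n_perm = r$n_perm, seed = r$seed))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path_tsv))
    utils::write.table(out, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  if (is.null(path_tsv) && is.null(path_json)) out else invisible(out)
}
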