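#' Analysis configuration
#'
#' Collects the tunable parameters of the statistical cascade and of the
#' geometric quantification in one place.
#'
#' @param alpha Significance level for variable selection and reporting.
#' @param prune_threshold Spearman |rho| above which features are treated
#'   as redundant (default 0.9).
#' @param n_boot Bootstrap replicates for the AUC confidence interval.
#' @param seed Integer seed driving all randomness (bootstrap, simulation).
#' @param welch Use Welch's t-test instead of the pooled-variance Student
#'   t-test in group comparison.
#' @param n_rays Rays per frame for quantification.
#' @param conf Confidence level for intervals.
#' @return A list of class `oct_config`.
#' @export
oct_config <- function(alpha = 0.05, prune_threshold = 0.9, n_boot = 2000L,
                       seed = 1L, welch = FALSE, n_rays = 360L,
                       conf = 0.95) {
  stopifnot(alpha > 0, alpha < 1, prune_threshold > 0, n_boot >= 200L,
            conf > 0, conf < 1)
  structure(list(alpha = alpha, prune_threshold = prune_threshold,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 welch = welch, n_rays = as.integer(n_rays), conf = conf),
            class = "oct_config")
}

.cohort_feature_cols <- function(table) {
  intersect(oct_feature_keys(), colnames(table))
}

.check_outcome <- function(table) {
  if (!"outcome" %in% colnames(table)) stop("cohort table lacks an 'outcome' column")
  y <- table$outcome
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  invisible(as.integer(y))
}

#' Group comparison of plaque features by outcome
#'
#' Compares every feature between the event and no-event groups:
#' continuous features with a two-sample t-test (pooled variance by
#' default, Welch optionally) reported as mean +/- SD per group;
#' binary features with a Pearson chi-square test without continuity
#' correction, reported as count (percent). Missing values are dropped per
#' feature; a zero-variance feature gets `NA` with a warning.
#'
#' @param table Cohort data.frame with feature columns (keys of
#'   [oct_features()]) and a 0/1 `outcome` column.
#' @param welch Use Welch's t-test for continuous features.
#' @return data.frame: `feature`, `label`, `type`, `event_summary`,
#'   `noevent_summary`, `statistic`, `p_value`.
#' @export
compare_groups <- function(table, welch = FALSE) {
  y <- .check_outcome(table)
  reg <- oct_features()
  keys <- .cohort_feature_cols(table)
  res <- lapply(keys, function(k) {
    x <- table[[k]]
    keep <- !is.na(x)
    xk <- x[keep]; yk <- y[keep]
    type <- reg$type[match(k, reg$key)]
    summ <- function(v) {
      if (type == "continuous")
        sprintf("%.3g ± %.3g", mean(v), stats::sd(v))
      else sprintf("%d (%.1f%%)", sum(v == 1), 100 * mean(v == 1))
    }
    out <- data.frame(feature = k, label = .key_to_label(k), type = type,
                      event_summary = summ(xk[yk == 1]),
                      noevent_summary = summ(xk[yk == 0]),
                      statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (type == "continuous") {
      if (stats::sd(xk) == 0) {
        warning("feature '", k, "' has zero variance; p set to NA")
        return(out)
      }
      tt <- stats::t.test(xk[yk == 1], xk[yk == 0], var.equal = !welch)
      out$statistic <- unname(tt$statistic); out$p_value <- tt$p.value
    } else {
      tb <- table(factor(xk, levels = c(0, 1)), factor(yk, levels = c(0, 1)))
      if (any(rowSums(tb) == 0)) {
        warning("feature '", k, "' has zero variance; p set to NA")
        return(out)
      }
      ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
      out$statistic <- unname(ct$statistic); out$p_value <- ct$p.value
    }
    out
  })
  do.call(rbind, res)
}

#' Redundancy pruning by Spearman correlation
#'
#' Computes the pairwise Spearman |rho| matrix over all features, orders it
#' by average-linkage hierarchical clustering on distance `1 - |rho|` (the
#' heatmap ordering), groups features into connected components of the
#' graph linking pairs with `|rho| > threshold`, and within each component
#' retains the most representative member — the one with the highest
#' median |rho| to the other members, which keeps a total (e.g. the
#' all-thickness cap surface area) over its near-duplicate class
#' components — dropping the rest. Ties break deterministically by the
#' standard feature order. Pruning depends only on the feature matrix,
#' never on the outcome. Constant features are excluded from the
#' correlation with a warning.
#'
#' @param table Cohort data.frame of features (an `outcome` column, if
#'   present, is ignored).
#' @param threshold Redundancy threshold on |rho| (default 0.9).
#' @return List: `retained`, `dropped` (character vectors in feature
#'   order), `rho` (correlation matrix), `linkage` (`hclust`),
#'   `components` (list of redundant groups).
#' @export
spearman_prune <- function(table, threshold = 0.9) {
  keys <- .cohort_feature_cols(table)
  const <- keys[vapply(keys, function(k)
    stats::sd(table[[k]], na.rm = TRUE) == 0 ||
      all(is.na(table[[k]])), logical(1))]
  if (length(const))
    warning("constant feature(s) excluded from correlation: ",
            paste(const, collapse = ", "))
  keys <- setdiff(keys, const)
  if (length(keys) < 2L) stop("need at least 2 non-constant features")
  X <- as.matrix(table[keys])
  rho <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  arho <- abs(rho)
  linkage <- stats::hclust(stats::as.dist(1 - arho), method = "average")

  adj <- arho > threshold
  diag(adj) <- FALSE
  # connected components of the redundancy graph
  comp <- rep(NA_integer_, length(keys))
  cid <- 0L
  for (i in seq_along(keys)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  retained <- character(0); dropped <- character(0); groups <- list()
  for (g in unique(comp)) {
    members <- keys[comp == g]
    if (length(members) == 1L) { retained <- c(retained, members); next }
    groups[[length(groups) + 1L]] <- members
    centrality <- vapply(members, function(m)
      stats::median(arho[m, setdiff(members, m)]), numeric(1))
    best <- members[order(-centrality,
                          match(members, oct_feature_keys()))][1]
    retained <- c(retained, best)
    dropped <- c(dropped, setdiff(members, best))
  }
  ord <- function(v) v[order(match(v, oct_feature_keys()))]
  list(retained = ord(retained), dropped = ord(dropped), rho = rho,
       linkage = linkage, components = groups)
}

.fit_logistic_one <- function(y, X) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = as.data.frame(X), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # diverging slope estimates are (quasi-)separation even when glm stops
  # inside its iteration cap without warning
  co <- stats::coef(fit)
  slopes <- co[setdiff(names(co), "(Intercept)")]
  if (any(!is.na(slopes) & abs(slopes) > 15)) sep <- TRUE
  list(fit = fit, separation = sep)
}

#' Univariate logistic regression per feature
#'
#' Fits a single-predictor maximum-likelihood logistic model of the
#' outcome on each feature and reports the odds ratio with a Wald
#' confidence interval. Complete or quasi-complete separation is flagged
#' (`separation = TRUE`, with the diverging interval reported as
#' `[0, Inf]`), not raised as an error.
#'
#' @param table Cohort data.frame (features + `outcome`).
#' @param features Feature keys to fit (default: all present).
#' @param conf Confidence level (default 0.95).
#' @return data.frame: `feature`, `p_value`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `separation`.
#' @export
univariate_logistic <- function(table, features = NULL, conf = 0.95) {
  y <- .check_outcome(table)
  if (is.null(features)) features <- .cohort_feature_cols(table)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  res <- lapply(features, function(k) {
    x <- table[[k]]
    keep <- !is.na(x)
    r <- .fit_logistic_one(y[keep], data.frame(x = x[keep]))
    cf <- summary(r$fit)$coefficients
    b <- cf["x", "Estimate"]; se <- cf["x", "Std. Error"]
    p <- cf["x", "Pr(>|z|)"]
    lo <- exp(b - zq * se); hi <- exp(b + zq * se)
    if (r$separation) { lo <- 0; hi <- Inf }
    data.frame(feature = k, p_value = p, odds_ratio = exp(b),
               ci_low = lo, ci_high = hi, separation = r$separation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Multivariate logistic regression on selected features
#'
#' Joint maximum-likelihood logistic fit of the outcome on the selected
#' features (conventionally those with univariate p below alpha), with
#' Wald statistics and confidence intervals. A rank-deficient design is an
#' error naming the collinear columns. When the events-per-variable ratio
#' falls below 10 a warning is emitted (small-sample Wald inference is
#' fragile), mirroring standard epidemiological practice.
#'
#' @param table Cohort data.frame (features + `outcome`).
#' @param selected Character vector of feature keys to include jointly.
#' @param conf Confidence level.
#' @return data.frame: `feature`, `p_value`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `separation` (fit-level flag, repeated per row).
#' @export
multivariate_logistic <- function(table, selected, conf = 0.95) {
  y <- .check_outcome(table)
  if (length(selected) < 1L) stop("no features selected")
  X <- table[selected]
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; yk <- y[keep]
  if (sum(yk) / length(selected) < 10)
    warning(sprintf(
      "events-per-variable ratio %.1f < 10; Wald inference may be unstable",
      sum(yk) / length(selected)))
  if (nrow(X) <= length(selected))
    stop("fewer records than predictors")
  r <- .fit_logistic_one(yk, X)
  co <- stats::coef(r$fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(r$fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- rownames(cf) != "(Intercept)"
  b <- cf[rows, "Estimate"]; se <- cf[rows, "Std. Error"]
  data.frame(feature = selected, p_value = cf[rows, "Pr(>|z|)"],
             odds_ratio = exp(b), ci_low = exp(b - zq * se),
             ci_high = exp(b + zq * se), separation = r$separation,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC analysis with bootstrap confidence interval and optimal cutoff
#'
#' Empirical AUC in the Mann-Whitney formulation (ties counted half), a
#' stratified percentile bootstrap confidence interval (cases and controls
#' resampled separately), and the operating point maximizing
#' sensitivity + specificity over the observed thresholds (a positive call
#' is `score >= threshold`; ties broken toward the smallest threshold,
#' i.e. the more sensitive cutoff).
#'
#' @param scores Numeric risk scores, one per lesion.
#' @param outcome 0/1 outcome vector.
#' @param n_boot Bootstrap replicates (>= 200; default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return Object of class `oct_roc`: `auc`, `ci_low`, `ci_high`,
#'   `optimal_cutoff`, `sensitivity_at_cutoff`, `specificity_at_cutoff`,
#'   `points` (data.frame threshold/sensitivity/specificity), `n_boot`.
#' @export
roc_analysis <- function(scores, outcome, n_boot = 2000L, seed = NULL,
                         conf = 0.95) {
  stopifnot(length(scores) == length(outcome), n_boot >= 200L)
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- as.integer(outcome[keep])
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")

  auc_mw <- function(x, y) {
    r <- rank(x)
    n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_mw(scores, outcome)

  thr <- sort(unique(scores))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  # cumulative counts below each threshold give sens/spec in O(n log n)
  c1 <- vapply(split(outcome, factor(scores, levels = thr)),
               sum, numeric(1))
  c0 <- vapply(split(1 - outcome, factor(scores, levels = thr)),
               sum, numeric(1))
  below1 <- unname(c(0, cumsum(c1))[seq_along(thr)])
  below0 <- unname(c(0, cumsum(c0))[seq_along(thr)])
  sens <- (n1 - below1) / n1
  spc <- below0 / n0
  j <- sens + spc
  best <- which(j == max(j))[1]   # thresholds ascending: smallest wins ties

  if (!is.null(seed)) set.seed(seed)
  icase <- which(outcome == 1); ictrl <- which(outcome == 0)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(icase, n1, replace = TRUE),
           sample(ictrl, n0, replace = TRUE))
    auc_mw(scores[i], outcome[i])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)

  structure(list(auc = auc, ci_low = qs[1], ci_high = qs[2],
                 optimal_cutoff = thr[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spc[best],
                 points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spc),
                 n_boot = as.integer(n_boot)),
            class = "oct_roc")
}

#' @export
print.oct_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$ci_low, x$ci_high, x$optimal_cutoff,
              x$sensitivity_at_cutoff, x$specificity_at_cutoff))
  invisible(x)
}

#' Run the full inference cascade on a cohort table
#'
#' Executes, in order: group comparison, Spearman redundancy pruning,
#' univariate logistic regression on the retained features, multivariate
#' logistic regression on the univariate-significant features (p < alpha),
#' and ROC analysis (AUC, bootstrap CI, optimal cutoff) for each
#' multivariate-significant feature. Fully deterministic given
#' `config$seed`.
#'
#' @param table Cohort data.frame (feature columns + `outcome`).
#' @param config An [oct_config()].
#' @return Object of class `oct_report`: a list with elements `config`,
#'   `n`, `n_events`, `comparison`, `pruning`, `univariate`, `selected`,
#'   `multivariate`, `significant`, and `roc` (named list of `oct_roc`).
#' @export
run_pipeline <- function(table, config = oct_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  y <- stage("input", .check_outcome(table))
  comparison <- stage("compare_groups",
                      compare_groups(table, welch = config$welch))
  pruning <- stage("spearman_prune",
                   spearman_prune(table, threshold = config$prune_threshold))
  uni <- stage("univariate_logistic",
               univariate_logistic(table, pruning$retained,
                                   conf = config$conf))
  selected <- uni$feature[!is.na(uni$p_value) & uni$p_value < config$alpha]
  multivariate <- NULL
  significant <- character(0)
  if (length(selected)) {
    multivariate <- stage("multivariate_logistic",
                          suppressWarnings(
                            multivariate_logistic(table, selected,
                                                  conf = config$conf)))
    significant <- multivariate$feature[
      !is.na(multivariate$p_value) & multivariate$p_value < config$alpha]
  }
  roc <- list()
  for (i in seq_along(significant)) {
    k <- significant[i]
    roc[[k]] <- stage("roc_analysis",
                      roc_analysis(table[[k]], table$outcome,
                                   n_boot = config$n_boot,
                                   seed = config$seed + i,
                                   conf = config$conf))
  }
  structure(list(config = unclass(config), n = nrow(table),
                 n_events = sum(table$outcome == 1),
                 comparison = comparison, pruning = pruning,
                 univariate = uni, selected = selected,
                 multivariate = multivariate, significant = significant,
                 roc = roc),
            class = "oct_report")
}

#' @export
print.oct_report <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d lesions, %d events (%.1f%%)\n",
              x$n, x$n_events, 100 * x$n_events / x$n))
  cat(sprintf("Pruning: %d features retained, %d dropped (|rho| > %.2g)\n",
              length(x$pruning$retained), length(x$pruning$dropped),
              x$config$prune_threshold))
  cat("Univariate-significant:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat("Multivariate-significant:",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "(none)", "\n")
  for (k in names(x$roc)) {
    cat(sprintf("  %s: ", k)); print(x$roc[[k]])
  }
  invisible(x)
}
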