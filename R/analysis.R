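# Group-comparison statistics: ANOVA/ANCOVA with Tukey post hoc,
# Mann-Whitney, chi-square, Jonckheere-Terpstra trend, bootstrap comparison
# of regional involvement frequencies, and AIC-based grouping comparison.

new_group_comparison <- function(outcome, method, statistic, p_value,
                                 pairwise = NULL, details = list()) {
  stopifnot(is.null(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(outcome = outcome, method = method,
         statistic = unname(statistic), p_value = min(unname(p_value), 1),
         pairwise = pairwise, details = details),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s on '%s': statistic = %.4g, p = %.4g\n",
              x$method, x$outcome, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey-adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble::tibble(outcome = x$outcome, method = x$method,
                   statistic = x$statistic, p.value = x$p_value)
  } else {
    dplyr::mutate(x$pairwise, outcome = x$outcome, method = x$method,
                  .before = 1)
  }
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, method = x$method,
                 statistic = x$statistic, p.value = x$p_value)
}

#' Compare an outcome across amyloid groups
#'
#' One entry point for the group-comparison battery. Methods:
#' \describe{
#'   \item{`anova`}{One-way ANOVA F test across groups.}
#'   \item{`ancova_age`}{ANCOVA: linear model `outcome ~ covariates + group`,
#'     F test for the group factor after adjusting for the covariates
#'     (default `"age"`).}
#'   \item{`tukey_posthoc`}{All pairwise group contrasts with
#'     studentized-range (Tukey) adjusted p-values. Without covariates this
#'     is [stats::TukeyHSD()]; with covariates the contrasts are between
#'     covariate-adjusted means (at the cohort mean covariate values) via
#'     emmeans. The omnibus F and p are reported alongside.}
#'   \item{`mann_whitney`}{Two-group Wilcoxon rank-sum (Mann-Whitney) test:
#'     exact for small untied samples, normal approximation with tie
#'     correction otherwise.}
#'   \item{`chi_square`}{Pearson chi-square on the group-by-outcome
#'     contingency table (no continuity correction).}
#'   \item{`jonckheere`}{Jonckheere-Terpstra trend test across the ordered
#'     group levels; see [jonckheere_trend()].}
#' }
#'
#' @param data A data frame (e.g., a staged cohort joined to covariates).
#' @param outcome Name of the outcome column (numeric; categorical for
#'   `chi_square`).
#' @param method One of the methods above.
#' @param group Name of the grouping column (default `"group"`); its factor
#'   level order defines the trend direction for `jonckheere`.
#' @param covariates Character vector of adjustment covariates (used by
#'   `ancova_age` and `tukey_posthoc`; default `"age"` for `ancova_age`,
#'   none for the others).
#' @param alternative Alternative hypothesis for `mann_whitney` /
#'   `jonckheere` (default two-sided).
#' @param ... Passed to the underlying method (e.g., `n_perm`, `seed` for
#'   `jonckheere`).
#' @return A `group_comparison` object; use [tidy()] / [glance()] for tibbles.
#' @export
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 10),
#'                 age = rnorm(30, 70, 5), y = rnorm(30))
#' tidy(compare_groups(d, "y", "ancova_age"))
compare_groups <- function(data, outcome,
                           method = c("anova", "ancova_age", "tukey_posthoc",
                                      "mann_whitney", "chi_square",
                                      "jonckheere"),
                           group = "group",
                           covariates = NULL,
                           alternative = "two.sided",
                           ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), outcome %in% names(data),
            group %in% names(data))
  data <- data[!is.na(data[[outcome]]) & !is.na(data[[group]]), , drop = FALSE]
  g <- droplevels(as.factor(data[[group]]))
  y <- data[[outcome]]
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  if (any(table(g) < 2) && method != "chi_square") {
    stop("every group needs at least 2 observations")
  }

  if (method == "chi_square") {
    tab <- table(g, as.factor(y))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(new_group_comparison(outcome, method,
                                ht$statistic, ht$p.value,
                                details = list(table = tab)))
  }

  if (!is.numeric(y)) stop("outcome must be numeric for method ", method)

  if (method == "mann_whitney") {
    if (nlevels(g) != 2) stop("mann_whitney requires exactly 2 groups")
    ht <- stats::wilcox.test(y[g == levels(g)[1]], y[g == levels(g)[2]],
                             alternative = alternative, ...)
    return(new_group_comparison(outcome, method, ht$statistic, ht$p.value))
  }

  if (method == "jonckheere") {
    return(jonckheere_trend(split(y, g), outcome = outcome,
                            alternative = alternative, ...))
  }

  if (stats::var(y) == 0 && method %in% c("anova", "tukey_posthoc")) {
    stop("outcome has zero variance; ANOVA is undefined")
  }

  if (method == "anova") {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    return(new_group_comparison(outcome, method,
                                an[["F value"]][1], an[["Pr(>F)"]][1]))
  }

  if (is.null(covariates) && method == "ancova_age") covariates <- "age"
  covariates <- covariates %||% character(0)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "))
  }

  df <- data.frame(.y = y, .g = g, data[, covariates, drop = FALSE])
  rhs <- paste(c(covariates, ".g"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  an <- stats::anova(fit)  # sequential; group term last = covariate-adjusted
  f_stat <- an[".g", "F value"]
  p_group <- an[".g", "Pr(>F)"]

  if (method == "ancova_age") {
    return(new_group_comparison(outcome, method, f_stat, p_group,
                                details = list(fit = fit)))
  }

  # tukey_posthoc
  pairwise <- if (length(covariates) == 0) {
    th <- stats::TukeyHSD(stats::aov(.y ~ .g, data = df))$`.g`
    tibble::tibble(
      contrast = rownames(th),
      estimate = th[, "diff"],
      p.value = th[, "p adj"]
    )
  } else {
    emm <- emmeans::emmeans(fit, ".g")
    prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
    tibble::tibble(
      contrast = gsub("[()]", "", prs$contrast),
      estimate = prs$estimate,
      p.value = prs$p.value
    )
  }
  new_group_comparison(outcome, "tukey_posthoc", f_stat, p_group,
                       pairwise = pairwise, details = list(fit = fit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a numeric outcome across ordered groups.
#' The JT statistic is the sum of pairwise Mann-Whitney counts over all
#' ordered group pairs (ties contribute 1/2); the p-value uses the normal
#' approximation with tie-corrected variance, optionally supplemented by a
#' Monte-Carlo permutation p-value.
#'
#' @param x Either a list of numeric vectors in hypothesized order, or a data
#'   frame (then give `outcome` and `group`; the group factor's level order
#'   is the hypothesized order).
#' @param outcome,group Column names when `x` is a data frame.
#' @param alternative `"two.sided"` (default), `"increasing"`, or
#'   `"decreasing"`.
#' @param n_perm Number of random permutations for the optional permutation
#'   p-value (0 = skip).
#' @param seed Seed for the permutation draw (required if `n_perm > 0`).
#' @return A `group_comparison` with method `"jonckheere"`; the permutation
#'   p (if computed) and the null mean/variance are in `$details`.
#' @export
#' @examples
#' jonckheere_trend(list(c(1, 2), c(2, 3), c(4, 5)),
#'                  alternative = "increasing")
jonckheere_trend <- function(x, outcome = "outcome", group = "group",
                             alternative = c("two.sided", "increasing",
                                             "decreasing"),
                             n_perm = 0, seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) {
    g <- droplevels(as.factor(x[[group]]))
    samples <- split(x[[outcome]], g)
  } else {
    samples <- x
  }
  samples <- lapply(samples, function(v) as.numeric(v[!is.na(v)]))
  k <- length(samples)
  if (k < 3) stop("jonckheere_trend requires at least 3 ordered groups")
  n <- lengths(samples)
  if (any(n == 0)) stop("empty group")
  N <- sum(n)

  jt <- jt_statistic(samples)
  e_jt <- (N^2 - sum(n^2)) / 4
  t_j <- table(unlist(samples))
  v_jt <- jt_null_variance(n, t_j)

  if (v_jt <= 0) {
    p <- 1
    z <- 0
  } else {
    z <- (jt - e_jt) / sqrt(v_jt)
    p <- switch(alternative,
      increasing = stats::pnorm(z, lower.tail = FALSE),
      decreasing = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    )
    p <- min(p, 1)
  }

  details <- list(z = z, null_mean = e_jt, null_var = v_jt,
                  alternative = alternative)
  if (n_perm > 0) {
    if (is.null(seed)) stop("permutation p-value needs a seed")
    pooled <- unlist(samples)
    idx_groups <- rep(seq_len(k), n)
    perm_jt <- with_preserved_rng(seed, {
      vapply(seq_len(n_perm), function(i) {
        jt_statistic(split(sample(pooled), idx_groups))
      }, numeric(1))
    })
    details$perm_p <- switch(alternative,
      increasing = mean(perm_jt >= jt),
      decreasing = mean(perm_jt <= jt),
      two.sided = mean(abs(perm_jt - e_jt) >= abs(jt - e_jt))
    )
  }

  new_group_comparison(outcome, "jonckheere", jt, p, details = details)
}

jt_statistic <- function(samples) {
  k <- length(samples)
  jt <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      xi <- samples[[i]]
      xj <- samples[[j]]
      cmp <- outer(xi, xj, "<")
      tie <- outer(xi, xj, "==")
      jt <- jt + sum(cmp) + 0.5 * sum(tie)
    }
  }
  jt
}

jt_null_variance <- function(n, t_j) {
  N <- sum(n)
  t_j <- as.numeric(t_j)
  a <- N * (N - 1) * (2 * N + 5) -
    sum(n * (n - 1) * (2 * n + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  b <- sum(n * (n - 1) * (n - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  cc <- sum(n * (n - 1)) * sum(t_j * (t_j - 1))
  a / 72 +
    b / (36 * N * (N - 1) * (N - 2)) +
    cc / (8 * N * (N - 1))
}

# Run code under a temporary seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap comparison of lobar involvement frequencies
#'
#' Among participants with focal-type involvement (1-9 involved regions, the
#' default; whole-brain participants are excluded because every lobe is
#' involved by definition), computes the fraction of participants involved in
#' each of the five lobes (either hemisphere), then compares lobes pairwise
#' by bootstrap: participants are resampled with replacement `n_resamples`
#' times and the two-sided p-value for a lobe pair is
#' `2 * min(P(freq_A <= freq_B), P(freq_A >= freq_B))` over resamples,
#' floored at `1/n_resamples` for the -log10 scale.
#'
#' @param staging A staging tibble from [stage_cohort()].
#' @param n_resamples Number of bootstrap resamples (default 1000, minimum
#'   100).
#' @param seed RNG seed for the resampling.
#' @param include `"focal"` (default: 1-9 involved regions) or
#'   `"any_involved"` (>= 1 involved region, including whole-brain).
#' @return An object of class `freq_boot` with elements `frequencies`
#'   (tibble: `lobe`, `frequency`, `boot_mean`, `boot_sd`), `pairwise` (tibble:
#'   `lobe_a`, `lobe_b`, `p_value`, `neg_log10_p`), `n_included`,
#'   `n_resamples`.
#' @export
involvement_frequency_bootstrap <- function(staging, n_resamples = 1000,
                                            seed = 1L,
                                            include = c("focal",
                                                        "any_involved")) {
  include <- match.arg(include)
  stopifnot(is.data.frame(staging), n_resamples >= 100)
  flag_cols <- paste0("pos_", region_names())
  stopifnot(all(c(flag_cols, "n_involved") %in% names(staging)))

  keep <- if (include == "focal") {
    staging$n_involved >= 1 & staging$n_involved <= 9
  } else {
    staging$n_involved >= 1
  }
  s <- staging[keep, , drop = FALSE]
  if (nrow(s) == 0) stop("no participants with focal involvement")

  lobes <- lobe_names()
  lobe_mat <- sapply(lobes, function(l) {
    s[[paste0("pos_", l, "_left")]] | s[[paste0("pos_", l, "_right")]]
  })
  lobe_mat <- matrix(lobe_mat, nrow = nrow(s),
                     dimnames = list(NULL, lobes))
  freq <- colMeans(lobe_mat)

  n <- nrow(s)
  boot_freq <- with_preserved_rng(seed, {
    t(vapply(seq_len(n_resamples), function(b) {
      colMeans(lobe_mat[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(length(lobes))))
  })

  pairs <- utils::combn(lobes, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    fa <- boot_freq[, pr[1]]
    fb <- boot_freq[, pr[2]]
    p <- 2 * min(mean(fa <= fb), mean(fa >= fb))
    p <- min(p, 1)
    tibble::tibble(
      lobe_a = pr[1], lobe_b = pr[2], p_value = p,
      neg_log10_p = -log10(max(p, 1 / n_resamples))
    )
  })

  structure(
    list(
      frequencies = tibble::tibble(lobe = lobes, frequency = unname(freq),
                                   boot_mean = unname(colMeans(boot_freq)),
                                   boot_sd = unname(apply(boot_freq, 2,
                                                          stats::sd))),
      pairwise = pairwise,
      n_included = n,
      n_resamples = n_resamples,
      include = include
    ),
    class = "freq_boot"
  )
}

#' @export
print.freq_boot <- function(x, ...) {
  cat(sprintf(
    "lobar involvement frequencies (%d participants, %d resamples):\n",
    x$n_included, x$n_resamples))
  f <- x$frequencies[order(-x$frequencies$frequency), ]
  cat(paste(sprintf("  %-16s %5.1f%%", f$lobe, 100 * f$frequency),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname involvement_frequency_bootstrap
#' @param x A `freq_boot` object.
#' @param ... Unused.
#' @export
tidy.freq_boot <- function(x, ...) x$pairwise

#' @rdname involvement_frequency_bootstrap
#' @export
glance.freq_boot <- function(x, ...) {
  tidyr::pivot_wider(x$frequencies[, c("lobe", "frequency")],
                     names_from = "lobe", values_from = "frequency") |>
    dplyr::mutate(n_included = x$n_included, n_resamples = x$n_resamples)
}

#' Compare the global/focal grouping with a Centiloid-band grouping by AIC
#'
#' Fits the same Gaussian linear model `outcome ~ grouping (+ covariates)`
#' under two alternative three-level groupings — the global/focal group label
#' and a purely Centiloid-level banding (negative / subthreshold / positive,
#' see [cl_band_grouping()]) — and compares the fits by AIC (`2k - 2 lnL`);
#' the lower AIC wins, ties go to the global/focal grouping.
#'
#' @param data Data frame with the outcome, the group label, a `global_cl`
#'   column, and any covariates.
#' @param outcome Numeric outcome column name.
#' @param cl_bands Band edges for the Centiloid grouping
#'   (default `c(10, 25.11)`).
#' @param group Group-label column (default `"group"`).
#' @param cl Centiloid column (default `"global_cl"`).
#' @param covariates Adjustment covariates (default `"age"`).
#' @return An object of class `aic_comparison` with `aic_fg`, `aic_cl`,
#'   `preferred` (`"fg"` or `"cl"`).
#' @export
compare_groupings_aic <- function(data, outcome, cl_bands = c(10, 25.11),
                                  group = "group", cl = "global_cl",
                                  covariates = "age") {
  stopifnot(is.data.frame(data),
            all(c(outcome, group, cl, covariates) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(outcome, group, cl,
                                              covariates)]), , drop = FALSE]
  fg <- droplevels(as.factor(data[[group]]))
  band <- droplevels(cl_band_grouping(data[[cl]], cl_bands))
  if (nlevels(fg) < 2) stop("global/focal grouping is degenerate (< 2 levels)")
  if (nlevels(band) < 2) stop("Centiloid-band grouping is degenerate (< 2 levels)")

  fit_one <- function(grp) {
    df <- data.frame(.y = data[[outcome]], .g = grp,
                     data[, covariates, drop = FALSE])
    rhs <- paste(c(".g", covariates), collapse = " + ")
    stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  }
  aic_fg <- stats::AIC(fit_one(fg))
  aic_cl <- stats::AIC(fit_one(band))

  structure(
    list(outcome = outcome, aic_fg = aic_fg, aic_cl = aic_cl,
         preferred = if (aic_fg <= aic_cl) "fg" else "cl",
         cl_bands = cl_bands),
    class = "aic_comparison"
  )
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat(sprintf(
    "AIC for '%s': global/focal grouping %.3f vs Centiloid bands %.3f -> %s\n",
    x$outcome, x$aic_fg, x$aic_cl,
    if (x$preferred == "fg") "global/focal preferred"
    else "Centiloid bands preferred"))
  invisible(x)
}

#' @rdname compare_groupings_aic
#' @param x An `aic_comparison` object.
#' @param ... Unused.
#' @export
tidy.aic_comparison <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, aic_fg = x$aic_fg, aic_cl = x$aic_cl,
                 preferred = x$preferred)
}
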