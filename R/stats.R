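#' Mixed-model (split-plot) ANOVA: respiratory phase by group
#'
#' Two-way mixed ANOVA with respiratory phase as the within-subject
#' factor and group as the between-subject factor, Type-III sums of
#' squares (fitted through `car::Anova` on a multivariate linear model of
#' the two phase columns). Reports F, degrees of freedom, p and partial
#' eta squared for the group, phase and phase-by-group effects. Subjects
#' missing either phase are dropped listwise with a warning.
#'
#' @param data Long tibble with one row per subject and phase.
#' @param value,subject,group,phase Column names (strings) for the metric
#'   value, subject id, group label and phase label.
#' @return An object of class `phase_anova`: a tibble with `effect`,
#'   `df1`, `df2`, `statistic`, `p_value`, `partial_eta_sq`, plus the
#'   per-group phase means in `attr(, "cell_means")`.
#' @export
phase_group_anova <- function(data, value, subject = "subject_id",
                              group = "group", phase = "phase") {
  wide <- data |>
    dplyr::select(dplyr::all_of(c(subject, group, phase, value))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(phase),
                       values_from = dplyr::all_of(value))
  phase_levels <- setdiff(names(wide), c(subject, group))
  if (length(phase_levels) != 2) stop("need exactly two phase levels")
  complete <- stats::complete.cases(wide[, phase_levels])
  if (!all(complete)) {
    warning(sprintf("dropping %d subject(s) with a missing phase value",
                    sum(!complete)))
    wide <- wide[complete, ]
  }
  grp <- factor(wide[[group]])
  if (nlevels(grp) < 2 || min(table(grp)) < 2) {
    stop("need >= 2 groups with >= 2 subjects each")
  }
  y <- as.matrix(wide[, phase_levels])
  opt <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opt))
  mod <- stats::lm(y ~ grp)
  idata <- data.frame(phase = factor(phase_levels, levels = phase_levels))
  aov3 <- car::Anova(mod, idata = idata, idesign = ~phase, type = 3)
  uni <- summary(aov3, multivariate = FALSE)$univariate.tests
  pick <- function(row_name) {
    r <- uni[row_name, ]
    ss <- r[["Sum Sq"]]
    ess <- r[["Error SS"]]
    tibble::tibble(
      effect = row_name,
      df1 = unname(r[["num Df"]]),
      df2 = unname(r[["den Df"]]),
      statistic = unname(r[["F value"]]),
      p_value = unname(r[["Pr(>F)"]]),
      partial_eta_sq = unname(ss / (ss + ess))
    )
  }
  out <- dplyr::bind_rows(pick("grp"), pick("phase"), pick("grp:phase"))
  out$effect <- c("group", "phase", "phase:group")
  cell_means <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, phase)))) |>
    dplyr::summarise(mean = mean(.data[[value]], na.rm = TRUE),
                     .groups = "drop")
  class(out) <- c("phase_anova", class(out))
  attr(out, "cell_means") <- cell_means
  attr(out, "value") <- value
  out
}

shapiro_ok <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(TRUE)
  stats::shapiro.test(x)$p.value >= 0.05
}

#' Compare a variable across groups (one-way ANOVA / Welch / Kruskal-Wallis)
#'
#' In `"auto"` mode a Shapiro-Wilk pre-check (alpha = 0.05 per group)
#' selects the Kruskal-Wallis test when any group departs from
#' normality, otherwise one-way ANOVA. Pairwise follow-ups are
#' mean-rank (Dunn-type) comparisons after Kruskal-Wallis and pooled-SD t
#' contrasts after ANOVA (unpooled for Welch), Bonferroni-adjusted by
#' default.
#'
#' @param data A data frame.
#' @param variable,group Column names (strings) of the value and the
#'   group label.
#' @param mode `"auto"`, `"anova"`, `"welch"` or `"kruskal"`.
#' @param adjust Multiplicity adjustment method for pairwise p-values
#'   (see [stats::p.adjust()]).
#' @return An object of class `group_comparison`: list with `test`,
#'   `statistic`, `df`, `p_value`, `pairwise` (tibble), `normality`
#'   (per-group Shapiro p), `groups`.
#' @export
group_compare <- function(data, variable, group = "group",
                          mode = c("auto", "anova", "welch", "kruskal"),
                          adjust = "bonferroni") {
  mode <- match.arg(mode)
  x <- data[[variable]]
  g <- factor(data[[group]])
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (any(sizes < 2)) {
    warning(sprintf("excluding group(s) with n < 2: %s",
                    paste(names(sizes)[sizes < 2], collapse = ", ")))
    keep <- g %in% names(sizes)[sizes >= 2]
    x <- x[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need at least two groups with n >= 2")

  norm <- tapply(x, g, function(v) {
    if (length(v) >= 3 && stats::sd(v) > 0) stats::shapiro.test(v)$p.value
    else NA_real_
  })
  if (mode == "auto") {
    mode <- if (any(stats::na.omit(norm) < 0.05)) "kruskal" else "anova"
  }

  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  if (mode == "kruskal") {
    kt <- stats::kruskal.test(x, g)
    rk <- rank(x)
    N <- length(x)
    ties <- table(rk)
    tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
    mean_rank <- tapply(rk, g, mean)
    pw <- purrr::map(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                   (1 / sizes[[a]] + 1 / sizes[[b]]))
      z <- (mean_rank[[a]] - mean_rank[[b]]) / se
      tibble::tibble(group1 = a, group2 = b, statistic = z,
                     p_value = 2 * stats::pnorm(-abs(z)))
    }) |> dplyr::bind_rows()
    res <- list(test = "kruskal", statistic = unname(kt$statistic),
                df = unname(kt$parameter), p_value = kt$p.value)
  } else if (mode == "welch") {
    wt <- stats::oneway.test(x ~ g, var.equal = FALSE)
    pw <- pairwise_t(x, g, pairs, pooled = FALSE)
    res <- list(test = "welch", statistic = unname(wt$statistic),
                df = unname(wt$parameter), p_value = wt$p.value)
  } else {
    fit <- stats::aov(x ~ g)
    sm <- summary(fit)[[1]]
    pw <- pairwise_t(x, g, pairs, pooled = TRUE)
    res <- list(test = "anova", statistic = sm$`F value`[1],
                df = c(sm$Df[1], sm$Df[2]), p_value = sm$`Pr(>F)`[1])
  }
  pw$p_adj <- pmin(1, stats::p.adjust(pw$p_value, method = adjust))
  res$pairwise <- pw
  res$normality <- tibble::tibble(group = lv,
                                  shapiro_p = as.numeric(norm[lv]))
  res$groups <- tibble::tibble(group = lv, n = as.integer(sizes[lv]))
  structure(res, class = "group_comparison")
}

pairwise_t <- function(x, g, pairs, pooled = TRUE) {
  sp <- if (pooled) {
    ss <- tapply(x, g, function(v) sum((v - mean(v))^2))
    sqrt(sum(ss) / (length(x) - nlevels(g)))
  } else NA
  purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- x[g == pairs[1, j]]
    b <- x[g == pairs[2, j]]
    if (pooled) {
      se <- sp * sqrt(1 / length(a) + 1 / length(b))
      tstat <- (mean(a) - mean(b)) / se
      df <- length(x) - nlevels(g)
      p <- 2 * stats::pt(-abs(tstat), df)
    } else {
      tt <- stats::t.test(a, b)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   statistic = tstat, p_value = p)
  }) |> dplyr::bind_rows()
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.3f, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' Compare proportions across groups (chi-squared / Fisher exact)
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the chi-squared test.
#'
#' @param counts A matrix or table of counts (groups by outcomes).
#' @return An object of class `proportion_comparison`: `test`,
#'   `statistic` (`NA` for Fisher), `df`, `p_value`, `expected`.
#' @export
proportion_compare <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(counts)
    out <- list(test = "fisher", statistic = NA_real_, df = NA_real_,
                p_value = ft$p.value, expected = expected)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts))
    out <- list(test = "chisq", statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value,
                expected = expected)
  }
  structure(out, class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("<proportion_comparison> %s: p = %.4g\n", x$test, x$p_value))
  invisible(x)
}

#' Correlate respiratory modulation with resting hemodynamics
#'
#' Correlates the percent change in MSNA burst incidence between the two
#' respiratory phases with resting blood pressures and resting burst
#' incidence, pooled and per group. With `method = "auto"` Pearson's r is
#' used when both variables pass a Shapiro-Wilk pre-check, Spearman's rho
#' otherwise.
#'
#' @param data Cohort summary tibble (one row per subject).
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param group Group column name, or `NULL` for pooled only.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param min_n Minimum subjects per correlation; smaller scopes are
#'   skipped with a warning.
#' @return A tibble: `scope`, `predictor`, `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
modulation_bp_correlations <- function(data,
                                       outcome = "incidence_pct_change",
                                       predictors = c("sbp_mean", "dbp_mean",
                                                      "map_mean",
                                                      "bursts_per_100hb"),
                                       group = "group",
                                       method = c("auto", "pearson",
                                                  "spearman"),
                                       min_n = 5) {
  method <- match.arg(method)
  scopes <- list(pooled = rep(TRUE, nrow(data)))
  if (!is.null(group) && group %in% names(data)) {
    for (gl in unique(data[[group]])) scopes[[gl]] <- data[[group]] == gl
  }
  out <- list()
  for (sc in names(scopes)) {
    d <- data[scopes[[sc]], ]
    for (pr in predictors) {
      x <- d[[outcome]]; y <- d[[pr]]
      keep <- stats::complete.cases(x, y)
      x <- x[keep]; y <- y[keep]
      if (length(x) < min_n) {
        warning(sprintf("skipping %s ~ %s in %s: n = %d < %d",
                        outcome, pr, sc, length(x), min_n))
        next
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          scope = sc, predictor = pr, method = NA_character_,
          estimate = NA_real_, p_value = NA_real_, n = length(x))
        next
      }
      m <- if (method == "auto") {
        if (shapiro_ok(x) && shapiro_ok(y)) "pearson" else "spearman"
      } else method
      ct <- suppressWarnings(stats::cor.test(x, y, method = m))
      out[[length(out) + 1]] <- tibble::tibble(
        scope = sc, predictor = pr, method = m,
        estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
    }
  }
  dplyr::bind_rows(out)
}
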