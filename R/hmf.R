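## HMF statistics: assumption checks, one-/two-way ANOVA, Tukey and
## Games-Howell post hoc tests (raw data or summary-statistics mode),
## control comparisons and compact letter displays.

#' Summarize groups to (mean, sd, n)
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame `group, mean, sd, n`.
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.character(groups)
  g <- unique(groups)
  data.frame(group = g,
             mean = vapply(g, function(k) mean(values[groups == k]),
                           numeric(1)),
             sd = vapply(g, function(k) stats::sd(values[groups == k]),
                         numeric(1)),
             n = vapply(g, function(k) sum(groups == k), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group (requires n >= 3 per group) and Levene's test
#' across groups with the mean as centre.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list `normality_p` (named per group), `levene_p`.
#' @export
check_assumptions <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 3))
    stop("group(s) with n < 3, Shapiro-Wilk not defined: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  norm_p <- vapply(names(tab), function(k) {
    x <- values[groups == k]
    if (stats::sd(x) == 0) return(1)  # degenerate: trivially 'normal'
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  lev <- car::leveneTest(values ~ factor(groups), center = mean)
  list(normality_p = norm_p, levene_p = lev[["Pr(>F)"]][1])
}

#' Two-way ANOVA on the factorial heat-treatment subset
#'
#' Type-II sums of squares on the 4 temperatures x 4 times factorial
#' (control rows are dropped; the control has no factorial cell).
#'
#' @param hmf data.frame with `temperature_C`, `time_min`, `hmf_mg_kg`
#'   (one honey type).
#' @return data.frame with rows temperature, time, interaction and columns
#'   `F, df, p`.
#' @export
two_way_anova <- function(hmf) {
  d <- hmf[hmf$temperature_C != "CONTROL", , drop = FALSE]
  d$temperature_C <- factor(d$temperature_C)
  d$time_min <- factor(d$time_min)
  if (any(table(d$temperature_C, d$time_min) == 0))
    stop("empty factorial cell(s) in the temperature x time design")
  fit <- stats::lm(hmf_mg_kg ~ temperature_C * time_min, data = d)
  a <- car::Anova(fit, type = 2)
  rows <- c("temperature_C", "time_min", "temperature_C:time_min")
  data.frame(effect = c("temperature", "time", "interaction"),
             F = a[rows, "F value"],
             df = a[rows, "Df"],
             p = a[rows, "Pr(>F)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

## internal: all unordered pairs of 1..k
pair_index <- function(k) {
  which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
}

#' Pairwise post hoc comparisons from summary statistics or raw data
#'
#' `homogeneous = TRUE` applies Tukey's HSD (pooled variance, studentized
#' range); `FALSE` applies Games-Howell (per-pair Welch degrees of freedom).
#' Both are computed from group means, SDs and sizes only, so printed
#' summary tables can be analyzed directly.
#'
#' @param summaries data.frame `group, mean, sd, n` (see
#'   [summarize_groups()]), or raw data via `values`/`groups`.
#' @param homogeneous variance homogeneity flag selecting the method.
#' @param values,groups optional raw data, summarized internally.
#' @return data.frame of class `posthoc_result`: `group_a, group_b,
#'   statistic, df, p, significant` plus a `method` attribute.
#' @export
posthoc <- function(summaries = NULL, homogeneous = TRUE,
                    values = NULL, groups = NULL) {
  if (is.null(summaries)) summaries <- summarize_groups(values, groups)
  if (nrow(summaries) < 2) stop("need >= 2 groups")
  if (any(summaries$n < 2)) stop("group(s) with n < 2")
  k <- nrow(summaries)
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  pr <- pair_index(k)
  if (homogeneous) {
    df_err <- sum(n - 1)
    mse <- sum((n - 1) * s^2) / df_err
    se <- sqrt(mse / 2 * (1 / n[pr[, 1]] + 1 / n[pr[, 2]]))
    qstat <- abs(m[pr[, 1]] - m[pr[, 2]]) / se
    df <- rep(df_err, nrow(pr))
    p <- stats::ptukey(qstat, k, df_err, lower.tail = FALSE)
    method <- "tukey"
    statistic <- qstat
  } else {
    v1 <- s[pr[, 1]]^2 / n[pr[, 1]]
    v2 <- s[pr[, 2]]^2 / n[pr[, 2]]
    tstat <- abs(m[pr[, 1]] - m[pr[, 2]]) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
      (v1^2 / (n[pr[, 1]] - 1) + v2^2 / (n[pr[, 2]] - 1))
    p <- stats::ptukey(tstat * sqrt(2), k, df, lower.tail = FALSE)
    method <- "games_howell"
    statistic <- tstat
  }
  out <- data.frame(group_a = summaries$group[pr[, 1]],
                    group_b = summaries$group[pr[, 2]],
                    statistic = statistic, df = df, p = pmin(p, 1),
                    significant = p < 0.05,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Route a comparison family to Tukey or Games-Howell
#'
#' Levene p >= 0.05 (homogeneous variances) selects Tukey's HSD; otherwise
#' Games-Howell. Requires raw data for the Levene check.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return posthoc_result.
#' @export
posthoc_auto <- function(values, groups) {
  a <- check_assumptions(values, groups)
  posthoc(values = values, groups = groups,
          homogeneous = a$levene_p >= 0.05)
}

#' Which treatment levels differ from the control?
#'
#' One-way ANOVA across all levels; if significant (p < 0.05), each level is
#' compared with the control by a Welch t test ("dunnett-style" pairwise
#' control comparisons) and starred iff p < 0.05.
#'
#' @param hmf data.frame with `temperature_C`, `time_min`, `hmf_mg_kg`
#'   (one honey type, control rows included).
#' @return data.frame `temperature_C, time_min, p, star`.
#' @export
control_comparison <- function(hmf) {
  lvl <- paste(hmf$temperature_C, hmf$time_min, sep = "_")
  if (!any(hmf$temperature_C == "CONTROL"))
    stop("control rows missing")
  anova_p <- summary(stats::aov(hmf_mg_kg ~ factor(lvl),
                                data = hmf))[[1]][["Pr(>F)"]][1]
  ctrl <- hmf$hmf_mg_kg[hmf$temperature_C == "CONTROL"]
  levels_df <- unique(hmf[hmf$temperature_C != "CONTROL",
                          c("temperature_C", "time_min")])
  res <- lapply(seq_len(nrow(levels_df)), function(i) {
    x <- hmf$hmf_mg_kg[hmf$temperature_C == levels_df$temperature_C[i] &
                         hmf$time_min == levels_df$time_min[i]]
    p <- if (is.na(anova_p) || anova_p >= 0.05) 1.0 else
      stats::t.test(x, ctrl)$p.value
    data.frame(temperature_C = levels_df$temperature_C[i],
               time_min = levels_df$time_min[i],
               p = p, star = p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb algorithm: groups sharing a letter are exactly those
#' whose pairwise comparison is non-significant. Letters are assigned in
#' the given group order.
#'
#' @param ph posthoc_result (complete pairwise matrix for the groups).
#' @param group_order order in which groups receive letters (default: order
#'   of first appearance).
#' @param letters_pool letters to draw from (default lowercase).
#' @return named character vector: group -> concatenated letters.
#' @export
letter_display <- function(ph, group_order = NULL,
                           letters_pool = letters) {
  groups <- unique(c(ph$group_a, ph$group_b))
  if (!is.null(group_order)) {
    if (!setequal(group_order, groups))
      stop("group_order must contain exactly the compared groups")
    groups <- group_order
  }
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(ph))) {
    a <- ph$group_a[i]; b <- ph$group_b[i]
    sig[a, b] <- sig[b, a] <- ph$significant[i]
  }
  if (any(is.na(sig))) stop("incomplete pairwise matrix")
  # columns = letters; start with one column containing all groups
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        new1 <- cols[[ci]]; new1[j] <- FALSE
        new2 <- cols[[ci]]; new2[i] <- FALSE
        cols[[ci]] <- new1
        cols[[length(cols) + 1]] <- new2
      }
    }
    # absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
        keep[a] <- FALSE
      else if (a < b && keep[a] && keep[b] &&
               all(cols[[a]] == cols[[b]]))
        keep[b] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letter columns by first member so letter 'a' starts earliest
  first <- vapply(cols, function(cc) which(cc)[1], integer(1))
  cols <- cols[order(first)]
  out <- vapply(seq_len(k), function(i)
    paste(letters_pool[which(vapply(cols, `[[`, logical(1), i))],
          collapse = ""), character(1))
  stats::setNames(out, groups)
}

#' Read the bundled reference HMF summary table
#'
#' Published per-level HMF summaries (mean, SD, n = 3 replicate bottles) for
#' the three honey types of the heat-treatment study, as shipped in
#' `inst/extdata/hmf_reference_summary.csv`. Used by the
#' summary-statistics post hoc mode.
#'
#' @return data.frame `honey_type, temperature_C, time_min, mean, sd, n`.
#' @export
hmf_reference_summary <- function() {
  path <- system.file("extdata", "hmf_reference_summary.csv",
                      package = "aquaheat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(temperature_C = "character"))
}
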