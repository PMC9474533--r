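#' Container for one statistical test result
#'
#' @param name test label.
#' @param statistic test statistic.
#' @param dof degrees of freedom (scalar or pair).
#' @param p_value two-sided p-value.
#' @param estimate point estimate (difference, correlation, ...).
#' @param direction sign/direction of the effect, as text.
#' @param n number of observations used.
#' @param note free-text annotation (exclusions etc.).
#' @return a `stat_result`.
#' @export
stat_result <- function(name, statistic, dof, p_value, estimate = NA_real_,
                        direction = NA_character_, n = NA_integer_,
                        note = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_cvr("stats", "p-value outside [0, 1]")
  structure(list(name = name, statistic = statistic, dof = dof,
                 p_value = p_value, estimate = estimate,
                 direction = direction, n = n, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dof <- paste(signif(x$dof, 4), collapse = ", ")
  cat(sprintf("%s: stat = %.4g, dof = %s, p = %.4g, n = %d%s\n",
              x$name, x$statistic, dof, x$p_value,
              if (is.na(x$n)) NA_integer_ else x$n,
              if (is.na(x$direction)) "" else paste0(" [", x$direction, "]")))
  invisible(x)
}

#' Per-subject pre-treatment average CVR
#'
#' For each MS subject, the mean of the two pre-treatment sessions (1 and
#' 2); when one of the two is missing the other is taken as the
#' pre-treatment value; subjects with neither are excluded and logged.
#'
#' @param table cohort data.frame (see [read_cohort_table()]).
#' @param value_cols columns to average.
#' @return data.frame with one row per MS subject and columns
#'   `pre_<value_col>`; attribute `excluded` lists dropped subjects.
#' @export
pretreatment_average <- function(table,
                                 value_cols = c("cvr_gm", "cvr_wm")) {
  ms <- table[table$group == "MS" & table$session %in% c(1, 2), , drop = FALSE]
  if (nrow(ms) == 0) stop_cvr("stats", "no MS subjects in table")
  subjects <- unique(table$subject[table$group == "MS"])
  out <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (col in value_cols) {
    out[[paste0("pre_", col)]] <- vapply(subjects, function(s) {
      v <- ms[[col]][ms$subject == s]
      v <- v[is.finite(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  pre_cols <- paste0("pre_", value_cols)
  keep <- rowSums(is.na(out[pre_cols])) < length(pre_cols)
  excluded <- out$subject[!keep]
  out <- out[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Normality screening (Kolmogorov-Smirnov / Lilliefors)
#'
#' One-sample KS distance between the sample and a normal law. With
#' `method = "lilliefors"` (default) the normal parameters are estimated
#' from the sample and the p-value is obtained by Monte-Carlo simulation of
#' the same statistic under normal sampling; with `method = "ks"` the
#' classical test against a fully specified normal (mean/sd equal to the
#' sample values) is run via [stats::ks.test()].
#'
#' @param x numeric sample (n >= 5).
#' @param method `"lilliefors"` or `"ks"`.
#' @param n_mc Monte-Carlo replicates for the Lilliefors p-value.
#' @param seed seed for the Monte-Carlo p-value.
#' @return a `stat_result` (statistic = KS distance D).
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks"), n_mc = 2000,
                         seed = 1) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop_cvr("stats", "need n >= 5 for normality screening")
  if (sd(x) == 0) stop_cvr("stats", "zero variance sample")
  if (method == "ks") {
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x)))
    return(stat_result("ks_normality", unname(kt$statistic), NA, kt$p.value,
                       n = n, note = "naive KS, parameters fixed at sample values"))
  }
  D <- ks_distance_normal(x)
  Dnull <- with_seed(seed, vapply(seq_len(n_mc), function(i)
    ks_distance_normal(rnorm(n)), numeric(1)))
  p <- (1 + sum(Dnull >= D)) / (n_mc + 1)
  stat_result("ks_normality", D, NA, p, n = n,
              note = sprintf("Lilliefors-type, %d Monte-Carlo replicates", n_mc))
}

ks_distance_normal <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Two-sided t-tests
#'
#' `ttest_unpaired` is the classical pooled-variance two-sample t-test;
#' `ttest_paired` tests the difference scores of paired samples. Degenerate
#' (zero-variance) inputs are rejected.
#'
#' @param a,b,x,y numeric samples (paired lengths must match).
#' @return a `stat_result`.
#' @export
ttest_unpaired <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_cvr("stats", "need n >= 2 per group")
  scale <- max(abs(c(a, b)), 1e-300)
  if (sqrt(var(a) + var(b)) <= 1e-10 * scale)
    stop_cvr("stats", "zero pooled variance")
  tt <- t.test(a, b, var.equal = TRUE)
  stat_result("unpaired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, estimate = mean(a) - mean(b),
              direction = if (mean(a) > mean(b)) "a > b" else "a < b",
              n = length(a) + length(b))
}

#' @rdname ttest_unpaired
#' @export
ttest_paired <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop_cvr("stats", "need n >= 2 pairs")
  d <- x - y
  if (sd(d) <= 1e-10 * max(abs(d), 1e-300))
    stop_cvr("stats", "degenerate zero-variance paired differences")
  tt <- t.test(x, y, paired = TRUE)
  stat_result("paired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, estimate = mean(x - y),
              direction = if (mean(x) > mean(y)) "x > y" else "x < y",
              n = length(x))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F-test across k conditions (sessions) with the classical
#' subjects-by-conditions sum-of-squares decomposition:
#' `F = MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`. Subjects with any missing session are
#' dropped (complete cases) and counted in the result's note. An optional
#' Greenhouse-Geisser sphericity correction rescales both degrees of
#' freedom.
#'
#' @param wide numeric matrix, subjects x conditions.
#' @param gg apply the Greenhouse-Geisser correction.
#' @return a `stat_result` (statistic = F; dof = the pair).
#' @export
ranova_oneway <- function(wide, gg = FALSE) {
  wide <- as.matrix(wide)
  complete <- rowSums(!is.finite(wide)) == 0
  dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3) stop_cvr("stats", "need >= 3 complete subjects, got %d", n)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  eps <- 1
  if (gg) eps <- gg_epsilon(wide)
  if (ss_cond <= .Machine$double.eps * max(1, ss_tot)) {
    f <- 0; p <- 1
  } else if (ss_err <= .Machine$double.eps * max(1, ss_tot)) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
    p <- pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  }
  stat_result("ranova_oneway", f, c(eps * df1, eps * df2), p, n = n,
              note = sprintf("%d incomplete subject(s) dropped%s", dropped,
                             if (gg) sprintf("; GG epsilon = %.3f", eps) else ""))
}

# Greenhouse-Geisser epsilon from the sample covariance of conditions
gg_epsilon <- function(wide) {
  S <- stats::cov(wide)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Pearson correlation and Fisher z-transform
#'
#' Sample Pearson correlation with the classical two-sided t-based
#' p-value; `fisher_z` is the variance-stabilising `atanh` transform used
#' to compare correlations.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-degenerate).
#' @return a `stat_result` (statistic = t; estimate = r).
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_cvr("stats", "need n >= 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop_cvr("stats", "zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result("pearson", unname(ct$statistic), unname(ct$parameter),
              ct$p.value, estimate = unname(ct$estimate),
              direction = if (ct$estimate >= 0) "positive" else "negative",
              n = length(x))
}

#' @rdname pearson_cor
#' @param r correlation coefficient in (-1, 1).
#' @export
fisher_z <- function(r) atanh(r)

#' Full cohort statistical battery
#'
#' Runs the complete longitudinal/between-group analysis on a cohort
#' table: normality screens; unpaired t-tests of HC vs pre-treatment MS
#' CVR (GM and WM); three-session repeated-measures ANOVA with post-hoc
#' paired t-tests; paired pre- vs on-treatment comparison (on-treatment =
#' session 3, pre-treatment = average of sessions 1-2 with the
#' single-session fallback); correlation of the on-minus-pre CVR change
#' with the pre-treatment CVR (restoration effect) and with the change in
#' Gd+ lesion count (session 3 minus session 1); paired comparison of
#' lesion vs WM CVR per session among lesion-positive subjects; and
#' correlations of CVR with normalised tissue volumes per group/phase,
#' with their Fisher z-transforms. Sub-test failures are recorded, not
#' fatal. P-values are uncorrected for multiplicity.
#'
#' @param table cohort data.frame with columns `subject`, `group`,
#'   `session`, `cvr_gm`, `cvr_wm`, `cvr_lesion`, `gd_count`, `vol_gm`,
#'   `vol_wm`.
#' @param ks_seed seed for the Monte-Carlo normality p-values.
#' @return a `cvr_cohort_results` list: `tests` (named `stat_result`s or
#'   error messages), `delta` (per-subject changes), `exclusions`, `meta`.
#' @export
analyze_cohort <- function(table, ks_seed = 1) {
  req <- c("subject", "group", "session", "cvr_gm", "cvr_wm")
  if (!all(req %in% names(table)))
    stop_cvr("stats", "cohort table missing columns: %s",
             paste(setdiff(req, names(table)), collapse = ", "))
  tests <- list()
  run <- function(name, expr) {
    tests[[name]] <<- tryCatch(expr, error = function(e) conditionMessage(e))
    invisible(NULL)
  }

  hc <- table[table$group == "HC", , drop = FALSE]
  pre <- pretreatment_average(table)
  ms_on <- table[table$group == "MS" & table$session == 3, , drop = FALSE]

  for (tis in c("gm", "wm")) {
    cvr_col <- paste0("cvr_", tis); pre_col <- paste0("pre_cvr_", tis)
    run(paste0("ks_hc_", tis), ks_normality(hc[[cvr_col]], seed = ks_seed))
    run(paste0("ks_ms_pre_", tis), ks_normality(pre[[pre_col]], seed = ks_seed))

    # between groups: HC vs pre-treatment MS
    run(paste0("hc_vs_ms_", tis),
        ttest_unpaired(hc[[cvr_col]], pre[[pre_col]]))

    # longitudinal rANOVA across the three sessions, complete cases
    ms_subj <- unique(table$subject[table$group == "MS"])
    wide <- sapply(1:3, function(s) {
      idx <- match(paste(ms_subj, s), paste(table$subject, table$session))
      table[[cvr_col]][idx]
    })
    run(paste0("ranova_", tis), ranova_oneway(wide))
    run(paste0("s1_vs_s2_", tis), ttest_paired(wide[, 1], wide[, 2]))

    # paired pre vs on treatment
    on_val <- ms_on[[cvr_col]][match(pre$subject, ms_on$subject)]
    run(paste0("pre_vs_on_", tis), ttest_paired(on_val, pre[[pre_col]]))

    # restoration effect: change vs pre-treatment level
    delta <- on_val - pre[[pre_col]]
    run(paste0("delta_vs_pre_", tis), pearson_cor(pre[[pre_col]], delta))
    if (tis == "gm") delta_gm <- delta else delta_wm <- delta

    # change in CVR vs change in Gd+ lesion count (session 3 - session 1)
    if ("gd_count" %in% names(table)) {
      ms1 <- table[table$group == "MS" & table$session == 1, , drop = FALSE]
      d_gd <- ms_on$gd_count[match(pre$subject, ms_on$subject)] -
        ms1$gd_count[match(pre$subject, ms1$subject)]
      run(paste0("delta_vs_gd_change_", tis), pearson_cor(d_gd, delta))
    }
  }

  # lesion vs WM CVR, per session, among lesion-positive subjects
  if (all(c("cvr_lesion", "gd_count") %in% names(table))) {
    for (s in sort(unique(table$session[table$group == "MS"]))) {
      rows <- table[table$group == "MS" & table$session == s &
                      table$gd_count > 0 & is.finite(table$cvr_lesion), ,
                    drop = FALSE]
      run(paste0("lesion_vs_wm_s", s),
          ttest_paired(rows$cvr_lesion, rows$cvr_wm))
    }
  }

  # CVR vs normalised tissue volume, per group/phase, with Fisher z
  if (all(c("vol_gm", "vol_wm") %in% names(table))) {
    vol_sets <- list(
      hc = list(rows = hc, gm = hc$cvr_gm, wm = hc$cvr_wm),
      ms_pre = {
        ms1 <- table[table$group == "MS" & table$session == 1, , drop = FALSE]
        list(rows = ms1[match(pre$subject, ms1$subject), , drop = FALSE],
             gm = pre$pre_cvr_gm, wm = pre$pre_cvr_wm)
      },
      ms_on = list(rows = ms_on, gm = ms_on$cvr_gm, wm = ms_on$cvr_wm))
    for (nm in names(vol_sets)) {
      vs <- vol_sets[[nm]]
      for (tis in c("gm", "wm")) {
        key <- paste0("vol_vs_cvr_", nm, "_", tis)
        run(key, {
          r <- pearson_cor(vs$rows[[paste0("vol_", tis)]], vs[[tis]])
          r$note <- sprintf("fisher_z = %.4f", fisher_z(r$estimate))
          r
        })
      }
    }
  }

  structure(list(
    tests = tests,
    delta = data.frame(
      subject = pre$subject,
      delta_cvr_gm = if (exists("delta_gm", inherits = FALSE)) delta_gm else NA,
      delta_cvr_wm = if (exists("delta_wm", inherits = FALSE)) delta_wm else NA),
    exclusions = list(pretreatment = attr(pre, "excluded")),
    meta = list(p_adjustment = "none (uncorrected)",
                delta_definition = "session 3 minus pre-treatment average")
  ), class = "cvr_cohort_results")
}
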