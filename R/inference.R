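#' Linear mixed model for group and time effects on habituation slope
#'
#' Fits `b_prime ~ group + visit (+ group:visit) + (1 | participant)` by
#' REML: group as a fixed between-subject factor, visit (time) as a repeated
#' fixed factor, and a participant random intercept (compound symmetry).
#' Participants with a single visit are retained. For each fixed effect the
#' Wald F (squared t), denominator df, p-value, Cohen's d and — for the
#' group effect — the percent-slower re-expression are reported.
#'
#' Denominator df methods: `"between-within"` assigns the between-subject
#' (group) effect `n_subjects - 2` df and within-subject effects
#' `n_obs - n_subjects - p_within`; `"satterthwaite"` uses the lmerTest
#' approximation.
#'
#' @param slopes data.frame for one region with columns `participant_id`,
#'   `group` (control/patient), `visit`, `b_prime`.
#' @param interaction include the group x visit interaction.
#' @param ddf denominator-df method.
#' @param d_formula function `(t, df) -> d`; default `2 * t / sqrt(df)`.
#' @param region optional region label copied into the output.
#' @return data.frame, one row per effect: `region`, `effect`, `beta`, `se`,
#'   `F`, `df_num`, `df_den`, `p`, `cohen_d`, `percent_slower` (group row
#'   only, else `NA`).
#' @export
fit_group_time_model <- function(slopes, interaction = FALSE,
                                 ddf = c("between-within", "satterthwaite"),
                                 d_formula = function(t, df) 2 * t / sqrt(df),
                                 region = NA_character_) {
  ddf <- match.arg(ddf)
  need <- c("participant_id", "group", "visit", "b_prime")
  if (!all(need %in% names(slopes)))
    stop("slopes must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- slopes[is.finite(slopes$b_prime), need]
  if (nrow(d) == 0) stop("no usable slope values", call. = FALSE)
  d$group <- factor(d$group, levels = c("control", "patient"))
  d$visit <- factor(d$visit)
  if (nlevels(droplevels(d$group)) < 2)
    stop("both groups are required to estimate a group effect",
         call. = FALSE)
  if (min(table(d$group[!duplicated(d$participant_id)])) < 2)
    stop("need at least 2 participants per group", call. = FALSE)

  form <- if (interaction && nlevels(d$visit) > 1)
    b_prime ~ group * visit + (1 | participant_id)
  else if (nlevels(d$visit) > 1)
    b_prime ~ group + visit + (1 | participant_id)
  else b_prime ~ group + (1 | participant_id)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     control = ctrl))
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(d)
  n_subj <- length(unique(d$participant_id))

  terms_tab <- c(group = "patient vs control")
  eff_names <- grep("^grouppatient$", names(co), value = TRUE)
  rows <- list()
  effects <- c(group = "grouppatient")
  if (nlevels(d$visit) > 1)
    effects <- c(effects,
                 time = grep("^visit", names(co), value = TRUE)[1])
  if (interaction && nlevels(d$visit) > 1)
    effects <- c(effects,
                 `group:time` = grep(":", names(co), value = TRUE)[1])

  if (ddf == "satterthwaite") {
    tfit <- lmerTest::as_lmerModLmerTest(fit)
    sct <- stats::coef(summary(tfit))
  }
  n_within <- sum(names(effects) != "group")
  for (i in seq_along(effects)) {
    nm <- effects[i]; label <- names(effects)[i]
    beta <- unname(co[nm]); s <- unname(se[nm])
    tval <- beta / s
    df_den <- if (ddf == "satterthwaite") unname(sct[nm, "df"])
    else if (label == "group") n_subj - 2
    else max(n_obs - n_subj - n_within, 1)
    p <- stats::pf(tval^2, 1, df_den, lower.tail = FALSE)
    rows[[label]] <- data.frame(
      region = region, effect = label, beta = beta, se = s, F = tval^2,
      df_num = 1, df_den = df_den, p = p,
      cohen_d = d_formula(tval, df_den),
      percent_slower = if (label == "group") percent_slower(beta)
      else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' One-sample test for habituation (slope less than zero)
#'
#' One-sample t-test of the normalized slopes against 0 (no habituation),
#' one-sided toward negative means: significant results indicate reliable
#' habituation.
#'
#' @param x numeric vector of b' values (NAs dropped).
#' @return list: `n`, `mean`, `sd`, `t`, `df`, `p` (one-sided, H1: mean < 0).
#' @export
one_sample_habituation_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values, got ", n, call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  m <- mean(x)
  tval <- m / (s / sqrt(n))
  list(n = n, mean = m, sd = s, t = tval, df = n - 1,
       p = stats::pt(tval, df = n - 1))
}

#' Within-group habituation tests per group, visit and region
#'
#' @param slopes data.frame with `group`, `visit`, `region`, `b_prime`.
#' @return data.frame, one row per cell with the [one_sample_habituation_test()]
#'   fields.
#' @export
one_sample_by_cell <- function(slopes) {
  cells <- unique(slopes[, c("group", "visit", "region")])
  rownames(cells) <- NULL
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- slopes$group == cells$group[i] & slopes$visit == cells$visit[i] &
      slopes$region == cells$region[i]
    r <- one_sample_habituation_test(slopes$b_prime[sel])
    out[[i]] <- data.frame(n = r$n, mean = r$mean, sd = r$sd, t = r$t,
                           df = r$df, p = r$p)
  }
  cbind(cells, do.call(rbind, out))
}

#' Cohen's d from a model t or F statistic
#'
#' Default formula `d = 2 t / sqrt(df)` with `t = sqrt(F)` for
#' single-numerator-df effects; the formula is pluggable since several
#' variants circulate for mixed designs.
#'
#' @param t t statistic (signed); supply either `t` or `F`.
#' @param F F statistic with 1 numerator df.
#' @param df denominator degrees of freedom, > 0.
#' @param formula function `(t, df) -> d`.
#' @return effect size d (signed like `t` when `t` is supplied).
#' @export
cohen_d_from_model <- function(t = NULL, F = NULL, df,
                               formula = function(t, df) 2 * t / sqrt(df)) {
  stopifnot(df > 0)
  if (is.null(t)) {
    if (is.null(F)) stop("supply t or F", call. = FALSE)
    stopifnot(F >= 0)
    t <- sqrt(F)
  }
  formula(t, df)
}

#' Spearman correlation screen with familywise error control
#'
#' Correlates habituation slope with each clinical/cognitive measure, within
#' families defined by group x visit x region, and applies a familywise
#' correction (Holm step-down by default, valid under dependence) across the
#' measures of each family. Ties are handled by average ranks. A constant
#' column yields an undefined (NA) correlation, flagged rather than dropped.
#'
#' @param data data.frame containing `value_col`, the measure columns and
#'   the family columns.
#' @param measures character vector of measure column names.
#' @param family_vars columns defining a correction family.
#' @param value_col the habituation-slope column.
#' @param method correction method passed to [stats::p.adjust()].
#' @param alpha significance threshold applied to the adjusted p.
#' @param min_pairs minimum complete pairs per test.
#' @return data.frame: family columns, `measure`, `n`, `rho`, `p_raw`,
#'   `p_fwe`, `family_size`, `significant`, `note`.
#' @export
spearman_screen <- function(data, measures,
                            family_vars = c("group", "visit", "region"),
                            value_col = "b_prime", method = "holm",
                            alpha = 0.05, min_pairs = 4) {
  stopifnot(all(c(value_col, measures, family_vars) %in% names(data)))
  fams <- unique(data[, family_vars, drop = FALSE])
  rownames(fams) <- NULL
  out <- list()
  for (i in seq_len(nrow(fams))) {
    sel <- rep(TRUE, nrow(data))
    for (v in family_vars) sel <- sel & data[[v]] == fams[[v]][i]
    sub <- data[sel, ]
    rows <- vector("list", length(measures))
    for (j in seq_along(measures)) {
      x <- sub[[value_col]]; y <- sub[[measures[j]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      rho <- p <- NA_real_; note <- ""
      if (n < min_pairs) {
        note <- sprintf("only %d complete pairs (min %d)", n, min_pairs)
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        note <- "undefined: constant column"
      } else {
        # exact null distribution when tie-free and small; AS89/t otherwise
        ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                               method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[j]] <- data.frame(measure = measures[j], n = n, rho = rho,
                              p_raw = p, note = note)
    }
    fam <- do.call(rbind, rows)
    valid <- is.finite(fam$p_raw)
    fam$p_fwe <- NA_real_
    fam$p_fwe[valid] <- stats::p.adjust(fam$p_raw[valid], method = method)
    fam$family_size <- sum(valid)
    fam$significant <- !is.na(fam$p_fwe) & fam$p_fwe <= alpha
    out[[i]] <- cbind(fams[rep(i, nrow(fam)), , drop = FALSE], fam)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square test for a categorical group comparison
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction, df = (r-1)(c-1).
#'
#' @param tab matrix of non-negative counts, at least 2 x 2.
#' @return list: `statistic`, `df`, `p`, `expected`.
#' @export
categorical_group_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total: expected counts undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Reconstruct integer counts from a printed percentage
#'
#' Recovers the count behind a rounded percentage of a known group size:
#' nearest integer, ties rounded half up.
#'
#' @param percent percentage in `[0, 100]`.
#' @param n group size, > 0.
#' @return named integer vector `c(count, complement)`.
#' @export
reconstruct_counts <- function(percent, n) {
  stopifnot(percent >= 0, percent <= 100, n > 0)
  count <- as.integer(floor(percent * n / 100 + 0.5))
  c(count = count, complement = as.integer(n) - count)
}

#' Power of a two-sided two-sample t-test
#'
#' Exact power under the noncentral t distribution with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` df.
#'
#' @param d standardized effect size.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
two_sample_power <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}
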