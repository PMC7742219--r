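#' Repeated-measures ANOVA on a balanced within-subject table
#'
#' Classical univariate repeated-measures F tests for one or two
#' within-subject factors, fitted with [stats::aov()] using
#' `Error(subject/(A*B))` strata. The default reports uncorrected F tests;
#' `correction = "GG"` adds Greenhouse-Geisser sphericity-adjusted p values
#' computed from the per-effect contrast covariance.
#'
#' @param table long-format `data.frame`, one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of one or two within-subject factor
#'   columns.
#' @param subject name of the subject-identifier column.
#' @param correction `"none"` (default) or `"GG"`.
#' @return `data.frame` with one row per effect: effect, df1, df2, F, p (and
#'   gg_epsilon, p_gg under `"GG"`).
#' @export
rm_anova <- function(table, dv, within, subject = "subject",
                     correction = c("none", "GG")) {
  correction <- match.arg(correction)
  stopifnot(all(c(dv, within, subject) %in% names(table)),
            length(within) %in% 1:2)
  dat <- data.frame(
    y = table[[dv]],
    subject = factor(table[[subject]]),
    lapply(table[within], factor),
    check.names = FALSE
  )
  n_sub <- nlevels(dat$subject)
  if (n_sub < 3) stop("need at least 3 subjects")
  # balanced complete design check
  cells <- interaction(dat[within], drop = FALSE)
  tab <- table(dat$subject, cells)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop_imcoh("design_error",
               "unbalanced design; missing subject x cell combinations: %s",
               paste(utils::head(apply(miss, 1, function(i) {
                 paste(rownames(tab)[i[1]], colnames(tab)[i[2]], sep = ":")
               }), 10), collapse = ", "))
  }

  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(sprintf(
    "y ~ %s + Error(subject/(%s))", rhs, rhs))
  fit <- stats::aov(fml, data = dat)
  sm <- summary(fit)

  effects <- c(within, if (length(within) == 2) {
    paste(within, collapse = ":")
  })
  res <- do.call(rbind, lapply(effects, function(ef) {
    stratum <- sm[[paste0("Error: subject:", ef)]]
    tb <- stratum[[1]]
    row <- trimws(rownames(tb)) == ef
    ss_ef <- tb[row, "Sum Sq"]
    ss_res <- tb[!row, "Sum Sq"][1]
    Fv <- tb[row, "F value"]
    pv <- tb[row, "Pr(>F)"]
    if (!is.finite(Fv)) {   # constant dv: 0/0 -> define F = 0
      if (ss_ef < 1e-24 && ss_res < 1e-24) { Fv <- 0; pv <- 1 }
    }
    data.frame(effect = ef, df1 = tb[row, "Df"], df2 = tb[!row, "Df"][1],
               F = Fv, p = pv, stringsAsFactors = FALSE)
  }))
  if (correction == "GG") {
    wide <- cell_means_wide(dat, within)
    res$gg_epsilon <- vapply(res$effect, function(ef) {
      gg_epsilon(wide, strsplit(ef, ":")[[1]], within)
    }, 0)
    res$p_gg <- stats::pf(res$F, res$df1 * res$gg_epsilon,
                          res$df2 * res$gg_epsilon, lower.tail = FALSE)
    res$p_gg[res$F == 0] <- 1
  }
  rownames(res) <- NULL
  res
}

# subjects x cells matrix of means, with the cell factor layout retained
cell_means_wide <- function(dat, within) {
  cells <- interaction(rev(dat[within]), drop = FALSE, lex.order = FALSE)
  agg <- tapply(dat$y, list(dat$subject, cells), mean)
  attr(agg, "levels") <- lapply(dat[within], levels)
  agg
}

# Greenhouse-Geisser epsilon for one effect from its contrast covariance
gg_epsilon <- function(wide, effect_factors, within) {
  levs <- attr(wide, "levels")
  contr <- function(k) {
    # orthonormal polynomial-free contrasts: Helmert, normalized
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  mats <- lapply(within, function(f) {
    k <- length(levs[[f]])
    if (f %in% effect_factors) contr(k) else matrix(1 / sqrt(k), k, 1)
  })
  # cells vary fastest in the *last* factor of rev(within) layout; build
  # Kronecker in the order matching interaction(rev(dat[within]))
  M <- Reduce(kronecker, rev(mats))
  Y <- wide %*% M
  S <- stats::cov(Y)
  d <- ncol(S)
  if (d < 2) return(1)
  sum(diag(S))^2 / (d * sum(S * S))
}

#' Holm (step-down Bonferroni) adjustment
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return adjusted p values (monotone, capped at 1), same order as input.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Two-sided one-sample t test
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu null-hypothesis mean (default 0).
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    stop_imcoh("degenerate_sample", "zero variance; t statistic undefined")
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate))
}

#' Holm-adjusted pairwise post hoc comparisons
#'
#' Paired t tests between all level pairs of one within-subject factor on
#' per-subject cell means (averaged over any other factors), optionally
#' within each level of a second factor (interaction follow-up), with Holm
#' adjustment across the family.
#'
#' @param table long-format `data.frame`.
#' @param dv,subject column names as in [rm_anova()].
#' @param factor_name factor whose levels are compared.
#' @param by optional second factor: comparisons are run separately within
#'   each of its levels, forming a single Holm family.
#' @return `data.frame` with comparison, (by level,) t, df, p_raw,
#'   p_adjusted, significant (at 0.05).
#' @export
posthoc_pairwise <- function(table, dv, factor_name, subject = "subject",
                             by = NULL) {
  run_level <- function(sub_tab, label) {
    agg <- tapply(sub_tab[[dv]],
                  list(factor(sub_tab[[subject]]),
                       factor(sub_tab[[factor_name]])), mean)
    levs <- colnames(agg)
    combs <- utils::combn(levs, 2, simplify = FALSE)
    do.call(rbind, lapply(combs, function(cc) {
      d <- agg[, cc[1]] - agg[, cc[2]]
      tt <- stats::t.test(d)
      data.frame(by = label, comparison = paste(cc, collapse = " vs "),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  res <- if (is.null(by)) {
    run_level(table, NA_character_)
  } else {
    do.call(rbind, lapply(unique(table[[by]]), function(lv) {
      run_level(table[table[[by]] == lv, , drop = FALSE], as.character(lv))
    }))
  }
  res$p_adjusted <- holm_adjust(res$p_raw)
  res$significant <- res$p_adjusted < 0.05
  if (is.null(by)) res$by <- NULL
  rownames(res) <- NULL
  res
}
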