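# Gated statistical comparison: normality/equal-variance checks decide
# between parametric (repeated-measures ANOVA + Tukey) and nonparametric
# (ANOVA on ranks + Dunn) branches.

#' Normality / equal-variance gate
#'
#' Shapiro-Wilk in every cell and a Brown-Forsythe (median-centred Levene)
#' test across cells. The parametric branch is chosen only if no cell
#' rejects normality and variance homogeneity is not rejected; otherwise
#' the nonparametric branch. Cells with fewer than 3 values, or constant
#' cells (degenerate variance), force the nonparametric branch with a
#' warning.
#'
#' @param groups list of numeric vectors, one per design cell.
#' @param alpha gate significance level.
#' @return an object of class `gate_decision`: `branch`
#'   (`"parametric"`/`"nonparametric"`), per-cell Shapiro p-values, the
#'   Levene p-value, and `alpha`.
#' @export
distribution_gate <- function(groups, alpha = 0.05) {
  stop_if_not(is.list(groups) && length(groups) >= 2,
              "`groups` must be a list of >= 2 cells")
  ns <- lengths(groups)
  if (any(ns < 3)) {
    warning("cell with n < 3: nonparametric branch forced")
    return(structure(list(branch = "nonparametric", shapiro_p = NULL,
                          levene_p = NULL, alpha = alpha),
                     class = "gate_decision"))
  }
  if (any(vapply(groups, function(g) var(g) == 0, logical(1)))) {
    warning("degenerate (constant) cell: nonparametric branch forced")
    return(structure(list(branch = "nonparametric", shapiro_p = NULL,
                          levene_p = NULL, alpha = alpha),
                     class = "gate_decision"))
  }
  sw <- vapply(groups, function(g) shapiro.test(g)$p.value, numeric(1))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), ns))
  lev <- car::leveneTest(y, g)[["Pr(>F)"]][1]
  branch <- if (all(sw > alpha) && lev > alpha) "parametric" else
    "nonparametric"
  structure(list(branch = branch, shapiro_p = sw, levene_p = lev,
                 alpha = alpha),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("<gate_decision: %s branch (alpha = %g)>\n", x$branch,
              x$alpha))
  invisible(x)
}

#' Omnibus test and post hoc comparisons
#'
#' Parametric branch: repeated-measures ANOVA (`aov` with a
#' `Error(subject/epoch)` stratum; adding a between-subject `arm` factor
#' gives the mixed two-way design, with the arm-by-epoch interaction
#' tested against the within-subject error stratum) followed by
#' Tukey-adjusted pairwise comparisons via `emmeans`. Nonparametric
#' branch: Kruskal-Wallis ANOVA on ranks followed by Dunn's pairwise rank
#' tests with Holm adjustment. Subjects with incomplete within-subject
#' data are excluded listwise with a warning.
#'
#' @param design data frame with columns `subject`, `epoch`, `value`, and
#'   optionally `arm` (between-subject factor).
#' @param branch `"parametric"` or `"nonparametric"`, usually from
#'   [distribution_gate()].
#' @param alpha significance level for post hoc flags.
#' @param posthoc compute pairwise comparisons (set `FALSE` to skip, e.g.
#'   in simulations).
#' @return an object of class `stat_result`: `branch`, `statistic` (F or
#'   H), `df` (named), `p`, `label` (e.g. `"F(4,20) = 14.12"`), and a
#'   `posthoc` data frame with adjusted p-values and significance flags.
#' @export
omnibus_and_posthoc <- function(design, branch = c("parametric",
                                                   "nonparametric"),
                                alpha = 0.05, posthoc = TRUE) {
  branch <- match.arg(branch)
  stop_if_not(is.data.frame(design) &&
                all(c("subject", "epoch", "value") %in% names(design)),
              "`design` needs subject, epoch, value columns")
  design$subject <- factor(design$subject)
  design$epoch <- factor(design$epoch)
  two_way <- "arm" %in% names(design) &&
    length(unique(design$arm)) > 1
  if (two_way) design$arm <- factor(design$arm)
  # listwise exclusion of incomplete subjects
  n_lev <- nlevels(design$epoch)
  counts <- table(design$subject, design$epoch)
  complete <- rownames(counts)[apply(counts, 1, function(r) all(r == 1))]
  if (length(complete) < nlevels(design$subject)) {
    warning("incomplete within-subject data: subjects excluded listwise")
    design <- design[design$subject %in% complete, , drop = FALSE]
    design$subject <- droplevels(design$subject)
  }
  stop_if_not(nlevels(design$subject) >= 2, "need >= 2 complete subjects")

  if (branch == "parametric") {
    fml <- if (two_way) {
      value ~ arm * epoch + Error(subject / epoch)
    } else {
      value ~ epoch + Error(subject / epoch)
    }
    # do.call stores the evaluated formula/data in the call so that
    # emmeans can recover them later
    fit <- do.call(stats::aov, list(formula = fml, data = design))
    tab <- summary(fit)[["Error: subject:epoch"]][[1]]
    term <- if (two_way) "arm:epoch" else "epoch"
    row <- grep(paste0("^", term), trimws(rownames(tab)))[1]
    res_row <- grep("Residuals", rownames(tab))
    stat <- tab[row, "F value"]
    df <- c(df1 = tab[row, "Df"], df2 = tab[res_row, "Df"])
    p <- tab[row, "Pr(>F)"]
    label <- sprintf("F(%d,%d) = %.2f", df[1], df[2], stat)
    ph <- NULL
    if (posthoc) {
      em <- emmeans::emmeans(fit, "epoch")
      cmp <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                             adjust = "tukey"))
      ph <- data.frame(comparison = cmp$contrast, estimate = cmp$estimate,
                       p_adj = cmp$p.value,
                       significant = cmp$p.value < alpha)
    }
    statistic <- c(F = unname(stat))
  } else {
    kt <- kruskal.test(design$value, design$epoch)
    statistic <- c(H = unname(kt$statistic))
    df <- c(df = unname(kt$parameter))
    p <- kt$p.value
    label <- sprintf("H(%d) = %.2f", df[1], statistic)
    ph <- if (posthoc) {
      dunn_test(design$value, design$epoch, alpha = alpha)
    } else NULL
  }
  structure(list(branch = branch, statistic = statistic, df = df, p = p,
                 label = label, posthoc = ph, alpha = alpha),
            class = "stat_result")
}

# Dunn's pairwise rank comparisons with Holm adjustment (tie-corrected z
# statistics on the joint ranks).
dunn_test <- function(y, g, alpha = 0.05) {
  g <- factor(g)
  r <- rank(y)
  n <- length(y)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i] + 1 / ni[j]))
    (rbar[i] - rbar[j]) / se
  })
  p <- p.adjust(2 * pnorm(-abs(z)), method = "holm")
  data.frame(comparison = paste(pairs[1, ], "-", pairs[2, ]),
             estimate = z, p_adj = p, significant = p < alpha)
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result: %s, %s, p = %.4g>\n", x$branch, x$label, x$p))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

#' Serialise a statistical result to JSON
#'
#' @param x a `stat_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stat_json <- function(x, path) {
  out <- list(branch = x$branch, statistic = unname(x$statistic),
              statistic_name = names(x$statistic), df = as.list(x$df),
              p = x$p, label = x$label, posthoc = x$posthoc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
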