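# Group statistics in the conventions of the source field: one-way ANOVA,
# control-anchored multiple comparisons (Dunnett by default), unpaired
# two-tailed Student's t, and a/b/c significance letters.

#' Map a p-value to its significance letter
#'
#' `"a"` for p < 0.05, `"b"` for p < 0.01, `"c"` for p < 0.001 (the most
#' extreme applicable letter), `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of letters.
#' @export
significance_letter <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "c" else if (pi < 0.01) "b" else if (pi < 0.05) "a"
    else ""
  }, character(1))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with (k - 1, N - k) degrees of
#' freedom, computed via [stats::aov()]. Degenerate inputs follow the
#' documented conventions: zero within-group variance with equal group
#' means gives p = 1 (F = 0); with unequal means, p = 0 (F = Inf).
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return List: `F`, `p`, `df` (c(between, within)).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_param("groups", "need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop_param("groups", "each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  df <- c(between = length(groups) - 1L, within = length(y) - length(groups))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw < .Machine$double.eps * sum(y^2 + 1)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) < 1e-12)
      return(list(F = 0, p = 1, df = df))
    return(list(F = Inf, p = 0, df = df))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df = c(between = tab[1L, "Df"], within = tab[2L, "Df"]))
}

#' Unpaired two-tailed t-test
#'
#' Student (pooled-variance) by default; Welch optional. Two identical
#' constant samples give p = 1 by convention.
#'
#' @param sample_a,sample_b numeric vectors, each n >= 2.
#' @param welch logical; use the Welch unequal-variance statistic.
#' @return List: `t`, `p`, `df`.
#' @export
two_group_t_test <- function(sample_a, sample_b, welch = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop_param("sample_a/sample_b", "each sample needs n >= 2")
  v <- stats::var(sample_a) + stats::var(sample_b)
  if (v < .Machine$double.eps) {
    if (abs(mean(sample_a) - mean(sample_b)) < 1e-12)
      return(list(t = 0, p = 1,
                  df = length(sample_a) + length(sample_b) - 2L))
    return(list(t = Inf, p = 0,
                df = length(sample_a) + length(sample_b) - 2L))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare every group against a control group
#'
#' Runs the omnibus one-way ANOVA, then per-group comparisons against the
#' control: Dunnett's many-to-one procedure ([multcomp::glht()]) by
#' default, or Holm-adjusted pairwise Student t-tests. Each non-control
#' group receives the a/b/c letter of its adjusted p-value.
#'
#' @param groups named list of numeric vectors (names = group labels).
#' @param control_label name of the control group (e.g. `"WT"`).
#' @param method `"dunnett"` or `"holm_t"`.
#' @return A `group_comparison` object: `summary` data.frame (group, n,
#'   mean, sd), `anova` (F, p), `comparisons` data.frame (group, p_value,
#'   letter), `method`, `control`.
#' @export
compare_to_control <- function(groups, control_label,
                               method = c("dunnett", "holm_t")) {
  method <- match.arg(method)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_param("groups", "must be a named list of samples")
  if (!control_label %in% names(groups))
    stop_param("control_label",
               sprintf("group '%s' not present", control_label))
  if (any(lengths(groups) < 2L))
    stop_param("groups", "each group needs n >= 2")

  omnibus <- one_way_anova(groups)
  others <- setdiff(names(groups), control_label)
  summ <- data.frame(
    group = names(groups),
    n = as.integer(lengths(groups)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL)

  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (method == "dunnett" && ssw > .Machine$double.eps) {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)),
                levels = c(control_label, others))
    fit <- stats::aov(y ~ g)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    pv <- summary(gl)$test$pvalues
    pvals <- stats::setNames(as.numeric(pv)[seq_along(others)], others)
  } else {
    raw <- vapply(others, function(nm)
      two_group_t_test(groups[[nm]], groups[[control_label]])$p, numeric(1))
    pvals <- stats::setNames(stats::p.adjust(raw, "holm"), others)
    if (method == "dunnett") method <- "holm_t"   # degenerate-variance fallback
  }

  structure(
    list(summary = summ,
         anova = omnibus,
         comparisons = data.frame(group = others,
                                  p_value = unname(pvals[others]),
                                  letter = significance_letter(pvals[others]),
                                  row.names = NULL),
         method = method, control = control_label),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison vs control '%s' (%s)\n", x$control, x$method))
  cat(sprintf("  omnibus ANOVA: F = %.4g, p = %.3g\n", x$anova$F, x$anova$p))
  df <- merge(x$summary, rbind(
    data.frame(group = x$control, p_value = NA_real_, letter = ""),
    x$comparisons), by = "group", sort = FALSE)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

as_comparison_table <- function(gc, variable) {
  df <- merge(gc$summary,
              rbind(data.frame(group = gc$control, p_value = NA_real_,
                               letter = ""),
                    gc$comparisons),
              by = "group", sort = FALSE)
  cbind(variable = variable, df)
}
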