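#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' One within-subject factor (assembly model or complexity block) crossed
#' with one between-subject factor (assistance system). Sums of squares
#' follow the classical split-plot decomposition: the between-group effect is
#' tested against subjects-within-groups, the within effect and the
#' interaction against the within-subjects residual. Effect sizes are partial
#' eta squared, `SS_effect / (SS_effect + SS_error_of_effect)`. No
#' sphericity correction is applied (the headline complexity factor has two
#' levels, for which sphericity holds trivially; 4-level analyses report
#' uncorrected F).
#'
#' @param data Long-format data frame.
#' @param dv,within,between,id Column names (strings) of the dependent
#'   variable, within factor, between factor and subject identifier.
#' @return A tibble with one row per effect (`between`, `within`,
#'   `interaction`): `df1`, `df2`, `ss`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq`. F is `NA` when the corresponding error SS is zero.
#' @export
#' @examples
#' d <- expand.grid(id = paste0("s", 1:6), model = c("A", "B"))
#' d$grp <- rep(c("g1", "g2"), each = 6)
#' set.seed(1); d$y <- rnorm(12)
#' mixed_anova(d, dv = "y", within = "model", between = "grp", id = "id")
mixed_anova <- function(data, dv = "value", within = "model",
                        between = "system", id = "participant_id") {
  y <- data[[dv]]
  w <- as.factor(data[[within]])
  g <- as.factor(data[[between]])
  s <- as.factor(data[[id]])
  if (anyNA(y)) stop("missing values in the dependent variable")
  # every subject must have every within level exactly once
  tab <- table(s, w)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(bad)) {
    stop("incomplete within-subject data for: ",
         paste(bad, collapse = ", "))
  }
  subj_group <- tapply(as.character(g), s, function(x) unique(x)[1])
  n_g <- table(factor(subj_group, levels = levels(g)))
  if (any(n_g < 2)) stop("need >= 2 subjects per between-subject group")
  J <- nlevels(w)
  N <- nlevels(s)

  grand <- mean(y)
  m_subj <- tapply(y, s, mean)
  m_grp <- tapply(m_subj, factor(subj_group, levels = levels(g)), mean)
  m_cond <- tapply(y, w, mean)
  m_cell <- tapply(y, list(g, w), mean)

  ss_total <- sum((y - grand)^2)
  ss_subj_total <- J * sum((m_subj - grand)^2)
  ss_between <- J * sum(as.numeric(n_g) * (m_grp - grand)^2)
  ss_subj_within <- ss_subj_total - ss_between
  ss_cond <- N * sum((m_cond - grand)^2)
  resid_cell <- sweep(sweep(m_cell, 1, m_grp, "-"), 2,
                      m_cond - grand, "-")
  ss_inter <- sum(as.numeric(n_g) * resid_cell^2)
  ss_err_within <- ss_total - ss_subj_total - ss_cond - ss_inter

  G <- nlevels(g)
  eff <- function(name, ss, df1, ss_err, df2) {
    if (ss_err <= .Machine$double.eps * max(1, ss_total)) {
      f <- NA_real_; p <- NA_real_
    } else {
      f <- (ss / df1) / (ss_err / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else 0
    tibble::tibble(effect = name, df1 = df1, df2 = df2, ss = ss,
                   ss_error = ss_err, F = f, p = p, partial_eta_sq = pes)
  }
  dplyr::bind_rows(
    eff("between", ss_between, G - 1, ss_subj_within, N - G),
    eff("within", ss_cond, J - 1, ss_err_within, (N - G) * (J - 1)),
    eff("interaction", ss_inter, (G - 1) * (J - 1), ss_err_within,
        (N - G) * (J - 1))
  )
}
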