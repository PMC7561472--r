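#' Spearman correlation matrix over the descriptor panel
#'
#' Pairwise Spearman rank correlations with tie-corrected (asymptotic)
#' p-values, optionally restricted to a subset of stages (all stages,
#' 16-64, or per-stage analyses). Constant columns yield `NA` coefficients.
#'
#' @param records data.frame of blastomere records.
#' @param variables columns to correlate (default: the quantified shape and
#'   position panel plus `nc_yap`).
#' @param stages optional integer vector; keeps records whose `stage` is in
#'   the set.
#' @return object of class `correlation_report`: `rho` and `p` matrices
#'   (symmetric, unit diagonal), `n` pairwise counts, `stages`.
#' @export
correlate_records <- function(records,
                              variables = c("nc_yap", "prop_exposed",
                                            "prop_contact", "aj_ratio",
                                            "sphericity", "oblateness",
                                            "prolateness", "volume",
                                            "total_area"),
                              stages = NULL) {
  if (!is.null(stages)) records <- records[records$stage %in% stages, ]
  variables <- intersect(variables, names(records))
  if (nrow(records) < 5L) stop("need at least 5 records")
  X <- records[, variables, drop = FALSE]
  m <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, m, m,
                             dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      ok <- is.finite(X[[i]]) & is.finite(X[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 5L || stats::sd(X[[i]][ok]) == 0 ||
          stats::sd(X[[j]][ok]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(X[[i]][ok], X[[j]][ok], method = "spearman",
                        exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    nmat[i, i] <- sum(is.finite(X[[i]]))
  }
  structure(list(rho = rho, p = p, n = nmat, stages = stages),
            class = "correlation_report")
}

# Dunn's rank-based post-hoc test after Kruskal-Wallis, with tie correction;
# p-values reported raw and Holm-adjusted.
dunn_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  g <- levels(groups)
  cmb <- utils::combn(seq_along(g), 2)
  rows <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z <- (rbar[i] - rbar[j]) / se
    data.frame(group1 = g[i], group2 = g[j], z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Normality-gated group comparison
#'
#' Applies the Shapiro-Wilk test to each group at `alpha = 0.05`; when every
#' group is compatible with normality the omnibus test is one-way ANOVA
#' followed by Tukey's HSD, otherwise Kruskal-Wallis followed by Dunn's test
#' (raw and Holm-adjusted p-values). Groups with fewer than 3 observations
#' cause the omnibus test to be skipped with a warning.
#'
#' @param records data.frame.
#' @param grouping name of the grouping column.
#' @param variable name of the numeric response column.
#' @param alpha normality-gate level (default 0.05).
#' @return object of class `group_test`: `test` ("anova" or
#'   "kruskal-wallis"), `statistic`, `p`, `posthoc` table, `shapiro`
#'   per-group p-values.
#' @export
group_tests <- function(records, grouping, variable, alpha = 0.05) {
  g <- droplevels(as.factor(records[[grouping]]))
  v <- records[[variable]]
  ok <- is.finite(v) & !is.na(g)
  g <- droplevels(g[ok]); v <- v[ok]
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- tapply(v, g, length)
  if (any(ns < 3L)) {
    warning("group(s) with fewer than 3 observations: omnibus test skipped")
    return(structure(list(test = NA_character_, statistic = NA_real_,
                          p = NA_real_, posthoc = NULL, shapiro = NULL),
                     class = "group_test"))
  }
  shapiro_p <- vapply(levels(g), function(l) {
    x <- v[g == l]
    if (length(x) > 5000) x <- sample(x, 5000)
    if (stats::sd(x) == 0) return(0) # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))

  if (all(shapiro_p > alpha)) {
    fit <- stats::aov(v ~ g)
    sm <- summary(fit)[[1]]
    posthoc <- as.data.frame(stats::TukeyHSD(fit)$g)
    posthoc$comparison <- rownames(posthoc)
    rownames(posthoc) <- NULL
    out <- list(test = "anova", statistic = sm[["F value"]][1],
                p = sm[["Pr(>F)"]][1], posthoc = posthoc,
                shapiro = shapiro_p)
  } else {
    kw <- stats::kruskal.test(v, g)
    out <- list(test = "kruskal-wallis", statistic = unname(kw$statistic),
                p = kw$p.value, posthoc = dunn_test(v, g),
                shapiro = shapiro_p)
  }
  structure(out, class = "group_test")
}

#' Fisher's exact test for a 2 x 2 count table
#'
#' Convenience wrapper used for high/low N/C YAP composition contrasts
#' across stages or conditions.
#'
#' @param tab a 2 x 2 matrix or table of counts.
#' @return htest object from [stats::fisher.test()].
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  stats::fisher.test(tab)
}

#' Compare control and confined cohorts
#'
#' Per-variable medians and shift tests between a control (spherical) and a
#' confined (cylinder or slab) cohort, plus a joint Ward clustering of the
#' pooled records with per-cluster arm composition — the in-silico analogue
#' of comparing marginal distributions and cluster memberships between
#' freely developing and mechanically confined embryos.
#'
#' @param control data.frame of control blastomere records.
#' @param confined data.frame of confined blastomere records.
#' @param variables variables to compare (default `prop_exposed`, `nc_yap`).
#' @return object of class `confinement_report`: `medians` (per arm and
#'   variable), `shift_tests` (one [group_tests()] per variable),
#'   `cluster_model`, `composition` (percentage of each arm per cluster).
#' @export
confinement_compare <- function(control, confined,
                                variables = c("prop_exposed", "nc_yap")) {
  stopifnot(nrow(control) > 0, nrow(confined) > 0,
            all(variables %in% names(control)),
            all(variables %in% names(confined)))
  pooled <- rbind(
    cbind(control[, variables, drop = FALSE], arm = "control",
          stage = control$stage),
    cbind(confined[, variables, drop = FALSE], arm = "confined",
          stage = confined$stage))

  medians <- sapply(variables, function(v)
    tapply(pooled[[v]], pooled$arm, stats::median, na.rm = TRUE))
  shift_tests <- lapply(variables, function(v)
    tryCatch(group_tests(pooled, "arm", v),
             warning = function(w) { warning(w); NULL }))
  names(shift_tests) <- variables

  ok <- apply(is.finite(as.matrix(pooled[, variables])), 1, all)
  cm <- tryCatch(hier_cluster(pooled[ok, , drop = FALSE], variables),
                 warning = function(w) suppressWarnings(
                   hier_cluster(pooled[ok, , drop = FALSE], variables)))
  comp <- table(arm = pooled$arm[ok], cluster = cm$labels)
  comp_pct <- 100 * prop.table(comp, margin = 1)

  structure(list(medians = medians, shift_tests = shift_tests,
                 cluster_model = cm, composition = comp_pct,
                 counts = comp),
            class = "confinement_report")
}
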