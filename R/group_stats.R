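## canonical display order of the study groups; unknown labels follow
## alphabetically
.groupOrder <- function(groups) {
  canon <- c("H", "MSON-", "MSON+")
  c(intersect(canon, groups), sort(setdiff(groups, canon)))
}

.pairLabel <- function(g1, g2) paste(g1, "vs", g2)

## Welch two-sample test on subject means; fallback when the mixed fit
## fails. Collapsing to one value per subject removes the inter-eye
## dependence at the cost of some power.
.welchOnSubjectMeans <- function(sub, g1, g2) {
  m1 <- tapply(sub$value[sub$group == g1], sub$subject[sub$group == g1], mean)
  m2 <- tapply(sub$value[sub$group == g2], sub$subject[sub$group == g2], mean)
  if (length(m1) < 2L || length(m2) < 2L)
    return(list(estimate = mean(m1) - mean(m2), se = NA_real_,
                p = NA_real_))
  v <- var(m1) / length(m1) + var(m2) / length(m2)
  est <- mean(m1) - mean(m2)
  df <- v^2 / ((var(m1) / length(m1))^2 / (length(m1) - 1) +
               (var(m2) / length(m2))^2 / (length(m2) - 1))
  list(estimate = est, se = sqrt(v), p = 2 * pt(-abs(est / sqrt(v)), df))
}

#' Mixed-model group comparison of a feature table
#'
#' For every (layer, region, metric) cell, fits the linear mixed model
#' `value ~ 0 + group + (1 | subject)` by REML — the random intercept
#' per subject corrects for the correlation between two eyes of one
#' subject — and reports each pairwise group contrast with its Wald
#' standard error and normal-approximation p-value. When every subject
#' contributes a single eye the fit is singular and the contrasts
#' coincide with one-way ANOVA contrasts. If the mixed fit fails, the
#' cell falls back to Welch tests on subject means, with a warning.
#'
#' @param featureTable Long data.frame with columns
#'   `subject, group, layer, region, metric, value` (the `eye` column
#'   is not needed). Missing values are dropped per cell.
#' @param metric Optional filter: only these metrics are tested.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.001, a deliberately strict level standing in for
#'   multiplicity control).
#' @return data.frame with one row per cell and group pair: `layer`,
#'   `region`, `metric`, `pair`, `estimate` (first group minus second),
#'   `se`, `p_value`, `significant`, `method` (`"lmm"` or `"welch"`);
#'   a pair whose groups are not both present in a cell gets `NA`
#'   results.
#' @export
mixedModelCompare <- function(featureTable, metric = NULL, alpha = 0.001) {
  ft <- featureTable
  need <- c("subject", "group", "layer", "region", "metric", "value")
  stopifnot(all(need %in% names(ft)))
  if (!is.null(metric)) ft <- ft[ft$metric %in% metric, ]
  ft <- ft[!is.na(ft$value), ]
  if (!nrow(ft)) stop("no usable rows in the feature table")
  allGroups <- .groupOrder(unique(ft$group))
  if (length(allGroups) < 2L) stop("need at least two groups")
  pairs <- utils::combn(allGroups, 2L, simplify = FALSE)
  cells <- unique(ft[, c("layer", "region", "metric")])
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- ft[ft$layer == cells$layer[ci] & ft$region == cells$region[ci] &
              ft$metric == cells$metric[ci], ]
    present <- .groupOrder(unique(sub$group))
    fit <- NULL
    method <- "lmm"
    if (length(present) >= 2L) {
      sub$group <- factor(sub$group, levels = present)
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(value ~ 0 + group + (1 | subject), data = sub,
                     REML = TRUE, control = ctrl))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        ## with (near-)zero residual variance the REML variance
        ## partition degenerates (e.g. exactly duplicated eyes) and the
        ## Wald SEs overstate precision; subject means then carry all
        ## the information, so test those instead
        vc <- lme4::VarCorr(fit)
        residSd <- attr(vc, "sc")
        subjSd <- as.data.frame(vc)$sdcor[1L]
        if (is.finite(residSd) &&
            residSd^2 < 1e-8 * (residSd^2 + subjSd^2))
          fit <- NULL
      }
      if (is.null(fit)) {
        method <- "welch"
        warning(sprintf(
          "mixed fit unusable for %s / %s / %s; using Welch tests on subject means",
          cells$layer[ci], cells$region[ci], cells$metric[ci]))
      }
    }
    for (pr in pairs) {
      g1 <- pr[1L]; g2 <- pr[2L]
      est <- se <- p <- NA_real_
      meth <- NA_character_
      if (all(pr %in% present)) {
        if (!is.null(fit)) {
          beta <- lme4::fixef(fit)
          V <- as.matrix(stats::vcov(fit))
          L <- as.numeric(present == g1) - as.numeric(present == g2)
          est <- sum(L * beta)
          se <- sqrt(drop(t(L) %*% V %*% L))
          p <- 2 * pnorm(-abs(est / se))
          meth <- "lmm"
        } else {
          w <- .welchOnSubjectMeans(sub, g1, g2)
          est <- w$estimate; se <- w$se; p <- w$p
          meth <- "welch"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        layer = cells$layer[ci], region = cells$region[ci],
        metric = cells$metric[ci], pair = .pairLabel(g1, g2),
        estimate = est, se = se, p_value = p,
        significant = if (is.na(p)) NA else p < alpha,
        method = meth, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group summary table of a feature table
#'
#' Per (group, layer, region, metric): the number of eyes, mean, SD and
#' SE of the eye-level values, mirroring the layout of published group
#' tables (mean and dispersion per group column).
#'
#' @param featureTable Long feature-table data.frame.
#' @return data.frame with columns `group, layer, region, metric, n,
#'   mean, sd, se`; `sd`/`se` are `NA` for a single eye.
#' @export
summarizeGroups <- function(featureTable) {
  ft <- featureTable[!is.na(featureTable$value), ]
  key <- ft[, c("group", "layer", "region", "metric")]
  agg <- aggregate(ft$value, by = key, FUN = function(v)
    c(n = length(v), mean = mean(v), sd = sd(v)))
  stats <- as.data.frame(agg$x)
  out <- data.frame(agg[, c("group", "layer", "region", "metric")],
                    n = as.integer(stats$n), mean = stats$mean,
                    sd = stats$sd, se = stats$sd / sqrt(stats$n),
                    stringsAsFactors = FALSE)
  ord <- order(out$metric, out$layer, out$region,
               match(out$group, .groupOrder(unique(out$group))))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
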