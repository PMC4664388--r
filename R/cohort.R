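#' CohortSpec: parameters of the cohort-level feature simulator
#'
#' Drives draws of eye-level feature values with the statistical
#' structure the group comparison assumes: per (layer, region, metric)
#' cell and group, each subject receives a random intercept with
#' variance `rho * sigma^2` and each eye an independent residual with
#' variance `(1 - rho) * sigma^2` around the group mean, so two eyes of
#' one subject correlate at `rho`. When `dispersionIsSE` is `TRUE` the
#' printed dispersion is treated as a standard error of the group mean
#' and scaled to an eye-level SD by `sigma = dispersion * sqrt(n_eyes)`.
#'
#' @slot groups data.frame with columns `group`, `n_eyes`,
#'   `n_subjects`.
#' @slot params data.frame with columns `layer`, `region`, `metric`,
#'   `group`, `mean`, `dispersion`.
#' @slot rho Between-eye within-subject correlation, in `[0, 1)`.
#' @slot dispersionIsSE Interpret dispersions as standard errors.
#' @slot seed RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    groups         = "data.frame",
    params         = "data.frame",
    rho            = "numeric",
    dispersionIsSE = "logical",
    seed           = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  g <- object@groups
  if (!all(c("group", "n_eyes", "n_subjects") %in% names(g)))
    return("groups needs columns group, n_eyes, n_subjects")
  if (any(g$n_eyes < g$n_subjects))
    return("n_eyes must be >= n_subjects in every group")
  if (any(g$n_eyes > 2L * g$n_subjects))
    return("at most two eyes per subject")
  p <- object@params
  if (!all(c("layer", "region", "metric", "group", "mean", "dispersion")
           %in% names(p)))
    return("params needs columns layer, region, metric, group, mean, dispersion")
  if (any(p$dispersion <= 0)) return("dispersions must be positive")
  if (object@rho < 0 || object@rho >= 1) return("rho must be in [0, 1)")
  TRUE
})

#' Construct a cohort specification
#'
#' @param groups data.frame with columns `group`, `n_eyes`,
#'   `n_subjects`.
#' @param params data.frame with columns `layer`, `region`, `metric`,
#'   `group`, `mean`, `dispersion` (one row per cell and group).
#' @param rho Between-eye within-subject correlation (default 0.5).
#' @param dispersionIsSE Treat dispersions as SEs of the group mean and
#'   scale them to eye-level SDs (default `TRUE`; printed group tables
#'   usually report SEs this small).
#' @param seed RNG seed.
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(groups, params, rho = 0.5, dispersionIsSE = TRUE,
                       seed = 1L) {
  new("CohortSpec", groups = as.data.frame(groups),
      params = as.data.frame(params), rho = as.numeric(rho),
      dispersionIsSE = as.logical(dispersionIsSE), seed = as.integer(seed))
}

#' Simulate eye-level features for a cohort
#'
#' Draws one value per eye and per (layer, region, metric) cell under
#' the random-intercept model of [CohortSpec-class]. Eyes are assigned
#' to subjects so that the first `n_eyes - n_subjects` subjects of a
#' group contribute two eyes and the rest one; with
#' `n_subjects = n_eyes` the model degenerates to i.i.d. draws.
#'
#' @param spec A [CohortSpec-class].
#' @return A list with `features` (feature-table data.frame:
#'   eye, subject, group, layer, region, metric, value) and `truth`
#'   (the input cell means joined with the eye-level SD actually
#'   used).
#' @export
generateCohortFeatures <- function(spec) {
  validObject(spec)
  p <- spec@params
  sigma <- if (spec@dispersionIsSE) {
    p$dispersion * sqrt(spec@groups$n_eyes[match(p$group, spec@groups$group)])
  } else p$dispersion
  if (any(sigma <= 0)) stop("eye-level sigma must be positive")

  ## eye -> subject map per group
  assign <- do.call(rbind, lapply(seq_len(nrow(spec@groups)), function(i) {
    g <- spec@groups$group[i]
    ne <- spec@groups$n_eyes[i]; ns <- spec@groups$n_subjects[i]
    subjOf <- c(rep(seq_len(ne - ns), each = 2L),
                seq.int(ne - ns + 1L, length.out = 2L * ns - ne))
    data.frame(group = g,
               eye = sprintf("%s_eye%03d", g, seq_len(ne)),
               subject = sprintf("%s_subj%03d", g, subjOf),
               stringsAsFactors = FALSE)
  }))

  features <- withr::with_seed(spec@seed, {
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      eyes <- assign[assign$group == p$group[i], ]
      if (!nrow(eyes)) next
      subj <- unique(eyes$subject)
      b <- setNames(rnorm(length(subj), 0, sqrt(spec@rho) * sigma[i]), subj)
      val <- p$mean[i] + b[eyes$subject] +
        rnorm(nrow(eyes), 0, sqrt(1 - spec@rho) * sigma[i])
      rows[[i]] <- data.frame(
        eye = eyes$eye, subject = eyes$subject, group = eyes$group,
        layer = p$layer[i], region = p$region[i], metric = p$metric[i],
        value = unname(val), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  rownames(features) <- NULL
  truth <- cbind(p, sigma_eye = sigma)
  list(features = features, truth = truth)
}

## Reference group-level summary statistics (mean +/- printed
## dispersion) for the across-all-macular-regions cell of each metric
## and layer, for healthy eyes (H), MS eyes without optic neuritis
## (MSON-) and MS eyes with optic neuritis (MSON+). These published
## summary values parameterize realistic simulated cohorts.
.REF_PARAMS_WIDE <- local({
  txt <- "
metric|layer|H_mean|H_disp|MSONm_mean|MSONm_disp|MSONp_mean|MSONp_disp
thickness_um|RNFL|38.16|0.55|35.44|0.54|32.32|0.54
thickness_um|GCL+IPL|76.06|1.44|67.87|1.40|58.10|1.40
thickness_um|GCC|114.23|1.85|103.28|1.80|90.45|1.95
thickness_um|INL|35.19|0.35|35.38|0.35|35.26|0.36
thickness_um|OPL|41.70|0.58|41.58|0.55|39.92|0.59
thickness_um|ONL+IS|86.23|1.21|88.20|1.11|89.62|1.19
thickness_um|OS|16.48|0.59|16.58|0.57|16.28|0.62
thickness_um|RPE|13.15|0.18|13.58|0.17|13.21|0.19
contrast_au|RNFL|1562|26|1663|25|1820|27
contrast_au|GCL+IPL|1531|21|1587|21|1727|22
contrast_au|GCC|3093|43|3251|42|3546|46
contrast_au|INL|1394|31|1428|30|1577|32
contrast_au|OPL|1314|21|1325|20|1426|21
contrast_au|ONL+IS|851|15|862|14|839|15
contrast_au|OS|3506|70|3561|67|3650|73
contrast_au|RPE|5264|82|5222|80|5353|86
fractal_dimension_au|RNFL|1.621|0.009|1.637|0.009|1.655|0.009
fractal_dimension_au|GCL+IPL|1.699|0.002|1.695|0.002|1.690|0.002
fractal_dimension_au|GCC|3.321|0.008|3.332|0.008|3.344|0.008
fractal_dimension_au|INL|1.779|0.002|1.785|0.002|1.788|0.002
fractal_dimension_au|OPL|1.508|0.002|1.502|0.002|1.503|0.002
fractal_dimension_au|ONL+IS|1.778|0.006|1.788|0.006|1.794|0.006
fractal_dimension_au|OS|1.701|0.003|1.712|0.003|1.712|0.004
fractal_dimension_au|RPE|1.669|0.002|1.666|0.002|1.668|0.002
layer_index_au|RNFL|11.06|0.25|9.28|0.25|7.90|0.27
layer_index_au|GCL+IPL|13.49|0.33|11.32|0.32|9.84|0.34
layer_index_au|GCC|24.56|0.55|20.62|0.53|17.70|0.57
layer_index_au|INL|4.37|0.13|3.97|0.13|3.98|0.14
layer_index_au|OPL|6.39|0.20|5.84|0.20|5.57|0.21
layer_index_au|ONL+IS|7.49|0.23|6.67|0.22|6.83|0.24
layer_index_au|OS|6.05|0.14|5.70|0.13|5.67|0.14
layer_index_au|RPE|6.47|0.08|6.55|0.07|6.45|0.08
total_reflectance_db|RNFL|21.52|0.26|19.90|0.26|18.54|0.28
total_reflectance_db|GCL+IPL|22.50|0.29|20.76|0.28|19.62|0.30
total_reflectance_db|GCC|45.72|0.53|42.14|0.51|39.40|0.56
total_reflectance_db|INL|13.03|0.30|12.10|0.29|12.17|0.31
total_reflectance_db|OPL|14.30|0.29|13.52|0.28|13.48|0.30
total_reflectance_db|ONL+IS|16.98|0.32|15.99|0.31|16.28|0.34
total_reflectance_db|OS|15.89|0.21|15.30|0.20|15.20|0.22
total_reflectance_db|RPE|16.43|0.10|16.58|0.09|16.45|0.10
"
  read.csv(text = txt, sep = "|", stringsAsFactors = FALSE)
})

#' Reference cohort parameters for the three study groups
#'
#' Published group-level summary statistics (mean and printed
#' dispersion) of each metric for each intraretinal layer across all
#' macular regions, for healthy eyes and MS eyes without / with a
#' history of optic neuritis. In long format, ready to subset into a
#' [cohortSpec()] `params` argument.
#'
#' @param metrics,layers Optional filters.
#' @return data.frame with columns `layer`, `region` (always
#'   `"across_all"`), `metric`, `group`, `mean`, `dispersion`.
#' @seealso [referenceGroupSizes()]
#' @export
referenceCohortParams <- function(metrics = metricNames(),
                                  layers = analysisLayers()) {
  w <- .REF_PARAMS_WIDE
  long <- do.call(rbind, lapply(
    list(c("H", "H_mean", "H_disp"),
         c("MSON-", "MSONm_mean", "MSONm_disp"),
         c("MSON+", "MSONp_mean", "MSONp_disp")),
    function(g) data.frame(
      layer = w$layer, region = "across_all", metric = w$metric,
      group = g[1L], mean = w[[g[2L]]], dispersion = w[[g[3L]]],
      stringsAsFactors = FALSE)))
  out <- long[long$metric %in% metrics & long$layer %in% layers, ]
  rownames(out) <- NULL
  out
}

#' Reference study group sizes
#'
#' Eye and subject counts of the three groups: 29 healthy eyes of 24
#' subjects, 31 MSON- eyes of 25 subjects, 36 MSON+ eyes of 26
#' subjects.
#'
#' @return data.frame with columns `group`, `n_eyes`, `n_subjects`.
#' @export
referenceGroupSizes <- function() {
  data.frame(group = c("H", "MSON-", "MSON+"),
             n_eyes = c(29L, 31L, 36L),
             n_subjects = c(24L, 25L, 26L),
             stringsAsFactors = FALSE)
}
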