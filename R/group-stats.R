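# Per-condition aggregation, rank-based group comparisons, plate-assay math.

#' Summarize a per-cell statistic by condition
#'
#' Median, mean and sample SD (n - 1 denominator) of one measurement column
#' per condition. Undefined per-cell values (NA) are excluded and counted.
#'
#' @param measurements a data.frame of per-cell results (e.g. from
#'   [measurementsToDataFrame()] or a per-cell CSV), or a list of
#'   [CellMeasurement-class].
#' @param statistic column to summarize (default \code{"pcc"}).
#' @param groupBy grouping column (default \code{"condition"}).
#' @return data.frame with columns \code{condition}, \code{n},
#'   \code{nExcluded}, \code{median}, \code{mean}, \code{sd}
#' @examples
#' df <- data.frame(condition = "a", pcc = c(1, 2, 3))
#' summarizeGroups(df)
#' @export
summarizeGroups <- function(measurements, statistic = "pcc",
                            groupBy = "condition") {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- measurementsToDataFrame(measurements)
  if (!statistic %in% names(measurements))
    scStop(sprintf("unknown statistic column '%s'", statistic),
           "invalidParameter")
  if (!groupBy %in% names(measurements))
    scStop(sprintf("unknown grouping column '%s'", groupBy),
           "invalidParameter")
  if (!nrow(measurements))
    scStop("no measurements to summarize", "invalidParameter")
  groups <- split(measurements[[statistic]], measurements[[groupBy]])
  out <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    ok <- v[!is.na(v)]
    data.frame(condition = g, n = length(ok),
               nExcluded = length(v) - length(ok),
               median = if (length(ok)) stats::median(ok) else NA_real_,
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = stats::sd(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-group Wilcoxon-Mann-Whitney comparison
#'
#' Two-sided rank-sum test (delegated to [stats::wilcox.test()]; exact where
#' the implementation allows, normal approximation with ties). Completely
#' tied data (every pooled value identical) yields p = 1 with a warning.
#'
#' @param a,b numeric vectors, each with at least 3 values.
#' @return two-sided p-value (numeric scalar with attributes
#'   \code{statistic} and \code{method})
#' @examples
#' compareTwo(1:10, 101:110)
#' @export
compareTwo <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    scStop("each group needs at least 3 values", "invalidParameter")
  if (length(unique(c(a, b))) == 1L) {
    scWarn("all values tied across both groups; p = 1", "degenerateData")
    p <- 1
    attr(p, "statistic") <- NA_real_
    attr(p, "method") <- "Wilcoxon-Mann-Whitney (degenerate)"
    return(p)
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- min(ht$p.value, 1)
  attr(p, "statistic") <- unname(ht$statistic)
  attr(p, "method") <- "Wilcoxon-Mann-Whitney"
  p
}

#' Multi-group comparison: Kruskal-Wallis with Dunn's post-hoc test
#'
#' Omnibus Kruskal-Wallis rank test (delegated to [stats::kruskal.test()])
#' followed by Dunn's pairwise z tests on the pooled mid-ranks with tie
#' correction; pairwise p-values are multiplicity-adjusted (Bonferroni by
#' default). All-identical data yields omnibus p = 1 with a warning.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each >= 3
#'   values).
#' @param adjust multiplicity adjustment for the pairwise p-values, any
#'   method of [stats::p.adjust()] (default \code{"bonferroni"}).
#' @return list with \code{omnibusP}, \code{omnibusStatistic}, \code{df},
#'   \code{pairwise} (data.frame: group1, group2, z, p, pAdj) and
#'   \code{adjust}
#' @examples
#' compareMany(list(a = 1:5, b = 2:6, c = 20:24))
#' @export
compareMany <- function(groups, adjust = "bonferroni") {
  if (length(groups) < 3L)
    scStop("compareMany needs at least 3 groups", "invalidParameter")
  if (any(vapply(groups, length, 0L) < 3L))
    scStop("each group needs at least 3 values", "invalidParameter")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    scWarn("all values identical across groups; omnibus p = 1",
           "degenerateData")
    kwP <- 1; kwStat <- 0
  } else {
    kw <- stats::kruskal.test(groups)
    kwP <- kw$p.value; kwStat <- unname(kw$statistic)
  }
  # Dunn's test: z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)),
  # T = sum(t^3 - t) / (12 (N - 1)) over tie groups of the pooled mid-ranks.
  rk <- rank(pooled)
  N <- length(pooled)
  sizes <- vapply(groups, length, 0L)
  lab <- rep(names(groups), sizes)
  rbar <- tapply(rk, factor(lab, levels = names(groups)), mean)
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    sigma <- sqrt((N * (N + 1) / 12 - tieCorr) *
                  (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[k] <- if (sigma > 0) (rbar[[i]] - rbar[[j]]) / sigma else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = z, p = p,
                         pAdj = stats::p.adjust(p, method = adjust),
                         stringsAsFactors = FALSE)
  list(omnibusP = kwP, omnibusStatistic = kwStat,
       df = length(groups) - 1L, pairwise = pairwise, adjust = adjust)
}

#' Viability and cytotoxicity from plate optical densities
#'
#' Colorimetric (XTT-type) plate assay arithmetic:
#' viability (\%) = (OD_experimental - OD_tcellOnly) /
#' (OD_tumorOnly - OD_medium) x 100 and cytotoxicity (\%) = 100 - viability.
#' Viability outside [0, 100] (possible with noisy ODs) is clamped and
#' flagged, never silently; the viability + cytotoxicity = 100 identity
#' holds exactly pre-clamping.
#'
#' @param odExperimental OD of the experimental wells.
#' @param odTcellOnly OD of wells with the matched T-cell numbers only.
#' @param odTumorOnly OD of tumor-cell-only wells (mean of replicates).
#' @param odMedium background OD of medium-only wells.
#' @param clamp clamp viability to [0, 100] (default TRUE).
#' @return data.frame with columns \code{viability}, \code{cytotoxicity},
#'   \code{clamped} (and unclamped values in attributes
#'   \code{viabilityRaw} / \code{cytotoxicityRaw})
#' @examples
#' cytotoxicityFromOD(0.8, 0.2, 1.2, 0.2)  # viability 60, cytotoxicity 40
#' @export
cytotoxicityFromOD <- function(odExperimental, odTcellOnly, odTumorOnly,
                               odMedium, clamp = TRUE) {
  ods <- c(odExperimental, odTcellOnly, odTumorOnly, odMedium)
  if (anyNA(ods) || any(!is.finite(ods)))
    scStop("all ODs must be finite", "invalidParameter")
  denom <- odTumorOnly - odMedium
  if (any(denom <= 0))
    scStop("OD(tumor only) must exceed OD(medium)", "invalidParameter")
  viaRaw <- (odExperimental - odTcellOnly) / denom * 100
  cytRaw <- 100 - viaRaw
  via <- if (clamp) pmin(pmax(viaRaw, 0), 100) else viaRaw
  out <- data.frame(viability = via, cytotoxicity = 100 - via,
                    clamped = clamp & (viaRaw < 0 | viaRaw > 100))
  attr(out, "viabilityRaw") <- viaRaw
  attr(out, "cytotoxicityRaw") <- cytRaw
  out
}
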