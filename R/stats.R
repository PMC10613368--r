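#' Significance tier from a p-value
#'
#' Tiers follow the usual figure-legend convention: ns, * (< 0.05),
#' ** (< 0.01), *** (< 0.001), **** (< 0.0001).
#'
#' @param p p-value(s).
#' @return character vector of tiers.
#' @export
significanceTier <- function(p) {
    ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
    ifelse(p < 1e-2, "**",
    ifelse(p < 0.05, "*", "ns"))))
}

#' Two-sided Welch's t test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom. Degenerate zero-variance inputs are handled explicitly:
#' equal constant groups give t = 0, p = 1; different constant groups are
#' flagged with an infinite statistic and p reported as 0.
#'
#' @param x,y numeric sample vectors, each of length >= 2.
#' @return data.frame (t, df, p, tier, flag).
#' @export
welchT <- function(x, y) {
    .stopIfNot(length(x) >= 2 && length(y) >= 2,
               "both samples need at least two observations")
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        if (mean(x) == mean(y))
            return(data.frame(t = 0, df = NA_real_, p = 1, tier = "ns",
                              flag = "zero variance, equal means"))
        return(data.frame(t = sign(mean(x) - mean(y)) * Inf,
                          df = NA_real_, p = 0, tier = "****",
                          flag = "zero variance, unequal means"))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, tier = significanceTier(tt$p.value),
               flag = "")
}

#' All pairwise Welch tests with Bonferroni correction
#'
#' Every unordered pair of groups is tested (Welch variant) and p-values
#' are Bonferroni-adjusted across the pairs
#' (\code{p_adj = min(1, p * n_pairs)}), so \code{p_adj >= p} always.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return data.frame (groupA, groupB, t, df, p, pAdj, tier) with the
#'   tier computed from the adjusted p.
#' @export
pairwiseTBonferroni <- function(groups) {
    .stopIfNot(length(groups) >= 2, "at least two groups are required")
    prs <- utils::combn(names(groups), 2)
    rows <- lapply(seq_len(ncol(prs)), function(i) {
        w <- welchT(groups[[prs[1, i]]], groups[[prs[2, i]]])
        data.frame(groupA = prs[1, i], groupB = prs[2, i],
                   t = w$t, df = w$df, p = w$p)
    })
    out <- do.call(rbind, rows)
    out$pAdj <- stats::p.adjust(out$p, method = "bonferroni")
    out$tier <- significanceTier(out$pAdj)
    out
}

#' Principal component analysis of a sample-by-feature matrix
#'
#' Singular value decomposition of the (column-centered, optionally
#' scaled) matrix; zero-variance features are dropped with a message. A
#' fixed sign convention makes scores reproducible: within each
#' component, the loading of largest magnitude is positive.
#'
#' @param m numeric matrix, samples in rows.
#' @param center,scale passed to \code{\link[stats]{prcomp}}.
#' @return list(scores, loadings, varianceExplained).
#' @export
pcaSamples <- function(m, center = TRUE, scale = FALSE) {
    .stopIfNot(nrow(m) >= 2, "at least two samples are required")
    v <- apply(m, 2, stats::var)
    if (any(v == 0)) {
        message(sum(v == 0), " zero-variance feature(s) dropped")
        m <- m[, v > 0, drop = FALSE]
    }
    .stopIfNot(ncol(m) >= 1, "no variable features left")
    pc <- stats::prcomp(m, center = center, scale. = scale)
    for (j in seq_len(ncol(pc$rotation))) {
        if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    list(scores = pc$x, loadings = pc$rotation,
         varianceExplained = pc$sdev^2 / sum(pc$sdev^2))
}
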