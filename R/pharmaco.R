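#' Correlation screen of module scores against a drug-response panel
#'
#' For each compound, Pearson correlation between the bulk module scores and
#' the normalized -log IC50 values over pairwise-complete samples, with a
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#' Negative r means high module score associates with resistance (lower
#' -log IC50). Compounds with fewer than `minN` complete pairs are excluded
#' with the reason recorded. No multiple-testing correction gates the
#' significance flag (the screen draws its cutoff at nominal p = alpha); a
#' Benjamini-Hochberg column is reported alongside.
#'
#' @param scores [ModuleScores-class] (bulk) or named numeric vector; names
#'   must overlap the panel's rownames.
#' @param panel samples x compounds numeric matrix of normalized -log IC50
#'   values (higher = more sensitive); NA allowed.
#' @param minN minimum pairwise-complete samples per compound (default 10).
#' @param alpha significance level for the flag.
#' @return data.frame of class `"screenResult"`: compound, r, n, p, pBH,
#'   significant; excluded compounds in `attr(, "excluded")`.
#' @export
correlateScoreResponse <- function(scores, panel, minN = 10L, alpha = 0.05) {
  s <- if (is(scores, "ModuleScores")) scoreValues(scores) else scores
  common <- intersect(names(s), rownames(panel))
  if (length(common) < minN)
    stop("fewer than minN samples shared between scores and panel")
  s <- s[common]
  panel <- panel[common, , drop = FALSE]
  rows <- lapply(colnames(panel), function(cmpd) {
    y <- panel[, cmpd]
    ok <- is.finite(y) & is.finite(s)
    n <- sum(ok)
    if (n < minN)
      return(data.frame(compound = cmpd, r = NA_real_, n = n, p = NA_real_,
                        excluded = TRUE))
    r <- stats::cor(s[ok], y[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(compound = cmpd, r = r, n = n,
               p = 2 * stats::pt(-abs(tt), df = n - 2), excluded = FALSE)
  })
  res <- do.call(rbind, rows)
  excluded <- res[res$excluded, c("compound", "n")]
  res <- res[!res$excluded, setdiff(names(res), "excluded")]
  res$pBH <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  attr(res, "excluded") <- excluded
  attr(res, "alpha") <- alpha
  class(res) <- c("screenResult", "data.frame")
  res
}

#' Sort a correlation screen by association with resistance
#'
#' Compounds sorted ascending by r (most resistance-associated first); ties
#' broken by compound name. The significance boundary is annotated in the
#' `significant` column and `attr(, "alpha")`.
#'
#' @param result a screen result from [correlateScoreResponse()].
#' @return the sorted table with a `rank` column.
#' @export
rankScreen <- function(result) {
  if (!nrow(result)) stop("screen result is empty")
  out <- result[order(result$r, result$compound), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Four-parameter logistic dose-response (IC50) fit
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)` on log10
#' dose, with multi-start Levenberg-Marquardt initialization over a grid of
#' hill slopes and IC50 candidates. Bounds: top in `[0.5, 1.5] * max
#' response`, bottom in `[0, top]`. A monotone-increasing response profile
#' is flagged with a warning.
#'
#' @param doses positive concentrations (at least 4 distinct levels).
#' @param responses viability at each dose.
#' @return list of class `"doseResponseFit"`: top, bottom, hill, ic50,
#'   rmse, increasingFlag.
#' @examples
#' d <- 10^seq(-1, 3, length.out = 8)
#' y <- 0 + (1 - 0) / (1 + (d / 5)^1)
#' fitIC50(d, y)$ic50
#' @export
fitIC50 <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("doses/responses mismatch")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 4L) stop("at least 4 dose levels required")
  ld <- log10(doses)
  increasing <- stats::cor(ld, responses) > 0
  if (isTRUE(increasing))
    warning("response increases with dose; IC50 may be meaningless")
  topMax <- 1.5 * max(responses)
  topMin <- 0.5 * max(responses)
  starts <- expand.grid(
    hill = c(0.5, 1, 2),
    lic50 = unname(stats::quantile(ld, c(0.25, 0.5, 0.75))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) / (1 + 10^((ld - lic50) * hill)),
        start = list(top = max(responses), bottom = min(responses),
                     hill = starts$hill[i], lic50 = starts$lic50[i]),
        lower = c(top = topMin, bottom = 0, hill = 0.05,
                  lic50 = min(ld) - 3),
        upper = c(top = topMax, bottom = topMax, hill = 20,
                  lic50 = max(ld) + 3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::resid(fit)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fit = fit, rmse = rmse)
  }
  if (is.null(best))
    stop("4PL fit failed to converge from every start; ",
         "check dose range and response scale")
  cf <- stats::coef(best$fit)
  if (cf[["bottom"]] > cf[["top"]]) {     # enforce top >= bottom reporting
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
  }
  structure(list(top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
                 hill = unname(cf[["hill"]]),
                 ic50 = unname(10^cf[["lic50"]]), rmse = best$rmse,
                 increasingFlag = isTRUE(increasing)),
            class = "doseResponseFit")
}

#' Growth-rate-normalized drug response (GR value)
#'
#' `GR = 2^(log2(xTreated/x0) / log2(xCtrl/x0)) - 1`, which normalizes drug
#' sensitivity by cell division: GR = 1 means no effect, GR = 0 complete
#' cytostasis, GR < 0 cytotoxicity. Invariant to multiplying all counts by
#' a constant (plating density).
#'
#' @param x0 cell count at treatment start.
#' @param xCtrl untreated count at assay end; must exceed `x0`.
#' @param xTreated treated count(s) at assay end.
#' @return GR value(s).
#' @examples
#' grValue(1000, 4000, 4000)  # 1: untreated limit
#' grValue(1000, 4000, 1000)  # 0: cytostasis
#' @export
grValue <- function(x0, xCtrl, xTreated) {
  if (any(c(x0, xCtrl, xTreated) <= 0)) stop("all counts must be positive")
  if (xCtrl <= x0) stop("non-growing control: xCtrl must exceed x0")
  2^(log2(xTreated / x0) / log2(xCtrl / x0)) - 1
}

#' GR50: dose at which the GR curve crosses 0.5
#'
#' Fits a logistic GR dose-response
#' `GR(c) = grInf + (1 - grInf) / (1 + (c/gec50)^hill)` on log10 dose and
#' solves for the concentration where the fitted curve equals 0.5. Returns
#' `Inf` with a warning when the curve never reaches 0.5 (grInf >= 0.5).
#'
#' @param doses positive concentrations.
#' @param grValues GR values at each dose.
#' @return GR50 concentration.
#' @export
gr50 <- function(doses, grValues) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(doses) != length(grValues)) stop("doses/grValues mismatch")
  ld <- log10(doses)
  fit <- NULL
  for (h0 in c(1, 0.5, 2, 4)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      grValues ~ grInf + (1 - grInf) / (1 + 10^((ld - lgec50) * hill)),
      start = list(grInf = min(grValues), hill = h0,
                   lgec50 = unname(stats::median(ld))),
      lower = c(grInf = -1, hill = 0.05, lgec50 = min(ld) - 3),
      upper = c(grInf = 1, hill = 20, lgec50 = max(ld) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("GR curve fit failed to converge")
  cf <- stats::coef(fit)
  grInf <- cf[["grInf"]]; hill <- cf[["hill"]]; gec50 <- 10^cf[["lgec50"]]
  if (grInf >= 0.5) {
    warning("fitted GR curve never crosses 0.5; returning Inf")
    return(Inf)
  }
  gec50 * ((1 - grInf) / (0.5 - grInf) - 1)^(1 / hill)
}
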