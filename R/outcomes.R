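#' Fraction of cells expressing each module gene
#'
#' A gene counts as expressed in a cell when its value (e.g. TPM) is
#' strictly greater than `threshold` (default 0).
#'
#' @param tpm genes x cells numeric matrix.
#' @param genes a [GeneModule] or character vector; must intersect the
#'   matrix rows.
#' @param threshold expression threshold.
#' @return named per-gene proportion vector.
#' @export
fractionExpressing <- function(tpm, genes, threshold = 0) {
  if (is(genes, "GeneModule")) genes <- moduleGenes(genes)
  tpm <- .asMatrix(tpm)
  present <- intersect(genes, rownames(tpm))
  if (!length(present)) stop("no requested gene present in the matrix")
  rowMeans(tpm[present, , drop = FALSE] > threshold)
}

#' Per-patient pre/post-treatment score comparison
#'
#' For each patient, a two-sided Wilcoxon rank-sum test compares the
#' per-cell module-score distributions before and after treatment; the
#' direction records whether the post-treatment distribution is
#' stochastically higher. The summary counts patients significantly higher
#' post-treatment at `alpha`.
#'
#' @param preScores,postScores named lists (by patient id) of per-cell
#'   numeric score vectors; every patient must appear in both with at least
#'   3 cells per sample.
#' @param alpha significance level for the summary count.
#' @return data.frame (patient, p, direction, medianPre, medianPost) with
#'   `attr(, "nHigherPost")`.
#' @export
prePostScoreTest <- function(preScores, postScores, alpha = 0.05) {
  patients <- union(names(preScores), names(postScores))
  missing <- patients[!(patients %in% names(preScores) &
                        patients %in% names(postScores))]
  if (length(missing))
    stop("patient(s) missing a timepoint: ", paste(missing, collapse = ", "))
  rows <- lapply(patients, function(p) {
    pre <- preScores[[p]]; post <- postScores[[p]]
    if (length(pre) < 3L || length(post) < 3L)
      stop("patient ", p, " has a sample with fewer than 3 cells")
    # exact null distribution for small samples, normal approximation with
    # tie correction otherwise (wilcox.test's own switching rule)
    wt <- suppressWarnings(
      stats::wilcox.test(post, pre, alternative = "two.sided"))
    dirUp <- unname(wt$statistic) > length(pre) * length(post) / 2
    data.frame(patient = p, p = wt$p.value,
               direction = if (dirUp) "higher-post" else "lower-post",
               medianPre = stats::median(pre),
               medianPost = stats::median(post))
  })
  res <- do.call(rbind, rows)
  attr(res, "nHigherPost") <-
    sum(res$p < alpha & res$direction == "higher-post")
  res
}

#' Paired pre/post test of per-gene expressing fractions
#'
#' Per module gene, the fraction of cells expressing it
#' ([fractionExpressing()]) is averaged across patients at each timepoint;
#' the pre and post per-gene vectors are compared by a two-sided paired
#' t-test across genes.
#'
#' @param preMats,postMats named lists (by patient) of genes x cells TPM (or
#'   count) matrices.
#' @param module a [GeneModule]; at least 2 module genes must be measured
#'   in every matrix.
#' @param threshold expression threshold passed to [fractionExpressing()].
#' @return list with `statistic`, `p`, `meanDelta` (post - pre), and
#'   `perGene` data.frame.
#' @export
prePostFractionTest <- function(preMats, postMats, module, threshold = 0) {
  if (is(module, "GeneModule")) genes <- moduleGenes(module) else
    genes <- module
  common <- Reduce(intersect, c(lapply(preMats, rownames),
                                lapply(postMats, rownames), list(genes)))
  if (length(common) < 2L)
    stop("fewer than 2 module genes measured in every sample")
  fr <- function(mats) rowMeans(vapply(
    mats, function(m) fractionExpressing(m, common, threshold),
    numeric(length(common))))
  fPre <- fr(preMats); fPost <- fr(postMats)
  d <- fPost - fPre
  if (stats::sd(d) < .Machine$double.eps) {
    tt <- list(statistic = 0, p.value = 1)   # no paired variation
  } else tt <- stats::t.test(fPost, fPre, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       meanDelta = mean(d),
       perGene = data.frame(gene = common, pre = fPre, post = fPost))
}

#' Tertile classification of patients by score elevation
#'
#' Patients are sorted by decreasing delta score (post - pre); the top
#' `ceiling(n/3)` are labeled `"ISG-high"` and the remaining two-thirds
#' `"ISG-low"`. Ties at the boundary are broken by stable patient-id order
#' with a warning.
#'
#' @param deltaScores named per-patient numeric vector (names = patient
#'   ids); at least 3 patients, not all equal.
#' @return named factor of strata, levels `c("ISG-low", "ISG-high")`.
#' @examples
#' tertileClassify(setNames(rnorm(42), sprintf("pt%02d", 1:42)))
#' @export
tertileClassify <- function(deltaScores) {
  n <- length(deltaScores)
  if (n < 3L) stop("at least 3 patients required")
  if (diff(range(deltaScores)) < .Machine$double.eps)
    stop("no ordering: all delta scores are equal")
  if (is.null(names(deltaScores)))
    names(deltaScores) <- sprintf("patient%03d", seq_len(n))
  ord <- order(-deltaScores, names(deltaScores))
  nHigh <- ceiling(n / 3)
  boundary <- deltaScores[ord][nHigh]
  if (sum(deltaScores == boundary) > 1 &&
      any(deltaScores[ord][-seq_len(nHigh)] == boundary))
    warning("tie at the tertile boundary broken by patient-id order")
  stratum <- rep("ISG-low", n)
  stratum[ord[seq_len(nHigh)]] <- "ISG-high"
  stats::setNames(factor(stratum, levels = c("ISG-low", "ISG-high")),
                  names(deltaScores))
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function; at tied times events
#' are handled before censorings (censored subjects at time t remain in the
#' risk set for the event at t). Delegates to [survival::survfit()].
#'
#' @param times positive event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame (time, nRisk, nEvent, nCensor, survival) at each
#'   observed time, plus Greenwood standard errors.
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kaplanMeier <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             nCensor = fit$n.censor, survival = fit$surv,
             stdErr = fit$std.err * fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test: observed minus expected events summed over event
#' times with hypergeometric variance; p from chi-square with 1 df.
#' Delegates to [survival::survdiff()]; symmetric in group labels.
#'
#' @param times positive times; or a data.frame with columns `time`,
#'   `event`, `stratum` (then `events`/`groups` are ignored).
#' @param events 0/1 event indicators.
#' @param groups two-level group labels; both strata must be nonempty.
#' @return list with `statistic` (1-df chi-square), `p`, `observed`,
#'   `expected` per group.
#' @examples
#' sim <- simulateSurvivalCohort(40, 0.5, hazardRatio = 4, seed = 1)
#' logrankTest(sim$cohort)$p
#' @export
logrankTest <- function(times, events = NULL, groups = NULL) {
  if (is.data.frame(times)) {
    df <- times
    stopifnot(all(c("time", "event", "stratum") %in% names(df)))
    times <- df$time; events <- df$event; groups <- df$stratum
  }
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("exactly two nonempty strata required")
  groups <- droplevels(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}
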