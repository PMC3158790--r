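# Cohort-level aggregation: Fisher-z averaging of R^2 values, one-way
# repeated-measures ANOVA with Huynh-Feldt adjustment, single-df polynomial
# trend contrasts, and the quality-class table.

#' Fisher-z mean of R^2 values
#'
#' Converts each R^2 (percent) to a correlation \eqn{r = \sqrt{R^2/100}},
#' applies the variance-stabilising Fisher transform \eqn{z = \mathrm{atanh}(r)},
#' averages the z values arithmetically, and back-transforms the mean to an
#' R^2 in percent. The result lies between the minimum and maximum of the
#' inputs and equals the arithmetic mean to first order when the inputs are
#' tightly clustered.
#'
#' @param values Numeric vector of R^2 values in percent, each in (0, 100).
#' @return The Fisher-z mean R^2 in percent.
#' @examples
#' fisherZMean(c(97.8, 82.0, 90.3))
#' @export
fisherZMean <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0) || any(values >= 100))
    stop("R^2 values must lie strictly in (0, 100) percent")
  tanh(mean(atanh(sqrt(values / 100))))^2 * 100
}

#' Fisher z-transform of an R^2 in percent
#'
#' The scale on which the cohort R^2 analyses are run:
#' \eqn{z = \mathrm{atanh}(\sqrt{R^2/100})}.
#'
#' @param r2 R^2 values in percent, each in (0, 100).
#' @return z values.
#' @export
fisherZ <- function(r2) {
  if (any(r2 <= 0) || any(r2 >= 100)) stop("R^2 must lie in (0, 100)")
  atanh(sqrt(r2 / 100))
}

# Coerce a long subject/episode table to a complete subjects x episodes
# matrix for one measure.
.designMatrix <- function(table, measure) {
  stopifnot(all(c("subject", "nrem", measure) %in% names(table)))
  wide <- tapply(table[[measure]], list(table$subject, table$nrem), identity)
  if (anyNA(wide)) stop("incomplete design: every subject needs every episode")
  m <- matrix(as.numeric(wide), nrow = nrow(wide),
              dimnames = dimnames(wide))
  m
}

# Within-subject sums of squares for an n x k complete design.
.rmSS <- function(m) {
  n <- nrow(m); k <- ncol(m); gm <- mean(m)
  ssEffect <- n * sum((colMeans(m) - gm)^2)
  ssSubject <- k * sum((rowMeans(m) - gm)^2)
  ssError <- sum((m - gm)^2) - ssEffect - ssSubject
  list(n = n, k = k, ssEffect = ssEffect, ssError = ssError)
}

#' One-way repeated-measures ANOVA across NREM episodes
#'
#' Tests the time-of-night effect of a per-episode measure in a complete
#' subjects x episodes design. F is the ratio of the effect mean square to
#' the subject-by-episode interaction mean square and is reported unadjusted;
#' the Huynh-Feldt epsilon (computed from the within-subject covariance
#' matrix) adjusts the degrees of freedom of the p-value to protect against
#' sphericity violation.
#'
#' R^2 measures are analysed on the Fisher-z scale
#' (\code{fisherZ = TRUE}), the variance-stabilised scale on which their
#' cohort statistics are defined; counts such as TA are analysed raw.
#'
#' @param table Long-format data.frame with columns \code{subject},
#'   \code{nrem} and the measure column.
#' @param measure Column name to analyse (e.g. \code{"r2"} or \code{"ta"}).
#' @param fisherZ Analyse atanh(sqrt(measure/100)) instead of the raw values;
#'   defaults to TRUE when \code{measure == "r2"}.
#' @return A list with \code{F}, \code{dfEffect}, \code{dfError},
#'   \code{epsilon} (Huynh-Feldt), \code{p} (unadjusted) and \code{pAdjusted}.
#' @examples
#' tab <- referenceCohort()
#' rmAnova(tab, "ta")$F   # 12.28
#' @export
rmAnova <- function(table, measure, fisherZ = identical(measure, "r2")) {
  m <- .designMatrix(table, measure)
  if (fisherZ) m <- matrix(fisherZ(m), nrow = nrow(m), dimnames = dimnames(m))
  ss <- .rmSS(m)
  dfE <- ss$k - 1L; dfR <- (ss$n - 1L) * (ss$k - 1L)
  Fv <- if (ss$ssEffect == 0) 0 else (ss$ssEffect / dfE) / (ss$ssError / dfR)
  eps <- .huynhFeldt(m)
  list(F = Fv, dfEffect = dfE, dfError = dfR, epsilon = eps,
       p = stats::pf(Fv, dfE, dfR, lower.tail = FALSE),
       pAdjusted = stats::pf(Fv, dfE * eps, dfR * eps, lower.tail = FALSE))
}

# Huynh-Feldt epsilon from the within-subject covariance matrix, via the
# Greenhouse-Geisser estimate.
.huynhFeldt <- function(m) {
  n <- nrow(m); k <- ncol(m)
  S <- stats::cov(m)
  # double-centre
  Sd <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  gg <- sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
  if (!is.finite(gg)) return(1)   # degenerate (e.g. constant) data
  hf <- (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg))
  min(hf, 1)
}

#' Polynomial trend contrasts across NREM episodes
#'
#' Decomposes the within-subject episode effect over 4 equally spaced levels
#' into orthogonal linear (-3, -1, 1, 3), quadratic (1, -1, -1, 1) and cubic
#' (-1, 3, -3, 1) components. Each contrast is tested against its own error
#' term: the per-subject contrast scores are analysed as a one-sample
#' problem, giving F(1, n-1). The percent share is the contrast sum of
#' squares over the total within-subject effect sum of squares; the three
#' shares sum to 100 by orthogonality.
#'
#' @inheritParams rmAnova
#' @return A data.frame with rows linear/quadratic/cubic and columns
#'   \code{F}, \code{df1}, \code{df2}, \code{p}, \code{percent}.
#' @examples
#' polynomialTrends(referenceCohort(), "ta")
#' @export
polynomialTrends <- function(table, measure,
                             fisherZ = identical(measure, "r2")) {
  m <- .designMatrix(table, measure)
  if (fisherZ) m <- matrix(fisherZ(m), nrow = nrow(m), dimnames = dimnames(m))
  k <- ncol(m)
  if (k != 4L) stop("polynomial contrasts are defined for 4 episode levels")
  n <- nrow(m)
  contrasts <- list(linear = c(-3, -1, 1, 3), quadratic = c(1, -1, -1, 1),
                    cubic = c(-1, 3, -3, 1))
  ssEffect <- .rmSS(m)$ssEffect
  rows <- lapply(names(contrasts), function(nm) {
    cv <- contrasts[[nm]]
    s <- as.numeric(m %*% cv)           # per-subject contrast scores
    ssC <- n * mean(s)^2 / sum(cv^2)
    Fv <- mean(s)^2 / (stats::var(s) / n)
    data.frame(F = Fv, df1 = 1L, df2 = n - 1L,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               percent = 100 * ssC / ssEffect)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(contrasts)
  out
}

#' Percentage of episodes per quality class per NREM episode
#'
#' Classifies every overall R^2 with [classifyFit()] and tabulates the class
#' percentages within each episode column.
#'
#' @param table Long-format data.frame with columns \code{subject},
#'   \code{nrem}, \code{r2}.
#' @return A matrix (rows VG, G, F, BF; columns episodes) of percentages.
#' @examples
#' qualityTable(referenceCohort())
#' @export
qualityTable <- function(table) {
  m <- .designMatrix(table, "r2")
  cls <- apply(m, 2, function(col)
    table(factor(classifyFit(col), levels = c("VG", "G", "F", "BF"))))
  100 * sweep(cls, 2, colSums(cls), "/")
}

#' Packaged reference cohort table
#'
#' Loads the packaged per-subject fit-quality table: 30 healthy young adults,
#' NREM episodes 1-4, with the number of towards-away (TA) cycles and the
#' overall R^2 (percent) of the cascade-model fit for each episode.
#'
#' @param path Optional path to a user-supplied table in the same format
#'   (TSV with columns \code{subject}, \code{nrem}, \code{ta}, \code{r2}).
#' @return A data.frame with columns \code{subject}, \code{nrem}, \code{ta},
#'   \code{r2}.
#' @examples
#' head(referenceCohort())
#' @export
referenceCohort <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_fit_table.tsv", package = "ntpsleep",
                        mustWork = TRUE)
  readSubjectEpisodeTable(path)
}

#' Full cohort summary
#'
#' Fisher-z mean R^2 and arithmetic mean TA per episode, quality-class
#' percentages, repeated-measures ANOVA and polynomial trends for both
#' measures.
#'
#' @param table A subject/episode table as from [referenceCohort()].
#' @return A list with elements \code{meanR2}, \code{meanTA},
#'   \code{quality}, \code{anovaR2}, \code{anovaTA}, \code{trendsR2},
#'   \code{trendsTA}.
#' @export
cohortSummary <- function(table = referenceCohort()) {
  r2m <- .designMatrix(table, "r2")
  tam <- .designMatrix(table, "ta")
  list(meanR2 = apply(r2m, 2, fisherZMean),
       meanTA = colMeans(tam),
       quality = qualityTable(table),
       anovaR2 = rmAnova(table, "r2"),
       anovaTA = rmAnova(table, "ta", fisherZ = FALSE),
       trendsR2 = polynomialTrends(table, "r2"),
       trendsTA = polynomialTrends(table, "ta", fisherZ = FALSE))
}
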