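#' BIC and AICc
#'
#' `BIC = -2 loglik + k log(n)`;
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k parameter count (regression parameters, plus the residual SD
#'   for the growth-rate family).
#' @param n number of independent sampling units (`n > k + 1`).
#' @return named vector `c(BIC =, AICc =)`.
#' @export
informationCriteria <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  c(BIC = -2 * loglik + k * log(n),
    AICc = -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
}

#' Evidence table of Delta-BIC and Delta-AICc
#'
#' Ranks converged fits by Delta-BIC relative to the minimum; models with
#' Delta-BIC below the threshold are flagged evidentially equivalent to
#' the best model. Non-converged fits are listed separately and excluded
#' from the Delta computation. Ties in the minimum criterion go to the
#' smaller k. Random-effect parameters are not counted in k.
#'
#' @param fits list of [DCFit-class] objects (same family, same data).
#' @param logliks marginal log-likelihoods, one per fit (default computed
#'   via [marginalLoglik()]).
#' @param threshold evidential equivalence threshold.
#' @return a [ModelComparison-class].
#' @export
deltaTable <- function(fits, logliks = vapply(fits, marginalLoglik,
                                              numeric(1)),
                       threshold = 2.77) {
  conv <- vapply(fits, isConverged, logical(1))
  if (!any(conv)) stop("no converged model to rank")
  labels <- vapply(fits, function(f) f@spec$label, character(1))
  k <- vapply(fits, function(f) f@spec$kParams, numeric(1))
  n <- fits[[which(conv)[1]]]@n
  ic <- t(vapply(seq_along(fits), function(i)
    informationCriteria(logliks[i], k[i], n), numeric(2)))
  tb <- data.frame(model = labels, k = k, loglik = logliks,
                   BIC = ic[, 1], AICc = ic[, 2],
                   stringsAsFactors = FALSE)
  conv_tb <- tb[conv, , drop = FALSE]
  # tie-break the minimum toward smaller k
  ord0 <- order(conv_tb$BIC, conv_tb$k)
  conv_tb$dBIC <- conv_tb$BIC - conv_tb$BIC[ord0[1]]
  ordA <- order(conv_tb$AICc, conv_tb$k)
  conv_tb$dAICc <- conv_tb$AICc - conv_tb$AICc[ordA[1]]
  conv_tb$equivalent <- conv_tb$dBIC < threshold
  conv_tb <- conv_tb[order(conv_tb$dBIC, conv_tb$k), , drop = FALSE]
  rownames(conv_tb) <- NULL
  excl <- tb[!conv, c("model", "k", "loglik"), drop = FALSE]
  rownames(excl) <- NULL
  new("ModelComparison", table = conv_tb, excluded = excl,
      nEffective = n, threshold = threshold)
}

#' Nested candidate model set for a family
#'
#' The nested sequence intercept-only, + INB, + INB + COL,
#' + INB + COL + INBxCOL; the wait family includes the FIRST term in every
#' model. With `yearEffects = TRUE`, year-random-intercept variants (and a
#' year slope on F for models containing INB) are appended for the
#' families whose richest model defines them.
#'
#' @param family model family.
#' @param yearEffects include year-effect variants.
#' @return list of [modelSpec()] objects, nested by construction.
#' @export
candidateSet <- function(family = c("ri", "death", "afr", "wait"),
                         yearEffects = FALSE) {
  family <- match.arg(family)
  base <- if (family == "wait") "FIRST" else character()
  seqs <- list(character(), "INB", c("INB", "COL"),
               c("INB", "COL", "INBxCOL"))
  out <- lapply(seqs, function(tt)
    modelSpec(family, terms = c(tt, base)))
  if (yearEffects) {
    extra <- lapply(seqs, function(tt)
      modelSpec(family, terms = c(tt, base), yearIntercept = TRUE,
                yearSlope = ("INB" %in% tt) && family != "ri"))
    out <- c(out, extra)
  }
  out
}

#' Render a ModelComparison as CSV or Markdown
#'
#' @param comparison a [ModelComparison-class].
#' @param path output path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
writeDeltaTable <- function(comparison, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  tb <- comparison@table
  if (format == "csv") {
    write.csv(tb, path, row.names = FALSE)
  } else {
    lines <- c("| Model | K | dBIC | dAICc |", "|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %.2f |", tb$model, tb$k,
                       tb$dBIC, tb$dAICc),
               "",
               sprintf("K counts regression parameters (plus the residual SD for the growth-rate family); random-effect parameters are not counted. Models with dBIC < %.2f are evidentially equivalent.",
                       comparison@threshold))
    writeLines(lines, path)
  }
  invisible(path)
}
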