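#' @rdname GenotypeTable-class
#' @param x,object a `GenotypeTable` (or other package object).
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Beta measurement-error parameters per individual
#'
#' @param x an [InbreedingSummary-class] object.
#' @return data.frame with columns `id`, `A`, `B`.
#' @export
setGeneric("betaParams", function(x) standardGeneric("betaParams"))

#' Point estimates of individual inbreeding coefficients
#'
#' Posterior means of F at the final clone level.
#'
#' @param x an [InbreedingSummary-class] object.
#' @return named numeric vector.
#' @export
setGeneric("fEstimates", function(x) standardGeneric("fEstimates"))

#' @rdname DCFit-class
#' @param x a `DCFit`.
#' @export
setGeneric("mle", function(x) standardGeneric("mle"))

#' @rdname DCFit-class
#' @export
setGeneric("covMle", function(x) standardGeneric("covMle"))

#' @rdname DCFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

setMethod("individualIds", "GenotypeTable", function(x) x@individualIds)
setMethod("locusNames", "GenotypeTable", function(x) x@locusNames)
setMethod("nIndividuals", "GenotypeTable", function(x) length(x@individualIds))
setMethod("nLoci", "GenotypeTable", function(x) length(x@locusNames))

setMethod("betaParams", "InbreedingSummary", function(x)
  x@stats[, c("id", "A", "B")])
setMethod("fEstimates", "InbreedingSummary", function(x)
  setNames(x@stats$posterior_mean_F, x@stats$id))

setMethod("mle", "DCFit", function(x) x@mle)
setMethod("covMle", "DCFit", function(x) x@covMle)
setMethod("isConverged", "DCFit", function(x) x@converged)

setMethod("show", "GenotypeTable", function(object) {
  typed <- sum(!is.na(object@allele1))
  cat("GenotypeTable:", nIndividuals(object), "individuals x",
      nLoci(object), "loci\n")
  cat(sprintf("  typed calls: %d (%.1f%% missing)\n", typed,
              100 * (1 - typed / max(1, length(object@allele1)))))
  nal <- vapply(object@alleleRegistry, length, integer(1))
  if (length(nal))
    cat(sprintf("  alleles per locus: %d-%d (mean %.1f)\n",
                min(nal), max(nal), mean(nal)))
})

setMethod("show", "InbreedingSummary", function(object) {
  cat("InbreedingSummary:", nrow(object@stats), "individuals, clone schedule",
      paste(object@cloneSchedule, collapse = "/"), "\n")
  cat(sprintf("  posterior mean F: median %.4f, range %.4f-%.4f\n",
              median(object@stats$posterior_mean_F),
              min(object@stats$posterior_mean_F),
              max(object@stats$posterior_mean_F)))
  cat(sprintf("  max R-hat(F): %.3f (%s)\n", max(object@stats$rhat_F),
              if (object@converged) "converged" else "check convergence"))
})

setMethod("show", "DCFit", function(object) {
  cat("DCFit [", object@family, "]:",
      paste(object@spec$label, collapse = ""), "\n")
  cat("  clones:", paste(object@cloneSchedule, collapse = "/"),
      " converged:", object@converged, "\n")
  est <- cbind(MLE = object@mle, SE = sqrt(diag(object@covMle)),
               object@waldCI)
  print(round(est, 4))
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison (n =", object@nEffective, ", equivalence <",
      object@threshold, ")\n")
  print(object@table, row.names = FALSE)
  if (nrow(object@excluded))
    cat("excluded (non-converged):",
        paste(object@excluded$model, collapse = ", "), "\n")
})
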