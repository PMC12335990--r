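#' @include AllClasses.R
NULL

#' Accessors for ThermoBench containers
#'
#' `profileData()` and `featureData()` return the underlying long-format
#' data.frame; `tableScale()` the scale flag; `designChannels()` the channel
#' annotation table; `designTemperatures()` the ordered Celsius values of the
#' measurement ladder; `normFactors()` the per-temperature factors.
#'
#' @param object a ThermoBench S4 object.
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileData", function(object) standardGeneric("profileData"))
#' @rdname accessors
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname accessors
#' @export
setGeneric("tableScale", function(object) standardGeneric("tableScale"))
#' @rdname accessors
#' @export
setGeneric("designChannels", function(object) standardGeneric("designChannels"))
#' @rdname accessors
#' @export
setGeneric("designTemperatures",
           function(object) standardGeneric("designTemperatures"))
#' @rdname accessors
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))
#' @rdname accessors
#' @export
setGeneric("cellMeans", function(object) standardGeneric("cellMeans"))
#' @rdname accessors
#' @export
setGeneric("varComponents", function(object) standardGeneric("varComponents"))
#' @rdname accessors
#' @export
setGeneric("templateMeans", function(object) standardGeneric("templateMeans"))

#' @rdname accessors
setMethod("profileData", "ProteinProfileTable", function(object) object@data)
#' @rdname accessors
setMethod("featureData", "FeatureTable", function(object) object@data)
#' @rdname accessors
setMethod("tableScale", "ProteinProfileTable", function(object) object@scale)
#' @rdname accessors
setMethod("tableScale", "FeatureTable", function(object) object@scale)
#' @rdname accessors
setMethod("designChannels", "StudyDesign", function(object) object@channels)
#' @rdname accessors
setMethod("designTemperatures", "StudyDesign", function(object) {
  ch <- object@channels
  ch <- ch[ch$role %in% c("measurement", "reference") &
             !is.na(ch$temperature_index), , drop = FALSE]
  tt <- unique(ch[, c("temperature_index", "temperature")])
  tt <- tt[order(tt$temperature_index), ]
  stats::setNames(tt$temperature, tt$temperature_index)
})
#' @rdname accessors
setMethod("normFactors", "NormFactors", function(object) object@Q)
#' @rdname accessors
setMethod("cellMeans", "MixedFit", function(object) object@cell_means)
#' @rdname accessors
setMethod("varComponents", "MixedFit", function(object)
  c(sigma_bio_sq = object@sigma_bio_sq,
    sigma_error_sq = object@sigma_error_sq))
#' @rdname accessors
setMethod("varComponents", "ScamFit", function(object)
  c(sigma_bio_sq = object@sigma_bio_sq,
    sigma_error_sq = object@sigma_error_sq))
#' @rdname accessors
setMethod("templateMeans", "Template", function(object) object@mu)

setMethod("show", "StudyDesign", function(object) {
  ch <- object@channels
  meas <- ch[ch$role %in% c("measurement", "reference"), , drop = FALSE]
  cat("StudyDesign:", length(unique(ch$plex)), "plex(es),",
      length(unique(meas$condition)), "condition(s),",
      length(unique(meas$replicate)), "replicate label(s),",
      length(unique(meas$temperature_index)), "temperature(s)\n")
  d <- validateDesign(object)
  if (length(d)) cat("  ", length(d), "design diagnostic(s); see validateDesign()\n")
})

setMethod("show", "ProteinProfileTable", function(object) {
  d <- object@data
  cat("ProteinProfileTable (", object@scale, " scale): ",
      length(unique(d$protein)), " protein(s), ", nrow(d), " records\n",
      sep = "")
})

setMethod("show", "FeatureTable", function(object) {
  d <- object@data
  cat("FeatureTable (", object@scale, " scale): ",
      length(unique(d$protein)), " protein(s), ",
      length(unique(paste(d$protein, d$feature))), " feature(s), ",
      nrow(d), " records (", sum(is.na(d$intensity)), " missing)\n", sep = "")
})

setMethod("show", "NormFactors", function(object) {
  cat("NormFactors from condition", object@condition, "replicate",
      object@replicate, sprintf("(R2 = %.4f),", object@fit_r2),
      length(object@normset), "NormSet proteins\n")
  print(round(object@Q, 4))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("SigmoidFit: p = %.4f, a = %.1f, b = %.3f, Tm = %.2f, R2 = %.4f%s\n",
              object@p, object@a, object@b, object@tm, object@r2,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "MixedFit", function(object) {
  cat(sprintf("MixedFit (%s): %d cell means, sigma_bio^2 = %.4f, sigma_err^2 = %.4f%s\n",
              if (object@balanced) "balanced closed form" else "lme4 REML",
              length(object@cell_means), object@sigma_bio_sq,
              object@sigma_error_sq,
              if (object@singular) " [boundary]" else ""))
})

setMethod("show", "Template", function(object) {
  cat("Template (", object@kind, "): ", ncol(object@mu),
      " temperatures, max |treated - vehicle| = ",
      sprintf("%.3f", max(abs(object@mu["treated", ] - object@mu["vehicle", ]))),
      " log2 units\n", sep = "")
})

setMethod("show", "DesignSpec", function(object) {
  cat("DesignSpec [", object@mode, "]: ", object@n_replicates,
      " replicates/condition, ", object@n_plexes, " plex(es)",
      if (object@mode == "thermal")
        paste0(", fit {", paste(object@temperatures_fit, collapse = ","),
               "}, test {", paste(object@temperatures_test, collapse = ","), "}")
      else
        paste0(", pooled {", paste(object@pooled_indices, collapse = ","), "}"),
      "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: sigma_bio^2 = %.3f, sigma_err^2 = %.3f (ICC %.1f%%), %d instances, seed %d\n",
              object@sigma_bio_sq, object@sigma_error_sq,
              100 * icc(object@sigma_bio_sq, object@sigma_error_sq),
              object@n_instances, object@seed))
  show(object@design)
})
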