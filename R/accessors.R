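#' Accessors for mrse data classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param object an mrse S4 object.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("coords", "BiasedTrajectory", function(object, ...) object@coords)

#' @rdname accessors
#' @export
setMethod("biasValues", "BiasedTrajectory", function(object, ...) object@bias)

#' @rdname accessors
#' @export
setMethod("ctValues", "BiasedTrajectory", function(object, ...) object@ct)

#' @rdname accessors
#' @export
setMethod("frameTimes", "BiasedTrajectory", function(object, ...) object@time)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "BiasedTrajectory", function(object, ...) object@weight)

#' @rdname accessors
#' @export
setMethod("nSamples", "BiasedTrajectory", function(object, ...) length(object@time))

#' @rdname accessors
#' @export
setMethod("features", "LandmarkSet", function(object, ...) object@features)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "LandmarkSet", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("nSamples", "LandmarkSet", function(object, ...) nrow(object@features))

#' @rdname accessors
#' @export
setMethod("mixtureMatrix", "MultiscaleP", function(object, ...) object@mixture)

#' @rdname accessors
#' @export
setMethod("lossHistory", "EmbeddingModel", function(object, ...) object@lossHistory)

#' @rdname accessors
#' @export
setMethod("fesValues", "FreeEnergySurface", function(object, ...) object@values)

#' @rdname accessors
#' @export
setMethod("fesAxes", "FreeEnergySurface", function(object, ...) object@axes)

setMethod("show", "BiasedTrajectory", function(object) {
  cat("BiasedTrajectory:", nSamples(object), "frames,",
      ncol(object@coords), "feature(s)\n")
  cat("  time range:", format(range(object@time)), "\n")
  if (!is.null(object@weight))
    cat("  weights attached, max =", format(max(object@weight)), "\n")
  else cat("  weights not attached\n")
  md <- Filter(function(v) is.atomic(v) && length(v) == 1L, object@metadata)
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nSamples(object), "landmarks,",
      ncol(object@features), "feature(s), alpha =", object@alpha, "\n")
  invisible(NULL)
})

setMethod("show", "MultiscaleP", function(object) {
  cat("MultiscaleP:", nrow(object@mixture), "x", ncol(object@mixture),
      "mixture of", length(object@perplexities), "perplexities (",
      paste(object@perplexities, collapse = ", "), ")\n")
  cat("  reweighted:", object@reweighted, "\n")
  invisible(NULL)
})

setMethod("show", "EmbeddingModel", function(object) {
  cat("EmbeddingModel: layers [",
      paste(object@layerSizes, collapse = ", "), "]\n")
  if (length(object@lossHistory))
    cat("  trained", length(object@lossHistory), "epochs, final loss",
        format(utils::tail(object@lossHistory, 1)), "\n")
  invisible(NULL)
})

setMethod("show", "FreeEnergySurface", function(object) {
  dims <- vapply(object@axes, length, integer(1))
  cat("FreeEnergySurface:", paste(dims, collapse = " x "), "grid,",
      if (object@weighted) "reweighted" else "unweighted", "KDE\n")
  fin <- object@values[is.finite(object@values)]
  cat("  F range: [0,", format(max(fin)), "] (1/beta units), beta =",
      object@beta, "\n")
  invisible(NULL)
})

setMethod("show", "BiasState", function(object) {
  cat("BiasState:", nrow(object@hills), "hills, c(t) =",
      format(object@ct), "\n")
  invisible(NULL)
})
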