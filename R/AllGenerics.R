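#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots directly:
#' \code{topology()}, \code{nDownstream()}, \code{speciesNames()},
#' \code{reactions()}, \code{modelTotals()}, \code{microstates()},
#' \code{stationaryProbs()}, \code{aValue()}, \code{jointPmf()},
#' \code{lnaMeans()}, \code{lnaCovariance()}.
#'
#' @param object an object of the corresponding class.
#' @return the slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("nDownstream", function(object) standardGeneric("nDownstream"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("modelTotals", function(object) standardGeneric("modelTotals"))
#' @rdname accessors
#' @export
setGeneric("microstates", function(object) standardGeneric("microstates"))
#' @rdname accessors
#' @export
setGeneric("stationaryProbs", function(object) standardGeneric("stationaryProbs"))
#' @rdname accessors
#' @export
setGeneric("aValue", function(object) standardGeneric("aValue"))
#' @rdname accessors
#' @export
setGeneric("jointPmf", function(object) standardGeneric("jointPmf"))
#' @rdname accessors
#' @export
setGeneric("lnaMeans", function(object) standardGeneric("lnaMeans"))
#' @rdname accessors
#' @export
setGeneric("lnaCovariance", function(object) standardGeneric("lnaCovariance"))

#' @rdname accessors
#' @export
setMethod("topology", "ModelSpec", function(object) object@topology)
#' @rdname accessors
#' @export
setMethod("nDownstream", "ModelSpec", function(object) object@nDownstream)
#' @rdname accessors
#' @export
setMethod("speciesNames", "ModelSpec", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("reactions", "ModelSpec", function(object) object@reactions)
#' @rdname accessors
#' @export
setMethod("modelTotals", "ModelSpec", function(object) object@totals)
#' @rdname accessors
#' @export
setMethod("microstates", "StationaryDistribution", function(object) object@states)
#' @rdname accessors
#' @export
setMethod("stationaryProbs", "StationaryDistribution", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("microstates", "TrajectorySummary", function(object) object@states)
#' @rdname accessors
#' @export
setMethod("stationaryProbs", "TrajectorySummary", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("aValue", "AConstant", function(object) object@value)
#' @rdname accessors
#' @export
setMethod("aValue", "ZChannel", function(object) object@A)
#' @rdname accessors
#' @export
setMethod("jointPmf", "ZChannel", function(object) object@joint)
#' @rdname accessors
#' @export
setMethod("lnaMeans", "LNASteadyState", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("lnaCovariance", "LNASteadyState", function(object) object@covariance)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@topology, "\n")
  cat("  species  :", paste(object@species, collapse = ", "), "\n")
  cat("  reactions:", length(object@reactions),
      " (N =", object@nDownstream, ", Q =", object@qConnected, ")\n")
  tot <- object@totals
  cat("  totals   :", paste(names(tot), tot, sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "StationaryDistribution", function(object) {
  cat("StationaryDistribution over", nrow(object@states), "microstates",
      sprintf("(i1=%d, i2=%d)\n", object@condition[1], object@condition[2]))
  cat("  residual:", format(object@residual, digits = 3), "\n")
  sup <- which(object@probs > 0)
  k <- utils::head(order(object@probs, decreasing = TRUE), 5L)
  for (i in k) {
    s <- object@states[i, ]
    lab <- paste(names(s)[s > 0], s[s > 0], sep = "=", collapse = " ")
    if (lab == "") lab <- "(all zero)"
    cat(sprintf("  %-30s %.6f\n", lab, object@probs[i]))
  }
  if (nrow(object@states) > 5L) cat("  ...\n")
  cat("  support size:", length(sup), "\n")
  invisible(object)
})

setMethod("show", "ZChannel", function(object) {
  cat("ZChannel: A =", format(object@A, digits = 6),
      " P01 =", format(object@P01, digits = 6), "\n")
  J <- object@joint
  dimnames(J) <- list(input = c("0", "1"), output = c("0", "1"))
  print(round(J, 6))
  if (length(object@branchConditionals)) {
    cat("  branch conditionals:",
        paste(names(object@branchConditionals),
              format(object@branchConditionals, digits = 6),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "AConstant", function(object) {
  cat(sprintf("AConstant [%s, %s]: %.6g\n",
              object@model, object@regime, object@value))
  invisible(object)
})

setMethod("show", "LNASteadyState", function(object) {
  cat("LNASteadyState (omega =", object@omega, ")\n")
  cat("  means:", paste(names(object@means),
                        format(object@means, digits = 6),
                        sep = "=", collapse = ", "), "\n")
  if (length(object@covariance))
    cat("  variances:", paste(format(diag(object@covariance), digits = 6),
                              collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "TrajectorySummary", function(object) {
  cat("TrajectorySummary:", nrow(object@states), "states,",
      "T =", object@totalTime, " burn-in =", object@burnIn,
      " seed =", object@seed, "\n")
  invisible(object)
})
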