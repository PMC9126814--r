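#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for dynfc S4 objects
#'
#' Small accessor functions for the slots of the package's data classes;
#' user code should use these rather than \code{@} access.
#'
#' @param x a dynfc S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectId", "BetaSeries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "TrialFC", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "BlockFC", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "DeltaFC", function(x) x@subjectId)

#' @rdname accessors
setMethod("phase", "BetaSeries", function(x) x@phase)
#' @rdname accessors
setMethod("phase", "TrialFC", function(x) x@phase)

#' @rdname accessors
setMethod("csType", "BlockFC", function(x) x@csType)
#' @rdname accessors
setMethod("csType", "DeltaFC", function(x) x@csType)

#' @rdname accessors
setMethod("values", "BetaSeries", function(x) x@values)
#' @rdname accessors
setMethod("trialTable", "BetaSeries", function(x) x@trialTable)
#' @rdname accessors
setMethod("trialTable", "TrialFC", function(x) x@trialTable)
#' @rdname accessors
setMethod("fcTensor", "TrialFC", function(x) x@tensor)
#' @rdname accessors
setMethod("fcMethod", "TrialFC", function(x) x@method)
#' @rdname accessors
setMethod("blocks", "BlockFC", function(x) x@blocks)
#' @rdname accessors
setMethod("edgeVector", "DeltaFC", function(x) x@edgeVector)
#' @rdname accessors
setMethod("edgeIndex", "DeltaFC", function(x) x@edgeIndex)
#' @rdname accessors
setMethod("edgeIndex", "EdgeStatMap", function(x) x@edgeIndex)

#' @rdname accessors
setMethod("components", "NBSResult", function(x) x@components)
#' @rdname accessors
setMethod("componentStats", "NBSResult", function(x) x@componentStats)
#' @rdname accessors
setMethod("pFwe", "NBSResult", function(x) x@componentStats$p_fwe)
#' @rdname accessors
setMethod("edgeStats", "NBSResult", function(x) x@edgeStats)

#' @rdname accessors
setMethod("canonicalR", "CCAResult", function(x) x@canonicalR)

#' @rdname accessors
setMethod("truth", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("subjects", "SyntheticCohort", function(x) x@subjects)
#' @rdname accessors
setMethod("clinicalTable", "SyntheticCohort", function(x) x@clinical)

setMethod("show", "BetaSeries", function(object) {
  cat("BetaSeries | subject", object@subjectId, "| phase", object@phase, "\n")
  cat("  ", nrow(object@values), "trials x", ncol(object@values), "regions;",
      "CS types:", paste(unique(object@trialTable$cs_type), collapse = ", "), "\n")
})

setMethod("show", "TrialFC", function(object) {
  d <- dim(object@tensor)
  cat("TrialFC | subject", object@subjectId, "| phase", object@phase,
      "| method", object@method, "\n")
  cat("  ", d[1L], "trials x", d[2L], "x", d[3L], "regions;",
      object@nFlagged, "zero-variance entries flagged\n")
})

setMethod("show", "BlockFC", function(object) {
  d <- dim(object@blocks)
  cat("BlockFC | subject", object@subjectId, "|", object@csType, "|",
      d[1L], "blocks of", object@nTrialsPerBlock, "trials,", d[2L], "regions\n")
})

setMethod("show", "DeltaFC", function(object) {
  cat("DeltaFC | subject", object@subjectId, "|", object@csType, "|",
      length(object@edgeVector), "edges; mean",
      signif(mean(object@edgeVector), 4), "\n")
})

setMethod("show", "EdgeStatMap", function(object) {
  cat("EdgeStatMap | contrast", object@contrast, "| df", object@df, "|",
      length(object@t), "edges; |t| max", signif(max(abs(object@t)), 4), "\n")
})

setMethod("show", "NBSResult", function(object) {
  cat("NBSResult | direction", object@direction, "| threshold p <",
      object@thresholdP, "|", object@nPerm,
      if (object@exhaustive) "exhaustive assignments\n" else "permutations\n")
  if (nrow(object@componentStats) == 0L) {
    cat("  no supra-threshold components\n")
  } else {
    st <- object@componentStats
    for (k in seq_len(min(5L, nrow(st))))
      cat(sprintf("  component %d: %d edges, p_fwe = %.4g\n", k, st$size[k], st$p_fwe[k]))
    if (nrow(st) > 5L) cat("  ...", nrow(st) - 5L, "more\n")
  }
})

setMethod("show", "CCAResult", function(object) {
  cat(sprintf("CCAResult | canonical r = %.3f (rank %d reduction)\n",
              object@canonicalR, object@reductionRank))
  if (!is.na(object@permP)) cat(sprintf("  permutation p = %.4g (n_perm = %d)\n",
                                        object@permP, object@nPerm))
  if (!is.na(object@cvR)) cat(sprintf("  cross-validated r = %.3f, p = %.4g\n",
                                      object@cvR, object@cvPermP))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@subjects$group)
  cat("SyntheticCohort |", nrow(object@subjects), "subjects:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(object@betaSeries)) {
    b <- object@betaSeries[[1L]]
    cat("  ", nrow(b@values), "trials x", ncol(b@values), "regions per subject;",
        nrow(object@truth$planted_edges), "planted edges\n")
  }
})
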