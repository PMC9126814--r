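#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Average trial-resolved FC into time-blocks per CS type
#'
#' Reorders the trial FC tensor by CS type and presentation time, evenly
#' divides each CS type's trials into \code{nBlocks} contiguous time-blocks
#' (block 1 = earliest learning), and averages the trial matrices within
#' each block.
#'
#' @param tfc a [TrialFC-class]; its trial table supplies CS type and order.
#' @param nBlocks number of time-blocks (default 4).
#' @param remainder what to do when the trial count per CS type is not
#'   divisible by \code{nBlocks}: \code{"error"} (default) or
#'   \code{"truncate_late"} (drop the last trials).
#' @return named list of [BlockFC-class], one per CS type present.
#' @rdname blockAverage
#' @export
setMethod("blockAverage", "TrialFC",
  function(tfc, nBlocks = 4L, remainder = c("error", "truncate_late")) {
    remainder <- match.arg(remainder)
    tt <- trialTable(tfc)
    tensor <- fcTensor(tfc)
    R <- dim(tensor)[2L]
    out <- list()
    for (cs in unique(tt$cs_type)) {
      trials <- which(tt$cs_type == cs)
      trials <- trials[order(tt$trial[trials])]  # presentation order
      extra <- length(trials) %% nBlocks
      if (extra != 0L) {
        if (remainder == "error")
          stop(length(trials), " ", cs, " trials not divisible by ", nBlocks,
               " blocks (remainder ", extra,
               "); use remainder = \"truncate_late\" to drop the last trials")
        trials <- trials[seq_len(length(trials) - extra)]
      }
      per <- length(trials) %/% nBlocks
      if (per < 1L) stop("fewer trials than blocks for ", cs)
      blk <- array(0, c(nBlocks, R, R))
      for (b in seq_len(nBlocks)) {
        sel <- trials[((b - 1L) * per + 1L):(b * per)]
        blk[b, , ] <- colMeans(tensor[sel, , , drop = FALSE], dims = 1L)
      }
      out[[cs]] <- new("BlockFC", subjectId = subjectId(tfc), csType = cs,
                       blocks = blk, nTrialsPerBlock = per)
    }
    out
  })

#' Early-to-late connectivity change (last block minus first)
#'
#' The central quantity of the pipeline: connectivity in the last time-block
#' minus the first, as an upper-triangle edge vector.
#'
#' @param bfc a [BlockFC-class].
#' @return a [DeltaFC-class].
#' @rdname deltaFC
#' @export
setMethod("deltaFC", "BlockFC", function(bfc) {
  b <- blocks(bfc)
  nb <- dim(b)[1L]
  R <- dim(b)[2L]
  idx <- edgeIndexTable(R)
  d <- b[nb, , ][idx] - b[1L, , ][idx]
  new("DeltaFC", subjectId = subjectId(bfc), csType = csType(bfc),
      edgeVector = d, edgeIndex = idx)
})

#' Cue-specific differential connectivity change
#'
#' ([CS+ - CS-] at the last block) - ([CS+ - CS-] at the first block),
#' which algebraically equals \code{deltaFC(CS+) - deltaFC(CS-)} edge-wise.
#' Isolates learning dynamics specific to the conditioned cue.
#'
#' @param deltaPlus,deltaMinus [DeltaFC-class] for CS+ and CS- of the same
#'   subject.
#' @return a [DeltaFC-class] with \code{csType = "differential"}.
#' @export
differentialChange <- function(deltaPlus, deltaMinus) {
  stopifnot(is(deltaPlus, "DeltaFC"), is(deltaMinus, "DeltaFC"))
  if (!identical(dim(edgeIndex(deltaPlus)), dim(edgeIndex(deltaMinus))))
    stop("edge indices do not align between CS types")
  new("DeltaFC", subjectId = subjectId(deltaPlus), csType = "differential",
      edgeVector = edgeVector(deltaPlus) - edgeVector(deltaMinus),
      edgeIndex = edgeIndex(deltaPlus))
}

#' Mean connectivity of an edge component per time-block
#'
#' Per time-block mean of connectivity over a fixed component's edges —
#' the per-subject trajectory used for learning-curve summaries and the
#' component-level group test.
#'
#' @param bfc a [BlockFC-class].
#' @param edges edge matrix (columns i, j) defining the component.
#' @return numeric vector, one mean per time-block.
#' @rdname componentMeanSeries
#' @export
setMethod("componentMeanSeries", "BlockFC", function(bfc, edges) {
  edges <- normalizeEdges(edges)
  if (nrow(edges) == 0L) stop("empty edge set")
  b <- blocks(bfc)
  R <- dim(b)[2L]
  if (max(edges) > R) stop("component edges reference regions beyond matrix size")
  vapply(seq_len(dim(b)[1L]), function(k) mean(b[k, , ][edges]), numeric(1))
})

#' Stack per-subject DeltaFC objects into a subjects x edges matrix
#'
#' Convenience for the group-inference stage: aligns a list of
#' [DeltaFC-class] by subject and binds the edge vectors row-wise.
#'
#' @param deltaList list of [DeltaFC-class] with identical edge indices.
#' @return numeric matrix, rownames = subject ids.
#' @export
deltaMatrix <- function(deltaList) {
  stopifnot(length(deltaList) > 0L)
  idx <- edgeIndex(deltaList[[1L]])
  m <- do.call(rbind, lapply(deltaList, function(d) {
    if (!identical(dim(edgeIndex(d)), dim(idx)))
      stop("edge indices do not align across subjects")
    edgeVector(d)
  }))
  rownames(m) <- vapply(deltaList, subjectId, character(1))
  m
}
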