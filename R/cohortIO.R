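#' @include AllClasses.R syntheticCohort.R
NULL

## full-precision numeric formatting so matrices round-trip exactly
.fmtNum <- function(x) formatC(x, digits = 17, format = "g")

.writeMatrixTSV <- function(mat, path) {
  df <- as.data.frame(apply(mat, 2L, .fmtNum, simplify = FALSE),
                      optional = TRUE, check.names = FALSE)
  if (nrow(mat) == 0L) {
    df <- as.data.frame(matrix(character(), 0L, ncol(mat),
                               dimnames = list(NULL, colnames(mat))))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to a BIDS-flavoured file tree
#'
#' Writes, under \code{directory}: \code{subjects.csv}, \code{clinical.csv},
#' \code{recall_activation.csv}, optionally \code{recall_edge_fc.tsv},
#' \code{truth.json}, and per subject a directory with a BIDS-style events
#' table (\code{onset}, \code{duration}, \code{trial_type}) plus the
#' trials x regions beta table as TSV. Numeric values are written at full
#' float precision so the tree round-trips losslessly through
#' [readCohort()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  utils::write.csv(subjects(cohort), file.path(directory, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  clin <- clinicalTable(cohort)
  clinOut <- clin
  for (cn in names(clinOut)) if (is.numeric(clinOut[[cn]])) clinOut[[cn]] <- .fmtNum(clinOut[[cn]])
  utils::write.csv(clinOut, file.path(directory, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  .writeMatrixTSV(cohort@recall, file.path(directory, "recall_activation.tsv"))
  if (length(cohort@recallEdgeFC))
    .writeMatrixTSV(cohort@recallEdgeFC, file.path(directory, "recall_edge_fc.tsv"))
  tr <- truth(cohort)
  jsonlite::write_json(
    list(planted_edges = unname(apply(tr$planted_edges, 1L, as.integer, simplify = FALSE)),
         true_slopes = as.list(tr$true_slopes),
         subject_slopes = as.list(tr$subject_slopes),
         change_proxy = as.list(tr$change_proxy),
         recall_region = tr$recall_region,
         recall_slopes = as.list(tr$recall_slopes),
         recall_fc_slopes = as.list(tr$recall_fc_slopes)),
    file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA)
  for (id in names(cohort@betaSeries)) {
    b <- cohort@betaSeries[[id]]
    sdir <- file.path(directory, id)
    dir.create(sdir, showWarnings = FALSE)
    tt <- trialTable(b)
    ev <- data.frame(onset = .fmtNum(tt$onset),
                     duration = .fmtNum(if ("duration" %in% names(tt)) tt$duration else 0),
                     trial_type = tt$cs_type)
    utils::write.table(ev, file.path(sdir, paste0(id, "_task-extinction_events.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeMatrixTSV(values(b), file.path(sdir, paste0(id, "_beta-extinction.tsv")))
  }
  invisible(directory)
}

#' Read a cohort file tree written by [writeCohort()]
#'
#' @param directory directory produced by [writeCohort()].
#' @return a [SyntheticCohort-class] (config slot holds only what the tree
#'   records; ground truth is restored from \code{truth.json}).
#' @export
readCohort <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  subjectsDf <- utils::read.csv(file.path(directory, "subjects.csv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(subject_id = "character"))
  clin <- utils::read.csv(file.path(directory, "clinical.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  recall <- as.matrix(utils::read.delim(file.path(directory, "recall_activation.tsv"),
                                        check.names = FALSE))
  if (nrow(subjectsDf)) rownames(recall) <- subjectsDf$subject_id
  fcPath <- file.path(directory, "recall_edge_fc.tsv")
  recallEdgeFC <- if (file.exists(fcPath)) {
    m <- as.matrix(utils::read.delim(fcPath, check.names = FALSE))
    if (nrow(subjectsDf)) rownames(m) <- subjectsDf$subject_id
    m
  } else matrix(numeric(0), 0L, 0L)
  tr <- jsonlite::read_json(file.path(directory, "truth.json"), simplifyVector = TRUE)
  truth <- list(planted_edges = normalizeEdges(tr$planted_edges),
                true_slopes = unlist(tr$true_slopes),
                subject_slopes = unlist(tr$subject_slopes),
                change_proxy = unlist(tr$change_proxy),
                recall_region = as.integer(tr$recall_region),
                recall_slopes = unlist(tr$recall_slopes),
                recall_fc_slopes = unlist(tr$recall_fc_slopes))
  betaList <- list()
  for (id in subjectsDf$subject_id) {
    sdir <- file.path(directory, id)
    ev <- utils::read.delim(file.path(sdir, paste0(id, "_task-extinction_events.tsv")),
                            stringsAsFactors = FALSE)
    X <- as.matrix(utils::read.delim(file.path(sdir, paste0(id, "_beta-extinction.tsv")),
                                     check.names = FALSE))
    tt <- data.frame(trial = seq_len(nrow(ev)), cs_type = ev$trial_type,
                     onset = ev$onset, duration = ev$duration,
                     stringsAsFactors = FALSE)
    betaList[[id]] <- new("BetaSeries", subjectId = id,
                          phase = "extinction_learning", trialTable = tt,
                          values = X)
  }
  new("SyntheticCohort", betaSeries = betaList, recall = recall,
      recallEdgeFC = recallEdgeFC, clinical = clin, subjects = subjectsDf,
      truth = truth, config = list())
}
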