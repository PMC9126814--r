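#' @include utils.R
NULL

#' Load a region/atlas table
#'
#' Reads a CSV with columns \code{region_id}, \code{label}, \code{network}
#' (optional centroid columns \code{x}, \code{y}, \code{z}) assigning every
#' region to one canonical network. Validates that assignments are unique
#' and complete.
#'
#' @param path CSV path.
#' @return data.frame atlas table.
#' @seealso [defaultAtlas()]
#' @export
loadAtlas <- function(path) {
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "label", "network")
  if (!all(need %in% names(at)))
    stop("atlas table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(at$region_id)) stop("duplicate region_id in atlas")
  if (anyNA(at$network) || any(!nzchar(at$network)))
    stop("every region must be assigned to a network")
  at[order(at$region_id), , drop = FALSE]
}

#' Default 432-region, 8-network atlas table
#'
#' The package's default parcellation bookkeeping: 400 cortical parcels
#' assigned to the seven canonical cortical systems (visual, somatomotor,
#' dorsal attention, ventral attention, limbic, frontoparietal control,
#' default mode) plus 32 subcortical regions as the eighth network.
#' The table is a synthetic stand-in with the same schema and granularity
#' as the published parcellations (label strings follow their naming style,
#' e.g. \code{LH_Cont_PFCl_2} for left lateral-prefrontal control regions);
#' region-to-network bookkeeping, not anatomy, is what the pipeline uses.
#' Substitute any table of the same schema via [loadAtlas()].
#'
#' @return data.frame with columns \code{region_id}, \code{label},
#'   \code{network}.
#' @export
defaultAtlas <- function() {
  loadAtlas(system.file("extdata", "atlas_432_8networks_synthetic.csv",
                        package = "dynfc", mustWork = TRUE))
}

#' The eight canonical network names in display order
#' @return character vector of length 8.
#' @export
canonicalNetworks <- function() {
  c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default",
    "Subcortex")
}

.checkComponentAtlas <- function(edges, atlas) {
  edges <- normalizeEdges(edges)
  unknown <- setdiff(unique(as.vector(edges)), atlas$region_id)
  if (length(unknown))
    stop("edge references region(s) not in atlas: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  edges
}

#' Proportion of component edges per network pair
#'
#' For every pair of canonical networks (A, B), the number of component
#' edges with one endpoint in A and one in B divided by the total number of
#' possible such edges: |A||B| for A != B and |A|(|A|-1)/2 within a network.
#' High cells mark network pairs whose connections are extensively affected.
#'
#' @param edges component edge matrix (columns i, j; region ids).
#' @param atlas atlas table from [loadAtlas()] / [defaultAtlas()].
#' @return list with \code{proportion} and \code{count} (symmetric
#'   networks x networks matrices) and \code{denominator} (possible edges
#'   per pair).
#' @export
edgeFractionMatrix <- function(edges, atlas) {
  edges <- .checkComponentAtlas(edges, atlas)
  nets <- intersect(canonicalNetworks(), unique(atlas$network))
  nets <- c(nets, setdiff(unique(atlas$network), nets))
  k <- length(nets)
  sizes <- vapply(nets, function(nw) sum(atlas$network == nw), numeric(1))
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  dimnames(denom) <- list(nets, nets)
  cnt <- matrix(0, k, k, dimnames = list(nets, nets))
  nw <- atlas$network[match(as.vector(edges), atlas$region_id)]
  nw <- matrix(nw, ncol = 2L)
  for (r in seq_len(nrow(nw))) {
    a <- nw[r, 1L]; b <- nw[r, 2L]
    cnt[a, b] <- cnt[a, b] + 1
    if (a != b) cnt[b, a] <- cnt[b, a] + 1
  }
  prop <- cnt / denom
  prop[denom == 0] <- 0
  list(proportion = prop, count = cnt, denominator = denom)
}

#' Per-region degree in a component (optionally |t|-weighted)
#'
#' Number of component edges incident to each atlas region — the quantity
#' rendered as sphere size in connectome displays. The weighted variant
#' sums |t| over incident edges.
#'
#' @param edges component edge matrix; if it carries a \code{t} attribute
#'   (as components from [nbs()] do) the weighted variant can use it.
#' @param atlas atlas table.
#' @param weights optional per-edge weights (e.g. |t|); default unweighted.
#' @return named numeric vector over all atlas regions (zeros included).
#' @export
nodeAbnormalDegree <- function(edges, atlas, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, max(nrow(edges), 0L))
  edges <- .checkComponentAtlas(edges, atlas)
  deg <- stats::setNames(numeric(nrow(atlas)), atlas$region_id)
  if (nrow(edges)) {
    stopifnot(length(weights) == nrow(edges))
    for (r in seq_len(nrow(edges))) {
      deg[as.character(edges[r, 1L])] <- deg[as.character(edges[r, 1L])] + abs(weights[r])
      deg[as.character(edges[r, 2L])] <- deg[as.character(edges[r, 2L])] + abs(weights[r])
    }
  }
  names(deg) <- atlas$label
  deg
}

#' Intersection of two edge components
#'
#' Edges present in both components (same atlas) — the shared impairment
#' across two group contrasts.
#'
#' @param a,b edge matrices (columns i, j).
#' @return edge matrix of the intersection (possibly 0 rows).
#' @export
componentIntersection <- function(a, b) {
  a <- normalizeEdges(a); b <- normalizeEdges(b)
  ka <- paste(a[, 1L], a[, 2L])
  kb <- paste(b[, 1L], b[, 2L])
  a[ka %in% kb, , drop = FALSE]
}

#' Connection profile of a seed region label
#'
#' All component edges incident to regions whose label contains
#' \code{seedLabel} (case-insensitive substring — multi-parcel seeds such
#' as a lateral-prefrontal label match every parcel), grouped by partner
#' region and sorted by incident edge count.
#'
#' @param edges component edge matrix.
#' @param atlas atlas table.
#' @param seedLabel substring matched against atlas labels.
#' @return data.frame with \code{partner_id}, \code{partner_label},
#'   \code{partner_network}, \code{n_edges}, sorted by \code{n_edges}
#'   decreasing; zero rows when the seed has no incident edges.
#' @export
seedRegionProfile <- function(edges, atlas, seedLabel) {
  seedIds <- atlas$region_id[grepl(seedLabel, atlas$label, ignore.case = TRUE)]
  if (length(seedIds) == 0L)
    stop("no atlas label matches '", seedLabel, "'; available labels include: ",
         paste(utils::head(atlas$label, 8L), collapse = ", "), ", ...")
  edges <- .checkComponentAtlas(edges, atlas)
  hit <- edges[, 1L] %in% seedIds | edges[, 2L] %in% seedIds
  e <- edges[hit, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(partner_id = integer(0), partner_label = character(0),
                      partner_network = character(0), n_edges = integer(0)))
  partner <- ifelse(e[, 1L] %in% seedIds, e[, 2L], e[, 1L])
  tab <- table(partner)
  ids <- as.integer(names(tab))
  out <- data.frame(partner_id = ids,
                    partner_label = atlas$label[match(ids, atlas$region_id)],
                    partner_network = atlas$network[match(ids, atlas$region_id)],
                    n_edges = as.integer(tab))
  out[order(-out$n_edges, out$partner_id), , drop = FALSE]
}
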