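#' Build the temporal unit-disc cell graph of a TrackSet
#'
#' For every movie and every frame, forms a node per track observed at that
#' frame and an undirected edge between each pair of cells whose centroid
#' distance is within \code{radiusUm} (inclusive boundary — the unit-disc
#' convention). The default radius of 7 micrometers approximates the reach
#' of a lymphocyte surface, so edges mark potential cell-cell contacts.
#' Edges connect any marker pair (B-B, B-T, T-T) but never cross movies.
#'
#' @param x a \linkS4class{TrackSet} (may be empty: yields an empty graph).
#' @param radiusUm positive contact radius in micrometers (default 7).
#' @return A \linkS4class{TemporalCellGraph}.
#' @export
buildTemporalGraph <- function(x, radiusUm = 7) {
  stopifnot(is(x, "TrackSet"))
  if (length(radiusUm) != 1L || !is.finite(radiusUm) || radiusUm <= 0)
    stop("radiusUm must be a single positive number", call. = FALSE)
  p <- x@points
  emptyEdges <- data.frame(movie_id = character(0), frame = integer(0),
                           track_a = character(0), track_b = character(0),
                           distance_um = numeric(0))
  nodes <- data.frame(movie_id = character(0), frame = integer(0),
                      track_id = character(0))
  if (!nrow(p))
    return(new("TemporalCellGraph", nodes = nodes, edges = emptyEdges,
               radiusUm = radiusUm))

  movie <- paste(p$case_id, p$movie_id, sep = "/")
  nodes <- data.frame(movie_id = movie, frame = p$frame,
                      track_id = p$track_id, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$movie_id, nodes$frame, nodes$track_id), ]
  rownames(nodes) <- NULL

  groups <- split(seq_len(nrow(p)), list(movie = movie, frame = p$frame),
                  drop = TRUE)
  edgeList <- lapply(groups, function(ii) {
    n <- length(ii)
    if (n < 2L) return(NULL)
    xyz <- cbind(p$x_um[ii], p$y_um[ii], p$z_um[ii])
    d <- stats::dist(xyz)
    hit <- which(d <= radiusUm)
    if (!length(hit)) return(NULL)
    ## row/col indices of the lower-triangle dist entries
    j <- rep(seq_len(n - 1L), times = (n - 1L):1L)[hit]
    i <- (sequence((n - 1L):1L) + rep(seq_len(n - 1L), times = (n - 1L):1L))[hit]
    a <- p$track_id[ii[j]]
    b <- p$track_id[ii[i]]
    swap <- a > b
    data.frame(movie_id = movie[ii[1L]], frame = p$frame[ii[1L]],
               track_a = ifelse(swap, b, a), track_b = ifelse(swap, a, b),
               distance_um = as.numeric(d)[hit], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edgeList, list(emptyEdges)))
  edges <- edges[order(edges$movie_id, edges$frame,
                       edges$track_a, edges$track_b), ]
  rownames(edges) <- NULL
  new("TemporalCellGraph", nodes = nodes, edges = edges, radiusUm = radiusUm)
}

#' @rdname accessors
#' @export
setMethod("graphNodes", "TemporalCellGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "TemporalCellGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("radiusUm", "TemporalCellGraph", function(x) x@radiusUm)

setMethod("show", "TemporalCellGraph", function(object) {
  cat(sprintf(
    "TemporalCellGraph: r = %g um, %d frame-node(s), %d frame-edge(s), %d movie(s)\n",
    object@radiusUm, nrow(object@nodes), nrow(object@edges),
    length(unique(object@nodes$movie_id))))
  invisible(NULL)
})

#' Export a temporal cell graph as a per-frame edge list
#'
#' Writes one CSV row per frame-edge (movie_id, frame, track_a, track_b,
#' distance_um), loadable by downstream visualization. An empty graph yields
#' a header-only file.
#'
#' @param graph a \linkS4class{TemporalCellGraph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportTemporalGraph <- function(graph, path) {
  stopifnot(is(graph, "TemporalCellGraph"))
  utils::write.csv(graph@edges, file = path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
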