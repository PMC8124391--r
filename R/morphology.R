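#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Skeletonize a binary vessel mask
#'
#' Iterative Zhang-Suen thinning until the foreground is one pixel wide,
#' followed by a staircase-cleanup pass that deletes redundant pixels whose
#' neighbours are already mutually connected (making the skeleton minimally
#' 8-thin, so that neighbour counts classify junctions exactly). Topology is
#' preserved, and the operation is idempotent: the skeleton of a skeleton is
#' itself.
#'
#' @param mask binary matrix (0/1).
#' @return 0/1 integer matrix of the medial skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  minthin_cpp(thin_cpp(m))
}

#' Skeleton neighbour counts
#'
#' For each skeleton pixel, the number of skeleton pixels among its 8
#' neighbours (the 3 x 3 window sum excluding the centre). Chain interior
#' pixels count 2, endpoints 1, bifurcations 3, crossovers more than 3.
#'
#' @param skeleton 0/1 matrix.
#' @return integer matrix of neighbour counts (0 off the skeleton).
#' @export
neighborCount <- function(skeleton) {
  neighbor_count_cpp(matrix(as.integer(skeleton > 0),
                            nrow(skeleton), ncol(skeleton)))
}

#' Locate bifurcations and crossovers on a skeleton
#'
#' Bifurcation points have exactly three skeleton neighbours; crossover
#' points have more than three.
#'
#' @param skeleton 0/1 matrix.
#' @return list with `bifurcations` and `crossovers`, each an m x 2 matrix of
#'   (row, col) coordinates.
#' @export
classifyJunctions <- function(skeleton) {
  nc <- neighborCount(skeleton)
  list(bifurcations = which(nc == 3, arr.ind = TRUE),
       crossovers = which(nc > 3, arr.ind = TRUE))
}

# Order the pixels of a junction-free component into a chain by walking from
# an endpoint (or, on a closed loop, from the smallest (row, col) pixel),
# preferring 4-connected steps over diagonal ones.
trace_chain <- function(coords) {
  n <- nrow(coords)
  if (n == 1) return(coords)
  key <- coords[, 1] + coords[, 2] * 1e6
  deg <- integer(n)
  adj <- vector("list", n)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  offs <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                dc = c(0, 0, -1, 1, -1, 1, -1, 1))
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (k in seq_len(8)) {
      kk <- as.character(coords[i, 1] + offs[k, 1] +
                         (coords[i, 2] + offs[k, 2]) * 1e6)
      j <- mget(kk, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    adj[[i]] <- nb
    deg[i] <- length(nb)
  }
  ends <- which(deg <= 1)
  start <- if (length(ends)) {
    cand <- ends
    cand[order(coords[cand, 1], coords[cand, 2])][1]
  } else {
    order(coords[, 1], coords[, 2])[1]
  }
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    path[step] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) {
      if (step < n) {           # disconnected remainder: append in scan order
        rest <- which(!visited)
        path[(step + 1):n] <- rest[order(coords[rest, 1], coords[rest, 2])]
      }
      break
    }
    if (length(nxt) > 1) {      # prefer 4-connected continuation
      d4 <- abs(coords[nxt, 1] - coords[cur, 1]) +
            abs(coords[nxt, 2] - coords[cur, 2])
      nxt <- nxt[order(d4, coords[nxt, 1], coords[nxt, 2])]
    }
    cur <- nxt[1]
  }
  coords[path, , drop = FALSE]
}

offs8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Remove skeleton spurs: branches shorter than minLen that run from an
# endpoint into a junction. These arise from boundary bumps of the rasterized
# mask and would otherwise fragment long vessels at spurious junctions.
prune_spurs <- function(skel, minLen) {
  h <- nrow(skel)
  w <- ncol(skel)
  for (iter in 1:10) {
    nc <- neighbor_count_cpp(skel)
    ends <- which(skel == 1 & nc == 1, arr.ind = TRUE)
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      cur <- as.integer(ends[e, ])
      if (!skel[cur[1], cur[2]]) next
      prev <- c(-1L, -1L)
      path <- matrix(0L, minLen, 2)
      spur <- FALSE
      len <- 0
      for (step in seq_len(minLen - 1)) {
        len <- step
        path[step, ] <- cur
        nr <- cur[1] + offs8[, 1]
        ncol_ <- cur[2] + offs8[, 2]
        ok <- nr >= 1 & nr <= h & ncol_ >= 1 & ncol_ <= w
        nr <- nr[ok]
        ncl <- ncol_[ok]
        on <- skel[cbind(nr, ncl)] == 1 & !(nr == prev[1] & ncl == prev[2])
        nr <- nr[on]
        ncl <- ncl[on]
        if (!length(nr)) break                       # isolated chain: keep
        if (any(nc[cbind(nr, ncl)] >= 3)) {          # reached a junction
          spur <- TRUE
          break
        }
        prev <- cur
        cur <- c(nr[1], ncl[1])
      }
      if (spur) {
        skel[path[seq_len(len), , drop = FALSE]] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
    skel <- thin_cpp(skel)
  }
  skel
}

#' Separate a skeleton into identified vessel segments
#'
#' Skeleton spurs shorter than `minLen` (endpoint branches created by
#' boundary bumps of the mask) are pruned first. Junction pixels (neighbour
#' count >= 3) are then removed so that each vessel segment becomes its own
#' 8-connected component; components shorter than `minLen` pixels are
#' discarded as fragments that do not represent a connected vascular
#' network. Each surviving segment is traced into an ordered centerline
#' chain starting at the endpoint with the smaller (row, col), and its
#' length is the pixel count along the chain.
#'
#' @param skeleton 0/1 skeleton matrix.
#' @param minLen minimum segment length in pixels (default 20).
#' @return a [VesselGraph-class]; diameters are NA until
#'   [measureDiameters()] is applied.
#' @export
extractSegments <- function(skeleton, minLen = 20) {
  skel <- matrix(as.integer(skeleton > 0), nrow(skeleton), ncol(skeleton))
  skel <- prune_spurs(skel, minLen)
  jx <- classifyJunctions(skel)
  pruned <- skel
  for (m in jx) if (nrow(m)) pruned[m] <- 0L
  lab <- label8_cpp(pruned)
  nlab <- max(lab)
  segs <- list()
  id <- 0
  for (l in seq_len(nlab)) {
    coords <- which(lab == l, arr.ind = TRUE)
    if (nrow(coords) < minLen) next
    id <- id + 1
    chain <- trace_chain(unname(coords))
    colnames(chain) <- c("row", "col")
    segs[[id]] <- list(id = id, pixels = chain, lengthPx = nrow(chain),
                       diameterPx = NA_real_)
  }
  new("VesselGraph", segments = segs,
      bifurcations = jx$bifurcations, crossovers = jx$crossovers,
      dim = dim(skel))
}

#' Measure per-segment vessel diameters
#'
#' For every centerline pixel, the Euclidean distance d to the nearest
#' background pixel is taken from the distance transform of the vessel mask;
#' the pixel's local width is 2d - 1 (exact for odd discrete widths, since d
#' is measured centre-to-centre), and the segment diameter is the median of
#' its pixels' widths, which is robust to inflation near junctions.
#'
#' @param graph a [VesselGraph-class].
#' @param mask the binary vessel mask the skeleton came from.
#' @return the graph with `diameterPx` filled in for every segment.
#' @export
measureDiameters <- function(graph, mask) {
  stopifnot(is(graph, "VesselGraph"))
  dm <- from_ebimage(EBImage::distmap(as_ebimage((mask > 0) * 1)))
  segs <- lapply(graph@segments, function(s) {
    d <- dm[s$pixels]
    if (any(d == 0))
      stopf("segment %d has centerline pixels on the background", s$id)
    s$diameterPx <- stats::median(2 * d - 1)
    s
  })
  graph@segments <- segs
  graph
}

#' @rdname segments
#' @export
setMethod("segments", "VesselGraph", function(x) x@segments)

#' @rdname segments
#' @export
setMethod("junctions", "VesselGraph", function(x) {
  list(bifurcations = x@bifurcations, crossovers = x@crossovers)
})

#' Vessel segment summary table
#'
#' By default `length_px` is the raw pixel count along the chain;
#' `weightDiagonals = TRUE` instead accumulates step lengths (1 for
#' 4-connected steps, sqrt(2) for diagonal ones), which better approximates
#' the Euclidean arc length of oblique vessels.
#'
#' @param x a [VesselGraph-class].
#' @param micronsPerPixel optional scale to add physical-unit columns.
#' @param weightDiagonals use sqrt(2)-weighted diagonal steps for length?
#' @param ... unused.
#' @return data.frame with id, length and diameter per segment.
#' @name segments
#' @export
setMethod("segmentTable", "VesselGraph", function(x, micronsPerPixel = NA,
                                                  weightDiagonals = FALSE,
                                                  ...) {
  seg_len <- function(s) {
    if (!weightDiagonals) return(s$lengthPx)
    if (nrow(s$pixels) < 2) return(as.numeric(nrow(s$pixels)))
    st <- abs(diff(s$pixels))
    1 + sum(ifelse(rowSums(st) == 2, sqrt(2), 1))
  }
  df <- data.frame(
    id = vapply(x@segments, `[[`, numeric(1), "id"),
    n_pixels = vapply(x@segments, `[[`, numeric(1), "lengthPx"),
    length_px = vapply(x@segments, seg_len, numeric(1)),
    diameter_px = vapply(x@segments, `[[`, numeric(1), "diameterPx"))
  if (!is.na(micronsPerPixel)) {
    df$length_um <- df$length_px * micronsPerPixel
    df$diameter_um <- df$diameter_px * micronsPerPixel
  }
  df
})

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf("VesselGraph: %d segments, %d bifurcations, %d crossovers\n",
              length(object@segments), nrow(object@bifurcations),
              nrow(object@crossovers)))
  if (length(object@segments)) {
    len <- vapply(object@segments, `[[`, numeric(1), "lengthPx")
    cat(sprintf("  length: %d-%d px (median %.0f)\n",
                min(len), max(len), stats::median(len)))
  }
  invisible(NULL)
})

#' Label image of vessel segments
#'
#' @param graph a [VesselGraph-class].
#' @return integer matrix with each centerline pixel carrying its segment id.
#' @export
segmentLabelImage <- function(graph) {
  lab <- matrix(0L, graph@dim[1], graph@dim[2])
  for (s in graph@segments) lab[s$pixels] <- as.integer(s$id)
  lab
}

#' Full morphology pass from a mask
#'
#' Convenience wrapper: skeletonize, split at junctions, prune, and measure
#' diameters.
#'
#' @param mask binary vessel mask.
#' @param minLen pruning threshold in pixels.
#' @return a measured [VesselGraph-class].
#' @export
vesselGraph <- function(mask, minLen = 20) {
  measureDiameters(extractSegments(skeletonize(mask), minLen = minLen), mask)
}
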