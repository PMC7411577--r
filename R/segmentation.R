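#' @name segmentation
#' @title Vessel mask, skeleton and centerline segments
#' @description
#' The vesselness map is binarized by hysteresis thresholding, cleaned of
#' small objects, thinned to a one-pixel skeleton and traced into ordered
#' centerline segments between skeleton endpoints and branch points.
#' Coordinates follow the (row, col) convention, 0 at the top-left, rows
#' increasing downward (reported 1-based as usual in R).
NULL

# linear-index neighbors: the 8 offsets in a matrix with nr rows
neighbor_offsets <- function(nr) {
  c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
}

# 8- (or 4-) connected component labels of a logical matrix
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    dr <- offs[[i]][1]; dc <- offs[[i]][2]
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    sel <- mask[nb]
    edges[[i]] <- cbind(id[idx[ok][sel]], id[nb[sel]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Hysteresis binarization of a vesselness map
#'
#' Pixels with vesselness `>= high` seed the mask; pixels `>= low` are kept
#' iff they are 8-connected to a seed.
#'
#' @param map A `vesselness_map` from [jerman_multiscale()] or a plain
#'   numeric matrix.
#' @param low,high Thresholds with `0 < low < high <= 1`.
#' @return A logical matrix (the vessel mask).
#' @export
binarize_vesselness <- function(map, low = 0.05, high = 0.25) {
  v <- if (inherits(map, "vesselness_map")) map$values else map
  if (!is.matrix(v)) stop("`map` must be a vesselness_map or matrix")
  if (!(low > 0 && low < high && high <= 1))
    stop("need 0 < low < high <= 1")
  weak <- v >= low
  strong <- v >= high
  if (!any(strong)) return(matrix(FALSE, nrow(v), ncol(v)))
  lab <- label_components(weak, 8L)
  keep <- logical(max(lab))
  keep[unique(lab[strong])] <- TRUE
  out <- matrix(FALSE, nrow(v), ncol(v))
  nz <- lab != 0L
  out[nz] <- keep[lab[nz]]
  out
}

#' Remove small objects and fill pinholes in a vessel mask
#'
#' Drops 8-connected components with fewer than `min_object_px` pixels and
#' fills interior background holes of at most 4 pixels (4-connected
#' background components not touching the border).
#'
#' @param mask Logical matrix.
#' @param min_object_px Minimum surviving component size (>= 1).
#' @return A logical matrix.
#' @export
clean_mask <- function(mask, min_object_px = 30) {
  if (!is.matrix(mask)) stop("`mask` must be a logical matrix")
  mask <- mask != 0
  if (min_object_px < 1) stop("`min_object_px` must be >= 1")
  lab <- label_components(mask, 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab != 0L])
    small <- which(sizes < min_object_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  # pinholes: tiny enclosed background components
  bg <- !mask
  blab <- label_components(bg, 4L)
  if (max(blab) > 0) {
    border_labs <- unique(c(blab[1, ], blab[nrow(blab), ],
                            blab[, 1], blab[, ncol(blab)]))
    bsizes <- tabulate(blab[blab != 0L])
    holes <- setdiff(which(bsizes <= 4), border_labs)
    if (length(holes)) mask[blab %in% holes] <- TRUE
  }
  mask
}

# value of the 8 neighbors of every pixel, zero-padded shift
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rd <- max(1L, 1L - dr):min(nr, nr - dr)
  cd <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rd, cd] <- m[rd + dr, cd + dc]
  out
}

#' Topological thinning of a binary mask (Guo-Hall)
#'
#' Iteratively peels boundary pixels while preserving connectivity until a
#' one-pixel-wide skeleton remains. The Guo-Hall two-subiteration scheme is
#' used because it erodes line ends less than the Zhang-Suen scheme and
#' leaves fewer staircase artifacts.
#'
#' @param mask Logical matrix.
#' @return A logical matrix (the skeleton).
#' @export
skeletonize <- function(mask) {
  m <- (mask != 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north: p2..p9
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L); p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L); p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      mm <- if (step == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & !mm
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

skeleton_neighbor_count <- function(skel) {
  s <- skel * 1
  Reduce(`+`, lapply(list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                          c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)),
                     function(o) shift_mat(s, o[1], o[2])))
}

# Remove redundant staircase pixels: a skeleton pixel whose only two
# neighbors are themselves 8-adjacent adds nothing to connectivity but
# inflates neighbor counts along 8-connected staircases, which would be
# misread as junctions. Removal is sequential so adjacent candidates are
# re-checked against the live skeleton.
simplify_skeleton <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  offs <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  repeat {
    removed <- FALSE
    for (i in which(skel)) {
      r <- (i - 1L) %% nr + 1L
      cc <- (i - 1L) %/% nr + 1L
      if (r < 2L || cc < 2L || r > nr - 1L || cc > nc - 1L) next
      hit <- which(skel[cbind(r + offs[, 1], cc + offs[, 2])])
      if (length(hit) == 2L) {
        d <- abs(offs[hit[1], ] - offs[hit[2], ])
        if (max(d) == 1L) {  # the two neighbors touch each other
          skel[i] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  skel
}

#' Prune short spurs from a skeleton
#'
#' Boundary wobble of the vessel mask leaves short twigs on the skeleton;
#' each twig introduces a branch point that would otherwise chop the main
#' centerline into fragments. A spur is a branch-free path shorter than
#' `max_spur_len` with a free endpoint hanging off a branch point; spurs are
#' removed iteratively until none remain.
#'
#' @param skel Logical skeleton matrix.
#' @param max_spur_len Maximum twig length (points) to prune.
#' @return A logical skeleton matrix.
#' @export
prune_spurs <- function(skel, max_spur_len = 10) {
  for (iter in 1:20) {
    ncount <- skeleton_neighbor_count(skel)
    branch <- skel & ncount > 2
    if (!any(branch)) break
    free_end <- skel & ncount == 1
    branch_adj <- matrix(FALSE, nrow(skel), ncol(skel))
    for (dr in -1:1) for (dc in -1:1)
      branch_adj <- branch_adj | shift_mat(branch * 1, dr, dc) > 0
    lab <- label_components(skel & !branch, 8L)
    if (max(lab) == 0) break
    nz <- lab != 0L
    sizes <- tabulate(lab[nz], nbins = max(lab))
    has_free <- has_branch <- logical(max(lab))
    has_free[unique(lab[free_end & nz])] <- TRUE
    has_branch[unique(lab[branch_adj & nz])] <- TRUE
    spur <- which(sizes < max_spur_len & has_free & has_branch)
    if (!length(spur)) break
    skel[nz][lab[nz] %in% spur] <- FALSE
  }
  skel
}

#' Skeletonize a mask and trace centerline segments
#'
#' The mask is thinned ([skeletonize()]), short spurs are pruned
#' ([prune_spurs()]), and the skeleton is traced. Branch points are skeleton
#' pixels with more than two skeleton neighbors. Segments are maximal
#' branch-point-free 8-connected paths between endpoints/branch points,
#' ordered from one end; branch pixels belong to no segment, so segments
#' stop one pixel short of a junction. Isolated loops are traced from their
#' lexicographically smallest pixel. Tracing is deterministic.
#'
#' @param mask Logical matrix (a cleaned vessel mask).
#' @param min_segment_len Minimum number of points for a segment to be kept.
#' @return A list of `vessel_segment` objects: each has `points` (n x 2
#'   matrix of (row, col)), `arc_length` (pixels), and `n_points`.
#' @export
skeletonize_and_trace <- function(mask, min_segment_len = 10) {
  skel <- skeletonize(mask)
  # simplification exposes new spurs and vice versa: iterate to a fixpoint
  for (i in 1:5) {
    s0 <- skel
    skel <- prune_spurs(simplify_skeleton(skel), min_segment_len)
    if (identical(skel, s0)) break
  }
  trace_skeleton(skel, min_segment_len)
}

#' Trace an existing one-pixel skeleton into segments
#'
#' @param skel Logical skeleton matrix.
#' @param min_segment_len Minimum points per kept segment.
#' @return A list of `vessel_segment` objects (see [skeletonize_and_trace()]).
#' @export
trace_skeleton <- function(skel, min_segment_len = 10) {
  nr <- nrow(skel); nc <- ncol(skel)
  if (!any(skel)) return(list())
  branch <- skel & skeleton_neighbor_count(skel) > 2
  segmask <- skel & !branch
  lab <- label_components(segmask, 8L)
  n_comp <- max(lab)
  offs <- neighbor_offsets(nr)
  segs <- list()
  comp_pix <- split(which(lab != 0L), lab[lab != 0L])
  for (l in seq_len(n_comp)) {
    pix <- sort(comp_pix[[as.character(l)]])
    np <- length(pix)
    if (np < min_segment_len) next
    # in-component neighbor lists
    nb_of <- lapply(pix, function(i) {
      r <- ((i - 1L) %% nr) + 1L
      nbs <- i + offs
      ok <- nbs >= 1L & nbs <= nr * nc
      # exclude wrap-around across matrix columns
      rr <- ((nbs - 1L) %% nr) + 1L
      ok <- ok & abs(rr - r) <= 1L
      nbs <- nbs[ok]
      nbs[lab[nbs] == l]
    })
    deg <- lengths(nb_of)
    start_pos <- if (any(deg <= 1)) which(deg <= 1)[1L] else 1L
    pos_of <- structure(seq_len(np), names = pix)
    walk_from <- function(cur, visited) {
      out <- integer(0)
      repeat {
        out <- c(out, cur)
        visited[cur] <- TRUE
        nxt_pos <- pos_of[as.character(nb_of[[cur]])]
        nxt_pos <- nxt_pos[!visited[nxt_pos]]
        if (!length(nxt_pos)) break
        cur <- min(nxt_pos)  # deterministic tie-break
      }
      list(seq = out, visited = visited)
    }
    w1 <- walk_from(start_pos, logical(np))
    order_pos <- w1$seq
    # if the start sat mid-path (staircase tip), walk the other arm too
    other <- pos_of[as.character(nb_of[[start_pos]])]
    other <- other[!w1$visited[other]]
    if (length(other)) {
      w2 <- walk_from(min(other), w1$visited)
      order_pos <- c(rev(w2$seq), order_pos)
    }
    if (length(order_pos) < min_segment_len) next
    pidx <- pix[order_pos]
    pts <- cbind(row = ((pidx - 1L) %% nr) + 1L,
                 col = ((pidx - 1L) %/% nr) + 1L)
    steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    segs[[length(segs) + 1L]] <- structure(
      list(points = pts, arc_length = sum(steps), n_points = nrow(pts)),
      class = "vessel_segment")
  }
  segs
}

#' Smooth and resample a centerline segment
#'
#' Coordinates are smoothed with a centered moving average (window shrinks
#' symmetrically near the ends, so endpoints are preserved exactly), then
#' resampled at uniform arc-length spacing by linear interpolation.
#' Segments shorter than `window` points are returned unsmoothed with
#' `smoothed = FALSE`.
#'
#' @param segment A `vessel_segment`.
#' @param window Odd moving-average window (points), default 5.
#' @param spacing Target arc-length spacing (pixels), default 1.
#' @return A `vessel_segment` with fields `points`, `arc_length`,
#'   `n_points`, `spacing`, `smoothed`.
#' @export
smooth_resample <- function(segment, window = 5, spacing = 1) {
  pts <- segment$points
  n <- nrow(pts)
  if (n < window) {
    segment$smoothed <- FALSE
    segment$spacing <- NA_real_
    return(segment)
  }
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  cr <- cumsum(c(0, pts[, 1])); cc <- cumsum(c(0, pts[, 2]))
  sr <- (cr[i + hh + 1L] - cr[i - hh]) / (2 * hh + 1)
  sc <- (cc[i + hh + 1L] - cc[i - hh]) / (2 * hh + 1)
  d <- sqrt(diff(sr)^2 + diff(sc)^2)
  s <- c(0, cumsum(d))
  L <- s[n]
  if (L <= spacing) {  # degenerate: collapses to (almost) a point
    segment$points <- cbind(row = sr, col = sc)
    segment$arc_length <- L
    segment$n_points <- n
    segment$spacing <- NA_real_
    segment$smoothed <- TRUE
    return(segment)
  }
  keep <- c(TRUE, diff(s) > 1e-12)
  tt <- seq(0, L, by = spacing)
  if (tt[length(tt)] < L - 1e-9) tt <- c(tt, L)
  rr <- stats::approx(s[keep], sr[keep], xout = tt)$y
  rc <- stats::approx(s[keep], sc[keep], xout = tt)$y
  pts2 <- cbind(row = rr, col = rc)
  steps <- sqrt(diff(rr)^2 + diff(rc)^2)
  structure(list(points = pts2, arc_length = sum(steps),
                 n_points = nrow(pts2), spacing = spacing, smoothed = TRUE),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("vessel segment: %d points, arc length %.1f px\n",
              x$n_points, x$arc_length))
  invisible(x)
}
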