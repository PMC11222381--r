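# 3D topology-preserving thinning and centerline graphs.
#
# Thinning removes "simple" border voxels — voxels whose deletion changes
# neither the foreground nor the background topology — until only a
# one-voxel-wide skeleton remains, protecting curve endpoints. Simplicity is
# checked with the standard (26, 6)-connectivity characterization: a voxel is
# simple iff (a) the foreground in its 26-neighborhood forms exactly one
# 26-connected component and (b) the background in its 18-neighborhood forms
# exactly one 6-connected component that touches a face neighbor. Voxels are
# processed in increasing distance-from-background order so the skeleton
# stays centered in tubular structures.

# ---- static 3x3x3 neighborhood tables (computed once at load) --------------

.nbhdTables <- local({
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  center <- which(rowSums(abs(offs)) == 0)            # 14
  n26 <- setdiff(seq_len(27), center)
  # 26-adjacency among the 26 neighbor cells
  adj26 <- lapply(n26, function(a) {
    d <- abs(sweep(offs[n26, , drop = FALSE], 2, offs[a, ]))
    n26[apply(d, 1, max) == 1]
  })
  names(adj26) <- as.character(n26)
  # 18-neighborhood (faces + edges), 6-adjacency within it
  n18 <- which(rowSums(abs(offs)) <= 2 & rowSums(abs(offs)) > 0)
  adj6 <- lapply(n18, function(a) {
    d <- sweep(offs[n18, , drop = FALSE], 2, offs[a, ])
    n18[rowSums(abs(d)) == 1]
  })
  names(adj6) <- as.character(n18)
  faces <- which(rowSums(abs(offs)) == 1)
  list(offs = offs, center = center, n26 = n26, adj26 = adj26,
       n18 = n18, adj6 = adj6, faces = faces)
})

# Count connected components of `cells` (subset of neighborhood indices)
# under a precomputed adjacency list keyed by cell index.
.nbhdComponents <- function(cells, adj) {
  if (!length(cells)) return(0L)
  seen <- logical(28)
  inSet <- logical(28)
  inSet[cells] <- TRUE
  ncomp <- 0L
  for (s in cells) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (inSet[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  ncomp
}

# Is the center of a 27-cell logical neighborhood a simple point?
isSimplePoint <- function(nb27) {
  tb <- .nbhdTables
  fg <- tb$n26[nb27[tb$n26]]
  if (!length(fg)) return(FALSE)                 # isolated voxel
  if (.nbhdComponents(fg, tb$adj26) != 1L) return(FALSE)
  bg18 <- tb$n18[!nb27[tb$n18]]
  if (!any(tb$faces %in% bg18)) return(FALSE)    # interior voxel
  # components of 6-connected background in N18 that touch a face neighbor
  if (!length(bg18)) return(FALSE)
  seen <- logical(28); inSet <- logical(28); inSet[bg18] <- TRUE
  ncomp <- 0L
  for (s in intersect(tb$faces, bg18)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in tb$adj6[[as.character(v)]])
        if (inSet[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  ncomp == 1L
}

# Integer distance-from-background transform (6-connected BFS, padded).
.bfsDistance <- function(pad, dp) {
  dist <- array(NA_integer_, dim = dp)
  lin6 <- c(-1L, 1L, -dp[1L], dp[1L], -dp[1L] * dp[2L], dp[1L] * dp[2L])
  frontier <- which(!pad)
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(as.vector(outer(frontier, lin6, `+`)))
    nxt <- nxt[nxt >= 1L & nxt <= length(pad)]
    nxt <- nxt[pad[nxt] & is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Thin a 3D mask to a one-voxel-wide skeleton
#'
#' Sequential topology-preserving thinning under (26, 6) connectivity with
#' curve-endpoint preservation, processing voxels in increasing
#' distance-from-background order for centeredness.
#'
#' @param mask 3D logical array (or [VolumeGrid-class]).
#' @return 3D logical array of the same shape, TRUE on the skeleton.
#' @export
thinMask <- function(mask) {
  vg <- NULL
  if (is(mask, "VolumeGrid")) { vg <- mask; mask <- voxelData(mask) != 0 }
  shape <- dim(mask)
  dp <- shape + 2L
  pad <- array(FALSE, dim = dp)
  pad[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)] <- mask
  tb <- .nbhdTables
  linOff <- tb$offs[, 1] + tb$offs[, 2] * dp[1] + tb$offs[, 3] * dp[1] * dp[2]
  lin6 <- linOff[tb$faces]
  dist <- .bfsDistance(pad, dp)

  # 6 directional subiterations per cycle (only voxels whose face neighbor
  # in the current direction is background are candidates), each split into
  # 8 parity subfields so that voxels removed within one pass are never
  # 26-adjacent: sequential removal is then equivalent to parallel removal,
  # which keeps elongated structures from being consumed end-to-end.
  parity <- array(0L, dim = dp)
  pidx <- allVoxelIndices(dp)
  parity[] <- (pidx[, 1] %% 2L) + 2L * (pidx[, 2] %% 2L) +
    4L * (pidx[, 3] %% 2L)
  spurLen <- max(dist, na.rm = TRUE) + 1L
  inner <- 2:(shape[1] + 1)
  repeat {
    removed <- 0L
    for (d in lin6) {
      for (sf in 0:7) {
        fg <- which(pad)
        if (!length(fg)) break
        cand <- fg[!pad[fg + d] & parity[fg] == sf]
        if (!length(cand)) next
        cand <- cand[order(dist[cand], cand)]
        for (v in cand) {
          nb <- pad[v + linOff]
          if (sum(nb[tb$n26]) == 1L) next       # curve endpoint: keep
          if (isSimplePoint(nb)) { pad[v] <- FALSE; removed <- removed + 1L }
        }
      }
    }
    if (removed > 0L) next
    # prune surface spurs (leaf twigs no longer than the tube radius:
    # thinning artifacts from endpoints protected mid-erosion); pruning can
    # expose new simple points, so thin again until jointly stable
    out <- array(pad[inner, 2:(shape[2] + 1), 2:(shape[3] + 1)], dim = shape)
    pruned <- .pruneSpurs(out, spurLen)
    if (sum(pruned) == sum(out)) break
    pad[inner, 2:(shape[2] + 1), 2:(shape[3] + 1)] <- pruned
  }
  array(pad[inner, 2:(shape[2] + 1), 2:(shape[3] + 1)], dim = shape)
}

# Remove leaf branches of length <= spurLen that attach to a junction;
# repeats until stable. Genuine branches (longer than the vessel radius)
# are untouched.
.pruneSpurs <- function(skel, spurLen) {
  shape <- dim(skel)
  repeat {
    vox <- linearVox(which(skel), shape)
    if (nrow(vox) < 3L) return(skel)
    g <- .skeletonGraph(vox, shape)
    deg <- igraph::degree(g)
    junction <- deg >= 3L
    if (!any(junction)) return(skel)
    sub <- igraph::induced_subgraph(g, which(!junction))
    subIds <- which(!junction)
    comp <- igraph::components(sub)
    drop <- integer(0)
    for (ci in seq_len(comp$no)) {
      members <- subIds[comp$membership == ci]
      if (length(members) > spurLen) next
      nJn <- sum(vapply(members, function(v)
        any(junction[as.integer(igraph::neighbors(g, v))]), TRUE))
      hasLeaf <- any(deg[members] == 1L)
      if (hasLeaf && nJn == 1L) drop <- c(drop, members)
    }
    if (!length(drop)) return(skel)
    skel[voxLinear(vox[drop, , drop = FALSE], shape)] <- FALSE
  }
}

# igraph over skeleton voxels: vertices = voxels (n x 3 index matrix rows),
# edges between 26-adjacent pairs.
.skeletonGraph <- function(vox, shape) {
  n <- nrow(vox)
  lin <- voxLinear(vox, shape)
  lut <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = lut)
  offs <- .nbhdTables$offs[.nbhdTables$n26, , drop = FALSE]
  half <- offs[seq_len(13L), , drop = FALSE]     # one of each +/- pair
  edges <- integer(0)
  for (h in seq_len(13L)) {
    nb <- sweep(vox, 2L, -half[h, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 &
      nb[, 2] <= shape[2] & nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(ok)) next
    linNb <- voxLinear(nb[ok, , drop = FALSE], shape)
    from <- which(ok)
    for (q in seq_along(from)) {
      j <- get0(as.character(linNb[q]), envir = lut)
      if (!is.null(j)) edges <- c(edges, from[q], j)
    }
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

#' Longest path through a skeletonized mask
#'
#' Thins the mask and extracts the longest path through the skeleton (double
#' breadth-first search), returning the voxels in path order. This is the
#' centerline used for the sinus VIF.
#'
#' @param mask 3D logical array or [VolumeGrid-class]; must be non-empty and
#'   26-connected.
#' @return integer matrix (n x 3) of ordered voxel indices.
#' @export
maskCenterline <- function(mask) {
  if (is(mask, "VolumeGrid")) mask <- voxelData(mask) != 0
  if (!any(mask)) stop("centerline extraction failed: mask is empty")
  shape <- dim(mask)
  voxAll <- linearVox(which(mask), shape)
  gAll <- .skeletonGraph(voxAll, shape)
  if (igraph::count_components(gAll) > 1L)
    stop("centerline extraction failed: mask is not 26-connected (",
         igraph::count_components(gAll), " components)")
  skel <- thinMask(mask)
  vox <- linearVox(which(skel), shape)
  if (nrow(vox) == 1L) return(vox)
  g <- .skeletonGraph(vox, shape)
  # double BFS: farthest from an arbitrary vertex, then farthest from that
  d1 <- igraph::distances(g, v = 1)
  u <- which.max(replace(d1, !is.finite(d1), -1))
  d2 <- igraph::distances(g, v = u)
  v <- which.max(replace(d2, !is.finite(d2), -1))
  p <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
  path <- vox[as.integer(p), , drop = FALSE]
  path <- .extendEnds(path, mask)
  # deterministic orientation: start at the lexicographically smaller end
  a <- path[1, ]; b <- path[nrow(path), ]
  if (isTRUE(b[1] < a[1] || (b[1] == a[1] && (b[2] < a[2] ||
      (b[2] == a[2] && b[3] < a[3])))))
    path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  path
}

#' Skeletonize a vascular mask into a branch-decomposed centerline tree
#'
#' Thins the mask to a one-voxel skeleton and subdivides it into branches at
#' junction voxels (voxels with three or more skeleton neighbors). Each
#' branch is an ordered voxel path; adjacent junction voxels terminate the
#' paths they touch.
#'
#' @param mask 3D logical array or [VolumeGrid-class] (vessel segmentation).
#' @param spacing voxel spacing, mm.
#' @return a [CenterlineTree-class]. An empty mask yields an empty tree. A
#'   mask touching the volume boundary is processed with a warning (branches
#'   are clipped at the boundary).
#' @export
skeletonize <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "VolumeGrid")) {
    spacing <- voxelSpacing(mask)
    mask <- voxelData(mask) != 0
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  emptyTree <- new("CenterlineTree", branches = list(), tangents = list(),
                   radius = numeric(0), branchClass = character(0),
                   spacing = spacing)
  if (!any(mask)) return(emptyTree)
  shape <- dim(mask)
  if (any(mask[c(1, shape[1]), , ]) || any(mask[, c(1, shape[2]), ]) ||
      any(mask[, , c(1, shape[3])]))
    warning("mask touches the volume boundary; branches are clipped")
  skel <- thinMask(mask)
  vox <- linearVox(which(skel), shape)
  n <- nrow(vox)
  g <- .skeletonGraph(vox, shape)
  deg <- igraph::degree(g)
  junction <- deg >= 3L

  branchList <- list()
  if (any(!junction)) {
    sub <- igraph::induced_subgraph(g, which(!junction))
    subIds <- which(!junction)
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      members <- subIds[comp$membership == ci]
      ordered <- .orderPath(g, sub, comp$membership == ci, members)
      # attach adjacent junction voxels at the ends
      for (endPos in c(1L, length(ordered))) {
        endV <- ordered[[endPos]]
        jn <- intersect(as.integer(igraph::neighbors(g, endV)),
                        which(junction))
        if (length(jn)) {
          jn <- min(jn)
          ordered <- if (endPos == 1L) c(jn, ordered) else c(ordered, jn)
        }
        if (length(ordered) >= 2L && ordered[1] == ordered[length(ordered)])
          ordered <- ordered[-length(ordered)]   # guard tiny loops
      }
      if (length(ordered) >= 2L)
        branchList[[length(branchList) + 1L]] <-
          vox[ordered, , drop = FALSE]
    }
  }
  if (!length(branchList)) {
    # pure junction cluster or single voxel: one degenerate branch
    branchList <- list(vox)
  }
  nb <- length(branchList)
  new("CenterlineTree", branches = branchList, tangents = list(),
      radius = rep(NA_real_, nb), branchClass = rep(NA_character_, nb),
      spacing = spacing)
}

# Extend both ends of a centerline path along the local tangent while still
# inside the mask: thinning erodes roughly one tube radius from each flat
# end, which this reconstructs.
.extendEnds <- function(path, mask) {
  shape <- dim(mask)
  for (rev2 in c(FALSE, TRUE)) {
    if (rev2) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
    n <- nrow(path)
    w <- min(4L, n - 1L)
    if (w < 1L) next
    d <- path[n, ] - path[n - w, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) next
    d <- d / nd
    p <- as.numeric(path[n, ])
    for (step in seq_len(64L)) {
      p <- p + d
      v <- as.integer(round(p))
      if (any(v < 1L) || any(v > shape) || !mask[v[1], v[2], v[3]]) break
      if (!any(path[, 1] == v[1] & path[, 2] == v[2] & path[, 3] == v[3]))
        path <- rbind(path, v)
    }
  }
  path[rev(seq_len(nrow(path))), , drop = FALSE]
}

# Order the vertices of a path-like component. `markers` is the logical
# membership over the subgraph's vertex set; `members` the parent ids.
.orderPath <- function(g, sub, inComp, members) {
  local <- which(inComp)
  sg <- igraph::induced_subgraph(sub, local)
  dsg <- igraph::degree(sg)
  if (length(members) == 1L) return(members)
  start <- if (any(dsg <= 1L)) which(dsg <= 1L)[1] else which.min(members)
  ord <- as.integer(igraph::dfs(sg, root = start)$order)
  members[ord]
}
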