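# Grid helpers shared by the ReHo, clustering and ROI code.

#' Neighbourhood offsets for a cubic neighbourhood
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @param includeCenter include the (0,0,0) offset.
#' @return integer matrix with one (di, dj, dk) row per offset.
#' @keywords internal
neighborOffsets <- function(connectivity = 26L, includeCenter = FALSE) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = l1 == 1L,
                 "18" = l1 >= 1L & l1 <= 2L,
                 "26" = l1 >= 1L)
  if (includeCenter) keep <- keep | l1 == 0L
  unname(g[keep, , drop = FALSE])
}

# Map a neighbourhood size (7/19/27 incl. center) to offsets incl. center.
rehoOffsets <- function(neighborhood) {
  conn <- c("7" = 6L, "19" = 18L, "27" = 26L)[as.character(neighborhood)]
  if (is.na(conn)) stop("neighborhood must be 7, 19 or 27")
  neighborOffsets(conn, includeCenter = TRUE)
}

# Shift a 3D logical/numeric array by (di,dj,dk), zero-padding at the faces.
shiftArray3d <- function(a, off) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1L), d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    i[i >= 1L & i <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] - off[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Linear index <-> (i,j,k) on a grid of dim d (1-based).
linearIndex <- function(ijk, d) {
  ijk <- rbind(ijk)
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2])
}

gridCoords <- function(lin, d) {
  lin <- as.integer(lin) - 1L
  i <- lin %% d[1]
  j <- (lin %/% d[1]) %% d[2]
  k <- lin %/% (d[1] * d[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

#' Convert 1-based voxel indices to world mm
#'
#' The synthetic grid carries a diagonal affine centred at the grid centre,
#' so world coordinates are \code{(ijk - centre) * voxelSizeMM}.
#' @param ijk voxel index triplet(s), rows.
#' @param dim grid dimensions.
#' @param voxelSizeMM isotropic voxel size.
#' @return numeric matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(ijk, dim, voxelSizeMM = 3) {
  ijk <- rbind(ijk)
  sweep(ijk, 2, (dim + 1) / 2) * voxelSizeMM
}

# Logical sphere of voxels whose centres are within radiusMM of centerVox.
sphereMask <- function(centerVox, radiusMM, dim, voxelSizeMM) {
  rv <- radiusMM / voxelSizeMM
  rng <- lapply(1:3, function(ax)
    max(1L, ceiling(centerVox[ax] - rv)):min(dim[ax], floor(centerVox[ax] + rv)))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- rowSums(sweep(g, 2, centerVox)^2)
  m <- array(FALSE, dim)
  m[g[d2 <= rv^2 + 1e-12, , drop = FALSE]] <- TRUE
  m
}

# Solid sphere in voxel units (for planted-effect ROIs).
roiMaskFromSpec <- function(center, radius, dim) {
  sphereMask(center, radius, dim, voxelSizeMM = 1)
}

# Rebuild the effectRois list from JSON (simplifyVector may yield either a
# data.frame with a list column or a plain list of lists).
parseEffectRois <- function(er) {
  if (is.data.frame(er)) {
    lapply(seq_len(nrow(er)), function(i)
      list(center = unlist(er$center[[i]]), radius = er$radius[[i]]))
  } else {
    lapply(er, function(r) list(center = unlist(r$center),
                                radius = r$radius))
  }
}
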