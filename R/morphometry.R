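# Internal: soma centroid (mean position of type-1 nodes; falls back to
# the root node if no node is typed soma).
soma_center <- function(m) {
  nd <- m$nodes
  s <- nd[nd$type == 1, ]
  if (nrow(s) == 0L) s <- nd[nd$parent == -1, ]
  c(x = mean(s$x), y = mean(s$y), z = mean(s$z))
}

# Internal: dendritic segments (parent-child chords whose child node is
# type 3 or 4) as a data.frame of endpoint coordinates and radii.
# A segment whose parent is a soma node takes the soma centroid as its
# proximal endpoint.
dendrite_segments <- function(m) {
  nd <- m$nodes
  ctr <- soma_center(m)
  child <- nd[nd$type %in% c(3, 4) & nd$parent != -1, ]
  if (nrow(child) == 0L)
    stop("morphology has no dendritic segments (types 3/4)")
  pidx <- match(child$parent, nd$id)
  par <- nd[pidx, ]
  from_soma <- par$type == 1
  data.frame(
    x1 = ifelse(from_soma, ctr["x"], par$x),
    y1 = ifelse(from_soma, ctr["y"], par$y),
    z1 = ifelse(from_soma, ctr["z"], par$z),
    r1 = par$radius,
    x2 = child$x, y2 = child$y, z2 = child$z, r2 = child$radius
  )
}

#' Sholl analysis of a morphology
#'
#' Overlays concentric spheres of increasing radius (default 20.6-um
#' increments) centered on the soma and counts, per sphere, the
#' dendritic segments whose endpoint distances from the center straddle
#' the radius (Neurolucida-style chord counting; a segment tangent to a
#' sphere without endpoint straddle is not counted). Radii run from one
#' increment up to the largest node distance. `flatten_z = TRUE` drops
#' the z coordinate first, reproducing a 2D projected analysis.
#'
#' @param m A [morphology()].
#' @param increment Shell spacing in um.
#' @param flatten_z Use 2D (projected) distances instead of 3D.
#' @return List with `radii` (um) and `intersections` (integer), class
#'   `"sholl_result"`.
#' @export
sholl_analysis <- function(m, increment = 20.6, flatten_z = FALSE) {
  stopifnot(inherits(m, "morphology"))
  seg <- dendrite_segments(m)
  ctr <- soma_center(m)
  if (flatten_z) {
    seg$z1 <- 0
    seg$z2 <- 0
    ctr["z"] <- 0
  }
  d1 <- sqrt((seg$x1 - ctr["x"])^2 + (seg$y1 - ctr["y"])^2 +
               (seg$z1 - ctr["z"])^2)
  d2 <- sqrt((seg$x2 - ctr["x"])^2 + (seg$y2 - ctr["y"])^2 +
               (seg$z2 - ctr["z"])^2)
  dmin <- pmin(d1, d2)
  dmax <- pmax(d1, d2)
  rmax <- max(dmax)
  radii <- increment * seq_len(max(1L, floor(rmax / increment)))
  counts <- vapply(radii, function(r) sum(dmin < r & dmax >= r),
                   numeric(1))
  structure(list(radii = radii, intersections = as.integer(counts)),
            class = "sholl_result")
}

#' Total dendritic length
#'
#' Sum of Euclidean parent-child distances over dendritic segments, um.
#'
#' @param m A [morphology()].
#' @export
total_dendritic_length <- function(m) {
  stopifnot(inherits(m, "morphology"))
  seg <- dendrite_segments(m)
  sum(sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
             (seg$z2 - seg$z1)^2))
}

#' Dendritic surface area (frustum model)
#'
#' Each dendritic segment is a conical frustum between its endpoint
#' radii; the lateral area is `pi * (r1 + r2) * slant` with
#' `slant = sqrt(L^2 + (r1 - r2)^2)`. A cylinder (equal radii) reduces
#' to `2*pi*r*L`. Soma surface, spines, and axons are excluded.
#'
#' @param m A [morphology()].
#' @return Surface area in um^2.
#' @export
dendritic_surface_area <- function(m) {
  stopifnot(inherits(m, "morphology"))
  seg <- dendrite_segments(m)
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
                (seg$z2 - seg$z1)^2)
  slant <- sqrt(len^2 + (seg$r1 - seg$r2)^2)
  sum(pi * (seg$r1 + seg$r2) * slant)
}

#' All morphometric measures for one reconstruction
#'
#' @param m A [morphology()].
#' @param sholl_increment Shell spacing in um.
#' @return List with `sholl`, `total_length_um`, `surface_area_um2`.
#' @export
morphometry_report <- function(m, sholl_increment = 20.6) {
  list(sholl = sholl_analysis(m, increment = sholl_increment),
       total_length_um = total_dendritic_length(m),
       surface_area_um2 = dendritic_surface_area(m))
}
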