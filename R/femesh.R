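#' Hexahedral mesh from a voxel model
#'
#' Converts a voxel model into a conforming mesh of identical cubic 8-node
#' hexahedra by direct voxel-to-element transformation: a cubic voxel maps
#' to one element, an elongated 36 x 36 x d voxel to d/h stacked cubic
#' elements. Shared nodes are merged exactly through integer lattice
#' addressing.
#'
#' @param model A [voxel_model()] whose voxel dimensions are integer
#'   multiples of `h` (in-plane sizes must equal `h`).
#' @param h Element edge length in micrometres; defaults to the model's
#'   in-plane voxel size.
#' @return An object of class `hex_mesh`: list with `nodes` (n x 3 matrix,
#'   um), `elems` (nel x 8 node indices), `h` (um), `elem_ijk` (element grid
#'   coordinates), `grid_dim`, `area_mm2` (nominal cross-section) and
#'   `height_um`.
#' @export
voxels_to_elements <- function(model, h = model$dx) {
  stopifnot(inherits(model, "voxel_model"))
  if (abs(model$dx - h) > 1e-9 || abs(model$dy - h) > 1e-9)
    stop("in-plane voxel size must equal the element size `h`", call. = FALSE)
  r <- model$dz / h
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("voxel length dz must be an integer multiple of `h`", call. = FALSE)
  r <- as.integer(round(r))
  occ <- model$occupancy
  d <- dim(occ)
  # replicate each voxel layer r times along the axis
  egrid <- occ[, , rep(seq_len(d[3]), each = r), drop = FALSE]
  gd <- dim(egrid)
  eidx <- which(egrid == 1L, arr.ind = TRUE)
  if (nrow(eidx) == 0L) stop("model contains no bone voxels", call. = FALSE)
  mesh_from_element_grid(eidx, gd, h,
                         area_mm2 = nominal_area_mm2(model),
                         provenance = model$provenance)
}

nominal_area_mm2 <- function(model) {
  d <- dim(model$occupancy)
  if (is.null(model$mask)) {
    d[1] * d[2] * model$dx * model$dy / 1e6
  } else {
    sum(model$mask) * model$dx * model$dy / 1e6
  }
}

# Build a hex_mesh from occupied element-grid cells (nel x 3, 1-based).
mesh_from_element_grid <- function(eidx, gd, h, area_mm2, provenance = NULL) {
  nd <- gd + 1L  # node lattice
  corner <- rbind(  # standard trilinear node ordering (counter-clockwise
    c(0L, 0L, 0L), # bottom face, then top face)
    c(1L, 0L, 0L),
    c(1L, 1L, 0L),
    c(0L, 1L, 0L),
    c(0L, 0L, 1L),
    c(1L, 0L, 1L),
    c(1L, 1L, 1L),
    c(0L, 1L, 1L))
  nel <- nrow(eidx)
  lat <- matrix(0L, nel, 8L)
  for (c8 in 1:8) {
    ix <- eidx[, 1] - 1L + corner[c8, 1]
    iy <- eidx[, 2] - 1L + corner[c8, 2]
    iz <- eidx[, 3] - 1L + corner[c8, 3]
    lat[, c8] <- 1L + ix + nd[1] * (iy + nd[2] * iz)
  }
  used <- sort(unique(as.vector(lat)))
  renum <- integer(nd[1] * nd[2] * nd[3])
  renum[used] <- seq_along(used)
  elems <- matrix(renum[lat], nel, 8L)
  u0 <- used - 1L
  ix <- u0 %% nd[1]
  iy <- (u0 %/% nd[1]) %% nd[2]
  iz <- u0 %/% (nd[1] * nd[2])
  nodes <- cbind(ix, iy, iz) * h
  structure(list(nodes = nodes, elems = elems, h = h,
                 elem_ijk = eidx, grid_dim = gd,
                 area_mm2 = area_mm2,
                 height_um = gd[3] * h,
                 provenance = provenance),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf(
    "<hex_mesh> %d elements (h = %g um), %d nodes | A = %.4g mm^2, H = %g um\n",
    nrow(x$elems), x$h, nrow(x$nodes), x$area_mm2, x$height_um))
  invisible(x)
}

#' Remove poorly connected elements
#'
#' Keeps only the largest face-connected component of the element adjacency
#' graph (ties broken in favour of the component containing the lowest
#' element index). Elements attached to the rest of the model solely through
#' shared edges or corners transmit no stiffness through conforming
#' hexahedra and destabilise the solve, so they are eliminated here.
#'
#' @param mesh A `hex_mesh`.
#' @return A filtered `hex_mesh` (nodes renumbered, provenance preserved).
#' @export
filter_connectivity <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nel <- nrow(mesh$elems)
  if (nel == 0L) stop("empty mesh", call. = FALSE)
  comp <- face_components(mesh$elem_ijk, mesh$grid_dim)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) best <- comp[which(comp %in% best)[1]]
  keep <- comp == best[1]
  if (all(keep)) return(mesh)
  mesh_from_element_grid(mesh$elem_ijk[keep, , drop = FALSE], mesh$grid_dim,
                         mesh$h, area_mm2 = mesh$area_mm2,
                         provenance = mesh$provenance)
}

# Face-connected component label per element (6-neighbourhood on the grid).
face_components <- function(eidx, gd) {
  nel <- nrow(eidx)
  cell <- 1L + (eidx[, 1] - 1L) + gd[1] * ((eidx[, 2] - 1L) +
                                             gd[2] * (eidx[, 3] - 1L))
  id_of <- integer(prod(gd))
  id_of[cell] <- seq_len(nel)
  edges <- list()
  step <- c(1L, gd[1], gd[1] * gd[2])
  for (ax in 1:3) {
    ok <- eidx[, ax] < gd[ax]
    nb <- cell[ok] + step[ax]
    nb_id <- id_of[nb]
    hit <- nb_id > 0L
    if (any(hit))
      edges[[ax]] <- cbind(which(ok)[hit], nb_id[hit])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0L) return(seq_len(nel))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nel - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nel)]
}

#' Export a mesh as plain text
#'
#' Writes a simple node/element block format (one header line, node lines
#' `id x y z` in micrometres, element lines `id n1..n8`) readable by generic
#' mesh tooling.
#'
#' @param mesh A `hex_mesh`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("hexmesh %d %d %g %.8g", nrow(mesh$nodes),
                     nrow(mesh$elems), mesh$h, mesh$area_mm2), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(paste(seq_len(nrow(mesh$elems)),
                   apply(mesh$elems, 1, paste, collapse = " ")), con)
  invisible(path)
}
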