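#' Discrete cuboid surface objects
#'
#' A cuboid of dimensions `Dx x Dy x Dz` (in unit cells) is represented by the
#' `2 * (Dx*Dy + Dy*Dz + Dx*Dz)` unit square cells tiling its surface.  Cells
#' are addressed either by a flat index `1..p` or by a `(face, x, y)` triple
#' with 1-based coordinates inside the face.  Faces are numbered in a fixed
#' order: 1 = top, 2 = front, 3 = bottom, 4 = back, 5 = left, 6 = right, each
#' carrying a local frame as seen from outside the object; the frames of the
#' top and bottom faces are chosen so that `(face 1, x = 1, y = 1)` and
#' `(face 3, x = 1, y = 2)` on the 2 x 2 x 2 cube sit diagonally opposite each
#' other, matching the start/goal geometry used in the navigation experiments.
#'
#' Two cells are adjacent when their unit squares share an edge segment in 3D,
#' which covers both same-face neighbours and neighbours across a cuboid edge.
#' Every cell therefore has exactly four neighbours and the adjacency graph is
#' connected.
#'
#' @param dims integer vector of length 3, the cuboid dimensions in unit
#'   cells; all entries must be >= 1.
#' @return An object of class `cuboid`: a list with elements `dims`, `p`
#'   (number of surface cells), `cells` (tibble with `cell`, `face`, `x`,
#'   `y`), `graph` (igraph adjacency), `landmarks` (integer vector, 0 where
#'   no landmark), and internal geometry tables used by the hand simulator.
#' @examples
#' cube <- build_cuboid(c(2, 2, 2))
#' cube$p  # 24 surface cells
#' @export
build_cuboid <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || anyNA(dims) || any(dims < 1)) {
    stop("`dims` must be three positive integers", call. = FALSE)
  }
  dx <- dims[1]; dy <- dims[2]; dz <- dims[3]

  # face frames: origin, in-face unit axes u (x direction) and v (y direction),
  # outward normal, and face width/height in cells
  frames <- list(
    list(o = c(0, 0, dz),  u = c(1, 0, 0),  v = c(0, 1, 0), nrm = c(0, 0, 1),  w = dx, h = dy),  # top
    list(o = c(0, 0, 0),   u = c(1, 0, 0),  v = c(0, 0, 1), nrm = c(0, -1, 0), w = dx, h = dz),  # front
    list(o = c(dx, 0, 0),  u = c(-1, 0, 0), v = c(0, 1, 0), nrm = c(0, 0, -1), w = dx, h = dy),  # bottom
    list(o = c(dx, dy, 0), u = c(-1, 0, 0), v = c(0, 0, 1), nrm = c(0, 1, 0),  w = dx, h = dz),  # back
    list(o = c(0, 0, 0),   u = c(0, 1, 0),  v = c(0, 0, 1), nrm = c(-1, 0, 0), w = dy, h = dz),  # left
    list(o = c(dx, dy, 0), u = c(0, -1, 0), v = c(0, 0, 1), nrm = c(1, 0, 0),  w = dy, h = dz)   # right
  )

  face <- integer(0); xx <- integer(0); yy <- integer(0)
  for (f in 1:6) {
    fr <- frames[[f]]
    g <- expand.grid(x = seq_len(fr$w), y = seq_len(fr$h))
    face <- c(face, rep.int(f, nrow(g)))
    xx <- c(xx, g$x); yy <- c(yy, g$y)
  }
  p <- length(face)
  stopifnot(p == 2L * (dx * dy + dy * dz + dx * dz))

  centers <- matrix(0, p, 3)
  normals <- matrix(0, p, 3)
  for (j in seq_len(p)) {
    fr <- frames[[face[j]]]
    centers[j, ] <- fr$o + (xx[j] - 0.5) * fr$u + (yy[j] - 0.5) * fr$v
    normals[j, ] <- fr$nrm
  }

  # adjacency via shared edge segments: the edge of cell j in tangent
  # direction d is the unit segment with midpoint center + d/2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pt_key <- function(pt) paste(round(pt * 2), collapse = ",")  # half-integer safe
  edge_key <- function(c1, c2) {
    k <- sort(c(pt_key(c1), pt_key(c2)))
    paste(k, collapse = "|")
  }
  edge_owner <- new.env(parent = emptyenv())
  cell_edge_keys <- matrix(NA_character_, p, 6)
  for (j in seq_len(p)) {
    nrm <- normals[j, ]
    for (d in 1:6) {
      dv <- dirs[d, ]
      if (sum(dv * nrm) != 0) next           # not tangent to this face
      ev <- c(nrm[2] * dv[3] - nrm[3] * dv[2],  # nrm x dv: along the edge
              nrm[3] * dv[1] - nrm[1] * dv[3],
              nrm[1] * dv[2] - nrm[2] * dv[1])
      mid <- centers[j, ] + 0.5 * dv
      k <- edge_key(mid + 0.5 * ev, mid - 0.5 * ev)
      cell_edge_keys[j, d] <- k
      edge_owner[[k]] <- c(edge_owner[[k]], j)
    }
  }

  nb_face <- matrix(NA_integer_, p, 6)   # same-face neighbour in 3D direction d
  nb_cross <- matrix(NA_integer_, p, 6)  # across-edge neighbour in direction d
  edges <- NULL
  for (j in seq_len(p)) {
    for (d in 1:6) {
      k <- cell_edge_keys[j, d]
      if (is.na(k)) next
      owners <- edge_owner[[k]]
      other <- owners[owners != j]
      if (length(other) != 1) {
        stop("surface edge not shared by exactly two cells; geometry bug")
      }
      if (face[other] == face[j]) nb_face[j, d] <- other else nb_cross[j, d] <- other
      if (other > j) edges <- rbind(edges, c(j, other))
    }
  }

  graph <- igraph::graph_from_edgelist(edges, directed = FALSE)

  structure(list(
    dims = dims,
    p = p,
    cells = tibble::tibble(cell = seq_len(p), face = face, x = xx, y = yy),
    face_dims = t(vapply(frames, function(fr) c(fr$w, fr$h), numeric(2))),
    centers = centers,
    normals = normals,
    dirs = dirs,
    face_u = t(vapply(frames, function(fr) fr$u, numeric(3))),
    face_v = t(vapply(frames, function(fr) fr$v, numeric(3))),
    nb_face = nb_face,
    nb_cross = nb_cross,
    graph = graph,
    landmarks = integer(p),
    n_landmarks = 0L
  ), class = "cuboid")
}

#' @export
print.cuboid <- function(x, ...) {
  cat(sprintf("<cuboid %s: %d surface cells, %d landmarks>\n",
              paste(x$dims, collapse = "x"), x$p, x$n_landmarks))
  invisible(x)
}

#' Flat cell index of a (face, x, y) triple
#'
#' @param obj a [build_cuboid()] object.
#' @param face face index 1-6.
#' @param x,y 1-based coordinates within the face.
#' @return integer cell index in `1..obj$p`.
#' @export
cell_index <- function(obj, face, x, y) {
  stopifnot(inherits(obj, "cuboid"))
  i <- which(obj$cells$face == face & obj$cells$x == x & obj$cells$y == y)
  if (length(i) != 1) stop("no such surface cell", call. = FALSE)
  i
}

#' Surface cells as a tibble
#'
#' @param obj a [build_cuboid()] object.
#' @return tibble with one row per cell: `cell`, `face`, `x`, `y`,
#'   `landmark` (0 when the cell carries none).
#' @export
surface_cells <- function(obj) {
  stopifnot(inherits(obj, "cuboid"))
  dplyr::mutate(obj$cells, landmark = obj$landmarks)
}

#' Scatter unique tactile landmarks over an object
#'
#' Chooses `count` distinct cells uniformly at random (without replacement)
#' and labels them `1..count`.  Each landmark is unique: it fires its own
#' Boolean percept bit and no two cells share a label.  The draw is
#' reproducible per `seed` and does not disturb the caller's RNG state.
#'
#' @param obj a [build_cuboid()] object.
#' @param count number of landmarks, `0 <= count <= obj$p`.
#' @param seed integer seed for the placement.
#' @return the object with `landmarks` and `n_landmarks` filled in.
#' @export
place_landmarks <- function(obj, count, seed) {
  stopifnot(inherits(obj, "cuboid"))
  count <- as.integer(count)
  if (count < 0 || count > obj$p) {
    stop("`count` must be between 0 and the number of surface cells", call. = FALSE)
  }
  lm <- integer(obj$p)
  if (count > 0) {
    cells <- with_preserved_rng(seed, sample.int(obj$p, count))
    lm[cells] <- seq_len(count)
  }
  obj$landmarks <- lm
  obj$n_landmarks <- count
  obj
}

#' Geodesic distance on the surface graph
#'
#' Shortest-path distance (Dijkstra, unit edge weights) between two cells in
#' the surface adjacency graph.
#'
#' @param obj a [build_cuboid()] object.
#' @param a,b cell indices.
#' @return non-negative integer distance.
#' @export
geodesic <- function(obj, a, b) {
  stopifnot(inherits(obj, "cuboid"))
  if (!all(c(a, b) %in% seq_len(obj$p))) stop("invalid cell index", call. = FALSE)
  as.numeric(igraph::distances(obj$graph, v = a, to = b, algorithm = "dijkstra"))
}

#' All-pairs geodesic distance matrix
#'
#' @param obj a [build_cuboid()] object.
#' @return `p x p` numeric matrix of shortest-path distances.
#' @export
geodesic_matrix <- function(obj) {
  stopifnot(inherits(obj, "cuboid"))
  igraph::distances(obj$graph, algorithm = "dijkstra")
}

# run expr with a given seed, restoring the caller's RNG state afterwards
with_preserved_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
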