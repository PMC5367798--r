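## The d-dimensional search space and its grid. Dimension order: 3 ligand
## translations spanning the docking cube, 3 rigid-rotation parameters
## (axis azimuth, cosine of axis polar angle, spin about the axis),
## torsions in ascending bond index, then moveable receptor atoms in
## ascending atom index times (x, y, z). Grid nodes sit at cell centers,
## x = a + (i - 0.5) * (b - a) / n for 1-based i, so no node lies on a box
## face and periodic dimensions cover [0, 2*pi) without duplicating the
## endpoint.

#' Build the search space for a system
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param m grid bits; every dimension gets n = 2^m nodes.
#' @param cubeCenter docking-cube center; default = the input ligand's
#'   geometric center.
#' @param cubeEdge docking-cube edge in Angstrom (default 10).
#' @param atomCubeEdge small-cube edge for moveable atoms (default 1, i.e.
#'   each coordinate within +/- 0.5 Angstrom of its input value).
#' @return A \linkS4class{SearchSpace} with
#'   d = 6 + #torsions + 3 * #moveable dimensions.
#' @examples
#' sys <- makeToyComplex()$system
#' buildSearchSpace(sys, m = 5)
#' @export
buildSearchSpace <- function(system, m, cubeCenter = NULL, cubeEdge = 10,
                             atomCubeEdge = 1) {
  n <- as.integer(2^m)
  lig <- ligandIndices(system)
  if (is.null(cubeCenter))
    cubeCenter <- colMeans(system@coords[lig, , drop = FALSE])
  rot <- data.frame(kind = "rotation",
                    lower = c(0, -1, 0), upper = c(2 * pi, 1, 2 * pi),
                    periodic = c(TRUE, FALSE, TRUE),
                    atom = NA_integer_, axis = NA_integer_,
                    bond = NA_integer_)
  trn <- data.frame(kind = "translation",
                    lower = cubeCenter - cubeEdge / 2,
                    upper = cubeCenter + cubeEdge / 2,
                    periodic = FALSE, atom = NA_integer_,
                    axis = 1:3, bond = NA_integer_)
  dims <- rbind(trn, rot)
  for (b in system@rotatableBonds)
    dims <- rbind(dims, data.frame(kind = "torsion", lower = 0,
                                   upper = 2 * pi, periodic = TRUE,
                                   atom = NA_integer_, axis = NA_integer_,
                                   bond = b))
  for (a in moveableIndices(system)) for (ax in 1:3)
    dims <- rbind(dims, data.frame(
      kind = "atom_coord",
      lower = system@coords[a, ax] - atomCubeEdge / 2,
      upper = system@coords[a, ax] + atomCubeEdge / 2,
      periodic = FALSE, atom = a, axis = ax, bond = NA_integer_))
  dims$n <- n
  rownames(dims) <- NULL
  sp <- new("SearchSpace", dims = dims, cubeCenter = as.numeric(cubeCenter),
            cubeEdge = cubeEdge, atomCubeEdge = atomCubeEdge,
            m = as.integer(m))
  attr(sp, "ligandFrame") <- ligandFrame(system)
  sp
}

## Precomputed ligand geometry shared by every decode call: local ligand
## coordinates about the geometric center and the torsion tree (root =
## largest rigid fragment, bonds in BFS root-to-leaf order, each with its
## moving atom set on the distal side).
ligandFrame <- function(system) {
  lig <- ligandIndices(system)
  coords <- system@coords[lig, , drop = FALSE]
  center <- colMeans(coords)
  rot <- system@rotatableBonds
  tree <- list()
  if (length(rot) > 0L) {
    g <- ligandGraph(system)
    gcut <- g
    for (r in rot)
      gcut <- igraph::delete_edges(
        gcut, igraph::get_edge_ids(gcut, c(system@bonds$i[r],
                                           system@bonds$j[r])))
    comp <- igraph::components(gcut)$membership
    fragOf <- comp[lig]
    sizes <- table(comp[lig])
    rootFrag <- as.integer(names(sizes)[order(-as.integer(sizes),
                                              as.integer(names(sizes)))][1L])
    ## BFS over the fragment tree from the root fragment
    fragEdges <- lapply(rot, function(r)
      c(comp[system@bonds$i[r]], comp[system@bonds$j[r]]))
    visited <- rootFrag
    remaining <- seq_along(rot)
    ordered <- integer(0)
    while (length(remaining) > 0L) {
      nxt <- remaining[vapply(remaining, function(q)
        any(fragEdges[[q]] %in% visited), logical(1))]
      if (length(nxt) == 0L) stop("internal error: disconnected torsion tree")
      nxt <- nxt[order(vapply(nxt, function(q)
        min(system@bonds$i[rot[q]], system@bonds$j[rot[q]]), integer(1)))]
      for (q in nxt) {
        visited <- unique(c(visited, fragEdges[[q]]))
        ordered <- c(ordered, q)
      }
      remaining <- setdiff(remaining, nxt)
    }
    g2 <- g
    for (q in ordered) {
      r <- rot[q]
      i <- system@bonds$i[r]; j <- system@bonds$j[r]
      sides <- splitAtBond(g, i, j)
      ## the distal side (away from the root fragment) moves
      rootAtoms <- lig[fragOf == rootFrag]
      distal <- if (any(rootAtoms %in% sides[[1L]])) 2L else 1L
      axisFrom <- if (distal == 2L) i else j
      axisTo <- if (distal == 2L) j else i
      moving <- setdiff(sides[[distal]], axisTo)
      tree[[length(tree) + 1L]] <-
        list(bond = r, axisFrom = match(axisFrom, lig),
             axisTo = match(axisTo, lig), moving = match(moving, lig))
    }
  }
  list(lig = lig, local = sweep(coords, 2L, center), center = center,
       tree = tree)
}

#' Map grid multi-index to continuous DOF values (cell centers)
#'
#' @param idx integer multi-index, 1-based.
#' @param space a \linkS4class{SearchSpace}.
#' @return Numeric d-vector of DOF values.
#' @export
gridToPoint <- function(idx, space) {
  d <- space@dims
  if (any(idx < 1L) || any(idx > d$n)) stop("grid index out of range")
  d$lower + (idx - 0.5) * (d$upper - d$lower) / d$n
}

#' Map continuous DOF values to the nearest grid node
#'
#' Inverse of [gridToPoint()] on nodes; ties on cell boundaries resolve to
#' the lower index. Periodic dimensions wrap first.
#'
#' @param point numeric d-vector.
#' @param space a \linkS4class{SearchSpace}.
#' @return Integer multi-index.
#' @export
pointToGrid <- function(point, space) {
  d <- space@dims
  x <- point
  per <- d$periodic
  x[per] <- d$lower[per] +
    (x[per] - d$lower[per]) %% (d$upper[per] - d$lower[per])
  i <- ceiling((x - d$lower) / (d$upper - d$lower) * d$n)
  as.integer(pmin(pmax(i, 1L), d$n))
}

#' Decode a search-space point into a full conformation
#'
#' Grid indices decode to cell centers; continuous points are used as is.
#' Ligand coordinates are built by applying torsions in root-to-leaf order
#' in the ligand's local frame, rotating the resulting conformer about its
#' geometric center, and translating that center to the decoded cube
#' position — so the ligand's geometric center always lies exactly at the
#' decoded translation, inside the docking cube. Moveable receptor atoms go
#' to their decoded absolute positions; all other receptor atoms keep their
#' input coordinates bit-exactly.
#'
#' @param x integer multi-index or numeric d-vector of DOF values.
#' @param space a \linkS4class{SearchSpace} built for \code{system}.
#' @param system the \linkS4class{MolecularSystem}.
#' @return A \linkS4class{Conformation} (energy unset).
#' @export
decodeConformation <- function(x, space, system) {
  point <- if (is.integer(x)) gridToPoint(x, space) else as.numeric(x)
  dm <- space@dims
  bad <- !dm$periodic & (point < dm$lower - 1e-9 | point > dm$upper + 1e-9)
  if (any(bad)) stop("DOF value out of bounds in dimension ",
                     paste(which(bad), collapse = ", "))
  Conformation(point, buildCoords(point, space, system))
}

buildCoords <- function(point, space, system) {
  fr <- attr(space, "ligandFrame")
  if (is.null(fr)) fr <- ligandFrame(system)
  ## torsions root-to-leaf, in the local frame
  loc <- fr$local
  nd <- 6L
  for (tw in fr$tree) {
    nd <- nd + 1L
    ang <- point[nd]
    if (ang != 0) {
      ax <- loc[tw$axisTo, ] - loc[tw$axisFrom, ]
      loc[tw$moving, ] <- rotateAbout(loc[tw$moving, , drop = FALSE],
                                      loc[tw$axisFrom, ], ax, ang)
    }
  }
  ## recenter the torsioned conformer, then rigid placement: its geometric
  ## center lands exactly on the decoded translation (inside the cube)
  loc <- sweep(loc, 2L, colMeans(loc))
  theta <- point[4L]; z <- min(1, max(-1, point[5L])); psi <- point[6L]
  sphi <- sqrt(1 - z^2)
  axis <- c(sphi * cos(theta), sphi * sin(theta), z)
  lc <- loc %*% t(rotationMatrixAxis(axis, psi))
  lc <- sweep(lc, 2L, point[1:3], `+`)
  coords <- system@coords
  coords[fr$lig, ] <- lc
  dm <- space@dims
  ac <- which(dm$kind == "atom_coord")
  if (length(ac) > 0L)
    coords[cbind(dm$atom[ac], dm$axis[ac])] <- point[ac]
  coords
}

#' Mark moveable receptor atoms by proximity to reference ligand poses
#'
#' A receptor atom is moveable when its distance to at least one atom of at
#' least one reference ligand pose is at most the moveable-layer thickness.
#'
#' @param system a \linkS4class{MolecularSystem} (or an n x 3 receptor
#'   coordinate matrix).
#' @param referencePoses list of ligand coordinate matrices (n_lig x 3).
#' @param mlt moveable-layer thickness in Angstrom (typically up to 3).
#' @return Sorted integer vector of receptor atom indices.
#' @export
markMoveableAtoms <- function(system, referencePoses, mlt) {
  if (mlt < 0) stop("mlt must be nonnegative")
  if (!is.list(referencePoses) || length(referencePoses) == 0L)
    stop("at least one reference ligand pose is required")
  rc <- if (is(system, "MolecularSystem"))
    system@coords[receptorIndices(system), , drop = FALSE] else as.matrix(system)
  hit <- rep(FALSE, nrow(rc))
  for (pose in referencePoses) {
    pose <- as.matrix(pose)
    d2 <- outer(rowSums(rc^2), rowSums(pose^2), `+`) -
      2 * rc %*% t(pose)
    hit <- hit | apply(d2, 1L, min) <= mlt^2 + 1e-12
  }
  which(hit)
}

#' Flag a set of receptor atoms as moveable
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param indices receptor atom indices to confine to small cubes.
#' @return The updated system.
#' @export
setMoveable <- function(system, indices) {
  if (any(system@atoms$owner[indices] != "receptor"))
    stop("only receptor atoms can be moveable")
  system@atoms$moveable <- FALSE
  system@atoms$moveable[indices] <- TRUE
  system
}
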