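# Minimal closed-triangle-mesh machinery.
#
# The bone solids used here are simplified parametric extrusions, so the
# package carries its own small mesh kernel instead of a general-purpose
# geometry library: indexed triangle soup with consistent outward winding,
# signed-volume and watertightness checks, plane clipping with planar caps,
# and STL/PLY export.

#' Construct a triangle mesh
#'
#' @param vertices N x 3 numeric matrix (mm)
#' @param faces M x 3 integer matrix of 1-based vertex indices, counter-
#'   clockwise when seen from outside.
#' @return object of class `hto_mesh`
#' @export
hto_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, all(is.finite(vertices)),
            all(faces >= 1L), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "hto_mesh")
}

#' @export
print.hto_mesh <- function(x, ...) {
  cat("<hto_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

#' Signed volume enclosed by a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-wound closed surfaces. Multi-shell meshes sum over shells.
#'
#' @param mesh `hto_mesh`
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
      a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Watertightness check
#'
#' A mesh is watertight when every directed edge is matched by exactly one
#' opposite directed edge (each undirected edge borders exactly two faces
#' with consistent orientation).
#'
#' @param mesh `hto_mesh`
#' @return logical
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # orientation consistency: each undirected edge appears once per direction
  dirkey <- paste(e[, 1L], e[, 2L])
  !any(duplicated(dirkey))
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh `hto_mesh`
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  used <- sort(unique(as.vector(f)))
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  length(used) - length(key) + nrow(f)
}

#' Mirror a mesh in the sagittal (x = 0) plane
#'
#' Vertex x-coordinates are negated and face winding is reversed so the
#' surface stays outward-oriented.
#'
#' @param mesh `hto_mesh`
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  hto_mesh(v, mesh$faces[, c(1L, 3L, 2L)])
}

#' Transform a mesh by a rigid motion
#' @param mesh `hto_mesh`
#' @param tf `hto_rigid`
#' @export
transform_mesh <- function(mesh, tf) {
  hto_mesh(apply_rigid(tf, mesh$vertices), mesh$faces)
}

#' Concatenate meshes into a single (possibly multi-shell) mesh
#' @param ... `hto_mesh` objects
#' @keywords internal
mesh_concat <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  off <- 0L
  vs <- list(); fs <- list()
  for (m in parts) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  hto_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Clip a closed mesh by a plane, keeping one side, and cap the opening
#'
#' Triangles are split along the plane; the boundary polyline(s) of the cut
#' are triangulated by a fan around the loop centroid (cut cross-sections of
#' the parametric bone solids are star-shaped, so the fan is valid). The
#' result is again a closed, outward-oriented mesh. Returns `NULL` when
#' nothing of the mesh lies on the kept side.
#'
#' @param mesh closed `hto_mesh`
#' @param point a point on the clipping plane
#' @param normal plane normal; the side with `dot(p - point, normal) >= 0`
#'   is kept.
#' @param tol distance below which a vertex counts as lying on the plane
#' @return `hto_mesh` or `NULL`
#' @export
clip_mesh <- function(mesh, point, normal, tol = 1e-9) {
  n <- unitv(normal)
  v <- mesh$vertices
  # nudge the plane off any coincident vertices: exact vertex-on-plane
  # configurations are combinatorially fragile, and a sub-micrometre shift
  # is far below every geometric tolerance used downstream
  d <- plane_signed_distance(v, point, n)
  shift <- 0
  while (any(abs(d - shift) < 1e-7) && shift < 1e-4) {
    shift <- shift + 3.7e-7
  }
  d <- d - shift
  if (all(d <= 0)) return(NULL)
  if (all(d >= 0)) return(mesh)

  f <- mesh$faces
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  nv <- length(verts)
  dd <- d
  new_faces <- list()
  cut_edges <- list()  # each: c(index_a, index_b) directed along kept boundary

  # cache of interpolated vertices per undirected original edge
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  interp <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t_ <- dd[i] / (dd[i] - dd[j])
    p <- verts[[i]] + t_ * (verts[[j]] - verts[[i]])
    nv <<- nv + 1L
    verts[[nv]] <<- p
    dd[nv] <<- 0
    edge_cache[[key]] <- nv
    nv
  }

  for (k in seq_len(nrow(f))) {
    idx <- f[k, ]
    dk <- d[idx]
    if (all(dk >= 0)) {            # fully kept
      new_faces[[length(new_faces) + 1L]] <- idx
      if (sum(dk == 0) == 2L) {    # an edge in the plane bounds the cap
        for (r in 0:2) {
          a <- idx[r + 1L]; b <- idx[(r + 1L) %% 3L + 1L]
          if (d[a] == 0 && d[b] == 0) {
            cut_edges[[length(cut_edges) + 1L]] <- c(a, b)
          }
        }
      }
      next
    }
    if (all(dk <= 0)) next         # fully discarded
    # rotate so the classification pattern is canonical
    for (r in 0:2) {
      ii <- idx[((0:2 + r) %% 3L) + 1L]
      dv <- d[ii]
      if (dv[1L] >= 0 && dv[2L] < 0 && dv[3L] < 0) {
        # one kept vertex
        a <- interp(ii[1L], ii[2L]); b <- interp(ii[1L], ii[3L])
        new_faces[[length(new_faces) + 1L]] <- c(ii[1L], a, b)
        cut_edges[[length(cut_edges) + 1L]] <- c(a, b)
        break
      }
      if (dv[1L] >= 0 && dv[2L] >= 0 && dv[3L] < 0) {
        # two kept vertices
        a <- interp(ii[2L], ii[3L]); b <- interp(ii[1L], ii[3L])
        new_faces[[length(new_faces) + 1L]] <- c(ii[1L], ii[2L], a)
        new_faces[[length(new_faces) + 1L]] <- c(ii[1L], a, b)
        cut_edges[[length(cut_edges) + 1L]] <- c(a, b)
        break
      }
      # patterns with d == 0 vertices on the plane
      if (dv[1L] == 0 && dv[2L] >= 0 && dv[3L] >= 0) {
        new_faces[[length(new_faces) + 1L]] <- ii
        # edges lying exactly in the plane still bound the cap
        if (dv[2L] == 0) cut_edges[[length(cut_edges) + 1L]] <- c(ii[1L], ii[2L])
        if (dv[3L] == 0) cut_edges[[length(cut_edges) + 1L]] <- c(ii[3L], ii[1L])
        break
      }
      if (dv[1L] == 0 && dv[2L] > 0 && dv[3L] < 0) {
        a <- interp(ii[2L], ii[3L])
        new_faces[[length(new_faces) + 1L]] <- c(ii[1L], ii[2L], a)
        cut_edges[[length(cut_edges) + 1L]] <- c(a, ii[1L])
        break
      }
      if (dv[1L] == 0 && dv[2L] < 0 && dv[3L] > 0) {
        a <- interp(ii[3L], ii[2L])
        new_faces[[length(new_faces) + 1L]] <- c(ii[1L], a, ii[3L])
        cut_edges[[length(cut_edges) + 1L]] <- c(ii[1L], a)
        break
      }
      if (dv[1L] == 0 && dv[2L] == 0 && dv[3L] > 0) {
        new_faces[[length(new_faces) + 1L]] <- ii
        break
      }
      if (dv[1L] == 0 && dv[2L] == 0 && dv[3L] < 0) {
        break  # degenerate sliver on the plane, dropped
      }
      if (r == 2L) stop("unclassifiable triangle in clip_mesh")
    }
  }

  if (length(new_faces) == 0L) return(NULL)
  vmat <- do.call(rbind, verts)

  # assemble cut boundary loops and cap them
  cap_faces <- list()
  if (length(cut_edges) > 0L) {
    em <- do.call(rbind, cut_edges)
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(em))) nxt[[as.character(em[i, 1L])]] <- em[i, 2L]
    visited <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(em))) {
      s <- em[i, 1L]
      if (!is.null(visited[[as.character(s)]])) next
      loop <- integer(0)
      cur <- s
      repeat {
        if (!is.null(visited[[as.character(cur)]])) break
        visited[[as.character(cur)]] <- TRUE
        loop <- c(loop, cur)
        cur <- nxt[[as.character(cur)]]
        if (is.null(cur)) break
        if (cur == s) break
      }
      if (length(loop) >= 3L && !is.null(cur) && cur == s) {
        centroid <- colMeans(vmat[loop, , drop = FALSE])
        vmat <- rbind(vmat, centroid)
        ci <- nrow(vmat)
        # cut edges are wound so that (a -> b -> centroid) faces outward
        # on the kept side (cap normal opposite the kept normal direction)
        for (j in seq_along(loop)) {
          a <- loop[j]
          b <- loop[if (j == length(loop)) 1L else j + 1L]
          cap_faces[[length(cap_faces) + 1L]] <- c(b, a, ci)
        }
      }
    }
  }

  fmat <- do.call(rbind, c(new_faces, cap_faces))
  # drop unreferenced vertices, remap indices
  used <- sort(unique(as.vector(fmat)))
  remap <- integer(nrow(vmat))
  remap[used] <- seq_along(used)
  hto_mesh(vmat[used, , drop = FALSE],
           matrix(remap[fmat], ncol = 3L))
}

#' Mediolateral extent of a mesh in a thin axial slab
#'
#' Measures the x-range of all vertices with |z - level| <= half_width; used
#' to check the generated plateau width.
#'
#' @param mesh `hto_mesh`
#' @param level z level (mm)
#' @param half_width slab half-thickness (mm)
#' @export
mesh_ml_extent_at <- function(mesh, level, half_width = 1.0) {
  sel <- abs(mesh$vertices[, 3L] - level) <= half_width
  if (!any(sel)) stop("no vertices in slab at z = ", level)
  diff(range(mesh$vertices[sel, 1L]))
}

# -- STL / PLY export ---------------------------------------------------------

#' Write a mesh as STL
#'
#' @param mesh `hto_mesh`
#' @param path output path
#' @param binary write binary STL (default) or ASCII
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    lines <- c("solid htosim")
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g", a[i, 1L], a[i, 2L], a[i, 3L]),
                 sprintf("    vertex %.9g %.9g %.9g", b[i, 1L], b[i, 2L], b[i, 3L]),
                 sprintf("    vertex %.9g %.9g %.9g", c_[i, 1L], c_[i, 2L], c_[i, 3L]),
                 "  endloop",
                 "endfacet")
    }
    writeLines(c(lines, "endsolid htosim"), path)
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @param mesh `hto_mesh`
#' @param path output path
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0", "comment htosim",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  body_v <- sprintf("%.12g %.12g %.12g", v[, 1L], v[, 2L], v[, 3L])
  body_f <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(header, body_v, body_f), path)
  invisible(path)
}

#' Read an ASCII PLY file written by [write_ply()]
#' @param path file path
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vlines <- lines[(end + 1L):(end + nv)]
  flines <- lines[(end + nv + 1L):(end + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(vlines, " "), as.numeric))
  f <- do.call(rbind, lapply(strsplit(flines, " "), function(x) as.integer(x[2:4]) + 1L))
  hto_mesh(v, f)
}
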