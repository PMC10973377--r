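# Collective variables: distances, angles, dihedrals, differences of
# distances, and frame-fixed coordinate projections, with analytic gradients
# so instantaneous rates of change are exact (grad(CV) . v).

.cv_kinds <- c(distance = 2L, angle = 3L, dihedral = 4L,
               difference_of_distances = 4L, coordinate_projection = 1L)

#' Define a collective variable
#'
#' @param kind one of `"distance"`, `"angle"`, `"dihedral"`,
#'   `"difference_of_distances"` (d(i,j) - d(k,l)), or
#'   `"coordinate_projection"` (one flat coordinate; frame-fixed)
#' @param atom_indices particle indices: 2 for distance, 3 for angle
#'   (vertex second), 4 for dihedral and for difference_of_distances; a
#'   single flat coordinate index for coordinate_projection
#' @param cv_id stable identifier (auto-generated if omitted)
#' @param units unit label (informational)
#' @return a `cv_def`
#' @export
cv_def <- function(kind, atom_indices, cv_id = NULL, units = NULL) {
  kind <- match.arg(kind, names(.cv_kinds))
  atom_indices <- as.integer(atom_indices)
  if (length(atom_indices) != .cv_kinds[[kind]]) {
    stop_config("kind '%s' needs %d indices, got %d", kind,
                .cv_kinds[[kind]], length(atom_indices))
  }
  if (any(atom_indices < 1L)) stop_config("atom indices must be >= 1")
  if (kind %in% c("distance", "angle", "dihedral") &&
      anyDuplicated(atom_indices)) {
    stop_config("kind '%s' requires distinct atom indices", kind)
  }
  if (is.null(cv_id)) {
    prefix <- c(distance = "d", angle = "a", dihedral = "t",
                difference_of_distances = "dd", coordinate_projection = "x")[[kind]]
    cv_id <- paste(c(prefix, atom_indices), collapse = "_")
  }
  if (is.null(units)) {
    units <- if (kind %in% c("angle", "dihedral")) "rad" else "length"
  }
  structure(list(cv_id = cv_id, kind = kind, atom_indices = atom_indices,
                 units = units), class = "cv_def")
}

#' @export
print.cv_def <- function(x, ...) {
  cat(sprintf("<cv '%s': %s(%s) [%s]>\n", x$cv_id, x$kind,
              paste(x$atom_indices, collapse = ","), x$units))
  invisible(x)
}

# particle p -> flat coordinate indices
coord_idx <- function(p, dim) ((p - 1L) * dim + 1L):(p * dim)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pad3 <- function(p) c(p, rep(0, 3 - length(p)))

#' Evaluate a collective variable on a frame
#'
#' Distances are non-negative; angles lie in `[0, pi]`; dihedrals follow the
#' IUPAC right-handed convention with trans = pi, in `(-pi, pi]`.
#' Degenerate geometries (coincident points, collinear angle arms of a
#' dihedral) raise an error rather than returning a silent 0.
#'
#' @param cv a [cv_def()]
#' @param frm a [frame()] (or flat position vector)
#' @param dim spatial dimension of the system (default 3; ignored for
#'   coordinate projections)
#' @return scalar CV value
#' @export
evaluate_cv <- function(cv, frm, dim = 3L) {
  x <- if (inherits(frm, "frame")) frm$x else as.numeric(frm)
  pt <- function(p) x[coord_idx(p, dim)]
  ai <- cv$atom_indices
  switch(cv$kind,
    coordinate_projection = {
      if (ai[1] > length(x)) stop_config("coordinate index %d out of range", ai[1])
      x[ai[1]]
    },
    distance = sqrt(sum((pt(ai[1]) - pt(ai[2]))^2)),
    difference_of_distances =
      sqrt(sum((pt(ai[1]) - pt(ai[2]))^2)) - sqrt(sum((pt(ai[3]) - pt(ai[4]))^2)),
    angle = {
      u <- pt(ai[1]) - pt(ai[2])
      v <- pt(ai[3]) - pt(ai[2])
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu < 1e-10 || nv < 1e-10) {
        stop_config("degenerate geometry: coincident points in angle '%s'", cv$cv_id)
      }
      u3 <- pad3(u / nu); v3 <- pad3(v / nv)
      atan2(sqrt(sum(cross3(u3, v3)^2)), sum(u3 * v3))
    },
    dihedral = {
      if (dim != 3L) stop_config("dihedrals require dim = 3")
      b1 <- pt(ai[2]) - pt(ai[1])
      b2 <- pt(ai[3]) - pt(ai[2])
      b3 <- pt(ai[4]) - pt(ai[3])
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      nb2 <- sqrt(sum(b2^2))
      if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10 || nb2 < 1e-10) {
        stop_config("degenerate geometry: collinear points in dihedral '%s'", cv$cv_id)
      }
      phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
      if (phi <= -pi + 1e-14) pi else phi
    }
  )
}

# Analytic gradient of a CV w.r.t. the flat coordinate vector.
cv_gradient <- function(cv, x, dim = 3L) {
  g <- numeric(length(x))
  pt <- function(p) x[coord_idx(p, dim)]
  ai <- cv$atom_indices
  dist_grad <- function(i, j) {
    r <- pt(i) - pt(j)
    nr <- sqrt(sum(r^2))
    if (nr < 1e-10) stop_config("degenerate geometry: coincident points in '%s'", cv$cv_id)
    list(i = r / nr, j = -r / nr)
  }
  switch(cv$kind,
    coordinate_projection = { g[ai[1]] <- 1 },
    distance = {
      gr <- dist_grad(ai[1], ai[2])
      g[coord_idx(ai[1], dim)] <- gr$i
      g[coord_idx(ai[2], dim)] <- gr$j
    },
    difference_of_distances = {
      g1 <- dist_grad(ai[1], ai[2])
      g2 <- dist_grad(ai[3], ai[4])
      g[coord_idx(ai[1], dim)] <- g[coord_idx(ai[1], dim)] + g1$i
      g[coord_idx(ai[2], dim)] <- g[coord_idx(ai[2], dim)] + g1$j
      g[coord_idx(ai[3], dim)] <- g[coord_idx(ai[3], dim)] - g2$i
      g[coord_idx(ai[4], dim)] <- g[coord_idx(ai[4], dim)] - g2$j
    },
    angle = {
      u <- pt(ai[1]) - pt(ai[2])
      v <- pt(ai[3]) - pt(ai[2])
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu < 1e-10 || nv < 1e-10) {
        stop_config("degenerate geometry: coincident points in angle '%s'", cv$cv_id)
      }
      uh <- u / nu; vh <- v / nv
      ct <- sum(uh * vh)
      st <- sqrt(max(1 - ct^2, 0))
      if (st < 1e-8) {
        stop_config("degenerate geometry: collinear angle '%s'", cv$cv_id)
      }
      g1 <- (ct * uh - vh) / (nu * st)
      g3 <- (ct * vh - uh) / (nv * st)
      g[coord_idx(ai[1], dim)] <- g1
      g[coord_idx(ai[3], dim)] <- g3
      g[coord_idx(ai[2], dim)] <- -(g1 + g3)
    },
    dihedral = {
      if (dim != 3L) stop_config("dihedrals require dim = 3")
      b1 <- pt(ai[2]) - pt(ai[1])
      b2 <- pt(ai[3]) - pt(ai[2])
      b3 <- pt(ai[4]) - pt(ai[3])
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      n1sq <- sum(n1^2); n2sq <- sum(n2^2)
      nb2 <- sqrt(sum(b2^2))
      if (n1sq < 1e-20 || n2sq < 1e-20 || nb2 < 1e-10) {
        stop_config("degenerate geometry: collinear points in dihedral '%s'", cv$cv_id)
      }
      gA <- -nb2 / n1sq * n1
      gD <- nb2 / n2sq * n2
      s12 <- sum(b1 * b2) / nb2^2
      s32 <- sum(b3 * b2) / nb2^2
      gB <- -gA - s12 * gA + s32 * gD
      gC <- -gD + s12 * gA - s32 * gD
      g[coord_idx(ai[1], dim)] <- gA
      g[coord_idx(ai[2], dim)] <- gB
      g[coord_idx(ai[3], dim)] <- gC
      g[coord_idx(ai[4], dim)] <- gD
    }
  )
  g
}

#' Instantaneous rate of change of a CV
#'
#' Computed analytically by the chain rule, `grad(CV)(x) . v`, rather than
#' from a two-frame difference.
#'
#' @inheritParams evaluate_cv
#' @return scalar d(CV)/dt
#' @export
cv_rate <- function(cv, frm, dim = 3L) {
  if (is.null(frm$v)) stop_config("frame carries no velocities")
  sum(cv_gradient(cv, frm$x, dim) * frm$v)
}

#' Evaluate a CV over every frame of a position matrix (vectorized)
#'
#' @param cv a [cv_def()]
#' @param pos matrix of flat coordinate vectors, frames in rows
#' @param dim spatial dimension
#' @return numeric vector, one value per frame
#' @export
evaluate_cv_traj <- function(cv, pos, dim = 3L) {
  ai <- cv$atom_indices
  cols <- function(p) pos[, coord_idx(p, dim), drop = FALSE]
  dist2 <- function(i, j) {
    d <- cols(i) - cols(j)
    sqrt(rowSums(d * d))
  }
  switch(cv$kind,
    coordinate_projection = pos[, ai[1]],
    distance = dist2(ai[1], ai[2]),
    difference_of_distances = dist2(ai[1], ai[2]) - dist2(ai[3], ai[4]),
    # angles/dihedrals fall back to the per-frame path
    vapply(seq_len(nrow(pos)), function(i) evaluate_cv(cv, pos[i, ], dim),
           numeric(1))
  )
}

# Values and rates of a list of CVs at one frame -> named vectors.
cv_vector <- function(cvs, frm, dim) {
  ids <- vapply(cvs, `[[`, "", "cv_id")
  vals <- vapply(cvs, evaluate_cv, numeric(1), frm = frm, dim = dim)
  rates <- if (is.null(frm$v)) rep(NA_real_, length(cvs))
           else vapply(cvs, cv_rate, numeric(1), frm = frm, dim = dim)
  list(values = setNames(vals, ids), rates = setNames(rates, ids))
}

#' Enumerate candidate CVs around a set of reactive atoms
#'
#' Mirrors automated CV screening: atoms within `cutoff` of any reactive
#' atom participate; the catalogue contains all pairwise distances among
#' participating atoms, one angle per index-ordered triple (vertex = middle
#' index) and one dihedral per index-ordered quadruple of participating
#' atoms (both subject to caps, since the combinatorics explode), plus all
#' differences of distances between reactive-atom pairs.  Ordering is
#' deterministic.
#'
#' @param positions reference geometry: matrix (`n` x `dim`) or flat vector
#' @param reactive_atoms indices of the reactive atoms (non-empty)
#' @param cutoff inclusion radius around each reactive atom (`0` keeps only
#'   the reactive atoms themselves)
#' @param dim spatial dimension
#' @param max_angles,max_dihedrals caps on the angle/dihedral catalogue
#' @return list of [cv_def()]s
#' @export
enumerate_cvs <- function(positions, reactive_atoms, cutoff, dim = 3L,
                          max_angles = 500L, max_dihedrals = 500L) {
  if (length(reactive_atoms) == 0L) stop_config("reactive_atoms must be non-empty")
  x <- as.numeric(positions)
  n <- length(x) %/% dim
  pt <- function(p) x[coord_idx(p, dim)]
  reactive_atoms <- sort(unique(as.integer(reactive_atoms)))
  if (any(reactive_atoms > n)) stop_config("reactive atom index out of range")
  in_cut <- sort(unique(c(reactive_atoms, Filter(function(a) {
    any(vapply(reactive_atoms, function(r) sqrt(sum((pt(a) - pt(r))^2)) <= cutoff,
               logical(1)))
  }, seq_len(n)))))
  if (length(in_cut) == 0L) stop_config("no atoms inside the cutoff")
  cvs <- list()
  m <- length(in_cut)
  if (m >= 2L) {
    prs <- combn(in_cut, 2L)
    for (i in seq_len(ncol(prs))) cvs <- c(cvs, list(cv_def("distance", prs[, i])))
  }
  if (m >= 3L) {
    tri <- combn(in_cut, 3L)
    for (i in seq_len(min(ncol(tri), max_angles))) {
      t <- tri[, i] # sorted; vertex = middle index by convention
      cvs <- c(cvs, list(cv_def("angle", c(t[1], t[2], t[3]))))
    }
  }
  if (m >= 4L && dim == 3L) {
    quad <- combn(in_cut, 4L)
    for (i in seq_len(min(ncol(quad), max_dihedrals))) {
      cvs <- c(cvs, list(cv_def("dihedral", quad[, i])))
    }
  }
  if (length(reactive_atoms) >= 2L) {
    rp <- combn(reactive_atoms, 2L)
    if (ncol(rp) >= 2L) {
      dd <- combn(seq_len(ncol(rp)), 2L)
      for (i in seq_len(ncol(dd))) {
        cvs <- c(cvs, list(cv_def("difference_of_distances",
                                  c(rp[, dd[1, i]], rp[, dd[2, i]]))))
      }
    }
  }
  cvs
}

#' Serialize a CV catalogue to JSON
#' @param cvs list of [cv_def()]s
#' @param path output file (or `NULL` to return the JSON string)
#' @export
write_cv_catalogue <- function(cvs, path = NULL) {
  js <- jsonlite::toJSON(lapply(cvs, unclass), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a CV catalogue from JSON
#' @param path file written by [write_cv_catalogue()]
#' @return list of [cv_def()]s
#' @export
read_cv_catalogue <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) cv_def(r$kind, unlist(r$atom_indices), r$cv_id, r$units))
}
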