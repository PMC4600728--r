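# Rigid-body superposition: Kabsch fit of instantaneous coordinates onto
# reference coordinates, and extraction of per-molecule rotation series.

#' Least-squares rigid-body rotation fit (Kabsch)
#'
#' Finds the proper rotation R minimizing the RMSD between `R %*% (reference -
#' centroid)` and `mobile - centroid` over a selected atom subset, i.e. the
#' rotation carrying the reference into the instantaneous (mobile)
#' orientation. Reflection-optimal cases are resolved to a proper rotation
#' (determinant forced to +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, matched row for row.
#' @param selection Optional integer/logical row selection applied to both.
#' @return List with `rotation` (3x3, maps centered reference to centered
#'   mobile), `rmsd` (Angstrom, over the selection after fitting).
#' @export
fit_rotation <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (!is.null(selection)) {
    mobile <- mobile[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(mobile) < 3) {
    stop("rotation fit needs >= 3 selected atoms", call. = FALSE)
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); Rf <- sweep(reference, 2, rc)
  sv_ref <- svd(Rf)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    stop("degenerate rotation fit: selected reference atoms are collinear",
         call. = FALSE)
  }
  # R minimizing ||R Rf' - M'||: H = t(Rf) %*% M, svd H = U D V', R = V W U'
  H <- crossprod(Rf, M)
  s <- svd(H)
  dsign <- sign(det(s$v %*% t(s$u)))
  W <- diag(c(1, 1, dsign))
  R <- s$v %*% W %*% t(s$u)
  fitted <- Rf %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - M)^2)))
  list(rotation = R, rmsd = rmsd)
}

#' Per-molecule rotation-matrix series from a trajectory
#'
#' For every molecule and frame, the molecule's coordinates are mapped back
#' into the template frame using the stored lattice transform (when present)
#' and the small-angle rotation connecting the instantaneous coordinates to
#' the reference coordinates is obtained by a Kabsch fit of the selected atoms
#' (by default the Calpha set, mirroring a secondary-structure Calpha
#' selection). The returned matrices carry the rocking signal of each
#' molecule: they map reference orientation to instantaneous orientation.
#'
#' @param traj A `"rock_trajectory"`.
#' @param reference Optional `"crystal_frame"` supplying reference coordinates
#'   and back-transforms; defaults to the transforms stored on the trajectory
#'   and the first-frame coordinates mapped to the template frame. If the
#'   trajectory carries no transforms, each molecule's first frame is its own
#'   reference.
#' @param selection Atom selection: integer/logical index into the atom table,
#'   or a character atom name (default `"CA"`).
#' @param residues Optional residue-range restriction of the selection
#'   (e.g. a secondary-structure residue set).
#' @return List of `"rotation_series"` objects (class
#'   `"rotation_series_set"`), one per molecule, each with per-frame fit RMSD.
#' @export
rotation_series <- function(traj, reference = NULL, selection = "CA",
                            residues = NULL) {
  stopifnot(inherits(traj, "rock_trajectory"))
  d <- dim(traj$coords)
  sel <- if (is.character(selection)) {
    which(traj$atoms$atom %in% selection)
  } else if (is.logical(selection)) which(selection) else as.integer(selection)
  if (!is.null(residues)) {
    sel <- sel[traj$atoms$residue[sel] %in% residues]
  }
  if (length(sel) < 3) stop("selection must keep >= 3 atoms", call. = FALSE)

  out <- vector("list", d[3])
  for (m in seq_len(d[3])) {
    if (!is.null(reference)) {
      # map the molecule into the template frame via its stored symmetry
      # transform, so all copies are fitted against common reference
      # coordinates
      stopifnot(inherits(reference, "crystal_frame"))
      tr <- reference$transforms[[m]]
      Rinv <- t(tr$R)
      ref_m <- t(Rinv %*% (t(reference$coords[sel, , m]) - tr$t))
      back <- function(X) t(Rinv %*% (t(X) - tr$t))
    } else {
      # first frame of each molecule as its own reference, in the lab frame;
      # isotropic rocking correlation functions are invariant to this choice
      ref_m <- traj$coords[sel, , m, 1]
      back <- identity
    }
    mats <- array(NA_real_, c(3, 3, d[4]))
    rmsd <- numeric(d[4])
    for (f in seq_len(d[4])) {
      X <- traj$coords[sel, , m, f]
      if (anyNA(X)) {
        stop("missing coordinates for molecule ", m, " in frame ", f,
             call. = FALSE)
      }
      fit <- fit_rotation(back(X), ref_m)
      mats[, , f] <- fit$rotation
      rmsd[f] <- fit$rmsd
    }
    out[[m]] <- structure(
      list(matrices = mats, time_step = traj$time_step, molecule_id = m,
           fit_rmsd = rmsd, process = NULL),
      class = "rotation_series")
  }
  structure(out, class = "rotation_series_set")
}

#' @export
print.rotation_series_set <- function(x, ...) {
  cat("<rotation_series_set> ", length(x), " molecules x ",
      dim(x[[1]]$matrices)[3], " frames\n", sep = "")
  invisible(x)
}
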