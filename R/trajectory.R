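# Trajectory container and assembly: lattice frame + per-molecule rocking
# rotations about the Calpha centroid + amide-H internal cone motion.

#' Internal-motion specification (amide NH cone wobble)
#'
#' Jump-refresh diffusion-in-a-cone stand-in for fast internal dynamics: at
#' rate `1/internal_correlation_time` the NH unit vector is redrawn uniformly
#' within a cone of the given semi-angle about its reference direction. The
#' stationary distribution is exactly uniform in the cone, so the order
#' parameter equals the diffusion-in-a-cone closed form
#' \eqn{S^2 = [\cos\theta_0 (1 + \cos\theta_0)/2]^2}, and the memory is exactly
#' exponential with the stated correlation time. Only amide H positions move
#' (N stays fixed), so Calpha-based rigid-body fitting is unaffected.
#'
#' @param cone_semiangle Cone semi-angle in degrees (0 = rigid NH).
#' @param internal_correlation_time Refresh correlation time in seconds.
#' @return Object of class `"internal_motion"`.
#' @export
internal_motion <- function(cone_semiangle = 0,
                            internal_correlation_time = 1e-9) {
  stopifnot(cone_semiangle >= 0, cone_semiangle < 90,
            internal_correlation_time > 0)
  structure(list(cone_semiangle = cone_semiangle,
                 internal_correlation_time = internal_correlation_time),
            class = "internal_motion")
}

#' Diffusion-in-a-cone order parameter (closed form)
#'
#' \eqn{S^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2} for uniform disorder within
#' a cone of semi-angle theta0.
#'
#' @param semiangle_deg Cone semi-angle, degrees.
#' @return Order parameter.
#' @export
cone_s2 <- function(semiangle_deg) {
  ct <- cos(semiangle_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}

# draw n unit vectors uniformly within a cone of semi-angle theta0 about +z,
# then rotate so the cone axis is `axis`
runif_cone <- function(n, theta0, axis = c(0, 0, 1)) {
  ct <- 1 - stats::runif(n) * (1 - cos(theta0))
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- stats::runif(n, 0, 2 * pi)
  v <- cbind(st * cos(ph), st * sin(ph), ct)
  z <- c(0, 0, 1)
  ax <- pracma::cross(z, axis)
  na <- sqrt(sum(ax^2))
  if (na < 1e-12) {
    if (sum(z * axis) > 0) return(v)
    return(v %*% diag(c(1, -1, -1)))
  }
  ang <- acos(min(1, max(-1, sum(z * axis))))
  v %*% t(rotation_about_axis(ax, ang))
}

#' Assemble a synthetic crystal trajectory
#'
#' Builds a frame-by-frame trajectory from a reference lattice: each molecule
#' is rotated about the centroid of its Calpha selection by its rocking series
#' (no translational diffusion, centroids are stationary), and amide H
#' positions are optionally perturbed by the internal cone process.
#'
#' @param lattice A `"crystal_frame"` from [build_reference_lattice()].
#' @param rocking A single [rocking_process()] shared by all molecules, or a
#'   list with one process per molecule.
#' @param internal Optional [internal_motion()]; `NULL` disables it.
#' @param n_frames Number of frames.
#' @param time_step Frame spacing, seconds.
#' @param seed Integer seed; per-molecule sub-seeds are derived from it and
#'   recorded in the output metadata.
#' @return Object of class `"rock_trajectory"`: list with `coords` (array
#'   `n_atom x 3 x n_mol x n_frames`), `atoms`, `molecules`, `time_step`,
#'   `transforms` (inherited from the lattice), `rocking_input` (the list of
#'   generated rotation series, ground truth for tests) and `seeds`.
#' @export
assemble_trajectory <- function(lattice, rocking, internal = NULL,
                                n_frames = 100, time_step = 1e-9,
                                seed = 1) {
  stopifnot(inherits(lattice, "crystal_frame"), n_frames >= 2, time_step > 0)
  n_mol <- dim(lattice$coords)[3]
  if (inherits(rocking, "rocking_process")) {
    rocking <- rep(list(rocking), n_mol)
  }
  if (length(rocking) != n_mol) {
    stop("need one rocking process per molecule (got ", length(rocking),
         " for ", n_mol, " molecules)", call. = FALSE)
  }
  if (!is.null(internal)) stopifnot(inherits(internal, "internal_motion"))

  n_atom <- dim(lattice$coords)[1]
  ca_idx <- which(lattice$atoms$atom == "CA")
  if (length(ca_idx) < 3) stop("lattice template needs >= 3 CA atoms", call. = FALSE)
  seeds <- seed + seq_len(n_mol) * 1000L

  series <- vector("list", n_mol)
  coords <- array(NA_real_, c(n_atom, 3, n_mol, n_frames))
  n_idx <- which(lattice$atoms$atom == "N")
  h_idx <- which(lattice$atoms$atom == "H")
  has_nh <- length(n_idx) > 0 && length(n_idx) == length(h_idx)

  for (m in seq_len(n_mol)) {
    series[[m]] <- simulate_rocking_series(rocking[[m]], n_frames, time_step,
                                           seed = seeds[m])
    X0 <- t(lattice$coords[, , m])              # 3 x n_atom
    piv <- rowMeans(X0[, ca_idx, drop = FALSE])
    Xc <- X0 - piv
    for (f in seq_len(n_frames)) {
      coords[, , m, f] <- t(series[[m]]$matrices[, , f] %*% Xc + piv)
    }
    if (!is.null(internal) && has_nh && internal$cone_semiangle > 0) {
      set.seed(seeds[m] + 500L)
      th0 <- internal$cone_semiangle * pi / 180
      p_refresh <- 1 - exp(-time_step / internal$internal_correlation_time)
      for (r in seq_along(n_idx)) {
        # reference NH direction in the molecular (pre-rocking) frame
        u_ref <- X0[, h_idx[r]] - X0[, n_idx[r]]
        u_ref <- u_ref / sqrt(sum(u_ref^2))
        u <- runif_cone(1, th0, u_ref)[1, ]
        for (f in seq_len(n_frames)) {
          if (f > 1 && stats::runif(1) < p_refresh) {
            u <- runif_cone(1, th0, u_ref)[1, ]
          }
          Rf <- series[[m]]$matrices[, , f]
          n_pos <- coords[n_idx[r], , m, f]
          coords[h_idx[r], , m, f] <- n_pos + 1.02 * as.numeric(Rf %*% u)
        }
      }
    }
  }
  for (m in seq_len(n_mol)) series[[m]]$molecule_id <- m
  structure(
    list(coords = coords, atoms = lattice$atoms,
         molecules = lattice$molecules, time_step = time_step,
         transforms = lattice$transforms, rocking_input = series,
         seeds = seeds),
    class = "rock_trajectory"
  )
}

#' @export
print.rock_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<rock_trajectory> ", d[4], " frames x ", d[3], " molecules x ",
      d[1], " atoms, dt = ", format(x$time_step), " s\n", sep = "")
  invisible(x)
}

#' Write a trajectory as a tidy coordinate table
#'
#' One row per frame/molecule/atom with columns
#' `frame, molecule, chain, atom, residue, x, y, z`; TSV with `#`-prefixed
#' header metadata lines (time step, creation seed).
#'
#' @param traj A `"rock_trajectory"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_table <- function(traj, file) {
  stopifnot(inherits(traj, "rock_trajectory"))
  d <- dim(traj$coords)
  tab <- tidyr::expand_grid(frame = seq_len(d[4]), molecule = seq_len(d[3]),
                            i_atom = seq_len(d[1]))
  tab$chain <- traj$molecules$chain[tab$molecule]
  tab$atom <- traj$atoms$atom[tab$i_atom]
  tab$residue <- traj$atoms$residue[tab$i_atom]
  idx <- cbind(tab$i_atom, 1L, tab$molecule, tab$frame)
  tab$x <- traj$coords[idx]
  idx[, 2] <- 2L; tab$y <- traj$coords[idx]
  idx[, 2] <- 3L; tab$z <- traj$coords[idx]
  tab$i_atom <- NULL
  con <- file(file, "w")
  writeLines(c(sprintf("# latticerock trajectory table"),
               sprintf("# time_step_s\t%.12g", traj$time_step)), con)
  close(con)
  readr::write_tsv(tab, file, append = TRUE, col_names = TRUE)
  invisible(file)
}

#' Read a trajectory coordinate table
#'
#' Inverse of [write_trajectory_table()].
#'
#' @param file Path to a table written by [write_trajectory_table()].
#' @return A `"rock_trajectory"` (without generator metadata).
#' @export
read_trajectory_table <- function(file) {
  hdr <- readLines(file, n = 10)
  ts_line <- grep("^# time_step_s", hdr, value = TRUE)
  time_step <- if (length(ts_line)) as.numeric(strsplit(ts_line, "\t")[[1]][2]) else NA_real_
  tab <- readr::read_tsv(file, comment = "#", show_col_types = FALSE)
  frames <- sort(unique(tab$frame))
  mols <- sort(unique(tab$molecule))
  one <- tab[tab$frame == frames[1] & tab$molecule == mols[1], ]
  n_atom <- nrow(one)
  coords <- array(NA_real_, c(n_atom, 3, length(mols), length(frames)))
  tab <- dplyr::arrange(tab, .data$frame, .data$molecule)
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  coords[] <- aperm(array(t(xyz), c(3, n_atom, length(mols), length(frames))),
                    c(2, 1, 3, 4))
  structure(
    list(coords = coords,
         atoms = tibble::tibble(atom = one$atom, residue = one$residue),
         molecules = tibble::tibble(
           molecule = mols,
           chain = tab$chain[match(mols, tab$molecule)]),
         time_step = time_step, transforms = NULL, rocking_input = NULL,
         seeds = NULL),
    class = "rock_trajectory"
  )
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL; molecules are distinguished by chain
#' identifiers (cycled through A-Z, a-z, 0-9 when there are many copies).
#' Readable by standard structural-biology tools.
#'
#' @param traj A `"rock_trajectory"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "rock_trajectory"))
  d <- dim(traj$coords)
  chain_pool <- c(LETTERS, letters, 0:9)
  chains <- chain_pool[((seq_len(d[3]) - 1) %% length(chain_pool)) + 1]
  atom_names <- formatC(traj$atoms$atom, width = 3, flag = "-")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   latticerock trajectory, time step %.6g s",
                     traj$time_step), con)
  serial_fmt <- "ATOM  %5d  %-3s%4s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00"
  for (f in seq_len(d[4])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (m in seq_len(d[3])) {
      for (a in seq_len(d[1])) {
        serial <- serial + 1L
        writeLines(sprintf(serial_fmt, serial, atom_names[a], "GLY",
                           chains[m], traj$atoms$residue[a],
                           traj$coords[a, 1, m, f], traj$coords[a, 2, m, f],
                           traj$coords[a, 3, m, f]), con)
      }
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Uses bio3d to parse the file; models become frames and chain identifiers
#' define molecules. All molecules must share one atom ordering.
#'
#' @param file PDB path.
#' @param time_step Frame spacing in seconds to record on the trajectory.
#' @return A `"rock_trajectory"`.
#' @export
read_trajectory_pdb <- function(file, time_step = 1e-9) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB trajectories requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  at <- pdb$atom
  n_frames <- nrow(pdb$xyz)
  chains <- unique(at$chain)
  n_mol <- length(chains)
  per <- nrow(at) / n_mol
  if (per != round(per)) stop("molecules differ in atom count", call. = FALSE)
  n_atom <- as.integer(per)
  coords <- array(NA_real_, c(n_atom, 3, n_mol, n_frames))
  for (f in seq_len(n_frames)) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    for (m in seq_len(n_mol)) {
      rows <- which(at$chain == chains[m])
      coords[, , m, f] <- xyz[rows, ]
    }
  }
  first <- at[at$chain == chains[1], ]
  structure(
    list(coords = coords,
         atoms = tibble::tibble(atom = trimws(first$elety),
                                residue = first$resno),
         molecules = tibble::tibble(molecule = seq_len(n_mol),
                                    chain = chains),
         time_step = time_step, transforms = NULL, rocking_input = NULL,
         seeds = NULL),
    class = "rock_trajectory"
  )
}
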