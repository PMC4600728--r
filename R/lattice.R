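# Crystal lattice construction: unit cell geometry, symmetry expansion,
# replication into a block of cells, with the generating transform of every
# molecular copy stored so analyses can map copies back to a common frame.

#' Triclinic cell matrix
#'
#' Matrix A whose columns are the cell vectors in a Cartesian frame
#' (a along x, b in the xy plane); Cartesian = A %*% fractional.
#'
#' @param cell Numeric length-6: a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @return 3x3 matrix (Angstrom).
#' @export
cell_matrix <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0),
            all(cell[4:6] > 0), all(cell[4:6] < 180))
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  # cospi/sinpi keep right angles exact (cos(90 deg) == 0 identically)
  ca <- cospi(cell[4] / 180); cb <- cospi(cell[5] / 180)
  cg <- cospi(cell[6] / 180); sg <- sinpi(cell[6] / 180)
  cx <- cb
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0) stop("invalid cell angles (degenerate cell)", call. = FALSE)
  matrix(c(a, 0, 0,
           b * cg, b * sg, 0,
           cc * cx, cc * cy, cc * sqrt(cz2)), 3, 3)
}

#' Unit-cell volume
#'
#' General triclinic volume
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}}; reduces to `a*b*c` exactly for
#' orthorhombic cells.
#'
#' @inheritParams cell_matrix
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(length(cell) == 6)
  ca <- cospi(cell[4] / 180); cb <- cospi(cell[5] / 180)
  cg <- cospi(cell[6] / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) stop("invalid cell angles (degenerate cell)", call. = FALSE)
  cell[1] * cell[2] * cell[3] * sqrt(arg)
}

#' Crystal lattice specification
#'
#' Describes how a full lattice block is generated from one template chain:
#' unit-cell geometry, symmetry operators in fractional coordinates, the number
#' of chains per asymmetric unit and an integer replication of the unit cell.
#'
#' Each symmetry operator must be a proper rigid transform: its rotation part,
#' expressed in the Cartesian frame (`A R A^-1` with A the cell matrix), must
#' be orthonormal with determinant +1.
#'
#' @param unit_cell Length-6 cell parameters (a, b, c A; alpha, beta, gamma deg).
#' @param symmetry_ops List of operators, each `list(R = 3x3, t = length-3)`
#'   in fractional coordinates. Default: identity only.
#' @param n_chains_asu Chains per asymmetric unit; the template must contain
#'   `n_chains_asu` chains (its `chain` column must have that many levels).
#' @param chain_template Tibble/data.frame with columns `chain`, `atom`,
#'   `residue`, `x`, `y`, `z` (Cartesian Angstrom) for one asymmetric unit.
#' @param replication Integer length-3: unit-cell copies along a, b, c.
#' @return Object of class `"lattice_spec"`.
#' @export
lattice_spec <- function(unit_cell,
                         symmetry_ops = list(list(R = diag(3), t = c(0, 0, 0))),
                         n_chains_asu = 1,
                         chain_template,
                         replication = c(1, 1, 1)) {
  A <- cell_matrix(unit_cell)
  Ainv <- solve(A)
  for (op in symmetry_ops) {
    if (!is.list(op) || is.null(op$R) || is.null(op$t)) {
      stop("each symmetry operator needs elements R (3x3) and t (length 3)",
           call. = FALSE)
    }
    Rc <- A %*% op$R %*% Ainv
    if (!is_rotation_matrix(Rc, tol = 1e-6)) {
      stop("symmetry operator is not a proper rigid transform ",
           "(Cartesian rotation part not orthonormal with det +1)",
           call. = FALSE)
    }
  }
  stopifnot(is.data.frame(chain_template), nrow(chain_template) > 0,
            all(c("chain", "atom", "residue", "x", "y", "z") %in%
                  names(chain_template)))
  chains <- unique(chain_template$chain)
  if (length(chains) != n_chains_asu) {
    stop("chain_template has ", length(chains), " chains but n_chains_asu = ",
         n_chains_asu, call. = FALSE)
  }
  replication <- as.integer(replication)
  stopifnot(length(replication) == 3, all(replication >= 1))
  structure(
    list(unit_cell = unit_cell, symmetry_ops = symmetry_ops,
         n_chains_asu = n_chains_asu,
         chain_template = tibble::as_tibble(chain_template),
         replication = replication),
    class = "lattice_spec"
  )
}

#' Total molecule count implied by a lattice specification
#' @param spec A [lattice_spec()].
#' @return Integer count.
#' @export
n_molecules <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  spec$n_chains_asu * length(spec$symmetry_ops) * prod(spec$replication)
}

#' Build the reference lattice frame
#'
#' Applies every symmetry operator and unit-cell translation to every chain of
#' the template, producing one static frame containing all molecular copies,
#' together with the exact Cartesian transform `(R, t)` that generated each
#' copy from its template chain (`x_copy = R x_template + t`). The stored
#' inverse transforms let downstream analyses map any copy back into the
#' template frame.
#'
#' @param spec A [lattice_spec()].
#' @return Object of class `"crystal_frame"`: list with
#'   * `coords`: array `n_atom x 3 x n_mol` (Angstrom),
#'   * `atoms`: tibble (`atom`, `residue`) shared by all molecules,
#'   * `molecules`: tibble (`molecule`, `chain`, `sym_op`, `cell`),
#'   * `transforms`: list of `list(R, t)` per molecule,
#'   * `template`: per-chain list of template coordinate matrices.
#' @export
build_reference_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  A <- cell_matrix(spec$unit_cell)
  Ainv <- solve(A)
  tpl <- spec$chain_template
  chains <- unique(tpl$chain)

  # all template chains must share one atom ordering
  split_tpl <- lapply(chains, function(ch) tpl[tpl$chain == ch, , drop = FALSE])
  atoms0 <- split_tpl[[1]][, c("atom", "residue")]
  for (s in split_tpl) {
    if (nrow(s) != nrow(atoms0) ||
        !all(s$atom == atoms0$atom) || !all(s$residue == atoms0$residue)) {
      stop("all template chains must share an identical atom ordering",
           call. = FALSE)
    }
  }
  tpl_xyz <- lapply(split_tpl, function(s) t(as.matrix(s[, c("x", "y", "z")])))
  names(tpl_xyz) <- as.character(chains)

  shifts <- expand.grid(i = seq_len(spec$replication[1]) - 1L,
                        j = seq_len(spec$replication[2]) - 1L,
                        k = seq_len(spec$replication[3]) - 1L)
  n_mol <- n_molecules(spec)
  n_atom <- nrow(atoms0)
  coords <- array(NA_real_, c(n_atom, 3, n_mol))
  transforms <- vector("list", n_mol)
  meta <- vector("list", n_mol)

  m <- 0L
  for (s in seq_len(nrow(shifts))) {
    cell_shift <- as.numeric(shifts[s, ])
    for (o in seq_along(spec$symmetry_ops)) {
      op <- spec$symmetry_ops[[o]]
      Rc <- A %*% op$R %*% Ainv
      tc <- as.numeric(A %*% (op$t + cell_shift))
      for (ch in seq_along(chains)) {
        m <- m + 1L
        X <- Rc %*% tpl_xyz[[ch]] + tc          # 3 x n_atom
        coords[, , m] <- t(X)
        transforms[[m]] <- list(R = Rc, t = tc)
        meta[[m]] <- tibble::tibble(
          molecule = m, chain = as.character(chains[ch]),
          sym_op = o, cell = s)
      }
    }
  }
  structure(
    list(coords = coords,
         atoms = tibble::as_tibble(atoms0),
         molecules = dplyr::bind_rows(meta),
         transforms = transforms,
         template = tpl_xyz),
    class = "crystal_frame"
  )
}

#' @export
print.crystal_frame <- function(x, ...) {
  cat("<crystal_frame> ", dim(x$coords)[3], " molecules x ",
      dim(x$coords)[1], " atoms\n", sep = "")
  invisible(x)
}

#' Synthetic template chain
#'
#' Generates a compact synthetic mini-protein backbone for use as a lattice
#' template: Calpha atoms along an idealised helical path plus backbone N and
#' amide H atoms placed at canonical geometry. Entirely synthetic -- it stands
#' in for a crystallographic chain so that lattice and trajectory machinery can
#' be exercised without external coordinates.
#'
#' @param n_residues Number of residues.
#' @param chain Chain label.
#' @return Tibble with columns `chain`, `atom` ("N", "H", "CA"), `residue`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
synthetic_chain_template <- function(n_residues = 12, chain = "A") {
  stopifnot(n_residues >= 3)
  i <- seq_len(n_residues)
  # idealized alpha-helix Calpha trace: radius 2.3 A, rise 1.5 A, 100 deg/res
  th <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
  # N displaced from Calpha, H off the N along a varying direction
  n_at <- ca + matrix(c(-0.9, 0.9, -0.8), n_residues, 3, byrow = TRUE)
  nh_dir <- cbind(cos(th + 2.5), sin(th + 2.5), 0.35)
  nh_dir <- nh_dir / sqrt(rowSums(nh_dir^2))
  h_at <- n_at + 1.02 * nh_dir
  dplyr::bind_rows(
    tibble::tibble(chain = chain, atom = "N", residue = i,
                   x = n_at[, 1], y = n_at[, 2], z = n_at[, 3]),
    tibble::tibble(chain = chain, atom = "H", residue = i,
                   x = h_at[, 1], y = h_at[, 2], z = h_at[, 3]),
    tibble::tibble(chain = chain, atom = "CA", residue = i,
                   x = ca[, 1], y = ca[, 2], z = ca[, 3])
  ) |>
    dplyr::arrange(.data$residue, match(.data$atom, c("N", "H", "CA")))
}
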