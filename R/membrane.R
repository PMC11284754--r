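# Bilayer construction, receptor assignment and system assembly.
# The builders are the synthetic-input generators for the whole
# pipeline: every simulated system starts from these.

#' Build a flat two-leaflet bilayer on a lattice
#'
#' Places `n_lipids_x * n_lipids_y` three-bead lipids per leaflet
#' (head, tail1, tail2; two FENE bonds and one harmonic angle each),
#' tails pointing inward, head-tail1-tail2 collinear along z at the
#' approximate bond rest length, zero initial velocities. The box is
#' square in XY with area `n_lipids_x * n_lipids_y * area_per_lipid`
#' (periodic in X and Y, open in Z). The default area per lipid,
#' 1.1345 sigma^2, reproduces the published system scale: 10,452
#' lipids (78 x 67 per leaflet) fill a 77 x 77 sigma box; the
#' zero-tension barostat then finds the equilibrium area.
#'
#' @param n_lipids_x,n_lipids_y Lipids per leaflet along X and Y.
#' @param area_per_lipid Initial area per (leaflet) lipid, sigma^2.
#' @return A `system_state` object.
#' @export
build_bilayer <- function(n_lipids_x, n_lipids_y, area_per_lipid = 1.1345) {
  if (n_lipids_x < 1 || n_lipids_y < 1) stop("lipid counts must be positive")
  if (area_per_lipid <= 0) stop("area_per_lipid must be positive")
  nx <- as.integer(n_lipids_x); ny <- as.integer(n_lipids_y)
  L <- sqrt(nx * ny * area_per_lipid)
  ax <- L / nx; ay <- L / ny
  d <- 0.965                       # FENE + WCA approximate rest length
  gx <- (rep(seq_len(nx), times = ny) - 0.5) * ax
  gy <- (rep(seq_len(ny), each = nx) - 0.5) * ay
  nleaf <- nx * ny
  n_lipids <- 2L * nleaf
  n <- 3L * n_lipids
  pos <- matrix(0, n, 3)
  kinds <- integer(n)
  # bead order per lipid: head, tail1, tail2
  # upper leaflet: head at +(0.5 + 2d), tails below; lower mirrored
  zs_up <- c(0.5 + 2 * d, 0.5 + d, 0.5)
  for (leaf in 0:1) {
    sgn <- if (leaf == 0) 1 else -1
    off <- leaf * nleaf
    for (b in 1:3) {
      idx <- (off + seq_len(nleaf) - 1L) * 3L + b
      pos[idx, 1] <- gx + leaf * ax / 2   # stagger leaflets half a cell
      pos[idx, 2] <- gy + leaf * ay / 2
      pos[idx, 3] <- sgn * zs_up[b]
      kinds[idx] <- if (b == 1) 1L else 2L
    }
  }
  pos[, 1] <- pos[, 1] %% L
  pos[, 2] <- pos[, 2] %% L
  head_idx <- (seq_len(n_lipids) - 1L) * 3L + 1L
  fene <- rbind(cbind(head_idx, head_idx + 1L),
                cbind(head_idx + 1L, head_idx + 2L))
  angles <- cbind(head_idx, head_idx + 1L, head_idx + 2L)
  state <- list(
    positions = pos,
    velocities = matrix(0, n, 3),
    kinds = kinds,
    fene_bonds = unname(fene),
    angles = unname(angles),
    lr_bonds = integer(0),      # ligand index -> receptor index map
    box = c(Lx = L, Ly = L, Lz = 6 * (0.5 + 2 * d) + 20),
    time = 0,
    n_lipids = n_lipids,
    head_idx = head_idx,
    tail2_idx = head_idx + 2L,
    particle_idx = integer(0)
  )
  class(state) <- "system_state"
  state
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d beads: %d lipids (%d receptor heads), %d particle beads (%d ligands)\n",
              nrow(x$positions), x$n_lipids, sum(x$kinds == 3L),
              length(x$particle_idx), sum(x$kinds == 5L)))
  cat(sprintf("  box %.3f x %.3f sigma (periodic XY), t = %.4g tau, %d ligand-receptor bonds\n",
              x$box[1], x$box[2], x$time, n_lr_bonds(x)))
  invisible(x)
}

#' Number of current ligand-receptor bonds
#' @param state A `system_state`.
#' @return Integer bond count.
#' @export
n_lr_bonds <- function(state) {
  if (length(state$lr_bonds) == 0) return(0L)
  sum(state$lr_bonds > 0L)
}

#' Relabel a fraction of lipid heads as receptors
#'
#' Rounds `fraction * n_heads` heads to receptor kind, chosen uniformly
#' at random with the given seed (default fraction 0.5: half the lipid
#' heads are receptors). Receptors keep the full lipid topology.
#'
#' @param state A `system_state` with lipid heads.
#' @param fraction Fraction of heads in [0, 1].
#' @param seed Integer seed.
#' @return The modified `system_state`.
#' @export
assign_receptors <- function(state, fraction = 0.5, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  heads <- state$head_idx
  if (length(heads) == 0) stop("state has no lipid heads")
  state$kinds[heads] <- 1L      # reset any previous assignment
  k <- round(fraction * length(heads))
  if (k > 0) {
    sel <- with_local_seed(seed, sample(heads, k))
    state$kinds[sel] <- 3L
  }
  state
}

#' Insert a rigid particle above the membrane
#'
#' Centers the particle in XY and places it so its lowest bead sits at
#' the WCA contact distance (2^(1/6) sigma) plus `standoff` above the
#' mean upper-leaflet head plane. Errors if the particle does not fit
#' the box laterally (minimum-image safe) or overlaps membrane beads.
#'
#' @param membrane A `system_state` (bilayer, receptors assigned).
#' @param particle A `surface_beads` object (may be empty).
#' @param standoff Extra gap above contact distance, sigma (default 1).
#' @return A combined `system_state`; particle beads are rigid.
#' @export
assemble_system <- function(membrane, particle, standoff = 1) {
  np <- nrow(particle$coordinates)
  if (is.null(np) || np == 0) return(membrane)
  ext <- 2 * max(abs(particle$coordinates[, 1:2]))
  if (ext + 2 >= min(membrane$box[1:2])) {
    stop("particle does not fit the box laterally")
  }
  heads_up <- membrane$head_idx[membrane$positions[membrane$head_idx, 3] > 0]
  zplane <- mean(membrane$positions[heads_up, 3])
  shift <- c(membrane$box[1] / 2, membrane$box[2] / 2,
             zplane + 2^(1 / 6) + standoff - min(particle$coordinates[, 3]))
  pxyz <- sweep(particle$coordinates, 2, shift, "+")
  n0 <- nrow(membrane$positions)
  state <- membrane
  state$positions <- rbind(membrane$positions, pxyz)
  state$velocities <- rbind(membrane$velocities, matrix(0, np, 3))
  if (!is.null(membrane$xu)) state$xu <- rbind(membrane$xu, pxyz)
  state$kinds <- c(membrane$kinds, kind_code(particle$kind))
  state$particle_idx <- n0 + seq_len(np)
  state$site_id <- c(rep(NA_integer_, n0), particle$site_id)
  state$lr_bonds <- integer(0)
  # overlap audit: particle sits above the membrane by construction;
  # verify no pair closer than 0.9 of the relevant exclusion diameter
  minz <- min(pxyz[, 3])
  near <- which(membrane$positions[, 3] > minz - 1.2)
  if (length(near)) {
    for (k in near) {
      d <- sqrt(min(rowSums(sweep(pxyz, 2, membrane$positions[k, ], "-")^2)))
      if (d < 0.9) stop("overlap after particle placement")
    }
  }
  state
}

#' Export a system as a LAMMPS data file (atom_style molecular dialect)
#'
#' Plain-text snapshot readable by a reference engine for
#' cross-validation: atoms with molecule ids (lipid index or 0 for the
#' particle), FENE bonds (type 1) and angles (type 1).
#'
#' @param state A `system_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  n <- nrow(state$positions)
  nb <- nrow(state$fene_bonds)
  na <- nrow(state$angles)
  mol <- integer(n)
  mol[seq_len(3L * state$n_lipids)] <- rep(seq_len(state$n_lipids), each = 3L)
  zlo <- min(state$positions[, 3]) - 10
  zhi <- max(state$positions[, 3]) + 10
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("starwrap system", "",
               sprintf("%d atoms", n), sprintf("%d bonds", nb),
               sprintf("%d angles", na), "",
               "5 atom types", "1 bond types", "1 angle types", "",
               sprintf("0 %.10g xlo xhi", state$box[1]),
               sprintf("0 %.10g ylo yhi", state$box[2]),
               sprintf("%.10g %.10g zlo zhi", zlo, zhi), "",
               "Masses", "", paste(1:5, "1.0"), "",
               "Atoms # molecular", ""), con)
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g", seq_len(n), mol,
                     state$kinds, state$positions[, 1],
                     state$positions[, 2], state$positions[, 3]), con)
  if (nb > 0) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", seq_len(nb),
                       state$fene_bonds[, 1], state$fene_bonds[, 2]), con)
  }
  if (na > 0) {
    writeLines(c("", "Angles", ""), con)
    writeLines(sprintf("%d 1 %d %d %d", seq_len(na), state$angles[, 1],
                       state$angles[, 2], state$angles[, 3]), con)
  }
  invisible(path)
}

#' Save / load a system checkpoint
#'
#' Run-time checkpoint containing every named array needed to resume a
#' simulation (positions, velocities, kinds, topology, dynamic bonds,
#' box, time).
#'
#' @param state A `system_state`.
#' @param path Checkpoint path (RDS container).
#' @return `write_checkpoint`: `path` invisibly; `read_checkpoint`: the
#'   `system_state`.
#' @export
write_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  readRDS(path)
}
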