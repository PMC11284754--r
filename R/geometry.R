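# Nanoparticle surface generation: bead shells for spheres and spiked
# nanostars, ligand placement on tips or patches, and shape metrics.

#' Near-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic golden-angle spiral; the even-spacing scheme used for
#' surface beads, tip axes and patch centers alike.
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere_points <- function(n) {
  if (n < 1) stop("n must be >= 1")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Geometric recipe for a nanoparticle
#'
#' Defaults follow the simulated particles: spiked nanostars with a core
#' radius of 7 sigma, tip length 5 sigma (maximum radial extent 12
#' sigma), basal tip radius 3 sigma and tip radius 1.5 sigma; spheres
#' with radius 12 sigma, matching the stars' maximum extent. Ligands
#' cover the outermost `ligand_depth` (3 sigma) of star tips, or form
#' `n_patches` evenly distributed patches on spheres.
#'
#' @param shape "star" or "sphere".
#' @param core_radius Star core radius, sigma.
#' @param tip_count Number of tips (star).
#' @param tip_length Tip length beyond the core, sigma.
#' @param basal_tip_radius Tip radius where it leaves the core, sigma.
#' @param tip_radius Tip radius at the apex, sigma.
#' @param sphere_radius Sphere radius, sigma.
#' @param bead_spacing Target nearest-neighbor bead spacing, sigma
#'   (default 1, the WCA diameter of particle beads, so the shell is
#'   impenetrable to lipids).
#' @param ligand_depth Radial depth of the ligand shell on tips, sigma.
#' @param n_patches Number of ligand patches (sphere).
#' @param ligands_per_site Ligands per tip or per patch.
#' @return An object of class `nanoparticle_spec`.
#' @export
nanoparticle_spec <- function(shape = c("star", "sphere"),
                              core_radius = 7, tip_count = 35,
                              tip_length = 5, basal_tip_radius = 3,
                              tip_radius = 1.5, sphere_radius = 12,
                              bead_spacing = 1, ligand_depth = 3,
                              n_patches = 35, ligands_per_site = 8) {
  shape <- match.arg(shape)
  if (bead_spacing <= 0) stop("bead_spacing must be positive")
  if (shape == "star") {
    if (core_radius <= 0 || tip_length < 0) stop("non-positive star dimensions")
    if (!(tip_radius <= basal_tip_radius && basal_tip_radius <= core_radius)) {
      stop("require tip_radius <= basal_tip_radius <= core_radius")
    }
    if (tip_count < 0) stop("tip_count must be >= 0")
  } else {
    if (sphere_radius <= 0) stop("sphere_radius must be positive")
    if (n_patches < 1) stop("n_patches must be >= 1")
  }
  spec <- list(shape = shape, core_radius = core_radius,
               tip_count = tip_count, tip_length = tip_length,
               basal_tip_radius = basal_tip_radius, tip_radius = tip_radius,
               sphere_radius = sphere_radius, bead_spacing = bead_spacing,
               ligand_depth = ligand_depth, n_patches = n_patches,
               ligands_per_site = ligands_per_site)
  class(spec) <- "nanoparticle_spec"
  spec
}

#' @export
print.nanoparticle_spec <- function(x, ...) {
  if (x$shape == "star") {
    cat(sprintf(
      "<nanoparticle_spec> star: core %g sigma, %d tips of length %g (basal %g -> tip %g), max extent %g sigma\n",
      x$core_radius, x$tip_count, x$tip_length, x$basal_tip_radius,
      x$tip_radius, x$core_radius + x$tip_length))
  } else {
    cat(sprintf("<nanoparticle_spec> sphere: radius %g sigma, %d ligand patches\n",
                x$sphere_radius, x$n_patches))
  }
  invisible(x)
}

#' Maximum radial extent of a particle spec
#' @param spec A [nanoparticle_spec()].
#' @return Radius in sigma.
#' @export
max_radius <- function(spec) {
  if (spec$shape == "star") spec$core_radius + spec$tip_length else spec$sphere_radius
}

surface_beads <- function(coordinates, kind, site_id) {
  structure(list(coordinates = unname(as.matrix(coordinates)),
                 kind = unname(kind), site_id = unname(site_id)),
            class = "surface_beads")
}

#' @export
print.surface_beads <- function(x, ...) {
  cat(sprintf("<surface_beads> %d beads (%d ligands), %d sites, max radius %.3f sigma\n",
              nrow(x$coordinates), sum(x$kind == "ligand"),
              length(unique(x$site_id[x$site_id >= 0])),
              sqrt(max(rowSums(x$coordinates^2)))))
  invisible(x)
}

# beads per area for a hexagonal-like packing with nearest-neighbor
# distance = spacing (area per bead = sqrt(3)/2 spacing^2)
n_beads_for_area <- function(area, spacing) {
  max(4L, as.integer(round(area / (sqrt(3) / 2 * spacing^2))))
}

#' Generate an evenly spaced spherical bead surface
#'
#' Beads are placed on a Fibonacci lattice so the nearest-neighbor
#' spacing is close to `bead_spacing` everywhere (homogeneous surface).
#'
#' @param radius Sphere radius, sigma (> 0).
#' @param bead_spacing Target spacing, sigma (0 < spacing; for
#'   `bead_spacing >= radius` a degenerate small surface of >= 4 beads
#'   is produced).
#' @return A `surface_beads` object (all beads `np_surface`, site -1).
#' @export
generate_sphere_surface <- function(radius, bead_spacing = 1) {
  if (radius <= 0) stop("radius must be positive")
  if (bead_spacing <= 0) stop("bead_spacing must be positive")
  n <- n_beads_for_area(4 * pi * radius^2, bead_spacing)
  xyz <- fibonacci_sphere_points(n) * radius
  surface_beads(xyz, rep("np_surface", n), rep(-1L, n))
}

# arc distance (sigma) from each bead direction to each axis, on the
# sphere of each bead's own radius
bead_axis_arc <- function(xyz, axes) {
  rad <- sqrt(rowSums(xyz^2))
  u <- xyz / rad
  cosang <- pmin(pmax(u %*% t(axes), -1), 1)
  acos(cosang) * rad
}

#' Generate a spiked nanostar bead surface
#'
#' The star is a core sphere plus `tip_count` truncated-cone tips whose
#' axes follow the same even-spacing (Fibonacci) scheme as the surface
#' beads. Each tip tapers from `basal_tip_radius` to `tip_radius` over
#' `tip_length` and is capped at the apex on the sphere of maximum
#' radius, so the maximum radial extent is exactly `core_radius +
#' tip_length`. Core beads under a tip base are removed, and tip flank
#' beads are trimmed at the midline between adjacent tips (with a
#' clearance of 1.6 bead spacings) so that every tip is a distinct
#' connected component above the core.
#'
#' With `tip_count = 0` the result is identical to
#' `generate_sphere_surface(core_radius, bead_spacing)`.
#'
#' Beads carry `site_id`: the tip index (0-based) for tip beads, -1 for
#' core beads.
#'
#' @param spec A [nanoparticle_spec()] with `shape = "star"`.
#' @return A `surface_beads` object.
#' @export
generate_nanostar_surface <- function(spec) {
  if (!inherits(spec, "nanoparticle_spec") || spec$shape != "star") {
    stop("spec must be a star nanoparticle_spec")
  }
  s <- spec$bead_spacing
  core <- generate_sphere_surface(spec$core_radius, s)
  if (spec$tip_count == 0L) return(core)

  axes <- fibonacci_sphere_points(spec$tip_count)
  Rc <- spec$core_radius; L <- spec$tip_length
  rb <- spec$basal_tip_radius; rt <- spec$tip_radius
  Rmax <- Rc + L

  # tips merging at the base into a single blob (axis of one tip inside
  # another's basal circle) is a degenerate parameterization
  if (spec$tip_count > 1) {
    ang <- acos(pmin(pmax(tcrossprod(axes), -1), 1))
    diag(ang) <- Inf
    theta_base <- asin(min(1, rb / Rc))
    if (min(ang) < theta_base) {
      stop("tips geometrically overlapping beyond tolerance: axis separation ",
           sprintf("%.3f", min(ang)), " rad < basal angular radius ",
           sprintf("%.3f", theta_base), " rad")
    }
  }

  # drop core beads lying under any tip base (arc distance < basal
  # radius + half a spacing)
  core_arc <- bead_axis_arc(core$coordinates, axes)
  keep <- apply(core_arc, 1, min) > rb + 0.5 * s
  core_xyz <- core$coordinates[keep, , drop = FALSE]

  tip_xyz <- vector("list", spec$tip_count)
  slant <- sqrt(L^2 + (rb - rt)^2)
  nring <- max(1L, ceiling(slant / s))
  for (k in seq_len(spec$tip_count)) {
    u <- axes[k, ]
    e1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(0, -u[3], u[2])
    e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    pts <- NULL
    # flank rings from base (t = 0) up to just below the apex plane
    for (j in 0:(nring - 1L)) {
      t_ax <- L * j / nring
      rho <- rb + (rt - rb) * j / nring
      m <- max(3L, round(2 * pi * rho / s))
      phi <- 2 * pi * seq_len(m) / m + (j %% 2) * pi / m
      ring <- cbind((Rc + t_ax) * u[1] + rho * (cos(phi) * e1[1] + sin(phi) * e2[1]),
                    (Rc + t_ax) * u[2] + rho * (cos(phi) * e1[2] + sin(phi) * e2[2]),
                    (Rc + t_ax) * u[3] + rho * (cos(phi) * e1[3] + sin(phi) * e2[3]))
      pts <- rbind(pts, ring)
    }
    # apex cap: concentric rings projected onto the max-radius sphere
    ncap <- ceiling(rt / s)
    for (j in seq_len(ncap)) {
      arc <- rt * (ncap - j + 1) / ncap
      th <- arc / Rmax
      rho <- Rmax * sin(th); hz <- Rmax * cos(th)
      m <- max(3L, round(2 * pi * rho / s))
      phi <- 2 * pi * seq_len(m) / m
      ring <- cbind(hz * u[1] + rho * (cos(phi) * e1[1] + sin(phi) * e2[1]),
                    hz * u[2] + rho * (cos(phi) * e1[2] + sin(phi) * e2[2]),
                    hz * u[3] + rho * (cos(phi) * e1[3] + sin(phi) * e2[3]))
      pts <- rbind(pts, ring)
    }
    pts <- rbind(pts, Rmax * u) # apex bead, radial distance exactly Rmax
    tip_xyz[[k]] <- pts
  }
  tip_id <- rep(seq_len(spec$tip_count) - 1L,
                vapply(tip_xyz, nrow, 1L))
  tip_all <- do.call(rbind, tip_xyz)

  # trim flank beads near the midline between adjacent tips so tips
  # remain distinct connected components (clearance 1.6 spacings)
  if (spec$tip_count > 1) {
    arc <- bead_axis_arc(tip_all, axes)
    own <- arc[cbind(seq_len(nrow(arc)), tip_id + 1L)]
    arc[cbind(seq_len(nrow(arc)), tip_id + 1L)] <- Inf
    other <- apply(arc, 1, min)
    keep_tip <- (other - own) >= 1.6 * s
    tip_all <- tip_all[keep_tip, , drop = FALSE]
    tip_id <- tip_id[keep_tip]
    if (length(unique(tip_id)) < spec$tip_count) {
      stop("tips geometrically overlapping beyond tolerance: a tip lost all beads")
    }
  }

  xyz <- rbind(core_xyz, tip_all)
  surface_beads(xyz,
                rep("np_surface", nrow(xyz)),
                c(rep(-1L, nrow(core_xyz)), tip_id))
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Place ligands on the tips of a nanostar
#'
#' Relabels exactly `ligands_per_site` beads per tip as ligands, all in
#' the outermost `ligand_depth` of the maximum radius (for the default
#' star: the outermost 3 sigma of the 12 sigma extent, so every ligand
#' sits at radial distance >= 9 sigma). Ligands are drawn uniformly at
#' random (seeded) from each tip's eligible shell.
#'
#' @param star A `surface_beads` star with tip `site_id`s.
#' @param ligand_depth Radial depth of the eligible shell, sigma (> 0).
#' @param ligands_per_site Ligands per tip (>= 1).
#' @param seed Integer seed.
#' @return The `surface_beads` with ligand kinds set.
#' @export
place_tip_ligands <- function(star, ligand_depth = 3, ligands_per_site = 8,
                              seed = 1) {
  if (ligand_depth <= 0) stop("ligand_depth must be positive")
  if (ligands_per_site < 1) stop("ligands_per_site must be >= 1")
  tips <- sort(unique(star$site_id[star$site_id >= 0]))
  if (length(tips) == 0) stop("surface has no tips")
  rad <- sqrt(rowSums(star$coordinates^2))
  rmin <- max(rad) - ligand_depth
  kind <- star$kind
  with_local_seed(seed, {
    for (tp in tips) {
      elig <- which(star$site_id == tp & rad >= rmin & kind != "ligand")
      if (length(elig) < ligands_per_site) {
        stop(sprintf("tip %d has only %d beads in the outermost %.3g sigma; %d ligands requested",
                     tp, length(elig), ligand_depth, ligands_per_site))
      }
      sel <- if (length(elig) == 1) elig else sample(elig, ligands_per_site)
      kind[sel[seq_len(ligands_per_site)]] <- "ligand"
    }
  })
  star$kind <- kind
  star
}

#' Place evenly distributed ligand patches on a sphere
#'
#' Patch centers follow the same even-spacing (Fibonacci) scheme as the
#' surface beads. Patches are built in index order; each claims its
#' `ligands_per_site` nearest unclaimed surface beads, so patches are
#' disjoint and equidistant ties resolve deterministically to the
#' lowest patch index. The construction is deterministic; `seed` is
#' accepted for interface symmetry with tip placement but unused.
#'
#' @param sphere A `surface_beads` sphere.
#' @param n_patches Number of patches (>= 1).
#' @param ligands_per_site Ligands per patch.
#' @param seed Ignored (placement is deterministic).
#' @return The `surface_beads` with ligand kinds and patch `site_id`s.
#' @export
place_patch_ligands <- function(sphere, n_patches, ligands_per_site,
                                seed = 1) {
  n <- nrow(sphere$coordinates)
  if (n_patches * ligands_per_site > n) {
    stop("n_patches * ligands_per_site exceeds surface bead count")
  }
  radius <- mean(sqrt(rowSums(sphere$coordinates^2)))
  centers <- fibonacci_sphere_points(n_patches) * radius
  kind <- sphere$kind
  site <- sphere$site_id
  claimed <- rep(FALSE, n)
  d2 <- outer(rowSums(sphere$coordinates^2), rowSums(centers^2), "+") -
    2 * sphere$coordinates %*% t(centers)
  for (p in seq_len(n_patches)) {
    ord <- order(d2[, p])
    sel <- ord[!claimed[ord]][seq_len(ligands_per_site)]
    claimed[sel] <- TRUE
    kind[sel] <- "ligand"
    site[sel] <- p - 1L
  }
  sphere$kind <- kind
  sphere$site_id <- site
  sphere
}

#' Mean nearest-neighbor separation between ligand sites
#'
#' Site centers are the mean positions of each site's ligand beads.
#' Reports three variants: `chord` (Euclidean center-to-center distance
#' to the nearest other site, averaged over sites), `geodesic` (the
#' same measured along the sphere of the mean site radius) and `gap`
#' (geodesic separation minus both patches' geodesic radii, floored at
#' zero; an edge-to-edge measure). The ordering across layouts, not the
#' absolute value, is the meaningful contract: the published separation
#' column is not defined precisely enough to pin a single metric.
#'
#' @param layout A `surface_beads` with >= 2 ligand sites.
#' @param variant Which number to return: "chord" (default), "geodesic"
#'   or "gap"; "all" returns the full list.
#' @return Separation in sigma (or a named list for "all").
#' @export
patch_separation <- function(layout, variant = c("chord", "geodesic", "gap", "all")) {
  variant <- match.arg(variant)
  lig <- layout$kind == "ligand"
  sites <- sort(unique(layout$site_id[lig]))
  if (length(sites) < 2) stop("need >= 2 ligand sites")
  centers <- t(vapply(sites, function(sid) {
    colMeans(layout$coordinates[lig & layout$site_id == sid, , drop = FALSE])
  }, numeric(3)))
  dd <- as.matrix(stats::dist(centers))
  diag(dd) <- Inf
  chord <- mean(apply(dd, 1, min))
  reff <- mean(sqrt(rowSums(centers^2)))
  u <- centers / sqrt(rowSums(centers^2))
  ang <- acos(pmin(pmax(tcrossprod(u), -1), 1))
  diag(ang) <- Inf
  geo <- mean(apply(ang, 1, min)) * reff
  # mean patch geodesic radius
  prad <- mean(vapply(seq_along(sites), function(k) {
    pts <- layout$coordinates[lig & layout$site_id == sites[k], , drop = FALSE]
    pu <- pts / sqrt(rowSums(pts^2))
    max(acos(pmin(pmax(pu %*% u[k, ], -1), 1))) * reff
  }, 0))
  out <- list(chord = chord, geodesic = geo, gap = max(0, geo - 2 * prad))
  switch(variant, all = out, out[[variant]])
}

#' Solidity of a binary projection
#'
#' Projection area divided by the area of its convex hull; 1 for convex
#' shapes, lower for spiky ones.
#'
#' @param mask Logical (or 0/1) matrix with >= 1 foreground pixel.
#' @return Solidity in (0, 1].
#' @export
solidity <- function(mask) {
  mask <- mask != 0
  npix <- sum(mask)
  if (npix == 0) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (npix <= 3) return(1)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  hx <- idx[h, 1]; hy <- idx[h, 2]
  m <- length(h)
  area_hull <- abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2
  # half-perimeter correction: pixels are unit squares, hull vertices
  # are pixel centers
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  area_hull <- area_hull + per / 2 + 1
  min(1, npix / area_hull)
}

#' Rasterized projection of a bead surface
#'
#' Projects beads (as disks of `bead_radius`) along an axis onto a
#' binary pixel mask, for solidity measurements. Resolution >= 10
#' pixels/sigma keeps discretization error below ~1%.
#'
#' @param surface A `surface_beads`.
#' @param resolution Pixels per sigma (default 10).
#' @param bead_radius Projected disk radius per bead, sigma (default
#'   0.5, half the WCA diameter).
#' @param axis Projection axis: 1, 2 or 3 (z, default).
#' @return Logical matrix mask.
#' @export
project_mask <- function(surface, resolution = 10, bead_radius = 0.5, axis = 3) {
  keep <- setdiff(1:3, axis)
  xy <- surface$coordinates[, keep, drop = FALSE]
  ext <- max(abs(xy)) + bead_radius + 2 / resolution
  npx <- ceiling(2 * ext * resolution)
  cellc <- (seq_len(npx) - 0.5) / resolution - ext
  mask <- matrix(FALSE, npx, npx)
  r2 <- bead_radius^2
  for (b in seq_len(nrow(xy))) {
    ix <- which(abs(cellc - xy[b, 1]) <= bead_radius)
    iy <- which(abs(cellc - xy[b, 2]) <= bead_radius)
    if (!length(ix) || !length(iy)) next
    dx2 <- (cellc[ix] - xy[b, 1])^2
    dy2 <- (cellc[iy] - xy[b, 2])^2
    mask[ix, iy] <- mask[ix, iy] | outer(dx2, dy2, "+") <= r2
  }
  mask
}

#' Write / read a bead surface in XYZ format
#'
#' Standard XYZ with the element column encoding bead kind (`NP` for
#' surface beads, `LG` for ligands, and the lipid codes `HD`, `TL`,
#' `RC` when used for whole systems); the comment line carries the
#' site-id table.
#'
#' @param surface A `surface_beads`.
#' @param path Output (input) file path.
#' @return `write_xyz`: `path` invisibly. `read_xyz`: a
#'   `surface_beads`.
#' @export
write_xyz <- function(surface, path) {
  codes <- c(lipid_head = "HD", lipid_tail = "TL", receptor_head = "RC",
             np_surface = "NP", ligand = "LG")
  el <- codes[surface$kind]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(surface$coordinates)), con)
  writeLines(paste("site_id:", paste(surface$site_id, collapse = " ")), con)
  writeLines(sprintf("%s %.10g %.10g %.10g", el,
                     surface$coordinates[, 1], surface$coordinates[, 2],
                     surface$coordinates[, 3]), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(ln[1])
  site <- as.integer(strsplit(sub("^site_id:\\s*", "", ln[2]), "\\s+")[[1]])
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[`, "", 1L)
  xyz <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3, byrow = TRUE)
  names <- c(HD = "lipid_head", TL = "lipid_tail", RC = "receptor_head",
             NP = "np_surface", LG = "ligand")
  surface_beads(xyz, unname(names[el]), site)
}

#' Orient a particle so a ligand site faces a given direction
#'
#' Rigid-rotates the surface so the centroid direction of `site`'s
#' ligands points along `direction` (default straight down, toward the
#' membrane). Used when inserting a particle so that wrapping starts
#' from ligand-membrane contact regardless of layout sparsity.
#'
#' @param surface A `surface_beads` with ligands placed.
#' @param site Site id to orient (default 0).
#' @param direction Unit target direction (default c(0, 0, -1)).
#' @return The rotated `surface_beads`.
#' @export
orient_particle <- function(surface, site = 0L, direction = c(0, 0, -1)) {
  lig <- surface$kind == "ligand" & surface$site_id == site
  if (!any(lig)) stop("site has no ligands")
  u <- colMeans(surface$coordinates[lig, , drop = FALSE])
  u <- u / sqrt(sum(u^2))
  w <- direction / sqrt(sum(direction^2))
  v <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(v^2)); cth <- sum(u * w)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  surface$coordinates <- surface$coordinates %*% t(R)
  surface
}
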