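# Interaction model: FENE bonds, harmonic angles, WCA excluded volume,
# cosine-squared tail attraction, and Morse ligand-receptor adhesion,
# all in reduced Lennard-Jones units (sigma, epsilon, tau).

#' Bead kind labels
#'
#' Integer codes used throughout the package for the five bead species:
#' `lipid_head` (1), `lipid_tail` (2), `receptor_head` (3), `np_surface`
#' (4), `ligand` (5). Receptor heads are ordinary lipid heads that have
#' been relabeled; they keep head excluded-volume parameters against
#' lipids and additionally form Morse bonds with ligands.
#'
#' @return Character vector of the five kind labels, in code order.
#' @export
bead_kinds <- function() {
  c("lipid_head", "lipid_tail", "receptor_head", "np_surface", "ligand")
}

kind_code <- function(kind) {
  i <- match(kind, bead_kinds())
  if (anyNA(i)) stop("unknown bead kind: ", paste(kind[is.na(i)], collapse = ", "))
  i
}

#' Construct the coarse-grained force field
#'
#' Returns the full interaction parameterization in reduced units:
#' FENE bond strength `K1` = 30 epsilon with maximum extension
#' `fene_rmax` = 1.5 sigma; harmonic angle strength `K2` = 10 epsilon
#' about `theta0` = 180 degrees; a symmetric kind-pair table selecting
#' WCA or cosine attraction per bead-kind pair; and Morse adhesion
#' parameters (`eps_LR` = 30 epsilon, `r0` = 1 sigma, `alpha` =
#' 1 / sigma) evaluated only on explicitly bonded ligand-receptor pairs
#' up to the break distance.
#'
#' The pair table follows the published parameter matrix: head and
#' receptor beads take `b = 0.95` sigma against lipid beads; all
#' nanoparticle-surface and ligand interactions with the membrane take
#' `b = 1` sigma; lipid tails attract each other via the cosine potential
#' with `wc = 1.5` sigma; intra-particle pairs (surface-surface,
#' surface-ligand, ligand-ligand) are non-interacting ("-" entries) since
#' the particle is rigid.
#'
#' Note on `alpha`: the source parameterization prints the Morse range
#' parameter with units of length; dimensional analysis requires inverse
#' length, so `alpha` is taken as 1 / sigma.
#'
#' @param epsilon Energy unit (default 1).
#' @param K1 FENE spring constant (epsilon / sigma^2 scale, default 30).
#' @param fene_rmax FENE divergence (maximum extension) radius, sigma.
#' @param K2 Harmonic angle constant (epsilon / rad^2, default 10).
#' @param theta0 Rest angle, degrees (default 180).
#' @param eps_LR Morse dissociation energy (default 30 epsilon).
#' @param morse_r0 Morse equilibrium length, sigma (default 1).
#' @param morse_alpha Morse range parameter, 1/sigma (default 1).
#' @param morse_rcut Morse evaluation cutoff, sigma (default 4, the bond
#'   break distance).
#' @return An object of class `starwrap_ff`.
#' @export
forcefield <- function(epsilon = 1, K1 = 30, fene_rmax = 1.5,
                       K2 = 10, theta0 = 180,
                       eps_LR = 30, morse_r0 = 1, morse_alpha = 1,
                       morse_rcut = 4) {
  kinds <- bead_kinds()
  nk <- length(kinds)
  ptype <- matrix("none", nk, nk, dimnames = list(kinds, kinds))
  pb <- matrix(0, nk, nk, dimnames = list(kinds, kinds))
  pwc <- matrix(0, nk, nk, dimnames = list(kinds, kinds))
  set <- function(a, b, type, bb, wc = 0) {
    ptype[a, b] <<- type; ptype[b, a] <<- type
    pb[a, b] <<- bb; pb[b, a] <<- bb
    pwc[a, b] <<- wc; pwc[b, a] <<- wc
  }
  # published nonbonded parameter matrix
  set("lipid_head", "lipid_head", "wca", 0.95)
  set("lipid_head", "lipid_tail", "wca", 0.95)
  set("lipid_tail", "lipid_tail", "cos", 1.0, 1.5)
  set("np_surface", "lipid_head", "wca", 1.0)
  set("np_surface", "lipid_tail", "wca", 1.0)
  set("ligand", "lipid_head", "wca", 1.0)
  set("ligand", "lipid_tail", "wca", 1.0)
  # np_surface-ligand: "-" (none); intra-particle pairs never interact
  set("receptor_head", "ligand", "wca", 1.0)
  set("receptor_head", "lipid_head", "wca", 0.95)
  set("receptor_head", "lipid_tail", "wca", 0.95)
  set("receptor_head", "np_surface", "wca", 1.0)
  # receptors are heads: head-head parameters between receptors
  set("receptor_head", "receptor_head", "wca", 0.95)

  ff <- list(
    epsilon = epsilon,
    K1 = K1, fene_rmax = fene_rmax,
    K2 = K2, theta0 = theta0,
    pair_type = ptype, pair_b = pb, pair_wc = pwc,
    morse = list(eps_LR = eps_LR, r0 = morse_r0, alpha = morse_alpha,
                 rcut = morse_rcut)
  )
  class(ff) <- "starwrap_ff"
  ff
}

#' @export
print.starwrap_ff <- function(x, ...) {
  cat("<starwrap_ff> reduced-unit coarse-grained force field\n")
  cat(sprintf("  FENE: K1 = %g, rmax = %g sigma\n", x$K1, x$fene_rmax))
  cat(sprintf("  angle: K2 = %g, theta0 = %g deg\n", x$K2, x$theta0))
  cat(sprintf("  Morse: eps_LR = %g, r0 = %g, alpha = %g, rcut = %g\n",
              x$morse$eps_LR, x$morse$r0, x$morse$alpha, x$morse$rcut))
  cat("  pair table:\n")
  print(x$pair_type)
  invisible(x)
}

#' Look up the nonbonded interaction for a kind pair
#'
#' @param kind_a,kind_b Bead kind labels (see [bead_kinds()]).
#' @param ff A [forcefield()] object.
#' @return List with `potential` ("wca", "cos" or "none"), `b` and `wc`
#'   (sigma).
#' @export
pair_dispatch <- function(kind_a, kind_b, ff = forcefield()) {
  ia <- kind_code(kind_a); ib <- kind_code(kind_b)
  list(potential = ff$pair_type[ia, ib],
       b = ff$pair_b[ia, ib],
       wc = ff$pair_wc[ia, ib])
}

#' FENE bond energy and force
#'
#' U(r) = -1/2 K1 rmax^2 log(1 - (r/rmax)^2), diverging at the maximum
#' extension rmax = 1.5 sigma. `fene_force` returns the scalar radial
#' force -dU/dr (negative = attractive, pulling the pair together).
#'
#' @param r Bond length(s), sigma; must satisfy 0 <= r < rmax.
#' @param ff A [forcefield()] object.
#' @return Energy in epsilon (or force in epsilon/sigma).
#' @export
fene_energy <- function(r, ff = forcefield()) {
  if (any(r < 0)) stop("negative bond length")
  if (any(r >= ff$fene_rmax)) {
    stop(sprintf("FENE bond overstretched: r = %.4g >= rmax = %.4g (timestep too large?)",
                 max(r), ff$fene_rmax))
  }
  -0.5 * ff$K1 * ff$fene_rmax^2 * log(1 - (r / ff$fene_rmax)^2)
}

#' @rdname fene_energy
#' @export
fene_force <- function(r, ff = forcefield()) {
  if (any(r < 0)) stop("negative bond length")
  if (any(r >= ff$fene_rmax)) stop("FENE bond overstretched")
  # -dU/dr = -K1 r / (1 - (r/rmax)^2)
  -ff$K1 * r / (1 - (r / ff$fene_rmax)^2)
}

#' Harmonic angle energy
#'
#' U(theta) = K2 (theta - theta0)^2 with the deviation measured in
#' radians; rest angle theta0 = 180 degrees keeps the three lipid beads
#' collinear.
#'
#' @param theta Angle(s), degrees, in (0, 180].
#' @param ff A [forcefield()] object.
#' @return Energy in epsilon.
#' @export
angle_energy <- function(theta, ff = forcefield()) {
  if (any(theta <= 0 | theta > 180)) stop("angle must be in (0, 180] degrees")
  dth <- (theta - ff$theta0) * pi / 180
  ff$K2 * dth^2
}

#' WCA (cut-and-shifted Lennard-Jones) energy and force
#'
#' U(r) = 4 eps ((b/r)^12 - (b/r)^6) + eps for r < 2^(1/6) b, exactly 0
#' beyond; purely repulsive excluded volume of diameter b.
#'
#' @param r Distance(s), sigma; r > 0.
#' @param b Exclusion diameter, sigma.
#' @param epsilon Energy scale (default 1).
#' @return Energy in epsilon (or radial force -dU/dr in epsilon/sigma).
#' @export
wca_energy <- function(r, b, epsilon = 1) {
  if (any(r <= 0)) stop("WCA singular at r <= 0")
  rc <- 2^(1 / 6) * b
  s6 <- (b / r)^6
  u <- 4 * epsilon * (s6^2 - s6) + epsilon
  ifelse(r < rc, u, 0)
}

#' @rdname wca_energy
#' @export
wca_force <- function(r, b, epsilon = 1) {
  if (any(r <= 0)) stop("WCA singular at r <= 0")
  rc <- 2^(1 / 6) * b
  s6 <- (b / r)^6
  f <- 24 * epsilon * (2 * s6^2 - s6) / r
  ifelse(r < rc, f, 0)
}

#' Cosine-squared tail attraction energy and force
#'
#' The implicit-solvent attraction between lipid tail beads:
#' -eps for r < rc; -eps cos^2(pi (r - rc) / (2 wc)) for rc <= r < rc +
#' wc; 0 beyond, with rc = 2^(1/6) b. Together with the WCA core this
#' gives a smooth potential with minimum -eps at contact.
#'
#' @param r Distance(s), sigma; r > 0.
#' @param b Exclusion diameter, sigma.
#' @param wc Attraction width, sigma (tail-tail default 1.5).
#' @param epsilon Energy scale (default 1).
#' @return Energy in epsilon (or radial force in epsilon/sigma).
#' @export
cos_attraction_energy <- function(r, b, wc, epsilon = 1) {
  if (any(r <= 0)) stop("singular at r <= 0")
  rc <- 2^(1 / 6) * b
  u <- numeric(length(r))
  u[r < rc] <- -epsilon
  mid <- r >= rc & r < rc + wc
  u[mid] <- -epsilon * cos(pi * (r[mid] - rc) / (2 * wc))^2
  u
}

#' @rdname cos_attraction_energy
#' @export
cos_attraction_force <- function(r, b, wc, epsilon = 1) {
  if (any(r <= 0)) stop("singular at r <= 0")
  rc <- 2^(1 / 6) * b
  f <- numeric(length(r))
  mid <- r >= rc & r < rc + wc
  arg <- pi * (r[mid] - rc) / (2 * wc)
  # -dU/dr = -eps * pi/wc * cos(arg) sin(arg)
  f[mid] <- -epsilon * pi / (2 * wc) * sin(2 * arg)
  f
}

#' Morse ligand-receptor bond energy and force
#'
#' U(r) = eps_LR ((1 - exp(-alpha (r - r0)))^2 - 1): well depth eps_LR =
#' 30 epsilon at r0 = 1 sigma, approaching 0 at dissociation. Evaluated
#' only on currently bonded ligand-receptor pairs, and only below the
#' evaluation cutoff (the 4 sigma break distance).
#'
#' @param r Distance(s), sigma; r >= 0.
#' @param morse Morse parameter list (from `forcefield()$morse`).
#' @param apply_cutoff If TRUE (default), return 0 beyond `morse$rcut`.
#' @return Energy in epsilon (or radial force in epsilon/sigma).
#' @export
morse_energy <- function(r, morse = forcefield()$morse, apply_cutoff = TRUE) {
  if (any(r < 0)) stop("negative distance")
  e <- exp(-morse$alpha * (r - morse$r0))
  u <- morse$eps_LR * ((1 - e)^2 - 1)
  if (apply_cutoff) u[r >= morse$rcut] <- 0
  u
}

#' @rdname morse_energy
#' @export
morse_force <- function(r, morse = forcefield()$morse, apply_cutoff = TRUE) {
  if (any(r < 0)) stop("negative distance")
  e <- exp(-morse$alpha * (r - morse$r0))
  f <- -2 * morse$eps_LR * morse$alpha * e * (1 - e)
  if (apply_cutoff) f[r >= morse$rcut] <- 0
  f
}

#' Maximum nonbonded interaction range of a force field
#'
#' @param ff A [forcefield()] object.
#' @return Cutoff in sigma (largest 2^(1/6) b + wc over the pair table).
#' @export
ff_max_cutoff <- function(ff = forcefield()) {
  rc <- 2^(1 / 6) * ff$pair_b + ifelse(ff$pair_type == "cos", ff$pair_wc, 0)
  rc[ff$pair_type == "none"] <- 0
  max(rc)
}

#' Reference all-pairs nonbonded energy (O(N^2))
#'
#' Independent, deliberately simple double-loop evaluation of the total
#' nonbonded energy (pair table only; no bonds, angles or Morse), with
#' minimum-image convention in X and Y and an open Z direction. Used as
#' the oracle against the neighbor-list engine path; not for production.
#'
#' @param positions N x 3 matrix, sigma.
#' @param kinds Integer kind codes (1..5) or labels.
#' @param box Numeric `c(Lx, Ly)` (a third element, Lz, is ignored).
#' @param ff A [forcefield()] object.
#' @return Total energy in epsilon.
#' @export
nonbonded_energy_ref <- function(positions, kinds, box, ff = forcefield()) {
  if (is.character(kinds)) kinds <- kind_code(kinds)
  n <- nrow(positions)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- positions[j, ] - positions[i, ]
      d[1] <- d[1] - box[1] * round(d[1] / box[1])
      d[2] <- d[2] - box[2] * round(d[2] / box[2])
      r <- sqrt(sum(d^2))
      type <- ff$pair_type[kinds[i], kinds[j]]
      if (type == "none") next
      b <- ff$pair_b[kinds[i], kinds[j]]
      if (type == "wca") {
        e <- e + wca_energy(r, b, ff$epsilon)
      } else {
        e <- e + wca_energy(r, b, ff$epsilon) +
          cos_attraction_energy(r, b, ff$pair_wc[kinds[i], kinds[j]], ff$epsilon)
      }
    }
  }
  e
}

#' Serialize / restore a force field as flat key-value text
#'
#' Writes every scalar parameter and pair-table entry as `key = value`
#' lines mirroring the published parameter matrix, so an alternative
#' parameterization is one text edit away.
#'
#' @param ff A [forcefield()] object.
#' @param path File to write (for `ff_write`) or read (`ff_read`).
#' @return `ff_write` returns `path` invisibly; `ff_read` a
#'   `starwrap_ff`.
#' @export
ff_write <- function(ff, path) {
  ln <- c(
    sprintf("epsilon = %.17g", ff$epsilon),
    sprintf("K1 = %.17g", ff$K1),
    sprintf("fene_rmax = %.17g", ff$fene_rmax),
    sprintf("K2 = %.17g", ff$K2),
    sprintf("theta0 = %.17g", ff$theta0),
    sprintf("morse.eps_LR = %.17g", ff$morse$eps_LR),
    sprintf("morse.r0 = %.17g", ff$morse$r0),
    sprintf("morse.alpha = %.17g", ff$morse$alpha),
    sprintf("morse.rcut = %.17g", ff$morse$rcut)
  )
  kinds <- bead_kinds()
  for (i in seq_along(kinds)) {
    for (j in i:length(kinds)) {
      key <- paste0("pair.", kinds[i], ".", kinds[j])
      ln <- c(ln, sprintf("%s = %s %.17g %.17g", key,
                          ff$pair_type[i, j], ff$pair_b[i, j], ff$pair_wc[i, j]))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname ff_write
#' @export
ff_read <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  ff <- forcefield()
  num <- function(k) as.numeric(vals[match(k, keys)])
  ff$epsilon <- num("epsilon"); ff$K1 <- num("K1")
  ff$fene_rmax <- num("fene_rmax"); ff$K2 <- num("K2")
  ff$theta0 <- num("theta0")
  ff$morse$eps_LR <- num("morse.eps_LR"); ff$morse$r0 <- num("morse.r0")
  ff$morse$alpha <- num("morse.alpha"); ff$morse$rcut <- num("morse.rcut")
  for (k in grep("^pair\\.", keys)) {
    parts <- strsplit(keys[k], ".", fixed = TRUE)[[1]]
    fld <- strsplit(vals[k], "\\s+")[[1]]
    i <- kind_code(parts[2]); j <- kind_code(parts[3])
    ff$pair_type[i, j] <- ff$pair_type[j, i] <- fld[1]
    ff$pair_b[i, j] <- ff$pair_b[j, i] <- as.numeric(fld[2])
    ff$pair_wc[i, j] <- ff$pair_wc[j, i] <- as.numeric(fld[3])
  }
  ff
}
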