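# Analysis observables: wrapping fraction and time, membrane thickness
# maps, vesicle membership, lipid displacement, wrapping-time ratios,
# and the transwell permeability utility.

#' Wrapping fraction of a configuration
#'
#' Total ligand-receptor binding energy over current bonds, normalized
#' by its maximum magnitude (all ligands bound at the Morse well
#' depth): |sum U_Morse| / (N_ligands * eps_LR), clamped to [0, 1].
#'
#' @param state A `system_state` with at least one ligand.
#' @param ff A [forcefield()].
#' @return Fraction in [0, 1].
#' @export
wrapping_fraction <- function(state, ff = forcefield()) {
  lig <- which(state$kinds == 5L)
  if (length(lig) == 0) stop("no ligands in system")
  lr <- state_lr_vec(state)
  bonded <- lig[lr[lig] > 0L]
  if (length(bonded) == 0) return(0)
  d <- state$positions[lr[bonded], , drop = FALSE] -
    state$positions[bonded, , drop = FALSE]
  d[, 1] <- d[, 1] - state$box[1] * round(d[, 1] / state$box[1])
  d[, 2] <- d[, 2] - state$box[2] * round(d[, 2] / state$box[2])
  r <- sqrt(rowSums(d^2))
  u <- sum(morse_energy(r, ff$morse))
  min(1, max(0, -u / (length(lig) * ff$morse$eps_LR)))
}

#' Wrapping time of a trace
#'
#' First time the (smoothed) wrapping fraction reaches `threshold` and
#' stays at or above it for `hold` tau. Returns `NA` if the trace never
#' completes (an "N/A" layout). Thermal fluctuations keep the
#' energy-based fraction below its ideal value of one, so completion is
#' declared at a sustained high threshold (default 0.9 for 100 tau),
#' both recorded in run metadata.
#'
#' @param trace A `wrapping_trace`, or a list/data.frame with `times`
#'   and `wrap_fraction`.
#' @param threshold Completion threshold in (0, 1].
#' @param hold Sustain requirement, tau.
#' @param smooth Half-width (samples) of the running-mean smoother
#'   (0 = raw).
#' @return Wrapping time in tau, or `NA_real_`.
#' @export
wrapping_time <- function(trace, threshold = 0.9, hold = 100, smooth = 2L) {
  times <- trace$times
  wf <- trace$wrap_fraction
  if (length(times) == 0) stop("empty trace")
  if (smooth > 0 && length(wf) > 2 * smooth) {
    k <- 2L * as.integer(smooth) + 1L
    wf <- stats::filter(wf, rep(1 / k, k), sides = 2)
    # running mean is NA at the ends; fall back to raw there
    wf[is.na(wf)] <- trace$wrap_fraction[is.na(wf)]
    wf <- as.numeric(wf)
  }
  above <- wf >= threshold
  if (!any(above)) return(NA_real_)
  idx <- which(above)
  horizon <- max(times)
  for (i in idx) {
    j <- which(times >= times[i] & times <= times[i] + hold)
    if (all(above[j])) {
      # the hold window must be observable within the trace
      if (times[i] + hold <= horizon + 1e-9 || all(above[times >= times[i]])) {
        return(times[i])
      }
    }
  }
  NA_real_
}

#' Binned membrane thickness map
#'
#' Projects lipid heads onto an XY grid of bins of width ~`bin_width`
#' (0.5 sigma), assigns each head to a leaflet by the sign of the
#' z-component of its tail2-to-head vector, averages head Z per bin and
#' leaflet, linearly interpolates empty bins from filled neighbors
#' (row-wise then column-wise), and reports per-bin thickness =
#' upper - lower with its mean and SD. Bins that required
#' interpolation are flagged in `interpolated_mask`.
#'
#' @param state A `system_state` (or a frame with `x`, plus `kinds`,
#'   `head_idx`, `tail2_idx`, `box` supplied via `topology`).
#' @param bin_width Target bin width, sigma (default 0.5).
#' @param exclude_lipids Optional lipid indices to drop (e.g. lipids in
#'   a detached vesicle).
#' @return A `thickness_map`: list with `grid` (matrix, sigma),
#'   `interpolated_mask`, `mean`, `sd`, `bin_width`.
#' @export
membrane_thickness <- function(state, bin_width = 0.5, exclude_lipids = NULL) {
  pos <- state$positions
  heads <- state$head_idx
  tails2 <- state$tail2_idx
  if (!is.null(exclude_lipids) && length(exclude_lipids)) {
    heads <- heads[-exclude_lipids]
    tails2 <- tails2[-exclude_lipids]
  }
  Lx <- state$box[1]; Ly <- state$box[2]
  nbx <- max(2L, round(Lx / bin_width))
  nby <- max(2L, round(Ly / bin_width))
  hx <- pos[heads, 1] %% Lx; hy <- pos[heads, 2] %% Ly; hz <- pos[heads, 3]
  up <- pos[heads, 3] - pos[tails2, 3] > 0    # tail2 -> head points up
  ix <- pmin(nbx, 1L + floor(hx / Lx * nbx))
  iy <- pmin(nby, 1L + floor(hy / Ly * nby))
  bin_mean <- function(sel) {
    s <- matrix(0, nbx, nby); cnt <- matrix(0L, nbx, nby)
    id <- cbind(ix[sel], iy[sel])
    for (k in seq_len(sum(sel))) {
      s[id[k, 1], id[k, 2]] <- s[id[k, 1], id[k, 2]] + hz[which(sel)[k]]
      cnt[id[k, 1], id[k, 2]] <- cnt[id[k, 1], id[k, 2]] + 1L
    }
    m <- s / cnt
    m[cnt == 0L] <- NA_real_
    m
  }
  zu <- bin_mean(up)
  zl <- bin_mean(!up)
  if (all(is.na(zu)) || all(is.na(zl))) stop("a leaflet is empty everywhere")
  fill <- function(m) {
    filled_na <- is.na(m)
    # pass 1: rows (x fixed), pass 2: columns, pass 3: global mean
    for (i in seq_len(nrow(m))) {
      row <- m[i, ]
      if (anyNA(row) && sum(!is.na(row)) >= 2) {
        m[i, ] <- stats::approx(which(!is.na(row)), row[!is.na(row)],
                                xout = seq_along(row), rule = 2)$y
      }
    }
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (anyNA(col) && sum(!is.na(col)) >= 2) {
        m[, j] <- stats::approx(which(!is.na(col)), col[!is.na(col)],
                                xout = seq_along(col), rule = 2)$y
      }
    }
    m[is.na(m)] <- mean(m, na.rm = TRUE)
    list(m = m, interpolated = filled_na)
  }
  fu <- fill(zu); fl <- fill(zl)
  grid <- fu$m - fl$m
  interp <- fu$interpolated | fl$interpolated
  structure(list(grid = grid, interpolated_mask = interp,
                 mean = mean(grid), sd = stats::sd(as.numeric(grid)),
                 bin_width = c(Lx / nbx, Ly / nby)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d bins (%.3g x %.3g sigma): thickness %.3f +/- %.3f sigma (%d interpolated bins)\n",
              nrow(x$grid), ncol(x$grid), x$bin_width[1], x$bin_width[2],
              x$mean, x$sd, sum(x$interpolated_mask)))
  invisible(x)
}

#' Lipids belonging to the (forming) vesicle around the particle
#'
#' Lipids with any bead within the interaction range (2^(1/6) b + wc)
#' of any particle bead, closed under tail-tail contact clustering
#' (single linkage at the same range), so the whole wrapped patch is
#' captured. Measuring only these lipids reduces noise in displacement
#' analyses.
#'
#' Note that the contact closure is meaningful for a detached (or
#' nearly detached) vesicle: on a flat membrane still attached to the
#' particle's surroundings, the tail network is connected and the
#' closure floods the whole sheet. Use `closure = FALSE` to obtain the
#' directly contacting lipids only (the wrapping front).
#'
#' @param state A `system_state` containing a particle.
#' @param ff A [forcefield()].
#' @param closure Close the set under tail-tail contact (default TRUE).
#' @return Integer vector of lipid indices (possibly empty).
#' @export
vesicle_lipids <- function(state, ff = forcefield(), closure = TRUE) {
  if (length(state$particle_idx) == 0) return(integer(0))
  rc <- 2^(1 / 6) * 1 + ff$pair_wc["lipid_tail", "lipid_tail"]
  pos <- state$positions
  box <- state$box
  ppos <- pos[state$particle_idx, , drop = FALSE]
  n_lip <- state$n_lipids
  lip_of_bead <- rep(seq_len(n_lip), each = 3L)
  # seed set: lipids with a bead near the particle
  lip_beads <- seq_len(3L * n_lip)
  near <- rep(FALSE, n_lip)
  for (b in lip_beads) {
    d <- sweep(ppos, 2, pos[b, ], "-")
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    if (min(rowSums(d^2)) <= rc^2) near[lip_of_bead[b]] <- TRUE
  }
  if (!any(near)) return(integer(0))
  if (!closure) return(which(near))
  # closure under tail-tail contact: breadth-first over lipid contacts
  tails <- cbind(state$tail2_idx, state$tail2_idx - 1L)
  tpos1 <- pos[tails[, 1], , drop = FALSE]
  tpos2 <- pos[tails[, 2], , drop = FALSE]
  members <- which(near)
  frontier <- members
  remaining <- setdiff(seq_len(n_lip), members)
  while (length(frontier) > 0 && length(remaining) > 0) {
    newly <- integer(0)
    for (lp in frontier) {
      for (tp in list(tpos1[lp, ], tpos2[lp, ])) {
        for (mat in list(tpos1, tpos2)) {
          d <- sweep(mat[remaining, , drop = FALSE], 2, tp, "-")
          d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
          d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
          hit <- remaining[rowSums(d^2) <= rc^2]
          newly <- union(newly, hit)
        }
      }
      remaining <- setdiff(remaining, newly)
    }
    members <- union(members, newly)
    frontier <- newly
  }
  sort(members)
}

#' Windowed lipid displacement
#'
#' Mean over a lipid set of |x(t + window) - x(t)| of the head beads,
#' one value per non-overlapping window (default 100 tau), computed on
#' unwrapped coordinates. Errors if a single-frame displacement
#' exceeds half the box (a periodic-jump artifact, meaning wrapped
#' coordinates were supplied).
#'
#' @param trace A `wrapping_trace` (with frames) or a list of frames.
#' @param window Window length, tau.
#' @param lipids Lipid indices to average over (default: all).
#' @param head_idx Head bead indices (taken from the trace if absent).
#' @return data.frame with `window_start` (tau) and
#'   `mean_displacement` (sigma).
#' @export
lipid_displacement <- function(trace, window = 100, lipids = NULL,
                               head_idx = NULL) {
  frames <- if (!is.null(trace$frames)) trace$frames else trace
  if (length(frames) < 2) stop("need at least two frames")
  if (is.null(head_idx)) head_idx <- trace$head_idx
  if (is.null(head_idx)) stop("head_idx required")
  if (!is.null(lipids) && length(lipids)) head_idx <- head_idx[lipids]
  times <- vapply(frames, function(f) f$time, 0)
  box <- frames[[1]]$box
  # artifact guard: consecutive-frame jumps beyond half a box
  for (k in 2:length(frames)) {
    jump <- abs(frames[[k]]$xu[head_idx, 1:2, drop = FALSE] -
                  frames[[k - 1]]$xu[head_idx, 1:2, drop = FALSE])
    if (any(jump > rep(box / 2, each = length(head_idx)))) {
      stop("periodic-jump artifact: supply unwrapped coordinates")
    }
  }
  starts <- seq(times[1], max(times) - window, by = window)
  out <- data.frame(window_start = starts, mean_displacement = NA_real_)
  for (w in seq_along(starts)) {
    i0 <- which.min(abs(times - starts[w]))
    i1 <- which.min(abs(times - (starts[w] + window)))
    if (i1 <= i0) next
    d <- frames[[i1]]$xu[head_idx, , drop = FALSE] -
      frames[[i0]]$xu[head_idx, , drop = FALSE]
    out$mean_displacement[w] <- mean(sqrt(rowSums(d^2)))
  }
  out
}

#' Relative wrapping time: sphere group over star group
#'
#' Mean wrapping time over completed sphere replicas divided by the
#' mean over completed star replicas. `NA` if no sphere replica
#' completes (the published "N/A" layouts); an error if the star
#' baseline never completes.
#'
#' @param sphere_traces,star_traces Lists of `wrapping_trace` (or
#'   numeric vectors of wrapping times; `NA` = incomplete).
#' @param threshold,hold Completion criterion (see [wrapping_time()]).
#' @return Ratio (dimensionless) or `NA_real_`.
#' @export
relative_wrapping_time <- function(sphere_traces, star_traces,
                                   threshold = 0.9, hold = 100) {
  tw <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, wrapping_time, 0, threshold = threshold, hold = hold)
  }
  ts <- tw(star_traces)
  tp <- tw(sphere_traces)
  if (all(is.na(ts))) stop("star group never completes: no baseline")
  if (all(is.na(tp))) return(NA_real_)
  mean(tp, na.rm = TRUE) / mean(ts, na.rm = TRUE)
}

#' Transwell apparent permeability coefficient
#'
#' Papp = (V / (A C0)) (dC / dt) in cm/s, with the published chamber
#' constants as defaults: basolateral volume 750 uL, insert membrane
#' area 0.3 cm^2, initial apical concentration 0.5 mg/mL, diffusion
#' time 4 h.
#'
#' @param dC Basolateral concentration change, mg/mL (>= 0).
#' @param V Basolateral volume, uL.
#' @param A Membrane area, cm^2.
#' @param C0 Initial apical concentration, mg/mL.
#' @param dt_h Diffusion time, hours.
#' @return Papp in cm/s.
#' @export
transwell_papp <- function(dC, V = 750, A = 0.3, C0 = 0.5, dt_h = 4) {
  if (A <= 0 || C0 <= 0 || dt_h <= 0 || V <= 0) {
    stop("V, A, C0 and dt_h must be positive")
  }
  if (any(dC < 0)) stop("dC must be >= 0")
  V_ml <- V * 1e-3
  (V_ml / (A * C0)) * (dC / (dt_h * 3600))
}

#' Write observable tables as CSV
#'
#' @param obs Observable data.frame (e.g. from [simulate_dynamics()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observables_csv <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}
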