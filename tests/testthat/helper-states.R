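# Builders for small synthetic systems used across tests.

# minimal system_state from raw arrays
toy_state <- function(positions, kinds, box = c(20, 20, 40),
                      fene_bonds = matrix(integer(0), 0, 2),
                      angles = matrix(integer(0), 0, 3),
                      lr_bonds = integer(0),
                      particle_idx = integer(0),
                      n_lipids = 0L, head_idx = integer(0),
                      tail2_idx = integer(0)) {
  if (is.character(kinds)) kinds <- match(kinds, bead_kinds())
  n <- nrow(positions)
  if (length(lr_bonds) == 0) lr_bonds <- integer(n)
  structure(list(positions = positions,
                 velocities = matrix(0, n, 3),
                 kinds = as.integer(kinds),
                 fene_bonds = fene_bonds, angles = angles,
                 lr_bonds = as.integer(lr_bonds),
                 box = c(Lx = box[1], Ly = box[2], Lz = box[3]),
                 time = 0, n_lipids = as.integer(n_lipids),
                 head_idx = as.integer(head_idx),
                 tail2_idx = as.integer(tail2_idx),
                 particle_idx = as.integer(particle_idx)),
            class = "system_state")
}

# one unbound ligand-receptor pair at separation r
lr_pair_state <- function(r = 1.0, box = c(20, 20, 40)) {
  toy_state(rbind(c(10, 10, 10), c(10, 10, 10 + r)),
            kinds = c("ligand", "receptor_head"), box = box)
}

# a gas of n beads with random kinds in a periodic box (for energy
# oracles): jittered lattice so no two beads overlap deeply (keeps
# energies O(1) per pair and absolute FP comparisons meaningful)
random_gas <- function(n, box = c(12, 12, 10), seed = 1,
                       kinds_pool = c("lipid_head", "lipid_tail",
                                      "receptor_head")) {
  set.seed(seed)
  a <- 1.1
  g <- as.matrix(expand.grid(x = seq(0.5, box[1] - 0.6, a),
                             y = seq(0.5, box[2] - 0.6, a),
                             z = seq(1, box[3] - 1, a)))
  stopifnot(nrow(g) >= n)
  pos <- g[sample(nrow(g), n), ] + matrix(runif(3 * n, -0.2, 0.2), n, 3)
  toy_state(pos, sample(kinds_pool, n, replace = TRUE), box = box)
}

# two flat head sheets (with inward tails) separated by `gap`, on an
# exact lattice: the constructed thickness equals `gap` identically
flat_sheets_state <- function(nx = 12, ny = 12, gap = 4.51, a = 1.0,
                              jitter = 0, seed = 1) {
  set.seed(seed)
  L <- nx * a
  g <- expand.grid(x = (seq_len(nx) - 0.5) * a, y = (seq_len(ny) - 0.5) * a)
  nl <- nrow(g)
  pos <- matrix(0, 6 * nl, 3)
  kinds <- integer(6 * nl)
  # per lipid: head, tail1, tail2 (upper then lower leaflet)
  for (leaf in 0:1) {
    sgn <- if (leaf == 0) 1 else -1
    for (b in 1:3) {
      idx <- (leaf * nl + seq_len(nl) - 1L) * 3L + b
      pos[idx, 1] <- g$x + jitter * stats::runif(nl, -0.3, 0.3)
      pos[idx, 2] <- g$y + jitter * stats::runif(nl, -0.3, 0.3)
      pos[idx, 3] <- sgn * (gap / 2 - (b - 1) * 0.9 * sgn * sgn) * 1
      kinds[idx] <- if (b == 1) 1L else 2L
    }
  }
  # heads exactly at +/- gap/2; tails inward
  head_idx <- (seq_len(2 * nl) - 1L) * 3L + 1L
  for (lp in seq_len(2 * nl)) {
    sgn <- if (lp <= nl) 1 else -1
    pos[head_idx[lp], 3] <- sgn * gap / 2
    pos[head_idx[lp] + 1L, 3] <- sgn * (gap / 2 - 0.9)
    pos[head_idx[lp] + 2L, 3] <- sgn * (gap / 2 - 1.8)
  }
  toy_state(pos, kinds, box = c(L, ny * a, 40),
            n_lipids = 2L * nl, head_idx = head_idx,
            tail2_idx = head_idx + 2L)
}

# single-linkage connected components via breadth-first search on a
# distance threshold (independent clustering oracle for geometry tests)
single_linkage_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        hit <- which(comp == 0L & d[f, ] <= cutoff)
        comp[hit] <- cur
        nxt <- c(nxt, hit)
      }
      frontier <- nxt
    }
  }
  comp
}

# nearest-neighbor distances within a point set
nn_distances <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  apply(d, 1, min)
}
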