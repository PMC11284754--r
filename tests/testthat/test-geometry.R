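# Surface generation, ligand placement, and shape metrics.

test_that("sphere surfaces are on-radius, homogeneous, and scale with spacing", {
  s <- generate_sphere_surface(12, 1)
  rad <- sqrt(rowSums(s$coordinates^2))
  expect_true(all(abs(rad - 12) < 0.5))       # radius +/- spacing/2
  expect_equal(max(abs(s$coordinates)), 12, tolerance = 0.05)
  expect_true(all(s$kind == "np_surface"))
  expect_true(all(s$site_id == -1L))
  # halving the spacing quadruples the count (area scaling)
  s2 <- generate_sphere_surface(12, 0.5)
  expect_lt(abs(nrow(s2$coordinates) / nrow(s$coordinates) - 4), 0.8)
  # degenerate small surface: still >= 4 beads, no error
  tiny <- generate_sphere_surface(1, 1)
  expect_gte(nrow(tiny$coordinates), 4)
  expect_error(generate_sphere_surface(-1, 1), "positive")
  expect_error(generate_sphere_surface(5, 0), "positive")
  # homogeneity: nearest-neighbor spacing CV < 0.3, all within +/-30%
  nn <- nn_distances(s$coordinates)
  expect_lt(stats::sd(nn) / mean(nn), 0.3)
  expect_true(all(nn > 0.7 * 1 & nn < 1.3 * 1))
})

test_that("nanostar surface: extent, reduction to sphere, distinct tips", {
  spec <- nanoparticle_spec("star")   # 7 + 5 sigma, 35 tips
  star <- generate_nanostar_surface(spec)
  rad <- sqrt(rowSums(star$coordinates^2))
  expect_equal(max(rad), 12, tolerance = 1e-6)
  # all 35 tips carry beads (the dense 35-tip star has its core fully
  # covered by tip bases, so no core beads remain)
  expect_equal(sort(unique(star$site_id[star$site_id >= 0])), 0:34)
  # a sparse star keeps exposed core beads
  sparse <- generate_nanostar_surface(nanoparticle_spec("star", tip_count = 8))
  expect_gt(sum(sparse$site_id == -1L), 100)
  # tip_count = 0 reduces exactly to the core sphere
  spec0 <- nanoparticle_spec("star", tip_count = 0)
  star0 <- generate_nanostar_surface(spec0)
  core <- generate_sphere_surface(7, 1)
  expect_equal(star0$coordinates, core$coordinates)
  # independent single-linkage clustering of beads beyond the core
  # radius finds exactly 35 tips
  above <- star$coordinates[rad > 7 + 1e-9, , drop = FALSE]
  comp <- single_linkage_components(above, 1.5 * spec$bead_spacing)
  expect_identical(max(comp), 35L)
  # surface homogeneity on the star (CV of NN spacing)
  nn <- nn_distances(star$coordinates)
  expect_lt(stats::sd(nn) / mean(nn), 0.3)
  # degenerate parameterization: tips overlapping beyond tolerance
  expect_error(generate_nanostar_surface(
    nanoparticle_spec("star", tip_count = 200, basal_tip_radius = 3)),
    "overlap")
})

test_that("tip ligand placement covers the outermost shell", {
  spec <- nanoparticle_spec("star")
  star <- generate_nanostar_surface(spec)
  lig <- place_tip_ligands(star, ligand_depth = 3, ligands_per_site = 8,
                           seed = 42)
  expect_identical(sum(lig$kind == "ligand"), 280L)   # 35 x 8
  rad <- sqrt(rowSums(lig$coordinates^2))
  expect_true(all(rad[lig$kind == "ligand"] >= 9 - 1e-9))
  # every tip holds exactly the requested count
  cnt <- table(lig$site_id[lig$kind == "ligand"])
  expect_true(all(cnt == 8))
  # determinism under a fixed seed
  lig2 <- place_tip_ligands(star, 3, 8, seed = 42)
  expect_identical(lig$kind, lig2$kind)
  # degenerate inputs
  expect_error(place_tip_ligands(star, 0, 8), "positive")
  expect_error(place_tip_ligands(star, 0.4, 50), "tip [0-9]+ has only")
})

test_that("patch ligand placement is even, disjoint and deterministic", {
  sph <- generate_sphere_surface(12, 1)
  lay <- place_patch_ligands(sph, 56, 5)
  expect_identical(sum(lay$kind == "ligand"), 280L)   # 56 x 5
  cnt <- table(lay$site_id[lay$kind == "ligand"])
  expect_identical(length(cnt), 56L)
  expect_true(all(cnt == 5))
  # patches disjoint by construction: ligand count equals claimed beads
  expect_identical(sum(lay$site_id >= 0), 280L)
  # single patch: all ligands within one geodesic cap
  one <- place_patch_ligands(sph, 1, 12)
  lp <- one$coordinates[one$kind == "ligand", ]
  ctr <- colMeans(lp); ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(1, (lp / sqrt(rowSums(lp^2))) %*% ctr))
  expect_lt(max(ang), pi / 4)
  # even centers: min center-to-center >= 0.8 x mean
  centers <- t(sapply(0:55, function(s) {
    colMeans(lay$coordinates[lay$site_id == s & lay$kind == "ligand", ])
  }))
  dd <- as.matrix(dist(centers)); diag(dd) <- Inf
  nnc <- apply(dd, 1, min)
  expect_gte(min(nnc), 0.8 * mean(nnc))
  expect_error(place_patch_ligands(sph, 1000, 50), "exceeds")
})

test_that("patch separation: geometry, ordering and scale invariance", {
  # two antipodal sites on a 12-sigma sphere: chord = 24
  xyz <- rbind(c(0, 0, 12), c(0, 0, 12), c(0, 0, -12), c(0, 0, -12))
  lay <- list(coordinates = xyz, kind = rep("ligand", 4),
              site_id = c(0L, 0L, 1L, 1L))
  expect_equal(patch_separation(lay, "chord"), 24)
  expect_error(patch_separation(list(coordinates = xyz[1:2, ],
                                     kind = rep("ligand", 2),
                                     site_id = c(0L, 0L))), ">= 2")
  # separation decreases monotonically with patch count at a fixed
  # 280-ligand budget (the published layout series)
  sph <- generate_sphere_surface(12, 1)
  layouts <- uptake_layouts()
  seps <- vapply(seq_len(nrow(layouts)), function(i) {
    patch_separation(place_patch_ligands(sph, layouts$n_patches[i],
                                         layouts$ligands_per_site[i]),
                     "chord")
  }, 0)
  expect_true(all(diff(seps) > 0))   # 56 -> 10 patches: increasing sep
  # doubling the sphere radius doubles separations
  sph2 <- generate_sphere_surface(24, 1)
  s1 <- patch_separation(place_patch_ligands(sph, 20, 14), "chord")
  s2 <- patch_separation(place_patch_ligands(sph2, 20, 14), "chord")
  expect_equal(s2 / s1, 2, tolerance = 0.05)
  # all three variants are reported
  v <- patch_separation(place_patch_ligands(sph, 20, 14), "all")
  expect_named(v, c("chord", "geodesic", "gap"))
  expect_gt(v$geodesic, v$chord)    # arc exceeds chord
})

test_that("solidity: convex shapes at 1, stars below spheres", {
  # filled disk is convex
  n <- 201
  cc <- outer(seq_len(n) - 101, rep(1, n)) ^ 2 +
    outer(rep(1, n), seq_len(n) - 101) ^ 2
  disk <- cc <= 80 ^ 2
  expect_equal(solidity(disk), 1.0, tolerance = 0.02)
  expect_error(solidity(matrix(FALSE, 4, 4)), "empty")
  # a generated star projects less solid than the matched sphere
  star <- generate_nanostar_surface(nanoparticle_spec("star"))
  sph <- generate_sphere_surface(12, 1)
  sol_star <- solidity(project_mask(star, resolution = 10))
  sol_sph <- solidity(project_mask(sph, resolution = 10))
  expect_lt(sol_star, sol_sph)
  expect_gt(sol_sph, 0.97)
  expect_lt(sol_star, 0.95)
})

test_that("XYZ round trip preserves coordinates, kinds and sites", {
  star <- generate_nanostar_surface(
    nanoparticle_spec("star", tip_count = 6))
  star <- place_tip_ligands(star, 3, 4, seed = 7)
  path <- tempfile(fileext = ".xyz")
  on.exit(unlink(path))
  write_xyz(star, path)
  back <- read_xyz(path)
  expect_equal(back$coordinates, star$coordinates, tolerance = 1e-8)
  expect_identical(back$kind, star$kind)
  expect_identical(back$site_id, star$site_id)
})
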