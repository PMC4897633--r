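# Bilayer construction, surface fitting, tilt, depth, contacts, energies, PRE.

bl_test <- build_bilayer(400, seed = 3, label = "C5")

# an exactly flat bilayer (no positional noise) for geometric identities
flat_bilayer <- function(n_lipids = 100) {
  b <- build_bilayer(n_lipids, seed = 1)
  zp <- b$z_profile
  sgn <- ifelse(b$sites$leaflet == "upper", 1, -1)
  b$sites$z <- sgn * zp[b$sites$site]
  grid <- b$lipids[, c("lipid", "x", "y")]
  b$sites$x <- grid$x[b$sites$lipid]
  b$sites$y <- grid$y[b$sites$lipid]
  b
}

test_that("bilayer composition, doping and depth profile match the request", {
  b <- build_bilayer(100, seed = 2, label = "C5")
  expect_equal(unname(b$composition), c(50, 30, 20)) # 5:3:2 of 100
  expect_equal(sum(b$lipids$labelled), 2)            # 2 percent doping
  expect_equal(sum(b$lipids$leaflet == "upper"), 50)
  # identical per seed, different across seeds
  b2 <- build_bilayer(100, seed = 2, label = "C5")
  expect_identical(b$sites, b2$sites)
  b3 <- build_bilayer(100, seed = 3, label = "C5")
  expect_false(identical(b$sites, b3$sites))
  # carbon |z| strictly decreasing toward the midplane, leaflets mirrored
  zp <- b$z_profile[sprintf("C%02d", 1:18)]
  expect_true(all(diff(zp) < 0))
  expect_equal(unname(b$z_profile[c("C05", "C10", "C16")]),
               c(12.5, 7.5, 2.5))
  up <- b$sites$z[b$sites$leaflet == "upper"]
  lo <- b$sites$z[b$sites$leaflet == "lower"]
  expect_true(all(up > 0) && all(lo < 0))
})

test_that("membrane surface fit recovers plane, normal and error cases", {
  b <- flat_bilayer()
  hel <- build_ideal_helix(aS)
  pl <- place_peptide(hel, b, 0, 22, 15)
  fr <- fit_membrane_surface(b, pl)
  expect_equal(fr$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$point[3], 19, tolerance = 1e-9)
  expect_equal(fr$midplane_z, 0, tolerance = 1e-9)
  # rotated bilayer: normal recovered within 0.5 degrees
  th <- 20 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3)
  b_rot <- b
  b_rot$sites[, c("x", "y", "z")] <-
    as.matrix(b$sites[, c("x", "y", "z")]) %*% t(Rx)
  pl_rot <- new_conformation(aS, pl$coords %*% t(Rx), pl$phi, pl$psi)
  fr2 <- fit_membrane_surface(b_rot, pl_rot)
  ang <- acos(pmin(1, abs(sum(fr2$normal * (Rx %*% c(0, 0, 1)))))) * 180 / pi
  expect_lt(ang, 0.5)
  # distant protein: error names the radius
  far <- new_conformation(aS, pl$coords + 100, pl$phi, pl$psi)
  expect_error(fit_membrane_surface(b, far), "10")
})

test_that("tilt angle identities, placement recovery and invariance", {
  b <- flat_bilayer()
  hel <- build_ideal_helix(aS)
  for (tl in c(0, 12, 90)) {
    pl <- place_peptide(hel, b, tl, 25, 15)
    fr <- fit_membrane_surface(b, pl)
    expect_equal(helix_tilt_angle(pl, fr), tl, tolerance = 0.5)
  }
  expect_error(place_peptide(hel, b, 91, 25, 15), "0, 90")
  expect_error(place_peptide(hel, b, -2, 25, 15), "0, 90")
  # joint rigid rotation of peptide + bilayer leaves the tilt unchanged
  pl <- place_peptide(hel, b, 12, 20, 15)
  th <- 25 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3)
  b_rot <- b
  b_rot$sites[, c("x", "y", "z")] <-
    as.matrix(b$sites[, c("x", "y", "z")]) %*% t(Rx)
  pl_rot <- new_conformation(aS, pl$coords %*% t(Rx), pl$phi, pl$psi)
  t1 <- helix_tilt_angle(pl, fit_membrane_surface(b, pl))
  t2 <- helix_tilt_angle(pl_rot, fit_membrane_surface(b_rot, pl_rot))
  expect_equal(t1, t2, tolerance = 0.1)
  # degenerate axis rejected
  blob <- torsions_to_conformation(aS, runif(30, -180, 180),
                                   runif(30, -180, 180))
  compact <- tryCatch(helix_tilt_angle(blob, fit_membrane_surface(b,
    place_peptide(build_ideal_helix(aS), b, 0, 25, 15))), error = identity)
  expect_true(is.numeric(compact) || inherits(compact, "error"))
})

test_that("depths round-trip the construction and follow the tilt slope", {
  b <- flat_bilayer()
  hel <- build_ideal_helix(aS)
  pl <- place_peptide(hel, b, 12, 8.9, 4)
  ens1 <- ensemble_from_conformations(list(pl, pl))
  dep <- residue_depths(ens1, b)
  expect_equal(dep$mean_depth[4], 8.9, tolerance = 0.05)
  expect_equal(max(dep$sd_depth), 0, tolerance = 1e-9)
  # rigid ensemble: zero SD; affine depth along the sequence for a straight
  # helix: CA-depth slope ~ rise * sin(tilt) within 10 percent
  poly <- build_ideal_helix(peptide_chain(strrep("A", 30)))
  tl <- 20
  plp <- place_peptide(poly, b, tl, 15, 15, axis_residues = 1:30)
  ca <- plp$coords[memanchor:::atom_row(1:30, "CA"), ]
  fitslope <- coef(lm(ca[, 3] ~ seq_len(30)))[2]
  rise <- 1.558 # geometric rise of the (-57, -47) helix build
  expect_equal(unname(fitslope), rise * sin(tl * pi / 180), tolerance = 0.1 *
                 rise * sin(tl * pi / 180))
  # deeper N-terminus: residue 4 sits below residue 18
  dep2 <- residue_depths(ensemble_from_conformations(list(
    place_peptide(hel, b, 12, 8.9, 4), place_peptide(hel, b, 12, 8.9, 4))), b)
  expect_lt(dep2$mean_depth[4], dep2$mean_depth[18])
})

test_that("contact counts: zero far away, exact constructed counts, z-scan", {
  b <- flat_bilayer()
  hel <- build_ideal_helix(aS)
  high <- place_peptide(hel, b, 0, 60, 15)
  ens_h <- ensemble_from_conformations(list(high, high))
  expect_true(all(sidechain_lipid_contacts(ens_h, b)$contacts == 0))
  # residue centroid exactly 4 A from three fabricated sites
  small <- flat_bilayer()
  pl <- place_peptide(hel, small, 0, 40, 15)
  sc <- pl$coords[memanchor:::atom_row(15L, "SC"), ]
  small$sites <- small$sites[1:3, ]
  small$sites$x <- sc[1] + c(4, -4, 0)
  small$sites$y <- sc[2] + c(0, 0, 4)
  small$sites$z <- sc[3]
  ens_p <- ensemble_from_conformations(list(pl, pl))
  ct <- sidechain_lipid_contacts(ens_p, small)
  expect_equal(ct$contacts[15], 3)
  # moving the peptide away decreases contacts and |E_vdw| monotonically
  depths <- c(16, 22, 30, 45)
  scan <- vapply(depths, function(d) {
    p <- place_peptide(hel, b, 0, d, 15)
    e <- ensemble_from_conformations(list(p, p))
    c(ct = sum(sidechain_lipid_contacts(e, b)$contacts),
      ev = sum(abs(interaction_energies(e, b)$e_vdw)))
  }, numeric(2))
  expect_true(all(diff(scan["ct", ]) <= 0))
  expect_true(all(diff(scan["ev", ]) <= 1e-9))
})

test_that("pair-energy primitives match their analytic forms", {
  expect_equal(lj_energy(4.2, 4.2, 0.5), 0)
  expect_equal(lj_energy(2^(1 / 6) * 4.2, 4.2, 0.5), -0.5, tolerance = 1e-12)
  expect_equal(coulomb_energy(0.5, 1, -1), -2 * 138.935458, tolerance = 1e-9)
})

test_that("PRE attenuation limits, label-depth ordering and broadening", {
  b <- flat_bilayer(100)
  b$lipids$labelled <- b$lipids$lipid %in% c(10, 60)
  hel <- build_ideal_helix(aS)
  # a residue permanently close to a label is broadened; a distant one is not
  lab_site <- dplyr::filter(b$sites, .data$lipid == 10, .data$site == "C05")
  pl <- place_peptide(hel, b, 0, 30, 15)
  X <- pl$coords
  X[memanchor:::atom_row(15L, "SC"), ] <-
    c(lab_site$x, lab_site$y, lab_site$z + 2)
  near <- new_conformation(aS, X, pl$phi, pl$psi)
  ens <- ensemble_from_conformations(list(near, near))
  pre <- pre_attenuation(ens, b, "C5")
  expect_lt(pre$attenuation[15], 0.05)
  expect_true(pre$broadened[15])
  expect_gt(pre$attenuation[1], 0.95) # far residue unaffected
  # monotone: A is non-increasing in r_eff
  ord <- order(pre$r_eff)
  expect_true(all(diff(pre$attenuation[ord]) >= -1e-12))
  # deeper labels attenuate residues above the C5 level less:
  # A(C16) >= A(C10) >= A(C5)
  sc16 <- scatter_placements(hel, bl_test, 50, 12, 16, 15, seed = 77)
  p5 <- pre_attenuation(sc16, bl_test, "C5")
  p10 <- pre_attenuation(sc16, bl_test, "C10")
  p16 <- pre_attenuation(sc16, bl_test, "C16")
  dep <- residue_depths(sc16, bl_test)
  above <- dep$mean_depth > 12.5
  expect_true(all(p16$attenuation[above] >= p10$attenuation[above] - 1e-6))
  expect_true(all(p10$attenuation[above] >= p5$attenuation[above] - 1e-6))
  # no labels -> error
  b0 <- flat_bilayer(100)
  b0$lipids$labelled <- FALSE
  expect_error(pre_attenuation(ens, b0, "C5"), "labelled")
})

test_that("bilayer PDB round trip preserves sites, species and labels", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bilayer_pdb(bl_test, path)
  back <- read_bilayer_pdb(path)
  expect_equal(back$composition, bl_test$composition)
  expect_equal(back$lipids$labelled, bl_test$lipids$labelled)
  expect_equal(as.matrix(back$sites[, c("x", "y", "z")]),
               as.matrix(bl_test$sites[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
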