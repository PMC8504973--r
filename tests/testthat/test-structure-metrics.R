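pentamer <- build_synthetic_pentamer(radius = 20, layer_separation = 40)
regions <- attr(pentamer, "regions")

test_that("synthetic pentamer construction honours its parameters", {
  expect_s3_class(pentamer, "structure_frame")
  expect_length(unique(pentamer$atoms$chain), 5)
  expect_error(build_synthetic_pentamer(n_chains = 2), "at least 3")
})

test_that("twist angle is zero for aligned layers and equals the imposed offset", {
  expect_equal(unname(twist_angle(pentamer, regions)), rep(0, 5),
               tolerance = 1e-8)
  for (tw in c(10, -25)) {
    fr <- build_synthetic_pentamer(twist_deg = tw)
    expect_equal(unname(twist_angle(fr, attr(fr, "regions"))), rep(tw, 5),
                 tolerance = 0.01)
  }
})

test_that("twist angle is invariant under rigid-body motion", {
  fr <- build_synthetic_pentamer(twist_deg = 10)
  moved <- transform_frame(fr, random_rotation(2), c(11, -40, 3))
  expect_equal(twist_angle(moved, attr(fr, "regions")),
               twist_angle(fr, attr(fr, "regions")), tolerance = 1e-6)
})

test_that("pair distances follow Euclidean geometry and symmetry", {
  # constructed 3-4-5 triangle
  atoms <- tibble::tibble(chain = c("A", "A"), resno = c(1L, 2L),
                          resid = "GLY", atom = "CA", element = "C",
                          occupancy = 1)
  fr <- mwcgate:::.new_frame(atoms, rbind(c(0, 0, 0), c(3, 4, 0)))
  d <- pair_distance(fr, list(resno = 1), list(resno = 2), mode = "CA",
                     topology = "intra")
  expect_equal(d$value[1], 5)
  # C5 symmetry: five identical intra distances, SD exactly 0
  di <- pair_distance(pentamer, list(resno = 10), list(resno = 110),
                      mode = "CA", topology = "intra")
  expect_length(di$value, 5)
  expect_equal(sd(di$value), 0, tolerance = 1e-10)
  # inter mode walks the five ordered interfaces
  de <- pair_distance(pentamer, list(resno = 10), list(resno = 10),
                      mode = "CA", topology = "inter")
  expect_length(unique(de$group), 5)
  expect_equal(sd(de$value), 0, tolerance = 1e-10)
})

test_that("ECD compaction scales inter-subunit ECD distances exactly", {
  base <- pair_distance(pentamer, list(resno = 10), list(resno = 10),
                        mode = "CA", topology = "inter")
  squeezed <- build_synthetic_pentamer(radius = 20, layer_separation = 40,
                                       compaction_scale = 0.9)
  comp <- pair_distance(squeezed, list(resno = 10), list(resno = 10),
                        mode = "CA", topology = "inter")
  expect_equal(comp$value, 0.9 * base$value, tolerance = 1e-10)
})

test_that("missing atoms are reported with their location", {
  expect_error(pair_distance(pentamer, list(resno = 999), list(resno = 10),
                             mode = "CA", topology = "intra"),
               "residue 999")
  expect_error(pair_distance(pentamer, list(resno = 10, atom = "ZZ"),
                             list(resno = 10), mode = "named_atom",
                             topology = "intra"), "missing atom")
})

test_that("ring radius recovers the pentagon radius, with and without vdW", {
  r <- ring_radius(pentamer, 233, regions = regions)
  expect_equal(r, 20, tolerance = 1e-8)
  r_vdw <- ring_radius(pentamer, 233, subtract_vdw = TRUE, regions = regions)
  expect_equal(r_vdw, r - 1.7)
  moved <- transform_frame(pentamer, random_rotation(4), c(5, 6, 7))
  expect_equal(ring_radius(moved, 233, regions = regions), 20,
               tolerance = 1e-6)
})

test_that("collinear ring atoms are a degenerate-geometry error", {
  fr <- pentamer
  ring <- fr$atoms$resno == 233
  n <- sum(ring)
  fr$coords[ring, ] <- cbind(seq_len(n), seq_len(n), seq_len(n))
  expect_error(ring_radius(fr, 233, regions = regions), "collinear")
})

test_that("RMSD vanishes for self and rigid copies, measures pure translation", {
  traj <- structure(list(frames = list(pentamer), chains = regions$chains),
                    class = "structure_trajectory")
  expect_equal(rmsd_to_reference(traj, pentamer)$value, 0, tolerance = 1e-10)
  moved <- transform_frame(pentamer, random_rotation(8), c(-3, 12, 9))
  expect_equal(rmsd_to_reference(moved, pentamer, superpose = TRUE)$value, 0,
               tolerance = 1e-6)
  shifted <- transform_frame(pentamer, diag(3), c(3, 0, 0))
  expect_equal(rmsd_to_reference(shifted, pentamer, superpose = FALSE)$value,
               3, tolerance = 1e-10)
})

test_that("asymmetry statistics match hand arithmetic and flag declines", {
  ms <- tibble::tibble(frame = rep(1, 5), group = LETTERS[1:5],
                       metric = "d", value = c(10, 10, 10, 10, 14),
                       unit = "angstrom")
  st <- asymmetry_stats(ms)
  expect_equal(st$mean, 10.8)
  expect_equal(st$sd, 1.78885, tolerance = 1e-4)
  expect_equal(st$range, 4)
  expect_error(asymmetry_stats(ms[1, ]), "at least 2")
  ms2 <- tibble::tibble(frame = rep(1:2, each = 5),
                        value = c(rnorm(5, 10, 2), rep(10, 5)))
  expect_true(asymmetry_declines(ms2))
})

test_that("multi-model PDB round trip preserves frames and metrics", {
  f1 <- build_synthetic_pentamer(twist_deg = 0)
  f2 <- build_synthetic_pentamer(twist_deg = 12)
  f3 <- build_synthetic_pentamer(twist_deg = 12, compaction_scale = 0.9)
  path <- file.path(tempdir(), "traj.pdb")
  write_frames_pdb(list(f1, f2, f3), path)
  traj <- load_trajectory(path)
  expect_length(traj$frames, 3)
  expect_equal(unname(twist_angle(traj$frames[[2]], regions)), rep(12, 5),
               tolerance = 0.01)
  # per-frame metric series across the trajectory
  ms <- pair_distance(traj, list(resno = 10), list(resno = 10),
                      mode = "CA", topology = "inter")
  expect_equal(unique(ms$frame), 1:3)
  base <- ms$value[ms$frame == 2][1]
  expect_equal(ms$value[ms$frame == 3][1], 0.9 * base, tolerance = 1e-2)
  # single-model file loads as one frame; empty file errors
  path1 <- file.path(tempdir(), "single.pdb")
  write_frames_pdb(f1, path1)
  expect_length(load_trajectory(path1)$frames, 1)
  empty <- file.path(tempdir(), "empty.pdb")
  writeLines("END", empty)
  expect_error(load_trajectory(empty), "cannot read|no atoms")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  path <- file.path(tempdir(), "alt.pdb")
  pdb_line <- function(serial, alt, resno, x, occ) {
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, alt, resno, x, 0, 0, occ, 0)
  }
  writeLines(c(pdb_line(1, " ", 1, 0, 1.00),
               pdb_line(2, "A", 2, 1, 0.40),
               pdb_line(3, "B", 2, 2, 0.60),
               "END"), path)
  traj <- load_trajectory(path)
  fr <- traj$frames[[1]]
  expect_equal(nrow(fr$atoms), 2)
  expect_equal(fr$coords[fr$atoms$resno == 2, 1], 2.0)  # occupancy 0.60 wins
})

test_that("sidechain centroids average heavy atoms beyond the backbone", {
  atoms <- tibble::tibble(
    chain = "A", resno = 1L, resid = "LEU",
    atom = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C"), occupancy = 1)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
               c(0, 1, 0), c(0, 2, 0), c(0, 4, 0), c(0, 6, 0))
  fr <- mwcgate:::.new_frame(atoms, xyz)
  got <- mwcgate:::.select_atoms(fr, "A", 1, "sidechain_centroid")
  expect_equal(unname(got), c(0, 4, 0))  # mean of CG, CD1, CD2
})
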