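test_that("minimum-image unwrapping continues tracks across the boundary", {
  # +29 -> -29 in a 60 A box is a +2 step through the image, not a -58 jump
  z <- c(25, 29, -29, -25)
  u <- unwrap_coordinate(z, box = 60)
  expect_equal(u, c(25, 29, 31, 35))
  # wrapped coordinate is unchanged modulo the box
  expect_true(all(abs((u - z) %% 60) < 1e-6 | abs((u - z) %% 60 - 60) < 1e-6))
  # per-frame box lengths are honoured
  expect_equal(unwrap_coordinate(c(0, 24), box = c(50, 50)), c(0, 24))
  expect_equal(unwrap_coordinate(c(0, 26), box = c(50, 50)), c(0, -24))
})

test_that("channel-frame projection matches hand geometry", {
  fr <- channel_frame("A")
  expect_equal(project_to_channel_frame(c(0, 0, 5), fr)$z, 5)
  # the frame's own origin projects to exactly zero
  expect_identical(project_to_channel_frame(fr$origin, fr)$z, 0)
  # rotated frame: axis along x
  frx <- channel_frame("B", axis = c(1, 0, 0))
  expect_equal(project_to_channel_frame(c(7, 0, 0), frx)$z, 7)
  # lateral gate: far from the axis inside the slab
  pr <- project_to_channel_frame(c(30, 30, 5), fr)
  expect_equal(pr$z, 5)
  expect_false(pr$lateral_ok)
  # outside the slab the gate is TRUE by definition (bulk)
  pr2 <- project_to_channel_frame(c(30, 30, 20), fr)
  expect_true(pr2$lateral_ok)
})

test_that("channel frames are validated and built from residue centroids", {
  expect_error(channel_frame("A", axis = c(0, 0, 0)), "degenerate")
  expect_error(channel_frame("A", z_bulk_ec = -20), "z_bulk_ic < z_divide")
  # centroid-defined axis: EC at (0,0,10), IC at (0,0,-10)
  pdb_file <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00", 1, 1, 0, 0, 10),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00", 2, 2, 0, 0, -10),
    "END"), pdb_file)
  frames <- build_channel_frames(pdb_file,
                                 list(list(id = "M1", ec_residues = 1,
                                           ic_residues = 2)))
  expect_equal(frames$M1$axis, c(0, 0, 1))
  expect_error(
    build_channel_frames(pdb_file, list(list(id = "M1", ec_residues = 99,
                                             ic_residues = 2))),
    "residue group not found")
  # explicit tetramer spec passes straight through
  tet <- build_channel_frames(NULL, lapply(1:4, function(i) {
    list(id = LETTERS[i], origin = c(10 * i, 0, 0), axis = c(0, 0, 1))
  }))
  expect_length(tet, 4)
  expect_setequal(names(tet), LETTERS[1:4])
})

test_that("config file round-trips channel parameters", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "system:", "  temperature: 298.15",
    "channel:", "  z_divide: 0.0", "  z_bulk_ec: 12", "  z_bulk_ic: -12",
    "  radius_gate: 5",
    "monomers:",
    "  - id: A", "    origin: [1, 2, 3]", "    axis: [0, 0, 1]"), cfg)
  out <- read_channel_config(cfg)
  expect_equal(out$frames$A$z_bulk_ec, 12)
  expect_equal(out$frames$A$origin, c(1, 2, 3))
  expect_equal(out$system$temperature, 298.15)
})

test_that("DCD writer round-trips through the bio3d reader", {
  set.seed(42)
  nf <- 5; na <- 3
  xyz <- matrix(rnorm(nf * 3 * na, sd = 10), nf, 3 * na)
  f <- tempfile(fileext = ".dcd")
  write_dcd(xyz, f, cell = c(40, 40, 60))
  back <- bio3d::read.dcd(f, verbose = FALSE)
  expect_equal(dim(back), dim(xyz))
  # DCD stores single precision
  expect_equal(unclass(back), unclass(xyz), tolerance = 1e-5,
               ignore_attr = TRUE)
  cell <- bio3d::read.dcd(f, cell = TRUE, verbose = FALSE)
  expect_equal(unname(cell[1, 1:3]), c(40, 40, 60))  # a, b, c
  audit <- aqpflux:::dcd_frame_audit(f)
  expect_equal(audit$natoms, na)
  expect_equal(audit$nframes_complete, nf)
  expect_false(audit$truncated)
})

test_that("synthetic export is readable by the real-mode reader", {
  spec <- langevin_spec(n_particles = 4, n_steps = 20, save_stride = 2,
                        seed = 5)
  b <- simulate_langevin(spec)
  stem <- tempfile()
  export_trajectory(b, stem)
  traj <- read_topology_and_trajectory(paste0(stem, ".pdb"),
                                       paste0(stem, ".dcd"))
  expect_equal(traj$n_frames, b$frames_count)
  expect_length(traj$water_ids, 4)
  # stride doubles the frame interval and halves the count
  tr2 <- read_topology_and_trajectory(paste0(stem, ".pdb"),
                                      paste0(stem, ".dcd"), frame_stride = 2)
  expect_equal(tr2$n_frames, ceiling(b$frames_count / 2))
  expect_equal(tr2$dt_frame, 2 * traj$dt_frame)
  # projected tracks reproduce the generator's z series (single precision)
  tracks <- project_md_tracks(traj, channel_frame("A"))
  expect_equal(tracks$z, b$z, tolerance = 1e-5, ignore_attr = TRUE)
  # per-frame recentring subtracts the reference drift
  drift <- seq(0, 1, length.out = traj$n_frames)
  shifted <- project_md_tracks(traj, channel_frame("A"), reference_z = drift)
  expect_equal(shifted$z, tracks$z - drift, tolerance = 1e-12)
  expect_error(project_md_tracks(traj, channel_frame("A"), reference_z = 1:2),
               "per frame")
})

test_that("reader errors are informative", {
  spec <- langevin_spec(n_particles = 3, n_steps = 6, seed = 2)
  b <- simulate_langevin(spec)
  stem <- tempfile()
  export_trajectory(b, stem)
  # atom-count mismatch: topology with an extra atom
  pdb2 <- tempfile(fileext = ".pdb")
  lines <- readLines(paste0(stem, ".pdb"))
  atom1 <- grep("^ATOM", lines, value = TRUE)[1]
  writeLines(append(lines, atom1, after = grep("^ATOM", lines)[3]), pdb2)
  expect_error(
    suppressWarnings(read_topology_and_trajectory(pdb2, paste0(stem, ".dcd"))),
    "atom-count mismatch")
  # empty selection
  expect_error(
    read_topology_and_trajectory(paste0(stem, ".pdb"), paste0(stem, ".dcd"),
                                 water_selection = list(resid = "GLY")),
    "matched no atoms")
  # truncated trajectory names the last good frame
  sz <- file.size(paste0(stem, ".dcd"))
  trunc <- tempfile(fileext = ".dcd")
  writeBin(readBin(paste0(stem, ".dcd"), "raw", sz - 10), trunc)
  expect_error(read_topology_and_trajectory(paste0(stem, ".pdb"), trunc),
               "truncated.*frame is [0-9]+")
})

test_that("PSF atom section parses into an atom table", {
  psf <- tempfile(fileext = ".psf")
  writeLines(c(
    "PSF", "", "       2 !NTITLE", " REMARKS test", "",
    "       3 !NATOM",
    "         1 WT1      1        TIP3     OH2      OT      -0.834000       15.9994           0",
    "         2 WT1      1        TIP3     H1       HT       0.417000        1.0080           0",
    "         3 WT1      1        TIP3     H2       HT       0.417000        1.0080           0",
    ""), psf)
  at <- read_psf_atoms(psf)
  expect_equal(nrow(at), 3)
  expect_equal(at$elety, c("OH2", "H1", "H2"))
  expect_equal(at$resid[1], "TIP3")
  expect_equal(at$mass[1], 15.9994)
})

test_that("trajectory cache round-trip is bit-exact", {
  spec <- langevin_spec(n_particles = 6, n_steps = 40, seed = 9)
  b <- simulate_langevin(spec)
  stem <- tempfile()
  write_trajectory_cache(b, stem)
  back <- read_trajectory_cache(stem)
  expect_identical(back$z, unname(b$z))
  expect_identical(back$vz, unname(b$vz))
  expect_identical(back$times, b$times)
  expect_equal(back$temperature, b$temperature)
})

test_that("molecules are assigned to the nearest monomer axis", {
  frames <- build_channel_frames(NULL, list(
    list(id = "A", origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(id = "B", origin = c(20, 0, 0), axis = c(0, 0, 1))
  ))
  xyz <- rbind(c(1, 0, 5),    # near A
               c(19, 0, 5),   # near B
               c(10, 0, 5),   # equidistant, outside both gates (d = 10 > 6)
               c(0, 0, 40))   # outside the slab entirely
  idx <- assign_to_monomers(xyz, frames)
  expect_equal(idx[1:2], c(1L, 2L))
  expect_true(is.na(idx[3]) && is.na(idx[4]))
})
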