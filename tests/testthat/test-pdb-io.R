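test_that("single-model PDB files parse into a structure that echoes the input", {
  path <- withr::local_tempfile(fileext = ".pdb")
  xyz <- matrix(c(1, 2, 3, 2, 2, 3), 2, 3, byrow = TRUE)
  write_fixture_pdb(path, list(xyz))
  s <- read_pdb(path)
  expect_s3_class(s, "md_structure")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(unname(s$coords), unname(xyz))
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$mass, c(14.007, 12.011))
})

test_that("multi-MODEL files become trajectories with default 0,1,2,... ps times", {
  path <- withr::local_tempfile(fileext = ".pdb")
  frames <- lapply(0:2, function(k) matrix(c(1 + k / 10, 2, 3, 2, 2, 3), 2, 3, byrow = TRUE))
  write_fixture_pdb(path, frames)
  tr <- read_pdb(path, model_policy = "all")
  expect_s3_class(tr, "md_trajectory")
  expect_equal(n_frames(tr), 3L)
  expect_equal(tr$times, c(0, 1, 2))
  expect_equal(unname(traj_frame(tr, 2)[1, 1]), 1.1)
  # model_policy = "first" gives just the first model
  s <- read_pdb(path, model_policy = "first")
  expect_s3_class(s, "md_structure")
  expect_equal(unname(s$coords[1, 1]), 1.0)
})

test_that("inconsistent atom counts across MODELs raise an error naming the model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  expect_error(read_pdb(path, model_policy = "all"), "MODEL 2")
})

test_that("files with no ATOM records are a parse error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), path)
  expect_error(read_pdb(path))
})

test_that("altloc conflicts resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  N   GLY A   1       0.000   1.000   0.000  1.00  0.00           N",
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(unname(s$coords[s$atoms$name == "CA", 1]), 1.0)
  # occupancy tie goes to altloc A
  writeLines(c(
    "ATOM      1  CA BGLY A   1       9.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  expect_equal(unname(read_pdb(path)$coords[1, 1]), 1.0)
})

test_that("PDB write/read round trip preserves coordinates to 3 decimals and atom identity", {
  base <- build_ideal_helix(6)
  traj <- simulate_fluctuations(base, sigma = 1.2, n_frames = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 3L)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3L)
  back <- read_pdb(path, model_policy = "all")
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(round(back$coords, 3), round(back$coords, 3))
  expect_equal(back$atoms$name, traj$atoms$name)
  expect_equal(back$atoms$resid, traj$atoms$resid)
  # second round trip is exact: values are already on the 3-decimal grid
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, path2)
  expect_equal(read_pdb(path2, model_policy = "all")$coords, back$coords)
})

test_that("coordinates too wide for PDB fixed-width fields are a format error", {
  s <- build_ideal_helix(4)
  s$coords[1, 1] <- 12345.0
  expect_error(write_pdb(s, withr::local_tempfile(fileext = ".pdb")), "10\\^4")
})

test_that("plain-text trajectory tables read with declared or default times", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "frame,time,name,resid,x,y,z",
    "1,0,CA,1,0,0,0", "1,0,CA,2,1,0,0", "1,0,CA,3,2,0,0",
    "2,10,CA,1,0,0,1", "2,10,CA,2,1,0,1", "2,10,CA,3,2,0,1"), path)
  tr <- read_xyz_table(path)
  expect_equal(n_frames(tr), 2L)
  expect_equal(nrow(tr$atoms), 3L)
  expect_equal(tr$times, c(0, 10))
  expect_equal(traj_frame(tr, 2)[, 3], rep(1, 3))

  # missing time column: warn and default to 0,1,2,...
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,name,resid,x,y,z",
               "1,CA,1,0,0,0", "2,CA,1,0,0,1"), path2)
  expect_warning(tr2 <- read_xyz_table(path2), "time")
  expect_equal(tr2$times, c(0, 1))

  # ragged frames are a structure error
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time,name,resid,x,y,z",
               "1,0,CA,1,0,0,0", "1,0,CA,2,1,0,0", "2,10,CA,1,0,0,1"), path3)
  expect_error(read_xyz_table(path3), "ragged")
})

test_that("the mass table gives one consistent glycine backbone mass", {
  expected <- 14.007 + 12.011 + 12.011 + 15.999  # N + CA + C + O
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(path, list(matrix(rnorm(12), 4, 3)))
  s <- read_pdb(path)
  expect_equal(sum(s$atoms$mass), expected)
  # same masses wherever M is needed (element-keyed lookup)
  expect_equal(sum(trajmetrics:::mass_of(c("N", "C", "C", "O"))), expected)
})
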