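# Ensemble model: multi-model PDB I/O, region selection, component stripping.

test_that("loading multi-model PDBs gives correct bookkeeping and round-trips coordinates", {
  toy <- generate_toy_ensemble(toy_ensemble_spec(n_replicas = 2, n_frames = 5, seed = 42))
  dir <- withr::local_tempdir()
  paths <- write_toy_ensemble(toy, dir)
  rc <- read_region_config(paths$regions)
  ens <- load_ensemble(paths$bound, "bound", rc$chain_components)

  expect_s3_class(ens, "trajectory_ensemble")
  expect_identical(length(ens$xyz), 2L)
  expect_identical(unname(vapply(ens$xyz, nrow, 1L)), c(5L, 5L))
  expect_identical(nrow(ens$topology), nrow(toy$bound$topology))
  # PDB stores 3 decimals
  expect_equal(ens$xyz[[1]], toy$bound$xyz[[1]], tolerance = 1e-3,
               ignore_attr = TRUE)

  # write the loaded ensemble out again; reload reproduces it exactly
  p2 <- file.path(dir, c("rt1.pdb", "rt2.pdb"))
  write_ensemble(ens, p2)
  ens2 <- load_ensemble(p2, "bound", rc$chain_components)
  expect_equal(ens2$xyz, ens$xyz, ignore_attr = TRUE)
  expect_identical(ens2$topology$chain_id, ens$topology$chain_id)
  expect_identical(ens2$topology$residue_seq, ens$topology$residue_seq)
  # derived H-bond roles survive the round trip
  expect_identical(ens2$topology$donor, ens$topology$donor)
  expect_identical(ens2$topology$polar_h, ens$topology$polar_h)

  # a single-model single-file ensemble is a usable static trajectory
  one <- subset_frames(ens, 1L)
  p1 <- file.path(dir, c("single.pdb", "single2.pdb"))
  write_ensemble(one, p1)
  p1 <- p1[1]
  ens1 <- load_ensemble(p1, "unbound", rc$chain_components)
  expect_identical(unname(n_frames(ens1)), 1L)
  expect_s3_class(radius_of_gyration(ens1, toy$regions$CDR_A), "descriptor_series")
})

test_that("malformed or inconsistent trajectory files raise classed errors", {
  toy <- generate_toy_ensemble(toy_ensemble_spec(n_replicas = 2, n_frames = 3, seed = 7))
  dir <- withr::local_tempdir()
  paths <- write_toy_ensemble(toy, dir)
  rc <- read_region_config(paths$regions)

  # a MODEL missing one atom's coordinates
  lines <- readLines(paths$bound[1])
  atom_lines <- grep("^ATOM", lines)
  broken <- lines[-atom_lines[length(atom_lines)]]
  bad <- file.path(dir, "bad.pdb")
  writeLines(broken, bad)
  expect_error(load_ensemble(bad, "bound", rc$chain_components),
               class = "ensdiff_topology_error")

  # files that do not share a topology
  expect_error(load_ensemble(c(paths$bound[1], paths$unbound[1]), "bound",
                             rc$chain_components),
               class = "ensdiff_topology_error")

  # chain with no component mapping
  expect_error(load_ensemble(paths$bound, "bound", c(A = "receptor_alpha")),
               class = "ensdiff_config_error")

  # file with no models at all
  empty <- file.path(dir, "empty.pdb")
  writeLines("END", empty)
  expect_error(load_ensemble(empty, "bound", rc$chain_components),
               class = "ensdiff_error")
})

test_that("region selection is positional, ordered, idempotent, and errors when empty", {
  topo <- toy_topology(40, residue_seq = rep(1:10, each = 4))
  reg <- region_def("mid", "A", 5, 7)
  idx <- select_region(topo, reg)
  expect_length(idx, 12L)
  expect_identical(idx, select_region(topo, reg))          # idempotent
  expect_identical(idx, sort(idx))                         # topology order

  nxt <- select_region(topo, region_def("next", "A", 8, 9))
  expect_length(intersect(idx, nxt), 0L)
  expect_identical(sort(c(idx, nxt)), c(idx, nxt))         # union preserves order

  expect_error(select_region(topo, region_def("ghost", "Z", 1, 5)),
               class = "ensdiff_empty_region_error")
  expect_error(region_def("rev", "A", 7, 5), class = "ensdiff_argument_error")
})

test_that("strip_component projects atoms, is identity for all components, and commutes with frame subsetting", {
  toy <- generate_toy_ensemble(toy_ensemble_spec(n_replicas = 2, n_frames = 6, seed = 9))
  b <- toy$bound
  tcr <- strip_component(b, c("receptor_alpha", "receptor_beta"))
  keep_idx <- which(b$topology$component %in% c("receptor_alpha", "receptor_beta"))
  expect_identical(nrow(tcr$topology), length(keep_idx))
  expect_equal(tcr$xyz[[1]], b$xyz[[1]][, ensdiff:::xyz_cols(keep_idx)],
               ignore_attr = TRUE)

  ident <- strip_component(b, unique(b$topology$component))
  expect_equal(ident$xyz, b$xyz)

  a <- subset_frames(strip_component(b, "receptor_alpha"), 2:3)
  bb <- strip_component(subset_frames(b, 2:3), "receptor_alpha")
  expect_equal(a$xyz, bb$xyz)

  expect_error(strip_component(b, character(0)), class = "ensdiff_argument_error")
  expect_error(strip_component(b, "ligand_peptide"), class = "ensdiff_empty_input_error")
})
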