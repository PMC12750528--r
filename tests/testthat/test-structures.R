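test_that("parsing handles empty, minimal and altloc'd coordinate files", {
  # empty coordinate section
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), empty)
  expect_equal(nrow(parse_structure(empty)), 0)

  # five atoms, one ZN heteroatom
  f <- withr::local_tempfile(fileext = ".pdb")
  rows <- dplyr::bind_rows(
    pdb_row(name = "N", resno = 1, x = 0, element = "N"),
    pdb_row(name = "CA", resno = 1, x = 1.5, element = "C"),
    pdb_row(name = "C", resno = 1, x = 3.0, element = "C"),
    pdb_row(name = "O", resno = 1, x = 4.0, element = "O"),
    pdb_row(type = "HETATM", name = "ZN", resid = "ZN", resno = 2,
            x = 10, element = "Zn")
  )
  write_pdb_lines(f, rows)
  expect_equal(sum(grepl("^(ATOM|HETATM)", readLines(f))), 5)
  atoms <- parse_structure(f)
  expect_equal(nrow(atoms), 5)
  expect_equal(sum(atoms$element == "Zn"), 1)
  expect_false(atoms$is_polymer[atoms$element == "Zn"])
  expect_true(all(atoms$is_polymer[atoms$element != "Zn"]))

  # altloc collapse: occupancy 0.6 beats 0.4; tie goes to altloc A
  g <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(g, dplyr::bind_rows(
    pdb_row(name = "CA", altloc = "A", occ = 0.6, x = 0),
    pdb_row(name = "CA", altloc = "B", occ = 0.4, x = 1),
    pdb_row(name = "CB", altloc = "B", occ = 0.5, x = 5, resno = 2),
    pdb_row(name = "CB", altloc = "A", occ = 0.5, x = 6, resno = 2),
    pdb_row(name = "CG", altloc = "A", occ = 0.3, x = 8, resno = 3),
    pdb_row(name = "CG", altloc = "B", occ = 0.7, x = 9, resno = 3)
  ))
  got <- parse_structure(g)
  expect_equal(nrow(got), 3)
  expect_equal(got$altloc[got$atom_name == "CA"], "A")
  expect_equal(got$x[got$atom_name == "CA"], 0)
  expect_equal(got$altloc[got$atom_name == "CB"], "A")
  # occupancy beats the alphabetical default: conformer B wins here
  expect_equal(got$altloc[got$atom_name == "CG"], "B")
  expect_equal(got$x[got$atom_name == "CG"], 9)
})

test_that("unknown element symbols are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(f, dplyr::bind_rows(
    pdb_row(name = "CA", element = "C"),
    pdb_row(name = "XX", resno = 2, x = 3, element = "Xx")
  ))
  expect_warning(atoms <- parse_structure(f), "unknown element")
  expect_equal(nrow(atoms), 1)
  expect_equal(atoms$element, "C")
})

test_that("pdb and mmcif dialects parse to the same atoms", {
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TST", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
      "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    )),
    "ATOM 1 S SG . CYS A 1 1 ? 2.300 0.000 0.000 1.00 0.00 ? 1 CYS A SG 1",
    "HETATM 2 ZN ZN . ZN A 1 . ? 0.000 0.000 0.000 1.00 0.00 ? 2 ZN A ZN 1"
  ), cif)
  atoms <- parse_structure(cif, dialect = "mmcif")
  expect_equal(nrow(atoms), 2)
  expect_setequal(atoms$element, c("S", "Zn"))
  expect_false(atoms$is_polymer[atoms$element == "Zn"])

  sites <- detect_metal_sites(atoms)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$n_donors, 1)
})

test_that("site detection finds donors, flags adventitious ions, errors on
           degenerate structures", {
  # Zn at origin, four Cys S at 2.30 A, one water O at 4.0 A
  zn <- atoms_tbl(
    atom_row("Zn", 0, 0, 0, is_polymer = FALSE, res_name = "ZN",
             res_seq = 99),
    atom_row("S", 2.3, 0, 0, res_seq = 1, atom_name = "SG1",
             res_name = "CYS"),
    atom_row("S", -2.3, 0, 0, res_seq = 2, atom_name = "SG2",
             res_name = "CYS"),
    atom_row("S", 0, 2.3, 0, res_seq = 3, atom_name = "SG3",
             res_name = "CYS"),
    atom_row("S", 0, -2.3, 0, res_seq = 4, atom_name = "SG4",
             res_name = "CYS"),
    atom_row("O", 0, 0, 4.0, is_polymer = FALSE, res_name = "HOH",
             res_seq = 100)
  )
  sites <- detect_metal_sites(zn)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$n_donors, 4)
  expect_equal(sites$attributed_chain, "A")
  expect_false(sites$adventitious)
  expect_equal(sites$donors[[1]]$distance, rep(2.3, 4))

  # oracle agreement on the same structure
  orc <- oracle_metal_sites(zn, annotation_config())
  expect_equal(length(orc), 1)
  expect_setequal(
    paste(sites$donors[[1]]$chain_id, sites$donors[[1]]$res_seq,
          sites$donors[[1]]$atom_name, sep = "/"),
    orc[[1]]$donor_keys
  )

  # Na with nearest polymer donor beyond the 3.0 A cutoff -> adventitious
  na <- atoms_tbl(
    atom_row("Na", 0, 0, 0, is_polymer = FALSE, res_name = "NA",
             res_seq = 50),
    atom_row("O", 3.4, 0, 0, res_seq = 1, atom_name = "OD1")
  )
  s2 <- detect_metal_sites(na)
  expect_true(s2$adventitious)
  expect_true(is.na(s2$attributed_chain))

  # waters may be enabled as donors
  s3 <- detect_metal_sites(zn, annotation_config(include_waters = TRUE,
                                                 cutoff = 4.0))
  expect_equal(s3$n_donors, 5)

  # no metal atoms at all
  expect_equal(nrow(detect_metal_sites(zn[zn$element != "Zn", ])), 0)

  # two metals on identical coordinates
  dup <- atoms_tbl(
    atom_row("Zn", 1, 1, 1, is_polymer = FALSE),
    atom_row("Fe", 1, 1, 1, is_polymer = FALSE)
  )
  expect_error(detect_metal_sites(dup), "degenerate")
})

test_that("detection equals the all-pairs oracle on random structures and
           donors grow monotonically with the cutoff", {
  set.seed(202)
  cfg <- annotation_config()
  wide <- annotation_config(cutoff = 4.5)
  for (rep in 1:25) {
    atoms <- random_structure(sample(20:200, 1))
    # drop exact metal duplicates the generator cannot produce anyway
    sites <- detect_metal_sites(atoms, cfg)
    orc <- oracle_metal_sites(atoms, cfg)
    expect_equal(nrow(sites), length(orc))
    for (k in seq_along(orc)) {
      expect_equal(sites$metal[k], orc[[k]]$metal)
      keys <- paste(sites$donors[[k]]$chain_id, sites$donors[[k]]$res_seq,
                    sites$donors[[k]]$atom_name, sep = "/")
      expect_equal(keys, orc[[k]]$donor_keys)
      expect_equal(sites$donors[[k]]$distance, orc[[k]]$distances,
                   tolerance = 1e-12)
      expect_identical(sites$adventitious[k], orc[[k]]$n_polymer == 0)
    }
    # monotonicity: a larger cutoff never removes a donor
    sites_wide <- detect_metal_sites(atoms, wide)
    for (k in seq_len(nrow(sites))) {
      narrow_keys <- paste(sites$donors[[k]]$res_seq,
                           sites$donors[[k]]$atom_name)
      wide_keys <- paste(sites_wide$donors[[k]]$res_seq,
                         sites_wide$donors[[k]]$atom_name)
      expect_true(all(narrow_keys %in% wide_keys))
    }
  }
})

test_that("stoichiometry counts non-adventitious sites per chain and
           partitions them exactly", {
  empty <- detect_metal_sites(atoms_tbl(atom_row("C", 0, 0, 0)))
  expect_equal(nrow(stoichiometry_from_sites(empty)), 0)

  sites <- tibble::tibble(
    site_id = paste0("s", 1:4),
    metal = c("Zn", "Zn", "Fe", "Na"),
    x = 1:4, y = 0, z = 0,
    n_donors = c(4L, 4L, 6L, 1L), n_polymer_donors = c(4L, 4L, 6L, 0L),
    attributed_chain = c("A", "A", "B", NA),
    adventitious = c(FALSE, FALSE, FALSE, TRUE),
    donors = list(NULL, NULL, NULL,
                  tibble::tibble(chain_id = "A", distance = 2.5))
  )
  st_a <- stoichiometry_from_sites(sites, chain_id = "A")
  expect_equal(st_a$metal, "Zn")
  expect_equal(st_a$count, 2L)

  all_chains <- stoichiometry_from_sites(sites)
  expect_equal(sum(all_chains$count), sum(!sites$adventitious))

  # adventitious Na + bound Mg -> only Mg
  mg <- atoms_tbl(
    atom_row("Mg", 0, 0, 0, is_polymer = FALSE, res_seq = 90),
    atom_row("O", 2.1, 0, 0, res_seq = 1, atom_name = "OD1"),
    atom_row("Na", 30, 30, 30, is_polymer = FALSE, res_seq = 91)
  )
  st <- stoichiometry_from_sites(detect_metal_sites(mg))
  expect_equal(st$metal, "Mg")
  expect_equal(st$count, 1L)
})

test_that("chain attribution ties break to the lexicographically smallest
           chain and the chain partition is conserved", {
  tie <- atoms_tbl(
    atom_row("Zn", 0, 0, 0, is_polymer = FALSE, res_seq = 99),
    atom_row("N", 2.0, 0, 0, chain_id = "B", res_seq = 1,
             atom_name = "ND1"),
    atom_row("N", -2.0, 0, 0, chain_id = "A", res_seq = 2,
             atom_name = "ND2")
  )
  sites <- detect_metal_sites(tie)
  expect_equal(sites$attributed_chain, "A")

  set.seed(99)
  for (rep in 1:10) {
    atoms <- random_structure(150)
    sites <- detect_metal_sites(atoms)
    st <- stoichiometry_from_sites(sites)
    expect_equal(sum(st$count), sum(!sites$adventitious))
  }
})

test_that("the annotation store round-trips through JSON including apo
           chains", {
  gen <- generate_structures(6, metal_menu = c("Zn", "Fe", "Cu"),
                             seed = 42)
  store <- annotate_templates(gen$paths)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation_store(store, f)
  back <- read_annotation_store(f)
  expect_equal(
    dplyr::arrange(back, template_id, chain_id, metal),
    dplyr::arrange(store, template_id, chain_id, metal)
  )
  expect_true(any(back$count == 0)) # apo chains preserved
})
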