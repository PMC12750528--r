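# Independent oracles and small fixture builders shared across tests.

# Build an atom table row-by-row without touching the parser.
atom_row <- function(element, x, y, z, chain_id = "A", res_name = "GLY",
                     res_seq = 1L, is_polymer = TRUE, occupancy = 1,
                     altloc = "", atom_name = element) {
  tibble::tibble(
    element = element, x = x, y = y, z = z, chain_id = chain_id,
    res_name = res_name, res_seq = as.integer(res_seq), ins_code = "",
    atom_name = atom_name, is_polymer = is_polymer,
    occupancy = occupancy, altloc = altloc
  )
}

atoms_tbl <- function(...) dplyr::bind_rows(...)

# O(n^2) all-pairs distance-scan oracle for metal-site detection: a full
# distance matrix via dist(), then donor selection by explicit filtering.
# Independent of the per-metal vectorised path used by the implementation.
oracle_metal_sites <- function(atoms, config) {
  n <- nrow(atoms)
  D <- as.matrix(dist(atoms[, c("x", "y", "z")]))
  waters <- atoms$res_name %in% c("HOH", "WAT", "DOD", "H2O")
  is_metal <- atoms$element %in% config$metals
  donor_ok <- atoms$element %in% config$donors & !is_metal &
    (config$include_waters | !waters)
  metal_idx <- which(is_metal)
  lapply(metal_idx, function(i) {
    js <- which(donor_ok & D[i, ] > 0 & D[i, ] <= config$cutoff)
    js <- js[order(D[i, js])]
    list(
      metal = atoms$element[i],
      donor_keys = paste(atoms$chain_id[js], atoms$res_seq[js],
                         atoms$atom_name[js], sep = "/"),
      distances = unname(D[i, js]),
      n_polymer = sum(atoms$is_polymer[js])
    )
  })
}

# Textbook pooled-variance two-sample t-test, written out long-hand.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = na + nb - 2)
  list(statistic = tstat, p = p)
}

# Pearson r^2 from the closed-form sums, no call to cor().
oracle_r_squared <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Fixed-format PDB writer for hand-crafted parser fixtures (altlocs,
# unknown elements, ...). Kept separate from the generator's bio3d route.
write_pdb_lines <- function(path, rows, trailer = "END") {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      r$type, i, r$name, r$altloc, r$resid, r$chain, r$resno, " ",
      r$x, r$y, r$z, r$occ, 0, r$element
    )
  }, character(1))
  writeLines(c(lines, trailer), path)
  path
}

pdb_row <- function(type = "ATOM", name = "CA", altloc = "", resid = "GLY",
                    chain = "A", resno = 1L, x = 0, y = 0, z = 0, occ = 1,
                    element = "C") {
  tibble::tibble(type = type, name = name, altloc = altloc, resid = resid,
                 chain = chain, resno = as.integer(resno),
                 x = x, y = y, z = z, occ = occ, element = element)
}

# Random atom cloud (<= 200 atoms) for the oracle-equivalence property.
random_structure <- function(n_atoms, metals = c("Zn", "Fe", "Mn", "Na")) {
  pool <- c("C", "C", "N", "O", "S", metals)
  out <- tibble::tibble(
    element = sample(pool, n_atoms, replace = TRUE),
    x = runif(n_atoms, 0, 15), y = runif(n_atoms, 0, 15),
    z = runif(n_atoms, 0, 15),
    chain_id = sample(c("A", "B"), n_atoms, replace = TRUE),
    res_name = "GLY", res_seq = seq_len(n_atoms), ins_code = "",
    atom_name = paste0("X", seq_len(n_atoms)),
    is_polymer = sample(c(TRUE, TRUE, TRUE, FALSE), n_atoms, replace = TRUE),
    occupancy = 1, altloc = ""
  )
  # metals are heteroatoms, and identical metal positions are forbidden
  out$is_polymer <- out$is_polymer & !out$element %in% metals
  out[!duplicated(out[, c("x", "y", "z")]), ]
}

# Minimal annotation tibble: one row per (protein, metal, count).
ann_tbl <- function(protein_id, metal, count = 1L, confidence = 99) {
  tibble::tibble(protein_id = protein_id, metal = metal,
                 count = as.integer(count), template_id = "T001",
                 chain_id = "A", confidence = confidence)
}

# Long quant tibble from a named list of per-sample intensity vectors.
quant_tbl <- function(values, proteins = NULL, groups = NULL) {
  samples <- names(values)
  n <- length(values[[1]])
  if (is.null(proteins)) proteins <- sprintf("p%d", seq_len(n))
  if (is.null(groups)) groups <- setNames(samples, samples)
  purrr::map2(values, samples, function(v, s) {
    tibble::tibble(protein_id = proteins, sample_id = s,
                   group = unname(groups[s]), intensity = v)
  }) |> dplyr::bind_rows()
}
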