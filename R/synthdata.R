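# Coupled synthetic-data generators. Every stage of the pipeline can be
# exercised against known ground truth: planted template structures, a
# fold-recognition match table whose confidences straddle the 95% rule,
# replicate intensity matrices with log-normal noise, and quota tables
# decomposed into protein-bound metal, free-ion pools and luxury-uptake
# factors.

#' Default metal menu for simulations
#'
#' The ten metals most discussed for phytoplankton metallomes: the
#' macro-elements Mg, Ca and K plus the trace metals Fe, Zn, Mn, Cu, Ni,
#' Co and Mo.
#'
#' @return Character vector of element symbols.
#' @export
default_metal_menu <- function() {
  c("Mg", "Ca", "K", "Fe", "Zn", "Mn", "Cu", "Ni", "Co", "Mo")
}

#' Generate template structures with planted metal sites
#'
#' Writes minimal valid PDB files, each a single polymer chain ("A") with
#' planted metal ions whose donor atoms (N/O/S) sit at 2.0-2.6 Angstrom,
#' plus a decoy solvent ion and waters beyond the cutoff (an adventitious
#' site that must not enter stoichiometry). Roughly `frac_apo` of the
#' templates carry no metal at all. Identical seeds give byte-identical
#' files.
#'
#' @param n_templates Number of templates (>= 1).
#' @param metal_menu Metals to plant; each appears in at least one template
#'   when `n_templates` allows.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param frac_apo Fraction of metal-free templates.
#' @param max_sites Maximum planted sites per metal-bearing template.
#'
#' @return A list with `paths` (PDB files), `truth` (tibble `template_id`,
#'   `chain_id`, `metal`, `count`; apo chains as `metal = NA, count = 0`)
#'   and `manifest` (the parameters used).
#' @export
generate_structures <- function(n_templates, metal_menu = default_metal_menu(),
                                seed = 1, dir = tempfile("templates"),
                                frac_apo = 0.2, max_sites = 2) {
  stopifnot(n_templates >= 1)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  n_apo <- min(n_templates - 1, round(frac_apo * n_templates))
  if (n_templates == 1) n_apo <- 0
  n_holo <- n_templates - n_apo
  # guarantee menu coverage before sampling freely
  first <- rep_len(metal_menu, min(n_holo, length(metal_menu)))

  truth <- vector("list", n_templates)
  paths <- character(n_templates)
  for (i in seq_len(n_templates)) {
    tid <- sprintf("T%03d", i)
    holo <- i <= n_holo
    site_metals <- if (!holo) character() else if (i <= length(first)) {
      first[i]
    } else {
      sample(metal_menu, sample.int(max_sites, 1), replace = TRUE)
    }
    paths[i] <- .write_template_pdb(file.path(dir, paste0(tid, ".pdb")),
                                    site_metals)
    truth[[i]] <- if (holo) {
      tibble::tibble(template_id = tid, chain_id = "A") |>
        dplyr::bind_cols(
          tibble::as_tibble(table(metal = site_metals)) |>
            dplyr::rename(count = "n") |>
            dplyr::mutate(count = as.integer(.data$count))
        )
    } else {
      tibble::tibble(template_id = tid, chain_id = "A",
                     metal = NA_character_, count = 0L)
    }
  }
  list(
    paths = paths,
    truth = dplyr::bind_rows(truth),
    manifest = list(n_templates = n_templates, metal_menu = metal_menu,
                    seed = seed, dir = dir, frac_apo = frac_apo,
                    max_sites = max_sites)
  )
}

# One chain of backbone carbons plus, per site, donor atoms at 2.0-2.6 A;
# decoys: an isolated Na with only a water nearby, and free waters.
.write_template_pdb <- function(path, site_metals) {
  rows <- list()
  resno <- 0L
  # polymer scaffold: a short carbon backbone well away from the sites
  for (k in 1:6) {
    resno <- resno + 1L
    rows[[length(rows) + 1]] <- data.frame(
      type = "ATOM", elety = "CA", resid = "GLY", chain = "A",
      resno = resno, x = 100 + 3.8 * k, y = 100, z = 100,
      o = 1, elesy = "C"
    )
  }
  for (s in seq_along(site_metals)) {
    centre <- c(20 * s, 0, 0)
    n_don <- sample(3:6, 1)
    for (d in seq_len(n_don)) {
      resno <- resno + 1L
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- centre + runif(1, 2.0, 2.6) * u
      el <- sample(c("N", "O", "S"), 1)
      rows[[length(rows) + 1]] <- data.frame(
        type = "ATOM", elety = paste0(el, "D"), resid = "CYS", chain = "A",
        resno = resno, x = pos[1], y = pos[2], z = pos[3],
        o = 1, elesy = el
      )
    }
    resno <- resno + 1L
    rows[[length(rows) + 1]] <- data.frame(
      type = "HETATM", elety = toupper(site_metals[s]),
      resid = toupper(site_metals[s]),
      chain = "A", resno = resno,
      x = centre[1], y = centre[2], z = centre[3],
      o = 1, elesy = site_metals[s]
    )
  }
  # adventitious decoy: Na with its nearest (water) oxygen at 3.5 A
  resno <- resno + 1L
  rows[[length(rows) + 1]] <- data.frame(
    type = "HETATM", elety = "NA", resid = "NA", chain = "A",
    resno = resno, x = -50, y = -50, z = -50, o = 1, elesy = "Na"
  )
  resno <- resno + 1L
  rows[[length(rows) + 1]] <- data.frame(
    type = "HETATM", elety = "O", resid = "HOH", chain = "A",
    resno = resno, x = -50, y = -50, z = -46.5, o = 1, elesy = "O"
  )
  at <- do.call(rbind, rows)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = at$type, resno = at$resno, resid = at$resid,
    chain = at$chain, eleno = seq_len(nrow(at)), elety = at$elety,
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy
  )
  path
}

#' Generate an expressed proteome and its fold-recognition match table
#'
#' Each metalloprotein receives one passing match (confidence strictly
#' above 95) to a metal-bearing template; annotated non-metalloproteins
#' receive a passing match to an apo template; the rest receive
#' sub-threshold decoy matches or none. A fraction of metalloproteins also
#' carries extra sub-threshold decoy matches that a correct pipeline must
#' ignore.
#'
#' @param templates Template truth tibble (from [generate_structures()]).
#' @param n_proteins Number of expressed proteins.
#' @param frac_metalloproteins Fraction carrying metal (default 0.37, the
#'   share observed in expressed phytoplankton proteomes).
#' @param frac_apo_annotated Fraction of the non-metalloproteins given a
#'   passing match to an apo template.
#' @param decoy_rate Fraction of proteins given an extra sub-threshold
#'   match.
#' @param seed Integer seed.
#'
#' @return A list with `matches` (tibble `query_id`, `template_id`,
#'   `chain_id`, `confidence`), `truth_annotations` (planted per-protein
#'   stoichiometries), `truth_proteins` (per-protein metadata) and
#'   `manifest`.
#' @export
generate_proteome <- function(templates, n_proteins = 300,
                              frac_metalloproteins = 0.37,
                              frac_apo_annotated = 0.5,
                              decoy_rate = 0.2, seed = 1) {
  stopifnot(frac_metalloproteins >= 0, frac_metalloproteins <= 1)
  set.seed(seed)
  holo <- unique(templates$template_id[!is.na(templates$metal) &
                                         templates$count > 0])
  apo <- setdiff(unique(templates$template_id), holo)
  if (frac_metalloproteins > 0 && length(holo) == 0) {
    stop("no metal-bearing templates available")
  }

  ids <- sprintf("P%04d", seq_len(n_proteins))
  n_metallo <- round(frac_metalloproteins * n_proteins)
  is_metallo <- seq_len(n_proteins) <= n_metallo

  chosen <- character(n_proteins)
  chosen[is_metallo] <- sample(holo, n_metallo, replace = TRUE)
  n_other <- n_proteins - n_metallo
  apo_annot <- is_metallo == FALSE &
    seq_len(n_proteins) <= n_metallo + round(frac_apo_annotated * n_other)
  if (length(apo) > 0) {
    chosen[apo_annot] <- sample(apo, sum(apo_annot), replace = TRUE)
  } else {
    apo_annot[] <- FALSE
  }

  passing <- is_metallo | apo_annot
  matches <- tibble::tibble(
    query_id = ids[passing],
    template_id = chosen[passing],
    chain_id = "A",
    confidence = runif(sum(passing), 95.1, 100)
  )
  # sub-threshold decoys: never annotated, whatever template they hit
  decoy_for <- runif(n_proteins) < decoy_rate
  all_templates <- unique(templates$template_id)
  decoys <- tibble::tibble(
    query_id = ids[decoy_for],
    template_id = sample(all_templates, sum(decoy_for), replace = TRUE),
    chain_id = "A",
    confidence = runif(sum(decoy_for), 40, 95)
  )
  matches <- dplyr::bind_rows(matches, decoys) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$confidence))

  truth_annotations <- tibble::tibble(protein_id = ids[is_metallo],
                                      template_id = chosen[is_metallo]) |>
    dplyr::inner_join(
      templates[!is.na(templates$metal) & templates$count > 0,
                c("template_id", "metal", "count")],
      by = "template_id", relationship = "many-to-many"
    ) |>
    dplyr::select("protein_id", "metal", "count") |>
    dplyr::arrange(.data$protein_id, .data$metal)

  list(
    matches = matches,
    truth_annotations = truth_annotations,
    truth_proteins = tibble::tibble(
      protein_id = ids, is_metalloprotein = is_metallo,
      template_id = dplyr::if_else(passing, chosen, NA_character_)
    ),
    manifest = list(n_proteins = n_proteins,
                    frac_metalloproteins = frac_metalloproteins,
                    frac_apo_annotated = frac_apo_annotated,
                    decoy_rate = decoy_rate, seed = seed)
  )
}

#' Generate a replicate intensity table with known effects
#'
#' Per-protein base intensities are log-normal (wide dynamic range, as in
#' label-free LC-MS). Each measured intensity is
#' `base x group effect x exp(N(0, sigma_log^2))`. Missing values are
#' injected at an overall rate of `missing_rate` but preferentially in
#' low-abundance proteins (linearly decreasing in the protein's base-
#' intensity rank), the censoring pattern of label-free LC-MS, where
#' peptides near the detection limit drop out while dominant proteins are
#' always seen. Group effects are
#' specified per metal and applied multiplicatively to every protein
#' binding that metal (the route by which a planted expression difference
#' propagates into the reconstructed metallome).
#'
#' @param proteome Output of [generate_proteome()].
#' @param groups Group (strain) labels.
#' @param n_replicates Replicates per group.
#' @param sigma_log Log-normal noise sigma (natural log scale).
#' @param group_effects Named list: `list(OA16 = c(Cu = 2))` doubles every
#'   Cu-binding protein in group "OA16". Multiple applicable effects
#'   multiply.
#' @param missing_rate Overall fraction of intensities censored to NA.
#' @param base_meanlog,base_sdlog Parameters of the base-intensity
#'   log-normal.
#' @param seed Integer seed.
#'
#' @return A list with `quant` (long intensity tibble), `truth_bound`
#'   (tibble `group`, `metal`, `bound`: the noise-free expected relative
#'   metallome of each group) and `manifest`.
#' @export
generate_quant <- function(proteome, groups = c("OA1", "OA16"),
                           n_replicates = 3, sigma_log = 0.1,
                           group_effects = NULL, missing_rate = 0.05,
                           base_meanlog = log(1e6), base_sdlog = 1.5,
                           seed = 1) {
  set.seed(seed)
  ids <- proteome$truth_proteins$protein_id
  n <- length(ids)
  base <- rlnorm(n, base_meanlog, base_sdlog)
  names(base) <- ids
  # censoring probability decreases linearly with base-intensity rank;
  # mean over proteins equals missing_rate
  p_miss <- pmin(1, 2 * missing_rate * (1 - (rank(base) - 0.5) / n))
  names(p_miss) <- ids

  effect <- matrix(1, nrow = n, ncol = length(groups),
                   dimnames = list(ids, groups))
  ann <- proteome$truth_annotations
  for (g in names(group_effects)) {
    for (m in names(group_effects[[g]])) {
      hit <- unique(ann$protein_id[ann$metal == m & ann$count > 0])
      effect[hit, g] <- effect[hit, g] * group_effects[[g]][[m]]
    }
  }

  quant <- tidyr::crossing(
    protein_id = ids, group = groups, replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = paste0(.data$group, "_r", .data$replicate),
      intensity = unname(base[.data$protein_id]) *
        unname(effect[cbind(.data$protein_id, .data$group)]) *
        exp(rnorm(dplyr::n(), 0, sigma_log)),
      intensity = dplyr::if_else(
        runif(dplyr::n()) < unname(p_miss[.data$protein_id]),
        NA_real_, .data$intensity
      )
    ) |>
    dplyr::select("protein_id", "sample_id", "group", "intensity") |>
    dplyr::arrange(.data$sample_id, .data$protein_id)

  # noise-free expectation of the relative metallome, per group
  truth_bound <- purrr::map(groups, function(g) {
    rel <- base * effect[, g]
    rel <- rel / sum(rel)
    ann |>
      dplyr::mutate(contrib = rel[.data$protein_id] * .data$count) |>
      dplyr::group_by(.data$metal) |>
      dplyr::summarise(bound = sum(.data$contrib), .groups = "drop") |>
      dplyr::mutate(group = g, .before = 1)
  }) |> dplyr::bind_rows()

  list(
    quant = quant, truth_bound = truth_bound,
    manifest = list(groups = groups, n_replicates = n_replicates,
                    sigma_log = sigma_log, group_effects = group_effects,
                    missing_rate = missing_rate,
                    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                    seed = seed)
  )
}

#' Generate ICP-MS-style quota tables from ground truth
#'
#' Per strain and metal, the quota is
#' `scale x (bound + free) x luxury x (1 + eps)` with
#' `eps ~ N(0, rel_sd^2)` truncated above -1: the protein-bound component
#' from the true metallome, a free-ion pool invisible to proteome
#' inference (Ca/Mg/K excess), and a luxury-uptake multiplier (e.g. Fe
#' stored beyond metabolic need).
#'
#' @param truth_bound Tibble `group`, `metal`, `bound` from
#'   [generate_quant()].
#' @param free_pool Named vector of free-ion pools in bound-abundance
#'   units (default: none).
#' @param luxury Named list per group: `list(OA16 = c(Fe = 2))`.
#' @param scale Multiplier converting bound-abundance units to
#'   mmol/mol C.
#' @param rel_sd Relative SD of the quota noise and of the reported
#'   measurement SD.
#' @param n_replicates Reported replicate count.
#' @param seed Integer seed.
#'
#' @return A list with `quotas` (tibble `strain`, `metal`, `mean_quota`,
#'   `sd`, `n`) and `manifest`.
#' @export
generate_quotas <- function(truth_bound, free_pool = NULL, luxury = NULL,
                            scale = 100, rel_sd = 0.05, n_replicates = 3,
                            seed = 1) {
  set.seed(seed)
  q <- truth_bound |>
    dplyr::mutate(
      free = if (is.null(free_pool)) 0 else
        dplyr::coalesce(unname(free_pool[.data$metal]), 0),
      lux = purrr::map2_dbl(.data$group, .data$metal, function(g, m) {
        v <- luxury[[g]]
        if (is.null(v) || !m %in% names(v)) 1 else unname(v[[m]])
      }),
      eps = pmax(rnorm(dplyr::n(), 0, rel_sd), -0.999),
      mean_quota = scale * (.data$bound + .data$free) * .data$lux *
        (1 + .data$eps),
      sd = rel_sd * .data$mean_quota,
      n = as.integer(n_replicates)
    ) |>
    dplyr::select(strain = "group", "metal", "mean_quota", "sd", "n") |>
    dplyr::arrange(.data$strain, .data$metal)
  list(
    quotas = q,
    manifest = list(free_pool = free_pool, luxury = luxury, scale = scale,
                    rel_sd = rel_sd, n_replicates = n_replicates,
                    seed = seed)
  )
}

#' Simulate a complete metallome study
#'
#' Chains the four generators into one coupled dataset: template
#' structures on disk, a match table, a replicate intensity table and
#' quota tables, plus every layer of ground truth. Defaults describe a
#' two-strain study with triplicate label-free proteomics (log-normal
#' noise sigma 0.1), a 37% metalloproteome, and quotas proportional to the
#' protein-bound metallome (no free pools, no luxury uptake) so that
#' departures are always planted explicitly.
#'
#' @param n_proteins,n_templates Problem size.
#' @param metals Metal menu.
#' @param frac_metalloproteins Metalloprotein fraction.
#' @param groups Strain labels.
#' @param n_replicates Proteomic replicates per strain.
#' @param sigma_log Intensity noise.
#' @param missing_rate Missing-value rate.
#' @param group_effects,free_pool,luxury,quota_rel_sd,quota_scale Passed to
#'   the respective generators.
#' @param seed Integer seed; sub-generators derive their own seeds from it.
#' @param dir Directory for the PDB files.
#' @param write_tables Also write the match, intensity (MaxQuant-style) and
#'   quota tables as TSV next to the structures.
#'
#' @return A list: `paths` (files written), `templates_truth`, `matches`,
#'   `truth_annotations`, `truth_proteins`, `quant`, `truth_bound`,
#'   `quotas`, `manifest`.
#' @export
simulate_metallome_study <- function(n_proteins = 300, n_templates = 24,
                                     metals = default_metal_menu(),
                                     frac_metalloproteins = 0.37,
                                     groups = c("OA1", "OA16"),
                                     n_replicates = 3, sigma_log = 0.1,
                                     missing_rate = 0.05,
                                     group_effects = NULL,
                                     free_pool = NULL, luxury = NULL,
                                     quota_rel_sd = 0.05, quota_scale = 100,
                                     seed = 1, dir = tempfile("study"),
                                     write_tables = FALSE) {
  seeds <- seed + 0:3
  st <- generate_structures(n_templates, metal_menu = metals,
                            seed = seeds[1], dir = dir)
  pr <- generate_proteome(st$truth, n_proteins = n_proteins,
                          frac_metalloproteins = frac_metalloproteins,
                          seed = seeds[2])
  qt <- generate_quant(pr, groups = groups, n_replicates = n_replicates,
                       sigma_log = sigma_log, group_effects = group_effects,
                       missing_rate = missing_rate, seed = seeds[3])
  qu <- generate_quotas(qt$truth_bound, free_pool = free_pool,
                        luxury = luxury, scale = quota_scale,
                        rel_sd = quota_rel_sd, n_replicates = n_replicates,
                        seed = seeds[4])

  paths <- list(structures = st$paths)
  if (write_tables) {
    paths$matches <- file.path(dir, "matches.tsv")
    readr::write_tsv(pr$matches, paths$matches)
    paths$quant <- file.path(dir, "proteinGroups.tsv")
    .write_maxquant(qt$quant, paths$quant)
    paths$quotas <- file.path(dir, "quotas.tsv")
    readr::write_tsv(
      dplyr::rename(qu$quotas, mean_mmol_per_molC = "mean_quota"),
      paths$quotas
    )
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(annotations = pr$truth_annotations, bound = qt$truth_bound),
      paths$truth, dataframe = "rows", pretty = TRUE
    )
  }
  list(
    paths = paths,
    templates_truth = st$truth,
    matches = pr$matches,
    truth_annotations = pr$truth_annotations,
    truth_proteins = pr$truth_proteins,
    quant = qt$quant,
    truth_bound = qt$truth_bound,
    quotas = qu$quotas,
    manifest = list(structures = st$manifest, proteome = pr$manifest,
                    quant = qt$manifest, quotas = qu$manifest, seed = seed)
  )
}

# MaxQuant proteinGroups dialect: "Intensity <sample>" columns, zeros for
# missing, Reverse / Potential contaminant flag columns.
.write_maxquant <- function(quant, path) {
  wide <- quant |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity, 0)) |>
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "sample_id",
                       values_from = "intensity",
                       names_prefix = "Intensity ")
  wide <- dplyr::rename(wide, `Majority protein IDs` = "protein_id")
  wide$Reverse <- ""
  wide$`Potential contaminant` <- ""
  readr::write_tsv(wide, path)
  invisible(path)
}
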