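# Structure parsing and coordination-sphere analysis: the local
# metal-binding characterisation stage that turns template structures into
# per-chain metal stoichiometries.

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a protein structure file into an atom table
#'
#' Reads a PDB or mmCIF file (via bio3d) and returns one row per atom with
#' alternate locations collapsed to the highest-occupancy conformer.
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"` or `"mmcif"`.
#'
#' @return A tibble with columns `element`, `x`, `y`, `z`, `chain_id`,
#'   `res_name`, `res_seq`, `ins_code`, `atom_name`, `is_polymer`
#'   (`TRUE` for polymer `ATOM` records; waters and heteroatoms are
#'   `FALSE`), `occupancy`, and `altloc`. Atoms whose element symbol is not a
#'   known chemical element are dropped with a warning. An empty coordinate
#'   section yields a zero-row tibble.
#' @export
parse_structure <- function(path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("structure file does not exist: ", path)

  raw <- tryCatch(
    if (dialect == "pdb") {
      # rm.alt would silently keep conformer A only; the collapse rule
      # below wants the highest-occupancy conformer instead
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      if (dialect == "pdb" &&
          !any(grepl("^(ATOM|HETATM)", lines))) {
        return(NULL) # no coordinate section: empty structure
      }
      stop("failed to parse ", dialect, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(raw) || nrow(raw$atom) == 0) return(.empty_atom_table())

  at <- tibble::as_tibble(raw$atom)
  atoms <- tibble::tibble(
    element   = .normalise_element(at$elesy, at$elety),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    chain_id  = dplyr::coalesce(as.character(at$chain), ""),
    res_name  = as.character(at$resid),
    res_seq   = as.integer(at$resno),
    ins_code  = dplyr::coalesce(as.character(at$insert), ""),
    atom_name = as.character(at$elety),
    is_polymer = at$type == "ATOM" & !(at$resid %in% .water_resnames),
    occupancy = dplyr::coalesce(as.numeric(at$o), 1),
    altloc    = dplyr::coalesce(as.character(at$alt), "")
  )

  unknown <- is.na(atoms$element)
  if (any(unknown)) {
    warning(sum(unknown), " atom(s) with unknown element symbol skipped in '",
            basename(path), "'", call. = FALSE)
    atoms <- atoms[!unknown, ]
  }
  bad_occ <- atoms$occupancy < 0 | atoms$occupancy > 1
  if (any(bad_occ)) {
    stop("occupancy outside [0,1] in '", path, "'")
  }
  .collapse_altlocs(atoms)
}

.empty_atom_table <- function() {
  tibble::tibble(
    element = character(), x = double(), y = double(), z = double(),
    chain_id = character(), res_name = character(), res_seq = integer(),
    ins_code = character(), atom_name = character(), is_polymer = logical(),
    occupancy = double(), altloc = character()
  )
}

# Map raw element strings ("ZN", " n") to canonical symbols; fall back to the
# atom name with digits stripped when the element column is blank.
.normalise_element <- function(elesy, elety) {
  sym <- stringr::str_trim(dplyr::coalesce(as.character(elesy), ""))
  fallback <- stringr::str_remove_all(as.character(elety), "[0-9'\\s]")
  sym <- dplyr::if_else(sym == "", fallback, sym)
  sym <- stringr::str_to_title(stringr::str_to_lower(sym))
  # atom names like "SG" resolve to S once the 2-letter form is not an element
  two <- sym %in% .element_symbols
  one <- substr(sym, 1, 1) %in% .element_symbols
  dplyr::case_when(two ~ sym, one ~ substr(sym, 1, 1),
                   .default = NA_character_)
}

# Keep one conformer per atom: highest occupancy, tie broken towards the
# lexicographically smallest altloc (i.e. 'A').
.collapse_altlocs <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain_id, .data$res_seq, .data$ins_code,
                    .data$res_name, .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain_id, .data$res_seq, .data$atom_name)
}

#' Detect metal sites and their first coordination spheres
#'
#' Every atom whose element is in the configured metal set becomes a
#' candidate site. Its donors are the atoms of donor elements (default N, O,
#' S; waters excluded unless `config$include_waters`) within the distance
#' cutoff, excluding the metal itself and any other metal-set atom. A site
#' with no polymer donor inside the cutoff is flagged adventitious — a
#' buffer or surface ion rather than a cofactor.
#'
#' @param atoms Atom table from [parse_structure()].
#' @param config An [annotation_config()].
#'
#' @return A tibble with one row per metal site: `site_id`, `metal`,
#'   `x`, `y`, `z`, `n_donors`, `n_polymer_donors`, `attributed_chain`
#'   (chain contributing the majority of polymer donors; ties go to the
#'   lexicographically smallest chain id; `NA` for adventitious sites),
#'   `adventitious`, and a `donors` list-column of tibbles sorted by
#'   increasing distance.
#' @export
detect_metal_sites <- function(atoms, config = annotation_config()) {
  stopifnot(inherits(config, "annotation_config"))
  is_metal <- atoms$element %in% config$metals
  metals <- atoms[is_metal, ]
  if (nrow(metals) == 0) return(.empty_site_table())

  if (anyDuplicated(metals[, c("x", "y", "z")]) > 0) {
    stop("degenerate structure: two metal atoms share identical coordinates")
  }

  is_water <- atoms$res_name %in% .water_resnames
  cand <- atoms[
    atoms$element %in% config$donors &
      !is_metal &
      (config$include_waters | !is_water),
  ]
  cxyz <- as.matrix(cand[, c("x", "y", "z")])

  sites <- purrr::map(seq_len(nrow(metals)), function(i) {
    pos <- c(metals$x[i], metals$y[i], metals$z[i])
    if (nrow(cand) > 0) {
      d <- sqrt(rowSums((cxyz - rep(pos, each = nrow(cxyz)))^2))
      keep <- which(d > 0 & d <= config$cutoff)
      donors <- cand[keep, c("element", "chain_id", "res_name", "res_seq",
                             "ins_code", "atom_name", "is_polymer")]
      donors$distance <- d[keep]
      donors <- dplyr::arrange(donors, .data$distance)
    } else {
      donors <- cand[0, c("element", "chain_id", "res_name", "res_seq",
                          "ins_code", "atom_name", "is_polymer")]
      donors$distance <- double()
    }
    poly <- donors[donors$is_polymer, ]
    adventitious <- nrow(poly) == 0
    chain <- if (adventitious) NA_character_ else .majority_chain(poly$chain_id)
    tibble::tibble(
      metal = metals$element[i],
      x = pos[1], y = pos[2], z = pos[3],
      n_donors = nrow(donors),
      n_polymer_donors = nrow(poly),
      attributed_chain = chain,
      adventitious = adventitious,
      donors = list(donors)
    )
  })
  out <- dplyr::bind_rows(sites)
  out$site_id <- sprintf("%s_%d", out$metal, seq_len(nrow(out)))
  dplyr::relocate(out, "site_id")
}

.majority_chain <- function(chains) {
  tab <- sort(table(chains), decreasing = TRUE)
  top <- names(tab[tab == tab[1]])
  sort(top)[1]
}

.empty_site_table <- function() {
  tibble::tibble(
    site_id = character(), metal = character(),
    x = double(), y = double(), z = double(),
    n_donors = integer(), n_polymer_donors = integer(),
    attributed_chain = character(), adventitious = logical(),
    donors = list()
  )
}

#' Per-chain metal stoichiometry from detected sites
#'
#' Counts non-adventitious sites per (chain, metal). Adventitious sites are
#' excluded (unless the configuration that produced the sites said otherwise
#' and `include_adventitious` is set), so buffer ions do not inflate the
#' stoichiometry transferred to homologous proteins.
#'
#' @param sites Site table from [detect_metal_sites()].
#' @param chain_id Optional chain to restrict to; `NULL` keeps all chains.
#' @param template_id Optional identifier stamped on the output rows.
#' @param include_adventitious Count adventitious sites too (attributed to
#'   their nearest-donor chain when one exists; pure-solvent sites can never
#'   be attributed and are always dropped).
#'
#' @return A tibble `template_id`, `chain_id`, `metal`, `count` with one row
#'   per (chain, metal) having `count > 0`. Empty input yields zero rows (an
#'   all-zero stoichiometry).
#' @export
stoichiometry_from_sites <- function(sites, chain_id = NULL,
                                     template_id = NA_character_,
                                     include_adventitious = FALSE) {
  used <- sites
  if (include_adventitious) {
    # attribute donor-bearing adventitious sites to the nearest donor's chain
    fill <- used$adventitious & used$n_donors > 0
    used$attributed_chain[fill] <-
      purrr::map_chr(used$donors[fill], ~ .x$chain_id[1])
  } else {
    used <- used[!used$adventitious, , drop = FALSE]
  }
  used <- used[!is.na(used$attributed_chain), , drop = FALSE]
  out <- used |>
    dplyr::count(chain_id = .data$attributed_chain, metal = .data$metal,
                 name = "count") |>
    dplyr::mutate(template_id = template_id, .before = 1) |>
    dplyr::arrange(.data$chain_id, .data$metal)
  if (!is.null(chain_id)) {
    out <- out[out$chain_id == chain_id, , drop = FALSE]
  }
  out
}

#' Annotate a set of template structures
#'
#' Convenience wrapper running [parse_structure()], [detect_metal_sites()]
#' and [stoichiometry_from_sites()] over several files. Template ids default
#' to file names without extension.
#'
#' @param paths Character vector of structure file paths.
#' @param config An [annotation_config()].
#' @param dialect Structure dialect, as in [parse_structure()].
#'
#' @return A template store: tibble `template_id`, `chain_id`, `metal`,
#'   `count`. Polymer chains without any metal site are retained as
#'   `metal = NA, count = 0` rows so that matches against apo chains resolve
#'   to an explicit empty stoichiometry rather than an unknown template.
#' @export
annotate_templates <- function(paths, config = annotation_config(),
                               dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  purrr::map(paths, function(p) {
    tid <- stringr::str_remove(basename(p), "\\.[^.]+$")
    atoms <- parse_structure(p, dialect = dialect)
    sites <- detect_metal_sites(atoms, config = config)
    st <- stoichiometry_from_sites(sites, template_id = tid)
    apo <- setdiff(unique(atoms$chain_id[atoms$is_polymer]), st$chain_id)
    if (length(apo) > 0) {
      st <- dplyr::bind_rows(st, tibble::tibble(
        template_id = tid, chain_id = apo,
        metal = NA_character_, count = 0L
      ))
    }
    st
  }) |>
    dplyr::bind_rows()
}

#' Write or read a template annotation store as JSON
#'
#' The store is serialised as `{template_id: {chain_id: {metal: count}}}`.
#'
#' @param store Tibble `template_id`, `chain_id`, `metal`, `count`.
#' @param path Output / input JSON path.
#' @return `write_annotation_store()` returns `path` invisibly;
#'   `read_annotation_store()` returns the store tibble.
#' @export
write_annotation_store <- function(store, path) {
  nested <- split(store, store$template_id) |>
    purrr::map(function(tpl) {
      split(tpl, tpl$chain_id) |>
        purrr::map(function(ch) {
          has_metal <- !is.na(ch$metal) & ch$count > 0
          as.list(setNames(ch$count[has_metal], ch$metal[has_metal]))
        })
    })
  jsonlite::write_json(nested, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation_store
#' @export
read_annotation_store <- function(path) {
  nested <- jsonlite::read_json(path)
  purrr::imap(nested, function(tpl, tid) {
    purrr::imap(tpl, function(ch, cid) {
      tibble::tibble(
        template_id = tid, chain_id = cid,
        metal = if (length(ch) > 0) names(ch) else NA_character_,
        count = if (length(ch) > 0) as.integer(unlist(ch)) else 0L
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}
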