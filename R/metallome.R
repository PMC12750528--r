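# Abundance-weighted metallome reconstruction and the count/percentage
# summaries of the annotated proteome.

#' Reconstruct a relative metallome profile
#'
#' The abundance of each metal is the sum, over annotated proteins, of the
#' protein's relative abundance multiplied by the number of ions of that
#' metal it binds. Units are arbitrary: only within-profile comparisons
#' between metals (and ratios between groups) are meaningful.
#'
#' When `rel` carries per-sample relative abundances (a `sample_id` column,
#' from `normalize_total(quant, by = "sample")`), a profile is built per
#' replicate and then summarised per group: the reported abundance is the
#' replicate mean and `sd` the sample standard deviation (n - 1 denominator)
#' across replicates. Group-level `rel` gives `sd = NA`, `n = 1`.
#'
#' Annotated proteins missing from `rel` are skipped with a message.
#'
#' @param rel Relative-abundance tibble from [normalize_total()].
#' @param annotations Annotation tibble from [transfer_annotations()].
#'
#' @return A metallome profile tibble: `group`, `metal`, `abundance`, `sd`,
#'   `n` (replicates), `n_proteins` (proteins contributing to the metal).
#' @export
#' @examples
#' rel <- tibble::tibble(protein_id = c("p1", "p2"), group = "wt",
#'                       rel_abundance = c(0.6, 0.4))
#' ann <- tibble::tibble(protein_id = c("p1", "p2"), metal = "Zn",
#'                       count = c(1L, 2L), template_id = "t",
#'                       chain_id = "A", confidence = 99)
#' compute_metallome(rel, ann)$abundance  # 0.6*1 + 0.4*2 = 1.4
compute_metallome <- function(rel, annotations) {
  per_sample <- "sample_id" %in% names(rel)
  reps <- metallome_by_sample(rel, annotations)
  if (nrow(reps) == 0) return(.empty_profile())

  if (per_sample) {
    reps |>
      dplyr::group_by(.data$group, .data$metal) |>
      dplyr::summarise(
        sd = if (dplyr::n() > 1) sd(.data$abundance) else NA_real_,
        n = dplyr::n(),
        n_proteins = max(.data$n_proteins),
        abundance = mean(.data$abundance),
        .groups = "drop"
      ) |>
      dplyr::select("group", "metal", "abundance", "sd", "n", "n_proteins") |>
      dplyr::arrange(.data$group, .data$metal)
  } else {
    reps |>
      dplyr::mutate(sd = NA_real_, n = 1L) |>
      dplyr::select("group", "metal", "abundance", "sd", "n", "n_proteins") |>
      dplyr::arrange(.data$group, .data$metal)
  }
}

#' Per-replicate metallome profiles
#'
#' The replicate-level building block of [compute_metallome()]: one
#' abundance per (unit, metal), where a unit is a sample when `rel` has a
#' `sample_id` column and a group otherwise. Metals annotated but absent
#' from a unit get abundance 0, so every unit reports the same metal set.
#'
#' @inheritParams compute_metallome
#' @return Tibble `group` (, `sample_id`), `metal`, `abundance`,
#'   `n_proteins`.
#' @export
metallome_by_sample <- function(rel, annotations) {
  unit <- if ("sample_id" %in% names(rel)) c("group", "sample_id") else "group"
  ann <- annotations[!is.na(annotations$metal) & annotations$count > 0,
                     c("protein_id", "metal", "count")]
  if (nrow(ann) == 0 || nrow(rel) == 0) return(.empty_replicate_profile(unit))

  missing_ids <- setdiff(unique(ann$protein_id), unique(rel$protein_id))
  if (length(missing_ids) > 0) {
    message(length(missing_ids),
            " annotated protein(s) absent from the abundance table; skipped")
    ann <- ann[!ann$protein_id %in% missing_ids, , drop = FALSE]
    if (nrow(ann) == 0) return(.empty_replicate_profile(unit))
  }

  joined <- dplyr::inner_join(rel, ann, by = "protein_id",
                              relationship = "many-to-many")
  prof <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(unit, "metal")))) |>
    dplyr::summarise(
      abundance = sum(.data$rel_abundance * .data$count),
      n_proteins = dplyr::n_distinct(
        .data$protein_id[.data$rel_abundance > 0]
      ),
      .groups = "drop"
    )
  # complete the (unit x metal) grid so replicates agree on the metal set
  units <- dplyr::distinct(rel[, unit, drop = FALSE])
  grid <- tidyr::crossing(units, metal = sort(unique(ann$metal)))
  grid |>
    dplyr::left_join(prof, by = c(unit, "metal")) |>
    dplyr::mutate(
      abundance = dplyr::coalesce(.data$abundance, 0),
      n_proteins = dplyr::coalesce(.data$n_proteins, 0L)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(unit, "metal"))))
}

.empty_profile <- function() {
  tibble::tibble(group = character(), metal = character(),
                 abundance = double(), sd = double(), n = integer(),
                 n_proteins = integer())
}

.empty_replicate_profile <- function(unit) {
  base <- tibble::tibble(group = character(), sample_id = character())
  base <- base[, unit, drop = FALSE]
  dplyr::bind_cols(base, tibble::tibble(metal = character(),
                                        abundance = double(),
                                        n_proteins = integer()))
}

#' Metalloprotein count summary
#'
#' Tabulates, per metal, the number of annotated proteins binding at least
#' one ion of that metal, with percentages of the total identified proteins.
#' A protein binding k different metals appears in k per-metal rows but is
#' counted once in the metalloprotein total. Percentages are rounded
#' half-up to one decimal; the raw fraction is retained alongside.
#'
#' @param annotations Annotation tibble from [transfer_annotations()].
#' @param total_proteins Total number of proteins identified in the
#'   proteome (the percentage denominator), at least the number of annotated
#'   proteins.
#'
#' @return A tibble `category` (`"total_proteins"`,
#'   `"total_metalloproteins"`, then one row per metal), `n`, `percent`
#'   (half-up, one decimal) and `fraction` (unrounded).
#' @export
summarize_counts <- function(annotations, total_proteins) {
  if (length(total_proteins) != 1 || total_proteins <= 0) {
    stop("`total_proteins` must be a single positive count")
  }
  n_annotated <- dplyr::n_distinct(annotations$protein_id)
  if (total_proteins < n_annotated) {
    stop("`total_proteins` (", total_proteins, ") is smaller than the ",
         "number of annotated proteins (", n_annotated, ")")
  }
  metal_rows <- annotations |>
    dplyr::filter(!is.na(.data$metal), .data$count > 0) |>
    dplyr::distinct(.data$protein_id, .data$metal) |>
    dplyr::count(.data$metal, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$metal) |>
    dplyr::rename(category = "metal")

  out <- dplyr::bind_rows(
    tibble::tibble(category = "total_proteins",
                   n = as.integer(total_proteins)),
    tibble::tibble(category = "total_metalloproteins",
                   n = length(metalloproteins(annotations))),
    metal_rows
  )
  out |>
    dplyr::mutate(
      fraction = .data$n / as.integer(total_proteins),
      percent = round_half_up(100 * .data$fraction, 1)
    ) |>
    dplyr::select("category", "n", "percent", "fraction")
}

#' Share of protein-metal associations per metal
#'
#' The denominator is the total number of (protein, metal) pairs with
#' positive stoichiometry; a protein binding two metals contributes two
#' pairs. Percentages are unrounded and sum to 100.
#'
#' @param annotations Annotation tibble.
#' @return Tibble `metal`, `n_associations`, `percent`.
#' @export
association_fractions <- function(annotations) {
  pairs <- annotations |>
    dplyr::filter(!is.na(.data$metal), .data$count > 0) |>
    dplyr::distinct(.data$protein_id, .data$metal)
  if (nrow(pairs) == 0) stop("no protein-metal associations")
  pairs |>
    dplyr::count(.data$metal, name = "n_associations") |>
    dplyr::mutate(percent = 100 * .data$n_associations / nrow(pairs)) |>
    dplyr::arrange(dplyr::desc(.data$n_associations), .data$metal)
}

#' Number of distinct metals with at least one association
#'
#' @param annotations Annotation tibble.
#' @return Integer count.
#' @export
distinct_metals <- function(annotations) {
  dplyr::n_distinct(
    annotations$metal[!is.na(annotations$metal) & annotations$count > 0]
  )
}

#' Write a metallome profile as TSV
#'
#' @param profile Profile tibble from [compute_metallome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metallome <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}
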