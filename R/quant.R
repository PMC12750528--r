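# Ingestion and normalisation of label-free proteomics intensity tables.
# Intensities are kept in long (tidy) form: one row per protein x sample,
# with NA for proteins not detected in a sample. Zeros reported by the
# search engine are censoring, not measured zeros, and become NA on read.

#' Read a protein intensity table
#'
#' Two dialects are supported. `"plain"`: first column is the protein id,
#' every remaining column a sample. `"maxquant"`: a proteinGroups-style TSV
#' with an identifier column (`Majority protein IDs`, falling back to
#' `Protein IDs`) and per-sample columns prefixed `Intensity `; rows flagged
#' `Reverse` or as contaminants are dropped.
#'
#' @param path TSV path.
#' @param dialect `"plain"` or `"maxquant"`.
#' @param groups Optional named character vector mapping sample id to
#'   replicate group (e.g. strain). Defaults to each sample forming its own
#'   group.
#'
#' @return A long tibble `protein_id`, `sample_id`, `group`, `intensity`
#'   with `NA` intensity where a protein was not detected. Errors on
#'   duplicate protein ids, on a table without intensity columns, and on a
#'   sample with no detected protein.
#' @export
read_quant_table <- function(path, dialect = c("plain", "maxquant"),
                             groups = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

  if (dialect == "maxquant") {
    id_col <- intersect(c("Majority protein IDs", "Protein IDs"), names(raw))[1]
    if (is.na(id_col)) {
      stop("maxquant table lacks an identifier column ",
           "('Majority protein IDs' or 'Protein IDs')")
    }
    for (flag in intersect(c("Reverse", "Potential contaminant",
                             "Contaminant"), names(raw))) {
      raw <- raw[is.na(raw[[flag]]) | raw[[flag]] != "+", ]
    }
    int_cols <- names(raw)[startsWith(names(raw), "Intensity ")]
    if (length(int_cols) == 0) stop("no 'Intensity <sample>' columns found")
    wide <- raw[, c(id_col, int_cols)]
    names(wide) <- c("protein_id",
                     stringr::str_remove(int_cols, "^Intensity "))
  } else {
    if (ncol(raw) < 2) stop("no intensity columns found")
    wide <- raw
    names(wide)[1] <- "protein_id"
  }

  if (anyDuplicated(wide$protein_id) > 0) {
    stop("duplicate protein id(s): ",
         paste(unique(wide$protein_id[duplicated(wide$protein_id)]),
               collapse = ", "))
  }

  long <- wide |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::mutate(intensity = as.numeric(.data$intensity),
                  intensity = dplyr::if_else(
                    !is.na(.data$intensity) & .data$intensity == 0,
                    NA_real_, .data$intensity
                  ))
  long$group <- if (is.null(groups)) {
    long$sample_id
  } else {
    unname(groups[long$sample_id])
  }
  long <- long[, c("protein_id", "sample_id", "group", "intensity")]
  validate_quant(long)
  long
}

#' Validate a long intensity table
#'
#' Checks the invariants: no negative intensities and at least one detected
#' (non-missing, positive) protein per sample.
#'
#' @param quant Long tibble `protein_id`, `sample_id`, `group`, `intensity`.
#' @return `quant`, invisibly.
#' @export
validate_quant <- function(quant) {
  required <- c("protein_id", "sample_id", "group", "intensity")
  missing <- setdiff(required, names(quant))
  if (length(missing) > 0) {
    stop("intensity table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(quant$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed")
  }
  detected <- quant |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n = sum(!is.na(.data$intensity) & .data$intensity > 0),
      .groups = "drop"
    )
  dead <- detected$sample_id[detected$n == 0]
  if (length(dead) > 0) {
    stop("sample(s) with no detected protein: ",
         paste(dead, collapse = ", "))
  }
  invisible(quant)
}

#' Median normalisation within each sample
#'
#' Divides every detected intensity by the median intensity of the detected
#' proteins in the same sample, so that samples measured at different depths
#' become comparable. Missing values stay missing; within-sample rank order
#' is unchanged.
#'
#' @param quant Long intensity tibble (see [read_quant_table()]).
#' @return The tibble with `intensity` replaced by the median-normalised
#'   value.
#' @export
#' @examples
#' q <- tibble::tibble(protein_id = c("a", "b", "c"), sample_id = "s1",
#'                     group = "g", intensity = c(1, 2, 4))
#' normalize_median(q)$intensity  # 0.5 1 2
normalize_median <- function(quant) {
  validate_quant(quant)
  quant |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      intensity = .data$intensity / median(.data$intensity, na.rm = TRUE)
    ) |>
    dplyr::ungroup()
}

#' Relative abundance by total-intensity normalisation
#'
#' Computes each protein's share of the total intensity. With
#' `by = "group"` (default), per-protein intensities are first averaged over
#' the group's samples (missing values excluded from the mean; a protein
#' absent from every sample of the group gets 0) and then divided by the
#' total over proteins, so the fractions sum to 1 within each group. With
#' `by = "sample"` each sample is normalised on its own — the per-replicate
#' relative abundances needed for replicate-level metallome profiles.
#'
#' @param quant Long intensity tibble.
#' @param group Optional single group label to restrict to.
#' @param by `"group"` or `"sample"`.
#'
#' @return A tibble `protein_id`, `group` (and `sample_id` for
#'   `by = "sample"`), `rel_abundance`. Fractions are nonnegative and sum to
#'   1 within each unit.
#' @export
normalize_total <- function(quant, group = NULL, by = c("group", "sample")) {
  by <- match.arg(by)
  validate_quant(quant)
  if (!is.null(group)) {
    quant <- quant[quant$group %in% group, , drop = FALSE]
    if (nrow(quant) == 0) stop("group not present: ", group)
  }

  if (by == "group") {
    means <- quant |>
      dplyr::group_by(.data$group, .data$protein_id) |>
      dplyr::summarise(
        value = if (all(is.na(.data$intensity))) 0 else
          mean(.data$intensity, na.rm = TRUE),
        .groups = "drop"
      )
    unit <- "group"
  } else {
    means <- quant |>
      dplyr::mutate(value = dplyr::coalesce(.data$intensity, 0)) |>
      dplyr::select("group", "sample_id", "protein_id", "value")
    unit <- c("group", "sample_id")
  }

  out <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::mutate(total = sum(.data$value)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) {
    stop("all-zero group: total intensity must be positive")
  }
  out |>
    dplyr::mutate(rel_abundance = .data$value / .data$total) |>
    dplyr::select(dplyr::all_of(c("protein_id", unit, "rel_abundance"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(unit, "protein_id"))))
}
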