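# Confidence filtering of fold-recognition matches and transfer of template
# metal stoichiometries to expressed proteins.

#' Read a fold-recognition match table
#'
#' Expects a TSV with columns `query_id`, `template_id`, `chain_id` and
#' `confidence` (percent, 0-100), as produced by a fold-recognition server
#' run on the expressed protein sequences.
#'
#' @param path TSV path.
#' @return A tibble of matches.
#' @export
read_match_table <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("query_id", "template_id", "chain_id", "confidence")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("match table is missing column(s): ", paste(missing, collapse = ", "))
  }
  m$query_id <- as.character(m$query_id)
  m$template_id <- as.character(m$template_id)
  m$chain_id <- as.character(m$chain_id)
  m$confidence <- as.numeric(m$confidence)
  if (any(m$confidence < 0 | m$confidence > 100, na.rm = TRUE)) {
    stop("confidence values must lie in [0, 100]")
  }
  m[required]
}

#' Filter matches at a confidence threshold
#'
#' Retains exactly the matches whose confidence is *strictly* greater than
#' the threshold; a match at exactly the threshold (e.g. 95.0 with the
#' default) is excluded. Input order is preserved.
#'
#' @param matches Match tibble (`query_id`, `template_id`, `chain_id`,
#'   `confidence`).
#' @param threshold Confidence threshold in percent, in (0, 100]. Default 95.
#' @return The retained matches, same columns and order.
#' @export
#' @examples
#' m <- tibble::tibble(query_id = c("p1", "p2", "p3"),
#'                     template_id = "t", chain_id = "A",
#'                     confidence = c(94.9, 95.0, 95.1))
#' filter_matches(m)$query_id  # only "p3"
filter_matches <- function(matches, threshold = 95) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 100) {
    stop("`threshold` must be a single percentage in (0, 100]")
  }
  matches[matches$confidence > threshold, , drop = FALSE]
}

#' Transfer template stoichiometries to query proteins
#'
#' For each query protein with at least one passing match that resolves in
#' the template store, the highest-confidence match is used (ties broken by
#' lexicographically smallest template id, then chain id); its template's
#' per-chain stoichiometry becomes the protein's metal annotation.
#' Alternatively `policy = "union_max"` takes, per metal, the maximum count
#' over all passing resolvable matches.
#'
#' Queries whose chosen template carries no metal are retained with a single
#' `metal = NA, count = 0` row: they are annotated non-metalloproteins and
#' still count in Table-style denominators. Matches referencing templates
#' absent from the store trigger a warning; a query with only unresolvable
#' matches is left unannotated (absent from the output).
#'
#' @param matches Filtered match tibble (see [filter_matches()]).
#' @param templates Template store tibble (`template_id`, `chain_id`,
#'   `metal`, `count`), e.g. from [annotate_templates()].
#' @param policy `"best"` (default) or `"union_max"`.
#'
#' @return Annotation tibble: `protein_id`, `metal`, `count`,
#'   `template_id`, `chain_id`, `confidence` (provenance of the chosen
#'   match; for `"union_max"` the best match's provenance is reported).
#' @export
transfer_annotations <- function(matches, templates,
                                 policy = c("best", "union_max")) {
  policy <- match.arg(policy)
  if (nrow(matches) == 0) return(.empty_annotation_table())

  key <- unique(templates[, c("template_id", "chain_id")])
  resolvable <- dplyr::semi_join(matches, key,
                                 by = c("template_id", "chain_id"))
  orphan <- dplyr::anti_join(matches, key, by = c("template_id", "chain_id"))
  if (nrow(orphan) > 0) {
    warning(nrow(orphan), " match(es) reference templates absent from the ",
            "store; affected queries with no other match are left ",
            "unannotated", call. = FALSE)
  }
  if (nrow(resolvable) == 0) return(.empty_annotation_table())

  ranked <- resolvable |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$confidence),
                   .data$template_id, .data$chain_id)
  best <- dplyr::distinct(ranked, .data$query_id, .keep_all = TRUE)

  stoich <- if (policy == "best") {
    dplyr::inner_join(best, templates, by = c("template_id", "chain_id"),
                      relationship = "many-to-many")
  } else {
    dplyr::inner_join(ranked, templates, by = c("template_id", "chain_id"),
                      relationship = "many-to-many") |>
      dplyr::group_by(.data$query_id, .data$metal) |>
      dplyr::summarise(count = max(.data$count), .groups = "drop")
  }

  prov <- best |>
    dplyr::select("query_id", "template_id", "chain_id", "confidence")
  out <- stoich |>
    dplyr::select("query_id", "metal", "count") |>
    dplyr::filter(.data$count > 0) |>
    dplyr::right_join(prov, by = "query_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::rename(protein_id = "query_id") |>
    dplyr::arrange(.data$protein_id, .data$metal)
  out[, c("protein_id", "metal", "count",
          "template_id", "chain_id", "confidence")]
}

.empty_annotation_table <- function() {
  tibble::tibble(
    protein_id = character(), metal = character(), count = integer(),
    template_id = character(), chain_id = character(), confidence = double()
  )
}

#' Which annotated proteins are metalloproteins?
#'
#' @param annotations Annotation tibble from [transfer_annotations()].
#' @return Character vector of protein ids with at least one metal ion.
#' @export
metalloproteins <- function(annotations) {
  unique(annotations$protein_id[!is.na(annotations$metal) &
                                  annotations$count > 0])
}

#' Write or read protein metal annotations as JSON
#'
#' Serialised as `{protein_id: {stoichiometry: {metal: count}, provenance:
#' {template_id, chain_id, confidence}}}`.
#'
#' @param annotations Annotation tibble.
#' @param path JSON path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` the annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  nested <- split(annotations, annotations$protein_id) |>
    purrr::map(function(p) {
      has_metal <- !is.na(p$metal) & p$count > 0
      list(
        stoichiometry = as.list(setNames(p$count[has_metal],
                                         p$metal[has_metal])),
        provenance = list(template_id = p$template_id[1],
                          chain_id = p$chain_id[1],
                          confidence = p$confidence[1])
      )
    })
  jsonlite::write_json(nested, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  nested <- jsonlite::read_json(path)
  purrr::imap(nested, function(p, pid) {
    st <- p$stoichiometry
    tibble::tibble(
      protein_id = pid,
      metal = if (length(st) > 0) names(st) else NA_character_,
      count = if (length(st) > 0) as.integer(unlist(st)) else 0L,
      template_id = p$provenance$template_id,
      chain_id = p$provenance$chain_id,
      confidence = as.numeric(p$provenance$confidence)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$protein_id, .data$metal)
}
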