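# Comparison of proteome-inferred metallomes with ICP-MS quotas:
# log-space correlation, between-strain ratios with first-order error
# propagation, and per-protein differential expression.

#' Read an ICP-MS quota table
#'
#' TSV with columns `strain`, `metal`, `mean_mmol_per_molC`, `sd`, `n`:
#' per-strain cellular metal content normalised to carbon.
#'
#' @param path TSV path.
#' @return A quota tibble (`strain`, `metal`, `mean_quota`, `sd`, `n`).
#' @export
read_quota_table <- function(path) {
  q <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         strain = readr::col_character(),
                         metal = readr::col_character(),
                         mean_mmol_per_molC = readr::col_double(),
                         sd = readr::col_double(),
                         n = readr::col_integer()
                       ))
  required <- c("strain", "metal", "mean_mmol_per_molC", "sd", "n")
  missing <- setdiff(required, names(q))
  if (length(missing) > 0) {
    stop("quota table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(q$mean_mmol_per_molC <= 0, na.rm = TRUE)) {
    stop("quota means must be positive")
  }
  if (any(q$sd < 0, na.rm = TRUE) || any(q$n < 1, na.rm = TRUE)) {
    stop("quota sd must be >= 0 and n >= 1")
  }
  dplyr::rename(q[required], mean_quota = "mean_mmol_per_molC")
}

# Reduce a metallome profile or quota table to one (metal, value, sd) row
# per metal, averaging over groups/strains when several are present.
.metal_stats <- function(x) {
  value_col <- intersect(c("abundance", "mean_quota"), names(x))[1]
  if (is.na(value_col)) {
    stop("expected a metallome profile ('abundance') or quota table ",
         "('mean_quota')")
  }
  sd_col <- if ("sd" %in% names(x)) x$sd else NA_real_
  tibble::tibble(metal = x$metal, value = x[[value_col]], sd = sd_col) |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(
      sd = if (dplyr::n() > 1) sd(.data$value) else .data$sd[1],
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("metal", "value", "sd")
}

#' Correlate measured quotas with a reconstructed metallome
#'
#' Pearson correlation between ICP-MS quotas and proteome-derived metal
#' abundances, by default on log10-transformed values: the metals span
#' orders of magnitude, and a linear-space correlation would be dominated
#' by the most abundant ones. Since the metallome is in arbitrary units,
#' the log transform makes the r-squared invariant to its overall scale.
#'
#' Metals absent from either input, or nonpositive in either, are excluded
#' from the fit but reported in the result's `excluded` table (free-ion
#' dominated metals such as Ca or Mg stay visible as unpaired rows rather
#' than disappearing). When several strains/groups are present, each side
#' is averaged per metal first.
#'
#' @param quota Quota tibble (see [read_quota_table()]).
#' @param profile Metallome profile from [compute_metallome()].
#' @param metals Optional metal selection.
#' @param log10 Correlate in log10 space (default) or linear space.
#'
#' @return An object of class `metallome_cor`: a list with `r_squared`,
#'   `n_points`, `pairs` (per-metal quota/abundance pairs used), and
#'   `excluded`. Errors when fewer than 3 usable pairs remain.
#' @export
correlate_metallome <- function(quota, profile, metals = NULL, log10 = TRUE) {
  q <- .metal_stats(quota)
  p <- .metal_stats(profile)
  if (!is.null(metals)) {
    q <- q[q$metal %in% metals, ]
    p <- p[p$metal %in% metals, ]
  }
  pairs <- dplyr::full_join(
    dplyr::select(q, "metal", quota = "value"),
    dplyr::select(p, "metal", abundance = "value"),
    by = "metal"
  )
  usable <- !is.na(pairs$quota) & !is.na(pairs$abundance) &
    pairs$quota > 0 & pairs$abundance > 0
  excluded <- pairs[!usable, , drop = FALSE]
  excluded$reason <- dplyr::case_when(
    is.na(excluded$quota) | excluded$quota <= 0 ~ "no positive quota",
    .default = "no positive proteome abundance"
  )
  used <- pairs[usable, , drop = FALSE]
  if (nrow(used) < 3) {
    stop("fewer than 3 metals usable for correlation (", nrow(used),
         " found)")
  }
  xs <- if (log10) log10(used$quota) else used$quota
  ys <- if (log10) log10(used$abundance) else used$abundance
  structure(
    list(
      r_squared = unname(cor(xs, ys)^2),
      n_points = nrow(used),
      pairs = used,
      excluded = excluded,
      log10 = log10
    ),
    class = "metallome_cor"
  )
}

#' @export
print.metallome_cor <- function(x, ...) {
  cat("Metallome vs quota correlation (",
      if (x$log10) "log10" else "linear", " space)\n", sep = "")
  cat("  r-squared:", format(x$r_squared, digits = 3),
      "on", x$n_points, "metals\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded$metal, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Between-strain metal ratios with propagated uncertainty
#'
#' For each metal present and positive in both inputs, computes
#' `ratio = numerator / denominator` of the mean values, with a standard
#' deviation from first-order (delta-method) propagation:
#' `sd = ratio * sqrt((sd_num/mean_num)^2 + (sd_den/mean_den)^2)`.
#' Both inputs may be metallome profiles or quota tables (each restricted
#' to one strain/group). Metals with a zero or missing denominator are
#' skipped with a warning.
#'
#' @param numerator,denominator Metallome profile or quota tibbles, e.g.
#'   the Southern Ocean strain over the North Sea strain.
#'
#' @return Tibble `metal`, `ratio`, `sd` (NA when either input lacks an
#'   SD), `value_num`, `value_den`.
#' @export
strain_ratio <- function(numerator, denominator) {
  num <- .metal_stats(numerator)
  den <- .metal_stats(denominator)
  joined <- dplyr::inner_join(num, den, by = "metal",
                              suffix = c("_num", "_den"))
  bad <- is.na(joined$value_num) | is.na(joined$value_den) |
    joined$value_num <= 0 | joined$value_den <= 0
  if (any(bad)) {
    warning("metal(s) skipped (zero/missing mean): ",
            paste(joined$metal[bad], collapse = ", "), call. = FALSE)
    joined <- joined[!bad, , drop = FALSE]
  }
  joined |>
    dplyr::mutate(
      ratio = .data$value_num / .data$value_den,
      sd = .data$ratio * sqrt((.data$sd_num / .data$value_num)^2 +
                                (.data$sd_den / .data$value_den)^2)
    ) |>
    dplyr::select("metal", "ratio", "sd", "value_num", "value_den") |>
    dplyr::arrange(.data$metal)
}

#' Per-protein differential expression between two groups
#'
#' Two-sided two-sample Student's t-test (pooled variance by default;
#' `var_equal = FALSE` gives Welch) on median-normalised intensities, with
#' `log2fc = log2(mean_b / mean_a)`. Proteins with fewer than 2 detected
#' replicates in either group are reported with an undefined p-value.
#'
#' @param quant Long intensity tibble (see [read_quant_table()]).
#' @param group_a,group_b Group labels; fold changes are B relative to A.
#' @param alpha Significance level (default 0.05).
#' @param annotations Optional annotation tibble; when supplied each
#'   protein's bound metals are attached as a `metals` list-column.
#' @param normalize Median-normalise before testing (default TRUE).
#' @param var_equal Pooled-variance Student's t-test (default) or Welch.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) reports raw p-values.
#'
#' @return A tibble of class `metallome_de`: `protein_id`, `mean_a`,
#'   `mean_b`, `log2fc`, `statistic`, `p`, `significant` (`p < alpha`),
#'   `n_a`, `n_b`, and `metals`.
#' @export
differential_expression <- function(quant, group_a, group_b, alpha = 0.05,
                                    annotations = NULL, normalize = TRUE,
                                    var_equal = TRUE, p_adjust = "none") {
  validate_quant(quant)
  for (g in c(group_a, group_b)) {
    if (!g %in% quant$group) stop("group label absent from table: ", g)
  }
  if (normalize) quant <- normalize_median(quant)

  q <- quant[quant$group %in% c(group_a, group_b), ]
  res <- q |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      test = list(.two_group_t(
        .data$intensity[.data$group == group_a],
        .data$intensity[.data$group == group_b],
        var_equal
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test")

  res$p_adj <- p.adjust(res$p, method = p_adjust)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  if (p_adjust == "none") res$p_adj <- NULL

  if (!is.null(annotations)) {
    met <- annotations |>
      dplyr::filter(!is.na(.data$metal), .data$count > 0) |>
      dplyr::distinct(.data$protein_id, .data$metal) |>
      dplyr::summarise(metals = list(sort(.data$metal)),
                       .by = "protein_id")
    res <- dplyr::left_join(res, met, by = "protein_id")
    res$metals <- purrr::map(res$metals, ~ if (is.null(.x)) character() else .x)
  }
  structure(res, class = c("metallome_de", class(res)),
            alpha = alpha, groups = c(a = group_a, b = group_b))
}

# t-test between the detected intensities of two groups; degenerate
# (zero-variance) inputs fall back to the limit of the t statistic.
.two_group_t <- function(a, b, var_equal) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  mean_a <- if (length(a) > 0) mean(a) else NA_real_
  mean_b <- if (length(b) > 0) mean(b) else NA_real_
  log2fc <- if (!is.na(mean_a) && !is.na(mean_b) && mean_a > 0 && mean_b > 0)
    log2(mean_b / mean_a) else NA_real_
  out <- list(mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
              statistic = NA_real_, p = NA_real_,
              n_a = length(a), n_b = length(b))
  if (length(a) < 2 || length(b) < 2) return(out)
  tt <- tryCatch(
    t.test(b, a, var.equal = var_equal),
    error = function(e) NULL
  )
  if (is.null(tt)) { # both groups essentially constant
    same <- isTRUE(all.equal(mean_a, mean_b))
    out$statistic <- if (same) 0 else sign(mean_b - mean_a) * Inf
    out$p <- if (same) 1 else 0
  } else {
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  out
}

#' Group-level test on reconstructed metal abundances
#'
#' Rolls the per-replicate metallome profiles up to one test per metal:
#' a two-sample Student's t-test on the replicate metal abundances of the
#' two groups, alongside the B/A ratio of group means. With fewer than 2
#' replicates in a group the ratio is still reported but the p-value is
#' undefined.
#'
#' @param replicate_profiles Per-replicate profiles from
#'   [metallome_by_sample()] (sample-level `rel`).
#' @param group_a,group_b Group labels; the ratio is B over A.
#' @param metals Optional metal selection.
#' @param alpha Significance level.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#'
#' @return Tibble `metal`, `ratio`, `statistic`, `p`, `significant`,
#'   `n_a`, `n_b`.
#' @export
metal_rollup_test <- function(replicate_profiles, group_a, group_b,
                              metals = NULL, alpha = 0.05,
                              var_equal = TRUE) {
  for (g in c(group_a, group_b)) {
    if (!g %in% replicate_profiles$group) {
      stop("group label absent from profiles: ", g)
    }
  }
  prof <- replicate_profiles[replicate_profiles$group %in%
                               c(group_a, group_b), ]
  if (!is.null(metals)) prof <- prof[prof$metal %in% metals, ]

  prof |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(
      test = list(.two_group_t(
        .data$abundance[.data$group == group_a],
        .data$abundance[.data$group == group_b],
        var_equal
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("test") |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$mean_a > 0,
                             .data$mean_b / .data$mean_a, NA_real_),
      significant = !is.na(.data$p) & .data$p < alpha
    ) |>
    dplyr::select("metal", "ratio", "statistic", "p", "significant",
                  "n_a", "n_b")
}
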