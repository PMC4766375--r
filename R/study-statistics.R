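#' Screen qPCR samples by housekeeping-gene spread
#'
#' Flags samples whose housekeeping Ct values disagree too widely —
#' evidence of low RNA yield or quality. A sample is retained when the
#' spread (max minus min Ct across the housekeeping set) does not exceed
#' the threshold; samples missing any housekeeping measurement are
#' excluded with a `missing_housekeeping` reason.
#'
#' @param ct Long-format Ct table: columns `sample_id`, `group`, `gene`,
#'   `ct` (cycles; finite, positive).
#' @param housekeeping Character vector of housekeeping gene names.
#' @param max_spread Maximum allowed Ct spread in cycles (default 5).
#' @return A tibble with one row per sample: `sample_id`, `spread`,
#'   `retained`, `reason` (NA when retained).
#' @export
quality_screen_ct <- function(ct, housekeeping, max_spread = 5) {
  stopifnot(length(housekeeping) >= 1, max_spread >= 0)
  hk <- dplyr::filter(ct, .data$gene %in% housekeeping)
  per_sample <- hk |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_hk = dplyr::n_distinct(.data$gene),
      spread = max(.data$ct) - min(.data$ct),
      .groups = "drop")
  all_samples <- tibble::tibble(sample_id = unique(ct$sample_id))
  all_samples |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      n_hk = dplyr::coalesce(.data$n_hk, 0L),
      missing = .data$n_hk < length(housekeeping),
      retained = !.data$missing & .data$spread <= max_spread,
      reason = dplyr::case_when(
        missing ~ "missing_housekeeping",
        spread > max_spread ~ "housekeeping_spread",
        TRUE ~ NA_character_)) |>
    dplyr::select("sample_id", "spread", "retained", "reason")
}

# Geometric mean; strictly positive inputs assumed (Ct cycles).
geometric_mean <- function(x) exp(mean(log(x)))

#' Relative expression by the 2^-ddCt method
#'
#' Per-sample fold change of a target gene versus a control group, with a
#' multi-gene normalization factor: each sample's normalization factor is
#' the geometric mean of its housekeeping Ct values (a single housekeeping
#' gene degenerates to that gene's Ct); dCt = Ct_target - NF;
#' ddCt = dCt - mean(dCt over the control group); fold change = 2^-ddCt.
#' By construction the control group's fold changes have geometric mean 1.
#'
#' @inheritParams quality_screen_ct
#' @param target_gene Name of the gene whose expression is reported.
#' @param control_group Label of the calibrator group in `ct$group`.
#' @return A tibble with one row per sample: `sample_id`, `group`,
#'   `norm_factor`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
relative_expression <- function(ct, target_gene, housekeeping, control_group) {
  stopifnot(length(housekeeping) >= 1)
  if (!any(ct$gene == target_gene)) {
    stop("target gene not present in Ct table", call. = FALSE)
  }
  nf <- ct |>
    dplyr::filter(.data$gene %in% housekeeping) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(norm_factor = geometric_mean(.data$ct), .groups = "drop")
  tgt <- ct |>
    dplyr::filter(.data$gene == target_gene) |>
    dplyr::select("sample_id", "group", ct_target = "ct")
  df <- dplyr::inner_join(tgt, nf, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$norm_factor)
  ctrl <- df$delta_ct[df$group == control_group]
  if (length(ctrl) == 0) {
    stop("invalid design: control group is empty", call. = FALSE)
  }
  df |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - mean(ctrl),
      fold_change = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("sample_id", "group", "norm_factor", "delta_ct",
                  "delta_delta_ct", "fold_change")
}

#' LOD-censored fold changes for an immunoassay panel
#'
#' Per-analyte fold change between two groups under limit-of-detection
#' (LOD) censoring. An analyte is reported not-detectable (`"N/D"`) when
#' more than half of all samples (pooled over groups) fall below its LOD;
#' otherwise censored values are substituted at `lod_substitution` times
#' the LOD (default 1/2) and the group-mean ratio is taken. Fold changes
#' below 1 are reported on the signed convention of antibody-array
#' figures: +fold = upregulation, and a ratio r < 1 is shown as
#' -1/r (downregulation).
#'
#' @param panel Long-format analyte table: columns `sample_id`, `group`,
#'   `analyte`, `concentration_pg_ml`, `below_lod` (0/1), `lod_pg_ml`.
#' @param numerator_group,denominator_group Group labels; the fold is
#'   numerator over denominator.
#' @param nd_fraction Censoring fraction above which an analyte is N/D
#'   (default 0.5, i.e. "more than half").
#' @param lod_substitution Multiple of the LOD substituted for censored
#'   values (default 0.5).
#' @return A tibble with one row per analyte: `analyte`, `fold_change`
#'   (signed; NA when not computable), `n_below_lod`, `n_samples`,
#'   `status` in `"ok"`, `"N/D"`, `"undefined"`.
#' @export
lod_fold_change <- function(panel, numerator_group, denominator_group,
                            nd_fraction = 0.5, lod_substitution = 0.5) {
  both <- dplyr::filter(panel,
                        .data$group %in% c(numerator_group, denominator_group))
  if (!any(both$group == numerator_group) ||
      !any(both$group == denominator_group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  both |>
    dplyr::mutate(value = ifelse(.data$below_lod == 1,
                                 lod_substitution * .data$lod_pg_ml,
                                 .data$concentration_pg_ml)) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_below_lod = sum(.data$below_lod == 1),
      mean_num = mean(.data$value[.data$group == numerator_group]),
      mean_den = mean(.data$value[.data$group == denominator_group]),
      .groups = "drop") |>
    dplyr::mutate(
      status = dplyr::case_when(
        n_below_lod > nd_fraction * n_samples ~ "N/D",
        mean_den == 0 ~ "undefined",
        TRUE ~ "ok"),
      ratio = .data$mean_num / .data$mean_den,
      fold_change = dplyr::case_when(
        status != "ok" ~ NA_real_,
        ratio >= 1 ~ ratio,
        TRUE ~ -1 / ratio)) |>
    dplyr::select("analyte", "fold_change", "n_below_lod", "n_samples",
                  "status")
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Rank correlation with the tau-b tie correction in both variables, as
#' used to relate relative gene expression to ordinal neuropathological
#' severity (Braak stage). Computed by pair classification:
#' `(concordant - discordant) / sqrt((n0 - t_x) * (n0 - t_y))`, where
#' `n0` is the number of pairs and `t_x`, `t_y` the tied pairs within
#' each variable.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` is typically an
#'   ordinal score.
#' @return The tau-b coefficient in \[-1, 1\], or `NA` (with a warning)
#'   when either variable is entirely tied.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(10, 20, 30, 40)) # 1
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("tau-b undefined: a variable is entirely tied")
    return(NA_real_)
  }
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])                   # concordant minus discordant
  n0 <- n * (n - 1) / 2
  tx <- sum(dx[up] == 0)                      # pairs tied in x
  ty <- sum(dy[up] == 0)
  s / sqrt((n0 - tx) * (n0 - ty))
}

#' T-maze spontaneous alternation ratio
#'
#' Scores a sequence of discrete alternation trials: 1 when the subject
#' entered the arm not chosen on the preceding forced choice
#' (`"alternated"`), 0 when it returned to the same arm (`"repeated"`).
#' Trials in which the subject did not move within the time limit
#' (`"failed"`) are excluded from both numerator and denominator; their
#' fraction is reported alongside.
#'
#' @param trials Character vector of outcomes in
#'   `c("alternated", "repeated", "failed")`, or a data frame with an
#'   `outcome` column.
#' @param max_trials Configured trial count (default 20: four trials a
#'   day for five days); longer sequences are rejected.
#' @return A one-row tibble with `alternation_ratio` (NA when every trial
#'   failed, flagged by `undefined`), `n_scored`, `n_failed`,
#'   `failed_fraction`.
#' @export
alternation_ratio <- function(trials, max_trials = 20) {
  if (is.data.frame(trials)) trials <- trials$outcome
  if (!all(trials %in% c("alternated", "repeated", "failed"))) {
    stop("outcomes must be 'alternated', 'repeated' or 'failed'", call. = FALSE)
  }
  if (length(trials) > max_trials) {
    stop("trial sequence longer than the configured trial count", call. = FALSE)
  }
  n_failed <- sum(trials == "failed")
  scored <- trials[trials != "failed"]
  undefined <- length(scored) == 0
  if (undefined) warning("all trials failed: alternation ratio undefined")
  tibble::tibble(
    alternation_ratio = if (undefined) NA_real_ else
      mean(scored == "alternated"),
    n_scored = length(scored),
    n_failed = n_failed,
    failed_fraction = n_failed / length(trials),
    undefined = undefined)
}
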