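# Substructure enrichment (fixed SMARTS panel, per-molecule presence
# frequencies) and two-sample Kolmogorov-Smirnov comparison of
# physicochemical property distributions between active and inactive sets.

.smiles_vector <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"smiles" %in% names(x)) abort(sprintf("`%s` needs a `smiles` column", what))
    return(as.character(x$smiles))
  }
  as.character(x)
}

# parse a SMILES set to an SDFset of largest fragments; returns list(sdfset,
# n_ok, n_failed)
.parse_set <- function(smiles, what) {
  kept <- character(0)
  failed <- 0L
  for (i in seq_along(smiles)) {
    g <- tryCatch(parse_smiles(smiles[i], sprintf("%s_%d", what, i)),
                  error = function(e) NULL)
    if (is.null(g)) failed <- failed + 1L else kept <- c(kept, g$canonical_smiles)
  }
  if (failed > 0) {
    warn(sprintf("%d unparsable molecule(s) excluded from the %s set", failed, what))
  }
  if (length(kept) == 0) abort(sprintf("no parsable molecules in the %s set", what))
  list(sdfset = ChemmineR::smiles2sdf(setNames(kept, sprintf("%s_%d", what, seq_along(kept)))),
       n = length(kept), n_failed = failed)
}

#' Substructure presence frequencies in active vs inactive molecules
#'
#' For each SMARTS pattern, counts the molecules of each set containing at
#' least one match (match multiplicity is ignored) and reports per-set
#' percentages. Unparsable molecules are excluded from the denominators
#' with a warning.
#'
#' @param actives,inactives Character vectors of SMILES, or data frames
#'   with a `smiles` column.
#' @param patterns Data frame with columns `name`, `smarts` (default: the
#'   shipped [fragment_panel()]).
#' @return A tibble: `pattern`, `smarts`, `n_active`, `n_inactive`,
#'   `matched_active`, `matched_inactive`, `freq_active`, `freq_inactive`
#'   (percent), ordered by decreasing active/inactive frequency ratio.
#' @export
fragment_frequencies <- function(actives, inactives, patterns = fragment_panel()) {
  sa <- .smiles_vector(actives, "active")
  si <- .smiles_vector(inactives, "inactive")
  if (length(sa) == 0 || length(si) == 0) {
    abort("both the active and inactive sets must be non-empty")
  }
  stopifnot(is.data.frame(patterns), all(c("name", "smarts") %in% names(patterns)))
  if (anyDuplicated(patterns$name)) abort("pattern names must be unique")

  pa <- .parse_set(sa, "active")
  pi_ <- .parse_set(si, "inactive")
  match_count <- function(sdfset, smarts) {
    res <- try(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      abort(sprintf("SMARTS pattern failed to compile: %s", smarts))
    }
    sum(res > 0)
  }
  out <- map(seq_len(nrow(patterns)), function(p) {
    ma <- match_count(pa$sdfset, patterns$smarts[p])
    mi <- match_count(pi_$sdfset, patterns$smarts[p])
    tibble(pattern = patterns$name[p], smarts = patterns$smarts[p],
           n_active = pa$n, n_inactive = pi_$n,
           matched_active = ma, matched_inactive = mi,
           freq_active = 100 * ma / pa$n,
           freq_inactive = 100 * mi / pi_$n)
  }) |> bind_rows()
  arrange(out, dplyr::desc((.data$freq_active + 1e-9) / (.data$freq_inactive + 1e-9)))
}

#' Two-sample Kolmogorov-Smirnov comparison of a property
#'
#' D = sup |ECDF_active - ECDF_inactive| with the two-sided asymptotic
#' p-value. Identical constant samples return D = 0, p = 1.
#'
#' @param values_active,values_inactive Numeric vectors (n >= 5 each).
#' @return One-row tibble: `statistic`, `p_value`, `n_active`, `n_inactive`.
#' @export
ks_property_comparison <- function(values_active, values_inactive) {
  if (length(values_active) < 5 || length(values_inactive) < 5) {
    abort("both samples need at least 5 values")
  }
  if (any(!is.finite(values_active)) || any(!is.finite(values_inactive))) {
    abort("samples must be finite")
  }
  if (length(unique(c(values_active, values_inactive))) == 1) {
    return(tibble(statistic = 0, p_value = 1,
                  n_active = length(values_active),
                  n_inactive = length(values_inactive)))
  }
  kt <- suppressWarnings(ks.test(values_active, values_inactive,
                                 alternative = "two.sided", exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_active = length(values_active), n_inactive = length(values_inactive))
}

#' KS screen over descriptor columns
#'
#' Applies [ks_property_comparison()] to every named property column of a
#' feature table, comparing active vs inactive molecules.
#'
#' @param features Feature table (e.g. from [featurize_batch()]) containing
#'   the property columns.
#' @param is_active Logical vector, one element per row of `features`.
#' @param properties Property column names (default: the 48 descriptors).
#' @return Tibble: `property`, `statistic`, `p_value`, plus Benjamini-
#'   Hochberg adjusted `p_adjusted`, ordered by `statistic`.
#' @export
ks_property_screen <- function(features, is_active,
                               properties = descriptor_manifest()$name) {
  stopifnot(is.data.frame(features), length(is_active) == nrow(features))
  properties <- intersect(properties, names(features))
  if (length(properties) == 0) abort("no property columns found")
  out <- map(properties, function(p) {
    r <- ks_property_comparison(features[[p]][is_active],
                                features[[p]][!is_active])
    tibble(property = p, statistic = r$statistic, p_value = r$p_value)
  }) |> bind_rows()
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  arrange(out, dplyr::desc(.data$statistic))
}

#' Enrichment bar chart
#'
#' @param enrichment Result of [fragment_frequencies()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  long <- enrichment |>
    select("pattern", "freq_active", "freq_inactive") |>
    tidyr::pivot_longer(c("freq_active", "freq_inactive"),
                        names_to = "set", values_to = "freq") |>
    mutate(set = sub("^freq_", "", .data$set))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$pattern, .data$freq),
                                     y = .data$freq, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "molecules containing fragment (%)",
                  title = "Substructure presence by activity class") +
    ggplot2::theme_minimal()
}
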