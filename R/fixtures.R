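#' Packaged reference summary statistics (PWS case-control design)
#'
#' Printed per-group summary statistics from a published Prader-Willi
#' syndrome brain-age study design, shipped so that summary-statistic
#' analyses (e.g. [t_test_from_summary()]) are runnable without any raw
#' data: per-group n / mean / SD (and printed range or IQR where that is
#' what was published) for age, sex counts, BMI, IQ, tissue volumes and
#' brain-PAD, for the main case-control cohort (cohort 1) and the
#' single-subject normative cohort (cohort 2).
#'
#' Known printing discrepancies in the source are retained, not resolved:
#' the cohort-2 control brain-PAD SD appears both as 6.48 (results) and
#' 6.52 (abstract) — both rows are present, distinguished by `source` —
#' and the cohort-1 age-comparison P was printed as 0.74 in the summary
#' table and .73 in the text (flagged in `note`).
#'
#' @param measure Optional filter on the `measure` column.
#' @param cohort Optional filter (1 or 2).
#' @return Tibble with columns `measure`, `cohort`, `group`, `n`, `mean`,
#'   `sd`, `lo`, `hi`, `units`, `source`, `note`.
#' @export
#' @examples
#' pws_reference_stats("brainpad", cohort = 1)
pws_reference_stats <- function(measure = NULL, cohort = NULL) {
  path <- system.file("extdata", "pws_reference_stats.csv", package = "brainpad")
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(measure)) out <- out[out$measure %in% measure, ]
  if (!is.null(cohort)) out <- out[out$cohort %in% cohort, ]
  out
}

#' One reference summary as an (n, mean, sd) triple
#'
#' Convenience accessor feeding [t_test_from_summary()].
#'
#' @param measure,group,cohort Row selectors.
#' @param source Disambiguates duplicated printings (default "results").
#' @return List with `n`, `mean`, `sd`, `label`.
#' @export
ref_summary <- function(measure, group, cohort = 1, source = NULL) {
  tab <- pws_reference_stats(measure, cohort)
  tab <- tab[tab$group == group, ]
  if (nrow(tab) > 1 && !is.null(source)) tab <- tab[tab$source == source, ]
  if (nrow(tab) > 1) tab <- tab[tab$source == "results", , drop = FALSE]
  if (nrow(tab) != 1) {
    stop("no unique reference row for ", measure, " / ", group, call. = FALSE)
  }
  list(n = tab$n, mean = tab$mean, sd = tab$sd,
       label = paste0(tab$group, " ", tab$measure))
}
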