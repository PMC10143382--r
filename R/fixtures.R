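#' Load a bundled retention-index evaluation table
#'
#' Two published evaluation sets for UDMH transformation products on a
#' wax-type (polar) GC column are shipped with the package:
#'
#' * `"table2"` — the re-evaluation set: 24 previously proposed structures
#'   with observed polar-phase retention indices and predicted (or, for
#'   two compounds, NIST reference) RIs. Compounds 3, 5 and 14 carry two
#'   alternative predictions (`ri_pred_2`); the RI criterion takes the
#'   better one. Three compounds (22-24) were not detected on the polar
#'   phase; compound 23 co-elutes with the solvent ("solvent cut").
#' * `"table3"` — the newly proposed set: 7 structures with observed and
#'   predicted RIs on both the polar and the non-polar phase, plus the
#'   in-silico EPA acute-toxicity category.
#'
#' @param source `"table2"` (alias `"refined_polar"`) or `"table3"`
#'   (alias `"new_dual"`).
#' @return a data.frame; `"table2"` has 24 rows with columns `compound`,
#'   `rt_min`, `mw`, `detected`, `ri_obs`, `ri_pred_1`, `ri_pred_2`,
#'   `ri_source`, `nist_spectrum`, `note`; `"table3"` has 7 rows with
#'   columns `compound`, `rt_min`, `ri_polar_obs`, `ri_polar_pred`,
#'   `ri_nonpolar_obs`, `ri_nonpolar_pred`, `epa_category`.
#' @examples
#' t3 <- loadFixture("table3")
#' t3[t3$compound == "II", ]
#' @export
loadFixture <- function(source = c("table2", "table3", "refined_polar",
                                   "new_dual")) {
  source <- match.arg(source)
  fname <- switch(source,
    table2 = , refined_polar = "tp_refined_ri_polar.csv",
    table3 = , new_dual = "tp_new_ri_dual.csv")
  path <- system.file("extdata", fname, package = "ntascreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound = "character"))
  if ("note" %in% names(df)) df$note[is.na(df$note)] <- ""
  df
}

#' Predicted-RI alternatives for one re-evaluation-set row
#'
#' Helper collecting the non-missing predicted/reference RIs of a
#' `"table2"` fixture row into a vector usable by [riCriterion()].
#'
#' @param row a single-row data.frame from `loadFixture("table2")`.
#' @return numeric vector of 0, 1 or 2 predicted RIs.
#' @export
fixturePredictedRis <- function(row) {
  stopifnot(nrow(row) == 1L)
  ris <- c(row$ri_pred_1, row$ri_pred_2)
  ris[!is.na(ris)]
}
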