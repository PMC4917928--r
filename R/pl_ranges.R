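# Published per-family similarity ranges for the CAZy polysaccharide
# lyase (PL) benchmark: for each of the 15 PL families that met the assay
# size requirement and each tested metric, the difference between the
# maximum and minimum mean similarity observed across the 0-100 %
# random-replacement levels. Shipped as reference numbers for comparing
# metric resolution; the GS2 column is an external metric reported only as
# printed values (its algorithm is not implemented here).

#' Published per-family degeneration ranges for the PL benchmark
#'
#' Reads the shipped reference table of per-family similarity ranges
#' (max - min of the mean score across replacement levels) for the 15
#' CAZy polysaccharide lyase families, for the metrics agreement, simUI,
#' simGIC, mUI, mGIC and GS2.
#'
#' @param long Return long format (`family`, `metric`, `range`) instead of
#'   the wide table?
#' @return A data frame.
#' @examples
#' head(pl_family_ranges())
#' @export
pl_family_ranges <- function(long = FALSE) {
  path <- system.file("extdata", "pl_family_ranges.tsv", package = "funcoh",
                      mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  metrics <- setdiff(names(wide), "family")
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(family = wide$family, metric = m, range = wide[[m]],
               stringsAsFactors = FALSE)
  }))
}

#' Express published ranges as a two-level profile
#'
#' Recasts per-family range values into the `degeneration_profile` shape
#' expected by [resolution()]: for each family and metric, one pseudo
#' level with mean equal to the published range and one at 0, so the
#' per-family max - min reproduces the published value exactly and
#' [resolution()] returns the across-family average range.
#'
#' @param ranges_long A long-format data frame with columns `family`,
#'   `metric`, `range` (see [pl_family_ranges()]).
#' @return A data frame with columns `family`, `metric`, `level`, `mean`.
#' @export
ranges_as_profile <- function(ranges_long) {
  stopifnot(all(c("family", "metric", "range") %in% names(ranges_long)))
  rbind(
    data.frame(family = ranges_long$family, metric = ranges_long$metric,
               level = 0, mean = ranges_long$range,
               stringsAsFactors = FALSE),
    data.frame(family = ranges_long$family, metric = ranges_long$metric,
               level = 1, mean = 0, stringsAsFactors = FALSE)
  )
}
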