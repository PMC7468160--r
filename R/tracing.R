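#' Per-region input fractions from retrograde tracing counts
#'
#' The input fraction of a region is its count of retrogradely labeled
#' presynaptic neurons as a percent of all labeled neurons counted in the
#' brain; the fractions sum to 100.
#'
#' @param counts named numeric vector of non-negative integer counts per
#'   region, or a data.frame with columns `region` and `count`.
#' @return data.frame: `region`, `count`, `input_fraction_pct`.
#' @examples
#' input_fraction(c(SPZ = 40, DMH = 25, PVH = 20, LS = 15))
#' @export
input_fraction <- function(counts) {
  if (is.data.frame(counts)) {
    df <- data.frame(region = as.character(counts$region),
                     count = as.numeric(counts$count))
  } else {
    if (is.null(names(counts))) stop("counts must be named by region")
    df <- data.frame(region = names(counts), count = as.numeric(counts))
  }
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  total <- sum(df$count)
  if (total == 0) stop("all-zero counts: input fractions undefined")
  df$input_fraction_pct <- 100 * df$count / total
  df
}

#' Remove starter-population regions before fraction computation
#'
#' Starter cells (co-expressing helper and rabies constructs) are not
#' afferent inputs; regions holding them can be excluded before computing
#' input fractions.
#'
#' @param counts as in [input_fraction()].
#' @param starter_regions character vector of region labels to drop.
#' @return counts object of the same form with the listed regions removed
#'   (removal is messaged).
#' @export
exclude_starter_regions <- function(counts, starter_regions) {
  if (length(starter_regions) == 0L) return(counts)
  if (is.data.frame(counts)) {
    drop <- counts$region %in% starter_regions
    if (any(drop)) message("excluding starter region(s): ",
                           paste(counts$region[drop], collapse = ", "))
    counts[!drop, , drop = FALSE]
  } else {
    drop <- names(counts) %in% starter_regions
    if (any(drop)) message("excluding starter region(s): ",
                           paste(names(counts)[drop], collapse = ", "))
    counts[!drop]
  }
}
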