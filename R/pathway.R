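# Pathway repetition-rate statistics: for each pathway, the fraction of
# modulators whose driver-gene profile has at least one member in the
# pathway's gene set, over a fixed denominator (the full modulator count,
# "numerator/254" style), plus the count of top-ranked driver genes present
# in each pathway.

# Display rounding is half-up (0.005 -> 0.01), matching printed two-decimal
# rates; the raw ratio is always reported alongside.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Modulator repetition rate of one pathway
#'
#' @param profiles named list: compound -> character vector of driver genes
#'   affected by the compound. May be empty.
#' @param pathway character vector: the pathway's gene set.
#' @param denominator fixed denominator (total modulator count); must be
#'   `>= 1`.
#' @return List: `numerator` (compounds whose profile intersects the
#'   pathway), `rate` (raw ratio) and `rate_2dp` (half-up rounded).
#' @export
repetition_rate <- function(profiles, pathway, denominator) {
  if (is.null(denominator) || denominator < 1) {
    stop_pertnet("repetition-rate denominator must be >= 1",
                 class = "pertnet_arithmetic_error")
  }
  pathway <- toupper(pathway)
  num <- sum(vapply(profiles, function(g) any(toupper(g) %in% pathway), TRUE))
  list(numerator = as.integer(num), rate = num / denominator,
       rate_2dp = round_half_up(num / denominator))
}

#' Count top-ranked driver genes inside a pathway
#'
#' @param top_drivers ordered, duplicate-free gene list (e.g. the top-10
#'   hubs of the translational network).
#' @param pathway character vector: the pathway's gene set.
#' @return Integer intersection size.
#' @export
top_driver_count <- function(top_drivers, pathway) {
  top_drivers <- toupper(top_drivers)
  if (!length(top_drivers)) {
    stop_pertnet("top_drivers must be non-empty",
                 class = "pertnet_validation_error")
  }
  if (anyDuplicated(top_drivers)) {
    stop_pertnet("top_drivers contains duplicates (%s)",
                 top_drivers[duplicated(top_drivers)][1L],
                 class = "pertnet_validation_error")
  }
  length(intersect(top_drivers, toupper(pathway)))
}

#' Per-pathway repetition-rate report
#'
#' One row per pathway, sorted by descending rate then identifier, with the
#' count of pathways touched by at least one modulator profile attached
#' ("10 out of 21"-style summary).
#'
#' @param profiles named list: compound -> driver gene vector.
#' @param collection a [pathway_collection()].
#' @param top_drivers ordered duplicate-free driver gene list.
#' @param denominator fixed modulator-count denominator.
#' @return Object of class `pathway_report`: data frame `pathway`,
#'   `description`, `numerator`, `denominator`, `rate`, `rate_2dp`,
#'   `top_driver_count`; attribute `n_active` = pathways with
#'   `numerator > 0`.
#' @export
pathway_report <- function(profiles, collection, top_drivers, denominator) {
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(id) {
    rr <- repetition_rate(profiles, collection[[id]], denominator)
    data.frame(pathway = id, description = unname(desc[id]),
               numerator = rr$numerator, denominator = denominator,
               rate = rr$rate, rate_2dp = rr$rate_2dp,
               top_driver_count = top_driver_count(top_drivers,
                                                   collection[[id]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), description = character(),
                      numerator = integer(), denominator = integer(),
                      rate = numeric(), rate_2dp = numeric(),
                      top_driver_count = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$rate, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pathway_report", "data.frame"),
            n_active = sum(out$numerator > 0))
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("pathway_report: %d pathways, %d touched by >=1 modulator\n",
              nrow(x), attr(x, "n_active")))
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}
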