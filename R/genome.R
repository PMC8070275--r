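#' Detector genome: the evolvable KNN parameters
#'
#' The unit of evolution is the full parameterisation of the nearest-
#' neighbour detector: the neighbourhood size `k`, a binary feature mask
#' (feature selection), per-feature non-negative weights, and the Minkowski
#' distance exponent (1 = Manhattan, 2 = Euclidean).
#'
#' @param k Positive integer neighbourhood size.
#' @param feature_mask Logical vector; at least one TRUE.
#' @param feature_weights Non-negative finite weights, same length as the
#'   mask. Default all 1.
#' @param distance_exponent 1 or 2. Default 2.
#' @return An object of class `detector_genome`.
#' @examples
#' g <- detector_genome(k = 3, feature_mask = c(TRUE, TRUE, FALSE))
#' @export
detector_genome <- function(k, feature_mask,
                            feature_weights = rep(1, length(feature_mask)),
                            distance_exponent = 2) {
  g <- structure(list(k = as.integer(k),
                      feature_mask = as.logical(feature_mask),
                      feature_weights = as.numeric(feature_weights),
                      distance_exponent = as.numeric(distance_exponent)),
                 class = "detector_genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  assert_that(is_count(g$k), "k must be a positive integer")
  assert_that(length(g$feature_mask) >= 1 && any(g$feature_mask),
              "feature_mask must have at least one bit set")
  assert_that(length(g$feature_weights) == length(g$feature_mask),
              "feature_weights and feature_mask lengths differ")
  assert_that(all(is.finite(g$feature_weights)) && all(g$feature_weights >= 0),
              "feature_weights must be finite and non-negative")
  assert_that(g$distance_exponent %in% c(1, 2),
              "distance_exponent must be 1 or 2")
  g
}

# Canonical serialization used as a fitness-cache key.
genome_key <- function(g) {
  paste(g$k, g$distance_exponent,
        paste(as.integer(g$feature_mask), collapse = ""),
        paste(sprintf("%.8g", g$feature_weights), collapse = ","),
        sep = "|")
}

#' @export
print.detector_genome <- function(x, ...) {
  cat(sprintf("<detector_genome> k=%d, %d/%d features, L%g distance\n",
              x$k, sum(x$feature_mask), length(x$feature_mask),
              x$distance_exponent))
  invisible(x)
}

#' Serialize / deserialize a detector genome as JSON
#' @param genome A [detector_genome()].
#' @param path JSON file path.
#' @return `write_genome` returns `path` invisibly; `read_genome` returns
#'   the genome.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  jsonlite::write_json(list(k = genome$k,
                            feature_mask = genome$feature_mask,
                            feature_weights = genome$feature_weights,
                            distance_exponent = genome$distance_exponent),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  detector_genome(j$k, j$feature_mask, j$feature_weights, j$distance_exponent)
}
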