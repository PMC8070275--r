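#' Construct a classification task
#'
#' A task maps every study state `(condition, volume_ml)` to a class label
#' or to `NA` (excluded from both training and testing). The preliminary
#' acoustic analysis found 200 ml injections nearly indistinguishable from
#' baseline, so most tasks exclude them.
#'
#' @param name Task identifier.
#' @param class_of Vectorised function `(condition, volume_ml) -> label` with
#'   `NA_character_` meaning excluded.
#' @param positive_classes Labels counted as "injury present" when collapsing
#'   a prediction to the binary sensitivity/specificity contrast.
#' @param volume_of Named numeric vector mapping class labels to an injected
#'   volume (ml), for predicted-vs-real volume correlation; only classes
#'   listed here take part. NULL when no class has a unique volume.
#' @return An object of class `classification_task`.
#' @seealso [build_task()] for the six study tasks.
#' @export
classification_task <- function(name, class_of, positive_classes,
                                volume_of = NULL) {
  assert_that(is.function(class_of), "class_of must be a function")
  structure(list(name = name, class_of = class_of,
                 positive_classes = positive_classes, volume_of = volume_of),
            class = "classification_task")
}

#' The six differentiation tasks of the study
#'
#' @param name One of:
#' \describe{
#'   \item{`"injury_vs_normal"`}{baseline vs any PTX/HTX as one combined
#'     injury class; 200 ml excluded.}
#'   \item{`"normal_ptx_htx"`}{three-way baseline / PTX / HTX; 200 ml
#'     excluded.}
#'   \item{`"ptx_vs_normal"`}{baseline vs PTX (200 ml excluded); HTX
#'     excluded entirely.}
#'   \item{`"ptx_volume_ladder"`}{baseline plus one class per PTX volume
#'     400/600/800/1000 ml; HTX and PTX 200 ml excluded. Class volumes feed
#'     the volume correlation.}
#'   \item{`"htx_vs_normal"`}{baseline vs HTX with *all* volumes included
#'     (200 ml retained for this contrast); PTX excluded.}
#'   \item{`"htx_vs_ptx"`}{HTX vs PTX, both without 200 ml; baseline
#'     excluded.}
#' }
#' @return A [classification_task()].
#' @examples
#' task <- build_task("injury_vs_normal")
#' task$class_of(c("BASELINE", "PTX", "HTX"), c(0, 200, 600))
#' @export
build_task <- function(name) {
  name <- match.arg(name, c("injury_vs_normal", "normal_ptx_htx",
                            "ptx_vs_normal", "ptx_volume_ladder",
                            "htx_vs_normal", "htx_vs_ptx"))
  excl200 <- function(condition, volume_ml, label)
    ifelse(condition != "BASELINE" & volume_ml == 200, NA_character_, label)
  switch(name,
    injury_vs_normal = classification_task(name,
      function(condition, volume_ml)
        excl200(condition, volume_ml,
                ifelse(condition == "BASELINE", "normal", "injury")),
      positive_classes = "injury"),
    normal_ptx_htx = classification_task(name,
      function(condition, volume_ml)
        excl200(condition, volume_ml,
                c(BASELINE = "normal", PTX = "PTX", HTX = "HTX")[condition]),
      positive_classes = c("PTX", "HTX")),
    ptx_vs_normal = classification_task(name,
      function(condition, volume_ml)
        ifelse(condition == "HTX", NA_character_,
               excl200(condition, volume_ml,
                       ifelse(condition == "BASELINE", "normal", "PTX"))),
      positive_classes = "PTX"),
    ptx_volume_ladder = classification_task(name,
      function(condition, volume_ml)
        ifelse(condition == "BASELINE", "normal",
               ifelse(condition == "PTX" & volume_ml >= 400,
                      sprintf("PTX_%d", volume_ml), NA_character_)),
      positive_classes = sprintf("PTX_%d", c(400, 600, 800, 1000)),
      volume_of = c(normal = 0, PTX_400 = 400, PTX_600 = 600,
                    PTX_800 = 800, PTX_1000 = 1000)),
    htx_vs_normal = classification_task(name,
      function(condition, volume_ml)
        ifelse(condition == "PTX", NA_character_,
               ifelse(condition == "BASELINE", "normal", "HTX")),
      positive_classes = "HTX"),
    htx_vs_ptx = classification_task(name,
      function(condition, volume_ml)
        ifelse(condition == "BASELINE", NA_character_,
               excl200(condition, volume_ml,
                       ifelse(condition == "HTX", "HTX", "PTX"))),
      positive_classes = "HTX"))
}

#' Apply a task's state-to-class mapping to a label table
#'
#' @param task A [classification_task()].
#' @param labels Data frame with `condition` and `volume_ml` columns.
#' @return Character vector of class labels, `NA` for excluded states.
#' @export
apply_task <- function(task, labels) {
  assert_that(inherits(task, "classification_task"), "not a classification_task")
  as.character(task$class_of(labels$condition, labels$volume_ml))
}

#' @export
print.classification_task <- function(x, ...) {
  cat(sprintf("<classification_task> %s (positive: %s)\n", x$name,
              paste(x$positive_classes, collapse = ", ")))
  invisible(x)
}
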