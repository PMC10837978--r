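#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  "tag_id", "receiver_id", "time", "new_event", "event_id", "n_detections",
  "duration_s", "value", ".", ".N", "start", "end"
))

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#' @keywords internal
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  expr
}
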