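#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct count n bind_rows
#'   rename relocate if_else case_when across pull first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dhyper phyper p.adjust qnorm plogis qlogis runif rbinom
#'   rnorm setNames
#' @importFrom utils head
NULL

# Ordered severity of lethality stages; earliest developmental stage first.
STAGE_LEVELS <- c("embryonic", "prenatal", "perinatal",
                  "preweaning_postnatal", "premature_death", "none")

INHERITANCE_CLASSES <- c("AR", "AD", "AR/AD", "XL", "MT", "unknown")

CONSTRAINT_CATEGORIES <- c("whole_gene", "regional_only", "none", "no_data")

`%notin%` <- function(x, table) !(x %in% table)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "devlethal_format_error")
  }
  invisible(df)
}

# Derive a per-stream seed from a root seed so that adding a stream does not
# reshuffle the others. Kept below 2^31 - 1.
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
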