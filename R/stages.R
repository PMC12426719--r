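#' Sleep stage alphabets
#'
#' The two stage sets used throughout the package: the 5-stage AASM
#' alphabet (W, N1, N2, N3, R) and the 4-stage alphabet obtained by
#' merging N1 and N2 into a single light-sleep class (W, N1+N2, N3, R).
#' A stage label is only meaningful relative to a declared stage set;
#' every container in this package carries its stage set and refuses to
#' mix alphabets.
#'
#' @param name `"aasm5"` or `"aasm4"`.
#' @return A character vector of stage labels with class `stage_set`.
#' @examples
#' stage_set("aasm4")
#' @export
stage_set <- function(name = c("aasm4", "aasm5")) {
  name <- match.arg(name)
  labels <- switch(name,
    aasm5 = c("W", "N1", "N2", "N3", "R"),
    aasm4 = c("W", "N1+N2", "N3", "R")
  )
  structure(labels, name = name, class = "stage_set")
}

#' @export
print.stage_set <- function(x, ...) {
  cat(sprintf("<stage_set '%s'> %s\n", attr(x, "name"),
              paste(unclass(x), collapse = " ")))
  invisible(x)
}

is_stage_set <- function(x) inherits(x, "stage_set")

stage_set_name <- function(x) attr(x, "name")

same_stage_set <- function(a, b) {
  identical(unclass(a), unclass(b))
}

# Built-in label aliases accepted on input; extensible via the `aliases`
# argument of the readers.
.stage_aliases <- c(
  "WAKE" = "W", "Wake" = "W", "wake" = "W", "w" = "W",
  "REM" = "R", "rem" = "R", "r" = "R",
  "n1" = "N1", "n2" = "N2", "n3" = "N3",
  "N12" = "N1+N2", "n12" = "N1+N2", "N1N2" = "N1+N2", "N1/N2" = "N1+N2"
)

resolve_stage_labels <- function(labels, stage_set, aliases = NULL) {
  map <- .stage_aliases
  if (!is.null(aliases)) map[names(aliases)] <- aliases
  out <- as.character(labels)
  hit <- out %in% names(map)
  out[hit] <- map[out[hit]]
  out
}
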