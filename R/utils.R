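#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a child seed below 2^31 from a parent seed and a stream label
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("cxr_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
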