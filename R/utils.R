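# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Classed error so callers can distinguish failure modes.
stop_measort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "measort_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Causal circular convolution: y[k] = sum_m f[m] * x[(k - m) mod n], m = 0..L-1.
circ_conv <- function(x, f) {
  if (length(f) > length(x)) {
    stop_measort("filter longer than signal", "measort_decomposition_error")
  }
  as.numeric(stats::filter(x, f, method = "convolution", sides = 1,
                           circular = TRUE))
}

## Circulant matrix C such that C %*% x == circ_conv(x, f) for length-L x.
## Used to convolve many short waveforms at once (columns of a matrix).
circulant_matrix <- function(f, L) {
  C <- matrix(0, L, L)
  for (m in seq_along(f)) {
    for (k in seq_len(L)) {
      j <- ((k - 1) - (m - 1)) %% L + 1
      C[k, j] <- C[k, j] + f[m]
    }
  }
  C
}

## Format numbers so that read.csv round-trips them bitwise.
fmt_num <- function(x, digits = 17) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

## Minimal CSV writer with deterministic formatting (no scientific notation
## surprises, no row names).  Columns of type double go through fmt_num.
write_csv_det <- function(df, path, digits = 10) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col, digits) else as.character(col)
  })
  lines <- c(
    paste(names(df), collapse = ","),
    if (nrow(df) > 0) do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) && x >= 0
}
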