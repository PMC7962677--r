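#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "microsacc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Deterministic child-stream seeds: Lehmer-style mixing of the root seed with
# a sequence of integer indices, kept strictly below 2^31 - 1 so the result is
# always a valid R seed. The scheme is part of the package contract: the
# stream for indices (i1, i2, ...) is
#   h <- root mod M;  h <- (h * 48271 + ik) mod M   for each index in order,
# with M = 2147483647.
child_seed <- function(root, ...) {
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k)) %% m
  }
  as.integer(h)
}

# Evaluate expr under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("field '%s' must be a single finite number", field,
          class = "microsacc_validation_error")
  }
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    stopf("field '%s' = %g is out of range %s%g, %g]", field, x,
          if (allow_equal_lower) "[" else "(", lower, upper,
          class = "microsacc_validation_error")
  }
  if (integer && x != round(x)) {
    stopf("field '%s' must be an integer", field,
          class = "microsacc_validation_error")
  }
  invisible(x)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  out[!is.finite(as.numeric(x))] <- as.character(x[!is.finite(as.numeric(x))])
  out
}

write_tsv_exact <- function(df, path, num_cols = NULL) {
  out <- df
  if (is.null(num_cols)) num_cols <- names(df)[vapply(df, is.double, TRUE)]
  for (cc in intersect(num_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
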