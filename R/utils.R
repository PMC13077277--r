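# Internal helpers: seed derivation, validation, deterministic CSV writing.

#' Derive a child seed from a base seed and stream offsets
#'
#' All stochastic operations in the package take an explicit integer seed and
#' derive per-stream seeds with this function, so there is no global random
#' state and any sub-computation is reproducible in isolation. Seeds stay
#' below 2^31 - 1.
#'
#' @param base integer base seed.
#' @param ... one or more non-negative integer stream offsets.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(base, ...) {
  offs <- c(...)
  s <- as.double(base) %% 2147483647
  for (o in offs) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

abort_gait <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gaitpipe_error"))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_gait(sprintf("`%s` must be a finite numeric scalar", name), "gait_validation_error")
  }
  if (positive && x <= 0) {
    abort_gait(sprintf("`%s` must be > 0", name), "gait_validation_error")
  }
  if (nonneg && x < 0) {
    abort_gait(sprintf("`%s` must be >= 0", name), "gait_validation_error")
  }
  invisible(x)
}

# Fixed-format numeric for bit-stable CSV output (15 significant digits,
# plain notation). Used by every writer whose output must be byte-identical
# across reruns.
fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g", flag = "")
  out[is.na(x)] <- "NA"
  trimws(out)
}

write_csv_stable <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
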