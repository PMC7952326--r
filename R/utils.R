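## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_eam <- function(msg, class, ...) {
  stop(rlang::error_cnd(class = c(class, "eam_error"), message = msg, ...))
}

## row-wise euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

## cross products of corresponding rows of two n x 3 matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  if (length(x) == 0L) x <- matrix(numeric(0), 0L, 3L)
  if (ncol(x) != 3L) stop_eam(sprintf("%s must have 3 columns", what), "eam_argument_error")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

## Pairwise Euclidean distances between rows of a (n x 3) and b (m x 3).
pairwise_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## mean nearest-neighbour spacing among rows of x (n >= 2)
mean_nn_spacing <- function(x) {
  d <- pairwise_dist(x, x)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

## Percentile with linear interpolation between closest order statistics
## (documented convention; identical to stats::quantile type 7).
eam_percentile <- function(x, q) {
  unname(stats::quantile(x, probs = q / 100, type = 7, names = FALSE))
}

## %.17g formatting: round-trips 64-bit doubles through text exactly.
fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NaN"   # NA treated as missing sentinel too
  out
}

## Write a data frame as CSV with bit-exact numeric text. Doubles use %.17g,
## integers plain, everything else as character. "NaN" encodes missing.
write_csv17 <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt17(col)
    else if (is.integer(col)) {
      out <- as.character(col); out[is.na(col)] <- "NaN"; out
    } else as.character(col)
  })
  header <- paste(names(df), collapse = ",")
  if (nrow(df) == 0L) {
    body <- character(0)
  } else {
    body <- do.call(paste, c(cols, sep = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

## timestamped stderr logging used by the CLI and batch import
eam_log <- function(..., verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible(NULL)
}
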