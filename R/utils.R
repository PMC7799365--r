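# internal helpers shared across modules

# seed the RNG for the remainder of the caller's frame, restoring the
# caller's RNG state when that frame exits
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- bquote({
    .old <- .(old)
    if (!is.null(.old)) assign(".Random.seed", .old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(seed)
}

# column-standardize with the sample-SD (n-1) convention; columns that are
# constant become all-zero (carry no information) unless strict = TRUE
scale_columns <- function(A, strict = FALSE) {
  A <- as.matrix(A)
  mu <- colMeans(A)
  A <- sweep(A, 2, mu)
  s <- sqrt(colSums(A^2) / max(1, nrow(A) - 1))
  bad <- !is.finite(s) | s < 1e-12
  if (any(bad) && strict)
    stop("zero-variance column(s): ",
         paste(colnames(A)[bad], collapse = ", "))
  s[bad] <- Inf
  sweep(A, 2, s, "/")
}

# TSV dialect used everywhere: tab-separated, header row, UTF-8, "." missing
write_tsv_table <- function(d, path) {
  d2 <- d
  for (j in seq_along(d2)) {
    v <- d2[[j]]
    if (is.numeric(v)) v <- as.character(v)
    v[is.na(v)] <- "."
    d2[[j]] <- v
  }
  utils::write.table(d2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

# md5 of a file; used for manifest provenance
file_md5 <- function(path) unname(tools::md5sum(path))
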