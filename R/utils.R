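# full-precision text serialisation of numeric matrices/vectors;
# %.17g guarantees bit-exact double round trips
write_matrix_txt <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(x), ncol(x)), con)
  writeLines(apply(x, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

read_matrix_txt <- function(path) {
  if (!file.exists(path)) stop("missing weight file: ", path)
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- as.numeric(unlist(strsplit(lines[-1], " "), use.names = FALSE))
  matrix(vals, dims[1], dims[2], byrow = TRUE)
}

file_md5 <- function(paths) unname(tools::md5sum(paths))

# content fingerprint of an R object (stable within an R version)
object_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, command, inputs, outputs, config, seed) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("depolyscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    inputs = if (length(inputs))
      stats::setNames(as.list(file_md5(inputs)), inputs) else list(),
    outputs = if (length(outputs))
      stats::setNames(as.list(file_md5(outputs)), outputs) else list())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
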