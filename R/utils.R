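# Atomic file writers: write to a temp file in the destination directory,
# then rename. Readers never see a partially written file.

atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file into place at ", path)
  invisible(path)
}

atomic_write_csv <- function(df, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, fileEnc = "UTF-8"))
}

atomic_write_json <- function(x, path) {
  atomic_write(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null"))
}
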