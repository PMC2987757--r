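# Full-precision numeric formatting for CSV output: doubles survive a
# write/read round trip exactly.
format_full <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a serialized R object (used for run manifests).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
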